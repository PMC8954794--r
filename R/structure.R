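#' Construct a multi-model structure ensemble
#'
#' All models must share one atom set in one order; coordinates are stored
#' as an `n_atoms x 3 x n_models` array.
#'
#' @param atoms Data frame with columns `resno`, `resid` (3-letter residue
#'   name), `elety` (atom name), `element`, `chain`.
#' @param xyz Numeric array `n_atoms x 3 x n_models` (a matrix is treated as
#'   one model), in Angstroms.
#' @param source Free-text provenance label.
#' @return A list of class `"ensemble"`.
#' @export
structure_ensemble <- function(atoms, xyz, source = "") {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  assert_that(length(dim(xyz)) == 3 && dim(xyz)[2] == 3,
              "xyz must be n_atoms x 3 x n_models")
  assert_that(nrow(atoms) == dim(xyz)[1],
              "atom table and coordinate array disagree on atom count")
  assert_that(all(is.finite(xyz)), "coordinates must be finite")
  need <- c("resno", "resid", "elety", "element", "chain")
  assert_that(all(need %in% names(atoms)),
              "atoms needs columns %s", paste(need, collapse = ", "))
  structure(list(atoms = atoms, xyz = xyz, source = source),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble '%s': %d model(s), %d atoms, residues %d-%d\n",
              x$source, n_models(x), nrow(x$atoms),
              min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' @rdname structure_ensemble
#' @param ensemble An ensemble.
#' @export
n_models <- function(ensemble) dim(ensemble$xyz)[3]

# crude element inference from a PDB atom name when the element column is
# blank: strip leading digits, take the first letter; names starting H/D/Q
# after digits are hydrogens or pseudo-atoms.
infer_element <- function(elety) {
  s <- sub("^[0-9]+", "", trimws(elety))
  toupper(substr(s, 1, 1))
}

#' Read a (multi-model) PDB file as an ensemble
#'
#' Parses MODEL/ENDMDL blocks via bio3d, collapses alternate locations to
#' the highest-occupancy conformer, and verifies that every model carries
#' the same atom set in the same order (hard error naming the first
#' mismatch otherwise). Hydrogens are retained but excluded from the
#' `"heavy"` atom class.
#'
#' @param path PDB file path.
#' @return An [structure_ensemble()] object.
#' @export
read_ensemble <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  # pre-check per-model ATOM counts so a mismatch fails with a clear message
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    assert_that(length(ends) == length(starts), "unbalanced MODEL/ENDMDL")
    sigs <- mapply(function(s, e) {
      at <- lines[(s + 1):(e - 1)]
      at <- at[grepl("^(ATOM|HETATM)", at)]
      paste(substr(at, 13, 27), collapse = "|")
    }, starts, ends)
    bad <- which(sigs != sigs[1])
    if (length(bad)) {
      stop_input("model %d atom set differs from model 1", bad[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nm <- nrow(pdb$xyz)
  na <- nrow(at)
  xyz <- aperm(array(t(pdb$xyz), dim = c(3, na, nm)), c(2, 1, 3))

  # collapse altlocs: keep the highest-occupancy copy of each atom
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(na), key), function(idx) {
      if (length(idx) == 1) return(idx)
      occ <- at$o[idx]; occ[is.na(occ)] <- 1
      idx[which.max(occ)]
    }))
    keep <- sort(keep)
    at <- at[keep, , drop = FALSE]
    xyz <- xyz[keep, , , drop = FALSE]
  }

  element <- at$elesy
  blank <- is.na(element) | trimws(element) == ""
  element[blank] <- infer_element(at$elety[blank])
  atoms <- data.frame(resno = at$resno, resid = at$resid, elety = at$elety,
                      element = trimws(element),
                      chain = ifelse(is.na(at$chain), "A", at$chain))
  structure_ensemble(atoms, xyz, source = basename(path))
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble An ensemble.
#' @param path Output path.
#' @param models Model indices to write (default all).
#' @param b_factors Optional per-atom B-factor vector.
#' @export
write_ensemble <- function(ensemble, path, models = NULL, b_factors = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  models <- models %||% seq_len(n_models(ensemble))
  a <- ensemble$atoms
  xyz_flat <- t(apply(ensemble$xyz[, , models, drop = FALSE], 3,
                      function(m) as.numeric(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz_flat,
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = a$chain, elesy = a$element,
                   b = b_factors %||% rep(0, nrow(a)))
  invisible(path)
}

#' Residue/atom selection
#'
#' @param ranges List of inclusive `c(first, last)` residue ranges, a single
#'   such vector, or a string like `"3-97,104-113"`.
#' @param atoms Atom class: `"backbone"` (N, CA, C), `"heavy"` (all
#'   non-hydrogen), `"calpha"`, or `"all"`.
#' @return A list of class `"residue_selection"`.
#' @export
residue_selection <- function(ranges = NULL,
                              atoms = c("backbone", "heavy", "calpha", "all")) {
  atoms <- match.arg(atoms)
  if (is.character(ranges)) {
    parts <- strsplit(ranges, ",")[[1]]
    ranges <- lapply(parts, function(p) {
      v <- as.numeric(strsplit(p, "-")[[1]])
      if (length(v) == 1) c(v, v) else v
    })
  }
  if (is.numeric(ranges)) ranges <- list(ranges)
  if (!is.null(ranges)) {
    for (r in ranges) {
      assert_that(length(r) == 2 && r[1] <= r[2], "bad residue range")
    }
    o <- order(vapply(ranges, `[`, numeric(1), 1))
    ranges <- ranges[o]
    if (length(ranges) > 1) {
      lo <- vapply(ranges, `[`, numeric(1), 1)
      hi <- vapply(ranges, `[`, numeric(1), 2)
      assert_that(all(lo[-1] > hi[-length(hi)]), "ranges overlap")
    }
  }
  structure(list(ranges = ranges, atoms = atoms),
            class = "residue_selection")
}

# indices of ensemble atoms matching a selection
select_atoms <- function(ensemble, selection) {
  a <- ensemble$atoms
  in_range <- if (is.null(selection$ranges)) rep(TRUE, nrow(a)) else {
    Reduce(`|`, lapply(selection$ranges,
                       function(r) a$resno >= r[1] & a$resno <= r[2]))
  }
  cls <- switch(selection$atoms,
    backbone = trimws(a$elety) %in% c("N", "CA", "C"),
    calpha = trimws(a$elety) == "CA",
    heavy = !(a$element %in% c("H", "D")),
    all = rep(TRUE, nrow(a)))
  which(in_range & cls)
}

# Kabsch: optimal proper rotation mapping centered P onto centered Q
# (rows are atoms). Returns list(R, rmsd_fn not applied).
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$u, sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Least-squares (Kabsch) superposition
#'
#' Superposes a mobile model onto a reference over a selection, returning
#' the proper rotation (reflection-corrected via the SVD determinant), the
#' translation, and the post-fit RMSD over the selected atoms. Models may
#' be given as `n x 3` coordinate matrices or as ensembles (with
#' `mobile_model` / `ref_model` picking the member).
#'
#' @param mobile,reference Coordinate matrices or ensembles.
#' @param selection A [residue_selection()] applied to both (ensembles
#'   only); atoms are paired by `(resno, elety)`.
#' @param mobile_model,ref_model Model indices for ensemble inputs.
#' @return A list of class `"superposition"`: `rotation` (3x3, det +1),
#'   `translation`, `rmsd`, `n_atoms`. The fitted mobile coordinates are
#'   `mobile %*% rotation + translation` (rows as atoms).
#' @export
superpose <- function(mobile, reference, selection = NULL,
                      mobile_model = 1L, ref_model = 1L) {
  pq <- paired_coords(mobile, reference, selection, mobile_model, ref_model)
  P <- pq$P; Q <- pq$Q
  assert_that(nrow(P) >= 3, "need at least 3 atom pairs to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2) stop_input("selected atoms are collinear")
  R <- kabsch_rotation(Pc, Qc)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - cp %*% R),
                 rmsd = rmsd, n_atoms = nrow(P)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d atoms: rmsd = %.3f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

# Extract paired coordinate matrices from two models/ensembles.
paired_coords <- function(mobile, reference, selection, mobile_model,
                          ref_model) {
  if (is.matrix(mobile) && is.matrix(reference)) {
    assert_that(nrow(mobile) == nrow(reference),
                "coordinate matrices differ in atom count")
    return(list(P = mobile, Q = reference))
  }
  stopifnot(inherits(mobile, "ensemble"), inherits(reference, "ensemble"))
  selection <- selection %||% residue_selection(NULL, "backbone")
  im <- select_atoms(mobile, selection)
  ir <- select_atoms(reference, selection)
  if (!length(im) || !length(ir)) stop_input("selection matches no atoms")
  km <- paste(mobile$atoms$resno[im], trimws(mobile$atoms$elety[im]))
  kr <- paste(reference$atoms$resno[ir], trimws(reference$atoms$elety[ir]))
  shared <- intersect(km, kr)
  if (!length(shared)) stop_input("no shared atoms under the selection")
  im <- im[match(shared, km)]
  ir <- ir[match(shared, kr)]
  list(P = mobile$xyz[im, , mobile_model], Q = reference$xyz[ir, , ref_model])
}

#' Pairwise ensemble RMSD
#'
#' For every unordered pair of models, superposes on the selection and
#' records the post-fit RMSD; reports the mean and SD over all C(n,2)
#' pairs — the convention behind "pairwise RMSD" lines of NMR-structure
#' statistics tables.
#'
#' @param ensemble An ensemble with at least 2 models.
#' @param selection A [residue_selection()].
#' @return A list of class `"pairwise_rmsd"`: `mean`, `sd`, `values`,
#'   `n_models`, `n_atoms`.
#' @export
ensemble_pairwise_rmsd <- function(ensemble,
                                   selection = residue_selection(NULL, "backbone")) {
  stopifnot(inherits(ensemble, "ensemble"))
  nm <- n_models(ensemble)
  assert_that(nm >= 2, "need at least 2 models")
  idx <- select_atoms(ensemble, selection)
  if (!length(idx)) stop_input("selection matches no atoms")
  pairs <- utils::combn(nm, 2)
  vals <- apply(pairs, 2, function(p) {
    superpose(ensemble$xyz[idx, , p[1]], ensemble$xyz[idx, , p[2]])$rmsd
  })
  structure(list(mean = mean(vals), sd = stats::sd(vals), values = vals,
                 n_models = nm, n_atoms = length(idx),
                 atoms = selection$atoms),
            class = "pairwise_rmsd")
}

#' @export
print.pairwise_rmsd <- function(x, ...) {
  cat(sprintf("pairwise RMSD (%s, %d atoms, %d models): %.3f +/- %.3f A\n",
              x$atoms, x$n_atoms, x$n_models, x$mean, x$sd))
  invisible(x)
}

#' Per-residue displacement between two superposed structures
#'
#' Superposes each model of ensemble B onto each model of ensemble A over a
#' common-frame selection, then measures the distance between the two
#' copies of a probe atom (e.g. the Calpha of a loop residue) — the metric
#' used to quantify loop rearrangements between apo and DNA-bound forms.
#' Cross-entry comparisons require consistent residue numbering; atoms are
#' paired strictly by `(resno, elety)`.
#'
#' @param ens_a,ens_b Ensembles.
#' @param selection Superposition frame (a [residue_selection()]).
#' @param probe_residue Residue number of the probe.
#' @param probe_atom Atom name of the probe (default `"CA"`).
#' @return A list of class `"residue_displacement"`: `designated` (model 1
#'   vs model 1), `mean`, `sd`, and the full `matrix` of model-pair
#'   distances (rows: models of A).
#' @export
residue_displacement <- function(ens_a, ens_b,
                                 selection = residue_selection(NULL, "backbone"),
                                 probe_residue, probe_atom = "CA") {
  stopifnot(inherits(ens_a, "ensemble"), inherits(ens_b, "ensemble"))
  pa <- which(ens_a$atoms$resno == probe_residue &
                trimws(ens_a$atoms$elety) == probe_atom)
  pb <- which(ens_b$atoms$resno == probe_residue &
                trimws(ens_b$atoms$elety) == probe_atom)
  assert_that(length(pa) == 1 && length(pb) == 1,
              "probe atom %s of residue %d must be present exactly once in both",
              probe_atom, probe_residue)
  na <- n_models(ens_a); nb <- n_models(ens_b)
  D <- matrix(NA_real_, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      sp <- superpose(ens_b, ens_a, selection, mobile_model = j,
                      ref_model = i)
      moved <- as.numeric(ens_b$xyz[pb, , j] %*% sp$rotation) + sp$translation
      D[i, j] <- sqrt(sum((moved - ens_a$xyz[pa, , i])^2))
    }
  }
  structure(list(designated = D[1, 1], mean = mean(D), sd = stats::sd(as.numeric(D)),
                 matrix = D, probe_residue = probe_residue,
                 probe_atom = probe_atom),
            class = "residue_displacement")
}

#' @export
print.residue_displacement <- function(x, ...) {
  cat(sprintf("displacement of %s %d: %.2f A (model 1 vs model 1); %.2f +/- %.2f A over %d pairs\n",
              x$probe_atom, x$probe_residue, x$designated, x$mean, x$sd,
              length(x$matrix)))
  invisible(x)
}
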