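test_that("multi-model PDB files round-trip through the ensemble container", {
  ens <- sim_ensemble(reference_model(30), n_models = 5, dispersion = 0.8,
                      cfg = sim_config(seed = 12))
  path <- file.path(tempdir(), "ens_roundtrip.pdb")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(n_models(back), 5)
  expect_equal(nrow(back$atoms), nrow(ens$atoms))
  # PDB coordinates are written at 3 decimals
  expect_lt(max(abs(back$xyz - ens$xyz)), 5e-4 + 1e-12)

  # single-model file reads as an ensemble of size 1
  write_ensemble(ens, path, models = 1L)
  expect_equal(n_models(read_ensemble(path)), 1)
})

test_that("models with mismatched atom sets are rejected with the offending model named", {
  mk_line <- function(no, name, res, x) {
    sprintf("ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            no, name, res, x, 0, 0, substr(name, 1, 1))
  }
  lines <- c("MODEL        1",
             mk_line(1, "N", 1, 0), mk_line(2, "CA", 1, 1.4),
             "ENDMDL",
             "MODEL        2",
             mk_line(1, "N", 1, 0),
             "ENDMDL", "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  expect_error(read_ensemble(tf), "model 2")
})

test_that("Kabsch superposition recovers rigid transforms and matches the quaternion oracle", {
  set.seed(42)
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  R_true <- random_rotation()
  shift <- c(3, -7, 2)
  Q <- sweep(P %*% R_true, 2, -shift)
  sp <- superpose(P, Q)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$rotation, R_true, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(sweep(P %*% sp$rotation, 2, -sp$translation), Q,
               tolerance = 1e-9)

  # identity on identical models
  spi <- superpose(P, P)
  expect_equal(spi$rotation, diag(3), tolerance = 1e-9)
  expect_equal(spi$rmsd, 0, tolerance = 1e-12)

  # random noisy instances: SVD route equals the quaternion eigen route
  for (k in 1:50) {
    A <- matrix(rnorm(30, sd = 3), 10, 3)
    B <- A %*% random_rotation() + matrix(rnorm(30, sd = 0.3), 10, 3)
    expect_equal(superpose(A, B)$rotation, quaternion_rotation(A, B),
                 tolerance = 1e-6)
  }

  expect_error(superpose(P[1:2, ], Q[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("pairwise ensemble RMSD is rigid-invariant and zero for rigid copies", {
  rc <- sim_rigid_copies(reference_model(25), n_copies = 4,
                         cfg = sim_config(seed = 8))
  r <- ensemble_pairwise_rmsd(rc, residue_selection(NULL, "backbone"))
  expect_equal(r$mean, 0, tolerance = 1e-9)
  expect_equal(length(r$values), choose(5, 2))

  ens <- sim_ensemble(reference_model(25), n_models = 6, dispersion = 1.0,
                      cfg = sim_config(seed = 13))
  base <- ensemble_pairwise_rmsd(ens, residue_selection(NULL, "backbone"))
  # rigidly transform one model: every pairwise RMSD is unchanged
  ens2 <- ens
  R <- with_seed <- local({ set.seed(99); random_rotation() })
  ens2$xyz[, , 3] <- ens$xyz[, , 3] %*% R + 5
  moved <- ensemble_pairwise_rmsd(ens2, residue_selection(NULL, "backbone"))
  expect_equal(moved$values, base$values, tolerance = 1e-9)

  # selections restrict the atom set
  sel <- residue_selection("3-10,15-20", atoms = "calpha")
  rs <- ensemble_pairwise_rmsd(ens, sel)
  expect_equal(rs$n_atoms, 14)
})

test_that("probe displacement reports constructed shifts outside the superposition frame", {
  ref <- reference_model(30)
  a <- sim_ensemble(ref, n_models = 2, dispersion = 0, cfg = sim_config(seed = 1))
  d0 <- residue_displacement(a, a, residue_selection("1-25", "backbone"),
                             probe_residue = 28, probe_atom = "CA")
  expect_equal(d0$designated, 0, tolerance = 1e-9)
  expect_equal(d0$mean, 0, tolerance = 1e-9)

  # displace residue 28 by 3 A in a rigidly transformed copy
  b <- a
  idx <- which(b$atoms$resno == 28)
  b$xyz[idx, 1, ] <- b$xyz[idx, 1, ] + 3
  R <- local({ set.seed(5); random_rotation() })
  for (m in 1:2) b$xyz[, , m] <- b$xyz[, , m] %*% R + 2
  d3 <- residue_displacement(a, b, residue_selection("1-25", "backbone"),
                             probe_residue = 28, probe_atom = "CA")
  expect_equal(d3$designated, 3, tolerance = 1e-9)
  expect_error(residue_displacement(a, b, residue_selection("1-25", "backbone"),
                                    probe_residue = 99), "probe")
})

test_that("restraint classification partitions NOEs by sequence separation", {
  recs <- data.frame(resid_i = c(10, 10, 10, 10, 10),
                     resid_j = c(10, 11, 14, 15, 16))
  st <- classify_restraints(recs)
  expect_equal(unname(st$counts[c("intra", "sequential", "medium", "long")]),
               c(1, 1, 2, 1))
  expect_equal(st$noe_total, 5)

  # single intra record: medium share 0
  expect_equal(classify_restraints(data.frame(resid_i = 3, resid_j = 3))$medium_share_pct, 0)

  # partition property on random records
  set.seed(77)
  rr <- data.frame(resid_i = sample(1:100, 300, TRUE),
                   resid_j = sample(1:100, 300, TRUE))
  str <- classify_restraints(rr)
  expect_equal(sum(str$counts[c("intra", "sequential", "medium", "long")]),
               300)
})

test_that("the XPLOR assign parser handles grammar, OR groups, hbond blocks and bad lines", {
  tf <- tempfile()
  writeLines(c(
    "! NOE distance restraints",
    "assign (resid 3 and name HA)(resid 10 and name HN) 4.0 2.2 1.0",
    "assign ((resid 5 and name HB1) or (resid 5 and name HB2))",
    "       (resid 6 and name HN) 3.5 1.7 0.5",
    "{ methyl pseudo-atom }",
    "assign (resid 7 and name HG#)(resid 30 and name HN) 5.0 3.2 1.0",
    "assign (resid 8 and name HA) garbage garbage",
    "! hydrogen bonds",
    "assign (resid 12 and name N)(resid 40 and name O) 2.9 0.5 0.5"), tf)
  recs <- suppressWarnings(read_restraints_xplor(tf))
  expect_equal(nrow(recs), 4)
  expect_equal(recs$resid_i, c(3, 5, 7, 12))
  expect_equal(recs$atom_j[1], "HN")
  expect_true(recs$ambiguous[2])
  expect_false(recs$ambiguous[1])
  expect_equal(recs$source, c("noe", "noe", "noe", "hbond"))
  errs <- attr(recs, "errors")
  expect_equal(nrow(errs), 1)
  expect_equal(errs$line, 7)

  # long-range classification of the grammar instance
  st <- classify_restraints(recs[1, ])
  expect_equal(unname(st$counts[["long"]]), 1)

  # empty file gives an empty record set
  empty <- tempfile()
  writeLines("! nothing here", empty)
  expect_equal(nrow(read_restraints_xplor(empty)), 0)
})
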