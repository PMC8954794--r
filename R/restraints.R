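#' Parse XPLOR-dialect distance restraints
#'
#' Reads `assign (resid I and name A)(resid J and name B) d dminus dplus`
#' statements (the dialect of deposited `.mr` NOE/H-bond restraint files).
#' `!`-comments and `{...}` blocks are stripped; statements may span lines.
#' OR-grouped ambiguous selections take the first `(resid ... name ...)`
#' pair of each side and are flagged `ambiguous`. A statement inside a
#' comment block announcing hydrogen bonds (a comment containing
#' "hydrogen bond" or "hbond") whose atom pair is donor-acceptor-like
#' (N/H/HN against O*) is classified `source = "hbond"`, otherwise
#' `"noe"`. Unparseable statements are collected into an error report with
#' line numbers; parsing continues.
#'
#' @param path Restraint file path.
#' @return Data frame of class `"restraint_records"` with columns
#'   `resid_i`, `atom_i`, `resid_j`, `atom_j`, `d`, `d_minus`, `d_plus`,
#'   `source`, `ambiguous`; attribute `errors` holds the per-line failure
#'   report.
#' @export
read_restraints_xplor <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  raw <- readLines(path, warn = FALSE)

  hbond_mode <- logical(length(raw))
  mode <- FALSE
  clean <- character(length(raw))
  for (i in seq_along(raw)) {
    line <- raw[i]
    com <- sub("^[^!]*", "", line)            # text from first '!' on
    if (grepl("hydrogen[ _-]?bond|hbond", com, ignore.case = TRUE) ||
        grepl("hydrogen[ _-]?bond|hbond", line, ignore.case = TRUE) &&
        grepl("^\\s*[!{]", line)) {
      mode <- TRUE
    } else if (grepl("^\\s*[!{].*(noe|distance)", line, ignore.case = TRUE)) {
      mode <- FALSE
    }
    hbond_mode[i] <- mode
    line <- sub("!.*$", "", line)
    clean[i] <- line
  }
  # strip {...} comments (may span lines): operate on the joined text while
  # tracking character offsets back to lines
  nl_offsets <- cumsum(nchar(clean) + 1L)
  text <- paste(clean, collapse = "\n")
  # blank out {...} comments with spaces so character offsets stay valid
  m <- gregexpr("\\{[^{}]*\\}", text)[[1]]
  if (m[1] != -1) {
    regmatches(text, list(m)) <-
      list(vapply(attr(m, "match.length"), strrep, character(1), x = " "))
  }

  starts <- gregexpr("(?i)\\bassign\\b", text, perl = TRUE)[[1]]
  recs <- list()
  errs <- list()
  if (starts[1] != -1) {
    bounds <- c(starts, nchar(text) + 1L)
    for (k in seq_along(starts)) {
      chunk <- substr(text, bounds[k], bounds[k + 1] - 1L)
      line_no <- findInterval(bounds[k] - 1L, nl_offsets) + 1L
      parsed <- parse_assign_chunk(chunk)
      if (is.null(parsed)) {
        errs[[length(errs) + 1L]] <- data.frame(
          line = line_no, text = trimws(substr(chunk, 1, 80)))
      } else {
        parsed$line <- line_no
        parsed$hbond_block <- hbond_mode[min(line_no, length(hbond_mode))]
        recs[[length(recs) + 1L]] <- parsed
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(resid_i = integer(), atom_i = character(),
               resid_j = integer(), atom_j = character(),
               d = numeric(), d_minus = numeric(), d_plus = numeric(),
               ambiguous = logical(), line = integer(),
               hbond_block = logical())
  is_don_acc <- function(a, b) {
    (grepl("^(H|HN|N)$", a) & grepl("^O", b)) |
      (grepl("^(H|HN|N)$", b) & grepl("^O", a))
  }
  out$source <- ifelse(nrow(out) > 0 &
                         out$hbond_block &
                         is_don_acc(out$atom_i, out$atom_j),
                       "hbond", "noe")
  out$hbond_block <- NULL
  err_df <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(), text = character())
  if (nrow(err_df)) {
    warning(sprintf("%d unparseable restraint statement(s); see attr(x, 'errors')",
                    nrow(err_df)))
  }
  attr(out, "errors") <- err_df
  class(out) <- c("restraint_records", "data.frame")
  out
}

# Parse one `assign ...` chunk. Returns NULL when it cannot be parsed.
parse_assign_chunk <- function(chunk) {
  body <- sub("(?i)^\\s*assign\\s*", "", chunk, perl = TRUE)
  groups <- extract_paren_groups(body, 2L)
  if (is.null(groups)) return(NULL)
  tail_txt <- groups$rest
  nums <- regmatches(tail_txt,
                     gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?",
                              tail_txt))[[1]]
  if (length(nums) < 3) return(NULL)
  sel <- lapply(groups$groups, parse_selection)
  if (any(vapply(sel, is.null, logical(1)))) return(NULL)
  data.frame(resid_i = sel[[1]]$resid, atom_i = sel[[1]]$name,
             resid_j = sel[[2]]$resid, atom_j = sel[[2]]$name,
             d = as.numeric(nums[1]), d_minus = as.numeric(nums[2]),
             d_plus = as.numeric(nums[3]),
             ambiguous = sel[[1]]$ambiguous || sel[[2]]$ambiguous)
}

# First `n` top-level balanced parenthesis groups and the remainder text.
extract_paren_groups <- function(s, n) {
  groups <- character(0)
  i <- 1L; len <- nchar(s)
  while (length(groups) < n) {
    while (i <= len && substr(s, i, i) != "(") {
      if (!grepl("^\\s$", substr(s, i, i))) return(NULL)
      i <- i + 1L
    }
    if (i > len) return(NULL)
    depth <- 0L; start <- i
    while (i <= len) {
      ch <- substr(s, i, i)
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") {
        depth <- depth - 1L
        if (depth == 0L) break
      }
      i <- i + 1L
    }
    if (depth != 0L) return(NULL)
    groups <- c(groups, substr(s, start + 1L, i - 1L))
    i <- i + 1L
  }
  list(groups = groups, rest = substr(s, i, len))
}

# Pull (resid, name) pairs out of one selection; OR groups give several.
parse_selection <- function(sel) {
  resids <- regmatches(sel, gregexpr("(?i)resid(?:ue)?\\s+([0-9]+)", sel,
                                     perl = TRUE))[[1]]
  names_ <- regmatches(sel, gregexpr("(?i)name\\s+([A-Za-z0-9#*%+']+)", sel,
                                     perl = TRUE))[[1]]
  if (!length(resids) || !length(names_)) return(NULL)
  list(resid = as.integer(sub("(?i)resid(?:ue)?\\s+", "", resids[1], perl = TRUE)),
       name = toupper(sub("(?i)name\\s+", "", names_[1], perl = TRUE)),
       ambiguous = length(resids) > 1 || length(names_) > 1)
}

#' Classify distance restraints by residue separation
#'
#' Bins NOE-derived records by sequence separation `s = |i - j|`:
#' intra-residue (s = 0), sequential (s = 1), medium range (1 < s <= 5),
#' long range (s > 5); hydrogen-bond records are counted separately. Also
#' reports the medium-range share as a percentage of the NOE-derived
#' distance restraints — a fingerprint of secondary-structure content
#' (beta-rich proteins have few medium-range NOEs).
#'
#' @param records A [read_restraints_xplor()] result or any data frame with
#'   `resid_i`, `resid_j` and optionally `source`.
#' @return A list of class `"restraint_stats"` with `counts` (intra,
#'   sequential, medium, long, hbond), `noe_total`, `total`,
#'   `medium_share_pct`.
#' @export
classify_restraints <- function(records) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "records must be a non-empty data frame")
  assert_that(all(c("resid_i", "resid_j") %in% names(records)),
              "records need resid_i and resid_j")
  assert_that(all(records$resid_i >= 1) && all(records$resid_j >= 1),
              "residue ids must be >= 1")
  src <- records[["source"]] %||% rep("noe", nrow(records))
  noe <- records[src == "noe", , drop = FALSE]
  s <- abs(noe$resid_i - noe$resid_j)
  counts <- c(intra = sum(s == 0), sequential = sum(s == 1),
              medium = sum(s > 1 & s <= 5), long = sum(s > 5),
              hbond = sum(src == "hbond"))
  noe_total <- sum(counts[c("intra", "sequential", "medium", "long")])
  stopifnot(noe_total == nrow(noe))
  structure(list(counts = counts, noe_total = noe_total,
                 total = nrow(records),
                 medium_share_pct = 100 * counts[["medium"]] / noe_total),
            class = "restraint_stats")
}

#' @export
print.restraint_stats <- function(x, ...) {
  cat("Distance-restraint statistics\n")
  cat(sprintf("  intra (|i-j| = 0):      %5d\n", x$counts[["intra"]]))
  cat(sprintf("  sequential (|i-j| = 1): %5d\n", x$counts[["sequential"]]))
  cat(sprintf("  medium (1 < |i-j| <= 5):%5d\n", x$counts[["medium"]]))
  cat(sprintf("  long (|i-j| > 5):       %5d\n", x$counts[["long"]]))
  cat(sprintf("  hydrogen bond:          %5d\n", x$counts[["hbond"]]))
  cat(sprintf("  NOE total %d; medium-range share %.1f%%\n",
              x$noe_total, x$medium_share_pct))
  invisible(x)
}
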