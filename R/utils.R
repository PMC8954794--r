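#' @keywords internal
#' @importFrom stats coef rnorm runif sd
#' @importFrom utils read.table write.table combn packageVersion
"_PACKAGE"

# Gas constant in kcal mol-1 K-1, used by every thermodynamic model here.
R_GAS_KCAL <- 1.98720425e-3

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed_local <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_input(...)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate a polynomial with coefficients in increasing powers at x.
polyval_inc <- function(coefs, x) {
  y <- rep(0, length(x))
  for (k in seq_along(coefs)) y <- y + coefs[k] * x^(k - 1L)
  y
}
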