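#' @useDynLib rpotatoes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx pnorm qnorm pchisq rnorm runif rpois
#' @importFrom utils read.csv write.csv
NULL

# Classed conditions so callers can distinguish usage errors from numerical
# failures.  Classes used throughout:
#   rps_invalid_matrix, rps_usage_error, rps_convergence_error,
#   rps_domain_error, rps_degenerate_error, rps_format_error
rps_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "rps_error"), call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate and exactly symmetrize a square numeric matrix.
check_square_symmetric <- function(x, arg = "x", tol = 1e-8) {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != ncol(x)) {
    rps_error(sprintf("`%s` must be a square numeric matrix", arg),
              "rps_invalid_matrix")
  }
  if (any(!is.finite(x))) {
    rps_error(sprintf("`%s` contains non-finite values", arg),
              "rps_invalid_matrix")
  }
  rel <- max(abs(x - t(x))) / max(abs(x), .Machine$double.eps)
  if (rel > tol) {
    rps_error(sprintf("`%s` is not symmetric (relative asymmetry %.2e)", arg, rel),
              "rps_invalid_matrix")
  }
  (x + t(x)) / 2
}

# Re-raise errors coming from the compiled layer (plain conditions) as classed
# invalid-matrix errors.
with_spd_errors <- function(expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "rps_error")) stop(e)
    rps_error(conditionMessage(e), "rps_invalid_matrix")
  })
}
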