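#' Build an among-population covariance matrix for simulation
#'
#' Constructs the K x K covariance matrix Omega of scaled allele frequencies
#' used by [simulate_frequencies()]. Omega encodes shared demographic history:
#' its diagonal is the per-population drift variance (an FST-like quantity,
#' typically 0.01-0.2 for regional population sets) and its off-diagonals the
#' covariance induced by shared ancestry or gene flow.
#'
#' @param n_pops number of populations K.
#' @param type covariance structure: `"identity"` (independent populations),
#'   `"block"` (groups of populations with within-block correlation `rho`),
#'   or `"spatial"` (correlation decaying as `exp(-d/range)` with distance
#'   `d` along a one-dimensional gradient, emulating populations ordered
#'   along a coastline).
#' @param scale drift variance on the diagonal.
#' @param rho within-block correlation (`type = "block"`).
#' @param n_blocks number of equally sized blocks (`type = "block"`).
#' @param range decay range in units of inter-population spacing
#'   (`type = "spatial"`).
#' @return a symmetric positive-definite `n_pops` x `n_pops` matrix.
#' @examples
#' make_omega(6, "block", scale = 0.05, rho = 0.6, n_blocks = 2)
#' @export
make_omega <- function(n_pops, type = c("spatial", "identity", "block"),
                       scale = 0.05, rho = 0.5, n_blocks = 3, range = 5) {
  type <- match.arg(type)
  stopifnot(n_pops >= 1, scale > 0)
  omega <- switch(type,
    identity = diag(n_pops),
    block = {
      blk <- sort(rep_len(seq_len(n_blocks), n_pops))
      cc <- outer(blk, blk, `==`) * rho
      diag(cc) <- 1
      cc
    },
    spatial = {
      d <- abs(outer(seq_len(n_pops), seq_len(n_pops), `-`))
      exp(-d / range)
    }
  )
  omega * scale
}

#' Wrap a covariance matrix with its Cholesky factor
#'
#' Validates symmetry and positive-definiteness and stores the lower
#' Cholesky factor L with L L' = Omega. Near-singular matrices are rescued
#' with a small trace-scaled ridge (with a warning); genuinely invalid input
#' fails.
#'
#' @param omega symmetric K x K covariance matrix.
#' @param estimator tag recording how the matrix was obtained
#'   (e.g. `"given"`, `"moments"`, `"shrinkage"`).
#' @return an object of class `omega_matrix` with elements `omega`, `chol`
#'   (lower triangular) and `estimator`.
#' @export
omega_matrix <- function(omega, estimator = "given") {
  omega <- as.matrix(omega)
  if (nrow(omega) != ncol(omega)) {
    stop("omega must be square")
  }
  if (max(abs(omega - t(omega))) > 1e-8 * max(1, max(abs(omega)))) {
    stop("omega must be symmetric")
  }
  omega <- (omega + t(omega)) / 2
  up <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(up)) {
    ridge <- 1e-6 * mean(diag(omega))
    for (i in 1:6) {
      up <- tryCatch(chol(omega + ridge * diag(nrow(omega))),
                     error = function(e) NULL)
      if (!is.null(up)) break
      ridge <- ridge * 10
    }
    if (is.null(up)) {
      stop("omega is not positive-definite (ridge rescue failed)")
    }
    warning(sprintf("omega rank-deficient; ridge %.3g added to the diagonal",
                    ridge))
    omega <- omega + ridge * diag(nrow(omega))
  }
  structure(
    list(omega = omega, chol = t(up), estimator = estimator),
    class = "omega_matrix"
  )
}

#' @export
print.omega_matrix <- function(x, ...) {
  k <- nrow(x$omega)
  cat(sprintf("omega_matrix: %d x %d (%s estimator)\n", k, k, x$estimator))
  cat(sprintf("  mean diagonal %.4g, mean |off-diagonal| %.4g\n",
              mean(diag(x$omega)),
              mean(abs(x$omega[upper.tri(x$omega)]))))
  invisible(x)
}

as_omega <- function(omega) {
  if (inherits(omega, "omega_matrix")) omega else omega_matrix(omega)
}
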