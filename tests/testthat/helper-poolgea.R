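# Shared builders for small fixtures, constructed in code.

# A tiny pool_counts object with explicit counts (populations x SNPs).
toy_counts <- function(ref, alt, scaffold = NULL, pos = NULL,
                       ref_allele = NULL, alt_allele = NULL) {
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  l <- ncol(ref)
  if (is.null(scaffold)) scaffold <- rep("scf001", l)
  if (is.null(pos)) pos <- seq_len(l) * 100L
  if (is.null(ref_allele)) ref_allele <- rep("A", l)
  if (is.null(alt_allele)) alt_allele <- rep("T", l)
  rownames(ref) <- rownames(alt) <- sprintf("P%02d", seq_len(nrow(ref)))
  pool_counts(
    data.frame(scaffold = scaffold, pos = as.integer(pos),
               ref = ref_allele, alt = alt_allele, stringsAsFactors = FALSE),
    ref, alt)
}

# An allele_freq object straight from a frequency matrix.
toy_freqs <- function(p, scaffold = NULL, pos = NULL) {
  p <- as.matrix(p)
  l <- ncol(p)
  if (is.null(scaffold)) scaffold <- rep("scf001", l)
  if (is.null(pos)) pos <- seq_len(l) * 100L
  rownames(p) <- sprintf("P%02d", seq_len(nrow(p)))
  colnames(p) <- paste0(scaffold, ":", pos)
  allele_freq(p, data.frame(scaffold = scaffold, pos = as.integer(pos),
                            ref = "A", alt = "T", stringsAsFactors = FALSE))
}

# Brute-force Lindley score: h_i = max(0, max over j <= i of sum x_j..x_i).
brute_lindley <- function(x) {
  n <- length(x)
  h <- numeric(n)
  for (i in seq_len(n)) {
    best <- 0
    for (j in seq_len(i)) {
      best <- max(best, sum(x[j:i]))
    }
    h[i] <- best
  }
  h
}

# Numerical-integration Bayes factor for z = beta * e + N(0, I),
# beta ~ N(0, tau), against beta = 0; returned in decibels.
quadrature_bfdb <- function(z, e, tau) {
  log_null <- sum(stats::dnorm(z, 0, 1, log = TRUE))
  f <- function(beta) {
    vapply(beta, function(b) {
      exp(sum(stats::dnorm(z, b * e, 1, log = TRUE)) - log_null) *
        stats::dnorm(b, 0, sqrt(tau))
    }, numeric(1))
  }
  bf <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  10 * log10(bf)
}

# Map adaptive SNP ids back to contiguous blocks (list of index vectors).
truth_blocks <- function(truth, freqs) {
  idx <- sort(match(truth$adaptive_snp_ids, colnames(freqs$freq)))
  split(idx, cumsum(c(1, diff(idx) != 1)))
}
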