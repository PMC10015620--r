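#' Simulation configuration for the synthetic pool-seq study
#'
#' Bundles and validates the parameters of the synthetic-data generator. The
#' defaults emulate the study design the package targets: 21 natural
#' populations sequenced as one pool each, allele frequencies correlated
#' among populations through a covariance matrix Omega, pooled read depth
#' around 60x, and a small minority of SNPs whose frequencies respond
#' linearly to an environmental gradient in clustered blocks (a stand-in for
#' linkage around a causal site, which the local-score stage exploits).
#'
#' @param n_pops number of populations (pools).
#' @param n_snps number of simulated SNPs.
#' @param n_scaffolds number of scaffolds the SNPs are tiled over.
#' @param omega K x K covariance matrix of scaled allele frequencies (see
#'   [make_omega()]), or an `omega_matrix`.
#' @param pi_range interval in (0, 1) for ancestral allele frequencies.
#' @param depth_mean mean pooled read depth per population and SNP.
#' @param n_adaptive number of environment-responsive SNPs.
#' @param beta effect size: allele-frequency shift per standard-deviation
#'   unit of the environmental covariate.
#' @param cluster_size adaptive SNPs are spiked in runs of this many
#'   adjacent SNPs (1 = independent positions).
#' @param seed integer seed; every generator consumes it deterministically.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_pops = 21, n_snps = 10000, n_scaffolds = 20,
                       omega = make_omega(n_pops), pi_range = c(0.1, 0.9),
                       depth_mean = 60, n_adaptive = 0, beta = 0.2,
                       cluster_size = 10, seed = 1) {
  omega <- as_omega(omega)
  stopifnot(
    n_pops >= 2, n_snps >= 1, n_scaffolds >= 1, n_scaffolds <= n_snps,
    length(pi_range) == 2, pi_range[1] > 0, pi_range[2] < 1,
    pi_range[1] < pi_range[2],
    depth_mean > 0, n_adaptive >= 0, cluster_size >= 1
  )
  if (n_adaptive > n_snps) {
    stop("n_adaptive must not exceed n_snps")
  }
  if (nrow(omega$omega) != n_pops) {
    stop("omega dimension does not match n_pops")
  }
  structure(
    list(n_pops = n_pops, n_snps = n_snps, n_scaffolds = n_scaffolds,
         omega = omega, pi_range = pi_range, depth_mean = depth_mean,
         n_adaptive = n_adaptive, beta = beta, cluster_size = cluster_size,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d pops, %d SNPs on %d scaffolds, depth %g, %d adaptive (beta %g), seed %d\n",
    x$n_pops, x$n_snps, x$n_scaffolds, x$depth_mean, x$n_adaptive, x$beta,
    x$seed))
  invisible(x)
}

pop_labels <- function(k) sprintf("P%02d", seq_len(k))

# Tile n_snps over n_scaffolds with strictly increasing positions.
snp_table <- function(n_snps, n_scaffolds) {
  scaffold_of <- sort(rep_len(seq_len(n_scaffolds), n_snps))
  scaffold <- sprintf("scf%03d", scaffold_of)
  gaps <- sample(20:200, n_snps, replace = TRUE)
  pos <- stats::ave(gaps, scaffold_of, FUN = cumsum)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  data.frame(scaffold = scaffold, pos = as.integer(pos), ref = ref,
             alt = unname(alt), stringsAsFactors = FALSE)
}

#' Simulate population allele frequencies under a covariance model
#'
#' For SNP j an ancestral frequency pi_j is drawn uniformly from
#' `pi_range`; population deviations y_j are drawn from a zero-mean
#' multivariate normal with covariance Omega; and population frequencies are
#' `p_ij = clamp(pi_j + sqrt(pi_j (1 - pi_j)) * y_ij, 0.005, 0.995)`.
#' Frequencies are generated on the natural scale with clamping (not through
#' a logistic link) so that they live in the linear geometry the scaled
#' allele-frequency model assumes; the clamp bounds avoid degenerate
#' Bernoulli cells when reads are drawn.
#'
#' @param config a [sim_config()].
#' @return a list with `freqs` (an `allele_freq` object, populations x SNPs)
#'   and `truth` (a `truth_table`: `adaptive_snp_ids`, `beta_per_snp`,
#'   `true_omega`, `true_pi`). Deterministic given `config$seed`.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_pops
  l <- config$n_snps
  snps <- snp_table(l, config$n_scaffolds)
  pi_j <- stats::runif(l, config$pi_range[1], config$pi_range[2])
  y <- config$omega$chol %*% matrix(stats::rnorm(k * l), k, l)
  p <- sweep(y, 2, sqrt(pi_j * (1 - pi_j)), `*`)
  p <- sweep(p, 2, pi_j, `+`)
  p <- pmin(pmax(p, 0.005), 0.995)
  dimnames(p) <- list(pop_labels(k), paste0(snps$scaffold, ":", snps$pos))
  freqs <- allele_freq(p, snps)
  truth <- structure(
    list(adaptive_snp_ids = character(0),
         beta_per_snp = stats::setNames(numeric(0), character(0)),
         true_omega = config$omega, true_pi = pi_j),
    class = "truth_table"
  )
  list(freqs = freqs, truth = truth)
}

#' Spike an environmental signal into simulated frequencies
#'
#' Shifts the frequencies of `n_adaptive` SNPs linearly along a standardized
#' environmental covariate: `p_ij <- clamp(p_ij + beta * std(env_i), 0.005,
#' 0.995)`. Adaptive SNPs are placed in runs of `cluster_size` adjacent SNPs
#' on a single scaffold, emulating the positional autocorrelation of a swept
#' haplotype that the local-score stage is designed to pick up.
#'
#' @param freqs an `allele_freq` object from [simulate_frequencies()].
#' @param env numeric covariate, one value per population.
#' @param config the [sim_config()] (uses `n_adaptive`, `beta`,
#'   `cluster_size`, and `seed + 1` for the placement draw).
#' @param truth optional `truth_table` to extend.
#' @return list with updated `freqs` and `truth`.
#' @export
spike_environment <- function(freqs, env, config, truth = NULL) {
  stopifnot(inherits(freqs, "allele_freq"), inherits(config, "sim_config"))
  if (length(env) != nrow(freqs$freq)) {
    stop("env must have one value per population")
  }
  if (config$n_adaptive > ncol(freqs$freq)) {
    stop("n_adaptive must not exceed the number of SNPs")
  }
  if (is.null(truth)) {
    truth <- structure(
      list(adaptive_snp_ids = character(0),
           beta_per_snp = stats::setNames(numeric(0), character(0)),
           true_omega = config$omega, true_pi = freqs$pi),
      class = "truth_table"
    )
  }
  if (config$n_adaptive == 0 || config$beta == 0) {
    return(list(freqs = freqs, truth = truth))
  }
  set.seed(config$seed + 1L)
  l <- ncol(freqs$freq)
  cs <- min(config$cluster_size, config$n_adaptive)
  n_blocks <- ceiling(config$n_adaptive / cs)
  scaffold <- freqs$snps$scaffold
  taken <- logical(l)
  idx <- integer(0)
  tries <- 0
  while (length(idx) < config$n_adaptive && tries < 10000) {
    tries <- tries + 1
    size <- min(cs, config$n_adaptive - length(idx))
    start <- sample.int(l - size + 1, 1)
    block <- start:(start + size - 1)
    if (any(taken[block])) next
    if (scaffold[start] != scaffold[block[length(block)]]) next
    taken[block] <- TRUE
    idx <- c(idx, block)
  }
  if (length(idx) < config$n_adaptive) {
    stop("could not place adaptive blocks; reduce n_adaptive or cluster_size")
  }
  idx <- sort(idx)
  e <- as.numeric(scale(env))
  p <- freqs$freq
  p[, idx] <- pmin(pmax(p[, idx] + config$beta * e, 0.005), 0.995)
  freqs$freq <- p
  freqs$pi <- colMeans(p)
  ids <- colnames(p)[idx]
  truth$adaptive_snp_ids <- union(truth$adaptive_snp_ids, ids)
  truth$beta_per_snp <- c(truth$beta_per_snp,
                          stats::setNames(rep(config$beta, length(ids)), ids))
  list(freqs = freqs, truth = truth)
}

#' Simulate pooled read counts from population frequencies
#'
#' Per population and SNP, the total depth is Poisson(`depth_mean`) and the
#' alternate-allele read count is Binomial(depth, p). Poisson (rather than
#' fixed) depth exercises the mean-depth filter realistically; zero-depth
#' cells become missing downstream.
#'
#' @param freqs an `allele_freq` object (frequencies in \[0, 1\]).
#' @param depth_mean mean pooled depth.
#' @param seed integer seed.
#' @return a `pool_counts` object.
#' @export
simulate_pool_reads <- function(freqs, depth_mean = 60, seed = 1) {
  stopifnot(inherits(freqs, "allele_freq"), depth_mean > 0)
  set.seed(as.integer(seed))
  p <- freqs$freq
  n <- length(p)
  depth <- matrix(stats::rpois(n, depth_mean), nrow(p), ncol(p))
  alt <- matrix(stats::rbinom(n, depth, p), nrow(p), ncol(p))
  ref <- depth - alt
  dimnames(ref) <- dimnames(alt) <- dimnames(p)
  pool_counts(freqs$snps, ref, alt)
}

# Fixed, uneven base visitation rates over the 12 pollinator functional
# categories (dominant long-tongue bees, small bees, honeybees as in the
# field observations this generator emulates).
pollinator_categories <- c(
  "bumblebees", "long_tongue_bees", "large_bees", "small_bees", "honeybees",
  "large_wasps", "small_flies", "large_flies", "hoverflies", "small_beetles",
  "large_beetles", "butterflies"
)

default_rate_matrix <- function(n_pops, categories = pollinator_categories,
                                mean_visits = 60) {
  base <- c(6, 14, 7, 12, 10, 1.5, 3, 2, 5, 1, 0.8, 2)[seq_along(categories)]
  base <- base / sum(base) * mean_visits
  m <- matrix(rep(base, each = n_pops), n_pops, length(categories),
              dimnames = list(pop_labels(n_pops), categories))
  m
}

#' Simulate an over-dispersed visitation matrix
#'
#' Draws visit counts per (population, pollinator category) from a negative
#' binomial with mean `rate_matrix` and dispersion `dispersion` (Poisson is
#' the `dispersion -> Inf` limit). Optionally decomposes each population's
#' counts over individual plants, with a lognormal population random effect,
#' for testing the visitation BLUP model.
#'
#' @param n_pops number of populations.
#' @param categories category names (default: the 12 pollinator functional
#'   categories).
#' @param rate_matrix nonnegative matrix of expected visits (populations x
#'   categories); a built-in uneven profile by default.
#' @param dispersion negative-binomial size parameter.
#' @param seed integer seed.
#' @param plants_per_pop optional number of observed plants per population;
#'   if given, per-plant draws are returned as well.
#' @param sigma_pop standard deviation of the log-scale population random
#'   effect used for the plant-level decomposition.
#' @return list with `matrix` (populations x categories counts) and, when
#'   requested, `plant_level` (data.frame population/plant/category/visits).
#' @export
simulate_visitation <- function(n_pops = 21, categories = pollinator_categories,
                                rate_matrix = NULL, dispersion = 2, seed = 1,
                                plants_per_pop = NULL, sigma_pop = 0.4) {
  set.seed(as.integer(seed))
  if (is.null(rate_matrix)) {
    rate_matrix <- default_rate_matrix(n_pops, categories)
  }
  rate_matrix <- as.matrix(rate_matrix)
  stopifnot(all(rate_matrix >= 0), nrow(rate_matrix) == n_pops,
            ncol(rate_matrix) == length(categories))
  dimnames(rate_matrix) <- list(pop_labels(n_pops), categories)
  rnb <- function(mu) {
    out <- integer(length(mu))
    pos <- mu > 0
    if (is.finite(dispersion)) {
      out[pos] <- stats::rnbinom(sum(pos), size = dispersion, mu = mu[pos])
    } else {
      out[pos] <- stats::rpois(sum(pos), mu[pos])
    }
    out
  }
  if (is.null(plants_per_pop)) {
    counts <- matrix(rnb(rate_matrix), n_pops, length(categories),
                     dimnames = dimnames(rate_matrix))
    return(list(matrix = counts, plant_level = NULL))
  }
  pop_eff <- exp(stats::rnorm(n_pops, 0, sigma_pop))
  rows <- vector("list", n_pops)
  for (i in seq_len(n_pops)) {
    mu <- rep(rate_matrix[i, ] * pop_eff[i] / plants_per_pop,
              each = plants_per_pop)
    visits <- rnb(mu)
    rows[[i]] <- data.frame(
      population = pop_labels(n_pops)[i],
      plant = rep(seq_len(plants_per_pop), times = length(categories)),
      category = rep(categories, each = plants_per_pop),
      visits = visits, stringsAsFactors = FALSE)
  }
  plant_level <- do.call(rbind, rows)
  agg <- stats::aggregate(visits ~ population + category, plant_level, sum)
  counts <- matrix(0L, n_pops, length(categories),
                   dimnames = list(pop_labels(n_pops), categories))
  counts[cbind(agg$population, agg$category)] <- agg$visits
  list(matrix = counts, plant_level = plant_level)
}

#' Simulate an environmental covariate along a latitude-like gradient
#'
#' A smooth gradient over the (ordered) populations plus independent noise;
#' with `confound > 0` the gradient is mixed with the leading eigenvector of
#' Omega so that environment and population structure are correlated, as in
#' real regional study designs.
#'
#' @param config a [sim_config()].
#' @param noise standard deviation of the independent noise.
#' @param confound weight in \[0, 1\] on Omega's leading eigenvector.
#' @return numeric vector of length `n_pops` (not standardized).
#' @export
simulate_environment <- function(config, noise = 0.5, confound = 0) {
  stopifnot(inherits(config, "sim_config"), confound >= 0, confound <= 1)
  set.seed(config$seed + 2L)
  k <- config$n_pops
  grad <- as.numeric(scale(seq_len(k)))
  if (confound > 0) {
    v1 <- eigen(config$omega$omega, symmetric = TRUE)$vectors[, 1]
    v1 <- as.numeric(scale(v1))
    if (stats::cor(v1, grad) < 0) v1 <- -v1
    grad <- (1 - confound) * grad + confound * v1
  }
  grad + stats::rnorm(k, 0, noise)
}
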