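test_that("frequency simulation is deterministic and respects its bounds", {
  cfg <- sim_config(n_pops = 6, n_snps = 500, n_scaffolds = 4, seed = 11)
  a <- simulate_frequencies(cfg)
  b <- simulate_frequencies(cfg)
  expect_identical(a$freqs$freq, b$freqs$freq)
  expect_identical(a$truth$true_pi, b$truth$true_pi)
  expect_true(all(a$freqs$freq >= 0.005 & a$freqs$freq <= 0.995))
  expect_true(all(a$truth$true_pi >= 0.1 & a$truth$true_pi <= 0.9))
  expect_length(a$truth$adaptive_snp_ids, 0)
  # positions strictly increasing within scaffold
  by_s <- split(a$freqs$snps$pos, a$freqs$snps$scaffold)
  expect_true(all(vapply(by_s, function(p) all(diff(p) > 0), logical(1))))
})

test_that("independent populations stay uncorrelated under an identity omega", {
  # at drift-realistic scales the clamp almost never binds and the scaled
  # frequencies of the two populations are uncorrelated
  for (sc in c(0.3, 0.05)) {
    cfg <- sim_config(n_pops = 2, n_snps = 50000, n_scaffolds = 1,
                      omega = make_omega(2, "identity", scale = sc), seed = 5)
    sim <- simulate_frequencies(cfg)
    pi_t <- sim$truth$true_pi
    y <- sweep(sweep(sim$freqs$freq, 2, pi_t, `-`), 2,
               sqrt(pi_t * (1 - pi_t)), `/`)
    cc <- tcrossprod(y) / ncol(y)
    expect_lt(abs(cc[1, 2]), 0.02)
    expect_lt(abs(cc[1, 1] / sc - 1), 0.25)
  }
})

test_that("scaled-frequency covariance converges to the generating omega", {
  om <- make_omega(8, "spatial", scale = 0.05, range = 3)
  err <- vapply(c(1000, 20000), function(l) {
    cfg <- sim_config(n_pops = 8, n_snps = l, n_scaffolds = 2, omega = om,
                      seed = 3)
    sim <- simulate_frequencies(cfg)
    pi_t <- sim$truth$true_pi
    y <- sweep(sweep(sim$freqs$freq, 2, pi_t, `-`), 2,
               sqrt(pi_t * (1 - pi_t)), `/`)
    est <- tcrossprod(y) / l
    norm(est - om, "F") / norm(om, "F")
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.10)
})

test_that("environment spiking shifts only the chosen SNPs toward the gradient", {
  cfg <- sim_config(n_pops = 21, n_snps = 2000, n_scaffolds = 4,
                    omega = make_omega(21, "identity", scale = 0.05),
                    n_adaptive = 100, beta = 0.15, cluster_size = 10,
                    seed = 21)
  sim <- simulate_frequencies(cfg)
  env <- as.numeric(scale(seq_len(21)))

  cfg0 <- sim_config(n_pops = 21, n_snps = 2000, n_scaffolds = 4,
                     omega = cfg$omega, n_adaptive = 100, beta = 0,
                     seed = 21)
  same <- spike_environment(sim$freqs, env, cfg0, sim$truth)
  expect_identical(same$freqs$freq, sim$freqs$freq)
  expect_length(same$truth$adaptive_snp_ids, 0)

  sp <- spike_environment(sim$freqs, env, cfg, sim$truth)
  expect_length(sp$truth$adaptive_snp_ids, 100)
  expect_true(all(sp$truth$beta_per_snp == 0.15))
  idx <- match(sp$truth$adaptive_snp_ids, colnames(sp$freqs$freq))
  untouched <- setdiff(seq_len(2000), idx)
  expect_identical(sp$freqs$freq[, untouched], sim$freqs$freq[, untouched])
  cors <- apply(sp$freqs$freq, 2, stats::cor, y = env)
  expect_gt(median(cors[idx]), median(cors[untouched]))
  expect_gt(median(cors[idx]), 0.3)
})

test_that("spiking every SNP records every SNP in the truth table", {
  cfg <- sim_config(n_pops = 5, n_snps = 60, n_scaffolds = 1,
                    n_adaptive = 60, beta = 0.1, cluster_size = 60, seed = 2)
  sim <- simulate_frequencies(cfg)
  sp <- spike_environment(sim$freqs, rnorm(5), cfg, sim$truth)
  expect_setequal(sp$truth$adaptive_snp_ids, colnames(sim$freqs$freq))
  expect_error(sim_config(n_pops = 5, n_snps = 10, n_scaffolds = 1,
                          n_adaptive = 20),
               "n_adaptive")
})

test_that("pooled read sampling matches binomial expectations", {
  p <- matrix(0.5, 4, 400)
  fr <- toy_freqs(p)
  counts <- simulate_pool_reads(fr, depth_mean = 10000, seed = 8)
  frac <- sum(counts$alt_count) / sum(counts$alt_count + counts$ref_count)
  expect_lt(abs(frac - 0.5), 0.02)
  # determinism
  counts2 <- simulate_pool_reads(fr, depth_mean = 10000, seed = 8)
  expect_identical(counts$alt_count, counts2$alt_count)
  # sampling variance of alt/depth - p scales like p(1-p)/depth
  for (pv in c(0.2, 0.5)) {
    for (d in c(20, 80)) {
      frd <- toy_freqs(matrix(pv, 4, 2000))
      cc <- simulate_pool_reads(frd, depth_mean = d, seed = 3)
      depth <- cc$ref_count + cc$alt_count
      ok <- depth > 0
      v <- stats::var((cc$alt_count[ok] / depth[ok]) - pv)
      expected <- mean(pv * (1 - pv) / depth[ok])
      expect_lt(abs(v / expected - 1), 0.15)
    }
  }
})

test_that("zero-depth cells become missing frequencies downstream", {
  counts <- toy_counts(rbind(c(3, 0), c(5, 4)), rbind(c(7, 0), c(5, 6)))
  fr <- allele_frequencies(counts)
  expect_identical(fr$freq[1, 1], 0.7)
  expect_true(is.na(fr$freq[1, 2]))
  expect_identical(fr$pi[2], 0.6)  # mean over non-missing pools only
})

test_that("visitation generator produces the expected specialization contrasts", {
  # equal rates: near-generalist populations (d-index near 0)
  eq <- matrix(30, 10, 12)
  vis <- simulate_visitation(10, rate_matrix = eq, dispersion = 50, seed = 4)
  idx <- network_indices(vis$matrix)
  expect_lt(mean(idx$d_index), 0.1)
  # one dominant category in one population lowers its partner diversity
  rates <- matrix(10, 6, 12)
  rates[1, 3] <- 400
  vis2 <- simulate_visitation(6, rate_matrix = rates, dispersion = 50,
                              seed = 5)
  idx2 <- network_indices(vis2$matrix)
  expect_lt(idx2$partner_diversity[1], min(idx2$partner_diversity[-1]))
  # zero rates: all-zero matrix rejected downstream
  vis0 <- simulate_visitation(3, rate_matrix = matrix(0, 3, 12), seed = 1)
  expect_true(all(vis0$matrix == 0))
  expect_error(network_indices(vis0$matrix), "all-zero")
  # negative binomial counts are over-dispersed relative to Poisson
  vis_od <- simulate_visitation(200, rate_matrix = matrix(20, 200, 12),
                                dispersion = 1, seed = 6)
  expect_gt(stats::var(as.numeric(vis_od$matrix)), 3 * 20)
  # plant-level decomposition aggregates to the population matrix
  vp <- simulate_visitation(4, rate_matrix = matrix(12, 4, 12), seed = 7,
                            plants_per_pop = 5)
  agg <- stats::aggregate(visits ~ population, vp$plant_level, sum)
  expect_equal(agg$visits[order(agg$population)],
               unname(rowSums(vp$matrix)))
})

test_that("synthetic inputs round-trip through the readers", {
  cfg <- sim_config(n_pops = 5, n_snps = 200, n_scaffolds = 3, seed = 13)
  sim <- simulate_frequencies(cfg)
  counts <- simulate_pool_reads(sim$freqs, depth_mean = 40, seed = 14)
  vis <- simulate_visitation(5, rate_matrix = matrix(15, 5, 12), seed = 15)
  env <- matrix(rnorm(10), 5, 2,
                dimnames = list(counts$pops, c("env1", "latitude")))
  outdir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(counts, env, vis$matrix, outdir)
  expect_true(all(file.exists(unlist(paths))))

  back <- read_pool_vcf(paths$vcf)
  expect_equal(back$ref_count, counts$ref_count)
  expect_equal(back$alt_count, counts$alt_count)
  expect_equal(back$snps$pos, counts$snps$pos)

  env_back <- read_pop_table(paths$env)
  expect_equal(pop_table_matrix(env_back), env)
  vis_back <- read_pop_table(paths$visitation)
  expect_equal(unname(pop_table_matrix(vis_back)), unname(vis$matrix))

  genes <- read_gene_annotation(paths$gff)
  expect_gt(nrow(genes), 0)
  expect_true(all(genes$start <= genes$end))
  expect_setequal(unique(genes$scaffold), unique(counts$snps$scaffold))

  # the emitted VCF is standard enough for an external parser
  if (nzchar(Sys.which("bcftools"))) {
    status <- system2("bcftools", c("view", paths$vcf),
                      stdout = FALSE, stderr = FALSE)
    expect_identical(status, 0L)
  }
})
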