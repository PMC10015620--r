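test_that("symmetric visitation gives the textbook index values", {
  m <- matrix(10, 4, 12,
              dimnames = list(sprintf("P%02d", 1:4), paste0("cat", 1:12)))
  idx <- network_indices(m)
  expect_equal(idx$normalized_degree, rep(1, 4))
  expect_equal(idx$partner_diversity, rep(log(12), 4), tolerance = 1e-12)
  expect_equal(idx$effective_partners, rep(12, 4), tolerance = 1e-12)
  expect_equal(idx$d_index, rep(0, 4))
  expect_equal(idx$proportional_similarity, rep(1, 4))
  expect_equal(idx$proportional_generality, rep(1, 4))
  expect_equal(idx$species_specificity, rep(0, 4))
  expect_equal(idx$species_strength, rep(12 / 4, 4))
})

test_that("a single-category visitor profile is maximally specialized", {
  m <- rbind(c(60, 0, 0), c(20, 20, 20))
  rownames(m) <- c("PA", "PB")
  idx <- network_indices(m)
  expect_equal(idx$partner_diversity[1], 0)
  expect_equal(idx$effective_partners[1], 1)
  expect_equal(idx$normalized_degree[1], 1 / 3)
  expect_gt(idx$d_index[1], idx$d_index[2])
})

test_that("indices match an independent hand computation and are row-symmetric", {
  m <- rbind(c(9, 1), c(1, 9))
  rownames(m) <- c("PA", "PB")
  idx <- network_indices(m)
  # hand oracle from the definitions
  p <- c(0.9, 0.1)
  q <- c(0.5, 0.5)
  h <- -sum(p * log(p))
  d <- sum(p * log(p / q))
  d_max <- log(1 / 0.5)
  expect_equal(idx$partner_diversity[1], h, tolerance = 1e-12)
  expect_equal(idx$effective_partners[1], exp(h), tolerance = 1e-12)
  expect_equal(idx$d_index[1], d / d_max, tolerance = 1e-12)
  expect_equal(idx$proportional_similarity[1], 1 - 0.5 * sum(abs(p - q)),
               tolerance = 1e-12)
  expect_equal(idx$proportional_generality[1], exp(h) / exp(log(2)),
               tolerance = 1e-12)
  expect_equal(idx$species_strength[1], 9 / 10 + 1 / 10)
  expect_equal(idx$species_specificity[1],
               stats::sd(c(9, 1)) / mean(c(9, 1)) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(idx$normalized_degree[1], 1)
  # row swap symmetry
  for (col in names(idx)[-1]) {
    expect_equal(idx[[col]][1], idx[[col]][2], tolerance = 1e-12,
                 label = col)
  }
})

test_that("index invariants hold on random matrices", {
  set.seed(42)
  for (r in 1:20) {
    m <- matrix(rpois(5 * 8, 6) + 1, 5, 8)
    rownames(m) <- sprintf("P%02d", 1:5)
    idx <- network_indices(m)
    expect_true(all(idx$d_index >= 0 & idx$d_index <= 1))
    expect_true(all(idx$normalized_degree >= 0 & idx$normalized_degree <= 1))
    expect_equal(idx$effective_partners, exp(idx$partner_diversity),
                 tolerance = 1e-12)
    expect_true(all(idx$effective_partners <= 8 + 1e-9))
    expect_true(all(idx$partner_diversity <= log(8) + 1e-9))
  }
})

test_that("populations with no visits are rejected by name", {
  m <- rbind(c(5, 5), c(0, 0))
  rownames(m) <- c("GOOD", "EMPTY")
  expect_error(network_indices(m), "EMPTY")
})

test_that("BLUP predictions equal the shrinkage formula and its limits", {
  # degenerate constant response: everything collapses to the grand mean
  const <- data.frame(population = rep(c("A", "B"), each = 4), visits = 3)
  fit0 <- blup_visits(const)
  expect_equal(unname(fit0$predictions), c(3, 3))
  expect_equal(fit0$sigma2_pop, 0)

  # balanced normal data: predictions follow mu + shrink * (ybar - mu)
  set.seed(7)
  n_k <- 8
  pops <- sprintf("P%02d", 1:12)
  dat <- data.frame(
    population = rep(pops, each = n_k),
    visits = rep(rnorm(12, 10, 2), each = n_k) + rnorm(12 * n_k, 0, 1))
  fit <- blup_visits(dat)
  shrink <- fit$sigma2_pop / (fit$sigma2_pop + fit$sigma2_res / n_k)
  ybar <- tapply(dat$visits, dat$population, mean)
  manual <- fit$mu + shrink * (ybar[names(fit$predictions)] - fit$mu)
  expect_equal(unname(fit$predictions), as.numeric(manual), tolerance = 1e-6)

  # no between-population variance: shrinkage collapses to the grand mean
  set.seed(8)
  flat <- data.frame(population = rep(pops, each = n_k),
                     visits = rnorm(12 * n_k, 5, 1))
  fit_flat <- blup_visits(flat)
  expect_lt(max(abs(fit_flat$predictions - fit_flat$mu)),
            0.2 * stats::sd(flat$visits))

  expect_error(blup_visits(data.frame(population = "A", visits = 1:3)),
               "two populations")
})

test_that("REML recovers the variance components of the one-way model", {
  set.seed(123)
  n_pop <- 50
  n_k <- 5
  reps <- 200
  est <- t(vapply(seq_len(reps), function(r) {
    u <- rnorm(n_pop, 0, 2)            # sigma2_pop = 4
    y <- rep(u, each = n_k) + rnorm(n_pop * n_k, 0, 1)  # sigma2_res = 1
    d <- data.frame(population = rep(sprintf("P%03d", 1:n_pop), each = n_k),
                    visits = 10 + y)
    fit <- blup_visits(d)
    c(fit$sigma2_pop, fit$sigma2_res)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) / 4 - 1), 0.3)
  expect_lt(abs(mean(est[, 2]) / 1 - 1), 0.3)
})

test_that("spearman pruning follows the deterministic greedy rule", {
  set.seed(5)
  base <- rnorm(21)
  env <- data.frame(
    population = sprintf("P%02d", 1:21),
    a = base,
    b = rank(base) + rnorm(21, 0, 1e-6),   # |rho(a,b)| = 1 in ranks
    c = rnorm(21),
    d = rnorm(21))
  kept <- spearman_prune(env, rho_max = 0.8)
  expect_true("a" %in% kept)
  expect_false("b" %in% kept)
  expect_true(all(c("c", "d") %in% kept))

  # all pairwise |rho| below the threshold: nothing dropped
  set.seed(6)
  indep <- data.frame(population = sprintf("P%02d", 1:30),
                      matrix(rnorm(30 * 4), 30, 4))
  expect_length(spearman_prune(indep, rho_max = 0.8), 4)
})

test_that("pruning a correlated triple matches a brute-force trace of the rule", {
  set.seed(9)
  n <- 40
  x <- rnorm(n)
  env <- cbind(v1 = x, v2 = x + rnorm(n, 0, 0.05),
               v3 = -x + rnorm(n, 0, 0.05), v4 = rnorm(n), v5 = rnorm(n))
  rownames(env) <- sprintf("P%02d", 1:n)

  # independent re-implementation of the stated greedy rule
  rho <- abs(stats::cor(env, method = "spearman"))
  pairs <- which(upper.tri(rho) & rho >= 0.8, arr.ind = TRUE)
  pr <- data.frame(v1 = colnames(env)[pairs[, 1]],
                   v2 = colnames(env)[pairs[, 2]],
                   r = rho[pairs])
  pr <- pr[order(-pr$r, pr$v1, pr$v2), ]
  dropped <- character(0)
  for (i in seq_len(nrow(pr))) {
    if (!(pr$v1[i] %in% dropped) && !(pr$v2[i] %in% dropped)) {
      dropped <- c(dropped, pr$v2[i])
    }
  }
  oracle <- setdiff(colnames(env), dropped)
  expect_setequal(as.character(spearman_prune(env)), oracle)

  # population row order must not matter
  perm <- sample(n)
  expect_setequal(as.character(spearman_prune(env[perm, ])), oracle)
})

test_that("constant variables are flagged and excluded from pruning", {
  env <- cbind(k = rep(1, 10), a = rnorm(10), b = rnorm(10))
  rownames(env) <- sprintf("P%02d", 1:10)
  kept <- spearman_prune(env)
  expect_true("k" %in% kept)
  expect_identical(attr(kept, "constant"), "k")
})

test_that("environmental PCA behaves on degenerate and orthogonal designs", {
  x <- rnorm(15)
  two <- cbind(a = x, b = 2 * x + 3)
  rownames(two) <- sprintf("P%02d", 1:15)
  pca <- env_pca(two)
  expect_equal(pca$var_explained[1], 1, tolerance = 1e-12)

  # exactly uncorrelated columns share the variance equally after scaling
  q <- stats::prcomp(matrix(rnorm(20 * 4), 20, 4))$x
  colnames(q) <- paste0("v", 1:4)
  pca_q <- env_pca(q)
  expect_equal(pca_q$var_explained, rep(0.25, 4), tolerance = 1e-9)

  # deterministic sign convention: stable across reruns
  set.seed(30)
  m <- matrix(rnorm(21 * 5), 21, 5, dimnames = list(NULL, paste0("v", 1:5)))
  p1 <- env_pca(m)
  p2 <- env_pca(m)
  expect_identical(p1$scores, p2$scores)
  expect_true(all(apply(p1$loadings, 2, function(v) v[which.max(abs(v))]) > 0))

  expect_error(env_pca(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
})

test_that("genomic PCs capture a planted gradient and its env correlation", {
  set.seed(77)
  k <- 12
  grad <- seq(-1, 1, length.out = k)
  p <- 0.5 + outer(grad, rep(0.3, 400)) + matrix(rnorm(k * 400, 0, 0.01), k)
  fr <- toy_freqs(pmin(pmax(p, 0.01), 0.99))
  gp <- genomic_pc(NULL, fr)
  expect_gt(gp$var_explained[1], 0.9)

  env <- cbind(pc = gp$scores[, 1], noise = rnorm(k))
  rownames(env) <- rownames(fr$freq)
  gp2 <- genomic_pc(env, fr)
  expect_equal(unname(abs(gp2$cor_pc1["pc"])), 1, tolerance = 1e-9)
  set.seed(11)
  gp3 <- genomic_pc(cbind(perm = as.numeric(sample(gp$scores[, 1]))), fr)
  expect_lt(abs(gp3$cor_pc1["perm"]), 0.6)

  expect_error(genomic_pc(NULL, toy_freqs(matrix(0.5, 2, 10))),
               "three populations")
})
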