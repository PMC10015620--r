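#' Species-level pollination-network indices per population
#'
#' Computes the eight category-level indices of a bipartite
#' population x pollinator-category visitation network, treating each plant
#' population as the focal "species" and the column-sum distribution `q` as
#' partner availability. With `p` the population's visit distribution over
#' categories:
#' \itemize{
#'   \item normalized degree: categories visited / categories available;
#'   \item species strength: sum over categories of the population's share
#'     of that category's total visits;
#'   \item species specificity: coefficient of variation of the
#'     population's interaction counts, normalized to \[0, 1\];
#'   \item partner diversity: Shannon entropy `H = -sum p log p` (natural
#'     log);
#'   \item effective partners: `exp(H)`;
#'   \item proportional similarity: `1 - 0.5 sum |p - q|`;
#'   \item proportional generality: `exp(H) / exp(H(q))`;
#'   \item d-index: Kullback-Leibler specialization
#'     `d = sum p log(p / q)` normalized by its marginal-preserving extremes
#'     (`d_min = 0`, attained at `p = q`; `d_max = log(1 / min q)`, attained
#'     by concentrating on the rarest available partner), so 0 is a perfect
#'     generalist and 1 a maximal specialist.
#' }
#'
#' @param m visitation matrix, populations x categories, nonnegative counts.
#' @return data.frame with one row per population and the eight indices.
#' @export
network_indices <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("visitation counts must be nonnegative")
  if (all(m == 0)) stop("all-zero visitation matrix")
  zero_rows <- rowSums(m) == 0
  if (any(zero_rows)) {
    stop("population(s) with no visits: ",
         paste(rownames(m)[zero_rows], collapse = ", "))
  }
  n_cat <- ncol(m)
  tot <- sum(m)
  q <- colSums(m) / tot
  p <- m / rowSums(m)
  h <- vegan::diversity(m, index = "shannon")
  h_q <- -sum(q[q > 0] * log(q[q > 0]))
  d <- vapply(seq_len(nrow(m)), function(i) {
    pi <- p[i, ]
    sum(pi[pi > 0] * log(pi[pi > 0] / q[pi > 0]))
  }, numeric(1))
  d_max <- log(1 / min(q[q > 0]))
  d_index <- if (d_max > 0) d / d_max else rep(0, nrow(m))
  cv <- apply(m, 1, function(x) stats::sd(x) / mean(x))
  data.frame(
    population = rownames(m),
    normalized_degree = rowSums(m > 0) / n_cat,
    species_strength = rowSums(sweep(m, 2, colSums(m), `/`)),
    species_specificity = cv / sqrt(n_cat),
    partner_diversity = as.numeric(h),
    effective_partners = exp(as.numeric(h)),
    proportional_similarity = 1 - 0.5 * rowSums(abs(sweep(p, 2, q, `-`))),
    proportional_generality = exp(as.numeric(h)) / exp(h_q),
    d_index = pmin(pmax(d_index, 0), 1),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way random-effects BLUP of per-population visitation
#'
#' Fits `y_i = mu + population + eps_i` by REML (population random) and
#' returns the shrinkage predictions
#' `mu + shrink_k (ybar_k - mu)` with
#' `shrink_k = sigma2_pop / (sigma2_pop + sigma2_res / n_k)`; predictions
#' interpolate between the population mean (large `n_k`) and the grand mean
#' (small `n_k` or no between-population variance).
#'
#' @param plant_level data.frame with columns `population` and the response.
#' @param response name of the response column (default `"visits"`).
#' @return list: `mu`, `sigma2_pop`, `sigma2_res`, `effects` (named
#'   deviations), `predictions` (named, `mu + effect`), `model` (the lme4
#'   fit, or `NULL` for the degenerate constant-response case).
#' @export
blup_visits <- function(plant_level, response = "visits") {
  stopifnot(is.data.frame(plant_level),
            all(c("population", response) %in% names(plant_level)))
  pops <- unique(plant_level$population)
  if (length(pops) < 2) {
    stop("at least two populations are required to separate variance components")
  }
  y <- plant_level[[response]]
  if (stats::var(y) == 0) {
    eff <- stats::setNames(rep(0, length(pops)), pops)
    return(list(mu = y[1], sigma2_pop = 0, sigma2_res = 0, effects = eff,
                predictions = eff + y[1], model = NULL))
  }
  dat <- data.frame(y = y, population = factor(plant_level$population))
  fit <- lme4::lmer(y ~ 1 + (1 | population), data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_pop <- vc$vcov[vc$grp == "population"]
  s2_res <- vc$vcov[vc$grp == "Residual"]
  mu <- unname(lme4::fixef(fit)[1])
  re <- lme4::ranef(fit)$population
  eff <- stats::setNames(re[, 1], rownames(re))
  list(mu = mu, sigma2_pop = s2_pop, sigma2_res = s2_res, effects = eff,
       predictions = mu + eff, model = fit)
}

#' Prune mutually rank-correlated ecological variables
#'
#' Computes all pairwise Spearman correlations and greedily resolves pairs
#' with `|rho| >= rho_max`: pairs are scanned in a deterministic order
#' (descending `|rho|`, then lexically by the pair's variable names) and the
#' second member (later in column order) of each still-offending pair is
#' dropped. Constant variables have undefined rank correlations; they are
#' excluded from the pruning decisions and flagged.
#'
#' @param env data.frame with a `population` column plus numeric variables,
#'   or a populations x variables matrix.
#' @param rho_max threshold; variables are retained while all pairwise
#'   `|rho| < rho_max`.
#' @return character vector of retained variable names, with attributes
#'   `dropped`, `constant` (flagged names) and `log` (the pair decisions).
#' @export
spearman_prune <- function(env, rho_max = 0.8) {
  x <- if (is.data.frame(env) && "population" %in% names(env)) {
    pop_table_matrix(env)
  } else {
    as.matrix(env)
  }
  if (ncol(x) < 2) stop("need at least two variables")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  constant <- colnames(x)[sds == 0]
  vars <- setdiff(colnames(x), constant)
  rho <- suppressWarnings(
    stats::cor(x[, vars, drop = FALSE], method = "spearman",
               use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(rho) & abs(rho) >= rho_max, arr.ind = TRUE)
  log_df <- data.frame(var1 = character(0), var2 = character(0),
                       rho = numeric(0), dropped = character(0),
                       stringsAsFactors = FALSE)
  dropped <- character(0)
  if (nrow(pairs) > 0) {
    pr <- data.frame(
      var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
      rho = rho[pairs], stringsAsFactors = FALSE)
    pr <- pr[order(-abs(pr$rho), pr$var1, pr$var2), , drop = FALSE]
    for (i in seq_len(nrow(pr))) {
      if (pr$var1[i] %in% dropped || pr$var2[i] %in% dropped) next
      dropped <- c(dropped, pr$var2[i])
      log_df <- rbind(log_df, data.frame(
        var1 = pr$var1[i], var2 = pr$var2[i], rho = pr$rho[i],
        dropped = pr$var2[i], stringsAsFactors = FALSE))
    }
  }
  retained <- setdiff(colnames(x), dropped)
  structure(retained, dropped = dropped, constant = constant, log = log_df)
}

#' PCA of the ecological variable table
#'
#' Principal component analysis on the correlation matrix (variables
#' standardized to zero mean, unit variance). Signs follow a deterministic
#' convention: each component is flipped so that its largest-magnitude
#' loading is positive.
#'
#' @param env data.frame with a `population` column plus numeric variables,
#'   or a matrix.
#' @return list: `scores` (populations x components), `loadings`,
#'   `var_explained` (proportion per component).
#' @export
env_pca <- function(env) {
  x <- if (is.data.frame(env) && "population" %in% names(env)) {
    pop_table_matrix(env)
  } else {
    as.matrix(env)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pr$rotation <- sweep(pr$rotation, 2, flip, `*`)
  pr$x <- sweep(pr$x, 2, flip, `*`)
  list(scores = pr$x, loadings = pr$rotation,
       var_explained = pr$sdev^2 / sum(pr$sdev^2))
}

#' Genomic principal components and their environmental correlations
#'
#' Singular value decomposition of the (column-centered) populations x SNPs
#' allele-frequency matrix, without population-structure correction: the
#' leading component summarizes the genomic variation among populations.
#' Reports the Pearson correlation of every ecological variable with PC1
#' and, when `latitude`/`longitude` columns are present, the linear model
#' `PC1 ~ latitude * longitude`.
#'
#' @param env ecological table (data.frame with `population` column or
#'   matrix); may be `NULL` to skip correlations.
#' @param freqs an `allele_freq` object.
#' @return list: `scores`, `var_explained`, `cor_pc1` (named vector),
#'   `geo_model` (lm fit or `NULL`).
#' @export
genomic_pc <- function(env, freqs) {
  stopifnot(inherits(freqs, "allele_freq"))
  if (nrow(freqs$freq) < 3) {
    stop("at least three populations are required")
  }
  x <- imputed_freq(freqs)
  x <- sweep(x, 2, colMeans(x), `-`)
  sv <- svd(x)
  flip <- apply(sv$u, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2, flip, `*`)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  var_explained <- sv$d^2 / sum(sv$d^2)
  cor_pc1 <- NULL
  geo_model <- NULL
  if (!is.null(env)) {
    e <- if (is.data.frame(env) && "population" %in% names(env)) {
      pop_table_matrix(env)
    } else {
      as.matrix(env)
    }
    if (!is.null(rownames(e)) && !is.null(rownames(scores)) &&
        all(rownames(scores) %in% rownames(e))) {
      e <- e[rownames(scores), , drop = FALSE]
    }
    cor_pc1 <- apply(e, 2, function(v) {
      if (stats::sd(v) == 0) NA_real_ else stats::cor(v, scores[, 1])
    })
    if (all(c("latitude", "longitude") %in% colnames(e))) {
      dat <- data.frame(pc1 = scores[, 1], latitude = e[, "latitude"],
                        longitude = e[, "longitude"])
      geo_model <- stats::lm(pc1 ~ latitude * longitude, data = dat)
    }
  }
  list(scores = scores, var_explained = var_explained, cor_pc1 = cor_pc1,
       geo_model = geo_model)
}
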