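#' Configuration for the Lindley local-score stage
#'
#' @param xi score offset: the per-SNP site score is `-log10(p) - xi`, so
#'   only SNPs with pseudo p-value below `10^-xi` contribute positively.
#'   The default 3 keeps the expected site score negative, making excursions
#'   of the Lindley process rare under the null.
#' @param alpha scaffold-level significance of a zone.
#' @param threshold_method how the per-scaffold significance threshold is
#'   obtained: `"resample"` (default) draws `n_resample` tracks of i.i.d.
#'   uniform pseudo p-values of the scaffold's length and takes the
#'   `1 - alpha` quantile of their Lindley maxima; `"permute"` permutes the
#'   observed site scores within the scaffold; `"gumbel"` fits a Gumbel
#'   location/scale to the resampled maxima and takes the analytic quantile.
#' @param n_resample number of resampled/permuted tracks per scaffold.
#' @param min_zone_snps minimum number of SNPs for a zone to be retained
#'   (default 4: strictly more than three).
#' @param seed integer seed for the resampling draws.
#' @return an object of class `local_score_config`.
#' @export
local_score_config <- function(xi = 3, alpha = 0.05,
                               threshold_method = c("resample", "permute",
                                                    "gumbel"),
                               n_resample = 1000, min_zone_snps = 4,
                               seed = 1) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(xi > 0, alpha > 0, alpha < 1, n_resample >= 10,
            min_zone_snps >= 1)
  structure(
    list(xi = xi, alpha = alpha, threshold_method = threshold_method,
         n_resample = as.integer(n_resample),
         min_zone_snps = as.integer(min_zone_snps), seed = as.integer(seed)),
    class = "local_score_config"
  )
}

#' Rank-based pseudo p-values
#'
#' `p_i = rank_i / N` with rank 1 for the largest score; ties are broken by
#' genomic position (the earlier SNP gets the smaller rank). Ranks are taken
#' over the full SNP set, not per scaffold.
#'
#' @param scores per-SNP real scores (e.g. BFdB or XtX), in genomic order.
#' @return numeric vector of pseudo p-values in (0, 1].
#' @export
pseudo_pvalues <- function(scores) {
  n <- length(scores)
  stopifnot(n >= 1)
  ord <- order(-scores, seq_len(n))
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  rank / n
}

# Vectorized Lindley recursion: h_i = max(0, h_{i-1} + x_i) equals
# S_i - min(0, min_{j<=i} S_j) for the running sum S.
lindley_track <- function(x) {
  s <- cumsum(x)
  s - pmin(0, cummin(s))
}

#' Lindley local-score process
#'
#' Per scaffold, the site score is `x_i = -log10(p_i) - xi` and the Lindley
#' score is `h_i = max(0, h_{i-1} + x_i)` with `h_0 = 0`; the process resets
#' at scaffold boundaries. Runs of positive `h` aggregate nearby weak
#' signals into region-level peaks.
#'
#' @param pseudo_p per-SNP pseudo p-values in (0, 1], genomic order.
#' @param xi score offset.
#' @param scaffold per-SNP scaffold labels (same length), or `NULL` for a
#'   single scaffold.
#' @return numeric vector of nonnegative Lindley scores.
#' @export
lindley <- function(pseudo_p, xi = 3, scaffold = NULL) {
  stopifnot(all(pseudo_p > 0), all(pseudo_p <= 1))
  x <- -log10(pseudo_p) - xi
  if (is.null(scaffold)) {
    return(lindley_track(x))
  }
  if (length(scaffold) != length(pseudo_p)) {
    stop("scaffold labels do not match the number of SNPs")
  }
  h <- numeric(length(x))
  for (s in unique(scaffold)) {
    i <- which(scaffold == s)
    h[i] <- lindley_track(x[i])
  }
  h
}

max_lindley <- function(x) {
  s <- cumsum(x)
  max(0, max(s - pmin(0, cummin(s))))
}

#' Per-scaffold significance thresholds for the Lindley score
#'
#' For each scaffold with at least `min_snps` SNPs, builds the null
#' distribution of the maximum Lindley score and returns its `1 - alpha`
#' quantile. The default `"resample"` method draws i.i.d. uniform pseudo
#' p-values (the null distribution of rank-based pseudo p-values on a null
#' scaffold), giving a continuous, well-calibrated null; `"permute"`
#' rearranges the observed site scores (conservative when few sites score
#' positively, because the permutation maxima then concentrate on a single
#' atom); `"gumbel"` fits a Gumbel to the resampled maxima by moments.
#'
#' @param pseudo_p per-SNP pseudo p-values.
#' @param scaffold per-SNP scaffold labels.
#' @param config a [local_score_config()].
#' @param min_snps scaffolds with fewer SNPs are skipped (threshold `NA`)
#'   with a warning.
#' @return named numeric vector of thresholds, one per scaffold.
#' @export
scaffold_threshold <- function(pseudo_p, scaffold, config = local_score_config(),
                               min_snps = 10) {
  stopifnot(inherits(config, "local_score_config"))
  # deterministic given config$seed, without clobbering the caller's RNG
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  scaffolds <- unique(scaffold)
  out <- stats::setNames(rep(NA_real_, length(scaffolds)), scaffolds)
  b <- config$n_resample
  k <- ceiling((1 - config$alpha) * (b + 1))
  if (k > b) k <- b
  for (s in scaffolds) {
    i <- which(scaffold == s)
    n <- length(i)
    if (n < min_snps) {
      warning(sprintf("scaffold %s has %d < %d SNPs; threshold skipped",
                      s, n, min_snps))
      next
    }
    maxima <- if (config$threshold_method == "permute") {
      x <- -log10(pseudo_p[i]) - config$xi
      vapply(seq_len(b), function(r) max_lindley(sample(x)), numeric(1))
    } else {
      vapply(seq_len(b), function(r) {
        max_lindley(-log10(stats::runif(n)) - config$xi)
      }, numeric(1))
    }
    out[s] <- if (config$threshold_method == "gumbel") {
      scale <- stats::sd(maxima) * sqrt(6) / pi
      loc <- mean(maxima) - 0.5772156649 * scale
      loc - scale * log(-log(1 - config$alpha))
    } else {
      sort(maxima)[k]
    }
  }
  out
}

#' Call significant zones from a Lindley track
#'
#' A zone is a maximal run of consecutive SNPs with positive Lindley score
#' whose maximum exceeds the scaffold threshold; zones with fewer than
#' `min_zone_snps` SNPs are dropped. The zone start is the first SNP of the
#' run and the end is the last SNP with positive score before the reset
#' (1-based inclusive positions at this interface).
#'
#' @param lindley_scores per-SNP Lindley scores.
#' @param thresholds named per-scaffold thresholds from
#'   [scaffold_threshold()].
#' @param snps SNP table with `scaffold` and `pos` (genomic order matching
#'   `lindley_scores`).
#' @param config a [local_score_config()].
#' @return data.frame of zones: scaffold, start, end, n_snps, peak,
#'   peak_pos.
#' @export
significant_zones <- function(lindley_scores, thresholds, snps,
                              config = local_score_config()) {
  stopifnot(length(lindley_scores) == nrow(snps))
  zones <- list()
  zid <- 0
  for (s in unique(snps$scaffold)) {
    thr <- thresholds[[s]]
    if (is.null(thr) || is.na(thr)) next
    i <- which(snps$scaffold == s)
    h <- lindley_scores[i]
    r <- rle(h > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (run in which(r$values)) {
      a <- starts[run]
      bb <- ends[run]
      n <- bb - a + 1
      peak <- max(h[a:bb])
      if (peak <= thr || n < config$min_zone_snps) next
      zid <- zid + 1
      peak_at <- i[a:bb][which.max(h[a:bb])]
      zones[[zid]] <- data.frame(
        zone = zid, scaffold = s, start = snps$pos[i[a]],
        end = snps$pos[i[bb]], n_snps = n, peak = peak,
        peak_pos = snps$pos[peak_at], stringsAsFactors = FALSE)
    }
  }
  if (length(zones) == 0) {
    return(data.frame(zone = integer(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), peak = numeric(0),
                      peak_pos = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, zones)
}

#' Full local-score scan of one score track
#'
#' Convenience wrapper chaining [pseudo_pvalues()], [lindley()],
#' [scaffold_threshold()] and [significant_zones()].
#'
#' @param scores per-SNP scores in genomic order (e.g. one BFdB column or
#'   XtX from a `scan_result`).
#' @param snps SNP table with `scaffold` and `pos`.
#' @param config a [local_score_config()].
#' @return list with `pseudo_p`, `lindley`, `thresholds`, `zones`.
#' @export
local_score_scan <- function(scores, snps, config = local_score_config()) {
  p <- pseudo_pvalues(scores)
  h <- lindley(p, config$xi, snps$scaffold)
  thr <- scaffold_threshold(p, snps$scaffold, config)
  zones <- significant_zones(h, thr, snps, config)
  list(pseudo_p = p, lindley = h, thresholds = thr, zones = zones)
}

#' Export zones as BED (0-based half-open)
#'
#' @param zones zone table from [significant_zones()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_zones_bed <- function(zones, path) {
  bed <- data.frame(zones$scaffold, zones$start - 1L, zones$end,
                    sprintf("zone%d", zones$zone), zones$peak)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
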