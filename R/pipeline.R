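#' Configuration for the end-to-end synthetic pipeline
#'
#' Collects every knob of the simulate -> filter -> GEA -> local score ->
#' enrichment -> genes chain. A single global `seed` is expanded into
#' per-stage seeds by fixed offsets (frequencies `seed`, spiking `seed + 1`,
#' environment `seed + 2`, reads `seed + 3`, visitation `seed + 4`,
#' thresholds `seed + 5`, enrichment `seed + 6`), so each stage is
#' independently reproducible.
#'
#' @param n_pops,n_snps,n_scaffolds,depth_mean,n_adaptive,beta,cluster_size
#'   see [sim_config()].
#' @param omega_type,omega_scale covariance structure passed to
#'   [make_omega()].
#' @param n_env_null number of additional null (non-causal) environmental
#'   variables.
#' @param tau,n_subdatasets see [gea_config()].
#' @param xi,alpha,n_resample,min_zone_snps see [local_score_config()].
#' @param tail_fraction,n_perm see [enrichment_table()].
#' @param seed global integer seed.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(n_pops = 21, n_snps = 20000, n_scaffolds = 20,
                            depth_mean = 60, n_adaptive = 50, beta = 0.2,
                            cluster_size = 10, omega_type = "spatial",
                            omega_scale = 0.05, n_env_null = 3, tau = 0.1,
                            n_subdatasets = 19, xi = 3, alpha = 0.05,
                            n_resample = 500, min_zone_snps = 4,
                            tail_fraction = 5e-4, n_perm = 1000, seed = 1) {
  cfg <- list(n_pops = n_pops, n_snps = n_snps, n_scaffolds = n_scaffolds,
              depth_mean = depth_mean, n_adaptive = n_adaptive, beta = beta,
              cluster_size = cluster_size, omega_type = omega_type,
              omega_scale = omega_scale, n_env_null = n_env_null, tau = tau,
              n_subdatasets = n_subdatasets, xi = xi, alpha = alpha,
              n_resample = n_resample, min_zone_snps = min_zone_snps,
              tail_fraction = tail_fraction, n_perm = n_perm,
              seed = as.integer(seed))
  stopifnot(n_env_null >= 0)
  # delegate the remaining validation to the stage configs
  sim_config(n_pops, n_snps, n_scaffolds,
             make_omega(n_pops, omega_type, scale = omega_scale),
             depth_mean = depth_mean, n_adaptive = n_adaptive, beta = beta,
             cluster_size = cluster_size, seed = seed)
  gea_config(tau = tau, n_subdatasets = n_subdatasets,
             tail_fraction = tail_fraction, xi = xi, seed = seed)
  local_score_config(xi = xi, alpha = alpha, n_resample = n_resample,
                     min_zone_snps = min_zone_snps, seed = seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, x)
}

#' Run the full synthetic pipeline
#'
#' Chains data generation, file round-trips, filtering, the GEA scan, the
#' local-score zone calling per variable (and for XtX), tail-overlap
#' enrichment, and candidate-gene mapping; writes every stage output as TSV
#' (plus VCF/GFF3/BED) under `outdir` together with a `manifest.json`
#' recording the configuration snapshot, seeds, file digests, stage timings
#' and package version. Outputs are byte-identical under a fixed seed and
#' configuration.
#'
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results (`truth`,
#'   `report`, `scan`, `local`, `enrichment`, `candidates`, `indices`,
#'   `manifest`).
#' @export
run_pipeline <- function(outdir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - start, 2)
  }

  # -- simulate ------------------------------------------------------------
  t <- proc.time()[["elapsed"]]
  sc <- sim_config(
    config$n_pops, config$n_snps, config$n_scaffolds,
    make_omega(config$n_pops, config$omega_type, scale = config$omega_scale),
    depth_mean = config$depth_mean, n_adaptive = config$n_adaptive,
    beta = config$beta, cluster_size = config$cluster_size,
    seed = config$seed)
  sim <- simulate_frequencies(sc)
  env <- simulate_environment(sc)
  sp <- spike_environment(sim$freqs, env, sc, sim$truth)
  counts <- simulate_pool_reads(sp$freqs, config$depth_mean,
                                seed = config$seed + 3L)
  vis <- simulate_visitation(config$n_pops, seed = config$seed + 4L)
  indices <- network_indices(vis$matrix)
  env_table <- cbind(
    env_causal = env,
    vapply(seq_len(config$n_env_null), function(i) {
      set.seed(config$seed + 100L + i)
      stats::rnorm(config$n_pops)
    }, numeric(config$n_pops)),
    partner_diversity = indices$partner_diversity,
    d_index = indices$d_index)
  if (config$n_env_null > 0) {
    colnames(env_table)[2:(1 + config$n_env_null)] <-
      paste0("env_null", seq_len(config$n_env_null))
  }
  rownames(env_table) <- counts$pops
  paths <- write_synthetic_inputs(counts, env_table, vis$matrix, outdir)
  tick("simulate", t)

  # -- read back and filter ------------------------------------------------
  t <- proc.time()[["elapsed"]]
  counts_in <- read_pool_vcf(paths$vcf)
  env_in <- read_pop_table(paths$env)
  flt <- filter_snps(counts_in)
  freqs <- allele_frequencies(flt$counts)
  jsonlite::write_json(unclass(flt$report),
                       file.path(outdir, "filter_report.json"),
                       auto_unbox = TRUE)
  tick("filter", t)

  # -- ecology -------------------------------------------------------------
  t <- proc.time()[["elapsed"]]
  utils::write.table(indices, file.path(outdir, "network_indices.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  retained <- spearman_prune(env_in)
  tick("ecology", t)

  # -- GEA scan ------------------------------------------------------------
  t <- proc.time()[["elapsed"]]
  gc_cfg <- gea_config(tau = config$tau, n_subdatasets = config$n_subdatasets,
                       tail_fraction = config$tail_fraction, xi = config$xi,
                       seed = config$seed)
  scan <- suppressMessages(
    run_gea(freqs, env_in[, c("population", retained)], gc_cfg))
  utils::write.table(as.data.frame(scan), file.path(outdir, "scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan$omega$omega, file.path(outdir, "omega.tsv"),
                     sep = "\t", quote = FALSE)
  tick("scan", t)

  # -- local score ---------------------------------------------------------
  t <- proc.time()[["elapsed"]]
  ls_cfg <- local_score_config(
    xi = config$xi, alpha = config$alpha, n_resample = config$n_resample,
    min_zone_snps = config$min_zone_snps, seed = config$seed + 5L)
  local <- list()
  lind <- matrix(NA_real_, nrow(scan$snps), length(scan$variables),
                 dimnames = list(NULL, scan$variables))
  zones_all <- list()
  for (v in scan$variables) {
    res <- local_score_scan(scan$bf[, v], scan$snps, ls_cfg)
    lind[, v] <- res$lindley
    if (nrow(res$zones) > 0) res$zones$variable <- v
    zones_all[[v]] <- res$zones
    local[[v]] <- res
  }
  local$xtx <- local_score_scan(scan$xtx, scan$snps, ls_cfg)
  nonempty <- zones_all[vapply(zones_all, nrow, 0L) > 0]
  zones <- if (length(nonempty) > 0) {
    do.call(rbind, c(nonempty, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  if (is.null(zones)) {
    zones <- data.frame(zone = integer(0), scaffold = character(0),
                        start = integer(0), end = integer(0),
                        n_snps = integer(0), peak = numeric(0),
                        peak_pos = integer(0), variable = character(0))
  } else {
    zones$zone <- seq_len(nrow(zones))
  }
  utils::write.table(zones, file.path(outdir, "zones.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(zones) > 0) {
    write_zones_bed(zones, file.path(outdir, "zones.bed"))
  }
  tick("local_score", t)

  # -- enrichment ----------------------------------------------------------
  t <- proc.time()[["elapsed"]]
  enr <- enrichment_table(lind, scan$xtx, fraction = config$tail_fraction,
                          n_perm = config$n_perm, seed = config$seed + 6L)
  utils::write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tick("enrichment", t)

  # -- candidate genes -----------------------------------------------------
  t <- proc.time()[["elapsed"]]
  genes <- read_gene_annotation(paths$gff)
  candidates <- zone_to_genes(zones, genes)
  utils::write.table(candidates, file.path(outdir, "candidate_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  shared <- if (nrow(candidates) > 0 && "variable" %in% names(candidates)) {
    shared_gene_sets(split(candidates$gene_id, candidates$variable))
  } else {
    NULL
  }
  if (!is.null(shared)) {
    utils::write.table(shared$exclusive,
                       file.path(outdir, "gene_set_intersections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("genes", t)

  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "poolgea",
    version = as.character(utils::packageVersion("poolgea")),
    config = unclass(config),
    seeds = list(frequencies = config$seed, spike = config$seed + 1,
                 environment = config$seed + 2, reads = config$seed + 3,
                 visitation = config$seed + 4, thresholds = config$seed + 5,
                 enrichment = config$seed + 6),
    inputs = as.list(tools::md5sum(unlist(paths))),
    outputs = as.list(tools::md5sum(outputs)),
    timings = timings,
    total_seconds = round(proc.time()[["elapsed"]] - t0, 2))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(truth = sp$truth, report = flt$report, scan = scan,
                 local = local, enrichment = enr, candidates = candidates,
                 indices = indices, zones = zones, manifest = manifest))
}
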