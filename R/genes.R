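#' Read a gene annotation from GFF3
#'
#' Imports a GFF3 file and keeps `gene` features as a data.frame of 1-based
#' inclusive intervals with a `gene_id` taken from the `ID` (or `Name`)
#' attribute.
#'
#' @param path GFF3 file.
#' @return data.frame: gene_id, scaffold, start, end, strand.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) == "gene"]
  }
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  data.frame(
    gene_id = id,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Map significant zones to candidate genes
#'
#' Candidates for a zone are all genes overlapping the zone interval by at
#' least one base pair, plus the single nearest non-overlapping gene on each
#' side (upstream and downstream in coordinate order, strand-agnostic; zones
#' are not stranded). Results are deduplicated and independent of the gene
#' record order.
#'
#' @param zones zone table from [significant_zones()] (1-based inclusive
#'   `start`/`end`), optionally with a `variable` column.
#' @param genes gene table from [read_gene_annotation()] (or any data.frame
#'   with gene_id, scaffold, start, end).
#' @return data.frame: zone, scaffold, gene_id, relation (one of
#'   `overlap`, `upstream`, `downstream`), plus `variable` when present.
#'   Zones on unannotated scaffolds yield no rows and a warning.
#' @export
zone_to_genes <- function(zones, genes) {
  stopifnot(all(c("scaffold", "start", "end") %in% names(zones)),
            all(c("gene_id", "scaffold", "start", "end") %in% names(genes)))
  if (nrow(zones) == 0) {
    return(data.frame(zone = integer(0), scaffold = character(0),
                      gene_id = character(0), relation = character(0),
                      stringsAsFactors = FALSE))
  }
  genes <- genes[order(genes$scaffold, genes$start), , drop = FALSE]
  gene_gr <- GenomicRanges::GRanges(
    genes$scaffold, IRanges::IRanges(genes$start, genes$end))
  zone_gr <- GenomicRanges::GRanges(
    zones$scaffold, IRanges::IRanges(zones$start, zones$end))
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(zone_gr, gene_gr))
  rows <- list()
  zone_ids <- if ("zone" %in% names(zones)) zones$zone else seq_len(nrow(zones))
  for (k in seq_len(nrow(zones))) {
    sc <- zones$scaffold[k]
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    if (nrow(g) == 0) {
      warning(sprintf("zone %s:%d-%d lies on an unannotated scaffold",
                      sc, zones$start[k], zones$end[k]))
      next
    }
    ov_idx <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]
    ov_ids <- genes$gene_id[ov_idx]
    up <- g[g$end < zones$start[k], , drop = FALSE]
    up_id <- if (nrow(up)) up$gene_id[which.max(up$end)] else character(0)
    dn <- g[g$start > zones$end[k], , drop = FALSE]
    dn_id <- if (nrow(dn)) dn$gene_id[which.min(dn$start)] else character(0)
    df <- data.frame(
      zone = zone_ids[k], scaffold = sc,
      gene_id = c(ov_ids, up_id, dn_id),
      relation = c(rep("overlap", length(ov_ids)),
                   rep("upstream", length(up_id)),
                   rep("downstream", length(dn_id))),
      stringsAsFactors = FALSE)
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
    if ("variable" %in% names(zones)) df$variable <- zones$variable[k]
    rows[[length(rows) + 1]] <- df
  }
  if (length(rows) == 0) {
    return(data.frame(zone = integer(0), scaffold = character(0),
                      gene_id = character(0), relation = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclusive intersection sizes of per-variable candidate-gene sets
#'
#' Upset-style decomposition: for every combination of variables that at
#' least one gene belongs to exactly, reports the exclusive intersection
#' size. The exclusive counts sum to the union size by construction.
#'
#' @param sets named list of character vectors (candidate gene ids per
#'   variable).
#' @return list with `exclusive` (data.frame: combination, degree, count),
#'   `set_sizes` (named vector), `union_size`, and `unique_counts` (per
#'   variable, genes in no other set).
#' @export
shared_gene_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets, use.names = FALSE))
  if (length(all_genes) == 0) {
    return(list(
      exclusive = data.frame(combination = character(0), degree = integer(0),
                             count = integer(0), stringsAsFactors = FALSE),
      set_sizes = vapply(sets, length, integer(1)),
      union_size = 0L,
      unique_counts = vapply(sets, function(x) 0L, integer(1))))
  }
  membership <- vapply(sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, names(sets)))
  pattern <- apply(membership, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  tab <- table(pattern)
  exclusive <- data.frame(
    combination = names(tab),
    degree = vapply(strsplit(names(tab), "&", fixed = TRUE), length,
                    integer(1)),
    count = as.integer(tab), stringsAsFactors = FALSE)
  exclusive <- exclusive[order(-exclusive$count, exclusive$combination), ,
                         drop = FALSE]
  rownames(exclusive) <- NULL
  unique_counts <- vapply(names(sets), function(v) {
    sum(membership[, v] & rowSums(membership) == 1)
  }, integer(1))
  list(exclusive = exclusive,
       set_sizes = vapply(sets, length, integer(1)),
       union_size = length(all_genes),
       unique_counts = unique_counts)
}
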