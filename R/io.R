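#' Allele read counts from pooled sequencing
#'
#' Container for per-SNP, per-population reference/alternate read counts.
#' Count matrices are populations x SNPs; a cell with zero total depth is a
#' missing observation (the pool was not sequenced at that site).
#'
#' @param snps data.frame with columns `scaffold`, `pos` (1-based),
#'   `ref`, `alt`, and optionally logical `multiallelic` and `indel` flags.
#' @param ref_count,alt_count integer matrices, populations x SNPs.
#' @return an object of class `pool_counts`.
#' @export
pool_counts <- function(snps, ref_count, alt_count) {
  stopifnot(is.data.frame(snps),
            all(c("scaffold", "pos", "ref", "alt") %in% names(snps)),
            all(dim(ref_count) == dim(alt_count)),
            ncol(ref_count) == nrow(snps))
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE)) {
    stop("read counts must be nonnegative")
  }
  if (is.null(snps$multiallelic)) snps$multiallelic <- grepl(",", snps$alt)
  if (is.null(snps$indel)) {
    snps$indel <- nchar(snps$ref) > 1 |
      vapply(strsplit(snps$alt, ","),
             function(a) any(nchar(a) > 1), logical(1))
  }
  ord <- order(snps$scaffold, snps$pos)
  if (is.unsorted(ord)) {
    snps <- snps[ord, , drop = FALSE]
    ref_count <- ref_count[, ord, drop = FALSE]
    alt_count <- alt_count[, ord, drop = FALSE]
    rownames(snps) <- NULL
  }
  if (any(duplicated(paste(snps$scaffold, snps$pos)))) {
    stop("positions must be unique within scaffold")
  }
  if (nrow(snps) > 0) {
    ids <- paste0(snps$scaffold, ":", snps$pos)
    colnames(ref_count) <- colnames(alt_count) <- ids
  }
  if (is.null(rownames(ref_count))) {
    rownames(ref_count) <- rownames(alt_count) <-
      sprintf("pool%02d", seq_len(nrow(ref_count)))
  }
  structure(
    list(snps = snps, ref_count = ref_count, alt_count = alt_count,
         pops = rownames(ref_count)),
    class = "pool_counts"
  )
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts: %d SNPs x %d populations on %d scaffolds\n",
              nrow(x$snps), length(x$pops), length(unique(x$snps$scaffold))))
  invisible(x)
}

#' Population x SNP allele-frequency matrix
#'
#' @param freq numeric matrix of alternate-allele frequencies, populations x
#'   SNPs, `NA` where the pool had zero depth.
#' @param snps SNP index table as in [pool_counts()].
#' @param pi optional per-SNP mean frequency; computed as the unweighted
#'   across-population mean of the non-missing frequencies if omitted (the
#'   population, not the read, is the unit of replication).
#' @return an object of class `allele_freq` with elements `freq`, `pi`,
#'   `snps`, `pops`.
#' @export
allele_freq <- function(freq, snps, pi = NULL) {
  stopifnot(is.matrix(freq), ncol(freq) == nrow(snps))
  if (is.null(pi)) pi <- colMeans(freq, na.rm = TRUE)
  structure(
    list(freq = freq, pi = as.numeric(pi), snps = snps,
         pops = rownames(freq)),
    class = "allele_freq"
  )
}

#' @export
print.allele_freq <- function(x, ...) {
  cat(sprintf("allele_freq: %d populations x %d SNPs (%.2f%% missing)\n",
              nrow(x$freq), ncol(x$freq), 100 * mean(is.na(x$freq))))
  invisible(x)
}

#' Mean-impute missing cells of an allele-frequency matrix
#'
#' Missing `p_ij` are replaced by the per-SNP mean `pi_j`. With at most a
#' couple of populations missing per retained SNP this keeps the linear
#' algebra dense at minimal bias.
#'
#' @param freqs an `allele_freq` object.
#' @return numeric matrix with no `NA`s.
#' @export
imputed_freq <- function(freqs) {
  p <- freqs$freq
  if (anyNA(p)) {
    miss <- which(is.na(p), arr.ind = TRUE)
    p[miss] <- freqs$pi[miss[, 2]]
  }
  p
}

#' Read a pooled VCF into a count matrix
#'
#' Parses a VCF with one sample per population pool and per-sample `AD`
#' (allelic depth) fields. Multiallelic records are retained at parse time
#' and flagged for the filtering stage; for those records the alternate
#' count is the sum over alternate alleles. Cells with zero total depth are
#' recorded as missing.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_order optional character vector giving the population order
#'   to enforce; must match the VCF sample names exactly as a set.
#' @return a `pool_counts` object.
#' @export
read_pool_vcf <- function(path, sample_order = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  fmt <- v@gt[, "FORMAT"]
  no_ad <- !grepl("(^|:)AD(:|$)", fmt)
  if (any(no_ad)) {
    i <- which(no_ad)[1]
    stop(sprintf("record %s:%s has no AD field in FORMAT",
                 fix[i, "CHROM"], fix[i, "POS"]))
  }
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_order)) {
    if (!setequal(samples, sample_order)) {
      stop("sample_order does not match the VCF sample names")
    }
  } else {
    sample_order <- samples
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  ad <- ad[, sample_order, drop = FALSE]
  n_rec <- nrow(ad)
  parse_col <- function(s) {
    parts <- strsplit(ifelse(is.na(s) | s == ".", "0,0", s), ",", fixed = TRUE)
    ref <- vapply(parts, function(x) suppressWarnings(as.integer(x[1])),
                  integer(1))
    alt <- vapply(parts, function(x) {
      a <- suppressWarnings(as.integer(x[-1]))
      if (length(a) == 0 || all(is.na(a))) 0L else sum(a, na.rm = TRUE)
    }, integer(1))
    ref[is.na(ref)] <- 0L
    cbind(ref, alt)
  }
  ref_count <- matrix(0L, length(sample_order), n_rec,
                      dimnames = list(sample_order, NULL))
  alt_count <- ref_count
  for (s in sample_order) {
    rc <- parse_col(ad[, s])
    ref_count[s, ] <- rc[, 1]
    alt_count[s, ] <- rc[, 2]
  }
  snps <- data.frame(
    scaffold = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE)
  colnames(ref_count) <- colnames(alt_count) <-
    paste0(snps$scaffold, ":", snps$pos)
  pool_counts(snps, ref_count, alt_count)
}

#' Filter report
#'
#' Per-step removal counts of [filter_snps()]. Steps are sequential, so each
#' count is taken on the set surviving the previous step and
#' `n_retained = n_input - sum(removals)`.
#'
#' @param x a `filter_report`.
#' @param ... unused.
#' @name filter_report
#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filtering (sequential):\n")
  cat(sprintf("  input                %9d\n", x$n_input))
  cat(sprintf("  - multiallelic       %9d\n", x$n_removed_multiallelic))
  cat(sprintf("  - indel              %9d\n", x$n_removed_indel))
  cat(sprintf("  - mean depth         %9d\n", x$n_removed_depth))
  cat(sprintf("  - missingness        %9d\n", x$n_removed_missing))
  cat(sprintf("  - scaffold subset    %9d\n", x$n_removed_scaffold))
  cat(sprintf("  retained             %9d\n", x$n_retained))
  invisible(x)
}

#' Apply the standard pool-seq SNP filters
#'
#' Sequentially removes (1) non-biallelic sites, (2) indels, (3) sites whose
#' mean read depth across populations is below `depth_min` or above
#' `depth_max`, (4) sites with missing values (zero depth) in more than
#' `max_missing_pops` populations, and (5) sites outside
#' `scaffold_whitelist`. The mean depth is taken over non-missing
#' populations: a zero-coverage pool is a missingness event, handled by the
#' missingness filter, not a depth observation.
#'
#' @param counts a `pool_counts` object.
#' @param depth_min,depth_max bounds on the mean read depth (a site is kept
#'   when `depth_min <= mean depth <= depth_max`).
#' @param max_missing_pops maximum number of populations allowed to be
#'   missing at a retained site.
#' @param scaffold_whitelist scaffolds to keep (`NULL` = all).
#' @return list with filtered `counts` and a `filter_report`.
#' @export
filter_snps <- function(counts, depth_min = 6, depth_max = 100,
                        max_missing_pops = 2, scaffold_whitelist = NULL) {
  stopifnot(inherits(counts, "pool_counts"))
  keep <- rep(TRUE, nrow(counts$snps))
  step <- function(drop) {
    n <- sum(keep & drop)
    keep[drop] <<- FALSE
    n
  }
  n_input <- nrow(counts$snps)
  n_multi <- step(counts$snps$multiallelic)
  n_indel <- step(keep & counts$snps$indel)
  depth <- counts$ref_count + counts$alt_count
  mean_depth <- apply(depth, 2, function(d) {
    d <- d[d > 0]
    if (length(d) == 0) 0 else mean(d)
  })
  n_depth <- step(keep & (mean_depth < depth_min | mean_depth > depth_max))
  n_miss_pop <- colSums(depth == 0)
  n_missing <- step(keep & (n_miss_pop > max_missing_pops))
  n_scaff <- if (is.null(scaffold_whitelist)) 0L else {
    step(keep & !(counts$snps$scaffold %in% scaffold_whitelist))
  }
  report <- structure(
    list(n_input = n_input, n_removed_multiallelic = n_multi,
         n_removed_indel = n_indel, n_removed_depth = n_depth,
         n_removed_missing = n_missing, n_removed_scaffold = n_scaff,
         n_retained = sum(keep)),
    class = "filter_report"
  )
  if (!any(keep)) warning("no SNPs retained after filtering")
  out <- pool_counts(
    counts$snps[keep, , drop = FALSE],
    counts$ref_count[, keep, drop = FALSE],
    counts$alt_count[, keep, drop = FALSE])
  list(counts = out, report = report)
}

#' Estimate population allele frequencies from pooled counts
#'
#' `p_ij = alt / (ref + alt)`, missing where the depth is zero. The per-SNP
#' mean `pi_j` is the unweighted mean over non-missing populations.
#'
#' @param counts a (filtered) `pool_counts` object.
#' @return an `allele_freq` object.
#' @export
allele_frequencies <- function(counts) {
  stopifnot(inherits(counts, "pool_counts"))
  depth <- counts$ref_count + counts$alt_count
  p <- counts$alt_count / depth
  p[depth == 0] <- NA_real_
  all_missing <- colSums(!is.na(p)) == 0
  if (any(all_missing)) {
    stop(sprintf(
      "%d SNP(s) missing in every population (e.g. %s); filter first",
      sum(all_missing),
      colnames(p)[which(all_missing)[1]]))
  }
  allele_freq(p, counts$snps)
}

#' Write a pooled VCF
#'
#' Emits a minimal VCF 4.2 with per-sample `DP` and `AD` (ref,alt) fields,
#' one sample per population. Round-trips losslessly through
#' [read_pool_vcf()].
#'
#' @param counts a `pool_counts` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(counts, path) {
  stopifnot(inherits(counts, "pool_counts"))
  snps <- counts$snps
  scaffolds <- unique(snps$scaffold)
  contig_len <- vapply(scaffolds, function(s) {
    max(snps$pos[snps$scaffold == s]) + 1000L
  }, integer(1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolgea",
    sprintf("##contig=<ID=%s,length=%d>", scaffolds, contig_len),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic Depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", counts$pops), collapse = "\t")
  )
  depth <- counts$ref_count + counts$alt_count
  gt <- matrix(sprintf("%d:%d,%d", depth, counts$ref_count,
                       counts$alt_count),
               nrow(depth), ncol(depth))
  body <- paste(
    snps$scaffold, snps$pos, ".", snps$ref, snps$alt, ".", ".", ".",
    "DP:AD", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write/read a population-by-variable TSV table
#'
#' Plain TSV with a `population` first column; used for both ecological
#' variables and visitation counts.
#'
#' @param x data.frame or matrix with populations as rows.
#' @param path file path.
#' @return `path` (write) or a data.frame with `population` column (read).
#' @export
write_pop_table <- function(x, path) {
  df <- as.data.frame(x)
  df <- cbind(population = rownames(df), df)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pop_table
#' @export
read_pop_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "population") {
    stop("expected a 'population' first column in ", path)
  }
  df
}

pop_table_matrix <- function(df) {
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$population
  m
}

#' Write a toy GFF3 gene annotation tiled over scaffolds
#'
#' Genes of fixed length are laid out at a regular spacing along each
#' scaffold, giving a known layout for testing candidate-gene mapping.
#'
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @param path output file.
#' @param gene_length,gene_spacing layout parameters in bp.
#' @return invisibly, the data.frame of genes written.
#' @export
write_toy_gff3 <- function(scaffold_lengths, path, gene_length = 2000,
                           gene_spacing = 5000) {
  rows <- list()
  gid <- 0
  for (s in names(scaffold_lengths)) {
    starts <- seq(1, max(1, scaffold_lengths[s] - gene_length),
                  by = gene_spacing)
    for (st in starts) {
      gid <- gid + 1
      rows[[gid]] <- data.frame(
        scaffold = s, start = as.integer(st),
        end = as.integer(st + gene_length - 1),
        strand = if (gid %% 2 == 0) "-" else "+",
        gene_id = sprintf("gene%05d", gid), stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", names(scaffold_lengths),
            scaffold_lengths),
    sprintf("%s\tpoolgea\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
            genes$scaffold, genes$start, genes$end, genes$strand,
            genes$gene_id, genes$gene_id)
  )
  writeLines(lines, path)
  invisible(genes)
}

#' Write the full set of synthetic inputs to a directory
#'
#' Emits the pooled VCF (`pooled.vcf`), the ecological variable table
#' (`env.tsv`), the visitation matrix (`visitation.tsv`) and a toy gene
#' annotation (`genes.gff3`), all of which round-trip through the package's
#' readers.
#'
#' @param counts a `pool_counts` object.
#' @param env data.frame/matrix of ecological variables (populations x
#'   variables) or a single numeric covariate.
#' @param visitation populations x categories count matrix.
#' @param outdir output directory (created if needed).
#' @param gene_length,gene_spacing toy annotation layout.
#' @return named list of file paths.
#' @export
write_synthetic_inputs <- function(counts, env, visitation, outdir,
                                   gene_length = 2000, gene_spacing = 5000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(outdir, "pooled.vcf"),
    env = file.path(outdir, "env.tsv"),
    visitation = file.path(outdir, "visitation.tsv"),
    gff = file.path(outdir, "genes.gff3"))
  write_pool_vcf(counts, paths$vcf)
  if (is.null(dim(env))) {
    env <- matrix(env, ncol = 1, dimnames = list(counts$pops, "env1"))
  }
  write_pop_table(env, paths$env)
  write_pop_table(visitation, paths$visitation)
  scaffolds <- unique(counts$snps$scaffold)
  lens <- vapply(scaffolds, function(s) {
    max(counts$snps$pos[counts$snps$scaffold == s]) + 1000L
  }, integer(1))
  write_toy_gff3(lens, paths$gff, gene_length, gene_spacing)
  paths
}
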