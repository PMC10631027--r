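#' Tally per-site, per-sample CpG counts
#'
#' Aggregates read-level CpG calls into a long table of methylated / total
#' counts per CpG site per sample. Sites covered below `min_coverage` in a
#' sample are dropped for that sample.
#'
#' @param reads a [methyl_reads] table (one or more samples).
#' @param min_coverage minimum reads covering a site in a sample (default 1).
#' @return data.table with columns `chrom`, `pos`, `sample_id`, `meth`,
#'   `total`.
#' @export
aggregate_cpg_counts <- function(reads, min_coverage = 1) {
  reads <- as.data.table(reads)
  k <- lengths(reads$cpg_positions)
  if (sum(k) == 0L)
    return(data.table(chrom = character(0), pos = integer(0),
                      sample_id = character(0), meth = integer(0),
                      total = integer(0)))
  long <- data.table(chrom = rep(reads$chrom, k),
                     pos = unlist(reads$cpg_positions),
                     sample_id = rep(reads$sample_id, k),
                     call = unlist(reads$cpg_calls))
  counts <- long[, .(meth = sum(call), total = .N), by = .(chrom, pos, sample_id)]
  counts <- counts[total >= min_coverage]
  setorder(counts, chrom, pos, sample_id)
  counts[]
}

#' Two-sided Fisher's exact test for 2x2 count tables (vectorised)
#'
#' Conditional on both margins, the first cell is hypergeometric; the
#' two-sided p-value sums the probabilities of all tables whose likelihood
#' does not exceed that of the observed table (the same definition as
#' `stats::fisher.test`).
#'
#' @param a,b successes / failures in group 1.
#' @param c_,d successes / failures in group 2.
#' @return numeric vector of p-values.
#' @export
fisher_test_2x2 <- function(a, b, c_, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c_) == n, length(d) == n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + c_[i]           # total successes
    nn <- b[i] + d[i]           # total failures
    kk <- a[i] + b[i]           # group 1 size
    lo <- max(0L, kk - nn); hi <- min(kk, m)
    support <- lo:hi
    dens <- dhyper(support, m, nn, kk)
    obs <- dens[support == a[i]]
    # relative tolerance guards against ties broken by floating-point noise
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  p
}

#' Call differentially methylated CpG sites (DMCs)
#'
#' Pools counts within each group, tests each site with a two-sided Fisher's
#' exact test, adjusts p-values with Benjamini-Hochberg across all tested
#' sites, and retains sites with `q < q_threshold` and an absolute
#' methylation difference (percentage points, group1 - group2) strictly
#' greater than `diff_threshold`. Direction is `hyper` when group 1 (tumor)
#' is more methylated, `hypo` otherwise.
#'
#' @param counts output of [aggregate_cpg_counts].
#' @param groups named character vector mapping `sample_id` to group.
#' @param group1,group2 the two group labels to contrast (tumor vs
#'   para-tumor by default).
#' @param q_threshold BH-adjusted significance cutoff (default 0.01).
#' @param diff_threshold methylation-difference cutoff in percentage points
#'   (default 25; strict inequality).
#' @param min_group_coverage minimum pooled coverage per group at a site for
#'   the site to be tested (default 5).
#' @return data.table of all tested sites (`chrom`, `pos`, `meth_diff`,
#'   `p_value`, `q_value`, `direction`, `is_dmc`); DMCs have `is_dmc == TRUE`.
#' @export
call_dmcs <- function(counts, groups, group1 = "tumor-tissue",
                      group2 = "para-tumor-tissue", q_threshold = 0.01,
                      diff_threshold = 25, min_group_coverage = 5) {
  counts <- as.data.table(counts)
  counts[, group := groups[sample_id]]
  pooled <- counts[group %in% c(group1, group2),
                   .(meth = sum(meth), total = sum(total)),
                   by = .(chrom, pos, group)]
  wide <- dcast(pooled, chrom + pos ~ group, value.var = c("meth", "total"),
                fill = 0L)
  m1 <- paste0("meth_", group1); t1 <- paste0("total_", group1)
  m2 <- paste0("meth_", group2); t2 <- paste0("total_", group2)
  for (col in c(m1, t1, m2, t2))
    if (!col %in% names(wide)) wide[, (col) := 0L]
  tested <- wide[get(t1) >= min_group_coverage & get(t2) >= min_group_coverage]
  if (nrow(tested) == 0L)
    return(data.table(chrom = character(0), pos = integer(0),
                      meth_diff = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), direction = character(0),
                      is_dmc = logical(0)))
  a <- tested[[m1]]; ta <- tested[[t1]]
  b <- tested[[m2]]; tb <- tested[[t2]]
  out <- data.table(chrom = tested$chrom, pos = tested$pos)
  out[, meth_diff := 100 * (a / ta - b / tb)]
  out[, p_value := fisher_test_2x2(a, ta - a, b, tb - b)]
  out[, q_value := p.adjust(p_value, method = "BH")]
  out[, direction := ifelse(meth_diff > 0, "hyper", "hypo")]
  out[, is_dmc := q_value < q_threshold & abs(meth_diff) > diff_threshold]
  setorder(out, chrom, pos)
  out[]
}

#' Assemble DMCs into differentially methylated regions (DMRs)
#'
#' Walks DMCs in genomic order and joins consecutive same-direction DMCs
#' whose gap does not exceed `max_gap` into runs; runs with at least
#' `min_dmcs` members become DMRs. A direction change or a chromosome change
#' breaks a run. The DMR span is `[first DMC, last DMC + 2)`, covering the
#' final CpG dinucleotide.
#'
#' @param dmcs data.table with `chrom`, `pos`, `direction` (e.g. the
#'   `is_dmc` rows of [call_dmcs]).
#' @param min_dmcs minimum DMCs per region (default 5).
#' @param max_gap maximum distance between consecutive DMCs in bp
#'   (default 300).
#' @return data.table with `dmr_id`, `chrom`, `start`, `end`, `direction`,
#'   `n_dmcs` and a list column `dmc_positions`.
#' @export
assemble_dmrs <- function(dmcs, min_dmcs = 5, max_gap = 300) {
  dmcs <- as.data.table(dmcs)
  if ("is_dmc" %in% names(dmcs)) dmcs <- dmcs[is_dmc == TRUE]
  empty <- data.table(dmr_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      direction = character(0), n_dmcs = integer(0),
                      dmc_positions = list())
  if (nrow(dmcs) == 0L) return(empty)
  setorder(dmcs, chrom, pos)
  new_run <- c(TRUE, dmcs$chrom[-1] != dmcs$chrom[-nrow(dmcs)] |
                 dmcs$direction[-1] != dmcs$direction[-nrow(dmcs)] |
                 diff(dmcs$pos) > max_gap)
  dmcs[, run := cumsum(new_run)]
  dmrs <- dmcs[, .(chrom = chrom[1], start = min(pos),
                   end = max(pos) + 2L, direction = direction[1],
                   n_dmcs = .N, dmc_positions = list(pos)),
               by = run]
  dmrs <- dmrs[n_dmcs >= min_dmcs]
  if (nrow(dmrs) == 0L) return(empty)
  setorder(dmrs, chrom, start)
  dmrs[, dmr_id := sprintf("dmr_%05d", seq_len(.N))]
  dmrs[, run := NULL]
  setcolorder(dmrs, c("dmr_id", "chrom", "start", "end", "direction",
                      "n_dmcs", "dmc_positions"))
  dmrs[]
}

#' Assign DMR-related genes by TSS proximity
#'
#' A gene is assigned to a DMR when the window `TSS +/- flank` overlaps the
#' DMR interval (0-based half-open).
#'
#' @param dmrs output of [assemble_dmrs].
#' @param tss data.table/data.frame with `chrom`, `pos` (0-based TSS
#'   coordinate) and `gene`, or a path to a BED file (`chrom`, `start`,
#'   `end`, `name`; the TSS is taken as `start`).
#' @param flank window half-width in bp (default 2000).
#' @return `dmrs` with an added list column `genes`.
#' @export
annotate_dmr_genes <- function(dmrs, tss, flank = 2000) {
  dmrs <- as.data.table(dmrs)
  if (is.character(tss) && length(tss) == 1L) {
    if (!file.exists(tss)) {
      warning("TSS BED not found; annotation skipped")
      dmrs[, genes := list(rep(list(character(0)), .N))]
      return(dmrs[])
    }
    bed <- fread(tss, header = FALSE)
    tss <- data.table(chrom = bed$V1, pos = bed$V2, gene = bed$V4)
  }
  tss <- as.data.table(tss)
  dmr_gr <- GenomicRanges::GRanges(dmrs$chrom,
    IRanges::IRanges(start = dmrs$start + 1L, end = dmrs$end))
  tss_gr <- GenomicRanges::GRanges(tss$chrom,
    IRanges::IRanges(start = pmax(1L, tss$pos + 1L - flank),
                     end = tss$pos + 1L + flank))
  hits <- GenomicRanges::findOverlaps(dmr_gr, tss_gr)
  genes <- rep(list(character(0)), nrow(dmrs))
  if (length(hits)) {
    sp <- split(tss$gene[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (q in names(sp)) genes[[as.integer(q)]] <- sort(unique(sp[[q]]))
  }
  dmrs[, genes := genes]
  dmrs[]
}

#' Write DMRs as BED plus a statistics TSV
#'
#' BED columns: chrom, start, end, name (`dmr_id`), score (`n_dmcs`),
#' strand (`.`). The companion TSV (same stem, `.tsv`) adds direction,
#' member DMC positions and, when present, filter statistics.
#'
#' @param dmrs DMR table.
#' @param path output BED path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dmrs <- as.data.table(dmrs)
  bed <- dmrs[, .(chrom, start, end, name = dmr_id, score = n_dmcs,
                  strand = ".")]
  fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  extra <- copy(dmrs)
  extra[, dmc_positions := vapply(dmc_positions, paste, "", collapse = ",")]
  if ("genes" %in% names(extra))
    extra[, genes := vapply(genes, paste, "", collapse = ",")]
  fwrite(extra, sub("\\.bed$", ".tsv", path), sep = "\t", quote = FALSE)
  invisible(path)
}
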