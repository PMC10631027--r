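#' Spike tumor reads into cfDNA reads at a defined fraction
#'
#' Each replicate draws `round(fraction * total_reads)` tumor reads and the
#' remainder from the cfDNA pool, uniformly at random without replacement
#' within the replicate (pools are re-used across replicates). Replicate `r`
#' is seeded with `seed + r`, so any replicate can be regenerated in
#' isolation.
#'
#' @param tumor_pool,cfdna_pool [methyl_reads] tables to draw from; they
#'   must be disjoint from any training data.
#' @param fraction target ctDNA fraction in `[0, 1]`.
#' @param total_reads reads per simulated sample.
#' @param n_replicates number of parallel simulated samples (default 100).
#' @param seed base seed.
#' @return a `methyl_reads` table with `replicate` and `source` columns;
#'   `sample_id` is rewritten to `mix_<fraction>_rep<r>`.
#' @export
mix_reads <- function(tumor_pool, cfdna_pool, fraction, total_reads,
                      n_replicates = 100, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  stopifnot_scalar_int(total_reads, "total_reads", min = 1)
  tumor_pool <- as.data.table(tumor_pool)
  cfdna_pool <- as.data.table(cfdna_pool)
  n_tumor <- round(fraction * total_reads)
  n_cf <- total_reads - n_tumor
  if (n_tumor > nrow(tumor_pool))
    stop(sprintf("tumor pool exhausted: need %d reads, have %d",
                 n_tumor, nrow(tumor_pool)), call. = FALSE)
  if (n_cf > nrow(cfdna_pool))
    stop(sprintf("cfDNA pool exhausted: need %d reads, have %d",
                 n_cf, nrow(cfdna_pool)), call. = FALSE)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_reads <- with_seed(seed + r, {
      tum <- tumor_pool[sample.int(nrow(tumor_pool), n_tumor)]
      cf <- cfdna_pool[sample.int(nrow(cfdna_pool), n_cf)]
      rbind(tum[, source := "tumor"], cf[, source := "cfdna"], fill = TRUE)
    })
    rep_reads[, `:=`(replicate = r,
                     sample_id = sprintf("mix_%g_rep%03d", fraction, r))]
    out[[r]] <- rep_reads
  }
  methyl_reads(rbindlist(out), validate = FALSE)
}

#' Uniform subsampling of a read set
#'
#' @param reads a [methyl_reads] table.
#' @param target_reads number of reads to keep (must not exceed available).
#' @param seed RNG seed.
#' @return the subsampled table (original order of the drawn rows).
#' @export
subsample_reads <- function(reads, target_reads, seed = 1) {
  reads <- as.data.table(reads)
  stopifnot_scalar_int(target_reads, "target_reads", min = 0)
  if (target_reads > nrow(reads))
    stop(sprintf("target %d exceeds available %d reads",
                 target_reads, nrow(reads)), call. = FALSE)
  idx <- with_seed(seed, sort(sample.int(nrow(reads), target_reads)))
  methyl_reads(reads[idx], validate = FALSE)
}

#' Titration analysis of risk score versus ctDNA fraction
#'
#' Summarises per-replicate risk scores over a spike-in fraction grid:
#' per-fraction mean and sd of RS, the Pearson correlation between the
#' per-fraction mean RS and the fraction, and a Wilcoxon rank-sum test of
#' the lowest non-zero fraction against the blank (fraction 0) controls.
#'
#' @param rs_table data.table/data.frame with columns `fraction`,
#'   `replicate`, `rs`.
#' @return list with `per_fraction` (mean/sd/n per fraction), `correlation`
#'   (estimate, r_squared, p_value; `NA` with a warning when RS is constant)
#'   and `blank_test` (Wilcoxon p-value, or `NULL` without a blank level).
#' @export
titration_analysis <- function(rs_table) {
  rs_table <- as.data.table(rs_table)
  stopifnot(all(c("fraction", "replicate", "rs") %in% names(rs_table)))
  per <- rs_table[, .(mean_rs = mean(rs), sd_rs = stats::sd(rs), n = .N),
                  by = fraction]
  setorder(per, fraction)
  if (nrow(per) < 2L) stop("need at least two fractions", call. = FALSE)
  correlation <- if (stats::sd(per$mean_rs) == 0) {
    warning("risk score constant across fractions; correlation undefined")
    list(estimate = NA_real_, r_squared = NA_real_, p_value = NA_real_)
  } else {
    ct <- cor.test(per$mean_rs, per$fraction, method = "pearson")
    list(estimate = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value)
  }
  blank_test <- NULL
  if (any(per$fraction == 0) && any(per$fraction > 0)) {
    low <- min(per$fraction[per$fraction > 0])
    wt <- suppressWarnings(wilcox.test(rs_table[fraction == low, rs],
                                       rs_table[fraction == 0, rs],
                                       alternative = "greater"))
    blank_test <- list(lowest_fraction = low, p_value = wt$p.value)
  }
  list(per_fraction = per[], correlation = correlation,
       blank_test = blank_test)
}
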