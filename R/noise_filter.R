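#' Methylation Continuity Score (MCS)
#'
#' Scores a read's CpG call vector by how many and how long its maximal runs
#' of consecutive methylated CpGs are:
#' \deqn{MCS = \sum_i i^2 n_i / L^2}
#' where `L` is the number of CpGs in the read and `n_i` the number of
#' maximal blocks of exactly `i` consecutive methylated CpGs. The score lies
#' in `[0, 1]`; it is 1 when every CpG is methylated (one block of length
#' `L`) and 0 when none is. Splitting a methylated block strictly lowers the
#' score, so the MCS rewards contiguity, not just methylation level.
#'
#' @param calls logical vector of CpG calls (`TRUE` = methylated), ordered
#'   along the read.
#' @return the MCS, a number in `[0, 1]`.
#' @export
mcs <- function(calls) {
  L <- length(calls)
  if (L == 0L) stop("MCS undefined for a read with zero CpGs", call. = FALSE)
  if (anyNA(calls)) stop("MCS input contains NA calls", call. = FALSE)
  r <- rle(as.logical(calls))
  blocks <- r$lengths[r$values]
  sum(blocks^2) / L^2
}

#' Sliding windows over a DMR
#'
#' DMRs of at most `window` bp are evaluated whole. Longer DMRs are tiled
#' with `window`-bp windows at `step`-bp offsets; the last window is anchored
#' at `end - window` so every base is covered.
#'
#' @param start,end DMR interval (0-based half-open).
#' @param window window length in bp (default 150).
#' @param step step size in bp (default 50).
#' @return data.table with `win_start`, `win_end`.
#' @export
dmr_windows <- function(start, end, window = 150, step = 50) {
  len <- end - start
  if (len <= window)
    return(data.table(win_start = as.integer(start), win_end = as.integer(end)))
  offs <- unique(c(seq(start, end - window, by = step), end - window))
  data.table(win_start = as.integer(offs), win_end = as.integer(offs + window))
}

# Calls of one read restricted to [wstart, wend); returns logical vector.
calls_in_interval <- function(pos, calls, wstart, wend) {
  calls[pos >= wstart & pos < wend]
}

#' Read eligibility within a DMR interval
#'
#' A read is eligible when it carries actual calls at three or more of the
#' DMR's member DMC positions inside the evaluated interval; overlapping a
#' DMC without a call there does not count.
#'
#' @param pos,calls the read's CpG positions and calls.
#' @param dmc_positions the DMR's member DMC coordinates.
#' @param wstart,wend evaluated interval (defaults: unrestricted).
#' @param min_dmc_calls minimum called DMCs (default 3).
#' @return logical.
#' @export
read_eligible <- function(pos, calls, dmc_positions, wstart = -Inf,
                          wend = Inf, min_dmc_calls = 3) {
  sum(pos %in% dmc_positions & pos >= wstart & pos < wend) >= min_dmc_calls
}

#' Healthy-cfDNA MCS bounds for a DMR
#'
#' For each window of the DMR (one whole-DMR window when the DMR is at most
#' 150 bp), computes the minimum and maximum MCS over all eligible healthy
#' cfDNA reads, with MCS evaluated on each read's calls inside the window.
#' Windows with no eligible healthy read get `NA` bounds and impose no
#' filtering.
#'
#' @param healthy_reads [methyl_reads] from healthy-individual cfDNA.
#' @param dmr single DMR row (needs `dmr_id`, `chrom`, `start`, `end`,
#'   `dmc_positions`).
#' @param window,step sliding-window geometry (150 / 50 bp).
#' @param min_dmc_calls eligibility cutoff (default 3).
#' @return data.table with `dmr_id`, `win_start`, `win_end`, `s_min`,
#'   `s_max`, `n_healthy`.
#' @export
compute_bounds <- function(healthy_reads, dmr, window = 150, step = 50,
                           min_dmc_calls = 3) {
  wins <- dmr_windows(dmr$start, dmr$end, window, step)
  dmcs <- dmr$dmc_positions[[1]]
  reads <- as.data.table(healthy_reads)[chrom == dmr$chrom &
                                          start < dmr$end & end > dmr$start]
  res <- wins[, .(win_start, win_end)]
  res[, `:=`(dmr_id = dmr$dmr_id, s_min = NA_real_, s_max = NA_real_,
             n_healthy = 0L)]
  for (w in seq_len(nrow(res))) {
    ws <- res$win_start[w]; we <- res$win_end[w]
    vals <- numeric(0)
    for (i in seq_len(nrow(reads))) {
      p <- reads$cpg_positions[[i]]; cl <- reads$cpg_calls[[i]]
      if (!read_eligible(p, cl, dmcs, ws, we, min_dmc_calls)) next
      cw <- calls_in_interval(p, cl, ws, we)
      if (length(cw)) vals <- c(vals, mcs(cw))
    }
    if (length(vals)) {
      set(res, w, "s_min", min(vals))
      set(res, w, "s_max", max(vals))
      set(res, w, "n_healthy", length(vals))
    }
  }
  setcolorder(res, c("dmr_id", "win_start", "win_end", "s_min", "s_max",
                     "n_healthy"))
  res[]
}

#' Filter tumor-tissue reads against healthy MCS bounds
#'
#' Tumor tissue contains non-tumor cells, so some tumor-tissue reads look
#' like healthy cfDNA. Per window: in a hypo-methylated DMR, eligible tumor
#' reads with window MCS at or above the healthy minimum (`s_min`) are
#' removed; in a hyper-methylated DMR, reads with window MCS at or below the
#' healthy maximum (`s_max`) are removed. A read is removed if any window in
#' which it is eligible flags it. Reads eligible in no window are excluded
#' from the pool entirely (they count neither before nor after).
#'
#' @param tumor_reads [methyl_reads] from tumor tissue (may span several
#'   individuals; `sample_id` identifies the individual).
#' @param dmr single DMR row.
#' @param bounds output of [compute_bounds] for this DMR.
#' @param min_dmc_calls eligibility cutoff (default 3).
#' @return list with `retained` (a `methyl_reads` subset) and `stats`
#'   (per-individual `reads_before`, `reads_after`, `t_i`).
#' @export
filter_tumor_reads <- function(tumor_reads, dmr, bounds, min_dmc_calls = 3) {
  dmcs <- dmr$dmc_positions[[1]]
  hypo <- identical(dmr$direction, "hypo")
  reads <- as.data.table(tumor_reads)[chrom == dmr$chrom &
                                        start < dmr$end & end > dmr$start]
  if (all(is.na(bounds$s_min)))
    return(list(retained = NULL, stats = NULL, dropped = TRUE))
  n <- nrow(reads)
  eligible <- logical(n); removed <- logical(n)
  for (i in seq_len(n)) {
    p <- reads$cpg_positions[[i]]; cl <- reads$cpg_calls[[i]]
    for (w in seq_len(nrow(bounds))) {
      ws <- bounds$win_start[w]; we <- bounds$win_end[w]
      if (!read_eligible(p, cl, dmcs, ws, we, min_dmc_calls)) next
      eligible[i] <- TRUE
      if (is.na(bounds$s_min[w])) next
      s <- mcs(calls_in_interval(p, cl, ws, we))
      if ((hypo && s >= bounds$s_min[w]) || (!hypo && s <= bounds$s_max[w])) {
        removed[i] <- TRUE
        break
      }
    }
  }
  pool <- reads[eligible]
  kept <- reads[eligible & !removed]
  stats <- pool[, .(reads_before = .N), by = sample_id]
  after <- kept[, .(reads_after = .N), by = sample_id]
  stats <- merge(stats, after, by = "sample_id", all.x = TRUE)
  stats[is.na(reads_after), reads_after := 0L]
  stats[, t_i := reads_after / reads_before]
  stats[, dmr_id := dmr$dmr_id]
  list(retained = kept, stats = stats[], dropped = FALSE)
}

#' DMR Universality Score (DUS)
#'
#' Summarises how uniformly a DMR's tumor reads survive noise filtering
#' across individuals:
#' \deqn{DUS = (\sum_i t_i / n) \times d}
#' where `n` is the number of individuals with reads in the DMR before
#' filtering, `t_i` the retained fraction for individual `i`, and `d` the
#' proportion of individuals with `t_i > 0`. DUS = 1 means no read was
#' filtered in any individual; DUS = 0 means every individual lost all
#' reads. Individuals with no reads before filtering do not contribute
#' (their `t_i` is undefined).
#'
#' @param t_i numeric vector of per-individual retained fractions.
#' @return the DUS, a number in `[0, 1]`.
#' @export
compute_dus <- function(t_i) {
  if (length(t_i) == 0L) stop("DUS undefined with zero individuals", call. = FALSE)
  if (any(t_i < 0 | t_i > 1)) stop("t_i must lie in [0, 1]", call. = FALSE)
  mean(t_i) * mean(t_i > 0)
}

#' Denoise tumor reads across all DMRs
#'
#' Runs [compute_bounds] and [filter_tumor_reads] for each DMR and attaches
#' the DUS and retained-read totals to the DMR table. DMRs whose every
#' window lacks eligible healthy reads are dropped.
#'
#' @param dmrs DMR table from [assemble_dmrs].
#' @param tumor_reads,healthy_reads [methyl_reads] tables.
#' @param window,step,min_dmc_calls see [compute_bounds].
#' @return list with `dmrs` (with `dus`, `retained_read_total`, `n_individuals`
#'   columns), `retained` (all retained tumor reads tagged with `dmr_id`) and
#'   `stats` (per-DMR, per-individual filter statistics).
#' @export
denoise_dmrs <- function(dmrs, tumor_reads, healthy_reads, window = 150,
                         step = 50, min_dmc_calls = 3) {
  dmrs <- as.data.table(dmrs)
  all_stats <- list(); retained <- list(); keep <- logical(nrow(dmrs))
  dus <- rep(NA_real_, nrow(dmrs)); total <- rep(NA_integer_, nrow(dmrs))
  n_ind <- rep(NA_integer_, nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    dmr <- dmrs[i]
    b <- compute_bounds(healthy_reads, dmr, window, step, min_dmc_calls)
    f <- filter_tumor_reads(tumor_reads, dmr, b, min_dmc_calls)
    if (f$dropped || is.null(f$stats) || nrow(f$stats) == 0L) next
    keep[i] <- TRUE
    dus[i] <- compute_dus(f$stats$t_i)
    total[i] <- sum(f$stats$reads_after)
    n_ind[i] <- nrow(f$stats)
    all_stats[[dmr$dmr_id]] <- f$stats
    if (nrow(f$retained)) {
      f$retained[, dmr_id := dmr$dmr_id]
      retained[[dmr$dmr_id]] <- f$retained
    }
  }
  dmrs[, `:=`(dus = dus, retained_read_total = total, n_individuals = n_ind)]
  list(dmrs = dmrs[keep],
       retained = if (length(retained)) rbindlist(retained) else NULL,
       stats = if (length(all_stats)) rbindlist(all_stats) else NULL)
}

#' Screen DMRs for model training
#'
#' Keeps DMRs with strictly more than `min_retained` retained tumor reads
#' (summed over individuals), sorts them by DUS descending (ties broken by
#' retained-read total descending, then chrom, then start), and selects the
#' top `n_hypo` hypo-methylated DMRs plus all qualifying hyper-methylated
#' DMRs.
#'
#' @param dmrs DMR table carrying `dus` and `retained_read_total`.
#' @param min_retained retained-read cutoff (default 200, strict).
#' @param n_hypo number of hypo-DMRs to keep (default 10000).
#' @return the selected DMRs, with a `selected` flag added to the input
#'   ordering semantics preserved.
#' @export
screen_dmrs <- function(dmrs, min_retained = 200, n_hypo = 10000) {
  dmrs <- as.data.table(dmrs)
  qual <- dmrs[!is.na(dus) & retained_read_total > min_retained]
  setorder(qual, -dus, -retained_read_total, chrom, start)
  hypo <- qual[direction == "hypo"]
  hyper <- qual[direction == "hyper"]
  if (nrow(hypo) < n_hypo)
    message(sprintf("only %d hypo-DMRs qualify (requested %d); keeping all",
                    nrow(hypo), n_hypo))
  sel <- rbind(head(hypo, n_hypo), hyper)
  setorder(sel, chrom, start)
  sel[]
}
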