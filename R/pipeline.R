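#' Clip reads to an interval
#'
#' Restricts each read to `[cstart, cend)` intersected with the read's own
#' span: sequence substring, CpG positions and calls are trimmed
#' consistently. Used to focus the classifier on the DMR portion of a read —
#' bases outside the DMR carry no tumor signal and only add nuisance
#' variation.
#'
#' @param reads a [methyl_reads] table.
#' @param cstart,cend clipping interval per read (vectors recycled to
#'   `nrow(reads)`).
#' @return the clipped `methyl_reads` table.
#' @export
clip_reads <- function(reads, cstart, cend) {
  reads <- copy(as.data.table(reads))
  n <- nrow(reads)
  cstart <- pmax(rep_len(as.integer(cstart), n), reads$start)
  cend <- pmin(rep_len(as.integer(cend), n), reads$end)
  if (any(cend <= cstart)) stop("empty clip interval", call. = FALSE)
  newpos <- vector("list", n); newcall <- vector("list", n)
  for (i in seq_len(n)) {
    p <- reads$cpg_positions[[i]]; cl <- reads$cpg_calls[[i]]
    keep <- p >= cstart[i] & p + 1L < cend[i]   # whole CpG inside the clip
    newpos[[i]] <- p[keep]; newcall[[i]] <- cl[keep]
  }
  reads[, converted_seq := substr(converted_seq, cstart - start + 1L,
                                  cend - start)]
  reads[, `:=`(start = cstart, end = cend,
               cpg_positions = newpos, cpg_calls = newcall)]
  methyl_reads(reads, validate = FALSE)
}

#' Reads overlapping DMRs, with DMC eligibility
#'
#' Assigns each read the first DMR it overlaps in which it carries calls at
#' `min_dmc_calls` or more member DMC positions; reads eligible in no DMR
#' are dropped.
#'
#' @param reads a [methyl_reads] table.
#' @param dmrs DMR table (needs `dmr_id`, `chrom`, `start`, `end`,
#'   `dmc_positions`).
#' @param min_dmc_calls eligibility cutoff (default 3; 0 disables it and
#'   keeps every overlapping read).
#' @param clip when `TRUE`, clip each assigned read to its DMR interval
#'   (plus `flank` bp of context) with [clip_reads].
#' @param flank clipping context in bp (default 8).
#' @return the eligible reads with a `dmr_id` column.
#' @export
reads_in_dmrs <- function(reads, dmrs, min_dmc_calls = 3, clip = FALSE,
                          flank = 8) {
  reads <- as.data.table(reads)
  dmrs <- as.data.table(dmrs)
  assigned <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(dmrs))) {
    d <- dmrs[i]
    cand <- which(is.na(assigned) & reads$chrom == d$chrom &
                    reads$start < d$end & reads$end > d$start)
    if (!length(cand)) next
    if (min_dmc_calls > 0) {
      ok <- vapply(cand, function(j)
        read_eligible(reads$cpg_positions[[j]], reads$cpg_calls[[j]],
                      d$dmc_positions[[1]], min_dmc_calls = min_dmc_calls),
        logical(1))
      cand <- cand[ok]
    }
    assigned[cand] <- d$dmr_id
  }
  out <- reads[!is.na(assigned)]
  out[, dmr_id := assigned[!is.na(assigned)]]
  if (clip && nrow(out)) {
    iv <- dmrs[match(out$dmr_id, dmr_id)]
    out <- clip_reads(out, iv$start - flank, iv$end + flank)
  }
  out[]
}

#' Run the full detection pipeline on a cohort
#'
#' End-to-end driver: DMR discovery on tumor / para-tumor tissue, MCS noise
#' reduction against healthy-reference cfDNA, DUS screening, methylation-
#' aware encoding, MLM pre-training, fine-tuning, per-read prediction on the
#' validation cohort, and four-fold individual risk classification.
#'
#' @param cohort a [synth_cohort]-shaped list (`reads`, `sample_sheet`), or
#'   any pair of a [methyl_reads] table and sheet with `group`, `label` and
#'   `role` (`discovery` / `reference` / `validation`) columns.
#' @param q_threshold,diff_threshold,min_group_coverage DMC calling.
#' @param min_dmcs,max_gap DMR assembly.
#' @param min_retained,n_hypo DMR screening.
#' @param k,max_len tokenization (k defaults to 6; 6-mers carry enough
#'   sequence context to tie a methylation pattern to its locus).
#' @param clip_flank reads are clipped to their DMR interval plus this many
#'   bp of context before encoding.
#' @param preset model size preset.
#' @param pretrain_epochs,finetune_epochs,lr,batch_size training schedule
#'   (5 fine-tuning epochs sharpen per-read probabilities enough for stable
#'   individual-level scoring at desk scale); `lr` defaults to 2e-3, the
#'   desk-scale choice (the full-scale default of the published
#'   configuration is 1e-4).
#' @param pretrain_reads cap on the pre-training corpus size.
#' @param folds,t_grid risk-scoring evaluation.
#' @param seed master seed.
#' @param verbose progress messages.
#' @return list with `dmcs`, `dmrs`, `screened`, `denoise`, `model`,
#'   `finetune` (held-out read metrics), `predictions`, `probs_by_sample`,
#'   `risk` (cross-fold report), `vocab`, `timings`.
#' @export
run_pipeline <- function(cohort, q_threshold = 0.01, diff_threshold = 25,
                         min_group_coverage = 5, min_dmcs = 5, max_gap = 300,
                         min_retained = 200, n_hypo = 10000, k = 6,
                         max_len = 512, preset = "desk", pretrain_epochs = 2,
                         finetune_epochs = 5, lr = 2e-3, batch_size = 16,
                         pretrain_reads = 1500, clip_flank = 8, folds = 4,
                         t_grid = seq(0.50, 0.99, by = 0.01), seed = 1,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  reads <- as.data.table(cohort$reads)
  sheet <- as.data.table(cohort$sample_sheet)
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  tic <- function() proc.time()[["elapsed"]]
  timings <- c(); t0 <- tic()

  disc <- reads[sample_id %in% sheet[role == "discovery", sample_id]]
  counts <- aggregate_cpg_counts(disc)
  dmcs <- call_dmcs(counts, groups, q_threshold = q_threshold,
                    diff_threshold = diff_threshold,
                    min_group_coverage = min_group_coverage)
  dmrs <- assemble_dmrs(dmcs, min_dmcs = min_dmcs, max_gap = max_gap)
  say("discovery: %d DMCs, %d DMRs", sum(dmcs$is_dmc), nrow(dmrs))
  timings["discovery"] <- tic() - t0; t0 <- tic()

  tumor_reads <- reads[sample_id %in% sheet[group == "tumor-tissue", sample_id]]
  healthy_ref <- reads[sample_id %in% sheet[role == "reference", sample_id]]
  den <- denoise_dmrs(dmrs, tumor_reads, healthy_ref)
  screened <- screen_dmrs(den$dmrs, min_retained = min_retained,
                          n_hypo = n_hypo)
  say("screening: %d DMRs selected", nrow(screened))
  if (nrow(screened) == 0L) stop("no DMRs survived screening", call. = FALSE)
  timings["denoise"] <- tic() - t0; t0 <- tic()

  pos_reads <- den$retained[dmr_id %in% screened$dmr_id]
  pos_reads <- pos_reads[!duplicated(read_id)]
  iv <- screened[match(pos_reads$dmr_id, dmr_id)]
  pos_reads <- clip_reads(pos_reads, iv$start - clip_flank, iv$end + clip_flank)
  neg_reads <- reads_in_dmrs(healthy_ref, screened, clip = TRUE,
                             flank = clip_flank)
  train_reads <- rbind(pos_reads[, label := 1L], neg_reads[, label := 0L],
                       fill = TRUE)
  say("training pool: %d tumor, %d cfDNA reads", nrow(pos_reads), nrow(neg_reads))

  rec <- recode_reads(train_reads)
  vocab <- build_vocab(rec$seq, k)
  train_ds <- encode_reads(train_reads, vocab = vocab, k = k,
                           max_len = max_len,
                           labels = stats::setNames(train_reads$label,
                                                    train_reads$read_id))
  timings["encode"] <- tic() - t0; t0 <- tic()

  model <- build_encoder(model_config(preset), vocab, seed = seed)
  neg_idx <- which(train_ds$meta$label == 0L)
  pre_idx <- with_seed(seed + 7L,
    sample(neg_idx, min(pretrain_reads, length(neg_idx))))
  pre_ds <- list(ids = train_ds$ids[pre_idx], vocab = vocab)
  pt <- pretrain_mlm(model, pre_ds,
                     train_config(lr = lr, batch_size = batch_size,
                                  epochs = pretrain_epochs, seed = seed),
                     verbose = verbose)
  model <- pt$model
  timings["pretrain"] <- tic() - t0; t0 <- tic()

  ft <- finetune(model, train_ds,
                 train_config(lr = lr, batch_size = batch_size,
                              epochs = finetune_epochs, seed = seed),
                 verbose = verbose)
  model <- ft$model
  say("held-out read AUC: %.3f", ft$metrics$auc)
  timings["finetune"] <- tic() - t0; t0 <- tic()

  val_ids <- sheet[role == "validation", sample_id]
  val_reads <- reads_in_dmrs(reads[sample_id %in% val_ids], screened,
                             clip = TRUE, flank = clip_flank)
  val_ds <- encode_reads(val_reads, vocab = vocab, k = k, max_len = max_len)
  preds <- predict_reads(model, val_ds)
  probs_by_sample <- split(preds$p, preds$sample_id)
  covered <- intersect(val_ids, names(probs_by_sample))
  if (length(covered) < length(val_ids))
    warning(length(val_ids) - length(covered),
            " validation individual(s) with no eligible in-DMR reads dropped")
  labels <- stats::setNames(sheet$label, sheet$sample_id)[covered]
  risk <- crossfold_evaluate(probs_by_sample[covered], labels, folds = folds,
                             seed = seed, t_grid = t_grid)
  timings["predict_score"] <- tic() - t0
  list(dmcs = dmcs, dmrs = dmrs, denoise = den, screened = screened,
       model = model, pretrain_trace = pt$loss_trace, finetune = ft,
       train_dataset = train_ds, predictions = preds,
       probs_by_sample = probs_by_sample, risk = risk, vocab = vocab,
       timings = timings)
}
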