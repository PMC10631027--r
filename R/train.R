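#' Pre-train with the methylation-aware masked-language-model objective
#'
#' Each epoch shuffles the corpus, applies the masking policy to every
#' sequence (fresh draws per epoch), and minimises the mean cross-entropy of
#' predicting the original tokens at the masked positions. Sequences in
#' which no token was selected are skipped for that epoch. Gradients are
#' averaged over `batch_size` sequences per Adam step.
#'
#' @param model a [build_encoder] model.
#' @param dataset an [encode_reads] result (`ids`, `vocab`, ...); the
#'   vocabulary must match the model's.
#' @param tc a [train_config]; `tc$seed` drives shuffling, masking and
#'   dropout.
#' @param policy a [masking_policy].
#' @param verbose print per-epoch mean loss.
#' @return list with `model` (trained) and `loss_trace` (mean masked-token
#'   cross-entropy per epoch).
#' @export
pretrain_mlm <- function(model, dataset, tc = train_config(),
                         policy = masking_policy(), verbose = FALSE) {
  if (length(dataset$ids) == 0L) stop("empty pre-training corpus", call. = FALSE)
  stopifnot(identical(dataset$vocab, model$vocab))
  is_ml <- grepl("ML", model$vocab, fixed = TRUE)
  vocab_ids <- which(!model$vocab %in% SPECIAL_TOKENS)
  n <- length(dataset$ids)
  state <- adam_init(model$params)
  trace <- numeric(tc$epochs)
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_tok <- 0L
      batch_starts <- seq(1L, n, by = tc$batch_size)
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + tc$batch_size - 1L, n)]
        gr <- zero_grads(model$params)
        b_loss <- 0; b_tok <- 0L; used <- 0L
        for (j in idx) {
          ids <- dataset$ids[[j]]
          m <- mask_ids(ids, is_ml, vocab_ids, model$mask_id, policy)
          if (length(m$pos) == 0L) next
          st <- mlm_step(model, m$ids, m$pos, m$targets, gr)
          b_loss <- b_loss + st$loss; b_tok <- b_tok + st$n
          used <- used + 1L
        }
        if (used == 0L) next
        upd <- adam_step(model$params, gr, state, tc, scale = 1 / b_tok,
                         skip = c("cls_W", "cls_b"))
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + b_loss; ep_tok <- ep_tok + b_tok
      }
      trace[ep] <- if (ep_tok > 0) ep_loss / ep_tok else NA_real_
      if (verbose) message(sprintf("epoch %d: MLM loss %.4f", ep, trace[ep]))
    }
  })
  list(model = model, loss_trace = trace)
}

# Id-level masking: same policy as apply_masking but operating on integer
# ids with a precomputed is-ML lookup (fast path for the training loop).
mask_ids <- function(ids, is_ml_vocab, vocab_ids, mask_id, policy) {
  n <- length(ids)
  sel <- logical(n)
  if (n > 1L) {
    sel[2:n] <- runif(n - 1L) < policy$p_random
    sel <- sel | (is_ml_vocab[ids] & runif(n) < policy$p_ml)
    sel[1L] <- FALSE
  }
  pos <- which(sel)
  targets <- ids[pos]
  if (length(pos)) {
    u <- runif(length(pos))
    ids[pos[u < policy$replace_mask]] <- mask_id
    rnd <- pos[u >= policy$replace_mask &
                 u < policy$replace_mask + policy$replace_random]
    if (length(rnd)) ids[rnd] <- sample(vocab_ids, length(rnd), replace = TRUE)
  }
  list(ids = ids, pos = pos, targets = targets)
}

#' Fine-tune the encoder for tumor-read classification
#'
#' Splits labelled reads 90/10 (stratified by label, seeded), trains the
#' 2-class head on the `[CLS]` representation with cross-entropy — all
#' encoder parameters remain trainable — and evaluates the held-out split.
#'
#' @param model a (typically pre-trained) model.
#' @param dataset an [encode_reads] result with 0/1 labels in `meta$label`.
#' @param tc a [train_config].
#' @param verbose print per-epoch loss.
#' @return list with `model`, `loss_trace`, `heldout` (data.table of
#'   held-out `read_id`, `label`, `p`) and `metrics` (accuracy, f1, MCC,
#'   AUC, AUPR on the held-out split).
#' @export
finetune <- function(model, dataset, tc = train_config(), verbose = FALSE) {
  labels <- dataset$meta$label
  if (anyNA(labels)) stop("fine-tuning requires 0/1 labels", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("fine-tuning requires both classes", call. = FALSE)
  stopifnot(identical(dataset$vocab, model$vocab))
  n <- length(dataset$ids)
  state <- adam_init(model$params)
  trace <- numeric(tc$epochs)
  split <- with_seed(tc$seed + 1L, {
    train_idx <- unlist(lapply(split(seq_len(n), labels), function(g)
      sample(g, floor(length(g) * tc$split_fraction))))
    sort(train_idx)
  })
  test_idx <- setdiff(seq_len(n), split)
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample(split)
      ep_loss <- 0
      for (bs in seq(1L, length(ord), by = tc$batch_size)) {
        idx <- ord[bs:min(bs + tc$batch_size - 1L, length(ord))]
        gr <- zero_grads(model$params)
        for (j in idx) {
          st <- cls_step(model, dataset$ids[[j]], labels[j], gr)
          ep_loss <- ep_loss + st$loss
        }
        upd <- adam_step(model$params, gr, state, tc, scale = 1 / length(idx),
                         skip = c("mlm_W", "mlm_b"))
        model$params <- upd$params; state <- upd$state
      }
      trace[ep] <- ep_loss / length(ord)
      if (verbose) message(sprintf("epoch %d: classification loss %.4f", ep, trace[ep]))
    }
  })
  heldout <- NULL; mets <- NULL
  if (length(test_idx)) {
    p <- vapply(test_idx, function(j)
      cls_step(model, dataset$ids[[j]], 0L)$p, 0)
    heldout <- data.table(read_id = dataset$meta$read_id[test_idx],
                          label = labels[test_idx], p = p)
    mets <- read_level_metrics(heldout$p, heldout$label)
  }
  list(model = model, loss_trace = trace, heldout = heldout, metrics = mets)
}

#' Predict per-read tumor-origin probabilities
#'
#' @param model fine-tuned model.
#' @param dataset an [encode_reads] result.
#' @return data.table `read_id`, `sample_id`, `p` (probability that the read
#'   is tumor-derived), in input order.
#' @export
predict_reads <- function(model, dataset) {
  stopifnot(identical(dataset$vocab, model$vocab))
  p <- vapply(dataset$ids, function(ids) {
    if (any(ids > length(model$vocab)))
      stop("token id outside vocabulary", call. = FALSE)
    cls_step(model, ids, 0L)$p
  }, 0)
  data.table(read_id = dataset$meta$read_id,
             sample_id = dataset$meta$sample_id, p = p)
}

#' Last-layer [CLS] attention over tokens
#'
#' Extracts the attention row of the sentinel token from the last encoder
#' layer, averaged over heads. Each head's row is a probability vector, so
#' the average also sums to 1.
#'
#' @param model fine-tuned model.
#' @param ids one encoded sequence (integer ids, sentinel first).
#' @return numeric vector of per-token weights (length = sequence length).
#' @export
cls_attention <- function(model, ids) {
  fw <- encoder_forward(model, ids, train = FALSE, need_cache = FALSE,
                        collect_attention = TRUE)
  rows <- vapply(fw$attention, function(A) A[1L, ], numeric(length(ids)))
  rowMeans(rows)
}

#' Map [CLS] token attention back to base positions
#'
#' A base at read offset `j` is covered by every k-mer token whose window
#' contains it; its weight is the mean of those tokens' `[CLS]` attention
#' weights. Profiles aggregated over read sets (e.g. tumor vs non-tumor
#' reads of one DMR) reveal which bases the classifier attends to.
#'
#' @param model fine-tuned model.
#' @param dataset an [encode_reads] result; reads should be aligned to one
#'   locus (their `start` offsets come from `reads`).
#' @param reads the [methyl_reads] the dataset was encoded from (for
#'   reference coordinates).
#' @return data.table `position` (reference coordinate), `weight` (mean
#'   base-level attention across reads covering it), `n_reads`.
#' @export
attention_base_profile <- function(model, dataset, reads) {
  reads <- as.data.table(reads)
  k <- dataset$k
  acc <- list()
  for (i in seq_along(dataset$ids)) {
    ids <- dataset$ids[[i]]
    w <- cls_attention(model, ids)[-1L]          # per-kmer weights
    ntok <- length(w)
    ri <- match(dataset$meta$read_id[i], reads$read_id)
    len <- min(nchar(reads$converted_seq[ri]), ntok + k - 1L)
    bw <- numeric(len); cnt <- integer(len)
    for (tpos in seq_len(ntok)) {
      span <- tpos:(tpos + k - 1L)
      bw[span] <- bw[span] + w[tpos]
      cnt[span] <- cnt[span] + 1L
    }
    acc[[i]] <- data.table(position = reads$start[ri] + seq_len(len) - 1L,
                           weight = bw / cnt)
  }
  long <- rbindlist(acc)
  out <- long[, .(weight = mean(weight), n_reads = .N), by = position]
  setorder(out, position)
  out[]
}

#' Per-position symbol frequencies of recoded reads over a locus
#'
#' For every reference position covered by at least one read, the frequency
#' of each recoded symbol (`A,C,G,T,N,M,L`) among the reads covering it.
#' Comparing tumor and non-tumor read sets shows which bases (and which
#' methylation marks) distinguish the classes.
#'
#' @param recoded output of [recode_reads] (has `start` and `seq`).
#' @return data.table `position`, `symbol`, `count`, `freq`.
#' @export
base_frequency_profile <- function(recoded) {
  recoded <- as.data.table(recoded)
  n <- vapply(recoded$seq, nchar, 0L)
  long <- data.table(
    position = unlist(lapply(seq_len(nrow(recoded)), function(i)
      recoded$start[i] + seq_len(n[i]) - 1L)),
    symbol = unlist(strsplit(recoded$seq, "", fixed = TRUE)))
  out <- long[, .(count = .N), by = .(position, symbol)]
  out[, freq := count / sum(count), by = position]
  setorder(out, position, symbol)
  out[]
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a versioned RDS archive of the weights, the model
#' configuration, the vocabulary and a hash of the vocabulary for integrity
#' checks at load time.
#'
#' @param model a `methyltrace_model`.
#' @param path checkpoint file.
#' @export
save_model <- function(model, path) {
  obj <- list(format = "methyltrace-checkpoint", version = 1L,
              params = model$params, config = model$config,
              vocab = model$vocab,
              vocab_hash = sum(utf8ToInt(paste(model$vocab, collapse = "\1"))))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "methyltrace-checkpoint"))
    stop("not a methyltrace checkpoint: ", path, call. = FALSE)
  structure(list(params = obj$params, config = obj$config, vocab = obj$vocab,
                 pad_id = match(TOK_PAD, obj$vocab),
                 mask_id = match(TOK_MASK, obj$vocab)),
            class = "methyltrace_model")
}
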