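test_that("configuration is validated and the desk preset runs a forward pass", {
  expect_error(model_config("desk", hidden = 10, n_heads = 4), "divisible")
  m <- tiny_model()
  ids <- c(2L, 5L, 6L, 7L, 8L, 9L, 10L, 5L, 6L, 7L)   # 10-token batch
  fw <- methyltrace:::encoder_forward(m, ids)
  expect_true(all(is.finite(fw$X)))
  p <- methyltrace:::cls_step(m, ids, 0L)
  expect_true(is.finite(p$loss) && p$p >= 0 && p$p <= 1)
})

test_that("attention rows are probability vectors at every layer and head", {
  m <- tiny_model()
  ids <- c(2L, 5L, 6L, 7L, 8L, 9L)
  fw <- methyltrace:::encoder_forward(m, ids, need_cache = TRUE)
  for (l in seq_along(fw$cache$layers))
    for (A in fw$cache$layers[[l]]$A) {
      expect_equal(rowSums(A), rep(1, length(ids)), tolerance = 1e-5)
      expect_true(all(A >= 0))
    }
  w <- cls_attention(m, ids)
  expect_equal(sum(w), 1, tolerance = 1e-5)
})

test_that("PAD tail positions do not influence the sentinel logit", {
  m <- tiny_model()
  ids <- c(2L, 5L, 6L, 7L)
  pad <- match("[PAD]", m$vocab)
  p0 <- methyltrace:::cls_step(m, ids, 0L)$p
  p1 <- methyltrace:::cls_step(m, c(ids, rep(pad, 5L)), 0L)$p
  expect_equal(p0, p1, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences for both heads", {
  m <- tiny_model(dropout = 0)
  ids <- c(2L, 5L, 6L, 7L, 8L, 5L)
  h <- 1e-5
  check <- function(loss_fn, gr) {
    worst <- 0
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (j in sample(length(p), min(3, length(p)))) {
        m2 <- m
        m2$params[[nm]][j] <- p[j] + h; l1 <- loss_fn(m2)
        m2$params[[nm]][j] <- p[j] - h; l0 <- loss_fn(m2)
        num <- (l1 - l0) / (2 * h); ana <- gr[[nm]][j]
        worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
      }
    }
    worst
  }
  set.seed(21)
  gr <- methyltrace:::zero_grads(m$params)
  methyltrace:::cls_step(m, ids, 1L, gr, train = FALSE)
  expect_lt(check(function(mm) methyltrace:::cls_step(mm, ids, 1L)$loss, gr),
            1e-3)
  gr <- methyltrace:::zero_grads(m$params)
  methyltrace:::mlm_step(m, c(2L, 3L, 6L, 3L, 8L), c(2L, 4L), c(5L, 7L), gr,
                         train = FALSE)
  expect_lt(check(function(mm)
    methyltrace:::mlm_step(mm, c(2L, 3L, 6L, 3L, 8L), c(2L, 4L), c(5L, 7L))$loss,
    gr), 1e-3)
})

test_that("MLM loss starts near ln(vocab) and decreases with training", {
  set.seed(31)
  seqs <- replicate(80, random_recoded_seq(60))
  vocab <- build_vocab(seqs, k = 4)
  ids <- lapply(seqs, function(s) tokens_to_ids(tokenize_seq(s, 4), vocab))
  ds <- list(ids = ids, vocab = vocab)
  cfg <- model_config("desk", n_layers = 1, n_heads = 2, hidden = 16,
                      intermediate = 32, dropout = 0)
  m <- build_encoder(cfg, vocab, seed = 31)
  # near-zero initial weights give near-uniform predictions
  st <- methyltrace:::mlm_step(m, ids[[1]], 2:4, ids[[1]][2:4])
  expect_equal(st$loss / st$n, log(length(vocab)), tolerance = 0.02)
  pt <- pretrain_mlm(m, ds, train_config(lr = 2e-3, batch_size = 16,
                                         epochs = 4, seed = 31))
  expect_lt(tail(pt$loss_trace, 1), pt$loss_trace[1])
  # a policy that selects nothing yields no updates and NA epoch losses
  pt0 <- pretrain_mlm(m, ds, train_config(epochs = 1, seed = 1),
                      policy = masking_policy(p_random = 0, p_ml = 0))
  expect_true(is.na(pt0$loss_trace))
  expect_equal(pt0$model$params$emb_tok, m$params$emb_tok)
  expect_error(pretrain_mlm(m, list(ids = list(), vocab = vocab),
                            train_config()), "empty")
})

test_that("fine-tuning separates a synthetic two-class corpus; prediction is deterministic", {
  # class 1 reads carry dense ML marks, class 0 none
  set.seed(41)
  s1 <- replicate(60, random_recoded_seq(60, p_ml = 0.3))
  s0 <- replicate(60, random_recoded_seq(60, p_ml = 0))
  seqs <- c(s1, s0); labels <- rep(1:0, each = 60)
  vocab <- build_vocab(seqs, k = 4)
  ids <- lapply(seqs, function(s) tokens_to_ids(tokenize_seq(s, 4), vocab))
  ds <- list(ids = ids,
             meta = data.table::data.table(
               read_id = sprintf("r%03d", seq_along(seqs)),
               sample_id = "s", label = labels),
             vocab = vocab, k = 4, max_len = 512)
  cfg <- model_config("desk", n_layers = 1, n_heads = 2, hidden = 16,
                      intermediate = 32)
  m <- build_encoder(cfg, vocab, seed = 41)
  ft <- finetune(m, ds, train_config(lr = 2e-3, batch_size = 8, epochs = 4,
                                     seed = 41))
  expect_gte(ft$metrics$auc, 0.95)
  # duplicate of a read scored twice gives identical p; batch order is
  # irrelevant at inference
  preds <- predict_reads(ft$model, ds)
  expect_true(all(preds$p >= 0 & preds$p <= 1))
  dup <- predict_reads(ft$model,
                       list(ids = ds$ids[c(1, 1)], meta = ds$meta[c(1, 1)],
                            vocab = vocab))
  expect_equal(dup$p[1], dup$p[2])
  rev_order <- predict_reads(ft$model,
                             list(ids = rev(ds$ids), meta = ds$meta[rev(seq_len(120))],
                                  vocab = vocab))
  expect_equal(rev(rev_order$p), preds$p, tolerance = 1e-12)
  expect_error(finetune(m, list(ids = ds$ids[1:5], meta = ds$meta[1:5],
                                vocab = vocab),
                        train_config()), "both classes")
})

test_that("a zeroed classification head gives p = 0.5", {
  m <- tiny_model()
  m$params$cls_W[] <- 0; m$params$cls_b[] <- 0
  expect_equal(methyltrace:::cls_step(m, c(2L, 5L, 6L), 0L)$p, 0.5)
})

test_that("attention maps back to bases and base frequencies match a direct tally", {
  reads <- bind_reads(
    make_read("r1", start = 100L, seq = "TTACGGACGT",
              cpg_positions = c(103L, 107L), cpg_calls = c(TRUE, TRUE)),
    make_read("r2", start = 100L, seq = "TTACGGATGT",
              cpg_positions = c(103L, 107L), cpg_calls = c(TRUE, FALSE)))
  ds <- encode_reads(reads, k = 4)
  m <- tiny_model(vocab = ds$vocab)
  prof <- attention_base_profile(m, ds, reads)
  expect_equal(prof$position, 100L:109L)
  expect_equal(prof$n_reads, rep(2L, 10))
  expect_true(all(prof$weight > 0))
  # direct aggregation oracle for read 1 alone
  w <- cls_attention(m, ds$ids[[1]])[-1]
  base_w <- sapply(1:10, function(j) {
    cover <- which(seq_along(w) <= j & seq_along(w) + 3 >= j)
    mean(w[cover])
  })
  prof1 <- attention_base_profile(m, list(ids = ds$ids[1], meta = ds$meta[1],
                                          k = 4), reads[1])
  expect_equal(prof1$weight, base_w)

  rec <- recode_reads(reads)
  bf <- base_frequency_profile(rec)
  # identical prefixes: frequency 1; planted 50/50 mixture at the second CpG
  expect_equal(bf[position == 100 & symbol == "T", freq], 1)
  expect_equal(bf[position == 107 & symbol == "M", freq], 0.5)
  expect_equal(bf[position == 107 & symbol == "T", freq], 0.5)
  # counts at every position sum to the covering reads
  expect_true(all(bf[, sum(count), by = position]$V1 == 2L))
})

test_that("checkpoints round-trip weights, config and vocabulary", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$params, m$params)
  expect_equal(back$vocab, m$vocab)
  ids <- c(2L, 5L, 6L)
  expect_equal(methyltrace:::cls_step(back, ids, 0L)$p,
               methyltrace:::cls_step(m, ids, 0L)$p)
})
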