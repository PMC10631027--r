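# Bidirectional transformer encoder for read classification, written in
# base R matrix algebra: token+position embeddings, post-norm encoder blocks
# (multi-head self-attention + gelu feed-forward), an MLM head over masked
# positions and a 2-class head over the [CLS] sentinel. Forward passes cache
# the intermediates needed for exact analytic backpropagation; gradients are
# verified against finite differences in the test suite.

#' Transformer model configuration
#'
#' The `desk` preset (2 layers, 2 heads, hidden 64, intermediate 256) trains
#' in minutes on one CPU and is the default throughout; the `paper` preset
#' is the BERT-base geometry (12 layers, 12 heads, hidden 768) used at full
#' scale.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param n_layers,n_heads,hidden,intermediate,max_positions,dropout
#'   overrides of the preset; `hidden` must be divisible by `n_heads`.
#' @param activation only `"gelu"` is implemented.
#' @return a config list.
#' @export
model_config <- function(preset = c("desk", "paper"), n_layers = NULL,
                         n_heads = NULL, hidden = NULL, intermediate = NULL,
                         max_positions = 512, dropout = 0.1,
                         activation = "gelu") {
  preset <- match.arg(preset)
  base <- switch(preset,
    desk = list(n_layers = 2L, n_heads = 2L, hidden = 64L, intermediate = 256L),
    paper = list(n_layers = 12L, n_heads = 12L, hidden = 768L, intermediate = 3072L))
  cfg <- list(n_layers = as.integer(n_layers %||% base$n_layers),
              n_heads = as.integer(n_heads %||% base$n_heads),
              hidden = as.integer(hidden %||% base$hidden),
              intermediate = as.integer(intermediate %||% base$intermediate),
              max_positions = as.integer(max_positions),
              dropout = dropout, activation = activation)
  if (cfg$hidden %% cfg$n_heads != 0L)
    stop("hidden size must be divisible by the number of heads", call. = FALSE)
  if (activation != "gelu") stop("only gelu activation is implemented", call. = FALSE)
  cfg
}

#' Training configuration
#'
#' Defaults follow the published pre-training hyperparameters: Adam with
#' learning rate 1e-4, beta1 0.9, beta2 0.999 and decoupled L2 weight decay
#' 0.01; 90% of labelled data used for training, 10% held out.
#'
#' @param lr,beta1,beta2,weight_decay Adam hyperparameters.
#' @param batch_size sequences per optimizer step.
#' @param epochs passes over the data.
#' @param seed RNG seed for shuffling, masking and dropout.
#' @param split_fraction fine-tuning train fraction (default 0.9).
#' @return a config list.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 0.01, batch_size = 16, epochs = 3,
                         seed = 1, split_fraction = 0.9) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  list(lr = lr, beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       seed = as.integer(seed), split_fraction = split_fraction)
}

#' Build an encoder model
#'
#' Initialises all weights N(0, 0.02^2) (layer-norm gains 1, shifts 0) under
#' the given seed.
#'
#' @param config from [model_config].
#' @param vocab vocabulary (character vector); its length fixes the
#'   embedding and MLM output size.
#' @param seed initialisation seed.
#' @return an object of class `methyltrace_model`.
#' @export
build_encoder <- function(config, vocab, seed = 1) {
  V <- length(vocab); H <- config$hidden; I <- config$intermediate
  P <- config$max_positions
  params <- with_seed(seed, {
    rn <- function(r, c) matrix(rnorm(r * c, sd = 0.02), r, c)
    p <- list(emb_tok = rn(V, H), emb_pos = rn(P, H),
              ln_emb_g = rep(1, H), ln_emb_b = rep(0, H))
    for (l in seq_len(config$n_layers)) {
      pre <- sprintf("l%d_", l)
      p[[paste0(pre, "Wq")]] <- rn(H, H); p[[paste0(pre, "bq")]] <- rep(0, H)
      p[[paste0(pre, "Wk")]] <- rn(H, H); p[[paste0(pre, "bk")]] <- rep(0, H)
      p[[paste0(pre, "Wv")]] <- rn(H, H); p[[paste0(pre, "bv")]] <- rep(0, H)
      p[[paste0(pre, "Wo")]] <- rn(H, H); p[[paste0(pre, "bo")]] <- rep(0, H)
      p[[paste0(pre, "ln1_g")]] <- rep(1, H); p[[paste0(pre, "ln1_b")]] <- rep(0, H)
      p[[paste0(pre, "W1")]] <- rn(H, I); p[[paste0(pre, "b1")]] <- rep(0, I)
      p[[paste0(pre, "W2")]] <- rn(I, H); p[[paste0(pre, "b2")]] <- rep(0, H)
      p[[paste0(pre, "ln2_g")]] <- rep(1, H); p[[paste0(pre, "ln2_b")]] <- rep(0, H)
    }
    p$mlm_W <- rn(H, V); p$mlm_b <- rep(0, V)
    p$cls_W <- rn(H, 2); p$cls_b <- rep(0, 2)
    p
  })
  structure(list(params = params, config = config, vocab = vocab,
                 pad_id = match(TOK_PAD, vocab),
                 mask_id = match(TOK_MASK, vocab)),
            class = "methyltrace_model")
}

#' @export
print.methyltrace_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<methyltrace_model> %d layers, %d heads, hidden %d, vocab %d (%s parameters)\n",
    x$config$n_layers, x$config$n_heads, x$config$hidden, length(x$vocab),
    format(n_par, big.mark = ",")))
  invisible(x)
}

# gelu via the sigmoid approximation x * sigmoid(1.702 x): within ~1e-3 of
# the exact erf form at a fraction of its cost.
gelu <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}
gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)          # m recycles down columns (one value per row)
  E / rowSums(E)
}

# Add a length-H bias to the columns of a T x H matrix without allocating a
# broadcast matrix: rep(b, each = T) matches column-major recycling.
add_bias <- function(X, b) X + rep(b, each = nrow(X))

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  T <- nrow(x)
  y <- add_bias(xhat * rep(g, each = T), b)
  list(y = y, xhat = xhat, sd = sd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; sd <- cache$sd
  dg <- colSums(dy * xhat); db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd
  list(dx = dx, dg = dg, db = db)
}

# Forward pass for one id sequence. Returns final hidden states and, when
# `need_cache`, everything required for the backward pass. PAD key positions
# are excluded from every attention row; `train` enables inverted dropout
# (masks drawn from the current RNG and cached for backward).
encoder_forward <- function(model, ids, train = FALSE, need_cache = train,
                            collect_attention = FALSE) {
  p <- model$params; cfg <- model$config
  T <- length(ids); H <- cfg$hidden; nh <- cfg$n_heads; dk <- H / nh
  scal <- 1 / sqrt(dk)
  drop_p <- if (train) cfg$dropout else 0
  dropout <- function(x) {
    if (drop_p <= 0) return(list(y = x, mask = NULL))
    mask <- matrix(runif(length(x)) >= drop_p, nrow(x), ncol(x)) / (1 - drop_p)
    list(y = x * mask, mask = mask)
  }
  pad <- which(ids == model$pad_id)
  X <- p$emb_tok[ids, , drop = FALSE] + p$emb_pos[seq_len(T), , drop = FALSE]
  dre <- dropout(X)
  lne <- layernorm_fwd(dre$y, p$ln_emb_g, p$ln_emb_b)
  X <- lne$y
  cache <- if (need_cache) list(ids = ids, emb_drop = dre$mask, ln_emb = lne,
                                layers = vector("list", cfg$n_layers)) else NULL
  attn_last <- NULL
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%d_", l)
    Q <- add_bias(X %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
    K <- add_bias(X %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
    Vm <- add_bias(X %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
    Oh <- matrix(0, T, H)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) * scal
      if (length(pad)) S[, pad] <- -Inf
      A <- softmax_rows(S)
      A_heads[[h]] <- A
      Oh[, cols] <- A %*% Vm[, cols, drop = FALSE]
    }
    if (l == cfg$n_layers) attn_last <- A_heads
    AO <- add_bias(Oh %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    dr1 <- dropout(AO)
    ln1 <- layernorm_fwd(X + dr1$y, p[[paste0(pre, "ln1_g")]],
                         p[[paste0(pre, "ln1_b")]])
    X1 <- ln1$y
    Hpre <- add_bias(X1 %*% p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    G <- gelu(Hpre)
    F2 <- add_bias(G %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    dr2 <- dropout(F2)
    ln2 <- layernorm_fwd(X1 + dr2$y, p[[paste0(pre, "ln2_g")]],
                         p[[paste0(pre, "ln2_b")]])
    if (need_cache)
      cache$layers[[l]] <- list(X_in = X, Q = Q, K = K, V = Vm, A = A_heads,
                                Oh = Oh, drop1 = dr1$mask, ln1 = ln1, X1 = X1,
                                Hpre = Hpre, G = G, drop2 = dr2$mask, ln2 = ln2)
    X <- ln2$y
  }
  out <- list(X = X)
  if (need_cache) out$cache <- cache
  if (collect_attention) out$attention <- attn_last
  out
}

# Backward pass through the encoder given dX at the final hidden states.
# Accumulates parameter gradients into the environment `gr` (matrices of the
# same shapes as the parameters, pre-initialised to zero).
encoder_backward <- function(model, cache, dX, gr) {
  p <- model$params; cfg <- model$config
  T <- nrow(dX); H <- cfg$hidden; nh <- cfg$n_heads; dk <- H / nh
  scal <- 1 / sqrt(dk)
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("l%d_", l)
    cc <- cache$layers[[l]]
    b2 <- layernorm_bwd(dX, cc$ln2, p[[paste0(pre, "ln2_g")]])
    gr[[paste0(pre, "ln2_g")]] <- gr[[paste0(pre, "ln2_g")]] + b2$dg
    gr[[paste0(pre, "ln2_b")]] <- gr[[paste0(pre, "ln2_b")]] + b2$db
    dres <- b2$dx                      # gradient on X1 + dropout(F2)
    dF2 <- if (is.null(cc$drop2)) dres else dres * cc$drop2
    gr[[paste0(pre, "W2")]] <- gr[[paste0(pre, "W2")]] + crossprod(cc$G, dF2)
    gr[[paste0(pre, "b2")]] <- gr[[paste0(pre, "b2")]] + colSums(dF2)
    dG <- tcrossprod(dF2, p[[paste0(pre, "W2")]])
    dHpre <- dG * gelu_grad(cc$Hpre)
    gr[[paste0(pre, "W1")]] <- gr[[paste0(pre, "W1")]] + crossprod(cc$X1, dHpre)
    gr[[paste0(pre, "b1")]] <- gr[[paste0(pre, "b1")]] + colSums(dHpre)
    dX1 <- dres + tcrossprod(dHpre, p[[paste0(pre, "W1")]])
    b1 <- layernorm_bwd(dX1, cc$ln1, p[[paste0(pre, "ln1_g")]])
    gr[[paste0(pre, "ln1_g")]] <- gr[[paste0(pre, "ln1_g")]] + b1$dg
    gr[[paste0(pre, "ln1_b")]] <- gr[[paste0(pre, "ln1_b")]] + b1$db
    dres1 <- b1$dx                     # gradient on X_in + dropout(AO)
    dAO <- if (is.null(cc$drop1)) dres1 else dres1 * cc$drop1
    gr[[paste0(pre, "Wo")]] <- gr[[paste0(pre, "Wo")]] + crossprod(cc$Oh, dAO)
    gr[[paste0(pre, "bo")]] <- gr[[paste0(pre, "bo")]] + colSums(dAO)
    dOh <- tcrossprod(dAO, p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, T, H); dK <- matrix(0, T, H); dV <- matrix(0, T, H)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cc$A[[h]]
      dOc <- dOh[, cols, drop = FALSE]
      dA <- tcrossprod(dOc, cc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOc)
      dS <- A * (dA - rowSums(A * dA))
      dQ[, cols] <- (dS %*% cc$K[, cols, drop = FALSE]) * scal
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) * scal
    }
    Xin <- cc$X_in
    gr[[paste0(pre, "Wq")]] <- gr[[paste0(pre, "Wq")]] + crossprod(Xin, dQ)
    gr[[paste0(pre, "bq")]] <- gr[[paste0(pre, "bq")]] + colSums(dQ)
    gr[[paste0(pre, "Wk")]] <- gr[[paste0(pre, "Wk")]] + crossprod(Xin, dK)
    gr[[paste0(pre, "bk")]] <- gr[[paste0(pre, "bk")]] + colSums(dK)
    gr[[paste0(pre, "Wv")]] <- gr[[paste0(pre, "Wv")]] + crossprod(Xin, dV)
    gr[[paste0(pre, "bv")]] <- gr[[paste0(pre, "bv")]] + colSums(dV)
    dX <- dres1 + tcrossprod(dQ, p[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, p[[paste0(pre, "Wk")]]) + tcrossprod(dV, p[[paste0(pre, "Wv")]])
  }
  be <- layernorm_bwd(dX, cache$ln_emb, p$ln_emb_g)
  gr$ln_emb_g <- gr$ln_emb_g + be$dg
  gr$ln_emb_b <- gr$ln_emb_b + be$db
  dE <- if (is.null(cache$emb_drop)) be$dx else be$dx * cache$emb_drop
  agg <- rowsum(dE, cache$ids)
  rows <- as.integer(rownames(agg))
  gr$emb_tok[rows, ] <- gr$emb_tok[rows, , drop = FALSE] + agg
  gr$emb_pos[seq_len(T), ] <- gr$emb_pos[seq_len(T), , drop = FALSE] + dE
  invisible(gr)
}

# Cross-entropy over rows of `logits` with integer targets (1-based).
# Returns summed loss and dlogits (per-row softmax - onehot).
softmax_xent <- function(logits, targets) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), targets)
  loss <- -sum(log(pmax(P[idx], 1e-12)))
  dl <- P
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl)
}

# MLM loss (and gradients when gr is supplied) for one masked sequence.
# `mask_pos` are positions whose original ids are `targets`; loss is the
# cross-entropy summed over those positions (caller averages).
mlm_step <- function(model, ids_masked, mask_pos, targets, gr = NULL,
                     train = !is.null(gr)) {
  fw <- encoder_forward(model, ids_masked, train = train,
                        need_cache = !is.null(gr))
  Xm <- fw$X[mask_pos, , drop = FALSE]
  logits <- add_bias(Xm %*% model$params$mlm_W, model$params$mlm_b)
  sx <- softmax_xent(logits, targets)
  if (!is.null(gr)) {
    dXm <- tcrossprod(sx$dlogits, model$params$mlm_W)
    gr$mlm_W <- gr$mlm_W + crossprod(Xm, sx$dlogits)
    gr$mlm_b <- gr$mlm_b + colSums(sx$dlogits)
    dX <- matrix(0, length(ids_masked), model$config$hidden)
    dX[mask_pos, ] <- dXm
    encoder_backward(model, fw$cache, dX, gr)
  }
  list(loss = sx$loss, n = length(mask_pos))
}

# Classification loss/gradient for one sequence with label in {0,1}.
cls_step <- function(model, ids, label, gr = NULL, train = !is.null(gr)) {
  fw <- encoder_forward(model, ids, train = train, need_cache = !is.null(gr))
  x <- fw$X[1L, , drop = FALSE]
  logits <- add_bias(x %*% model$params$cls_W, model$params$cls_b)
  sx <- softmax_xent(logits, label + 1L)
  if (!is.null(gr)) {
    gr$cls_W <- gr$cls_W + crossprod(x, sx$dlogits)
    gr$cls_b <- gr$cls_b + as.numeric(sx$dlogits)
    dX <- matrix(0, length(ids), model$config$hidden)
    dX[1L, ] <- sx$dlogits %*% t(model$params$cls_W)
    encoder_backward(model, fw$cache, dX, gr)
  }
  list(loss = sx$loss, p = softmax_rows(logits)[1L, 2L])
}

zero_grads <- function(params) {
  gr <- new.env(parent = emptyenv())
  for (nm in names(params)) gr[[nm]] <- params[[nm]] * 0
  gr
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# One AdamW step: decoupled weight decay on weight matrices only (biases and
# layer-norm parameters, stored as vectors, are not decayed). `skip` names
# parameters outside the active loss path (e.g. the MLM head during
# fine-tuning) that receive no update.
adam_step <- function(params, gr, state, tc, scale = 1, skip = character()) {
  state$t <- state$t + 1L
  b1 <- tc$beta1; b2 <- tc$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in setdiff(names(params), skip)) {
    g <- gr[[nm]] * scale
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    upd <- (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + 1e-8)
    if (is.matrix(params[[nm]]) && tc$weight_decay > 0)
      upd <- upd + tc$weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - tc$lr * upd
  }
  list(params = params, state = state)
}
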