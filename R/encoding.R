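# Special tokens shared by vocabulary, masking and the model.
TOK_PAD <- "[PAD]"; TOK_CLS <- "[CLS]"; TOK_MASK <- "[MASK]"; TOK_UNK <- "[UNK]"
SPECIAL_TOKENS <- c(TOK_PAD, TOK_CLS, TOK_MASK, TOK_UNK)

#' Recode methylated CpGs as "ML"
#'
#' In converted space an unmethylated CpG reads "TG" while a methylated CpG
#' survives as "CG". To make methylation explicit to the tokenizer, the "CG"
#' of each methylated CpG is rewritten as "ML". The transformation is
#' invertible given the call vector, and the sequence length is unchanged.
#'
#' @param seq converted-space read sequence (reference orientation).
#' @param start read start (0-based), used to convert CpG coordinates to
#'   read offsets.
#' @param cpg_positions,cpg_calls the read's CpG coordinates and calls.
#' @param read_id used in error messages.
#' @return the recoded sequence over the alphabet `{A,C,G,T,N,M,L}`.
#' @export
recode_seq <- function(seq, start, cpg_positions, cpg_calls,
                       read_id = "<read>") {
  meth <- cpg_positions[cpg_calls]
  if (!length(meth)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  off <- meth - start + 1L   # 1-based offset of the C
  bad <- off[off < 1L | off + 1L > length(chars)]
  if (length(bad) == 0L) {
    ok <- chars[off] == "C" & chars[off + 1L] == "G"
    if (!all(ok))
      stop("methylated CpG without 'CG' in converted sequence of read ",
           read_id, call. = FALSE)
  } else {
    stop("methylated CpG offset outside read ", read_id, call. = FALSE)
  }
  chars[off] <- "M"; chars[off + 1L] <- "L"
  paste(chars, collapse = "")
}

#' Undo the "ML" recoding
#'
#' @param seq recoded sequence.
#' @return converted-space sequence with "ML" restored to "CG".
#' @export
decode_seq <- function(seq) gsub("ML", "CG", seq, fixed = TRUE)

#' Recode a read table
#'
#' @param reads a [methyl_reads] table.
#' @return data.table with `read_id`, `sample_id`, `chrom`, `start`, `seq`
#'   (recoded).
#' @export
recode_reads <- function(reads) {
  reads <- as.data.table(reads)
  seqs <- character(nrow(reads))
  for (i in seq_len(nrow(reads)))
    seqs[i] <- recode_seq(reads$converted_seq[i], reads$start[i],
                          reads$cpg_positions[[i]], reads$cpg_calls[[i]],
                          reads$read_id[i])
  data.table(read_id = reads$read_id, sample_id = reads$sample_id,
             chrom = reads$chrom, start = reads$start, seq = seqs)
}

kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k", call. = FALSE)
  substring(seq, 1:(n - k + 1), k:n)
}

#' Build a k-mer vocabulary from a recoded corpus
#'
#' The vocabulary is the four special tokens followed by every k-mer
#' observed in the corpus, in lexicographic order (a deterministic function
#' of the corpus). k-mers containing `N` are excluded and map to `[UNK]` at
#' tokenization time, as does any unseen k-mer at inference.
#'
#' @param seqs character vector of recoded sequences.
#' @param k k-mer length (default 4, valid 1-8).
#' @return character vector of tokens; a token's id is its position.
#' @export
build_vocab <- function(seqs, k = 4) {
  if (length(seqs) == 0L) stop("empty corpus", call. = FALSE)
  stopifnot(k >= 1, k <= 8)
  km <- unique(unlist(lapply(seqs, kmers_of, k = k)))
  km <- sort(km[!grepl("N", km, fixed = TRUE)])
  c(SPECIAL_TOKENS, km)
}

#' Tokenize a recoded sequence
#'
#' Emits the `[CLS]` sentinel followed by all stride-1 overlapping k-mers,
#' truncated to `max_len` tokens. A sequence of length `n >= k` yields
#' `min(n - k + 2, max_len)` tokens.
#'
#' @param seq recoded sequence (length at least `k`).
#' @param k k-mer length.
#' @param max_len maximum token count including the sentinel (default 512).
#' @return character vector of tokens.
#' @export
tokenize_seq <- function(seq, k = 4, max_len = 512) {
  toks <- c(TOK_CLS, kmers_of(seq, k))
  if (length(toks) > max_len) toks <- toks[seq_len(max_len)]
  toks
}

#' Map tokens to integer ids
#'
#' @param tokens character vector of tokens.
#' @param vocab vocabulary from [build_vocab].
#' @return integer ids (1-based); unknown tokens map to `[UNK]`.
#' @export
tokens_to_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- match(TOK_UNK, vocab)
  ids
}

#' Masking policy for methylation-aware MLM pre-training
#'
#' @param p_random probability that any non-sentinel token is selected by
#'   the traditional random-masking rule (default 0.15).
#' @param p_ml probability that a token containing the "ML" methylation mark
#'   is (additionally, independently) selected (default 0.80). Methylated
#'   CpGs are rare genome-wide, so without this rule the model would almost
#'   never be asked to predict them.
#' @param replace_mask,replace_random of the selected tokens, the fraction
#'   replaced by `[MASK]` and by a random vocabulary token; the remainder is
#'   left unchanged (standard 80/10/10 scheme).
#' @return a masking-policy list.
#' @export
masking_policy <- function(p_random = 0.15, p_ml = 0.80, replace_mask = 0.8,
                           replace_random = 0.1) {
  stopifnot(p_random >= 0, p_random <= 1, p_ml >= 0, p_ml <= 1,
            replace_mask + replace_random <= 1)
  list(p_random = p_random, p_ml = p_ml, replace_mask = replace_mask,
       replace_random = replace_random)
}

#' Apply MLM masking to a token sequence
#'
#' Selection is the union of two independent draws: every non-sentinel token
#' with probability `p_random`, and every token containing "ML" with
#' probability `p_ml`. Each selected token is replaced by `[MASK]` with
#' probability `replace_mask`, by a random non-special vocabulary token with
#' probability `replace_random`, and left unchanged otherwise. Draws use the
#' current RNG state (seed via `set.seed` or the `seed` argument for
#' reproducibility).
#'
#' @param tokens character token vector (first token is the sentinel, never
#'   masked).
#' @param vocab vocabulary (for random replacements).
#' @param policy a [masking_policy].
#' @param seed optional seed applied locally.
#' @return list with `tokens` (masked) and `mask_labels` (original token at
#'   selected positions, `NA` elsewhere).
#' @export
apply_masking <- function(tokens, vocab, policy = masking_policy(),
                          seed = NULL) {
  with_seed(seed, {
    n <- length(tokens)
    sel <- logical(n)
    if (n > 1L) {
      cand <- 2:n
      sel[cand] <- runif(n - 1L) < policy$p_random
      is_ml <- grepl("ML", tokens, fixed = TRUE)
      sel <- sel | (is_ml & runif(n) < policy$p_ml)
      sel[1L] <- FALSE
    }
    labels <- rep(NA_character_, n)
    labels[sel] <- tokens[sel]
    idx <- which(sel)
    if (length(idx)) {
      u <- runif(length(idx))
      to_mask <- idx[u < policy$replace_mask]
      to_rand <- idx[u >= policy$replace_mask &
                       u < policy$replace_mask + policy$replace_random]
      tokens[to_mask] <- TOK_MASK
      if (length(to_rand)) {
        pool <- setdiff(vocab, SPECIAL_TOKENS)
        tokens[to_rand] <- sample(pool, length(to_rand), replace = TRUE)
      }
    }
    list(tokens = tokens, mask_labels = labels)
  })
}

#' Encode reads into model-ready token-id sequences
#'
#' Recodes, tokenizes and id-maps each read. Reads shorter than `k` are
#' dropped with a message (upstream QC removes fragments under 36 bp, so
#' this is rare).
#'
#' @param reads a [methyl_reads] table.
#' @param vocab vocabulary; built from this corpus when `NULL`.
#' @param k,max_len tokenization parameters.
#' @param labels optional named vector (by `read_id`) or single value of
#'   0/1 class labels.
#' @return list with `ids` (list of integer vectors), `meta` (data.table
#'   `read_id`, `sample_id`, `label`), `vocab`, `k`, `max_len`.
#' @export
encode_reads <- function(reads, vocab = NULL, k = 4, max_len = 512,
                         labels = NULL) {
  rec <- recode_reads(reads)
  ok <- nchar(rec$seq) >= k
  if (!all(ok)) {
    message(sum(!ok), " read(s) shorter than k dropped")
    rec <- rec[ok]
  }
  if (is.null(vocab)) vocab <- build_vocab(rec$seq, k)
  ids <- lapply(rec$seq, function(s) tokens_to_ids(tokenize_seq(s, k, max_len), vocab))
  lab <- if (is.null(labels)) rep(NA_integer_, nrow(rec))
         else if (length(labels) == 1L) rep(as.integer(labels), nrow(rec))
         else as.integer(labels[rec$read_id])
  list(ids = ids,
       meta = data.table(read_id = rec$read_id, sample_id = rec$sample_id,
                         label = lab),
       vocab = vocab, k = k, max_len = max_len)
}

#' Write / read a vocabulary file (one token per line; id = line number)
#' @param vocab character vector of tokens.
#' @param path file path.
#' @export
write_vocab <- function(vocab, path) { writeLines(vocab, path); invisible(path) }

#' @rdname write_vocab
#' @export
read_vocab <- function(path) readLines(path)
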