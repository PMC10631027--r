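# Shared fixture builders. Everything is generated in code; no binary data.

# One methyl_reads row from compact arguments.
make_read <- function(read_id = "r1", sample_id = "s1", chrom = "chr1",
                      start = 0L, seq = NULL, end = NULL, mapq = 40L,
                      cpg_positions = integer(0), cpg_calls = logical(0),
                      mate_merged = FALSE, ...) {
  if (is.null(seq)) {
    if (is.null(end)) end <- start + 50L
    seq <- strrep("A", end - start)
    # plant CG/TG at the call positions so the sequence stays consistent
    ch <- strsplit(seq, "")[[1]]
    for (i in seq_along(cpg_positions)) {
      off <- cpg_positions[i] - start + 1L
      ch[off] <- if (cpg_calls[i]) "C" else "T"
      ch[off + 1L] <- "G"
    }
    seq <- paste(ch, collapse = "")
  }
  if (is.null(end)) end <- start + nchar(seq)
  methyl_reads(data.table::data.table(
    read_id = read_id, sample_id = sample_id, chrom = chrom,
    start = as.integer(start), end = as.integer(end), mapq = as.integer(mapq),
    converted_seq = seq, cpg_positions = list(as.integer(cpg_positions)),
    cpg_calls = list(as.logical(cpg_calls)), mate_merged = mate_merged, ...))
}

bind_reads <- function(...) {
  methyl_reads(data.table::rbindlist(list(...), fill = TRUE), validate = FALSE)
}

# A single-DMR fixture shared by noise-filter tests.
make_dmr <- function(dmr_id = "dmr_00001", chrom = "chr1", start = 100L,
                     end = 200L, direction = "hypo",
                     dmc_positions = seq(100L, 196L, by = 12L)) {
  data.table::data.table(dmr_id = dmr_id, chrom = chrom,
                         start = as.integer(start), end = as.integer(end),
                         direction = direction,
                         n_dmcs = length(dmc_positions),
                         dmc_positions = list(as.integer(dmc_positions)))
}

# Tiny encoder for fast structural/gradient tests.
tiny_model <- function(vocab = NULL, seed = 3, dropout = 0) {
  if (is.null(vocab))
    vocab <- c("[PAD]", "[CLS]", "[MASK]", "[UNK]",
               "AAAA", "AMLT", "CGAT", "TTTT", "GGCA", "MLTA")
  cfg <- model_config("desk", n_layers = 2, n_heads = 2, hidden = 8,
                      intermediate = 16, max_positions = 64,
                      dropout = dropout)
  build_encoder(cfg, vocab, seed = seed)
}

# Independent MCS oracle: scan maximal methylated runs explicitly.
mcs_oracle <- function(calls) {
  L <- length(calls)
  total <- 0; run <- 0
  for (x in c(as.logical(calls), FALSE)) {
    if (isTRUE(x)) run <- run + 1
    else { if (run > 0) total <- total + run^2; run <- 0 }
  }
  total / L^2
}

# Random recoded sequences rich in "ML" marks (for masking-rate tests).
random_recoded_seq <- function(len = 250, p_ml = 0.25) {
  units <- sample(c("ML", "A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(p_ml, rep((1 - p_ml) / 4, 4)))
  substr(paste(units, collapse = ""), 1L, len)
}
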