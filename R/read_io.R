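#' Methylation read tables
#'
#' A `methyl_reads` object is a `data.table` holding one aligned
#' methyl-seq fragment per row, with per-read CpG methylation calls.
#' Coordinates are 0-based half-open on the reference; each CpG site is
#' identified by the position of its forward-strand C, and calls from either
#' strand are collapsed onto that coordinate.
#'
#' Columns: `read_id`, `sample_id`, `chrom`, `start`, `end` (exclusive),
#' `mapq`, `converted_seq` (read bases in converted space, reference
#' orientation), `cpg_positions` (list column of sorted integer vectors),
#' `cpg_calls` (list column of logical vectors, `TRUE` = methylated) and
#' `mate_merged` (logical).
#'
#' @param dt a data.frame/data.table with the columns above.
#' @param validate check the invariants (call/position lengths match,
#'   positions strictly increasing and inside `[start, end)`, sequence length
#'   equals `end - start`).
#' @return a `methyl_reads` data.table.
#' @export
methyl_reads <- function(dt, validate = TRUE) {
  dt <- as.data.table(dt)
  required <- c("read_id", "sample_id", "chrom", "start", "end", "mapq",
                "converted_seq", "cpg_positions", "cpg_calls")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("missing read columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!"mate_merged" %in% names(dt)) dt[, mate_merged := FALSE]
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            mapq = as.integer(mapq))]
  if (validate) validate_methyl_reads(dt)
  setattr(dt, "class", c("methyl_reads", class(data.table())))
  dt[]
}

#' @rdname methyl_reads
#' @export
validate_methyl_reads <- function(dt) {
  np <- lengths(dt$cpg_positions)
  nc <- lengths(dt$cpg_calls)
  bad <- which(np != nc)
  if (length(bad))
    stop("cpg_positions/cpg_calls length mismatch for read(s): ",
         paste(head(dt$read_id[bad], 3), collapse = ", "), call. = FALSE)
  if (any(dt$end - dt$start != nchar(dt$converted_seq)))
    stop("converted_seq length must equal end - start", call. = FALSE)
  for (i in seq_len(nrow(dt))) {
    p <- dt$cpg_positions[[i]]
    if (length(p) == 0L) next
    if (is.unsorted(p, strictly = TRUE))
      stop("cpg_positions not strictly increasing for read ", dt$read_id[i],
           call. = FALSE)
    if (p[1L] < dt$start[i] || p[length(p)] >= dt$end[i])
      stop("cpg_positions outside [start, end) for read ", dt$read_id[i],
           call. = FALSE)
  }
  invisible(dt)
}

#' Load aligned methyl-seq reads
#'
#' Parses reads with per-CpG methylation calls from the canonical TSV dialect
#' or from a BAM file carrying Bismark-style `XM` methylation-call strings.
#' Reads below the mapping-quality cutoff, flagged as duplicates, or flagged
#' as secondary/supplementary (multi-mapping) are skipped. Duplicate
#' *marking* is assumed to have been done upstream; the loader honours the
#' flag but does not re-deduplicate.
#'
#' @param path TSV or BAM file.
#' @param sample_id sample identifier to stamp on the reads; for TSV input
#'   defaults to the file's own `sample_id` column.
#' @param min_mapq minimum mapping quality; reads with `mapq < min_mapq` are
#'   skipped (default 30).
#' @param format `"auto"` (by extension), `"tsv"` or `"bam"`.
#' @return a [methyl_reads] table.
#' @export
load_reads <- function(path, sample_id = NULL, min_mapq = 30,
                       format = c("auto", "tsv", "bam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "tsv"
  reads <- switch(format,
    tsv = read_reads_tsv(path, sample_id = sample_id),
    bam = read_reads_bam(path, sample_id = sample_id))
  reads[mapq >= min_mapq]
}

#' Read the canonical reads TSV dialect
#'
#' Tab-separated with header: `read_id`, `sample_id`, `chrom`, `start`,
#' `end`, `mapq`, `converted_seq`, `cpg_positions` (comma-joined, 0-based
#' forward-strand C coordinates), `cpg_calls` (comma-joined 0/1). An optional
#' `read_number` column (1/2) supports bias profiling of unmerged pairs.
#'
#' @param path file path.
#' @param sample_id optional override of the file's `sample_id` column.
#' @return a [methyl_reads] table.
#' @export
read_reads_tsv <- function(path, sample_id = NULL) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("cpg_positions", "cpg_calls")))
  if (!is.null(sample_id)) dt[, sample_id := sample_id]
  parse_int_csv <- function(x) {
    out <- strsplit(x, ",", fixed = TRUE)
    lapply(out, function(v) if (length(v) == 1L && v == "") integer(0) else {
      r <- suppressWarnings(as.integer(v))
      if (anyNA(r)) stop("malformed cpg field: ", paste(v, collapse = ","),
                         call. = FALSE)
      r
    })
  }
  pos <- parse_int_csv(dt$cpg_positions)
  calls <- lapply(parse_int_csv(dt$cpg_calls), function(v) v == 1L)
  dt[, cpg_positions := pos]
  dt[, cpg_calls := calls]
  methyl_reads(dt)
}

#' Write reads in the canonical TSV dialect
#'
#' @param reads a [methyl_reads] table.
#' @param path output file.
#' @export
write_reads_tsv <- function(reads, path) {
  out <- as.data.table(reads)[, .(
    read_id, sample_id, chrom, start, end, mapq, converted_seq,
    cpg_positions = vapply(cpg_positions, paste, "", collapse = ","),
    cpg_calls = vapply(cpg_calls, function(v) paste(as.integer(v), collapse = ","), ""),
    mate_merged)]
  if ("read_number" %in% names(reads)) out[, read_number := reads$read_number]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Parse one Bismark XM methylation-call string into forward-strand CpG
# coordinates + calls. XM convention: 'Z' methylated CpG, 'z' unmethylated
# CpG (other letters are CHG/CHH/unknown contexts, ignored here). For a
# reverse-strand alignment the call sits on the G of the forward-strand CpG,
# so the coordinate is shifted by -1 to the forward-strand C.
parse_xm_calls <- function(xm, ref_offsets, is_reverse) {
  ch <- strsplit(xm, "", fixed = TRUE)[[1]]
  idx <- which(ch == "Z" | ch == "z")
  if (!length(idx)) return(list(pos = integer(0), call = logical(0)))
  pos <- ref_offsets[idx]
  keep <- !is.na(pos)
  pos <- pos[keep]; idx <- idx[keep]
  if (is_reverse) pos <- pos - 1L
  o <- order(pos)
  list(pos = pos[o], call = (ch[idx] == "Z")[o])
}

# Map read offsets (1-based in SEQ) to 0-based reference positions using the
# CIGAR. Insertions/soft-clips yield NA; deletions consume reference only.
cigar_ref_offsets <- function(cigar, pos0) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops)) stop("malformed CIGAR: ", cigar, call. = FALSE)
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  type <- sub("\\d+", "", ops)
  out <- integer(0); ref <- pos0
  for (i in seq_along(ops)) {
    n <- lens[i]
    if (type[i] %in% c("M", "=", "X")) {
      out <- c(out, ref + seq_len(n) - 1L); ref <- ref + n
    } else if (type[i] %in% c("I", "S")) {
      out <- c(out, rep(NA_integer_, n))
    } else if (type[i] %in% c("D", "N")) {
      ref <- ref + n
    }
  }
  out
}

read_reads_bam <- function(path, sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package", call. = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "XM",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(b$qname)
  if (n == 0L)
    return(methyl_reads(data.table(read_id = character(0), sample_id = character(0),
      chrom = character(0), start = integer(0), end = integer(0), mapq = integer(0),
      converted_seq = character(0), cpg_positions = list(), cpg_calls = list(),
      mate_merged = logical(0), read_number = integer(0))))
  xm <- b$tag$XM
  seqs <- as.character(b$seq)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pos0 <- b$pos[i] - 1L   # BAM 1-based -> 0-based
    offs <- cigar_ref_offsets(b$cigar[i], pos0)
    if (is.na(xm[i]) || nchar(xm[i]) != length(offs))
      stop("missing or malformed XM tag for read ", b$qname[i], call. = FALSE)
    is_rev <- bitwAnd(b$flag[i], 16L) > 0L
    calls <- parse_xm_calls(xm[i], offs, is_rev)
    covered <- offs[!is.na(offs)]
    end <- max(covered) + 1L
    # keep only calls whose forward-strand C lies inside the covered interval
    keep <- calls$pos >= pos0 & calls$pos < end
    rn <- if (bitwAnd(b$flag[i], 128L) > 0L) 2L else 1L
    rows[[i]] <- list(read_id = b$qname[i],
                      chrom = as.character(b$rname[i]),
                      start = pos0, end = end, mapq = b$mapq[i],
                      converted_seq = seqs[i],
                      cpg_positions = list(calls$pos[keep]),
                      cpg_calls = list(calls$call[keep]),
                      read_number = rn)
  }
  dt <- rbindlist(rows)
  dt[, sample_id := sample_id %||% basename(path)]
  dt[, mate_merged := FALSE]
  # converted_seq covers the reference span only for pure-match alignments;
  # pad mismatched lengths with N so the length invariant holds
  nlen <- dt$end - dt$start
  fix <- which(nchar(dt$converted_seq) != nlen)
  for (i in fix) {
    s <- substr(dt$converted_seq[i], 1L, nlen[i])
    if (nchar(s) < nlen[i]) s <- paste0(s, strrep("N", nlen[i] - nchar(s)))
    set(dt, i, "converted_seq", s)
  }
  methyl_reads(dt)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `path`, `group` and optionally
#' `label`. Recognised groups: `tumor-tissue`, `para-tumor-tissue`,
#' `cfDNA-healthy`, `cfDNA-LD`, `cfDNA-HCC`.
#'
#' @param path sample sheet TSV.
#' @return a data.table.
#' @export
read_sample_sheet <- function(path) {
  sheet <- fread(path, sep = "\t", header = TRUE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet needs at least sample_id and group columns", call. = FALSE)
  sheet
}

#' Merge overlapping mate pairs
#'
#' Merges two mates of a pair into a single fragment-spanning read: the
#' interval is the union, CpG calls are the union of both mates' calls, and
#' the merged read is flagged `mate_merged`. Where both mates call the same
#' CpG and disagree, read 1's call wins and the conflict is counted (returned
#' in the `conflicts` attribute). Mates that neither overlap nor abut are
#' returned unmerged.
#'
#' @param read1,read2 single-row [methyl_reads] tables (mate 1 and 2).
#' @return a single-row `methyl_reads` table (merged), or the two input rows
#'   unmerged when the mates are disjoint. The integer attribute `conflicts`
#'   counts discordant overlapping calls.
#' @export
merge_pairs <- function(read1, read2) {
  stopifnot(nrow(read1) == 1L, nrow(read2) == 1L)
  if (read1$chrom != read2$chrom)
    stop("mates on different chromosomes: ", read1$read_id, call. = FALSE)
  if (read1$start > read2$start) return(merge_pairs(read2, read1))
  if (read2$start > read1$end) {   # disjoint, not even abutting
    out <- rbind(read1, read2)
    setattr(out, "conflicts", 0L)
    return(out)
  }
  p1 <- read1$cpg_positions[[1]]; c1 <- read1$cpg_calls[[1]]
  p2 <- read2$cpg_positions[[1]]; c2 <- read2$cpg_calls[[1]]
  shared <- intersect(p1, p2)
  conflicts <- sum(c1[match(shared, p1)] != c2[match(shared, p2)])
  only2 <- !(p2 %in% p1)
  pos <- c(p1, p2[only2]); call <- c(c1, c2[only2])
  o <- order(pos)
  start <- min(read1$start, read2$start)
  end <- max(read1$end, read2$end)
  # sequence: read 1 bases where covered, read 2 elsewhere
  chars <- rep("N", end - start)
  s2 <- strsplit(read2$converted_seq, "")[[1]]
  chars[(read2$start - start + 1L):(read2$end - start)] <- s2
  s1 <- strsplit(read1$converted_seq, "")[[1]]
  chars[(read1$start - start + 1L):(read1$end - start)] <- s1
  out <- data.table(read_id = read1$read_id, sample_id = read1$sample_id,
                    chrom = read1$chrom, start = start, end = end,
                    mapq = min(read1$mapq, read2$mapq),
                    converted_seq = paste(chars, collapse = ""),
                    cpg_positions = list(pos[o]), cpg_calls = list(call[o]),
                    mate_merged = TRUE)
  out <- methyl_reads(out)
  setattr(out, "conflicts", as.integer(conflicts))
  out
}

#' Merge all mate pairs in a read table
#'
#' Groups reads by `read_id` (and chromosome) and merges pairs with
#' [merge_pairs]; singletons pass through unchanged.
#'
#' @param reads a [methyl_reads] table with a `read_number` column or at most
#'   two rows per `read_id`.
#' @return a merged `methyl_reads` table; attribute `conflicts` totals the
#'   discordant overlapping calls across all pairs.
#' @export
merge_read_pairs <- function(reads) {
  reads <- as.data.table(reads)
  ids <- reads$read_id
  dup <- unique(ids[duplicated(ids)])
  singles <- reads[!read_id %in% dup]
  total_conflicts <- 0L
  merged <- list()
  for (id in dup) {
    pair <- reads[read_id == id]
    if (nrow(pair) != 2L)
      stop("read_id ", id, " occurs ", nrow(pair), " times; expected 2", call. = FALSE)
    if ("read_number" %in% names(pair)) pair <- pair[order(read_number)]
    m <- merge_pairs(pair[1], pair[2])
    total_conflicts <- total_conflicts + attr(m, "conflicts")
    merged[[id]] <- m
  }
  out <- rbindlist(c(list(singles), merged), fill = TRUE)
  out <- methyl_reads(out, validate = FALSE)
  setattr(out, "conflicts", total_conflicts)
  out
}

#' Per-position methylation bias profile
#'
#' Tallies, for each position within the read (0-based offset from the read's
#' reference-orientation start), the number of methylated and total CpG calls
#' across reads — the standard M-bias QC used to spot artificial methylation
#' loss at fragment ends. Read 1 and read 2 are profiled separately when a
#' `read_number` column is present.
#'
#' @param reads unmerged [methyl_reads].
#' @return a data.table with columns `read_number`, `position`,
#'   `methylated_count`, `total_count` and `meth_fraction`.
#' @export
methylation_bias_profile <- function(reads) {
  reads <- as.data.table(reads)
  rn <- if ("read_number" %in% names(reads)) reads$read_number else rep(1L, nrow(reads))
  k <- lengths(reads$cpg_positions)
  if (sum(k) == 0L) {
    warning("no CpG-bearing reads; empty bias profile")
    return(data.table(read_number = integer(0), position = integer(0),
                      methylated_count = integer(0), total_count = integer(0),
                      meth_fraction = numeric(0)))
  }
  long <- data.table(
    read_number = rep(rn, k),
    position = unlist(reads$cpg_positions) - rep(reads$start, k),
    call = unlist(reads$cpg_calls))
  prof <- long[, .(methylated_count = sum(call), total_count = .N),
               by = .(read_number, position)]
  setorder(prof, read_number, position)
  prof[, meth_fraction := methylated_count / total_count]
  prof[]
}
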