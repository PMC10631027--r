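test_that("reads TSV dialect round-trips per-read call vectors exactly", {
  reads <- bind_reads(
    make_read("r1", start = 95L, end = 200L,
              cpg_positions = c(100L, 110L, 125L),
              cpg_calls = c(TRUE, FALSE, TRUE)),
    make_read("r2", start = 300L, end = 360L),          # zero CpG calls
    make_read("r3", start = 10L, end = 80L,
              cpg_positions = 20L, cpg_calls = TRUE, mapq = 12L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reads_tsv(reads, path)
  back <- read_reads_tsv(path)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$cpg_positions, reads$cpg_positions)
  expect_equal(back$cpg_calls, reads$cpg_calls)
  expect_equal(back$converted_seq, reads$converted_seq)

  # hand-written fixture parses to the documented fields
  fix <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("read_id", "sample_id", "chrom", "start", "end", "mapq",
          "converted_seq", "cpg_positions", "cpg_calls", sep = "\t"),
    paste("rx", "sA", "chr2", 95, 127, 44,
          paste(rep("A", 32), collapse = ""), "100,110,125", "1,0,1",
          sep = "\t")), fix)
  parsed <- read_reads_tsv(fix)
  expect_identical(parsed$cpg_positions[[1]], c(100L, 110L, 125L))
  expect_identical(parsed$cpg_calls[[1]], c(TRUE, FALSE, TRUE))
})

test_that("load_reads applies the mapping-quality filter and keeps empty-call reads", {
  reads <- bind_reads(
    make_read("lowq", mapq = 20L, start = 0L, end = 50L),
    make_read("ok", mapq = 30L, start = 0L, end = 50L),
    make_read("nocalls", mapq = 60L, start = 100L, end = 150L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reads_tsv(reads, path)
  got <- load_reads(path, min_mapq = 30)
  expect_setequal(got$read_id, c("ok", "nocalls"))
  expect_length(got[read_id == "nocalls"]$cpg_calls[[1]], 0L)
})

test_that("methyl_reads validation rejects inconsistent records", {
  expect_error(make_read(cpg_positions = c(10L, 5L),
                         cpg_calls = c(TRUE, TRUE), start = 0L, end = 50L),
               "increasing")
  oob <- data.table::data.table(
    read_id = "o", sample_id = "s", chrom = "c", start = 0L, end = 50L,
    mapq = 30L, converted_seq = strrep("A", 50),
    cpg_positions = list(60L), cpg_calls = list(TRUE))
  expect_error(methyl_reads(oob), "outside")
  bad <- data.table::data.table(
    read_id = "b", sample_id = "s", chrom = "c", start = 0L, end = 10L,
    mapq = 30L, converted_seq = "ACGTACGTAC",
    cpg_positions = list(c(1L, 3L)), cpg_calls = list(TRUE))
  expect_error(methyl_reads(bad), "length mismatch")
})

test_that("merge_pairs merges overlaps, resolves conflicts from read 1, and is idempotent", {
  r1 <- make_read("p", start = 0L, end = 150L,
                  cpg_positions = c(10L, 120L), cpg_calls = c(TRUE, TRUE))
  r2 <- make_read("p", start = 100L, end = 250L,
                  cpg_positions = c(120L, 200L), cpg_calls = c(TRUE, FALSE))
  m <- merge_pairs(r1, r2)
  expect_equal(c(m$start, m$end), c(0L, 250L))
  expect_true(m$mate_merged)
  expect_identical(m$cpg_positions[[1]], c(10L, 120L, 200L))
  expect_identical(m$cpg_calls[[1]], c(TRUE, TRUE, FALSE))
  expect_identical(attr(m, "conflicts"), 0L)
  expect_equal(nchar(m$converted_seq), 250L)

  # planted conflict at 120: read 1 wins, conflict counted
  r2c <- make_read("p", start = 100L, end = 250L,
                   cpg_positions = c(120L, 200L), cpg_calls = c(FALSE, FALSE))
  mc <- merge_pairs(r1, r2c)
  expect_true(mc$cpg_calls[[1]][2])
  expect_identical(attr(mc, "conflicts"), 1L)

  # identical mates: merged read equals either mate's interval
  mi <- merge_pairs(r1, r1)
  expect_equal(c(mi$start, mi$end), c(r1$start, r1$end))
  expect_identical(mi$cpg_calls[[1]], r1$cpg_calls[[1]])

  # distant mates come back unmerged
  far <- make_read("p", start = 500L, end = 600L)
  expect_equal(nrow(merge_pairs(r1, far)), 2L)

  # merged call count equals the union of CpG positions
  expect_length(m$cpg_calls[[1]],
                length(union(r1$cpg_positions[[1]], r2$cpg_positions[[1]])))
})

test_that("merge_read_pairs merges by read id and totals conflicts", {
  reads <- bind_reads(
    make_read("p", start = 0L, end = 150L, cpg_positions = 10L,
              cpg_calls = TRUE, read_number = 1L),
    make_read("p", start = 100L, end = 250L, cpg_positions = 120L,
              cpg_calls = FALSE, read_number = 2L),
    make_read("solo", start = 0L, end = 60L))
  out <- merge_read_pairs(reads)
  expect_equal(nrow(out), 2L)
  expect_true(out[read_id == "p", mate_merged])
})

test_that("bias profile tallies per-position methylation and equals a direct count", {
  # constant inputs
  all_m <- bind_reads(
    make_read("a", start = 0L, cpg_positions = c(5L, 9L), cpg_calls = c(TRUE, TRUE)),
    make_read("b", start = 100L, cpg_positions = c(105L, 109L), cpg_calls = c(TRUE, TRUE)))
  prof <- methylation_bias_profile(all_m)
  expect_true(all(prof$meth_fraction == 1))
  expect_equal(prof[position == 5, total_count], 2L)  # totals = covering reads

  all_u <- bind_reads(
    make_read("a", start = 0L, cpg_positions = 5L, cpg_calls = FALSE))
  expect_true(all(methylation_bias_profile(all_u)$meth_fraction == 0))

  # unmethylated calls planted only in the first 10 positions of read 2
  set.seed(42)
  rows <- lapply(1:40, function(i) {
    rn <- if (i %% 2 == 0) 2L else 1L
    pos <- sort(sample(seq(0L, 48L, by = 2L), 6)) + i * 100L
    off <- pos - i * 100L
    calls <- if (rn == 2L) off >= 10L else rep(TRUE, 6)
    make_read(sprintf("r%02d", i), start = i * 100L,
              cpg_positions = pos, cpg_calls = calls, read_number = rn)
  })
  reads <- do.call(bind_reads, rows)
  prof <- methylation_bias_profile(reads)
  expect_true(all(prof[read_number == 1, meth_fraction] == 1))
  expect_true(all(prof[read_number == 2 & position < 10, meth_fraction] == 0))
  expect_true(all(prof[read_number == 2 & position >= 10, meth_fraction] == 1))
  # totals equal a direct tally over the fixture
  direct <- table(unlist(mapply(function(p, s) p - s,
                                reads$cpg_positions, reads$start)))
  got <- prof[, .(n = sum(total_count)), by = position]
  expect_equal(got$n, as.integer(direct[as.character(got$position)]),
               ignore_attr = TRUE)

  expect_warning(methylation_bias_profile(make_read("z", start = 0L, end = 30L)),
                 "no CpG")
})

test_that("BAM records with Bismark XM tags parse to forward-strand CpG calls", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  # forward read spans ref 3..12 with a methylated CpG at 6 ("CG") and an
  # unmethylated one at 10 ("TG"); reverse read carries its call on the G at
  # ref 13, which collapses to the forward-strand C at 12. A duplicate and a
  # low-mapq record must be skipped.
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100",
    paste("fwd", 0, "chr1", 4, 42, "10M", "*", 0, 0,
          "AAACGAATGA", "IIIIIIIIII", "XM:Z:...Z...z..", sep = "\t"),
    paste("rev", 16, "chr1", 11, 42, "8M", "*", 0, 0,
          "AAAGAAAA", "IIIIIIII", "XM:Z:...Z....", sep = "\t"),
    paste("dup", 1024, "chr1", 21, 42, "5M", "*", 0, 0,
          "AAAAA", "IIIII", "XM:Z:.....", sep = "\t"),
    paste("lowq", 0, "chr1", 31, 10, "5M", "*", 0, 0,
          "AAAAA", "IIIII", "XM:Z:.....", sep = "\t")), sam)
  bam <- suppressWarnings(Rsamtools::asBam(sam, withr::local_tempfile(),
                                           overwrite = TRUE))
  reads <- load_reads(bam, sample_id = "sA", min_mapq = 30, format = "bam")
  expect_setequal(reads$read_id, c("fwd", "rev"))
  fwd <- reads[read_id == "fwd"]
  expect_identical(fwd$cpg_positions[[1]], c(6L, 10L))
  expect_identical(fwd$cpg_calls[[1]], c(TRUE, FALSE))
  rev <- reads[read_id == "rev"]
  expect_identical(rev$cpg_positions[[1]], 12L)   # G at ref 13 -> C at 12
  expect_true(rev$cpg_calls[[1]])
})
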