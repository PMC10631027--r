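test_that("MCS matches hand-enumerated block spectra", {
  expect_equal(mcs(rep(TRUE, 8)), 1)            # one block of 8: 64/64
  expect_equal(mcs(rep(FALSE, 5)), 0)           # no blocks
  # M,M,U,M: blocks of 2 and 1 -> (4 + 1) / 16
  expect_equal(mcs(c(TRUE, TRUE, FALSE, TRUE)), 0.3125)
  expect_equal(mcs(TRUE), 1)
  expect_error(mcs(logical(0)), "zero CpGs")
  expect_error(mcs(c(TRUE, NA)), "NA")
})

test_that("MCS equals the scanning oracle and obeys its invariants on fuzzed vectors", {
  set.seed(101)
  for (i in 1:2000) {
    calls <- runif(sample(1:40, 1)) < runif(1)
    s <- mcs(calls)
    expect_identical(s, mcs_oracle(calls))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s == 1, all(calls))
  }
  # fragmenting one methylated block strictly decreases MCS
  for (i in 1:200) {
    L <- sample(4:30, 1)
    calls <- rep(TRUE, L)
    cut <- sample(2:(L - 1), 1)
    frag <- calls; frag[cut] <- FALSE
    expect_lt(mcs(frag), mcs(calls))
  }
})

test_that("sliding windows use 150 bp length, 50 bp step, and an anchored last window", {
  # short DMR: evaluated whole
  w <- dmr_windows(100, 220)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$win_start, w$win_end), c(100L, 220L))
  # 400 bp DMR: offsets 0, 50, ..., 250
  w <- dmr_windows(0, 400)
  expect_equal(w$win_start, seq(0L, 250L, by = 50L))
  expect_true(all(w$win_end - w$win_start == 150L))
  # window count matches ceil((len - 150) / 50) + 1 by direct enumeration
  for (len in c(151, 199, 200, 201, 350, 420, 1000)) {
    w <- dmr_windows(0, len)
    expect_equal(nrow(w), ceiling((len - 150) / 50) + 1)
    expect_equal(w$win_end[nrow(w)], len)       # every base covered
    expect_true(all(w$win_end <= len))
  }
})

test_that("read eligibility needs actual calls at three or more DMC positions", {
  dmcs <- c(100L, 120L, 140L, 160L)
  expect_false(read_eligible(c(100L, 120L), c(TRUE, TRUE), dmcs))
  expect_true(read_eligible(c(100L, 120L, 140L), c(TRUE, FALSE, TRUE), dmcs))
  # covers 4 DMC positions but has calls at only 2 of them
  expect_false(read_eligible(c(100L, 160L), c(TRUE, TRUE), dmcs))
  # calls outside the evaluated interval do not count
  expect_false(read_eligible(c(100L, 120L, 140L), rep(TRUE, 3), dmcs,
                             wstart = 110, wend = 150))
})

test_that("healthy bounds are the min/max MCS of eligible reads per window", {
  dmr <- make_dmr(start = 100L, end = 150L,
                  dmc_positions = c(100L, 110L, 120L, 130L, 140L))
  mk <- function(id, calls) make_read(id, "h1", start = 95L, end = 160L,
                                      cpg_positions = c(100L, 110L, 120L, 130L, 140L),
                                      cpg_calls = calls)
  # MCS values: 0.2 (one of 5 block 1: 1/25... ) use crafted calls
  h <- bind_reads(
    mk("h1", c(TRUE, FALSE, TRUE, FALSE, FALSE)),   # blocks 1,1 -> 2/25 = 0.08
    mk("h2", c(TRUE, TRUE, TRUE, FALSE, FALSE)),    # 9/25 = 0.36
    mk("h3", rep(TRUE, 5)))                         # 1
  b <- compute_bounds(h, dmr)
  expect_equal(nrow(b), 1L)
  expect_equal(b$s_min, 0.08)
  expect_equal(b$s_max, 1)
  expect_equal(b$n_healthy, 3L)
  # single eligible read: s_min == s_max
  b1 <- compute_bounds(mk("only", c(TRUE, FALSE, TRUE, FALSE, TRUE)), dmr)
  expect_equal(b1$s_min, b1$s_max)
  # no eligible reads: NA bounds
  b0 <- compute_bounds(make_read("far", start = 500L, end = 560L), dmr)
  expect_true(is.na(b0$s_min))
})

test_that("tumor-read filtering removes at the healthy boundary, inclusive", {
  dmcs <- c(100L, 110L, 120L, 130L, 140L)
  dmr_hypo <- make_dmr(direction = "hypo", start = 100L, end = 150L,
                       dmc_positions = dmcs)
  bounds <- data.table::data.table(dmr_id = "dmr_00001", win_start = 100L,
                                   win_end = 150L, s_min = 0.2, s_max = 0.8,
                                   n_healthy = 5L)
  mk <- function(id, calls, sample = "t1")
    make_read(id, sample, start = 95L, end = 160L, cpg_positions = dmcs,
              cpg_calls = calls)
  # MCS 5/25 = 0.2 exactly -> removed (>= s_min); 0.12 -> retained
  at_bound <- mk("at", c(TRUE, TRUE, FALSE, FALSE, TRUE))   # 4+1 = 5/25 = 0.2
  below <- mk("below", c(TRUE, FALSE, TRUE, FALSE, TRUE))   # 3/25 = 0.12
  out <- filter_tumor_reads(bind_reads(at_bound, below), dmr_hypo, bounds)
  expect_identical(out$retained$read_id, "below")
  expect_equal(out$stats$reads_before, 2L)
  expect_equal(out$stats$reads_after, 1L)
  expect_equal(out$stats$t_i, 0.5)

  # hyper DMR: MCS == s_max removed, above retained
  dmr_hyper <- make_dmr(direction = "hyper", start = 100L, end = 150L,
                        dmc_positions = dmcs)
  at_max <- mk("atmax", c(TRUE, TRUE, TRUE, TRUE, FALSE))   # 16/25 = 0.64
  full <- mk("full", rep(TRUE, 5))                          # 1
  bounds64 <- data.table::copy(bounds); bounds64$s_max <- 0.64
  out2 <- filter_tumor_reads(bind_reads(at_max, full), dmr_hyper, bounds64)
  expect_identical(out2$retained$read_id, "full")

  # ineligible reads (< 3 DMC calls) are excluded from the pool entirely
  inel <- make_read("inel", "t1", start = 95L, end = 160L,
                    cpg_positions = c(100L, 110L), cpg_calls = c(TRUE, TRUE))
  out3 <- filter_tumor_reads(bind_reads(at_bound, inel), dmr_hypo, bounds)
  expect_equal(out3$stats$reads_before, 1L)   # only the eligible read counts
  # a DMR whose windows all lack bounds is dropped
  nob <- data.table::copy(bounds); nob$s_min <- NA_real_; nob$s_max <- NA_real_
  expect_true(filter_tumor_reads(bind_reads(at_bound), dmr_hypo, nob)$dropped)
})

test_that("windowed filtering removes a read flagged in any window", {
  # 400 bp hypo DMR. Healthy reads: one fully methylated, one sparsely
  # methylated below position 200 and fully methylated above, so early
  # windows get a low s_min and late windows s_min = 1.
  dmcs <- seq(0L, 396L, by = 12L)
  dmr <- make_dmr(direction = "hypo", start = 0L, end = 400L,
                  dmc_positions = dmcs)
  h1 <- make_read("h1", "h", start = 0L, end = 400L, cpg_positions = dmcs,
                  cpg_calls = rep(TRUE, length(dmcs)))
  h2 <- make_read("h2", "h", start = 0L, end = 400L, cpg_positions = dmcs,
                  cpg_calls = dmcs >= 200L |
                    (seq_along(dmcs) %% 4 == 0))
  bounds <- compute_bounds(bind_reads(h1, h2), dmr)
  expect_equal(nrow(bounds), ceiling((400 - 150) / 50) + 1)
  # tumor read unmethylated below 200 (clean in early windows) and fully
  # methylated above (MCS 1 >= s_min = 1 in the last windows): any-window
  # semantics must remove it
  tum <- make_read("t", "t1", start = 0L, end = 400L, cpg_positions = dmcs,
                   cpg_calls = dmcs >= 200L)
  out <- filter_tumor_reads(bind_reads(tum), dmr, bounds)
  expect_equal(nrow(out$retained), 0L)
  # restricted to the first window only, the same read survives
  out1 <- filter_tumor_reads(bind_reads(tum), dmr, bounds[1])
  expect_equal(nrow(out1$retained), 1L)
  expect_lte(out$stats$reads_after, out$stats$reads_before)
})

test_that("DUS matches the printed formula and its boundary interpretations", {
  expect_equal(compute_dus(rep(1, 5)), 1)   # no reads filtered anywhere
  expect_equal(compute_dus(rep(0, 5)), 0)   # everything filtered everywhere
  # n = 2, t = (0.5, 0): mean t = 0.25, d = 0.5
  expect_equal(compute_dus(c(0.5, 0)), 0.125)
  expect_error(compute_dus(numeric(0)), "zero individuals")
  expect_error(compute_dus(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing in each t_i
  set.seed(5)
  for (i in 1:50) {
    t <- runif(sample(2:8, 1))
    j <- sample(seq_along(t), 1)
    t2 <- t; t2[j] <- min(1, t[j] + runif(1) * (1 - t[j]))
    expect_gte(compute_dus(t2), compute_dus(t))
  }
})

test_that("DMR screening keeps top-DUS hypo DMRs and all hyper DMRs above the read cutoff", {
  dmrs <- data.table::data.table(
    dmr_id = sprintf("d%d", 1:6),
    chrom = "chr1", start = (1:6) * 1000L, end = (1:6) * 1000L + 200L,
    direction = c("hypo", "hypo", "hypo", "hyper", "hyper", "hypo"),
    n_dmcs = 6L,
    dus = c(0.9, 0.8, 0.7, 0.2, 0.1, 0.9),
    retained_read_total = c(300L, 300L, 200L, 300L, 201L, 250L))
  # exactly 200 retained reads is excluded (strictly more required)
  sel <- screen_dmrs(dmrs, min_retained = 200, n_hypo = 10)
  expect_false("d3" %in% sel$dmr_id)
  expect_true(all(c("d4", "d5") %in% sel$dmr_id))  # all qualifying hyper
  # top-k hypo by DUS with deterministic tie-break (retained total desc)
  sel1 <- suppressMessages(screen_dmrs(dmrs, min_retained = 200, n_hypo = 1))
  expect_identical(sel1[direction == "hypo", dmr_id], "d1")  # tie: 300 > 250
  expect_identical(sel1, suppressMessages(
    screen_dmrs(dmrs[sample.int(6)], min_retained = 200, n_hypo = 1)))
})

test_that("denoise_dmrs attaches DUS and retained totals per DMR", {
  dmcs <- c(100L, 112L, 124L, 136L, 148L)
  dmr <- make_dmr(start = 100L, end = 150L, dmc_positions = dmcs)
  healthy <- bind_reads(
    make_read("h1", "h1", start = 95L, end = 160L, cpg_positions = dmcs,
              cpg_calls = rep(TRUE, 5)),
    make_read("h2", "h2", start = 95L, end = 160L, cpg_positions = dmcs,
              cpg_calls = c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  tumor <- bind_reads(
    make_read("t1", "tumA", start = 95L, end = 160L, cpg_positions = dmcs,
              cpg_calls = rep(FALSE, 5)),       # MCS 0 < s_min: retained
    make_read("t2", "tumA", start = 95L, end = 160L, cpg_positions = dmcs,
              cpg_calls = rep(TRUE, 5)),        # MCS 1: removed
    make_read("t3", "tumB", start = 95L, end = 160L, cpg_positions = dmcs,
              cpg_calls = c(FALSE, TRUE, FALSE, FALSE, FALSE)))
  den <- denoise_dmrs(dmr, tumor, healthy)
  expect_equal(nrow(den$dmrs), 1L)
  # tumA: 1/2 retained; tumB: 1/1 -> DUS = mean(0.5, 1) * 1 = 0.75
  expect_equal(den$dmrs$dus, 0.75)
  expect_equal(den$dmrs$retained_read_total, 2L)
  expect_setequal(den$retained$read_id, c("t1", "t3"))
})
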