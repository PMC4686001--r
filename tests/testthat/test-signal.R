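test_that("count_fragments implements half-open counting with read shift", {
  f <- mk_fragments(c(100, 150, 199), shift = 0L)
  expect_equal(count_fragments(iv("chrA", 100, 200), f), 3L)
  expect_equal(count_fragments(iv("chrA", 100, 199), f), 2L)
  # + read at 100 with shift 150 counts at 250
  f <- mk_fragments(100, shift = 150L)
  expect_equal(count_fragments(iv("chrA", 100, 200), f), 0L)
  expect_equal(count_fragments(iv("chrA", 200, 300), f), 1L)
  # - read at 400 with shift 150 counts at 250
  f <- mk_fragments(400, strand = "-", shift = 150L)
  expect_equal(count_fragments(iv("chrA", 200, 300), f), 1L)
})

test_that("binary-search counting equals a linear scan on random data", {
  set.seed(41)
  pos <- sample.int(1e6, 1e4, replace = TRUE)
  strand <- sample(c("+", "-"), 1e4, replace = TRUE)
  f <- fragment_set("x", rep("chrA", 1e4), pos, strand, shift = 150L)
  shifted <- ifelse(strand == "-", pos - 150L, pos + 150L)
  for (i in 1:100) {
    s <- sample.int(1e6, 1)
    e <- s + sample.int(5000, 1)
    expect_equal(count_fragments(iv("chrA", s, e), f),
                 sum(shifted >= s & shifted < e))
  }
})

test_that("count_fragments is additive over a bin partition of a region", {
  set.seed(42)
  f <- mk_fragments(sample.int(10000, 500, replace = TRUE), shift = 0L)
  total <- count_fragments(iv("chrA", 2000, 4000), f)
  edges <- seq(2000, 4000, by = 100)
  parts <- vapply(seq_len(length(edges) - 1), function(i)
    count_fragments(iv("chrA", edges[i], edges[i + 1]), f), integer(1))
  expect_equal(sum(parts), total)
})

test_that("peak_fpkm follows the FPKM formula exactly", {
  f <- fragment_set("x", rep("chrA", 1e4), seq_len(1e4), rep("+", 1e4),
                    shift = 0L)
  f$library_size <- 1e7   # formula check with a stated library size
  f$shifted$chrA <- sort(sample.int(500, 20) + 99)   # 20 in [100, 600)
  expect_equal(peak_fpkm(iv("chrA", 100, 600), f), 20 / (0.5 * 10))
  expect_equal(peak_fpkm(iv("chrA", 5e5, 5e5 + 100), f), 0)
  expect_error(peak_fpkm(iv("chrA", 100, 100), f), "zero-length")
})

test_that("mean peak FPKM under uniform fragments matches the closed form", {
  set.seed(43)
  L <- 1e6; lambda <- 0.02
  n <- rpois(1, lambda * L)
  f <- fragment_set("x", rep("chrA", n), sample.int(L, n, replace = TRUE),
                    rep("+", n), shift = 0L)
  peaks <- genomic_intervals("chrA", seq(0, by = 5000, length.out = 200),
                             seq(500, by = 5000, length.out = 200))
  vals <- peak_fpkm(peaks, f)
  expected <- lambda * 1e9 / f$library_size
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se + 1e-9)
})

test_that("FRiP matches hand counts and a per-fragment membership oracle", {
  f <- mk_fragments(c(150, 160, 170), shift = 0L)
  expect_equal(frip(genomic_intervals("chrA", 100, 200), f), 1.0)
  set.seed(44)
  pos <- sample.int(50000, 1000, replace = TRUE)
  f <- mk_fragments(pos, shift = 0L)
  # overlapping peaks: merged before counting, no double counting
  peaks <- rbind(genomic_intervals("chrA", c(1000, 1200), c(1500, 1700)),
                 genomic_intervals("chrA", 30000, 31000))
  inside <- vapply(pos, function(p)
    any(p >= peaks$start & p < peaks$end), logical(1))
  expect_equal(frip(peaks, f), mean(inside))
  expect_lte(frip(peaks, f), 1)
})

test_that("FPKM and FRiP are invariant to duplicating every fragment", {
  set.seed(45)
  pos <- sample.int(50000, 500, replace = TRUE)
  f1 <- mk_fragments(pos, shift = 0L)
  f2 <- mk_fragments(c(pos, pos), shift = 0L)
  peaks <- genomic_intervals("chrA", c(1000, 9000), c(2000, 9800))
  expect_equal(peak_fpkm(peaks, f1), peak_fpkm(peaks, f2))
  expect_equal(frip(peaks, f1), frip(peaks, f2))
})

test_that("coverage_profile puts point mass in the central bin", {
  part <- structure(list(experiment_id = "e",
                         common = genomic_intervals("chrA", 1000, 1400),
                         sample_specific = genomic_intervals(character(0),
                                                             integer(0),
                                                             integer(0)),
                         undetected = genomic_intervals(character(0),
                                                        integer(0),
                                                        integer(0))),
                    class = "peak_partition")
  f <- mk_fragments(rep(1200, 50), shift = 0L)  # all at the midpoint
  pr <- coverage_profile(part, f, window_half_width = 200L, bin_width = 10L)
  curve <- pr$curves$common
  central <- which(pr$offsets == 5)   # bin [1200, 1210) holds the midpoint
  expect_equal(which(curve > 0), central)
  # empty sets give NA curves, not zeros
  expect_true(all(is.na(pr$curves$sample_specific)))
  # profile mass: back-converted counts equal fragments in the window
  counts <- curve * (10 / 1000) * (f$library_size / 1e6)
  expect_equal(sum(counts), 50)
})

test_that("uniform background gives a flat profile within 3 SE", {
  set.seed(46)
  L <- 2e6; lambda <- 0.05
  n <- rpois(1, lambda * L)
  f <- fragment_set("x", rep("chrA", n), sample.int(L, n, replace = TRUE),
                    rep("+", n), shift = 0L)
  peaks <- genomic_intervals("chrA", seq(10000, by = 9000, length.out = 150),
                             seq(10400, by = 9000, length.out = 150))
  part <- structure(list(experiment_id = "e", common = peaks,
                         sample_specific = peaks[0, ],
                         undetected = peaks[0, ]),
                    class = "peak_partition")
  pr <- coverage_profile(part, f)
  curve <- pr$curves$common
  expected <- lambda * 1e9 / f$library_size
  se <- stats::sd(curve) / sqrt(length(curve))
  expect_lt(abs(mean(curve) - expected), 3 * se + 1e-9)
  # flat: no bin deviates wildly (Poisson, 150 peaks averaged)
  expect_lt(max(abs(curve - expected)) / expected, 0.5)
})

test_that("enriched synthetic conditions order common above undetected", {
  gen <- generate_condition(SMALL_GENOME,
                            condition_spec("cov", "similar",
                                           n_true_sites = 300,
                                           library_size = 2e5,
                                           enrichment_fold = 5, seed = 47))
  parts <- partition_condition(gen$condition)
  for (i in seq_along(parts)) {
    pr <- coverage_profile(parts[[i]], gen$fragments[[i]])
    mu <- vapply(pr$curves, mean, numeric(1))
    expect_gt(mu[["common"]], mu[["undetected"]])
  }
})

test_that("depth_vs_peaks flags the discordant depth/peak-count case", {
  mkc <- function(n1, n2) {
    mk_condition(list(rand_intervals(n1), rand_intervals(n2)))
  }
  set.seed(48)
  cond <- mkc(40, 10)
  f_many <- mk_fragments(sample.int(4000, 3000, replace = TRUE), shift = 0L,
                         id = "rep1")
  f_few <- mk_fragments(sample.int(4000, 1000, replace = TRUE), shift = 0L,
                        id = "rep2")
  d <- depth_vs_peaks(cond, list(rep1 = f_many, rep2 = f_few))
  expect_true(d$depth_concordant)
  d <- depth_vs_peaks(cond, list(rep1 = f_few, rep2 = f_many))
  expect_false(d$depth_concordant)
  # missing fragment data degrades to a partial record
  d <- depth_vs_peaks(cond, list(rep1 = f_many))
  expect_false(d$complete)
  expect_null(d$depth_concordant)
})

test_that("higher enrichment brings more peaks than higher depth does", {
  # replicates at equal depth but 2x different ChIP efficiency: the
  # better-enriched replicate should detect more peaks and show higher
  # median common-peak FPKM in nearly every run
  tiny <- genome_spec(data.frame(name = "chr1", length = 1e6))
  hits <- 0L
  n_runs <- 40L
  for (s in seq_len(n_runs)) {
    gen <- generate_condition(
      tiny,
      condition_spec("enr", "sensitive", n_true_sites = 120,
                     sensitivity = c(0.9, 0.45),
                     enrichment_fold = c(6, 3), library_size = 5e4,
                     false_peak_rate = 1, seed = 5000 + s))
    d <- depth_vs_peaks(gen$condition, gen$fragments)
    if (isTRUE(d$enrichment_concordant)) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})
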