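test_that("narrowPeak fields map directly and degenerate BED6 gets sentinels", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t700\t900\tpk2\t10\t.\t1.1\t2.2\t3.3\t50",
               "chr1\t100\t600\tpk1\t800\t.\t5.2\t10.1\t8.3\t250"), path)
  p <- read_narrowpeak(path)
  expect_equal(nrow(p), 2L)
  # sorted by start, so pk1 first despite file order
  expect_equal(p$name, c("pk1", "pk2"))
  full <- p[p$name == "pk1", ]
  expect_equal(full$start, 100L)
  expect_equal(full$end, 600L)
  expect_equal(full$score, 800L)
  expect_equal(full$signal, 5.2)
  expect_equal(full$pvalue, 10.1)
  expect_equal(full$qvalue, 8.3)
  expect_equal(full$summit, 250L)
  writeLines("chr1\t50\t80\tpk0\t10\t+", path)
  bed6 <- read_narrowpeak(path)
  expect_true(is.na(bed6$signal) && is.na(bed6$pvalue) && is.na(bed6$qvalue))
  expect_equal(bed6$summit, -1L)
})

test_that("malformed peak files raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t600\tpk1\t0\t.",
               "chr1\t700\t700\tpk2\t0\t."), path)
  expect_error(read_narrowpeak(path), "line 2.*end <= start")
  writeLines("chr1\t100", path)
  expect_error(read_narrowpeak(path), "line 1")
  writeLines("chr1\t100\t600\tpk1\t0\t.\t1\t1\t1\t900", path)
  expect_error(read_narrowpeak(path), "summit")
})

test_that("write/read round trip of a synthetic 50-peak file is byte-identical", {
  gen <- generate_condition(SMALL_GENOME,
                            condition_spec("rt", "similar",
                                           n_true_sites = 50, seed = 11),
                            fragments = FALSE)
  peaks <- gen$condition$experiments[[1]]$peaks
  f1 <- withr::local_tempfile(fileext = ".narrowPeak")
  f2 <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(peaks, f1)
  back <- read_narrowpeak(f1)
  write_narrowpeak(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$start, peaks$start)
  expect_equal(back$signal, peaks$signal)
})

test_that("overlaps() implements the >=1 bp half-open rule", {
  expect_true(overlaps(iv("chr1", 100, 200), iv("chr1", 199, 300)))
  expect_false(overlaps(iv("chr1", 100, 200), iv("chr1", 200, 300)))
  expect_false(overlaps(iv("chr1", 100, 200), iv("chr2", 100, 200)))
  set.seed(21)
  a <- rand_intervals(30)
  b <- rand_intervals(30)
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      expect_equal(overlaps(a[i, ], b[j, ]),
                   oracle_overlaps(a[i, ], b[j, ]))
})

test_that("common_regions matches examples and the per-base oracle", {
  expect_equal(common_regions(list(genomic_intervals("chr1", 100, 300),
                                   genomic_intervals("chr1", 200, 400))),
               genomic_intervals("chr1", 200, 300),
               ignore_attr = TRUE)
  expect_equal(nrow(common_regions(list(genomic_intervals("chr1", 0, 100),
                                        genomic_intervals("chr1", 500, 600)))),
               0L)
  expect_error(common_regions(list(genomic_intervals("chr1", 0, 10))),
               "at least 2")
  set.seed(22)
  for (rep in 1:5) {
    lists <- replicate(3, rand_intervals(40), simplify = FALSE)
    got <- common_regions(lists)
    expect_equal(got, oracle_common(lists), ignore_attr = TRUE)
  }
})

test_that("merge_regions merges on >=1 bp only and matches the per-base oracle", {
  expect_equal(merge_regions(list(genomic_intervals("chr1", 100, 200),
                                  genomic_intervals("chr1", 150, 250))),
               genomic_intervals("chr1", 100, 250), ignore_attr = TRUE)
  abut <- merge_regions(list(genomic_intervals("chr1", 100, 200),
                             genomic_intervals("chr1", 200, 300)))
  expect_equal(nrow(abut), 2L)
  set.seed(23)
  for (rep in 1:5) {
    lists <- replicate(2, rand_intervals(40), simplify = FALSE)
    got <- merge_regions(lists)
    # abutting peaks stay split, so compare per-base coverage, not rows
    expect_equal(base_cover(got), base_cover(oracle_merge(lists)))
    expect_true(all(got$end > got$start))
    expect_equal(sum(got$end - got$start),
                 sum(vapply(base_cover(do.call(rbind, lists)), sum,
                            integer(1))))
  }
})

test_that("partition_condition matches the forced two-replicate example", {
  cond <- mk_condition(list(genomic_intervals("chr1", c(0, 200), c(100, 300)),
                            genomic_intervals("chr1", 250, 350)))
  parts <- partition_condition(cond)
  expect_equal(parts[[1]]$common[, c("start", "end")],
               data.frame(start = 200L, end = 300L), ignore_attr = TRUE)
  expect_equal(parts[[1]]$sample_specific$start, 0L)
  expect_equal(nrow(parts[[1]]$undetected), 0L)
  expect_equal(parts[[2]]$common$start, 250L)
  expect_equal(nrow(parts[[2]]$sample_specific), 0L)
  expect_equal(parts[[2]]$undetected,
               data.frame(chrom = "chr1", start = 0L, end = 100L),
               ignore_attr = TRUE)
})

test_that("identical replicate lists give empty specific and undetected sets", {
  l <- rand_intervals(20)
  parts <- partition_condition(mk_condition(list(l, l, l)))
  for (p in parts) {
    expect_equal(nrow(p$sample_specific), 0L)
    expect_equal(nrow(p$undetected), 0L)
    expect_equal(nrow(p$common), nrow(l))
  }
})

test_that("three-replicate partition agrees with a nested-loop census", {
  set.seed(24)
  for (rep in 1:5) {
    lists <- replicate(3, rand_intervals(25), simplify = FALSE)
    cond <- mk_condition(lists)
    parts <- partition_condition(cond)
    for (e in 1:3) {
      mine <- lists[[e]]
      others <- lists[-e]
      n_hit <- vapply(seq_len(nrow(mine)), function(i)
        sum(vapply(others, function(o)
          any(vapply(seq_len(nrow(o)), function(j)
            oracle_overlaps(mine[i, ], o[j, ]), logical(1))), logical(1))),
        numeric(1))
      expect_equal(nrow(parts[[e]]$common), sum(n_hit == 2))
      expect_equal(nrow(parts[[e]]$sample_specific), sum(n_hit == 0))
      # undetected census: merged others' regions with no overlap in e
      om <- oracle_merge(others)
      undet <- vapply(seq_len(nrow(om)), function(j)
        !any(vapply(seq_len(nrow(mine)), function(i)
          oracle_overlaps(om[j, ], mine[i, ]), logical(1))), logical(1))
      expect_equal(parts[[e]]$undetected, om[undet, , drop = FALSE],
                   ignore_attr = TRUE)
    }
  }
})

test_that("partition is symmetric under replicate relabeling and conserves counts", {
  set.seed(25)
  lists <- replicate(3, rand_intervals(20), simplify = FALSE)
  parts <- partition_condition(mk_condition(lists))
  perm <- c(3, 1, 2)
  parts_perm <- partition_condition(mk_condition(lists[perm]))
  for (k in 1:3)
    expect_equal(parts_perm[[k]]$common[, c("chrom", "start", "end")],
                 parts[[perm[k]]]$common[, c("chrom", "start", "end")],
                 ignore_attr = TRUE)
  # two replicates: every peak is either common or specific
  two <- partition_condition(mk_condition(lists[1:2]))
  for (k in 1:2)
    expect_equal(nrow(two[[k]]$common) + nrow(two[[k]]$sample_specific),
                 nrow(lists[[k]]))
})

test_that("interval algebra invariants hold on random inputs", {
  set.seed(26)
  lists <- replicate(3, rand_intervals(30), simplify = FALSE)
  bp <- function(df) sum(df$end - df$start)
  merged_bp <- vapply(lists, function(l) bp(merge_regions(list(l))),
                      numeric(1))
  expect_lte(bp(common_regions(lists)), min(merged_bp))
  expect_gte(bp(merge_regions(lists)), max(merged_bp))
  # half-open overlap length vs per-base count on random pairs
  a <- rand_intervals(15); b <- rand_intervals(15)
  for (i in seq_len(15)) {
    ol <- max(0, min(a$end[i], b$end[i]) - max(a$start[i], b$start[i]))
    if (a$chrom[i] != b$chrom[i]) ol <- 0
    per_base <- length(intersect(
      if (a$chrom[i] == b$chrom[i]) seq(a$start[i], a$end[i] - 1L) else integer(0),
      seq(b$start[i], b$end[i] - 1L)))
    expect_equal(ol, per_base)
  }
})
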