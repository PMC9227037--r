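test_that("signal aggregation handles constant and empty tracks", {
  asm <- tiny_assembly(c(chr1 = 50000L))
  set.seed(2)
  sites <- random_granges(asm, 15L, max_len = 400L)

  empty <- GenomicRanges::GRanges(seqinfo = asm)
  S4Vectors::mcols(empty)$score <- numeric(0)
  expect_equal(aggregate_signal(sites, empty), rep(0, 15))

  const <- assembly_ranges(asm)
  S4Vectors::mcols(const)$score <- 2.5
  expect_equal(aggregate_signal(sites, const), rep(2.5, 15))
  expect_equal(aggregate_signal(sites, const, statistic = "sum"),
               2.5 * GenomicRanges::width(sites))
  expect_equal(conservation_per_bp(sites, const), rep(2.5, 15))
})

test_that("per-site signal means match the per-base bitmap oracle", {
  asm <- tiny_assembly(c(chr1 = 60000L, chr2 = 40000L))
  set.seed(14)
  for (rep in 1:10) {
    track <- random_track(asm)
    sites <- random_granges(asm, 20L, max_len = 900L)
    expect_equal(aggregate_signal(sites, track),
                 bitmap_signal(sites, track, asm))
    expect_equal(aggregate_signal(sites, track, statistic = "sum"),
                 bitmap_signal(sites, track, asm, statistic = "sum"))
  }
})

test_that("values are invariant under splitting a track segment", {
  asm <- tiny_assembly(c(chr1 = 10000L))
  whole <- bed_gr("chr1", 1000, 3000, asm)
  S4Vectors::mcols(whole)$score <- 1.7
  halves <- bed_gr("chr1", c(1000, 2000), c(2000, 3000), asm)
  S4Vectors::mcols(halves)$score <- c(1.7, 1.7)
  set.seed(9)
  sites <- random_granges(asm, 25L, max_len = 600L)
  expect_equal(aggregate_signal(sites, whole), aggregate_signal(sites, halves))
})

test_that("repeat occupancy fractions are per-class and oracle-exact", {
  asm <- tiny_assembly(c(chr1 = 50000L))
  site <- bed_gr("chr1", 0, 100, asm)
  reps <- list(LTR = bed_gr("chr1", 50, 150, asm),
               SINE = GenomicRanges::GRanges(seqinfo = asm))
  occ <- repeat_occupancy(site, reps)
  expect_equal(occ[1, "LTR"], 0.5, ignore_attr = TRUE)
  expect_equal(occ[1, "SINE"], 0, ignore_attr = TRUE)

  full <- repeat_occupancy(site, list(LTR = bed_gr("chr1", 0, 200, asm)))
  expect_equal(full[1, 1], 1.0, ignore_attr = TRUE)

  set.seed(21)
  for (rep in 1:10) {
    sites <- random_granges(asm, 30L, max_len = 500L)
    classes <- list(LTR = random_granges(asm, 40L, max_len = 300L),
                    LINE = random_granges(asm, 25L, max_len = 600L))
    occ <- repeat_occupancy(sites, classes)
    for (cl in names(classes)) {
      map <- bitmap_of(classes[[cl]], asm)$chr1
      oracle <- vapply(seq_along(sites), function(i) {
        idx <- GenomicRanges::start(sites)[i]:GenomicRanges::end(sites)[i]
        mean(map[idx])
      }, numeric(1))
      expect_equal(unname(occ[, cl]), oracle)
    }
  }
})

test_that("four site groups produce exactly six pairwise comparisons", {
  asm <- tiny_assembly(c(chr1 = 200000L))
  set.seed(5)
  sites <- random_granges(asm, 60L, max_len = 400L)
  bounds <- bed_gr("chr1", seq(0, 180000, by = 20000),
                   seq(2000, 182000, by = 20000), asm)
  res <- group_and_compare(sites, bounds, asm,
                           value_fun = function(g) GenomicRanges::width(g) +
                             stats::runif(length(g)),
                           rng_seed = 31)
  expect_equal(nrow(res$pairs), 6L)
  expect_setequal(names(res$values),
                  c("all", "at_boundary", "non_boundary", "random_control"))
  expect_equal(res$group_sizes[["at_boundary"]] +
                 res$group_sizes[["non_boundary"]],
               res$group_sizes[["all"]])
  expect_equal(res$group_sizes[["random_control"]], res$group_sizes[["all"]])
})

test_that("identical groups give t = 0 and p = 1; tiny groups are untestable", {
  asm <- tiny_assembly(c(chr1 = 100000L))
  set.seed(8)
  sites <- random_granges(asm, 40L, max_len = 300L)
  everywhere <- assembly_ranges(asm)  # every site is at a boundary
  res <- group_and_compare(sites, everywhere, asm,
                           value_fun = function(g)
                             as.numeric(GenomicRanges::start(g)),
                           rng_seed = 3)
  row <- res$pairs[res$pairs$group1 == "all" &
                     res$pairs$group2 == "at_boundary", ]
  expect_equal(row$t_statistic, 0)
  expect_equal(row$p_value, 1)
  # non_boundary is empty -> its pairs are untestable, not dropped
  nb <- res$pairs[res$pairs$group1 == "non_boundary" |
                    res$pairs$group2 == "non_boundary", ]
  expect_true(all(!nb$testable))
  expect_equal(nrow(res$pairs), 6L)
})

test_that("a planted boundary-group difference is recovered by the t-tests", {
  asm <- tiny_assembly(c(chr1 = 2000000L))
  bounds <- bed_gr("chr1", seq(0, 1.9e6, by = 1e5),
                   seq(5000, 1.905e6, by = 1e5), asm)
  set.seed(12)
  # ~200 sites per group: half planted inside boundary windows
  b_start <- sample(seq(0, 1.9e6, by = 1e5), 200, replace = TRUE) +
    sample.int(4800, 200, replace = TRUE)
  o_start <- sample.int(2e6 - 200, 200, replace = TRUE)
  o_start <- o_start[!IRanges::overlapsAny(
    bed_gr("chr1", o_start, o_start + 200, asm), bounds)]
  sites <- c(bed_gr("chr1", b_start, b_start + 200, asm),
             bed_gr("chr1", o_start, o_start + 200, asm))
  value_fun <- function(g) {
    at_b <- IRanges::overlapsAny(g, bounds)
    0.4 + 0.2 * at_b + stats::rnorm(length(g), 0, 0.1)
  }
  set.seed(99)
  res <- group_and_compare(sites, bounds, asm, value_fun, rng_seed = 17)
  row <- res$pairs[res$pairs$group1 == "at_boundary" &
                     res$pairs$group2 == "non_boundary", ]
  expect_lt(row$p_value, 1e-6)
  expect_gt(row$mean1, row$mean2)
})

test_that("the random control group is reproducible under a fixed seed", {
  asm <- tiny_assembly(c(chr1 = 300000L))
  set.seed(4)
  sites <- random_granges(asm, 50L, max_len = 500L)
  bounds <- bed_gr("chr1", 100000, 120000, asm)
  vf <- function(g) as.numeric(GenomicRanges::start(g))
  r1 <- group_and_compare(sites, bounds, asm, vf, rng_seed = 42)
  r2 <- group_and_compare(sites, bounds, asm, vf, rng_seed = 42)
  expect_identical(r1$values$random_control, r2$values$random_control)
})

test_that("pairwise p-values are roughly uniform with no planted difference", {
  asm <- tiny_assembly(c(chr1 = 500000L))
  bounds <- bed_gr("chr1", seq(0, 4.5e5, by = 5e4),
                   seq(20000, 4.7e5, by = 5e4), asm)
  set.seed(61)
  frac <- mean(vapply(1:100, function(r) {
    sites <- random_granges(asm, 80L, max_len = 300L)
    res <- group_and_compare(sites, bounds, asm,
                             value_fun = function(g)
                               stats::rnorm(length(g)),
                             rng_seed = 1000 + r)
    # boundary vs non-boundary is the only a-priori independent pair
    res$pairs[res$pairs$group1 == "at_boundary" &
                res$pairs$group2 == "non_boundary", "p_value"] < 0.05
  }, logical(1)))
  expect_gte(frac, 0)
  expect_lte(frac, 0.12)
})

test_that("nearest-TSS assignment follows the distance and tie-break rules", {
  asm <- tiny_assembly(c(chr1 = 10000L, chr2 = 5000L))
  # single gene on the chromosome wins regardless of distance
  lone <- bed_gr("chr1", 9000, 9001, asm, name = "far_gene")
  site <- bed_gr("chr1", 0, 50, asm)
  res <- nearest_tss_targets(site, lone)
  expect_equal(res$gene, "far_gene")
  expect_equal(res$distance, 9000 - 50)

  # equidistant TSS at 50 and 250 around site [100, 200): tie -> smaller coord
  tss <- bed_gr("chr1", c(50, 250), c(51, 251), asm, name = c("gL", "gR"))
  res2 <- nearest_tss_targets(bed_gr("chr1", 100, 200, asm), tss)
  expect_equal(res2$gene, "gL")
  expect_equal(res2$distance, -50)

  # TSS inside the site: distance 0
  res3 <- nearest_tss_targets(bed_gr("chr1", 40, 60, asm),
                              bed_gr("chr1", 50, 51, asm, name = "in"))
  expect_equal(res3$distance, 0)

  # coordinate tie broken by gene name
  twin <- bed_gr("chr1", c(300, 300), c(301, 301), asm, name = c("zzz", "aaa"))
  res4 <- nearest_tss_targets(bed_gr("chr1", 400, 500, asm), twin)
  expect_equal(res4$gene, "aaa")

  # chromosome without TSS -> unassigned and counted
  two <- c(bed_gr("chr1", 100, 200, asm), bed_gr("chr2", 100, 200, asm))
  res5 <- nearest_tss_targets(two, tss)
  expect_true(is.na(res5$gene[2]))
  expect_equal(attr(res5, "n_unassigned"), 1L)

  expect_error(nearest_tss_targets(site, GenomicRanges::GRanges(seqinfo = asm)),
               "empty")
})

test_that("nearest-TSS assignments equal the all-pairs brute-force minimum", {
  asm <- tiny_assembly(c(chr1 = 80000L, chr2 = 50000L))
  set.seed(27)
  sites <- random_granges(asm, 100L, max_len = 400L)
  tpos <- sort(sample.int(79000, 20))
  tss <- c(bed_gr("chr1", tpos[1:15], tpos[1:15] + 1, asm,
                  name = sprintf("g%02d", 1:15)),
           bed_gr("chr2", tpos[16:20] %% 49000, tpos[16:20] %% 49000 + 1, asm,
                  name = sprintf("g%02d", 16:20)))
  res <- nearest_tss_targets(sites, tss)
  tss_ch <- as.character(GenomicRanges::seqnames(tss))
  tss_p0 <- GenomicRanges::start(tss) - 1L
  gene <- S4Vectors::mcols(tss)$name
  for (i in seq_along(sites)) {
    ch <- as.character(GenomicRanges::seqnames(sites))[i]
    s0 <- GenomicRanges::start(sites)[i] - 1L
    e0 <- GenomicRanges::end(sites)[i]
    cand <- which(tss_ch == ch)
    d <- ifelse(tss_p0[cand] < s0, s0 - tss_p0[cand],
                ifelse(tss_p0[cand] > e0, tss_p0[cand] - e0, 0))
    best <- cand[order(d, tss_p0[cand], gene[cand])][1]
    expect_equal(res$gene[i], gene[best])
    expect_equal(abs(res$distance[i]), min(d))
  }
})
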