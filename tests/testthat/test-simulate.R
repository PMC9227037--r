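test_that("config validation rejects impossible parameter combinations", {
  expect_error(sim_config(chrom_length = 1e6, tad_mean_length = 8e5),
               "2 \\* tad_mean_length")
  expect_error(sim_config(boundary_turnover = 1.5))
  expect_error(sim_config(boundary_enrichment = 0.5))
})

test_that("zero turnover freezes boundaries; full turnover replaces them", {
  cfg0 <- sim_config(seed = 3, boundary_turnover = 0)
  gs0 <- simulate_genome_and_stages(cfg0)
  for (s in STAGES[-1]) {
    expect_identical(GenomicRanges::ranges(gs0$tads[[s]]),
                     GenomicRanges::ranges(gs0$tads$ES))
  }
  sites <- simulate_sites(cfg0, gs0$assembly,
                          tad_boundaries(gs0$tads$CP, cfg0$boundary_flank))
  bounds <- lapply(gs0$tads, tad_boundaries, flank_bp = cfg0$boundary_flank)
  pats <- annotate_boundary_patterns(sites, bounds)
  expect_false(any(is_dynamic_pattern(pats)))

  cfg1 <- sim_config(seed = 3, boundary_turnover = 1)
  gs1 <- simulate_genome_and_stages(cfg1)
  # internal TAD edges shared between adjacent stages should (almost) vanish
  shared <- vapply(1:3, function(s) {
    a <- GenomicRanges::start(gs1$tads[[s]])
    b <- GenomicRanges::start(gs1$tads[[s + 1]])
    a <- a[a > 1]  # internal edges only
    b <- b[b > 1]
    mean(a %in% b)
  }, numeric(1))
  expect_lt(mean(shared), 0.05)
})

test_that("TAD partitions tile the genome at every stage", {
  cfg <- sim_config(seed = 9)
  gs <- simulate_genome_and_stages(cfg)
  for (s in STAGES) {
    tads <- gs$tads[[s]]
    expect_equal(sum(as.numeric(GenomicRanges::width(tads))),
                 assembly_size(gs$assembly))
    m <- merge_intervals(tads)
    expect_length(m, cfg$n_chroms)
  }
})

test_that("compartments are an A/B partition with the planted switch rate", {
  cfg <- sim_config(seed = 5, compartment_switch_rate = 0.25)
  gs <- simulate_genome_and_stages(cfg)
  for (s in STAGES) {
    comp <- gs$compartments[[s]]
    expect_true(all(S4Vectors::mcols(comp)$name %in% c("A", "B")))
    expect_equal(sum(as.numeric(GenomicRanges::width(comp))),
                 assembly_size(gs$assembly))
  }
  flips <- vapply(1:3, function(s) {
    mean(S4Vectors::mcols(gs$compartments[[s]])$name !=
           S4Vectors::mcols(gs$compartments[[s + 1]])$name)
  }, numeric(1))
  n_blocks <- length(gs$compartments$ES)
  ci <- qbinom(c(0.005, 0.995), n_blocks * 3, 0.25) / (n_blocks * 3)
  expect_gte(mean(flips), ci[1])
  expect_lte(mean(flips), ci[2])
})

test_that("site placement matches the closed-form boundary probability", {
  cfg <- sim_config(seed = 13, boundary_enrichment = 10,
                    tad_mean_length = 1.6e6, n_sites = 2000L)
  gs <- simulate_genome_and_stages(cfg)
  bounds <- tad_boundaries(gs$tads$CP, cfg$boundary_flank)
  b <- sum(as.numeric(GenomicRanges::width(bounds))) /
    assembly_size(gs$assembly)
  sites <- simulate_sites(cfg, gs$assembly, bounds)
  p_expected <- 10 * b / (10 * b + (1 - b))
  frac <- mean(IRanges::overlapsAny(sites, bounds))
  ci <- qbinom(c(0.005, 0.995), 2000, p_expected) / 2000
  # planted sites fall inside windows; overlap can only add edge cases
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2] + 0.02)

  expect_length(simulate_sites(sim_config(n_sites = 0), gs$assembly, bounds),
                0L)
})

test_that("unenriched site placement is consistent with the shuffle null", {
  cfg <- sim_config(seed = 17, boundary_enrichment = 1, n_sites = 400L)
  gs <- simulate_genome_and_stages(cfg)
  bounds <- tad_boundaries(gs$tads$CP, cfg$boundary_flank)
  sites <- simulate_sites(cfg, gs$assembly, bounds)
  res <- permutation_coverage_enrichment(sites, bounds, gs$assembly,
                                         n_shuffles = 100, rng_seed = 2)
  expect_lte(abs(res$z_score), 3)
})

test_that("planted signal peaks and conservation uplift are recoverable", {
  cfg <- sim_config(seed = 23, n_chroms = 1, chrom_length = 5e6,
                    n_sites = 200L, signal_site_fraction = 1,
                    signal_peak_height = 10, cons_boundary_shift = 0.2)
  gs <- simulate_genome_and_stages(cfg)
  bounds <- tad_boundaries(gs$tads$CP, cfg$boundary_flank)
  sites <- simulate_sites(cfg, gs$assembly, bounds)
  tr <- simulate_tracks_and_annotations(cfg, gs$assembly, sites, bounds)

  obs <- aggregate_signal(sites, tr$ctcf)
  rnd <- aggregate_signal(shuffle_intervals(sites, gs$assembly, 7), tr$ctcf)
  tt <- stats::t.test(obs, rnd)
  expect_lt(tt$p.value, 1e-6)
  expect_gt(mean(obs), mean(rnd))

  # no planted signal: site and random means agree within noise
  cfg0 <- sim_config(seed = 23, n_chroms = 1, chrom_length = 5e6,
                     n_sites = 200L, signal_peak_height = 0)
  tr0 <- simulate_tracks_and_annotations(cfg0, gs$assembly, sites, bounds)
  obs0 <- aggregate_signal(sites, tr0$ctcf)
  rnd0 <- aggregate_signal(shuffle_intervals(sites, gs$assembly, 7), tr0$ctcf)
  pooled_sem <- sqrt(stats::var(obs0) / length(obs0) +
                       stats::var(rnd0) / length(rnd0))
  expect_lte(abs(mean(obs0) - mean(rnd0)), 3 * pooled_sem)

  # conservation uplift at boundary sites
  cons_cmp <- group_and_compare(
    sites, bounds, gs$assembly,
    value_fun = function(g) conservation_per_bp(g, tr$cons),
    rng_seed = 11)
  row <- cons_cmp$pairs[cons_cmp$pairs$group1 == "at_boundary" &
                          cons_cmp$pairs$group2 == "non_boundary", ]
  expect_lt(row$p_value, 1e-3)
  expect_gt(row$mean1, row$mean2)
})

test_that("repeat classes follow their planted site enrichment directions", {
  cfg <- sim_config(seed = 29, n_chroms = 1, chrom_length = 5e6,
                    n_sites = 300L)
  gs <- simulate_genome_and_stages(cfg)
  bounds <- tad_boundaries(gs$tads$CP, cfg$boundary_flank)
  sites <- simulate_sites(cfg, gs$assembly, bounds)
  tr <- simulate_tracks_and_annotations(cfg, gs$assembly, sites, bounds)
  classes <- split(tr$repeats, S4Vectors::mcols(tr$repeats)$name)
  occ_site <- colMeans(repeat_occupancy(sites, as.list(classes)))
  rnd <- shuffle_intervals(sites, gs$assembly, 19, exclude = sites)
  occ_rnd <- colMeans(repeat_occupancy(rnd, as.list(classes)))
  expect_gt(occ_site[["LTR"]], occ_rnd[["LTR"]])
  expect_gt(occ_site[["SINE"]], occ_rnd[["SINE"]])
  expect_lt(occ_site[["LINE"]], occ_rnd[["LINE"]])
  expect_lt(occ_site[["DNA"]], occ_rnd[["DNA"]])
})

test_that("identical configurations produce byte-identical bundles", {
  cfg <- sim_config(seed = 37, n_chroms = 1, chrom_length = 3e6,
                    tad_mean_length = 5e5, n_sites = 100L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in setdiff(files, "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("a bundle round-trips through the readers cleanly", {
  cfg <- sim_config(seed = 41, n_chroms = 2, chrom_length = 3e6,
                    tad_mean_length = 5e5, n_sites = 150L)
  dir <- withr::local_tempdir()
  mem <- simulate_bundle(cfg, dir)
  back <- read_bundle(dir)
  expect_identical(GenomicRanges::ranges(back$sites),
                   GenomicRanges::ranges(mem$sites))
  expect_identical(GenomeInfoDb::seqlengths(back$assembly),
                   GenomeInfoDb::seqlengths(mem$assembly))
  for (s in STAGES) {
    expect_identical(GenomicRanges::ranges(back$tads[[s]]),
                     GenomicRanges::ranges(mem$tads[[s]]))
    expect_identical(S4Vectors::mcols(back$compartments[[s]])$name,
                     S4Vectors::mcols(mem$compartments[[s]])$name)
  }
  expect_equal(S4Vectors::mcols(back$ctcf)$score,
               S4Vectors::mcols(mem$ctcf)$score)
  expect_identical(S4Vectors::mcols(back$repeats)$name,
                   S4Vectors::mcols(mem$repeats)$name)
})
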