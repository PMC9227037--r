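#' Run the full triplex-site / 3D-genome analysis pipeline
#'
#' Reproduces the complete workflow on an input bundle (simulated via
#' [simulate_bundle()] or real data laid out the same way):
#'
#' 1. shuffle-null coverage enrichment of sites in TADs and in TAD
#'    boundaries of the reference stage;
#' 2. the 10-bin positional-occupancy profile within TADs, with a
#'    within-TAD randomized control and a two-sample KS test;
#' 3. dynamic-category chi-square tests across the four stages, for TAD
#'    boundary gain/loss and for A/B compartment switching;
#' 4. per-site profiling: ChIP-signal and conservation means with
#'    boundary/non-boundary/control grouping and 6 pairwise Welch t-tests
#'    each, repeat-class occupancy with the same grouping per class, and
#'    nearest-TSS target genes.
#'
#' All randomness derives from `rng_seed`; identical inputs and seed give
#' an identical report.
#'
#' @param bundle List as returned by [read_bundle()] or
#'   [simulate_bundle()].
#' @param out_dir Optional directory for `report.json` and TSV outputs.
#' @param flank_bp Boundary half-width in bp (analysis parameter; must be
#'   reported with results).
#' @param n_shuffles Shuffle replicates for the enrichment null.
#' @param n_bins Bins per TAD for the positional profile.
#' @param n_randomizations Random site sets for the chi-square tests.
#' @param rng_seed Integer master seed.
#' @param reference_stage Stage whose TADs anchor the static analyses
#'   (default `"CP"`).
#' @return A `pipeline_report` list with blocks `enrichment_tads`,
#'   `enrichment_boundaries`, `positional` (profiles + KS),
#'   `dynamics_boundary`, `dynamics_compartment`, `signal`,
#'   `conservation`, `repeats` (per class), `targets` (data.frame), and
#'   `provenance`.
#' @export
run_pipeline <- function(bundle, out_dir = NULL,
                         flank_bp = 40000, n_shuffles = 1000L,
                         n_bins = 10L, n_randomizations = 100L,
                         rng_seed = 1L, reference_stage = "CP") {
  assembly <- bundle$assembly
  sites <- bundle$sites
  tads <- bundle$tads[[reference_stage]]
  boundaries <- tad_boundaries(tads, flank_bp)
  boundaries_by_stage <- lapply(bundle$tads, tad_boundaries,
                                flank_bp = flank_bp)

  enr_tads <- permutation_coverage_enrichment(
    sites, tads, assembly, n_shuffles = n_shuffles,
    rng_seed = rng_seed, keep_null = FALSE)
  enr_bound <- permutation_coverage_enrichment(
    sites, boundaries, assembly, n_shuffles = n_shuffles,
    rng_seed = rng_seed + 10000L, keep_null = FALSE)

  control_sites <- within_tad_randomization(sites, tads, boundaries,
                                            assembly,
                                            rng_seed = rng_seed + 20000L)
  prof_obs <- bin_occupancy(sites, tads, n_bins = n_bins)
  prof_rnd <- bin_occupancy(control_sites, tads, n_bins = n_bins)
  ks <- positional_ks_test(sites, control_sites, tads)

  dyn_bound <- category_chi_square(
    sites, boundaries_by_stage, assembly, type = "boundary",
    n_randomizations = n_randomizations, rng_seed = rng_seed + 30000L)
  dyn_comp <- category_chi_square(
    sites, bundle$compartments, assembly, type = "compartment",
    n_randomizations = n_randomizations, rng_seed = rng_seed + 40000L)

  signal_cmp <- group_and_compare(
    sites, boundaries, assembly,
    value_fun = function(g) aggregate_signal(g, bundle$ctcf),
    rng_seed = rng_seed + 50000L)
  cons_cmp <- group_and_compare(
    sites, boundaries, assembly,
    value_fun = function(g) conservation_per_bp(g, bundle$cons),
    rng_seed = rng_seed + 60000L)

  rep_classes <- split(bundle$repeats,
                       S4Vectors::mcols(bundle$repeats)$name)
  rep_cmp <- lapply(names(rep_classes), function(cl) {
    group_and_compare(
      sites, boundaries, assembly,
      value_fun = function(g) {
        repeat_occupancy(g, rep_classes[cl])[, 1L]
      },
      rng_seed = rng_seed + 70000L)
  })
  names(rep_cmp) <- names(rep_classes)

  targets <- nearest_tss_targets(sites, bundle$tss)

  report <- list(
    enrichment_tads = enr_tads,
    enrichment_boundaries = enr_bound,
    positional = list(observed = prof_obs, random = prof_rnd,
                      ks_D = ks$D, ks_p_value = ks$p_value,
                      n_dropped_observed = ks$n_dropped_observed,
                      n_dropped_random = ks$n_dropped_random),
    dynamics_boundary = dyn_bound,
    dynamics_compartment = dyn_comp,
    signal = signal_cmp,
    conservation = cons_cmp,
    repeats = rep_cmp,
    targets = targets,
    provenance = list(
      rng_seed = as.integer(rng_seed),
      flank_bp = flank_bp,
      n_shuffles = as.integer(n_shuffles),
      n_bins = as.integer(n_bins),
      n_randomizations = as.integer(n_randomizations),
      reference_stage = reference_stage,
      n_sites = length(sites),
      genome_bp = assembly_size(assembly)
    )
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Serialize a pipeline report to JSON and TSV files
#'
#' Writes `report.json` (all statistics), `positional_profile.tsv`
#' (bin, observed mean/SEM, control mean/SEM), `pattern_counts.tsv`
#' (observed and expected per dynamic category, both annotations),
#' `pairwise_tests.tsv` (all group comparisons), and `target_genes.tsv`.
#' Timestamps and hostnames are deliberately excluded so reports are
#' diffable.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- data.frame(
    bin = seq_len(report$positional$observed$n_bins),
    mean = report$positional$observed$mean_fraction,
    sem = report$positional$observed$sem,
    random_mean = report$positional$random$mean_fraction,
    random_sem = report$positional$random$sem
  )
  utils::write.table(prof, file.path(out_dir, "positional_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pats <- rbind(
    data.frame(annotation = "boundary",
               pattern = names(report$dynamics_boundary$observed),
               observed = report$dynamics_boundary$observed,
               expected = report$dynamics_boundary$expected),
    data.frame(annotation = "compartment",
               pattern = names(report$dynamics_compartment$observed),
               observed = report$dynamics_compartment$observed,
               expected = report$dynamics_compartment$expected)
  )
  utils::write.table(pats, file.path(out_dir, "pattern_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp_blocks <- c(list(signal = report$signal,
                       conservation = report$conservation),
                  stats::setNames(report$repeats,
                                  paste0("repeat_", names(report$repeats))))
  tests <- do.call(rbind, lapply(names(cmp_blocks), function(nm) {
    cbind(measure = nm, cmp_blocks[[nm]]$pairs)
  }))
  utils::write.table(tests, file.path(out_dir, "pairwise_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$targets, file.path(out_dir, "target_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_as_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# internal: JSON-friendly view of the report (no GRanges, no large vectors)
report_as_list <- function(report) {
  cc_list <- function(x) {
    list(observed = as.list(x$observed), expected = as.list(x$expected),
         chi2 = x$chi2, df = x$df, p_value = x$p_value,
         n_sites_kept = x$n_sites_kept, n_dropped = x$n_dropped,
         pooled_bins = x$pooled_bins, degenerate = x$degenerate)
  }
  gc_list <- function(x) {
    list(group_sizes = as.list(x$group_sizes), pairs = x$pairs)
  }
  list(
    enrichment_tads = enrichment_as_list(report$enrichment_tads),
    enrichment_boundaries = enrichment_as_list(report$enrichment_boundaries),
    positional = list(
      observed_mean = unname(report$positional$observed$mean_fraction),
      observed_sem = unname(report$positional$observed$sem),
      random_mean = unname(report$positional$random$mean_fraction),
      random_sem = unname(report$positional$random$sem),
      n_tads = report$positional$observed$n_tads,
      ks_D = report$positional$ks_D,
      ks_p_value = report$positional$ks_p_value
    ),
    dynamics_boundary = cc_list(report$dynamics_boundary),
    dynamics_compartment = cc_list(report$dynamics_compartment),
    signal = gc_list(report$signal),
    conservation = gc_list(report$conservation),
    repeats = lapply(report$repeats, gc_list),
    n_target_genes = length(unique(stats::na.omit(report$targets$gene))),
    provenance = report$provenance
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Triplex-site / 3D-genome pipeline report ==\n")
  cat(sprintf("sites: %d | genome: %.1f Mb | flank: %d bp | seed: %d\n",
              x$provenance$n_sites, x$provenance$genome_bp / 1e6,
              x$provenance$flank_bp, x$provenance$rng_seed))
  cat("\n-- Enrichment in TADs --\n"); print(x$enrichment_tads)
  cat("\n-- Enrichment in TAD boundaries --\n"); print(x$enrichment_boundaries)
  cat(sprintf("\n-- Positional preference: KS D = %.3f, p = %.3g --\n",
              x$positional$ks_D, x$positional$ks_p_value))
  cat("\n-- Boundary gain/loss dynamics --\n"); print(x$dynamics_boundary)
  cat("\n-- Compartment switching --\n"); print(x$dynamics_compartment)
  cat("\n-- ChIP signal at sites --\n"); print(x$signal)
  cat("\n-- Conservation at sites --\n"); print(x$conservation)
  invisible(x)
}
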