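#' Simulation configuration with study-scale defaults
#'
#' Parameters of the synthetic input bundle. Defaults describe a compact
#' study-like dataset: a 2 x 10 Mb genome, four ordered differentiation
#' stages (ES, MES, CP, CM) of TAD partitions with moderate boundary
#' turnover, alternating A/B compartments with a 20% per-transition switch
#' rate, 1000 triplex-like sites of 1 kb with 5-fold boundary enrichment,
#' a ChIP-like signal peak planted over half the sites, four repeat classes
#' (LTR/SINE enriched in sites, LINE/DNA depleted), and a conservation
#' uplift at boundary-associated sites.
#'
#' @param seed Integer master seed; every component draws from documented
#'   offsets of it (stages +0, sites +1000, tracks +2000).
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome, bp.
#' @param tad_mean_length Mean TAD length, bp.
#' @param boundary_flank Boundary half-width, bp (same convention as
#'   [tad_boundaries()]).
#' @param boundary_turnover Probability each internal boundary is replaced
#'   at each stage transition, in [0, 1].
#' @param compartment_block_length Length of an A/B compartment block, bp.
#' @param compartment_switch_rate Per-block label flip probability per
#'   stage transition, in [0, 1].
#' @param n_sites Number of sites.
#' @param site_length Site length, bp.
#' @param boundary_enrichment Relative placement density at boundaries
#'   (>= 1; 1 = uniform, no planted signal).
#' @param signal_site_fraction Fraction of sites carrying a signal peak.
#' @param signal_peak_height Added signal over peak sites (baseline is
#'   exponential noise with mean 1).
#' @param repeat_density Per-class genome fraction covered by repeats.
#' @param repeat_length Individual repeat element length, bp.
#' @param repeat_site_multiplier Named per-class relative placement density
#'   inside sites (> 1 enriched, < 1 depleted).
#' @param cons_boundary_shift Mean conservation uplift at
#'   boundary-overlapping sites (conservation baseline ~ Beta(2, 6)).
#' @param track_bin Signal-track segment length, bp.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 10e6,
                       tad_mean_length = 1e6,
                       boundary_flank = 40000,
                       boundary_turnover = 0.15,
                       compartment_block_length = 1e6,
                       compartment_switch_rate = 0.2,
                       n_sites = 1000L,
                       site_length = 1000,
                       boundary_enrichment = 5,
                       signal_site_fraction = 0.5,
                       signal_peak_height = 5,
                       repeat_density = 0.05,
                       repeat_length = 300,
                       repeat_site_multiplier = c(LTR = 4, SINE = 4,
                                                  LINE = 0.25, DNA = 0.25),
                       cons_boundary_shift = 0.2,
                       track_bin = 1000) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length,
              tad_mean_length = tad_mean_length,
              boundary_flank = boundary_flank,
              boundary_turnover = boundary_turnover,
              compartment_block_length = compartment_block_length,
              compartment_switch_rate = compartment_switch_rate,
              n_sites = as.integer(n_sites), site_length = site_length,
              boundary_enrichment = boundary_enrichment,
              signal_site_fraction = signal_site_fraction,
              signal_peak_height = signal_peak_height,
              repeat_density = repeat_density, repeat_length = repeat_length,
              repeat_site_multiplier = repeat_site_multiplier,
              cons_boundary_shift = cons_boundary_shift,
              track_bin = track_bin)
  probs <- c(cfg$boundary_turnover, cfg$compartment_switch_rate,
             cfg$signal_site_fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$boundary_enrichment >= 1,
            cfg$chrom_length > 0, cfg$tad_mean_length > 0,
            cfg$boundary_flank > 0, cfg$site_length > 0)
  if (cfg$chrom_length < 2 * cfg$tad_mean_length) {
    stop("chrom_length must be at least 2 * tad_mean_length")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Stage labels used throughout the package
#' @export
STAGES <- c("ES", "MES", "CP", "CM")

#' Simulate the genome, 4-stage TAD partitions, and A/B compartments
#'
#' Stage-1 TADs tile each chromosome with lengths drawn from a truncated
#' exponential around `tad_mean_length`. Each subsequent stage is derived
#' from the previous one (memoryless turnover): every internal boundary is
#' independently removed with probability `boundary_turnover` and replaced
#' by a new uniformly placed internal boundary, so the TAD count per
#' chromosome is preserved. Compartments are fixed alternating A/B blocks
#' whose labels flip independently per stage transition with
#' `compartment_switch_rate`.
#'
#' @param config A [sim_config()].
#' @return List with `assembly` (Seqinfo), `tads` (named list of 4 GRanges)
#'   and `compartments` (named list of 4 labeled GRanges).
#' @export
simulate_genome_and_stages <- function(config) {
  assembly <- GenomeInfoDb::Seqinfo(
    seqnames = paste0("chr", seq_len(config$n_chroms)),
    seqlengths = as.integer(rep(config$chrom_length, config$n_chroms))
  )
  set.seed(config$seed)
  min_tad <- max(ceiling(config$tad_mean_length / 5), 50L)
  cuts <- lapply(GenomeInfoDb::seqnames(assembly), function(ch) {
    len <- config$chrom_length
    cp <- numeric(0)
    pos <- 0
    repeat {
      step <- min_tad + round(stats::rexp(1, 1 / (config$tad_mean_length - min_tad)))
      pos <- pos + step
      if (pos >= len - min_tad) break
      cp <- c(cp, pos)
    }
    cp
  })
  names(cuts) <- GenomeInfoDb::seqnames(assembly)
  tads <- vector("list", length(STAGES))
  names(tads) <- STAGES
  for (s in seq_along(STAGES)) {
    if (s > 1L) {
      cuts <- lapply(cuts, function(cp) {
        if (length(cp) == 0L) return(cp)
        drop <- stats::runif(length(cp)) < config$boundary_turnover
        n_new <- sum(drop)
        newcp <- if (n_new > 0L) {
          round(stats::runif(n_new, min_tad, config$chrom_length - min_tad))
        } else numeric(0)
        sort(unique(c(cp[!drop], newcp)))
      })
    }
    tads[[s]] <- cuts_to_tads(cuts, assembly)
  }
  compartments <- simulate_compartments(config, assembly)
  list(assembly = assembly, tads = tads, compartments = compartments)
}

# internal: turn per-chromosome 0-based cut points into a TAD GRanges
cuts_to_tads <- function(cuts, assembly) {
  parts <- lapply(names(cuts), function(ch) {
    len <- GenomeInfoDb::seqlengths(assembly)[[ch]]
    edges <- c(0, cuts[[ch]], len)
    data.frame(chrom = ch, start = edges[-length(edges)] + 1,
               end = edges[-1L])
  })
  df <- do.call(rbind, parts)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         seqinfo = assembly)
}

# internal: alternating A/B blocks with Markov label flipping across stages
simulate_compartments <- function(config, assembly) {
  parts <- lapply(GenomeInfoDb::seqnames(assembly), function(ch) {
    len <- GenomeInfoDb::seqlengths(assembly)[[ch]]
    starts <- seq(0, len - 1, by = config$compartment_block_length)
    data.frame(chrom = ch, start = starts + 1,
               end = pmin(starts + config$compartment_block_length, len))
  })
  df <- do.call(rbind, parts)
  blocks <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start, df$end),
                                   seqinfo = assembly)
  lab <- rep_len(c("A", "B"), length(blocks))
  out <- vector("list", length(STAGES))
  names(out) <- STAGES
  for (s in seq_along(STAGES)) {
    if (s > 1L) {
      flip <- stats::runif(length(blocks)) < config$compartment_switch_rate
      lab[flip] <- ifelse(lab[flip] == "A", "B", "A")
    }
    gr <- blocks
    S4Vectors::mcols(gr)$name <- lab
    out[[s]] <- gr
  }
  out
}

#' Simulate sites with a planted boundary-enrichment factor
#'
#' Each site is independently assigned to boundary space with probability
#' `E * b / (E * b + (1 - b))`, where `E` is `boundary_enrichment` and `b`
#' the boundary share of the genome, then placed uniformly within the
#' chosen space. With `E = 1` placement is uniform genome-wide (no planted
#' signal).
#'
#' @param config A [sim_config()].
#' @param assembly A [GenomeInfoDb::Seqinfo].
#' @param boundaries GRanges of boundary windows of the reference stage.
#' @param seed Integer seed; defaults to `config$seed + 1000`.
#' @return Sorted GRanges of `n_sites` sites of length `site_length`.
#' @export
simulate_sites <- function(config, assembly, boundaries,
                           seed = config$seed + 1000L) {
  if (config$n_sites == 0L) {
    return(GenomicRanges::GRanges(seqinfo = assembly))
  }
  b_merged <- merge_intervals(boundaries)
  b <- sum(as.numeric(GenomicRanges::width(b_merged))) / assembly_size(assembly)
  E <- config$boundary_enrichment
  p_b <- E * b / (E * b + (1 - b))
  set.seed(as.integer(seed))
  in_boundary <- stats::runif(config$n_sites) < p_b
  lens <- rep(as.integer(config$site_length), config$n_sites)
  parts <- list()
  if (any(in_boundary)) {
    parts$b <- place_uniform(lens[in_boundary],
                             allowed_spans(assembly, within = b_merged))
  }
  if (any(!in_boundary)) {
    parts$o <- place_uniform(lens[!in_boundary],
                             allowed_spans(assembly, exclude = b_merged))
  }
  GenomicRanges::sort(set_assembly(do.call(c, unname(parts)), assembly))
}

#' Simulate signal/conservation tracks, repeat annotations, and TSS
#'
#' The ChIP-like track is exponential noise (mean 1) over fixed
#' `track_bin` segments, plus a planted peak of `signal_peak_height` over a
#' random `signal_site_fraction` of the sites. The conservation track is
#' Beta(2, 6) noise with `cons_boundary_shift` added (clipped to [0, 1])
#' over segments intersecting boundary-overlapping sites. Repeats of four
#' classes are placed with class-specific relative density inside sites
#' (`repeat_site_multiplier`). TSS points are placed uniformly, one per
#' ~100 kb, with synthetic gene names.
#'
#' @param config A [sim_config()].
#' @param assembly A [GenomeInfoDb::Seqinfo].
#' @param sites GRanges of sites.
#' @param boundaries GRanges of boundary windows.
#' @param seed Integer seed; defaults to `config$seed + 2000`.
#' @return List with `ctcf`, `cons` (score GRanges), `repeats` (GRanges,
#'   `name` = class), `tss` (GRanges, `name` = gene).
#' @export
simulate_tracks_and_annotations <- function(config, assembly, sites,
                                            boundaries,
                                            seed = config$seed + 2000L) {
  set.seed(as.integer(seed))
  bins <- tile_assembly(assembly, config$track_bin)
  n <- length(bins)
  sites_m <- merge_intervals(sites)

  ctcf_val <- stats::rexp(n, rate = 1)
  n_peak <- round(config$signal_site_fraction * length(sites))
  peak_sites <- if (n_peak > 0L) {
    sites[sample.int(length(sites), n_peak)]
  } else GenomicRanges::GRanges(seqinfo = assembly)
  hit <- IRanges::overlapsAny(bins, peak_sites, ignore.strand = TRUE)
  ctcf_val[hit] <- ctcf_val[hit] + config$signal_peak_height
  ctcf <- bins
  S4Vectors::mcols(ctcf)$score <- round(ctcf_val, 4)

  cons_val <- stats::rbeta(n, 2, 6)
  bsite <- sites[IRanges::overlapsAny(sites, boundaries,
                                            ignore.strand = TRUE)]
  hit_b <- IRanges::overlapsAny(bins, bsite, ignore.strand = TRUE)
  cons_val[hit_b] <- pmin(1, cons_val[hit_b] + config$cons_boundary_shift)
  cons <- bins
  S4Vectors::mcols(cons)$score <- round(cons_val, 4)

  classes <- names(config$repeat_site_multiplier)
  genome_bp <- assembly_size(assembly)
  site_share <- sum(as.numeric(GenomicRanges::width(sites_m))) / genome_bp
  rep_parts <- lapply(classes, function(cl) {
    m <- config$repeat_site_multiplier[[cl]]
    n_rep <- round(config$repeat_density * genome_bp / config$repeat_length)
    p_in <- m * site_share / (m * site_share + (1 - site_share))
    inside <- stats::runif(n_rep) < p_in
    lens <- rep(as.integer(config$repeat_length), n_rep)
    parts <- list()
    if (any(inside) && length(sites_m) > 0L) {
      parts$i <- place_uniform(lens[inside],
                               allowed_spans(assembly, within = sites_m))
    }
    if (any(!inside)) {
      parts$o <- place_uniform(lens[!inside],
                               allowed_spans(assembly, exclude = sites_m))
    }
    gr <- do.call(c, unname(parts))
    S4Vectors::mcols(gr)$name <- rep(cl, length(gr))
    gr
  })
  repeats <- set_assembly(do.call(c, rep_parts), assembly)
  repeats <- GenomicRanges::sort(repeats)

  tss_parts <- lapply(GenomeInfoDb::seqnames(assembly), function(ch) {
    len <- GenomeInfoDb::seqlengths(assembly)[[ch]]
    n_tss <- max(1L, round(len / 1e5))
    pos <- sort(unique(round(stats::runif(n_tss, 1, len))))
    data.frame(chrom = ch, pos = pos)
  })
  df <- do.call(rbind, tss_parts)
  tss <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L),
                                seqinfo = assembly)
  S4Vectors::mcols(tss)$name <- sprintf("gene%05d", seq_along(tss))

  list(ctcf = ctcf, cons = cons, repeats = repeats, tss = tss)
}

# internal: fixed-width tiling of the assembly (last bin clipped)
tile_assembly <- function(assembly, bin_bp) {
  parts <- lapply(GenomeInfoDb::seqnames(assembly), function(ch) {
    len <- GenomeInfoDb::seqlengths(assembly)[[ch]]
    starts <- seq(0, len - 1, by = bin_bp)
    data.frame(chrom = ch, start = starts + 1,
               end = pmin(starts + bin_bp, len))
  })
  df <- do.call(rbind, parts)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         seqinfo = assembly)
}

#' Generate a complete input bundle on disk
#'
#' Runs the full generator and writes every pipeline input to `dir`:
#' `genome.chrom.sizes`, `tads_<stage>.bed`, `compartments_<stage>.bed`
#' (BED4 with A/B labels), `sites.bed`, `ctcf.bedgraph`, `cons.bedgraph`,
#' `repeats.bed` (BED6, name = class), `tss.bed`, and `manifest.json`
#' (configuration echo plus md5 checksums of every file). Identical
#' configurations produce byte-identical bundles.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the in-memory bundle: list with `assembly`, `tads`,
#'   `compartments`, `boundaries` (reference-stage boundary windows),
#'   `sites`, `ctcf`, `cons`, `repeats`, `tss`, `config`, `dir`.
#' @export
simulate_bundle <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- simulate_genome_and_stages(config)
  # reference stage for site planting: CP (the stage the site data describe)
  boundaries <- tad_boundaries(gs$tads$CP, config$boundary_flank)
  sites <- simulate_sites(config, gs$assembly, boundaries)
  tracks <- simulate_tracks_and_annotations(config, gs$assembly, sites,
                                            boundaries)
  chrom_path <- file.path(dir, "genome.chrom.sizes")
  writeLines(paste(GenomeInfoDb::seqnames(gs$assembly),
                   GenomeInfoDb::seqlengths(gs$assembly), sep = "\t"),
             chrom_path)
  for (s in STAGES) {
    write_bed(gs$tads[[s]], file.path(dir, paste0("tads_", tolower(s), ".bed")))
    write_bed(gs$compartments[[s]],
              file.path(dir, paste0("compartments_", tolower(s), ".bed")))
  }
  write_bed(sites, file.path(dir, "sites.bed"))
  write_bedgraph(tracks$ctcf, file.path(dir, "ctcf.bedgraph"))
  write_bedgraph(tracks$cons, file.path(dir, "cons.bedgraph"))
  write_bed(tracks$repeats, file.path(dir, "repeats.bed"))
  write_bed(tracks$tss, file.path(dir, "tss.bed"))
  files <- list.files(dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = unclass(config),
    checksums = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(gs, list(boundaries = boundaries, sites = sites), tracks,
              list(config = config, dir = dir)))
}

#' Read a simulated (or equivalent) bundle directory
#'
#' Loads the files written by [simulate_bundle()] back into memory; any
#' directory with the same layout works, so real data prepared in the same
#' formats can be analysed identically.
#'
#' @param dir Bundle directory.
#' @return List in the same shape as the [simulate_bundle()] return value
#'   (without `config`).
#' @export
read_bundle <- function(dir) {
  assembly <- read_chrom_sizes(file.path(dir, "genome.chrom.sizes"))
  tads <- lapply(STAGES, function(s) {
    read_bed(file.path(dir, paste0("tads_", tolower(s), ".bed")), assembly)
  })
  names(tads) <- STAGES
  compartments <- lapply(STAGES, function(s) {
    read_bed(file.path(dir, paste0("compartments_", tolower(s), ".bed")),
             assembly)
  })
  names(compartments) <- STAGES
  list(
    assembly = assembly,
    tads = tads,
    compartments = compartments,
    sites = read_bed(file.path(dir, "sites.bed"), assembly),
    ctcf = read_bedgraph(file.path(dir, "ctcf.bedgraph"), assembly),
    cons = read_bedgraph(file.path(dir, "cons.bedgraph"), assembly),
    repeats = read_bed(file.path(dir, "repeats.bed"), assembly),
    tss = read_bed(file.path(dir, "tss.bed"), assembly),
    dir = dir
  )
}
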