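#' Partition each TAD into equal-length bins
#'
#' Splits every TAD into `n_bins` contiguous sub-intervals that exactly tile
#' it. When the TAD length is not a multiple of `n_bins`, the remainder
#' (length mod n_bins) is distributed one base each to the first remainder
#' bins, so bin lengths differ by at most 1 bp. TADs shorter than `n_bins`
#' bp are skipped with a warning.
#'
#' @param tads GRanges of TAD intervals.
#' @param n_bins Number of bins per TAD (default 10).
#' @return A GRanges of bins with metadata columns `tad_id` (index into the
#'   kept TADs) and `bin` (1..n_bins, left to right). The attribute
#'   `n_skipped` records how many TADs were too short.
#' @export
bin_tads <- function(tads, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  keep <- GenomicRanges::width(tads) >= n_bins
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(n_skipped, " TAD(s) shorter than ", n_bins, " bp skipped")
  }
  tads <- tads[keep]
  if (length(tads) == 0L) stop("no TAD long enough to bin")
  L <- GenomicRanges::width(tads)
  q <- L %/% n_bins
  r <- L %% n_bins
  # per-TAD bin widths: first r bins get q+1, the rest q
  widths <- rep(q, each = n_bins) +
    as.integer(rep(seq_len(n_bins), times = length(tads)) <= rep(r, each = n_bins))
  tad_id <- rep(seq_along(tads), each = n_bins)
  offs <- unlist(lapply(split(widths, tad_id), function(w) cumsum(c(0L, w[-length(w)]))),
                 use.names = FALSE)
  starts <- rep(GenomicRanges::start(tads), each = n_bins) + offs
  bins <- GenomicRanges::GRanges(
    seqnames = rep(GenomicRanges::seqnames(tads), each = n_bins),
    ranges = IRanges::IRanges(start = starts, width = widths),
    tad_id = tad_id,
    bin = rep(seq_len(n_bins), times = length(tads)),
    seqinfo = GenomeInfoDb::seqinfo(tads)
  )
  attr(bins, "n_skipped") <- n_skipped
  bins
}

#' Per-bin site occupancy profile across TADs
#'
#' For every TAD and every one of its `n_bins` equal-length bins, computes
#' the fraction of the bin covered by (merged) sites, then aggregates the
#' mean and standard error of the mean (SEM) across TADs per bin index.
#' Because TADs differ in size, occupancy is a length fraction, not a raw
#' count, so large TADs do not dominate.
#'
#' @param sites GRanges of sites.
#' @param tads GRanges of TADs.
#' @param n_bins Bins per TAD (default 10).
#' @param fold If `TRUE`, mirror bins (bin i and bin n_bins + 1 - i) are
#'   averaged so the axis is distance from the nearer boundary; default
#'   `FALSE` (left-to-right profile).
#' @return An object of class `bin_occupancy_profile`: list with `n_bins`,
#'   `mean_fraction`, `sem`, `n_tads`, `fold`, and the per-TAD `fractions`
#'   matrix (TADs x bins).
#' @export
bin_occupancy <- function(sites, tads, n_bins = 10L, fold = FALSE) {
  bins <- bin_tads(tads, n_bins)
  n_bins <- as.integer(n_bins)
  sites_m <- merge_intervals(sites)
  ov <- GenomicRanges::findOverlaps(bins, sites_m, ignore.strand = TRUE)
  ovw <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(bins)[S4Vectors::queryHits(ov)],
    GenomicRanges::ranges(sites_m)[S4Vectors::subjectHits(ov)]
  ))
  bp <- numeric(length(bins))
  tt <- tapply(ovw, S4Vectors::queryHits(ov), sum)
  bp[as.integer(names(tt))] <- tt
  frac <- bp / GenomicRanges::width(bins)
  mat <- matrix(frac, ncol = n_bins, byrow = TRUE)
  colnames(mat) <- paste0("bin", seq_len(n_bins))
  if (fold) {
    half <- n_bins %/% 2L
    fmat <- (mat[, seq_len(half), drop = FALSE] +
               mat[, n_bins + 1L - seq_len(half), drop = FALSE]) / 2
    if (n_bins %% 2L == 1L) {
      fmat <- cbind(fmat, mat[, half + 1L, drop = FALSE])
    }
    colnames(fmat) <- paste0("dist", seq_len(ncol(fmat)))
    mat <- fmat
  }
  res <- list(
    n_bins = ncol(mat),
    mean_fraction = colMeans(mat),
    sem = apply(mat, 2L, stats::sd) / sqrt(nrow(mat)),
    n_tads = nrow(mat),
    fold = fold,
    fractions = mat
  )
  class(res) <- "bin_occupancy_profile"
  res
}

#' @export
print.bin_occupancy_profile <- function(x, ...) {
  cat("Per-bin occupancy over", x$n_tads, "TADs",
      if (x$fold) "(folded by boundary distance)" else "(left to right)", "\n")
  print(round(rbind(mean = x$mean_fraction, sem = x$sem), 5))
  invisible(x)
}

#' Reposition boundary-overlapping sites into TAD interiors
#'
#' Builds the within-TAD randomized control used by the positional test:
#' sites that overlap a TAD boundary are repositioned uniformly at random so
#' they fall only inside TADs, excluding the boundary windows; all other
#' sites are kept in place.
#'
#' @param sites GRanges of sites.
#' @param tads GRanges of TADs.
#' @param boundaries GRanges of boundary windows (see [tad_boundaries()]).
#' @param assembly A [GenomeInfoDb::Seqinfo].
#' @param rng_seed Integer seed.
#' @return GRanges with the boundary-overlapping sites repositioned.
#' @export
within_tad_randomization <- function(sites, tads, boundaries, assembly,
                                     rng_seed) {
  hit <- IRanges::overlapsAny(sites, boundaries, ignore.strand = TRUE)
  if (!any(hit)) return(sites)
  interior <- GenomicRanges::setdiff(merge_intervals(tads),
                                     merge_intervals(boundaries),
                                     ignore.strand = TRUE)
  moved <- shuffle_intervals(sites[hit], assembly, rng_seed = rng_seed,
                             within = interior)
  set_assembly(c(GenomicRanges::granges(sites[!hit]), moved), assembly)
}

#' KS test of positional preference within TADs
#'
#' Each site contributes its midpoint's relative position within its host
#' TAD, folded to a distance-from-the-nearer-boundary scale in [0, 0.5]
#' (0 = at a TAD edge, 0.5 = TAD centre). The observed sample is compared to
#' the sample from a randomized control site set with a two-sample
#' Kolmogorov-Smirnov test. Sites whose midpoint falls in no TAD are dropped
#' and counted.
#'
#' @param sites GRanges of observed sites.
#' @param random_sites GRanges of control sites.
#' @param tads GRanges of TADs.
#' @return List with `D`, `p_value`, `n_observed`, `n_random`,
#'   `n_dropped_observed`, `n_dropped_random`, and the two positional
#'   samples.
#' @export
positional_ks_test <- function(sites, random_sites, tads) {
  # TADs are used as given (sorted, NOT merged): adjacent TADs are distinct
  # position scales and must not be fused
  tads_s <- GenomicRanges::sort(tads)
  pos_obs <- folded_positions(sites, tads_s)
  pos_rnd <- folded_positions(random_sites, tads_s)
  if (length(pos_obs$values) == 0L || length(pos_rnd$values) == 0L) {
    stop("no sites with midpoints inside TADs")
  }
  ks <- suppressWarnings(stats::ks.test(pos_obs$values, pos_rnd$values))
  list(
    D = unname(ks$statistic),
    p_value = ks$p.value,
    n_observed = length(pos_obs$values),
    n_random = length(pos_rnd$values),
    n_dropped_observed = pos_obs$n_dropped,
    n_dropped_random = pos_rnd$n_dropped,
    positions_observed = pos_obs$values,
    positions_random = pos_rnd$values
  )
}

# internal: folded relative midpoint positions of sites within host TADs
folded_positions <- function(sites, tads_s) {
  if (length(sites) == 0L) return(list(values = numeric(0), n_dropped = 0L))
  mid <- (GenomicRanges::start(sites) + GenomicRanges::end(sites)) %/% 2L
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                                IRanges::IRanges(mid, width = 1L))
  ov <- GenomicRanges::findOverlaps(pts, tads_s, ignore.strand = TRUE,
                                    select = "first")
  keep <- !is.na(ov)
  tad <- tads_s[ov[keep]]
  rel <- (mid[keep] - GenomicRanges::start(tad)) /
    pmax(1L, GenomicRanges::width(tad) - 1L)
  list(values = pmin(rel, 1 - rel), n_dropped = sum(!keep))
}
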