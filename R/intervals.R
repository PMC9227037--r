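#' Merge overlapping and touching intervals
#'
#' Collapses a set of intervals to the minimal sorted, non-overlapping set
#' covering the same bases. Intervals that touch (the end of one equals the
#' start of the next in 0-based half-open terms) are merged into one.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @return A sorted, disjoint GRanges covering the same union of bases.
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(GenomicRanges::sort(gr), ignore.strand = TRUE)
}

#' Total base pairs of overlap between two interval sets
#'
#' The number of base pairs in the intersection of the merged unions of `a`
#' and `b` — the "observed coverage" statistic of the enrichment test.
#' Symmetric in its arguments.
#'
#' @param a,b [GenomicRanges::GRanges] on the same assembly.
#' @return Overlap in bp (numeric scalar).
#' @export
total_overlap_bp <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  am <- merge_intervals(a)
  bm <- merge_intervals(b)
  ov <- GenomicRanges::findOverlaps(am, bm, ignore.strand = TRUE)
  if (length(ov) == 0L) return(0)
  sum(as.numeric(GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(am)[S4Vectors::queryHits(ov)],
    GenomicRanges::ranges(bm)[S4Vectors::subjectHits(ov)]
  ))))
}

#' Randomly reposition intervals within the genome, preserving lengths
#'
#' The shuffle primitive behind every null model in the package: each input
#' interval is placed uniformly at random over all valid start positions in
#' the allowed space, preserving the multiset of interval lengths exactly.
#' The allowed space is the whole assembly, minus `exclude` if given,
#' intersected with `within` if given. The chromosome/span for each site is
#' chosen with probability proportional to its number of valid starts, so
#' placement is uniform over the genome-wide set of valid positions.
#'
#' Shuffled intervals may overlap one another (matching common shuffle-null
#' practice); set `non_overlapping = TRUE` for rejection-sampled disjoint
#' placement.
#'
#' @param sites A [GenomicRanges::GRanges] of intervals to reposition.
#' @param assembly A [GenomeInfoDb::Seqinfo].
#' @param rng_seed Integer seed; the same seed reproduces the same placement.
#' @param exclude Optional GRanges removed from the allowed space.
#' @param within Optional GRanges the placements must fall inside.
#' @param non_overlapping If `TRUE`, resample until placements are disjoint.
#' @return A GRanges with the same number and lengths of intervals as
#'   `sites`, in placement order.
#' @export
shuffle_intervals <- function(sites, assembly, rng_seed,
                              exclude = NULL, within = NULL,
                              non_overlapping = FALSE) {
  if (length(sites) == 0L) return(GenomicRanges::GRanges(seqinfo = assembly))
  spans <- allowed_spans(assembly, exclude = exclude, within = within)
  set.seed(as.integer(rng_seed))
  out <- place_uniform(GenomicRanges::width(sites), spans)
  if (non_overlapping) {
    for (iter in seq_len(1000L)) {
      hit <- overlaps_within_set(out)
      if (!any(hit)) break
      out[hit] <- place_uniform(GenomicRanges::width(out)[hit], spans)
    }
    if (any(overlaps_within_set(out))) {
      stop("could not place ", length(out),
           " non-overlapping intervals in the allowed space")
    }
  }
  set_assembly(out, assembly)
}

# internal: allowed placement spans (merged) for a shuffle
allowed_spans <- function(assembly, exclude = NULL, within = NULL) {
  spans <- assembly_ranges(assembly)
  if (!is.null(exclude) && length(exclude) > 0L) {
    spans <- GenomicRanges::setdiff(spans, merge_intervals(exclude),
                                    ignore.strand = TRUE)
  }
  if (!is.null(within)) {
    spans <- GenomicRanges::intersect(spans, merge_intervals(within),
                                      ignore.strand = TRUE)
  }
  if (length(spans) == 0L) stop("allowed placement space is empty")
  spans
}

# internal: uniform placement of interval lengths over spans; chromosome/span
# chosen proportional to its count of valid starts for that length. Consumes
# the current RNG stream.
place_uniform <- function(lens, spans) {
  w <- GenomicRanges::width(spans)
  sstart <- GenomicRanges::start(spans)
  schrom <- as.character(GenomicRanges::seqnames(spans))
  chrom <- character(length(lens))
  start <- integer(length(lens))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    valid <- pmax(0, w - L + 1)
    if (sum(valid) == 0) {
      stop("site of length ", L, " bp does not fit in any allowed span")
    }
    pick <- sample.int(length(spans), length(idx), replace = TRUE,
                       prob = valid)
    off <- floor(stats::runif(length(idx)) * valid[pick])
    chrom[idx] <- schrom[pick]
    start[idx] <- sstart[pick] + as.integer(off)
  }
  # carry every span chromosome as a level so placement outputs combine
  # cleanly regardless of which chromosomes were drawn
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = unique(schrom)),
    ranges = IRanges::IRanges(start = start, width = lens)
  )
}

# internal: which intervals overlap another interval of the same set
overlaps_within_set <- function(gr) {
  GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE) > 1L
}

# internal: seeded placement over precomputed spans (hot path for replicated
# shuffles: avoids recomputing the allowed space every replicate)
shuffle_with_spans <- function(widths, spans, rng_seed, assembly) {
  set.seed(as.integer(rng_seed))
  out <- place_uniform(widths, spans)
  set_assembly(out, assembly)
}

# --- fast numeric path for replicated shuffle nulls ------------------------
#
# Chromosomes are laid end to end on one global half-open coordinate line
# with a 1 bp spacer between them (so intervals on different chromosomes can
# never merge). Replicated placement and union-intersection coverage then
# run on plain numeric vectors, avoiding S4 container construction in the
# inner loop. The GRanges-based total_overlap_bp is the reference these
# helpers are checked against.

# per-chromosome offsets onto the global line
global_offsets <- function(assembly) {
  lens <- as.numeric(GenomeInfoDb::seqlengths(assembly))
  off <- cumsum(c(0, lens + 1))[seq_along(lens)]
  names(off) <- GenomeInfoDb::seqnames(assembly)
  off
}

# GRanges -> (start0, end0) on the global line
to_global <- function(gr, offsets) {
  o <- offsets[as.character(GenomicRanges::seqnames(gr))]
  list(start0 = o + GenomicRanges::start(gr) - 1,
       end0 = o + GenomicRanges::end(gr))
}

# total bp where the unions of A and B intervals both cover the line;
# event-sweep over the sorted breakpoints
sweep_overlap_bp <- function(a_start0, a_end0, b_start0, b_end0) {
  pos <- c(a_start0, a_end0, b_start0, b_end0)
  na <- length(a_start0)
  nb <- length(b_start0)
  da <- c(rep(1, na), rep(-1, na), rep(0, 2 * nb))
  db <- c(rep(0, 2 * na), rep(1, nb), rep(-1, nb))
  ord <- order(pos)
  pos <- pos[ord]
  cov_a <- cumsum(da[ord])
  cov_b <- cumsum(db[ord])
  n <- length(pos)
  sum(diff(pos) * (cov_a[-n] > 0 & cov_b[-n] > 0))
}

# null coverage samples: n_shuffles length-preserving placements of the
# given site widths over the allowed spans, each scored by overlap with the
# (merged) regions. Replicate r uses rng_seed + r, matching
# shuffle_intervals placement draws exactly.
null_coverage_samples <- function(widths, spans, regions_m, assembly,
                                  n_shuffles, rng_seed) {
  offsets <- global_offsets(assembly)
  sp <- to_global(spans, offsets)
  rg <- to_global(regions_m, offsets)
  w <- GenomicRanges::width(spans)
  uw <- unique(widths)
  idx_by_len <- lapply(uw, function(L) which(widths == L))
  valid_by_len <- lapply(uw, function(L) pmax(0, w - L + 1))
  vapply(seq_len(n_shuffles), function(r) {
    set.seed(as.integer(rng_seed + r))
    s0 <- numeric(length(widths))
    for (k in seq_along(uw)) {
      idx <- idx_by_len[[k]]
      valid <- valid_by_len[[k]]
      if (sum(valid) == 0) {
        stop("site of length ", uw[k], " bp does not fit in any allowed span")
      }
      pick <- sample.int(length(w), length(idx), replace = TRUE, prob = valid)
      off <- floor(stats::runif(length(idx)) * valid[pick])
      s0[idx] <- sp$start0[pick] + off
    }
    sweep_overlap_bp(s0, s0 + widths, rg$start0, rg$end0)
  }, numeric(1))
}

#' Derive boundary intervals from a TAD partition
#'
#' For every TAD edge coordinate, emits a symmetric window of `flank_bp` on
#' each side (total width `2 * flank_bp`), clipped at chromosome ends.
#' Edges shared by adjacent TADs produce one window; the result is merged.
#' The boundary width is an analysis parameter, not a measured quantity —
#' it must be reported with any result computed from boundaries.
#'
#' @param tads A [GenomicRanges::GRanges] of TAD intervals.
#' @param flank_bp Half-width of the boundary window in bp (> 0).
#' @return A merged GRanges of boundary windows.
#' @export
tad_boundaries <- function(tads, flank_bp) {
  stopifnot(flank_bp > 0)
  if (length(tads) == 0L) {
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(tads)))
  }
  # edge coordinates in 0-based terms: start0 and end0 of each TAD
  chrom <- rep(as.character(GenomicRanges::seqnames(tads)), 2L)
  edge0 <- c(GenomicRanges::start(tads) - 1L, GenomicRanges::end(tads))
  keep <- !duplicated(paste0(chrom, ":", edge0))
  chrom <- chrom[keep]
  edge0 <- edge0[keep]
  lens <- GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(tads))[chrom]
  start0 <- pmax(0, edge0 - flank_bp)
  end0 <- pmin(as.numeric(lens), edge0 + flank_bp)
  ok <- start0 < end0
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[ok],
    ranges = IRanges::IRanges(start = start0[ok] + 1L, end = end0[ok]),
    seqinfo = GenomeInfoDb::seqinfo(tads)
  )
  merge_intervals(gr)
}
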