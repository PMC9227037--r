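#' Aggregate a signal track over sites
#'
#' Summarizes a stepwise-constant signal track (bedGraph semantics) per
#' site: `mean_per_bp` divides the per-base sum by the full site length, so
#' bases not covered by any track segment contribute 0; `sum` returns the
#' per-base sum itself.
#'
#' @param sites GRanges of sites.
#' @param track GRanges with a numeric `score` column, non-overlapping
#'   segments (see [read_bedgraph()]).
#' @param statistic `"mean_per_bp"` (default) or `"sum"`.
#' @param flank_bp Extend each site symmetrically by this many bp (clipped
#'   at chromosome ends) before aggregating; default 0.
#' @return Numeric vector, one value per site.
#' @export
aggregate_signal <- function(sites, track,
                             statistic = c("mean_per_bp", "sum"),
                             flank_bp = 0) {
  statistic <- match.arg(statistic)
  if (flank_bp > 0) {
    sites <- GenomicRanges::trim(suppressWarnings(
      GenomicRanges::resize(sites, GenomicRanges::width(sites) + 2 * flank_bp,
                            fix = "center")
    ))
  }
  if (length(sites) == 0L) return(numeric(0))
  sums <- numeric(length(sites))
  if (length(track) > 0L) {
    ov <- GenomicRanges::findOverlaps(sites, track, ignore.strand = TRUE)
    if (length(ov) > 0L) {
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(sites)[S4Vectors::queryHits(ov)],
        GenomicRanges::ranges(track)[S4Vectors::subjectHits(ov)]
      ))
      contrib <- w * S4Vectors::mcols(track)$score[S4Vectors::subjectHits(ov)]
      tt <- tapply(contrib, S4Vectors::queryHits(ov), sum)
      sums[as.integer(names(tt))] <- tt
    }
  }
  switch(statistic,
         mean_per_bp = sums / GenomicRanges::width(sites),
         sum = sums)
}

#' Conservation score per base pair over sites
#'
#' Mean per-base conservation (e.g. phastCons) over each site's extent;
#' uncovered bases count as 0 in the denominator (the site length).
#' Identical contract to [aggregate_signal()] with `mean_per_bp`.
#'
#' @param sites GRanges of sites.
#' @param cons_track Conservation GRanges with `score` in [0, 1].
#' @return Numeric vector, one mean per site.
#' @export
conservation_per_bp <- function(sites, cons_track) {
  aggregate_signal(sites, cons_track, statistic = "mean_per_bp")
}

#' Per-site repeat-class occupancy fractions
#'
#' For each repeat class, the fraction of each site's length covered by
#' (merged) repeats of that class.
#'
#' @param sites GRanges of sites.
#' @param repeats_by_class Named list of GRanges, one per repeat class
#'   (typically LTR, SINE, LINE, DNA).
#' @return Numeric matrix, sites x classes, values in [0, 1].
#' @export
repeat_occupancy <- function(sites, repeats_by_class) {
  stopifnot(!is.null(names(repeats_by_class)))
  out <- vapply(repeats_by_class, function(rep_gr) {
    rep_m <- merge_intervals(rep_gr)
    bp <- numeric(length(sites))
    if (length(rep_m) > 0L && length(sites) > 0L) {
      ov <- GenomicRanges::findOverlaps(sites, rep_m, ignore.strand = TRUE)
      if (length(ov) > 0L) {
        w <- GenomicRanges::width(IRanges::pintersect(
          GenomicRanges::ranges(sites)[S4Vectors::queryHits(ov)],
          GenomicRanges::ranges(rep_m)[S4Vectors::subjectHits(ov)]
        ))
        tt <- tapply(w, S4Vectors::queryHits(ov), sum)
        bp[as.integer(names(tt))] <- tt
      }
    }
    bp / GenomicRanges::width(sites)
  }, numeric(length(sites)))
  if (length(sites) == 1L) {
    out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(repeats_by_class)))
  }
  out
}

#' Group sites by boundary association and run all pairwise comparisons
#'
#' Partitions sites into `at_boundary` (>= 1 bp overlap with the boundary
#' set) and `non_boundary`, adds the full set (`all`) and a
#' `random_control` group built by length-preserving repositioning of the
#' sites in the genome, evaluates `value_fun` on each group's intervals,
#' and runs a Welch two-sample t-test for every pair of the four groups
#' (6 comparisons). Raw p-values are reported without multiple-testing
#' correction. Pairs where either group has fewer than 2 values, or where
#' both samples are constant, are marked untestable rather than dropped.
#'
#' @param sites GRanges of sites.
#' @param boundaries GRanges of boundary windows.
#' @param assembly A [GenomeInfoDb::Seqinfo].
#' @param value_fun Function `GRanges -> numeric` measuring one value per
#'   interval (e.g. `function(g) conservation_per_bp(g, track)`).
#' @param rng_seed Integer seed for the random control placement.
#' @param exclude Optional GRanges excluded from control placement.
#' @return Object of class `group_comparison`: list with `values` (named
#'   list of per-group numeric vectors), `group_sizes`, and `pairs` (a
#'   data.frame: group1, group2, n1, n2, mean1, mean2, t_statistic,
#'   p_value, testable).
#' @export
group_and_compare <- function(sites, boundaries, assembly, value_fun,
                              rng_seed, exclude = NULL) {
  hit <- IRanges::overlapsAny(sites, boundaries, ignore.strand = TRUE)
  control <- shuffle_intervals(sites, assembly, rng_seed = rng_seed,
                               exclude = exclude)
  groups <- list(
    all = sites,
    at_boundary = sites[hit],
    non_boundary = sites[!hit],
    random_control = control
  )
  values <- lapply(groups, value_fun)
  nms <- names(groups)
  combos <- utils::combn(nms, 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1L, k]; g2 <- combos[2L, k]
    v1 <- values[[g1]]; v2 <- values[[g2]]
    tt <- if (length(v1) >= 2L && length(v2) >= 2L) {
      tryCatch(stats::t.test(v1, v2), error = function(e) NULL)
    } else NULL
    data.frame(
      group1 = g1, group2 = g2,
      n1 = length(v1), n2 = length(v2),
      mean1 = if (length(v1)) mean(v1) else NA_real_,
      mean2 = if (length(v2)) mean(v2) else NA_real_,
      t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value,
      testable = !is.null(tt),
      stringsAsFactors = FALSE
    )
  }))
  res <- list(values = values,
              group_sizes = vapply(values, length, integer(1)),
              pairs = pairs)
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Pairwise Welch t-tests over site groups\n")
  cat("  group sizes:",
      paste(names(x$group_sizes), x$group_sizes, sep = "=", collapse = ", "),
      "\n")
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Assign each site to the gene with the nearest transcription start site
#'
#' The distance from a site to a TSS is the minimum over the site span
#' (0 when the TSS lies inside the site). Ties are broken by the smaller
#' TSS coordinate, then by lexicographic gene name. The signed distance is
#' negative when the TSS lies to the left of the site, positive to the
#' right, 0 inside. Sites on chromosomes without any TSS are unassigned
#' (`NA`) and counted.
#'
#' @param sites GRanges of sites.
#' @param tss GRanges of TSS positions (the interval start is the TSS) with
#'   a `name` column of gene identifiers.
#' @return data.frame with one row per site: `chrom`, `start`, `end` (BED
#'   0-based half-open), `gene`, `distance` (signed bp). Attribute
#'   `n_unassigned` counts sites with no same-chromosome TSS.
#' @export
nearest_tss_targets <- function(sites, tss) {
  if (length(tss) == 0L) stop("TSS set is empty")
  gene <- S4Vectors::mcols(tss)$name
  if (is.null(gene)) stop("TSS intervals need a 'name' column")
  tss_chrom <- as.character(GenomicRanges::seqnames(tss))
  tss_pos <- GenomicRanges::start(tss)
  out_gene <- rep(NA_character_, length(sites))
  out_dist <- rep(NA_real_, length(sites))
  s_chrom <- as.character(GenomicRanges::seqnames(sites))
  s_start <- GenomicRanges::start(sites)
  s_end <- GenomicRanges::end(sites)
  for (ch in unique(s_chrom)) {
    ti <- which(tss_chrom == ch)
    si <- which(s_chrom == ch)
    if (length(ti) == 0L) next
    # order candidate TSS by the tie-break rule once
    ord <- ti[order(tss_pos[ti], gene[ti])]
    pos0 <- tss_pos[ord] - 1L  # TSS in BED coordinate space
    for (i in si) {
      s0 <- s_start[i] - 1L    # site as closed BED coordinate span [s0, e0]
      e0 <- s_end[i]
      d <- ifelse(pos0 < s0, pos0 - s0, ifelse(pos0 > e0, pos0 - e0, 0))
      best <- which.min(abs(d))  # first minimum = smaller coord, then name
      out_gene[i] <- gene[ord[best]]
      out_dist[i] <- d[best]
    }
  }
  res <- data.frame(
    chrom = s_chrom,
    start = s_start - 1L,
    end = s_end,
    gene = out_gene,
    distance = out_dist,
    stringsAsFactors = FALSE
  )
  attr(res, "n_unassigned") <- sum(is.na(out_gene))
  res
}
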