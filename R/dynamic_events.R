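#' Enumerate dynamic presence/absence patterns
#'
#' A site tracked across `n_stages` ordered stages has a binary state at
#' each stage (e.g. overlaps a TAD boundary, or lies in compartment A). A
#' pattern is *dynamic* when the state changes at least once, i.e. the tuple
#' is not constant. For four stages this yields the 2^4 - 2 = 14 dynamic
#' categories.
#'
#' @param n_stages Number of ordered stages (>= 1).
#' @return Character vector of dynamic patterns (e.g. `"0110"`), in
#'   lexicographic order; length `2^n_stages - 2` (0 for `n_stages = 1`).
#' @export
enumerate_dynamic_patterns <- function(n_stages) {
  n_stages <- as.integer(n_stages)
  stopifnot(n_stages >= 1L)
  grid <- expand.grid(rep(list(c("0", "1")), n_stages))[, rev(seq_len(n_stages)),
                                                        drop = FALSE]
  pats <- sort(apply(grid, 1L, paste0, collapse = ""))
  pats[!(pats %in% c(strrep("0", n_stages), strrep("1", n_stages)))]
}

#' Is a pattern dynamic?
#'
#' @param pattern Character vector of binary pattern strings.
#' @return Logical: `TRUE` when the state changes between some pair of
#'   consecutive stages (equivalently, the pattern is not constant).
#' @export
is_dynamic_pattern <- function(pattern) {
  n <- nchar(pattern)
  pattern != strrep("0", n) & pattern != strrep("1", n)
}

#' Annotate sites with per-stage boundary presence patterns
#'
#' State at a stage is 1 when the site overlaps that stage's boundary set by
#' at least 1 bp (boundaries are narrow targets, so any-overlap is the
#' natural association rule).
#'
#' @param sites GRanges of sites.
#' @param boundaries_by_stage Ordered list of per-stage boundary GRanges
#'   (see [tad_boundaries()]).
#' @return Character vector of patterns, one per site, stage order = list
#'   order.
#' @export
annotate_boundary_patterns <- function(sites, boundaries_by_stage) {
  states <- vapply(boundaries_by_stage, function(b) {
    IRanges::overlapsAny(sites, b, ignore.strand = TRUE)
  }, logical(length(sites)))
  if (length(sites) == 1L) states <- matrix(states, nrow = 1L)
  apply(states, 1L, function(s) paste0(as.integer(s), collapse = ""))
}

#' Annotate sites with per-stage compartment (A/B) patterns
#'
#' State at a stage is 1 when the site's midpoint lies in an A-compartment
#' interval of that stage (compartments are broad partitions, so the
#' midpoint decides). Sites whose midpoint is unassigned at any stage are
#' returned as `NA` and should be dropped (and counted) by the caller.
#'
#' @param sites GRanges of sites.
#' @param compartments_by_stage Ordered list of per-stage GRanges with a
#'   `name` column holding labels `"A"` or `"B"`.
#' @return Character vector of patterns (`NA` where unassigned).
#' @export
annotate_compartment_patterns <- function(sites, compartments_by_stage) {
  mid <- (GenomicRanges::start(sites) + GenomicRanges::end(sites)) %/% 2L
  pts <- GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                                IRanges::IRanges(mid, width = 1L))
  states <- vapply(compartments_by_stage, function(comp) {
    lab <- S4Vectors::mcols(comp)$name
    if (is.null(lab)) stop("compartment intervals need a 'name' label (A/B)")
    hit <- GenomicRanges::findOverlaps(pts, comp, ignore.strand = TRUE,
                                       select = "first")
    out <- rep(NA_integer_, length(pts))
    out[!is.na(hit)] <- as.integer(lab[hit[!is.na(hit)]] == "A")
    out
  }, integer(length(sites)))
  if (length(sites) == 1L) states <- matrix(states, nrow = 1L)
  apply(states, 1L, function(s) {
    if (anyNA(s)) NA_character_ else paste0(s, collapse = "")
  })
}

#' Tabulate pattern counts over the dynamic category space
#'
#' Counts patterns over all dynamic categories for the stage count, plus one
#' pooled `"static"` bin for constant patterns (never / always in state 1).
#'
#' @param patterns Character vector of pattern strings (NAs ignored).
#' @param n_stages Number of stages the patterns span.
#' @return Named integer vector over `c(enumerate_dynamic_patterns(n),
#'   "static")`.
#' @export
pattern_counts <- function(patterns, n_stages) {
  patterns <- patterns[!is.na(patterns)]
  cats <- enumerate_dynamic_patterns(n_stages)
  counts <- table(factor(ifelse(is_dynamic_pattern(patterns), patterns,
                                "static"),
                         levels = c(cats, "static")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Chi-square test of dynamic-category counts against randomized sites
#'
#' Annotates each observed site with its dynamic pattern (boundary
#' gain/loss, or A/B compartment switching), tabulates counts over the
#' dynamic categories, and compares them to expected counts obtained by
#' repositioning the sites uniformly at random in the genome
#' `n_randomizations` times and averaging the resulting category counts
#' (rescaled to the observed total). Bins with expected count below
#' `min_expected` are pooled into a single `"rare"` bin before the test
#' (classical chi-square validity rule); the pre-pooling table is returned.
#'
#' @param sites GRanges of observed sites.
#' @param series Ordered list of per-stage annotation GRanges: boundary sets
#'   for `type = "boundary"`, labeled A/B compartments for
#'   `type = "compartment"`.
#' @param assembly A [GenomeInfoDb::Seqinfo].
#' @param type `"boundary"` or `"compartment"`.
#' @param n_randomizations Number of random site sets (default 100).
#' @param rng_seed Integer base seed (randomization r uses seed + r).
#' @param include_static Include the pooled static bin in the chi-square
#'   (default `FALSE`: the test runs over the dynamic categories only, which
#'   are the "14 unique possibilities" for 4 stages).
#' @param min_expected Pooling threshold for expected counts (default 5).
#' @return Object of class `category_counts`: list with `observed`,
#'   `expected` (pre-pooling, rescaled), `chi2`, `df`, `p_value`,
#'   `n_sites_kept`, `n_dropped`, `pooled_bins`, `degenerate`.
#' @export
category_chi_square <- function(sites, series, assembly,
                                type = c("boundary", "compartment"),
                                n_randomizations = 100L, rng_seed = 1L,
                                include_static = FALSE, min_expected = 5) {
  type <- match.arg(type)
  stopifnot(n_randomizations >= 1L)
  n_stages <- length(series)
  annotate <- switch(type,
    boundary = function(g) annotate_boundary_patterns(g, series),
    compartment = function(g) annotate_compartment_patterns(g, series)
  )
  obs_pat <- annotate(sites)
  n_dropped <- sum(is.na(obs_pat))
  obs <- pattern_counts(obs_pat, n_stages)
  spans <- allowed_spans(assembly)
  widths <- GenomicRanges::width(sites)
  rand_mat <- vapply(seq_len(n_randomizations), function(r) {
    shuf <- shuffle_with_spans(widths, spans, rng_seed + r, assembly)
    pattern_counts(annotate(shuf), n_stages)
  }, numeric(length(obs)))
  exp_raw <- rowMeans(rand_mat)
  sel <- if (include_static) rep(TRUE, length(obs)) else names(obs) != "static"
  test <- chisq_counts(obs[sel], exp_raw[sel], min_expected = min_expected)
  expected <- exp_raw
  if (!test$degenerate) {
    expected[sel] <- exp_raw[sel] * sum(obs[sel]) / sum(exp_raw[sel])
  }
  res <- list(
    observed = obs,
    expected = expected,
    chi2 = test$chi2,
    df = test$df,
    p_value = test$p_value,
    n_sites_kept = sum(obs),
    n_dropped = n_dropped,
    pooled_bins = test$pooled_bins,
    degenerate = test$degenerate,
    include_static = include_static
  )
  class(res) <- "category_counts"
  res
}

# internal: chi-square goodness-of-fit of observed counts against expected
# counts. Expected are rescaled to the observed total; bins with expected
# below min_expected are pooled into one bin; chi2 = sum (O-E)^2 / E over
# bins with E > 0, df = bins - 1, upper-tail p. Set rescale = FALSE when the
# expected counts are already on the observed scale.
chisq_counts <- function(O, E, min_expected = 5, rescale = TRUE) {
  stopifnot(length(O) == length(E))
  if (sum(E) == 0 || sum(O) == 0) {
    return(list(chi2 = 0, df = NA_integer_, p_value = 1,
                pooled_bins = character(0), degenerate = TRUE))
  }
  if (rescale) E <- E * sum(O) / sum(E)
  rare <- E < min_expected
  pooled <- names(O)[rare]
  if (sum(rare) > 0L) {
    O <- c(O[!rare], rare = sum(O[rare]))
    E <- c(E[!rare], rare = sum(E[rare]))
  }
  keep <- E > 0
  O <- O[keep]
  E <- E[keep]
  if (length(O) < 2L) {
    return(list(chi2 = 0, df = NA_integer_, p_value = 1,
                pooled_bins = pooled, degenerate = TRUE))
  }
  chi2 <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       pooled_bins = if (is.null(pooled)) character(0) else pooled,
       degenerate = FALSE)
}

#' @export
print.category_counts <- function(x, ...) {
  cat("Dynamic-category chi-square vs randomized sites\n")
  cat(sprintf("  sites: %d kept, %d dropped; static excluded: %s\n",
              x$n_sites_kept, x$n_dropped, !x$include_static))
  cat(sprintf("  chi2 = %.3f, df = %s, p = %.3g%s\n", x$chi2,
              as.character(x$df), x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  if (length(x$pooled_bins) > 0L) {
    cat("  pooled rare bins:", paste(x$pooled_bins, collapse = " "), "\n")
  }
  invisible(x)
}
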