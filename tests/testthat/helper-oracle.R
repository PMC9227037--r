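# Per-base bitmap oracles for interval arithmetic, usable on genomes up to
# ~1 Mb. Deliberately brute-force and independent of the package's interval
# code paths: every base of every chromosome is materialized.

tiny_assembly <- function(lengths) {
  GenomeInfoDb::Seqinfo(seqnames = names(lengths),
                        seqlengths = as.integer(lengths))
}

# BED-style constructor: 0-based half-open coordinates in, GRanges out
bed_gr <- function(chrom, start0, end0, assembly = NULL, name = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(assembly)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(assembly)
    GenomeInfoDb::seqinfo(gr) <- assembly
  }
  gr
}

bitmap_of <- function(gr, assembly) {
  lens <- GenomeInfoDb::seqlengths(assembly)
  maps <- lapply(lens, function(l) logical(l))
  ch <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  for (i in seq_along(gr)) {
    maps[[ch[i]]][st[i]:en[i]] <- TRUE
  }
  maps
}

bitmap_union_bp <- function(gr, assembly) {
  sum(vapply(bitmap_of(gr, assembly), sum, numeric(1)))
}

bitmap_overlap_bp <- function(a, b, assembly) {
  ma <- bitmap_of(a, assembly)
  mb <- bitmap_of(b, assembly)
  sum(unlist(Map(function(x, y) sum(x & y), ma, mb)))
}

# per-base value vectors from a stepwise track, then per-site mean/sum
bitmap_signal <- function(sites, track, assembly,
                          statistic = c("mean_per_bp", "sum")) {
  statistic <- match.arg(statistic)
  lens <- GenomeInfoDb::seqlengths(assembly)
  vals <- lapply(lens, function(l) numeric(l))
  tch <- as.character(GenomicRanges::seqnames(track))
  for (i in seq_along(track)) {
    idx <- GenomicRanges::start(track)[i]:GenomicRanges::end(track)[i]
    vals[[tch[i]]][idx] <- S4Vectors::mcols(track)$score[i]
  }
  sch <- as.character(GenomicRanges::seqnames(sites))
  vapply(seq_along(sites), function(i) {
    v <- vals[[sch[i]]][GenomicRanges::start(sites)[i]:GenomicRanges::end(sites)[i]]
    if (statistic == "sum") sum(v) else sum(v) / length(v)
  }, numeric(1))
}

# random interval set on an assembly; consumes the current RNG stream
random_granges <- function(assembly, n, max_len = 500L) {
  lens <- GenomeInfoDb::seqlengths(assembly)
  ch <- sample(names(lens), n, replace = TRUE)
  L <- sample.int(max_len, n, replace = TRUE)
  st <- vapply(seq_len(n), function(i) {
    sample.int(lens[[ch[i]]] - L[i] + 1L, 1L)
  }, integer(1))
  GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = L),
                         seqinfo = assembly)
}

# random non-overlapping stepwise track covering part of the assembly
random_track <- function(assembly, n_segments = 30L) {
  gr <- GenomicRanges::reduce(random_granges(assembly, n_segments,
                                             max_len = 2000L))
  S4Vectors::mcols(gr)$score <- round(stats::runif(length(gr), -2, 5), 3)
  gr
}
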