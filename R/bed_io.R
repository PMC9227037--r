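#' Read a BED file of genomic intervals
#'
#' Reads BED3/BED4/BED6 (tab-separated, no header) into a
#' [GenomicRanges::GRanges] bound to `assembly`. File coordinates are BED
#' 0-based half-open; the returned GRanges uses the usual 1-based closed
#' convention. Column 4 becomes `name`, column 5 `score`, column 6 `strand`.
#' Intervals with `start >= end`, unknown chromosomes, or ends beyond the
#' chromosome length are rejected with the offending line number (no
#' clipping).
#'
#' @param path Path to a BED file.
#' @param assembly A [GenomeInfoDb::Seqinfo] governing the intervals.
#' @return A [GenomicRanges::GRanges].
#' @seealso [write_bed()]
#' @export
read_bed <- function(path, assembly) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = ""),
    error = function(e) NULL
  )
  if (is.null(tab) || nrow(tab) == 0L) {
    return(GenomicRanges::GRanges(seqinfo = assembly))
  }
  if (ncol(tab) < 3L) {
    stop("BED file '", path, "': fewer than 3 columns")
  }
  start0 <- suppressWarnings(as.numeric(tab[[2L]]))
  end0 <- suppressWarnings(as.numeric(tab[[3L]]))
  bad <- which(!is.finite(start0) | !is.finite(end0) | start0 < 0 |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad) > 0L) {
    stop("BED line ", bad[1L], " in '", path, "': malformed coordinates")
  }
  rev <- which(start0 >= end0)
  if (length(rev) > 0L) {
    stop("BED line ", rev[1L], " in '", path, "': start (", start0[rev[1L]],
         ") must be < end (", end0[rev[1L]], ")")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1L]],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
  if (ncol(tab) >= 4L) S4Vectors::mcols(gr)$name <- tab[[4L]]
  if (ncol(tab) >= 5L) {
    S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(tab[[5L]]))
  }
  if (ncol(tab) >= 6L) {
    str <- tab[[6L]]
    str[!str %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- str
  }
  bind_assembly(gr, assembly, what = paste0("BED line (", path, ")"))
}

#' Write genomic intervals to a BED file
#'
#' Writes BED3 (or BED4 with `name`, BED6 with `name` + `score` + strand)
#' using 0-based half-open coordinates, so `write_bed` then [read_bed()] is
#' the identity on (chrom, start, end, name).
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = format(GenomicRanges::start(gr) - 1L, scientific = FALSE,
                   trim = TRUE),
    end = format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  has_strand <- any(as.character(GenomicRanges::strand(gr)) != "*")
  if ("name" %in% colnames(mc) || has_strand) {
    df$name <- if ("name" %in% colnames(mc)) as.character(mc$name) else "."
  }
  if (("score" %in% colnames(mc)) || has_strand) {
    df$score <- if ("score" %in% colnames(mc)) mc$score else 0
    df$strand <- as.character(GenomicRanges::strand(gr))
    df$strand[df$strand == "*"] <- "."
    if (is.null(df$name)) df$name <- "."
    df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Reads a four-column bedGraph (`chrom`, `start`, `end`, `value`) into a
#' GRanges with a numeric `score` column. Input may be unsorted; the result
#' is sorted. Segments on the same chromosome must not overlap (stepwise-
#' constant track semantics); bases covered by no segment have value 0.
#'
#' @param path Path to a bedGraph file.
#' @param assembly A [GenomeInfoDb::Seqinfo].
#' @return A sorted [GenomicRanges::GRanges] with `score`.
#' @export
read_bedgraph <- function(path, assembly) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = ""),
    error = function(e) NULL
  )
  if (is.null(tab) || nrow(tab) == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = assembly)
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  if (ncol(tab) < 4L) {
    stop("bedGraph file '", path, "': expected 4 columns")
  }
  start0 <- suppressWarnings(as.numeric(tab[[2L]]))
  end0 <- suppressWarnings(as.numeric(tab[[3L]]))
  val <- suppressWarnings(as.numeric(tab[[4L]]))
  bad <- which(!is.finite(start0) | !is.finite(end0) | !is.finite(val) |
                 start0 < 0 | start0 >= end0)
  if (length(bad) > 0L) {
    stop("bedGraph line ", bad[1L], " in '", path, "': malformed record")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tab[[1L]],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    score = val
  )
  gr <- bind_assembly(gr, assembly, what = paste0("bedGraph line (", path, ")"))
  gr <- GenomicRanges::sort(gr)
  validate_track(gr)
  gr
}

#' Write a signal track as bedGraph
#'
#' @param track A GRanges with a numeric `score` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = format(GenomicRanges::start(track) - 1L, scientific = FALSE,
                   trim = TRUE),
    end = format(GenomicRanges::end(track), scientific = FALSE, trim = TRUE),
    score = format(S4Vectors::mcols(track)$score, scientific = FALSE,
                   trim = TRUE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal: assert stepwise-constant track invariants
validate_track <- function(track) {
  if (is.null(S4Vectors::mcols(track)$score)) {
    stop("signal track must carry a numeric 'score' column")
  }
  if (length(track) > 1L) {
    cov <- sum(as.numeric(GenomicRanges::width(track)))
    red <- sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(
      track, ignore.strand = TRUE))))
    if (red < cov) stop("signal track segments overlap")
  }
  invisible(track)
}
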