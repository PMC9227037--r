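#' Read a chromosome-sizes file into a genome assembly
#'
#' Parses a two-column whitespace-delimited file (`chromosome name`,
#' `length in bp`) into a [GenomeInfoDb::Seqinfo] object, the genome
#' assembly used throughout the package to define the shuffle space and to
#' validate interval coordinates.
#'
#' @param path Path to a `chrom.sizes`-style text file.
#' @return A [GenomeInfoDb::Seqinfo] with chromosomes in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), f)
#' asm <- read_chrom_sizes(f)
#' assembly_size(asm)  # 1500
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("chrom.sizes file '", path, "' is empty")
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed chrom.sizes line ", which(nf < 2L)[1L], " in '", path,
         "': expected <name> <length>")
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  bad <- which(!is.finite(len) | len <= 0 | len != floor(len))
  if (length(bad) > 0L) {
    stop("chrom.sizes line ", bad[1L], " in '", path,
         "': length must be a positive integer")
  }
  dup <- which(duplicated(nm))
  if (length(dup) > 0L) {
    stop("chrom.sizes line ", dup[1L], " in '", path,
         "': duplicate chromosome name '", nm[dup[1L]], "'")
  }
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Total genome length of an assembly
#'
#' @param assembly A [GenomeInfoDb::Seqinfo].
#' @return Total length in bp (numeric).
#' @export
assembly_size <- function(assembly) {
  sum(as.numeric(GenomeInfoDb::seqlengths(assembly)))
}

#' Whole-genome interval set for an assembly
#'
#' One interval spanning each chromosome end to end; the complement basis for
#' shuffle-space computations.
#'
#' @param assembly A [GenomeInfoDb::Seqinfo].
#' @return A [GenomicRanges::GRanges] covering every chromosome.
#' @export
assembly_ranges <- function(assembly) {
  GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(assembly),
    ranges = IRanges::IRanges(
      start = 1L,
      end = GenomeInfoDb::seqlengths(assembly)
    ),
    seqinfo = assembly
  )
}

# internal: attach assembly seqinfo to a GRanges whose seqlevels may be a
# subset or differently ordered (e.g. freshly built from placement output)
set_assembly <- function(gr, assembly) {
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(assembly)
  GenomeInfoDb::seqinfo(gr) <- assembly
  gr
}

# internal: bind a GRanges to an assembly, validating chrom membership and
# coordinate bounds. Used by every reader.
bind_assembly <- function(gr, assembly, what = "interval") {
  sn <- as.character(GenomicRanges::seqnames(gr))
  known <- GenomeInfoDb::seqnames(assembly)
  bad <- which(!(sn %in% known))
  if (length(bad) > 0L) {
    stop(what, " ", bad[1L], ": unknown chromosome '", sn[bad[1L]], "'")
  }
  lens <- GenomeInfoDb::seqlengths(assembly)[sn]
  over <- which(GenomicRanges::end(gr) > lens)
  if (length(over) > 0L) {
    stop(what, " ", over[1L], ": end ", GenomicRanges::end(gr)[over[1L]],
         " exceeds length of ", sn[over[1L]], " (", lens[over[1L]], ")")
  }
  GenomeInfoDb::seqlevels(gr) <- known
  GenomeInfoDb::seqinfo(gr) <- assembly
  gr
}
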