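#' Genomic interval tibbles
#'
#' Throughout the package a set of genomic intervals is an ordinary tibble
#' with columns `chrom` (character), `start`, `end` (integers) and optionally
#' `strand` (`"+"`, `"-"` or `"."`). Coordinates are **0-based half-open**
#' everywhere in memory (BED-native): `start` is the first base of the
#' interval, `end` is one past the last. Readers of 1-based dialects (the
#' chimeric table, GTF-lite) apply the offset exactly once, on read.
#'
#' @param x A data frame with at least `chrom`, `start`, `end` columns.
#' @param require_strand Require a valid `strand` column as well.
#' @return `x` invisibly, after validation.
#' @examples
#' validate_intervals(tibble::tibble(chrom = "chr1", start = 0L, end = 10L))
#' @export
validate_intervals <- function(x, require_strand = FALSE) {
  needed <- c("chrom", "start", "end", if (require_strand) "strand")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(paste0("interval table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | x$chrom == "")) abort("chrom must be non-empty")
  if (any(x$start < 0)) abort("start must be >= 0")
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    abort(paste0("end must be > start (row ", bad, ": start=", x$start[bad],
                 ", end=", x$end[bad], ")"))
  }
  if (require_strand && any(!x$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed)
as_granges <- function(x, stranded = FALSE) {
  validate_intervals(x, require_strand = stranded)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if (stranded) x$strand else "*"
  )
}

# single genomic positions (0-based) -> width-1 GRanges
points_as_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L)
  )
}

#' Canonical junction identifier
#'
#' Builds the `chrom:start-end:strand` key used to identify a back-splice
#' junction across the pipeline (coordinates 0-based half-open).
#'
#' @param chrom,start,end,strand Vectors of equal length.
#' @return Character vector of identifiers.
#' @export
junction_key <- function(chrom, start, end, strand = ".") {
  paste0(chrom, ":", start, "-", end, ":", strand)
}
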