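#' Read a BED3+ peak file
#'
#' Standard 0-based half-open BED intervals.
#'
#' @param path BED file path.
#' @param source_label Label recorded on the peak set.
#' @return Tibble `chrom, start, end, source` (a `peak_set`).
#' @export
read_peaks <- function(path, source_label = basename(path)) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)[, 1:3]
  names(tb) <- c("chrom", "start", "end")
  peak_set(tibble::as_tibble(tb), source_label)
}

#' Construct / validate a peak set
#'
#' @param peaks Tibble/data frame with `chrom, start, end` (0-based
#'   half-open).
#' @param source_label Label for provenance.
#' @return Validated tibble with a `source` column.
#' @export
peak_set <- function(peaks, source_label = "peaks") {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) {
    stop("peak intervals must satisfy start < end", call. = FALSE)
  }
  peaks$source <- source_label
  peaks
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chrom, length (bp).
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tb[[2]]), tb[[1]])
}

#' ChIP peak density per chromosome
#'
#' Peaks per megabase for each chromosome; with `normalize = TRUE` the
#' densities are additionally divided by the total peak count, so that
#' `sum(density * Mb)` equals 1 exactly (conservation identity).
#'
#' @param peaks A [peak_set()] tibble.
#' @param sizes Named chromosome lengths in bp ([read_chrom_sizes()]).
#' @param normalize Divide by the total number of peaks.
#' @return Tibble `chrom, length_bp, n_peaks, density` (peaks/Mb, or
#'   1/Mb-per-total-peak when normalised).
#' @export
peak_density <- function(peaks, sizes, normalize = FALSE) {
  if (any(sizes <= 0)) stop("chromosome lengths must be > 0",
                            call. = FALSE)
  unknown <- setdiff(unique(peaks$chrom), names(sizes))
  if (length(unknown)) {
    stop("peaks on chromosomes absent from the sizes table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cnt <- table(factor(peaks$chrom, levels = names(sizes)))
  out <- tibble::tibble(chrom = names(sizes),
                        length_bp = unname(sizes),
                        n_peaks = as.integer(cnt))
  out$density <- out$n_peaks / (out$length_bp / 1e6)
  if (normalize) out$density <- out$density / nrow(peaks)
  out
}

#' Reproducibly enriched intervals across peak sets
#'
#' Intersects two or more peak sets: the output intervals are the
#' genomic stretches present in every set, kept when the joint overlap
#' spans at least `min_overlap_bp`; zero-length touching does not count
#' as overlap.
#'
#' @param peaksets List of [peak_set()] tibbles (>= 2).
#' @param min_overlap_bp Minimum overlap width in bp.
#' @return A [peak_set()] of the intersections (0-based half-open).
#' @export
reproducible_peaks <- function(peaksets, min_overlap_bp = 1) {
  if (length(peaksets) < 2L) stop("need >= 2 peak sets", call. = FALSE)
  if (!requireNamespace("GenomicRanges", quietly = TRUE)) {
    stop("GenomicRanges is required for interval intersection",
         call. = FALSE)
  }
  grs <- lapply(peaksets, function(p) {
    GenomicRanges::GRanges(p$chrom,
                           IRanges::IRanges(p$start + 1, p$end))
  })
  inter <- Reduce(function(a, b) {
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  }, grs)
  inter <- inter[GenomicRanges::width(inter) >= min_overlap_bp]
  peak_set(tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(inter)),
    start = GenomicRanges::start(inter) - 1,
    end = GenomicRanges::end(inter)), "intersection")
}
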