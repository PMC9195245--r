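# Genome-size estimation from a k-mer depth histogram.
#
# The estimator is the classical survey formula
#   G = (total number of k-mer instances) / (depth at the k-mer peak),
# with the low-depth sequencing-error peak excluded by a minimum-depth
# cutoff before the peak is located.

#' Construct a k-mer depth histogram
#'
#' @param depth integer vector of depths (>= 1, unique).
#' @param count number of distinct k-mers observed at each depth (>= 0,
#'   at least one positive).
#' @param k the k-mer length the histogram was computed with (default 17).
#' @return a data.frame of class `kmer_histogram` with columns `depth` and
#'   `count`, sorted by depth, with attribute `k`.
#' @export
kmer_histogram <- function(depth, count, k = 17L) {
  depth <- as.integer(depth)
  count <- as.numeric(count)
  if (length(depth) != length(count) || length(depth) == 0L)
    stop("depth and count must be non-empty vectors of equal length")
  if (any(depth < 1L) || anyDuplicated(depth)) stop("depths must be unique and >= 1")
  if (any(count < 0) || !any(count > 0))
    stop("counts must be >= 0 with at least one positive entry")
  o <- order(depth)
  structure(data.frame(depth = depth[o], count = count[o]),
            k = as.integer(k), class = c("kmer_histogram", "data.frame"))
}

#' Read / write a k-mer histogram in the 2-column histo dialect
#'
#' The format is the plain `depth<TAB>count` (or space-separated) table that
#' k-mer counters emit as their histogram output.
#'
#' @param path file path.
#' @param k k-mer length to record on the object (default 17).
#' @return [read_kmer_histogram()] returns a [kmer_histogram()];
#'   [write_kmer_histogram()] returns `path` invisibly.
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("depth", "count"))
  kmer_histogram(tab$depth, tab$count, k = k)
}

#' @rdname read_kmer_histogram
#' @param hist a [kmer_histogram()].
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(as.data.frame(hist)[, c("depth", "count")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Total number of k-mer instances
#'
#' `sum(depth * count)` over the histogram: the number of k-mer occurrences
#' in the read set (the numerator of the genome-size formula).
#'
#' @param hist a [kmer_histogram()].
#' @return a (double) count.
#' @export
total_kmers <- function(hist) {
  stopifnot(inherits(hist, "kmer_histogram"))
  sum(as.numeric(hist$depth) * hist$count)
}

#' Depth at the k-mer peak
#'
#' The depth with the largest distinct-k-mer count among depths
#' `>= min_depth`; ties break toward the smaller depth.  The cutoff excludes
#' the error peak near depth 1.
#'
#' @param hist a [kmer_histogram()].
#' @param min_depth smallest depth eligible to be the peak (default 4).
#' @return integer peak depth.
#' @export
find_peak_depth <- function(hist, min_depth = 4L) {
  stopifnot(inherits(hist, "kmer_histogram"), min_depth >= 1)
  h <- hist[hist$depth >= min_depth & hist$count > 0, , drop = FALSE]
  if (nrow(h) == 0L)
    stop("no k-mers at depth >= ", min_depth)
  h$depth[which.max(h$count)]   # which.max takes the first (smallest depth) tie
}

#' Estimate genome size from a k-mer histogram
#'
#' Total k-mer instances divided by the depth at the k-mer peak.  The
#' `min_depth` cutoff that excludes the sequencing-error peak from the peak
#' search is applied to the numerator as well, so putative error k-mers
#' (depth < `min_depth`) do not inflate the estimate.
#'
#' @inheritParams find_peak_depth
#' @return estimated genome size in bases (double).
#' @export
estimate_genome_size <- function(hist, min_depth = 4L) {
  peak <- find_peak_depth(hist, min_depth)
  h <- hist[hist$depth >= min_depth, , drop = FALSE]
  sum(as.numeric(h$depth) * h$count) / peak
}
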