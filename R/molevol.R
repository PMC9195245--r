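# 4DTv: the proportion of fourfold-degenerate third codon positions that
# differ by a transversion between two codon-aligned coding sequences.
# Being restricted to transversions at neutral sites makes the statistic
# saturate slowly, which is why it is used to date duplication and
# speciation events.

# Codon prefixes whose third position is fourfold degenerate under the
# standard genetic code.
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Is a codon fourfold degenerate?
#'
#' TRUE when the codon's third position is free under the standard genetic
#' code, i.e. its first two bases are one of CT, GT, TC, CC, AC, GC, CG,
#' GG.  Codons containing gaps or ambiguity codes are FALSE.
#'
#' @param codon character vector of 3-letter codons.
#' @return logical vector.
#' @export
is_fourfold_degenerate <- function(codon) {
  codon <- toupper(codon)
  valid <- nchar(codon) == 3L & !grepl("[^ACGT]", codon)
  valid & substr(codon, 1, 2) %in% FOURFOLD_PREFIXES
}

#' Is a base change a transversion?
#'
#' A purine/pyrimidine exchange (`{A,G}` vs `{C,T}`).
#'
#' @param a,b single-base character vectors.
#' @return logical vector (FALSE for identical bases or transitions).
#' @export
is_transversion <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  (a %in% PURINES & b %in% PYRIMIDINES) |
    (a %in% PYRIMIDINES & b %in% PURINES)
}

# Split an aligned CDS into codons; error when the frame is broken.
.codons <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) %% 3L != 0L)
    stop("aligned sequence length must be a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' 4DTv of one codon-aligned sequence pair
#'
#' A third position counts as a usable fourfold-degenerate (4D) site iff
#' both codons are 4D, their first two positions are identical, and neither
#' codon contains a gap or ambiguity code.  The statistic is the number of
#' transversional differences at those sites divided by the number of
#' sites; no multiple-substitution correction is applied.
#'
#' @param seq_a,seq_b aligned coding sequences of equal length divisible by
#'   3 (gaps as `-`).
#' @return list of class `four_dtv` with `n_4d_sites`, `n_transversions`
#'   and `value` (`NA` when no 4D site exists).
#' @export
four_dtv <- function(seq_a, seq_b) {
  ca <- .codons(seq_a)
  cb <- .codons(seq_b)
  if (length(ca) != length(cb))
    stop("aligned sequences must have equal length")
  usable <- is_fourfold_degenerate(ca) & is_fourfold_degenerate(cb) &
    substr(ca, 1, 2) == substr(cb, 1, 2)
  third_a <- substr(ca[usable], 3, 3)
  third_b <- substr(cb[usable], 3, 3)
  n4d <- sum(usable)
  ntv <- sum(is_transversion(third_a, third_b))
  structure(list(n_4d_sites = n4d, n_transversions = ntv,
                 value = if (n4d > 0) ntv / n4d else NA_real_),
            class = "four_dtv")
}

#' @export
print.four_dtv <- function(x, ...) {
  cat(sprintf("4DTv: %d transversions / %d fourfold-degenerate sites = %s\n",
              x$n_transversions, x$n_4d_sites,
              if (is.na(x$value)) "NA" else format(x$value)))
  invisible(x)
}

#' Pooled 4DTv over the gene pairs of one syntenic block
#'
#' The block value is the ratio of pooled sums — total transversions over
#' total 4D sites across all pairs — not the mean of per-pair values.
#'
#' @param pairs a list whose elements are either `four_dtv` results or
#'   alignments given as `list(a =, b =)` / length-2 character vectors.
#' @return a `four_dtv` object for the pooled block.
#' @export
block_four_dtv <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  results <- lapply(pairs, function(p) {
    if (inherits(p, "four_dtv")) return(p)
    if (is.list(p)) four_dtv(p[["a"]] %||% p[[1]], p[["b"]] %||% p[[2]])
    else four_dtv(p[1], p[2])
  })
  n4d <- sum(vapply(results, `[[`, numeric(1), "n_4d_sites"))
  ntv <- sum(vapply(results, `[[`, numeric(1), "n_transversions"))
  structure(list(n_4d_sites = n4d, n_transversions = ntv,
                 value = if (n4d > 0) ntv / n4d else NA_real_),
            class = "four_dtv")
}

#' 4DTv for paired CDS FASTA files
#'
#' Reads two FASTA files with matching sequence ids (each id pair is one
#' pre-aligned gene pair) and computes per-pair 4DTv plus the pooled value;
#' with a block map, per-block pooled values instead.
#'
#' @param path_a,path_b FASTA files; ids present in both files are used.
#' @param blocks optional data.frame (`block`, `gene_id`) assigning pairs
#'   to syntenic blocks.
#' @return list with `per_pair` (data.frame `gene_id`, `n_4d_sites`,
#'   `n_transversions`, `value`) and `pooled` (a `four_dtv`, or a data.frame
#'   per block when `blocks` is given).
#' @export
four_dtv_files <- function(path_a, path_b, blocks = NULL) {
  a <- Biostrings::readDNAStringSet(path_a)
  b <- Biostrings::readDNAStringSet(path_b)
  ids <- intersect(names(a), names(b))
  if (!length(ids)) stop("no shared sequence ids between the two FASTA files")
  res <- lapply(ids, function(id)
    four_dtv(as.character(a[[id]]), as.character(b[[id]])))
  per_pair <- data.frame(
    gene_id = ids,
    n_4d_sites = vapply(res, `[[`, numeric(1), "n_4d_sites"),
    n_transversions = vapply(res, `[[`, numeric(1), "n_transversions"),
    value = vapply(res, `[[`, numeric(1), "value"))
  if (is.null(blocks))
    return(list(per_pair = per_pair, pooled = block_four_dtv(res)))
  bl <- split(res[match(blocks$gene_id, ids)], blocks$block)
  pooled <- do.call(rbind, lapply(names(bl), function(bid) {
    p <- block_four_dtv(bl[[bid]])
    data.frame(block = bid, n_4d_sites = p$n_4d_sites,
               n_transversions = p$n_transversions, value = p$value)
  }))
  list(per_pair = per_pair, pooled = pooled)
}
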