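# Delta-SNP-index bulked segregant analysis (QTL-seq style).
#
# Informative markers are sites where the two parents are homozygous for
# different alleles.  The SNP index of a pool at a marker is the fraction
# of its reads carrying the donor (resistant-parent) allele; the contrast
# delta = index_res - index_sus peaks near the causal locus, at +0.5 for a
# dominant donor allele in a BC1 design.

#' Select informative (parent-homozygous, parent-different) SNPs
#'
#' Keeps sites where both parents are homozygous and for different alleles,
#' recording which allele (ref or alt) came from the donor (resistant)
#' parent.
#'
#' @param vs a [variant_set()] containing both parent samples.
#' @param res_parent,sus_parent sample ids of the resistant (donor) and
#'   susceptible (recurrent) parent.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `donor_is_alt` (logical), `donor_allele` (base string).
#' @export
select_informative_snps <- function(vs, res_parent, sus_parent) {
  stopifnot(all(c(res_parent, sus_parent) %in% vs_samples(vs)))
  g_res <- vs$gt[, res_parent]
  g_sus <- vs$gt[, sus_parent]
  keep <- !is.na(g_res) & !is.na(g_sus) &
    g_res %in% c(0L, 2L) & g_sus %in% c(0L, 2L) & g_res != g_sus
  out <- vs$sites[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out$donor_is_alt <- g_res[keep] == 2L
  out$donor_allele <- ifelse(out$donor_is_alt, out$alt, out$ref)
  rownames(out) <- NULL
  out
}

#' Pooled donor/other read counts at informative markers
#'
#' Extracts the allele-depth (`AD`) counts of the two phenotype pools at the
#' informative markers and orients them so that the first count of each pair
#' is the donor allele.  Pools sequenced as several libraries may be given
#' as multiple sample ids; their depths are summed.
#'
#' @param vs a [variant_set()] read with `AD` depths present.
#' @param informative marker table from [select_informative_snps()].
#' @param res_pool,sus_pool sample id(s) of the resistant and susceptible
#'   pool.
#' @return data.frame (`chrom`, `pos`, `donor_res`, `other_res`,
#'   `donor_sus`, `other_sus`).
#' @export
pool_allele_counts <- function(vs, informative, res_pool, sus_pool) {
  if (is.null(vs$ad_ref) || is.null(vs$ad_alt))
    stop("variant set has no AD allele depths")
  stopifnot(all(c(res_pool, sus_pool) %in% vs_samples(vs)))
  key <- paste(vs$sites$chrom, vs$sites$pos)
  idx <- match(paste(informative$chrom, informative$pos), key)
  if (anyNA(idx)) stop("informative markers missing from variant set")
  pool_counts <- function(samples, mat)
    rowSums(mat[idx, samples, drop = FALSE], na.rm = TRUE)
  ref_res <- pool_counts(res_pool, vs$ad_ref)
  alt_res <- pool_counts(res_pool, vs$ad_alt)
  ref_sus <- pool_counts(sus_pool, vs$ad_ref)
  alt_sus <- pool_counts(sus_pool, vs$ad_alt)
  d <- informative$donor_is_alt
  data.frame(chrom = informative$chrom, pos = informative$pos,
             donor_res = ifelse(d, alt_res, ref_res),
             other_res = ifelse(d, ref_res, alt_res),
             donor_sus = ifelse(d, alt_sus, ref_sus),
             other_sus = ifelse(d, ref_sus, alt_sus))
}

#' SNP index of a pool at a marker
#'
#' The fraction of pooled reads carrying the donor allele:
#' `donor / (donor + other)`.  Undefined (NA) when total depth is zero.
#'
#' @param donor_count,other_count read counts (vectorized).
#' @return numeric in `[0, 1]`, `NA` where depth is zero.
#' @export
snp_index <- function(donor_count, other_count) {
  tot <- donor_count + other_count
  ifelse(tot > 0, donor_count / tot, NA_real_)
}

#' Delta SNP index
#'
#' The between-pool contrast `index_res - index_sus`, referenced to the
#' donor (resistant-parent) allele so that a resistance locus gives a
#' positive delta.
#'
#' @param index_res,index_sus pool SNP indices (vectorized).
#' @return numeric in `[-1, 1]`.
#' @export
delta_snp_index <- function(index_res, index_sus) index_res - index_sus

#' Per-marker SNP-index table
#'
#' Computes both pool indices and their delta, dropping markers where either
#' pool has zero depth (undefined index).
#'
#' @param pool_sites counts from [pool_allele_counts()] (or the simulator).
#' @return data.frame (`chrom`, `pos`, `index_res`, `index_sus`, `delta`).
#' @export
snp_index_table <- function(pool_sites) {
  ir <- snp_index(pool_sites$donor_res, pool_sites$other_res)
  is_ <- snp_index(pool_sites$donor_sus, pool_sites$other_sus)
  ok <- !is.na(ir) & !is.na(is_)
  data.frame(chrom = pool_sites$chrom[ok], pos = pool_sites$pos[ok],
             index_res = ir[ok], index_sus = is_[ok],
             delta = delta_snp_index(ir[ok], is_[ok]))
}

#' Filter loci by pool SNP indices
#'
#' Default rule (`"both"`): a locus is removed iff its SNP index is below
#' `low` in both pools or above `high` in both pools — i.e. loci that are
#' jointly near-monomorphic in the two pools and carry no segregation
#' signal.  The alternative parse (`"either"`) removes a locus if either
#' pool's index leaves `[low, high]`.  Boundary values are kept (strict
#' inequalities).  Idempotent.
#'
#' @param records SNP-index table from [snp_index_table()].
#' @param low,high index thresholds (defaults 0.3 and 0.7).
#' @param rule `"both"` (default) or `"either"`.
#' @return the surviving rows of `records`.
#' @export
filter_by_index <- function(records, low = 0.3, high = 0.7,
                            rule = c("both", "either")) {
  rule <- match.arg(rule)
  ir <- records$index_res
  is_ <- records$index_sus
  drop <- if (rule == "both")
    (ir < low & is_ < low) | (ir > high & is_ > high)
  else
    ir < low | ir > high | is_ < low | is_ > high
  records[!drop, , drop = FALSE]
}

#' Sliding-window mean of delta SNP index
#'
#' Windows are laid on the grid of [window_starts()]; each window's value is
#' the mean delta over markers it contains.  Windows with no markers are
#' kept with `mean_delta = NA`.
#'
#' @param records SNP-index table (sorted by chrom, pos).
#' @param window_size,step window width and step in bp (defaults 1 Mb and
#'   100 kb).
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   defaults to the last marker position per chromosome.
#' @return data.frame (`chrom`, `start`, `end`, `n_snps`, `mean_delta`).
#' @export
window_delta <- function(records, window_size = 1e6, step = 1e5,
                         chrom_lengths = NULL) {
  stopifnot(window_size >= step, step >= 1)
  chroms <- unique(records$chrom)
  out <- lapply(chroms, function(ch) {
    r <- records[records$chrom == ch, , drop = FALSE]
    L <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(r$pos)
    starts <- window_starts(L, window_size, step)
    if (!length(starts)) return(NULL)
    map <- site_window_pairs(r$pos, window_size, step, length(starts))
    n <- tabulate(map$win, nbins = length(starts))
    s <- rep(0, length(starts))
    if (length(map$site)) {
      agg <- tapply(r$delta[map$site], map$win, sum)
      s[as.integer(names(agg))] <- agg
    }
    data.frame(chrom = ch, start = starts,
               end = starts + window_size - 1,
               n_snps = n,
               mean_delta = ifelse(n > 0, s / n, NA_real_))
  })
  do.call(rbind, out)
}

#' Call the BSA candidate region
#'
#' Thresholds windows on `|mean delta|` (default: the genome-wide 95th
#' percentile over non-empty windows) and reports the contiguous run of
#' super-threshold windows containing the most extreme window, together with
#' that peak window.  Ties break toward the smaller coordinate.
#'
#' @param windows window table from [window_delta()].
#' @param threshold absolute-delta threshold; when `NULL` (default) the
#'   `quantile` of `|mean_delta|` over non-empty windows is used.
#' @param quantile quantile used for the automatic threshold (default 0.95).
#' @return list with `region` (data.frame `chrom`, `start`, `end`, or `NULL`
#'   when no window passes), `peak` (the most significant window row, or
#'   `NULL`), and `threshold`.
#' @export
call_candidate_region <- function(windows, threshold = NULL, quantile = 0.95) {
  w <- windows[!is.na(windows$mean_delta), , drop = FALSE]
  if (nrow(w) == 0L) stop("no non-empty windows")
  if (is.null(threshold))
    threshold <- stats::quantile(abs(w$mean_delta), quantile, names = FALSE)
  pass <- abs(w$mean_delta) > threshold
  if (!any(pass))
    return(list(region = NULL, peak = NULL, threshold = threshold))
  peak_i <- which(abs(w$mean_delta) == max(abs(w$mean_delta)))[1]
  # contiguous run of passing windows (same chromosome, adjacent on the
  # step grid) around the peak
  step <- if (nrow(w) > 1) min(diff(sort(unique(w$start)))) else w$end[1] - w$start[1] + 1
  run_lo <- peak_i
  while (run_lo > 1 && pass[run_lo - 1] &&
         w$chrom[run_lo - 1] == w$chrom[run_lo] &&
         w$start[run_lo] - w$start[run_lo - 1] <= step)
    run_lo <- run_lo - 1
  run_hi <- peak_i
  while (run_hi < nrow(w) && pass[run_hi + 1] &&
         w$chrom[run_hi + 1] == w$chrom[run_hi] &&
         w$start[run_hi + 1] - w$start[run_hi] <= step)
    run_hi <- run_hi + 1
  list(region = data.frame(chrom = w$chrom[peak_i],
                           start = w$start[run_lo],
                           end = w$end[run_hi]),
       peak = w[peak_i, , drop = FALSE],
       threshold = threshold)
}

#' Run the full BSA stage
#'
#' Convenience wrapper: informative-marker selection, pooled SNP indices,
#' the 0.3/0.7 both-pools filter, window means and the candidate-region
#' call.
#'
#' @param vs a [variant_set()] holding parents and pools with `AD` depths.
#' @param res_parent,sus_parent,res_pool,sus_pool sample ids.
#' @param window_size,step see [window_delta()].
#' @param chrom_lengths optional named chromosome lengths.
#' @param ... passed to [call_candidate_region()].
#' @return list with `informative`, `records` (filtered SNP-index table),
#'   `windows` and `call`.
#' @export
run_bsa <- function(vs, res_parent, sus_parent, res_pool, sus_pool,
                    window_size = 1e6, step = 1e5, chrom_lengths = NULL, ...) {
  informative <- select_informative_snps(vs, res_parent, sus_parent)
  counts <- pool_allele_counts(vs, informative, res_pool, sus_pool)
  records <- filter_by_index(snp_index_table(counts))
  windows <- window_delta(records, window_size, step, chrom_lengths)
  list(informative = informative, records = records, windows = windows,
       call = call_candidate_region(windows, ...))
}
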