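# Windowed two-group selective-sweep scan: nucleotide diversity (pi) per
# group, Tajima's D per group, and Hudson's Fst between groups, computed in
# 50-kb windows sliding by 10 kb (defaults), followed by top-5% selection
# and merging of selected windows into sweep regions.
#
# Per-site quantities, for a group with allele sample size n (= 2 x
# non-missing samples) and alt-allele frequency p:
#   unbiased heterozygosity  2 p (1-p) n / (n-1)      (theta_pi contribution)
#   Hudson Fst numerator     (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)
#   Hudson Fst denominator   p1(1-p2) + p2(1-p1)
# The window Fst is the ratio of sums (not the mean of ratios).

#' Construct a genotype matrix
#'
#' @param geno integer matrix (sites x samples) of alt-allele dosages in
#'   `{0, 1, 2}`, `NA` = missing.  Column names are sample ids.
#' @param chrom,pos site coordinates (1-based); positions must be strictly
#'   increasing within a chromosome.
#' @return object of class `genotype_matrix`: list with `geno` and a
#'   `sites` data.frame.
#' @export
genotype_matrix <- function(geno, chrom, pos) {
  geno <- as.matrix(geno)
  stopifnot(length(chrom) == nrow(geno), length(pos) == nrow(geno))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("S%03d", seq_len(ncol(geno)))
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (anyDuplicated(rle(chrom)$values)) stop("chromosome blocks must be contiguous")
  ok <- unlist(lapply(split(pos, factor(chrom, unique(chrom))),
                      function(p) length(p) < 2L || all(diff(p) > 0)))
  if (!all(ok)) stop("positions must be strictly increasing within chromosome")
  structure(list(geno = geno,
                 sites = data.frame(chrom = chrom, pos = pos)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples\n",
              nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

#' Convert a variant set to a genotype matrix
#'
#' @param vs a [variant_set()].
#' @return a [genotype_matrix()].
#' @export
as_genotype_matrix <- function(vs) {
  genotype_matrix(vs$gt, vs$sites$chrom, vs$sites$pos)
}

#' Two-group sample assignment
#'
#' @param sample_ids character vector of sample ids.
#' @param group character vector (same length) with values `"high"` and
#'   `"low"`; both groups must be non-empty.
#' @return named factor (levels `high`, `low`).
#' @export
group_assignment <- function(sample_ids, group) {
  stopifnot(length(sample_ids) == length(group))
  g <- factor(as.character(group), levels = c("high", "low"))
  if (anyNA(g)) stop("groups must be 'high' or 'low'")
  if (any(table(g) == 0L)) stop("both groups must be non-empty")
  stats::setNames(g, sample_ids)
}

#' Read a sample-to-group table
#'
#' Two-column TSV (`sample`, `group`) without header, groups coded
#' `high`/`low`.
#'
#' @param path file path.
#' @return named factor as from [group_assignment()].
#' @export
read_groups <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("sample", "group"),
                           colClasses = "character")
  group_assignment(tab$sample, tab$group)
}

#' Per-site allele frequency within a sample subset
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids (or indices) forming the group.
#' @return data.frame with per-site `p` (alt-allele frequency; `NA` when no
#'   sample is genotyped) and `n` (allele sample size, 2 x non-missing
#'   samples).
#' @export
site_allele_freq <- function(gm, samples) {
  g <- gm$geno[, samples, drop = FALSE]
  if (ncol(g) == 0L) stop("empty group")
  n <- 2L * rowSums(!is.na(g))
  p <- ifelse(n > 0, rowSums(g, na.rm = TRUE) / n, NA_real_)
  data.frame(p = p, n = n)
}

# Per-site unbiased heterozygosity 2p(1-p)n/(n-1); NA when n < 2.
.site_het <- function(p, n) ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)

#' Tajima's D normalizing constants
#'
#' The standard constants `a1, a2, b1, b2, c1, c2, e1, e2` for allele sample
#' size `n`.
#'
#' @param n allele sample size (>= 2; D itself needs n >= 4).
#' @return named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# Tajima's D from per-site (p, n) of one window.  Missing data makes n vary
# across sites while the variance formula assumes it fixed, so the modal n
# is used and sites deviating from it by more than n_dev are dropped from
# the D computation.  Returns NA when no segregating site remains or the
# modal n is < 4.
.tajima_d_from_sites <- function(p, n, n_dev = 0.2) {
  ok <- !is.na(p) & n >= 2
  p <- p[ok]; n <- n[ok]
  if (!length(p)) return(NA_real_)
  tab <- tabulate(n)
  n_modal <- which.max(tab)            # smallest mode on ties
  keep <- abs(n - n_modal) <= n_dev * n_modal
  p <- p[keep]; n <- n[keep]
  if (n_modal < 4) return(NA_real_)
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S < 1) return(NA_real_)
  theta_pi <- sum(.site_het(p, n))
  k <- tajima_constants(n_modal)
  theta_w <- S / k$a1
  (theta_pi - theta_w) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Windowed nucleotide diversity
#'
#' Per-bp pi of a sample group over one window: the sum of per-site
#' unbiased heterozygosities divided by the full window length.
#' Monomorphic, absent and fully missing positions contribute 0.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids forming the group.
#' @param chrom,start,end window coordinates (1-based inclusive).
#' @return per-bp diversity (numeric).
#' @export
window_pi <- function(gm, samples, chrom, start, end) {
  stopifnot(end >= start)
  in_w <- gm$sites$chrom == chrom & gm$sites$pos >= start & gm$sites$pos <= end
  if (!any(in_w)) return(0)
  af <- site_allele_freq(gm, samples)
  sum(.site_het(af$p[in_w], af$n[in_w]), na.rm = TRUE) / (end - start + 1)
}

#' Tajima's D of one window
#'
#' @inheritParams window_pi
#' @param n_dev tolerated relative deviation of a site's allele sample size
#'   from the window's modal value (default 0.2); deviating sites are
#'   excluded because the variance constants assume fixed n.
#' @return Tajima's D, or `NA` if the window has no segregating site or the
#'   modal allele sample size is below 4.
#' @export
tajimas_d <- function(gm, samples, chrom, start, end, n_dev = 0.2) {
  in_w <- gm$sites$chrom == chrom & gm$sites$pos >= start & gm$sites$pos <= end
  af <- site_allele_freq(gm, samples)
  .tajima_d_from_sites(af$p[in_w], af$n[in_w], n_dev)
}

#' Hudson's Fst of one window (ratio of sums)
#'
#' @inheritParams window_pi
#' @param groups named factor from [group_assignment()].
#' @return the window Fst, or `NA` when the denominator sum is zero or no
#'   site has both groups genotyped twice.
#' @export
hudson_fst <- function(gm, groups, chrom, start, end) {
  in_w <- gm$sites$chrom == chrom & gm$sites$pos >= start & gm$sites$pos <= end
  hi <- names(groups)[groups == "high"]
  lo <- names(groups)[groups == "low"]
  a1 <- site_allele_freq(gm, hi)[in_w, ]
  a2 <- site_allele_freq(gm, lo)[in_w, ]
  cmp <- .hudson_components(a1$p, a1$n, a2$p, a2$n)
  den <- sum(cmp$D, na.rm = TRUE)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  sum(cmp$N, na.rm = TRUE) / den
}

# Per-site Hudson numerator/denominator; NA when either group has n < 2.
.hudson_components <- function(p1, n1, p2, n2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  N <- ifelse(ok,
              (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1),
              NA_real_)
  D <- ifelse(ok, p1 * (1 - p2) + p2 * (1 - p1), NA_real_)
  list(N = N, D = D)
}

#' Scan the genome in sliding windows
#'
#' Computes, for every grid window (width `window_size`, step `step`, fully
#' inside the chromosome): the number of sites, per-bp pi in each group,
#' their ratio `pi_high/pi_low`, per-group Tajima's D and Hudson's Fst.
#'
#' @param gm a [genotype_matrix()].
#' @param groups named factor from [group_assignment()].
#' @param window_size,step window width and step in bp (defaults 50 kb and
#'   10 kb).
#' @param chrom_lengths optional named chromosome lengths; default last site
#'   position per chromosome.
#' @param n_dev see [tajimas_d()].
#' @return data.frame with one row per window: `chrom`, `start`, `end`,
#'   `n_sites`, `pi_high`, `pi_low`, `pi_ratio`, `d_high`, `d_low`, `fst`.
#' @export
scan_windows <- function(gm, groups, window_size = 50000, step = 10000,
                         chrom_lengths = NULL, n_dev = 0.2) {
  stopifnot(window_size >= step, step >= 1)
  hi <- names(groups)[groups == "high"]
  lo <- names(groups)[groups == "low"]
  af_hi <- site_allele_freq(gm, hi)
  af_lo <- site_allele_freq(gm, lo)
  het_hi <- .site_het(af_hi$p, af_hi$n)
  het_lo <- .site_het(af_lo$p, af_lo$n)
  cmp <- .hudson_components(af_hi$p, af_hi$n, af_lo$p, af_lo$n)

  chroms <- unique(gm$sites$chrom)
  res <- lapply(chroms, function(ch) {
    rows <- which(gm$sites$chrom == ch)
    L <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(gm$sites$pos[rows])
    starts <- window_starts(L, window_size, step)
    if (!length(starts)) return(NULL)
    map <- site_window_pairs(gm$sites$pos[rows], window_size, step,
                             length(starts))
    dt <- data.table::data.table(
      win = map$win,
      site = rows[map$site])
    dt[, `:=`(het_hi = het_hi[site], het_lo = het_lo[site],
              N = cmp$N[site], D = cmp$D[site],
              p_hi = af_hi$p[site], n_hi = af_hi$n[site],
              p_lo = af_lo$p[site], n_lo = af_lo$n[site])]
    agg <- dt[, {
      den <- sum(D, na.rm = TRUE)
      list(n_sites = .N,
           pi_high = sum(het_hi, na.rm = TRUE) / window_size,
           pi_low = sum(het_lo, na.rm = TRUE) / window_size,
           d_high = .tajima_d_from_sites(p_hi, n_hi, n_dev),
           d_low = .tajima_d_from_sites(p_lo, n_lo, n_dev),
           fst = if (is.finite(den) && den > 0)
             sum(N, na.rm = TRUE) / den else NA_real_)
    }, by = win]
    out <- data.frame(chrom = ch, start = starts,
                      end = starts + window_size - 1,
                      n_sites = 0L, pi_high = 0, pi_low = 0,
                      d_high = NA_real_, d_low = NA_real_, fst = NA_real_)
    out[agg$win, c("n_sites", "pi_high", "pi_low", "d_high", "d_low", "fst")] <-
      agg[, c("n_sites", "pi_high", "pi_low", "d_high", "d_low", "fst")]
    out
  })
  out <- do.call(rbind, res)
  out$pi_ratio <- ifelse(out$pi_low > 0, out$pi_high / out$pi_low, NA_real_)
  out[, c("chrom", "start", "end", "n_sites", "pi_high", "pi_low",
          "pi_ratio", "d_high", "d_low", "fst")]
}

#' Select candidate sweep windows by empirical quantiles
#'
#' Marks windows in the extreme `q` tail of each statistic: the smallest
#' `pi_ratio` values (strongest diversity reduction in the high group, when
#' `pi_direction = "low"`), the largest `fst` values, and the most negative
#' `d_high - d_low` differences.  Ties at the quantile are included, so
#' slightly more than `q` of windows can be marked.
#'
#' @param stats window table from [scan_windows()].
#' @param q tail fraction (default 0.05).
#' @param mode how the three criteria combine into the final selection:
#'   `"intersection"` (default), `"union"` or `"any-two"`.
#' @param pi_direction `"low"` (default) or `"high"` tail of the pi ratio.
#' @return `stats` with logical columns `sel_pi`, `sel_fst`, `sel_d` and
#'   `selected`, plus a `thresholds` attribute.
#' @export
select_sweep_windows <- function(stats, q = 0.05,
                                 mode = c("intersection", "union", "any-two"),
                                 pi_direction = c("low", "high")) {
  mode <- match.arg(mode)
  pi_direction <- match.arg(pi_direction)
  stopifnot(q > 0, q <= 1)
  d_diff <- stats$d_high - stats$d_low
  for (v in list(stats$pi_ratio, stats$fst, d_diff))
    if (sum(!is.na(v)) < 20L)
      stop("fewer than 20 windows with defined statistics; quantiles unreliable")
  thr_pi <- stats::quantile(stats$pi_ratio,
                            if (pi_direction == "low") q else 1 - q,
                            na.rm = TRUE, names = FALSE)
  thr_fst <- stats::quantile(stats$fst, 1 - q, na.rm = TRUE, names = FALSE)
  thr_d <- stats::quantile(d_diff, q, na.rm = TRUE, names = FALSE)
  stats$sel_pi <- !is.na(stats$pi_ratio) &
    (if (pi_direction == "low") stats$pi_ratio <= thr_pi
     else stats$pi_ratio >= thr_pi)
  stats$sel_fst <- !is.na(stats$fst) & stats$fst >= thr_fst
  stats$sel_d <- !is.na(d_diff) & d_diff <= thr_d
  k <- stats$sel_pi + stats$sel_fst + stats$sel_d
  stats$selected <- switch(mode,
                           intersection = k == 3L,
                           union = k >= 1L,
                           `any-two` = k >= 2L)
  attr(stats, "thresholds") <- c(pi_ratio = thr_pi, fst = thr_fst,
                                 d_diff = thr_d)
  stats
}

#' Merge selected windows into sweep regions and attach genes
#'
#' Overlapping or abutting selected windows are merged into maximal
#' intervals; genes overlapping a region by at least 1 bp are attached.
#'
#' @param selected window table (only rows with `selected == TRUE` are used
#'   when that column is present; otherwise all rows are merged).
#' @param gene_models optional gene-model data.frame
#'   ([read_gene_models()]).
#' @return list with `regions` (data.frame `chrom`, `start`, `end`,
#'   `n_genes` and list-column `genes`), `total_span` (bp) and `n_genes`
#'   (distinct genes across regions).
#' @export
merge_and_annotate <- function(selected, gene_models = NULL) {
  if (!is.null(selected$selected))
    selected <- selected[selected$selected, , drop = FALSE]
  if (nrow(selected) == 0L)
    return(list(regions = data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), n_genes = integer(0)),
                total_span = 0, n_genes = 0L))
  gr <- GenomicRanges::GRanges(selected$chrom,
                               IRanges::IRanges(selected$start, selected$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  regions <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                        start = GenomicRanges::start(merged),
                        end = GenomicRanges::end(merged))
  gene_sets <- rep(list(character(0)), nrow(regions))
  if (!is.null(gene_models) && nrow(gene_models) > 0) {
    gg <- GenomicRanges::GRanges(gene_models$chrom,
                                 IRanges::IRanges(gene_models$start,
                                                  gene_models$end))
    ov <- GenomicRanges::findOverlaps(merged, gg)
    hits <- split(gene_models$gene_id[S4Vectors::subjectHits(ov)],
                  factor(S4Vectors::queryHits(ov), seq_len(nrow(regions))))
    gene_sets <- lapply(hits, unique)
  }
  regions$n_genes <- lengths(gene_sets)
  regions$genes <- I(unname(gene_sets))
  list(regions = regions,
       total_span = sum(regions$end - regions$start + 1),
       n_genes = length(unique(unlist(gene_sets))))
}
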