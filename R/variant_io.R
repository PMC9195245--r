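# Variant input/output and population-level SNP quality filtering.
#
# The central container is the `variant_set`: a site table (chrom, pos, ref,
# alt, site mapping quality) plus per-sample matrices of alt-allele dosage
# (0/1/2, NA = missing), read depth, genotype quality and, when the VCF
# carries an AD field, ref/alt allele depths.  All coordinates are 1-based
# inclusive; BED input/output converts at the boundary.

#' Construct a variant set
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single alternate allele) and optionally `mq` (site mapping
#'   quality, Phred; `NA` if unknown).
#' @param gt integer matrix (sites x samples) of alt-allele dosages in
#'   `{0, 1, 2}`; `NA` marks a missing genotype.  Column names are sample
#'   ids.
#' @param dp,gq optional numeric matrices (same shape) of per-sample read
#'   depth and Phred genotype quality.
#' @param ad_ref,ad_alt optional numeric matrices of per-sample ref/alt
#'   allele read depths (VCF `AD` field).
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sites, gt, dp = NULL, gq = NULL,
                        ad_ref = NULL, ad_alt = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (is.null(sites$mq)) sites$mq <- NA_real_
  sites <- sites[, c("chrom", "pos", "ref", "alt", "mq")]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  gt <- as.matrix(gt)
  n <- nrow(sites)
  if (nrow(gt) != n) stop("genotype matrix and site table disagree in length")
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  bad <- !is.na(gt) & !(gt %in% 0:2)
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  # sites must ascend within chromosome, chromosomes in contiguous runs
  r <- rle(sites$chrom)
  if (anyDuplicated(r$values)) stop("chromosome blocks must be contiguous")
  ord_ok <- unlist(lapply(split(sites$pos, factor(sites$chrom, unique(sites$chrom))),
                          function(p) length(p) < 2L || all(diff(p) >= 0)))
  if (!all(ord_ok)) stop("sites must be sorted by position within chromosome")
  for (m in list(dp, gq, ad_ref, ad_alt))
    if (!is.null(m) && !all(dim(as.matrix(m)) == dim(gt)))
      stop("all per-sample matrices must have the same dimensions")
  structure(list(sites = sites, gt = gt,
                 dp = if (!is.null(dp)) as.matrix(dp),
                 gq = if (!is.null(gq)) as.matrix(gq),
                 ad_ref = if (!is.null(ad_ref)) as.matrix(ad_ref),
                 ad_alt = if (!is.null(ad_alt)) as.matrix(ad_alt)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples (%s)\n",
              n_sites(x), n_samples(x),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' Number of sites / samples in a variant set
#' @param x a `variant_set`.
#' @return integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) ncol(x$gt)

#' Sample ids of a variant set
#' @param x a `variant_set`.
#' @return character vector.
#' @export
vs_samples <- function(x) colnames(x$gt)

#' Subset a variant set by site and/or sample
#'
#' @param x a `variant_set`.
#' @param i site index (logical or integer).
#' @param j sample index (logical, integer or character).
#' @param ... ignored.
#' @return a `variant_set`.
#' @export
`[.variant_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_sites(x))
  if (missing(j)) j <- seq_len(n_samples(x))
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  variant_set(x$sites[i, , drop = FALSE], x$gt[i, j, drop = FALSE],
              dp = sub(x$dp), gq = sub(x$gq),
              ad_ref = sub(x$ad_ref), ad_alt = sub(x$ad_alt))
}

# "0/1"-style genotype strings -> dosage of a given alt allele index.
gt_string_to_dosage <- function(gt, allele = 1L) {
  al <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  vapply(al, function(a) {
    if (length(a) == 0L || any(is.na(a)) || any(a == ".")) return(NA_integer_)
    sum(a == as.character(allele))
  }, integer(1))
}

#' Read a VCF file into a variant set
#'
#' Reads VCF 4.x (optionally gzip-compressed) via \pkg{vcfR}.  Multi-allelic
#' records are skipped (default) or split into one biallelic record per
#' alternate allele.  Per-sample `DP`, `GQ` and `AD` fields and the site
#' `INFO/MQ` mapping quality are carried along when present.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file with records sorted by
#'   (chrom, pos); unsorted input is an error.
#' @param samples optional character vector restricting the sample columns.
#' @param multiallelic `"skip"` (drop sites with more than one alternate
#'   allele; default, since downstream statistics assume biallelic sites) or
#'   `"split"` (emit one record per alternate allele, dosage counted against
#'   that allele).
#' @return a [variant_set()].
#' @export
read_vcf <- function(path, samples = NULL,
                     multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF: ", conditionMessage(e),
                                         call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0L || ncol(v@gt) < 2L) stop("VCF has no sample columns")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ord_ok <- unlist(lapply(split(pos, factor(chrom, unique(chrom))),
                          function(p) length(p) < 2L || all(diff(p) >= 0)))
  if (!all(ord_ok) || anyDuplicated(rle(chrom)$values))
    stop("VCF records are not sorted by (chrom, pos)")
  mq <- suppressWarnings(vcfR::extract.info(v, "MQ", as.numeric = TRUE))
  if (is.null(mq)) mq <- rep(NA_real_, nrow(fix))
  gt_str <- vcfR::extract.gt(v, "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE))
  ad <- suppressWarnings(vcfR::extract.gt(v, "AD"))
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt_str))
    if (length(missing_s))
      stop("samples absent from VCF: ", paste(missing_s, collapse = ", "))
    gt_str <- gt_str[, samples, drop = FALSE]
    if (!is.null(dp)) dp <- dp[, samples, drop = FALSE]
    if (!is.null(gq)) gq <- gq[, samples, drop = FALSE]
    if (!is.null(ad)) ad <- ad[, samples, drop = FALSE]
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)

  ad_field <- function(ad_mat, idx) {
    # idx = 1 for ref depth, a + 1 for depth of alt allele a
    if (is.null(ad_mat)) return(NULL)
    out <- suppressWarnings(
      apply(ad_mat, 2, function(col) {
        as.numeric(vapply(strsplit(col, ",", fixed = TRUE), function(f) {
          if (length(f) < idx || is.na(f[idx]) || f[idx] == ".") NA_character_
          else f[idx]
        }, character(1)))
      }))
    matrix(out, ncol = ncol(ad_mat), dimnames = dimnames(ad_mat))
  }

  build <- function(rows, allele) {
    gt_num <- apply(gt_str[rows, , drop = FALSE], 2,
                    gt_string_to_dosage, allele = allele)
    gt_num <- matrix(gt_num, ncol = ncol(gt_str),
                     dimnames = list(NULL, colnames(gt_str)))
    alt_a <- vapply(strsplit(alt[rows], ",", fixed = TRUE), `[`, character(1),
                    allele)
    list(sites = data.frame(chrom = chrom[rows], pos = pos[rows],
                            ref = fix[rows, "REF"], alt = alt_a,
                            mq = mq[rows], stringsAsFactors = FALSE),
         gt = gt_num,
         dp = if (!is.null(dp)) dp[rows, , drop = FALSE],
         gq = if (!is.null(gq)) gq[rows, , drop = FALSE],
         ad_ref = ad_field(if (is.null(ad)) NULL else ad[rows, , drop = FALSE], 1L),
         ad_alt = ad_field(if (is.null(ad)) NULL else ad[rows, , drop = FALSE],
                           allele + 1L))
  }

  if (multiallelic == "skip" || !any(multi)) {
    rows <- which(!multi)
    p <- build(rows, 1L)
  } else {
    n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
    parts <- lapply(seq_len(max(n_alt)), function(a) build(which(n_alt >= a), a))
    cat_m <- function(f) {
      ms <- lapply(parts, `[[`, f)
      if (any(vapply(ms, is.null, logical(1)))) NULL else do.call(rbind, ms)
    }
    p <- list(sites = do.call(rbind, lapply(parts, `[[`, "sites")),
              gt = cat_m("gt"), dp = cat_m("dp"), gq = cat_m("gq"),
              ad_ref = cat_m("ad_ref"), ad_alt = cat_m("ad_alt"))
    o <- order(factor(p$sites$chrom, unique(chrom)), p$sites$pos)
    p$sites <- p$sites[o, , drop = FALSE]
    for (f in c("gt", "dp", "gq", "ad_ref", "ad_alt"))
      if (!is.null(p[[f]])) p[[f]] <- p[[f]][o, , drop = FALSE]
  }
  variant_set(p$sites, p$gt, dp = p$dp, gq = p$gq,
              ad_ref = p$ad_ref, ad_alt = p$ad_alt)
}

#' Write a variant set as VCF 4.2
#'
#' Emits a minimal but standards-conforming VCF with `INFO/MQ` and a
#' `GT:DP:GQ:AD` (or subset thereof) FORMAT column, suitable for round-trip
#' through [read_vcf()].
#'
#' @param vs a [variant_set()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=peachscan",
    sprintf("##contig=<ID=%s>", unique(vs$sites$chrom)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs_samples(vs)), collapse = "\t")), con)
  fmt <- c("GT",
           if (!is.null(vs$dp)) "DP",
           if (!is.null(vs$gq)) "GQ",
           if (!is.null(vs$ad_ref) && !is.null(vs$ad_alt)) "AD")
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[vs$gt + 1L], nrow = n_sites(vs))
  gt_chr[is.na(gt_chr)] <- "./."
  num_chr <- function(m) {
    if (is.null(m)) return(NULL)
    out <- matrix(as.character(m), nrow = nrow(m))
    out[is.na(out)] <- "."
    out
  }
  dp_chr <- num_chr(vs$dp); gq_chr <- num_chr(vs$gq)
  ad_chr <- if ("AD" %in% fmt) {
    r <- num_chr(vs$ad_ref); a <- num_chr(vs$ad_alt)
    matrix(ifelse(r == "." & a == ".", ".", paste(r, a, sep = ",")),
           nrow = n_sites(vs))
  }
  for (i in seq_len(n_sites(vs))) {
    cells <- gt_chr[i, ]
    if (!is.null(dp_chr)) cells <- paste(cells, dp_chr[i, ], sep = ":")
    if (!is.null(gq_chr)) cells <- paste(cells, gq_chr[i, ], sep = ":")
    if (!is.null(ad_chr)) cells <- paste(cells, ad_chr[i, ], sep = ":")
    info <- if (is.na(vs$sites$mq[i])) "." else sprintf("MQ=%g", vs$sites$mq[i])
    writeLines(paste(c(vs$sites$chrom[i], vs$sites$pos[i], ".",
                       vs$sites$ref[i], vs$sites$alt[i], ".", "PASS",
                       info, paste(fmt, collapse = ":"), cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Population-level SNP quality filter
#'
#' Applies the high-quality-SNP criteria used for population analyses:
#' individual genotype calls supported by fewer than `min_dp` mapped reads
#' or with Phred genotype quality below `min_gq` are set to missing, then
#' sites with mapping quality below `min_mq` or with a missing-call fraction
#' of `max_missing` or more are dropped.  Missing quality fields count as
#' failing (conservative).  The filter is idempotent.
#'
#' @param vs a [variant_set()] with per-sample `dp` and `gq` matrices.
#' @param min_dp minimum per-sample read depth (default 5).
#' @param min_mq minimum site mapping quality (default 20).
#' @param min_gq minimum per-sample genotype quality (default 5).
#' @param max_missing maximum tolerated missing-genotype fraction per site
#'   (default 0.2; sites at or above this are removed).
#' @return the filtered `variant_set` (possibly with zero sites).
#' @export
filter_population_snps <- function(vs, min_dp = 5, min_mq = 20, min_gq = 5,
                                   max_missing = 0.2) {
  gt <- vs$gt
  fail <- matrix(FALSE, nrow(gt), ncol(gt))
  if (!is.null(vs$dp)) fail <- fail | is.na(vs$dp) | vs$dp < min_dp
  else fail[] <- TRUE
  if (!is.null(vs$gq)) fail <- fail | is.na(vs$gq) | vs$gq < min_gq
  else fail[] <- TRUE
  gt[fail] <- NA_integer_
  miss_frac <- rowMeans(is.na(gt))
  keep <- !is.na(vs$sites$mq) & vs$sites$mq >= min_mq &
    miss_frac < max_missing
  out <- vs
  out$gt <- gt
  out[keep, ]
}

#' Read gene models from GFF3 or BED6
#'
#' Coordinates are converted to the package's 1-based inclusive convention
#' (BED half-open starts gain 1).  For GFF3, each `gene` feature yields one
#' model; CDS intervals are taken from the first mRNA of the gene (or from
#' CDS features parented directly on the gene).  For BED6 each line is a
#' gene whose single CDS spans the whole interval.
#'
#' @param path a `.gff3`/`.gff` or `.bed` file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and a list-column `cds` of data.frames (`start`, `end`).
#' @export
read_gene_models <- function(path) {
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  if (is_bed) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- data.frame(
      gene_id = if (!is.null(gr$name)) as.character(gr$name)
                else paste0("gene", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),   # rtracklayer already converts to 1-based
      end = GenomicRanges::end(gr),
      strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
      stringsAsFactors = FALSE)
    out$cds <- lapply(seq_len(nrow(out)), function(i)
      data.frame(start = out$start[i], end = out$end[i]))
    return(out)
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  genes <- which(type == "gene")
  if (!length(genes)) stop("no gene features in GFF3")
  parent_of <- function(i) {
    p <- meta$Parent[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }
  parents <- vapply(seq_along(gr), parent_of, character(1))
  out <- data.frame(
    gene_id = ids[genes],
    chrom = as.character(GenomicRanges::seqnames(gr))[genes],
    start = GenomicRanges::start(gr)[genes],
    end = GenomicRanges::end(gr)[genes],
    strand = as.character(GenomicRanges::strand(gr))[genes],
    stringsAsFactors = FALSE)
  out$cds <- lapply(seq_along(genes), function(k) {
    g <- genes[k]
    gid <- ids[g]
    mrnas <- which(type %in% c("mRNA", "transcript") & parents == gid)
    cds_parent <- if (length(mrnas)) ids[mrnas[1]] else gid
    cds <- which(type == "CDS" & parents == cds_parent)
    if (!length(cds)) return(data.frame(start = integer(0), end = integer(0)))
    d <- data.frame(start = GenomicRanges::start(gr)[cds],
                    end = GenomicRanges::end(gr)[cds])
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start < out$start[k] | d$end > out$end[k]))
      stop("CDS outside parent gene interval for ", gid)
    d
  })
  out[order(factor(out$chrom, unique(out$chrom)), out$start), , drop = FALSE]
}

#' Write gene models as BED6
#'
#' The inverse boundary conversion of [read_gene_models()]: internal 1-based
#' inclusive intervals become half-open 0-based BED records.
#'
#' @param models gene-model data.frame as returned by [read_gene_models()].
#' @param path output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(models, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   models$chrom, models$start - 1L, models$end,
                   models$gene_id, models$strand)
  writeLines(lines, path)
  invisible(path)
}
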