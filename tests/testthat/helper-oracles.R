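# Independent brute-force oracles used to validate the fast implementations.
# These deliberately take a different computational route (allele-pair
# enumeration, explicit dynamic programming, exhaustive translation) from
# the package code they check.

# Mean pairwise difference per bp over a window, by explicit enumeration of
# all ordered allele pairs at every site.  geno: sites x samples dosage
# matrix with no missing data.
oracle_window_pi <- function(geno, window_length) {
  total <- 0
  for (i in seq_len(nrow(geno))) {
    n <- 2L * ncol(geno)
    k <- sum(geno[i, ])
    alleles <- c(rep(1L, k), rep(0L, n - k))
    diffs <- sum(outer(alleles, alleles, "!=")) / 2   # unordered pairs
    total <- total + diffs / choose(n, 2)
  }
  total / window_length
}

# Textbook Tajima's D computed site-by-site from allele counts.
oracle_tajima_d <- function(geno) {
  n <- 2L * ncol(geno)
  S <- 0
  theta_pi <- 0
  for (i in seq_len(nrow(geno))) {
    k <- sum(geno[i, ])
    if (k > 0 && k < n) S <- S + 1
    theta_pi <- theta_pi + k * (n - k) / choose(n, 2)
  }
  if (S < 1) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hudson Fst (ratio of sums) recomputed per site from integer allele counts.
oracle_hudson_fst <- function(geno1, geno2) {
  n1 <- 2L * ncol(geno1)
  n2 <- 2L * ncol(geno2)
  num <- den <- 0
  for (i in seq_len(nrow(geno1))) {
    k1 <- sum(geno1[i, ]); k2 <- sum(geno2[i, ])
    p1 <- k1 / n1; p2 <- k2 / n2
    num <- num + (p1 - p2)^2 -
      k1 * (n1 - k1) / (n1^2 * (n1 - 1)) -
      k2 * (n2 - k2) / (n2^2 * (n2 - 1))
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (den <= 0) return(NA_real_)
  num / den
}

# Quadratic-space affine-gap Smith-Waterman DP.  A gap of length L costs
# open + L * extend (open, extend given as positive costs).
oracle_local_align <- function(a, b, match = 1, mismatch = -2,
                               open = 5, extend = 2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  if (la == 0 || lb == 0) return(0)
  H <- E <- F_ <- matrix(0, la + 1, lb + 1)
  E[] <- -Inf; F_[] <- -Inf
  best <- 0
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      s <- if (a[i - 1] == b[j - 1] && a[i - 1] %in% c("A", "C", "G", "T"))
        match else mismatch
      E[i, j] <- max(E[i, j - 1] - extend, H[i, j - 1] - open - extend)
      F_[i, j] <- max(F_[i - 1, j] - extend, H[i - 1, j] - open - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Fourfold degeneracy decided by exhaustive translation of all four
# third-base variants under the standard genetic code.
oracle_is_fourfold <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  if (grepl("[^ACGT]", codon) || nchar(codon) != 3) return(FALSE)
  aas <- vapply(c("A", "C", "G", "T"), function(b)
    gc[[paste0(substr(codon, 1, 2), b)]], character(1))
  length(unique(aas)) == 1L
}

# 4DTv by exhaustive per-codon classification.
oracle_four_dtv <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  n4d <- ntv <- 0
  pur <- c("A", "G")
  for (i in seq_along(ca)) {
    if (!oracle_is_fourfold(ca[i]) || !oracle_is_fourfold(cb[i])) next
    if (substr(ca[i], 1, 2) != substr(cb[i], 1, 2)) next
    n4d <- n4d + 1
    x <- substr(ca[i], 3, 3); y <- substr(cb[i], 3, 3)
    if (x != y && (x %in% pur) != (y %in% pur)) ntv <- ntv + 1
  }
  list(n_4d_sites = n4d, n_transversions = ntv,
       value = if (n4d > 0) ntv / n4d else NA_real_)
}

# Random dosage matrix without missing data.
random_geno <- function(n_sites, n_samples, maf_beta = c(0.8, 0.8)) {
  p <- stats::rbeta(n_sites, maf_beta[1], maf_beta[2])
  matrix(stats::rbinom(n_sites * n_samples, 2, rep(p, n_samples)),
         nrow = n_sites)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Small VCF fixture written as plain text; returns the path.
write_toy_vcf <- function(body_lines,
                          samples = c("s1", "s2"),
                          path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}
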