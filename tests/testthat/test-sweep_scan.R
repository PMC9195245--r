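gm_from <- function(geno, pos = NULL, chrom = "chr1") {
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 100
  genotype_matrix(geno, rep(chrom, nrow(geno)), pos)
}

test_that("allele frequencies count alleles, with missing data excluded", {
  g <- rbind(c(0, 1, 2), c(NA, NA, NA), c(2, NA, 0))
  colnames(g) <- c("a", "b", "c")
  gm <- gm_from(g)
  af <- site_allele_freq(gm, c("a", "b", "c"))
  expect_equal(af$p, c(0.5, NA, 0.5))
  expect_equal(af$n, c(6L, 0L, 4L))
  # brute-force allele counting on random matrices
  set.seed(12)
  for (rep in 1:5) {
    g <- matrix(sample(c(0:2, NA), 200, TRUE), 20, 10,
                dimnames = list(NULL, letters[1:10]))
    gm <- gm_from(g)
    af <- site_allele_freq(gm, letters[1:10])
    for (i in sample.int(20, 5)) {
      alleles <- unlist(lapply(g[i, ], function(d)
        if (is.na(d)) NULL else c(rep(1, d), rep(0, 2 - d))))
      expect_equal(af$n[i], length(alleles))
      if (length(alleles)) expect_equal(af$p[i], mean(alleles))
    }
  }
})

test_that("window pi matches the closed form and the pairwise oracle", {
  # one segregating site, p = 0.5, n = 20, 50-kb window
  g <- matrix(c(rep(1, 10)), nrow = 1,
              dimnames = list(NULL, paste0("s", 1:10)))
  gm <- gm_from(g, pos = 25000)
  expect_equal(window_pi(gm, paste0("s", 1:10), "chr1", 1, 50000),
               (2 * 0.25 * 20 / 19) / 50000)
  # empty window
  expect_equal(window_pi(gm, paste0("s", 1:10), "chr1", 50001, 100000), 0)
  # pairwise-difference oracle on random matrices
  set.seed(31)
  for (rep in 1:10) {
    ns <- sample(c(4, 10, 27), 1)
    g <- random_geno(100, ns)
    colnames(g) <- paste0("s", seq_len(ns))
    gm <- gm_from(g, pos = sort(sample.int(2e4, 100)))
    expect_equal(window_pi(gm, colnames(g), "chr1", 1, 2e4),
                 oracle_window_pi(g, 2e4), tolerance = 1e-12)
  }
})

test_that("pi is invariant to sample order and allele relabeling", {
  set.seed(8)
  g <- random_geno(50, 12)
  colnames(g) <- paste0("s", 1:12)
  gm <- gm_from(g, pos = sort(sample.int(1e4, 50)))
  pi1 <- window_pi(gm, colnames(g), "chr1", 1, 1e4)
  gm_flip <- gm_from(2 - g, pos = gm$sites$pos)
  expect_equal(window_pi(gm_flip, colnames(g), "chr1", 1, 1e4), pi1)
  perm <- sample(colnames(g))
  expect_equal(window_pi(gm, perm, "chr1", 1, 1e4), pi1)
})

test_that("Tajima's D equals the textbook oracle and is 0 when theta_pi = theta_w", {
  set.seed(77)
  for (ns in c(4, 10, 27)) {
    g <- random_geno(60, ns)
    colnames(g) <- paste0("s", seq_len(ns))
    gm <- gm_from(g, pos = sort(sample.int(5e4, 60)))
    expect_equal(tajimas_d(gm, colnames(g), "chr1", 1, 5e4),
                 oracle_tajima_d(g), tolerance = 1e-12)
  }
  # no segregating site -> undefined
  g0 <- matrix(0L, 5, 6, dimnames = list(NULL, paste0("s", 1:6)))
  gm0 <- gm_from(g0)
  expect_true(is.na(tajimas_d(gm0, paste0("s", 1:6), "chr1", 1, 1e4)))
})

test_that("sweep flanks show the expected negative Tajima's D shift", {
  s <- simulate_sweep(seed = 404, n_snps = 20000, chrom_length = 4e6,
                      sweep_interval = c(1.5e6, 2.5e6), gamma = 8)
  w <- scan_windows(s$gm, s$groups)
  ins <- w$start >= 1.5e6 & w$end <= 2.5e6
  expect_lt(mean(w$d_high[ins], na.rm = TRUE),
            mean(w$d_high[!ins], na.rm = TRUE))
  expect_lt(mean(w$d_high[ins], na.rm = TRUE), 0)
})

test_that("Hudson Fst matches the closed form and the count-based oracle", {
  # one fixed difference: p1 = 1, p2 = 0 -> Fst = 1
  g <- cbind(matrix(2L, 1, 5), matrix(0L, 1, 5))
  colnames(g) <- c(paste0("H", 1:5), paste0("L", 1:5))
  gm <- gm_from(g, pos = 500)
  groups <- group_assignment(colnames(g), rep(c("high", "low"), each = 5))
  expect_equal(hudson_fst(gm, groups, "chr1", 1, 1000), 1)
  # oracle equality on random two-group matrices
  set.seed(55)
  for (rep in 1:10) {
    g1 <- random_geno(80, 10); g2 <- random_geno(80, 14)
    # regenerate group 2 from the same p to stay near null sometimes
    g <- cbind(g1, g2)
    colnames(g) <- c(paste0("H", 1:10), paste0("L", 1:14))
    gm <- gm_from(g, pos = sort(sample.int(1e5, 80)))
    groups <- group_assignment(colnames(g), rep(c("high", "low"), c(10, 14)))
    expect_equal(hudson_fst(gm, groups, "chr1", 1, 1e5),
                 oracle_hudson_fst(g1, g2), tolerance = 1e-12)
  }
})

test_that("Fst of a same-population split is near zero", {
  set.seed(66)
  g <- random_geno(3000, 30)
  colnames(g) <- paste0("s", 1:30)
  gm <- gm_from(g, pos = sort(sample.int(1e6, 3000)))
  groups <- group_assignment(colnames(g), rep(c("high", "low"), c(12, 18)))
  expect_lt(abs(hudson_fst(gm, groups, "chr1", 1, 1e6)), 0.01)
})

test_that("the scan grid and per-window stats compose from single-window ops", {
  s <- simulate_sweep(seed = 5, n_snps = 3000, chrom_length = 3e5,
                      sweep_interval = c(1e5, 1.5e5))
  w <- scan_windows(s$gm, s$groups, chrom_lengths = c(chr1 = 3e5))
  # grid: starts at 1, 10001, ... while start + 49999 <= 3e5
  expect_equal(w$start, seq(1, 250001, by = 10000))
  hi <- names(s$groups)[s$groups == "high"]
  lo <- names(s$groups)[s$groups == "low"]
  for (i in sample.int(nrow(w), 8)) {
    expect_equal(w$pi_high[i],
                 window_pi(s$gm, hi, "chr1", w$start[i], w$end[i]),
                 tolerance = 1e-12)
    expect_equal(w$pi_low[i],
                 window_pi(s$gm, lo, "chr1", w$start[i], w$end[i]),
                 tolerance = 1e-12)
    expect_equal(w$d_high[i],
                 tajimas_d(s$gm, hi, "chr1", w$start[i], w$end[i]),
                 tolerance = 1e-12)
    expect_equal(w$fst[i],
                 hudson_fst(s$gm, s$groups, "chr1", w$start[i], w$end[i]),
                 tolerance = 1e-12)
  }
})

test_that("window selection respects quantile limits, modes and tie inclusion", {
  s <- simulate_sweep(seed = 6, n_snps = 5000, chrom_length = 1e6,
                      sweep_interval = c(4e5, 5e5))
  w <- scan_windows(s$gm, s$groups)
  sel_all <- select_sweep_windows(w, q = 1.0)
  defined <- !is.na(w$pi_ratio) & !is.na(w$fst) &
    !is.na(w$d_high - w$d_low)
  expect_true(all(sel_all$selected[defined]))
  sel_i <- select_sweep_windows(w, mode = "intersection")
  sel_u <- select_sweep_windows(w, mode = "union")
  sel_2 <- select_sweep_windows(w, mode = "any-two")
  expect_true(all(which(sel_i$selected) %in% which(sel_2$selected)))
  expect_true(all(which(sel_2$selected) %in% which(sel_u$selected)))
  expect_error(select_sweep_windows(w[1:10, ]), "20")
})

test_that("overlapping and abutting windows merge; genes attach by overlap", {
  sel <- data.frame(chrom = "chr1",
                    start = c(1, 10001, 70001),
                    end = c(50000, 60000, 120000))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(100, 59000, 300000),
                      end = c(150, 61000, 300500), strand = "+")
  m <- merge_and_annotate(sel, genes)
  expect_equal(m$regions$start, c(1, 70001))
  expect_equal(m$regions$end, c(60000, 120000))
  expect_equal(m$regions$genes[[1]], c("g1", "g2"))
  expect_equal(m$regions$n_genes, c(2L, 0L))
  expect_equal(m$total_span, 60000 + 50000)
  expect_equal(m$n_genes, 2L)
  # brute-force all-pairs overlap oracle on a random fixture
  set.seed(19)
  sel2 <- data.frame(chrom = "chr1",
                     start = sort(sample(seq(1, 1e6, 1e4), 30)))
  sel2$end <- sel2$start + 5e4 - 1
  genes2 <- data.frame(gene_id = sprintf("g%02d", 1:50), chrom = "chr1",
                       start = s2 <- sort(sample.int(1e6, 50)), strand = "+")
  genes2$end <- genes2$start + sample(500:5000, 50)
  m2 <- merge_and_annotate(sel2, genes2)
  expected <- unique(genes2$gene_id[vapply(seq_len(50), function(j)
    any(genes2$start[j] <= m2$regions$end &
        genes2$end[j] >= m2$regions$start), logical(1))])
  expect_setequal(unlist(m2$regions$genes), expected)
})
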