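test_that("a toy VCF round-trips with the stated genotypes", {
  path <- write_toy_vcf(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\tMQ=60\tGT:DP:GQ:AD\t0/1:10:30:6,4\t1/1:8:40:0,8",
    "chr1\t200\t.\tC\tT\t50\tPASS\tMQ=25\tGT:DP:GQ:AD\t0/0:12:20:12,0\t0/1:9:35:5,4",
    "chr1\t300\t.\tG\tA\t50\tPASS\tMQ=19\tGT:DP:GQ:AD\t./.:.:.:.\t0/1:7:22:3,4"))
  vs <- read_vcf(path)
  expect_equal(n_sites(vs), 3L)
  expect_equal(vs_samples(vs), c("s1", "s2"))
  expect_equal(vs$sites$pos, c(100L, 200L, 300L))
  expect_equal(unname(vs$gt[, "s1"]), c(1L, 0L, NA))
  expect_equal(unname(vs$gt[, "s2"]), c(2L, 1L, 1L))
  expect_equal(vs$sites$mq, c(60, 25, 19))
  expect_equal(unname(vs$ad_alt[, "s1"]), c(4, 0, NA))
})

test_that("multi-allelic sites are skipped or split per config", {
  path <- write_toy_vcf(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\tMQ=60\tGT\t0/1\t1/1",
    "chr1\t200\t.\tC\tT,G\t50\tPASS\tMQ=60\tGT\t1/2\t0/2",
    "chr1\t300\t.\tG\tA\t50\tPASS\tMQ=60\tGT\t0/0\t0/1"))
  skip <- read_vcf(path, multiallelic = "skip")
  expect_equal(skip$sites$pos, c(100L, 300L))
  split <- read_vcf(path, multiallelic = "split")
  expect_equal(split$sites$pos, c(100L, 200L, 200L, 300L))
  at200 <- split$sites$pos == 200L
  expect_setequal(split$sites$alt[at200], c("T", "G"))
  # dosage of each split allele counted separately
  expect_equal(unname(split$gt[split$sites$alt == "T" & at200, ]), c(1L, 0L))
  expect_equal(unname(split$gt[split$sites$alt == "G" & at200, ]), c(1L, 1L))
})

test_that("unsorted VCF input is rejected", {
  path <- write_toy_vcf(c(
    "chr1\t300\t.\tA\tG\t50\tPASS\tMQ=60\tGT\t0/1\t1/1",
    "chr1\t100\t.\tC\tT\t50\tPASS\tMQ=60\tGT\t0/0\t0/1"))
  expect_error(read_vcf(path), "sorted")
})

test_that("a synthetic variant set written to VCF re-reads identically", {
  set.seed(42)
  n <- 50
  gt <- matrix(sample(c(0:2, NA), n * 4, TRUE), n, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  sites <- data.frame(chrom = "chr7", pos = sort(sample.int(1e5, n)),
                      ref = "A", alt = "C", mq = 60)
  vs <- variant_set(sites, gt,
                    dp = matrix(20, n, 4), gq = matrix(90, n, 4))
  path <- tempfile(fileext = ".vcf")
  write_vcf(vs, path)
  back <- read_vcf(path)
  expect_equal(back$sites[, c("chrom", "pos", "ref", "alt")],
               vs$sites[, c("chrom", "pos", "ref", "alt")])
  expect_equal(unname(back$gt), unname(vs$gt))
})

test_that("population SNP filter reproduces a hand-enumerated fixture", {
  # 10 sites, 5 samples; missingness threshold 0.2 means one masked sample
  # in five kills a site.  Sites 1-5 fully clean; site 6 has mq 19 (killed
  # by mapping quality); sites 7-10 each have one sample at dp 4 (masked ->
  # missing fraction 0.2 -> killed).  Expect survivors = sites 1-5.
  n <- 10; m <- 5
  gt <- matrix(1L, n, m, dimnames = list(NULL, paste0("s", 1:m)))
  dp <- matrix(10, n, m)
  gq <- matrix(30, n, m)
  mq <- rep(60, n); mq[6] <- 19
  for (i in 7:10) dp[i, i - 6] <- 4
  vs <- variant_set(data.frame(chrom = "chr1", pos = 1:n * 100,
                               ref = "A", alt = "G", mq = mq),
                    gt, dp = dp, gq = gq)
  out <- filter_population_snps(vs)
  expect_equal(out$sites$pos, (1:5) * 100)
  # boundary: mapping quality exactly 20 is kept
  vs20 <- vs
  vs20$sites$mq[6] <- 20
  expect_equal(n_sites(filter_population_snps(vs20)), 6L)
})

test_that("population SNP filter is idempotent and survivors re-check", {
  set.seed(7)
  n <- 200; m <- 8
  gt <- matrix(sample(c(0:2, NA), n * m, TRUE, prob = c(.3, .3, .3, .1)),
               n, m, dimnames = list(NULL, paste0("s", 1:m)))
  vs <- variant_set(
    data.frame(chrom = "chr1", pos = sort(sample.int(1e6, n)),
               ref = "A", alt = "G", mq = sample(c(10, 30, 60), n, TRUE)),
    gt,
    dp = matrix(sample(0:30, n * m, TRUE), n, m),
    gq = matrix(sample(0:60, n * m, TRUE), n, m))
  f1 <- filter_population_snps(vs)
  f2 <- filter_population_snps(f1)
  expect_equal(f1$sites, f2$sites)
  expect_equal(f1$gt, f2$gt)
  expect_true(nrow(f1$sites) < n)   # fixture actually exercises removal
  # every survivor independently satisfies all criteria
  expect_true(all(f1$sites$mq >= 20))
  masked <- is.na(f1$gt) | is.na(f1$dp) | f1$dp < 5 | is.na(f1$gq) | f1$gq < 5
  gt_checked <- f1$gt
  gt_checked[masked] <- NA
  expect_true(all(rowMeans(is.na(gt_checked)) < 0.2))
})

test_that("empty filter input yields empty output", {
  gt <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("a", "b")))
  vs <- variant_set(data.frame(chrom = character(0), pos = integer(0),
                               ref = character(0), alt = character(0),
                               mq = numeric(0)),
                    gt, dp = gt, gq = gt)
  expect_equal(n_sites(filter_population_snps(vs)), 0L)
})

test_that("BED gene models use 1-based inclusive internal coordinates", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tg1\t0\t+", path)
  gm <- read_gene_models(path)
  expect_equal(gm$start, 100L)
  expect_equal(gm$end, 200L)
  expect_equal(gm$gene_id, "g1")
  # round trip preserves intervals
  out <- tempfile(fileext = ".bed")
  write_gene_models_bed(gm, out)
  gm2 <- read_gene_models(out)
  expect_equal(gm2[, c("chrom", "start", "end", "gene_id")],
               gm[, c("chrom", "start", "end", "gene_id")])
})

test_that("GFF3 gene models parse genes with their CDS", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t1000\t2000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttest\tCDS\t1100\t1400\t.\t+\t0\tID=gA.1.c1;Parent=gA.1",
    "chr1\ttest\tCDS\t1600\t1901\t.\t+\t0\tID=gA.1.c2;Parent=gA.1",
    "chr1\ttest\tgene\t5000\t6000\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t5000\t6000\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\ttest\tCDS\t5000\t5602\t.\t-\t0\tID=gB.1.c1;Parent=gB.1"), path)
  gm <- read_gene_models(path)
  expect_equal(nrow(gm), 2L)
  expect_equal(gm$gene_id, c("gA", "gB"))
  expect_equal(gm$cds[[1]]$start, c(1100, 1600))
  expect_equal(gm$cds[[1]]$end, c(1400, 1901))
})

test_that("CDS outside its parent gene is a consistency error", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t1000\t2000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttest\tCDS\t900\t1400\t.\t+\t0\tID=c;Parent=gA.1"), path)
  expect_error(read_gene_models(path), "outside")
})
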