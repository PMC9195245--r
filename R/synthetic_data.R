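# Seeded generators for every input the pipeline consumes, each emitting a
# machine-readable truth record so that recovery can be scored.
#
# Study-design defaults mirror the analyses the package implements: a BC1
# cross with 20/20 phenotype pools, a 10-vs-27 two-group resequencing panel,
# a 17-mer depth histogram, and codon pairs / donor catalogs with controlled
# divergence.

#' Simulate a BC1 bulked-segregant experiment
#'
#' A donor (resistant) parent homozygous for the donor allele at every
#' marker is crossed to a recurrent (susceptible) parent; each BC1 offspring
#' receives one recombinant F1 gamete (Haldane map, no interference) plus a
#' recurrent-parent gamete, so genotypes are heterozygous or
#' recurrent-homozygous.  Resistance is dominant and conferred by the donor
#' allele at `causal_pos`.  Phenotype pools are the first `pool_size`
#' offspring of each class after a seeded shuffle; pooled read counts are
#' Binomial(`depth`, pool donor-allele frequency) per marker.
#'
#' @param n_offspring BC1 population size (default 200).
#' @param n_markers number of evenly spaced markers (default 500; the
#'   causal position is added as a marker if not already on the grid).
#' @param chrom_length chromosome length in bp (default 25 Mb).
#' @param causal_pos position of the resistance locus (default 6.5 Mb).
#' @param rec_rate recombination rate in Morgans/bp (default 1e-7, i.e.
#'   10 cM/Mb: the default chromosome spans ~2.5 Morgans, so markers distal
#'   to the causal locus are effectively unlinked and the expected delta
#'   profile decays to 0 within the chromosome, as the BC1 design assumes).
#' @param pool_size seedlings per phenotype pool (default 20).
#' @param depth pooled read depth per marker (default 50).
#' @param chrom chromosome name (default `"chr2"`).
#' @param seed RNG seed.
#' @return list of class `bc1_sim`: `parents` (a [variant_set()] of the two
#'   parents, samples `P_res`, `P_sus`, donor allele = ALT),
#'   `pool_sites` (data.frame `chrom`, `pos`, `donor_res`, `other_res`,
#'   `donor_sus`, `other_sus`) and `truth` (causal position, marker grid,
#'   expected deltas, class sizes).
#' @export
simulate_bc1 <- function(n_offspring = 200, n_markers = 500,
                         chrom_length = 25e6, causal_pos = 6.5e6,
                         rec_rate = 1e-7, pool_size = 20, depth = 50,
                         chrom = "chr2", seed = NULL) {
  stopifnot(causal_pos >= 1, causal_pos <= chrom_length,
            pool_size >= 1, n_offspring >= 2 * pool_size)
  if (!is.null(seed)) set.seed(seed)
  pos <- unique(sort(c(round(seq(1, chrom_length, length.out = n_markers)),
                       round(causal_pos))))
  m <- length(pos)
  causal_idx <- match(round(causal_pos), pos)
  # recombination fractions between adjacent markers (Haldane)
  cfrac <- 0.5 * (1 - exp(-2 * rec_rate * diff(pos)))

  for (try in 1:20) {
    # F1 gamete per offspring: TRUE = donor allele, Markov chain along chrom
    start <- matrix(stats::runif(n_offspring) < 0.5, n_offspring, 1)
    if (m > 1) {
      sw <- matrix(stats::runif(n_offspring * (m - 1)), n_offspring) <
        rep(cfrac, each = n_offspring)
      flips <- t(apply(cbind(0L, sw), 1, cumsum)) %% 2
    } else flips <- matrix(0, n_offspring, 1)
    donor <- (as.integer(start[, 1]) + flips) %% 2 == 1
    resistant <- donor[, causal_idx]
    if (sum(resistant) >= pool_size && sum(!resistant) >= pool_size) break
    if (try == 20) stop("could not fill both phenotype pools")
  }
  shuffle <- sample.int(n_offspring)
  res_pool <- shuffle[resistant[shuffle]][seq_len(pool_size)]
  sus_pool <- shuffle[!resistant[shuffle]][seq_len(pool_size)]
  # donor-allele frequency among pooled chromosomes (each plant contributes
  # one gamete allele of two; the recurrent gamete never carries it)
  freq_res <- colSums(donor[res_pool, , drop = FALSE]) / (2 * pool_size)
  freq_sus <- colSums(donor[sus_pool, , drop = FALSE]) / (2 * pool_size)
  donor_res <- stats::rbinom(m, depth, freq_res)
  donor_sus <- stats::rbinom(m, depth, freq_sus)
  pool_sites <- data.frame(chrom = chrom, pos = pos,
                           donor_res = donor_res,
                           other_res = depth - donor_res,
                           donor_sus = donor_sus,
                           other_sus = depth - donor_sus)
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      mq = 60)
  gt <- cbind(P_res = rep(2L, m), P_sus = rep(0L, m))
  parents <- variant_set(sites, gt,
                         dp = matrix(30, m, 2), gq = matrix(99, m, 2))
  structure(list(
    parents = parents,
    pool_sites = pool_sites,
    truth = list(causal_pos = pos[causal_idx], marker_pos = pos,
                 freq_res = freq_res, freq_sus = freq_sus,
                 n_resistant = sum(resistant),
                 n_susceptible = sum(!resistant))),
    class = "bc1_sim")
}

#' Simulate a two-group genotype matrix with a planted sweep
#'
#' Background sites share an allele frequency drawn from a Beta
#' distribution; genotypes are Binomial(2, p) per sample.  Inside the sweep
#' interval the high group's frequency is warped toward the nearer boundary
#' (`p^gamma` below 0.5, `1 - (1-p)^gamma` above), which jointly produces
#' reduced diversity, an excess of rare variants (negative Tajima's D) and
#' elevated Fst in that group — the three signals the scan selects on.
#' `gamma = 1` is the null.
#'
#' @param n_high,n_low samples per group (defaults 10 and 27, the study's
#'   high/low-altitude design).
#' @param chrom_length chromosome length in bp (default 10 Mb).
#' @param n_snps number of segregating sites to draw (default 56000 for the
#'   default 10-Mb chromosome, i.e. ~5600 SNPs/Mb — the genome-wide density
#'   of the high-quality SNP set the scan is designed for).
#' @param beta shape parameters of the background frequency distribution
#'   (default `c(0.5, 0.5)`).
#' @param sweep_interval `c(start, end)` of the planted sweep (default the
#'   central 100 kb).
#' @param gamma sweep strength (>= 1; default 8).
#' @param chrom chromosome name.
#' @param seed RNG seed.
#' @return list: `gm` (a [genotype_matrix()]), `groups` (named factor),
#'   `truth` (sweep interval, midpoint, gamma).
#' @export
simulate_sweep <- function(n_high = 10, n_low = 27, chrom_length = 10e6,
                           n_snps = 56000, beta = c(0.5, 0.5),
                           sweep_interval = NULL, gamma = 8,
                           chrom = "chr1", seed = NULL) {
  stopifnot(n_high >= 2, n_low >= 2, gamma >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sweep_interval))
    sweep_interval <- c(max(1, chrom_length / 2 - 5e4),
                        min(chrom_length, chrom_length / 2 + 5e4))
  stopifnot(length(sweep_interval) == 2,
            sweep_interval[1] >= 1, sweep_interval[2] <= chrom_length)
  pos <- sort(sample.int(chrom_length, n_snps))
  p <- stats::rbeta(n_snps, beta[1], beta[2])
  in_sweep <- pos >= sweep_interval[1] & pos <= sweep_interval[2]
  p_high <- p
  p_high[in_sweep] <- ifelse(p[in_sweep] <= 0.5,
                             p[in_sweep]^gamma,
                             1 - (1 - p[in_sweep])^gamma)
  g_high <- matrix(stats::rbinom(n_snps * n_high, 2, rep(p_high, n_high)),
                   nrow = n_snps)
  g_low <- matrix(stats::rbinom(n_snps * n_low, 2, rep(p, n_low)),
                  nrow = n_snps)
  geno <- cbind(g_high, g_low)
  colnames(geno) <- c(sprintf("H%02d", seq_len(n_high)),
                      sprintf("L%02d", seq_len(n_low)))
  gm <- genotype_matrix(geno, rep(chrom, n_snps), pos)
  groups <- group_assignment(colnames(geno),
                             rep(c("high", "low"), c(n_high, n_low)))
  list(gm = gm, groups = groups,
       truth = list(sweep_start = sweep_interval[1],
                    sweep_end = sweep_interval[2],
                    midpoint = mean(sweep_interval), gamma = gamma))
}

#' Simulate a k-mer depth histogram
#'
#' `genome_size` distinct single-copy k-mers receive Poisson(`depth`)
#' observed depths; a sequencing-error peak of
#' `round(error_fraction * genome_size * depth)` singleton k-mers is added
#' at depth 1.
#'
#' @param genome_size number of distinct true k-mers (>= 1e4).
#' @param depth mean sequencing depth (default 40).
#' @param error_fraction error k-mers per true k-mer instance (default 0).
#' @param k recorded k-mer length (default 17).
#' @param seed RNG seed.
#' @return list: `hist` (a [kmer_histogram()]) and `truth` (genome size,
#'   depth, the simulator's exact total instance count, number of error
#'   k-mers).
#' @export
simulate_kmer_histogram <- function(genome_size = 1e6, depth = 40,
                                    error_fraction = 0, k = 17L,
                                    seed = NULL) {
  stopifnot(genome_size >= 1e4, depth > 0, error_fraction >= 0)
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rpois(genome_size, depth)
  counts <- tabulate(draws)              # counts[d] = k-mers at depth d >= 1
  n_err <- round(error_fraction * genome_size * depth)
  if (n_err > 0) counts[1] <- counts[1] + n_err
  keep <- which(counts > 0)
  list(hist = kmer_histogram(keep, counts[keep], k = k),
       truth = list(genome_size = genome_size, depth = depth,
                    total_instances = sum(draws) + n_err,
                    n_error_kmers = n_err))
}

# third-position substitution tables
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Simulate codon-aligned sequence pairs with controlled third-position
#' divergence
#'
#' Sequence A is built from fourfold-degenerate codons with a fraction of
#' spiked non-degenerate codons; sequence B copies A and mutates each third
#' position to a transversion with probability `tv_prob` or a transition
#' with probability `ts_prob`.
#'
#' @param n_pairs number of alignments to generate (default 1).
#' @param n_codons codons per sequence (default 1000).
#' @param tv_prob,ts_prob third-position transversion / transition
#'   probabilities (`tv_prob + ts_prob <= 1`).
#' @param non4d_fraction fraction of spiked non-degenerate codons
#'   (default 0.1).
#' @param seed RNG seed.
#' @return list: `pairs` (list of `list(a =, b =)` aligned sequences) and
#'   `truth` (`tv_prob`, `ts_prob`).
#' @export
simulate_codon_pairs <- function(n_pairs = 1, n_codons = 1000, tv_prob = 0,
                                 ts_prob = 0, non4d_fraction = 0.1,
                                 seed = NULL) {
  stopifnot(tv_prob >= 0, ts_prob >= 0, tv_prob + ts_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  fourfold <- paste0(rep(FOURFOLD_PREFIXES, each = 4), c("A", "C", "G", "T"))
  non4d <- c("ATG", "TGG", "AAA", "TTC", "GAT")   # no stops, none 4D
  make_pair <- function() {
    codons <- sample(fourfold, n_codons, replace = TRUE)
    spike <- stats::runif(n_codons) < non4d_fraction
    codons[spike] <- sample(non4d, sum(spike), replace = TRUE)
    third <- substr(codons, 3, 3)
    u <- stats::runif(n_codons)
    new_third <- third
    tv <- u < tv_prob
    ts <- !tv & u < tv_prob + ts_prob
    if (any(tv))
      new_third[tv] <- vapply(third[tv],
                              function(b) sample(.TRANSVERSIONS[[b]], 1),
                              character(1))
    if (any(ts)) new_third[ts] <- .TRANSITION[third[ts]]
    codons_b <- paste0(substr(codons, 1, 2), new_third)
    list(a = paste(codons, collapse = ""), b = paste(codons_b, collapse = ""))
  }
  list(pairs = replicate(n_pairs, make_pair(), simplify = FALSE),
       truth = list(tv_prob = tv_prob, ts_prob = ts_prob))
}

# Point-mutate a set of sequences: each position changes to a different
# base with probability `rate`.
.mutate_seq <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(ch)) < rate
    if (any(hit))
      ch[hit] <- vapply(ch[hit],
                        function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a gene-origin assignment fixture
#'
#' Each gene has an ancestral sequence from which every donor species'
#' ortholog diverges at that species' rate (`donor_divergences`); the query
#' copies the planted true donor's ortholog, further mutated at
#' `query_divergence`.  The true donor is drawn uniformly per gene.
#'
#' @param n_genes number of query genes (default 100).
#' @param donor_divergences named numeric vector (>= 2 entries): per-species
#'   divergence from the gene's ancestral sequence.
#' @param gene_length gene length in bp (default 500).
#' @param query_divergence extra divergence of the query from its true
#'   donor (default 0).
#' @param seed RNG seed.
#' @return list: `query` (named character vector), `catalog` (named list
#'   species -> named character vector) and `truth` (named character vector
#'   of planted donor labels).
#' @export
simulate_origin_fixture <- function(n_genes = 100,
                                    donor_divergences = c(mira = 0,
                                                          dulcis = 0.10),
                                    gene_length = 500,
                                    query_divergence = 0, seed = NULL) {
  stopifnot(length(donor_divergences) >= 1, !is.null(names(donor_divergences)))
  if (!is.null(seed)) set.seed(seed)
  species <- names(donor_divergences)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  ancestral <- vapply(gene_ids, function(g)
    paste(sample(c("A", "C", "G", "T"), gene_length, replace = TRUE),
          collapse = ""), character(1))
  catalog <- lapply(species, function(sp)
    stats::setNames(.mutate_seq(ancestral, donor_divergences[[sp]]), gene_ids))
  names(catalog) <- species
  truth <- stats::setNames(sample(species, n_genes, replace = TRUE), gene_ids)
  query <- vapply(gene_ids, function(g)
    .mutate_seq(catalog[[truth[[g]]]][[g]], query_divergence), character(1))
  list(query = query, catalog = catalog, truth = truth)
}

#' Write a simulated dataset with its truth sidecar
#'
#' Writes the standard-format files a consumer stage reads (VCF/TSV/FASTA)
#' plus a `*.truth.json` sidecar holding the generator's truth record.
#'
#' @param sim output of one of the `simulate_*` generators.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  truth <- NULL
  if (inherits(sim, "bc1_sim")) {
    write_vcf(sim$parents, p(".parents.vcf"))
    utils::write.table(sim$pool_sites, p(".pools.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out <- c(p(".parents.vcf"), p(".pools.tsv"))
    truth <- sim$truth[c("causal_pos", "n_resistant", "n_susceptible")]
  } else if (!is.null(sim$gm)) {
    gt <- sim$gm$geno
    vs <- variant_set(data.frame(chrom = sim$gm$sites$chrom,
                                 pos = sim$gm$sites$pos,
                                 ref = "A", alt = "T", mq = 60),
                      gt,
                      dp = matrix(30, nrow(gt), ncol(gt)),
                      gq = matrix(99, nrow(gt), ncol(gt)))
    write_vcf(vs, p(".vcf"))
    utils::write.table(data.frame(sample = names(sim$groups),
                                  group = as.character(sim$groups)),
                       p(".groups.tsv"), sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    out <- c(p(".vcf"), p(".groups.tsv"))
    truth <- sim$truth
  } else if (!is.null(sim$hist)) {
    write_kmer_histogram(sim$hist, p(".histo"))
    out <- p(".histo")
    truth <- sim$truth
  } else if (!is.null(sim$pairs)) {
    a <- vapply(sim$pairs, `[[`, character(1), "a")
    b <- vapply(sim$pairs, `[[`, character(1), "b")
    ids <- sprintf("pair%04d", seq_along(a))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(a, ids)), p(".a.fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(b, ids)), p(".b.fa"))
    out <- c(p(".a.fa"), p(".b.fa"))
    truth <- sim$truth
  } else if (!is.null(sim$catalog)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$query), p(".query.fa"))
    out <- p(".query.fa")
    for (sp in names(sim$catalog)) {
      f <- file.path(dir, paste0(prefix, ".", sp, ".fa"))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$catalog[[sp]]), f)
      out <- c(out, f)
    }
    truth <- list(labels = as.list(sim$truth))
  } else stop("unrecognized simulation object")
  jsonlite::write_json(truth, p(".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(out, p(".truth.json")))
}
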