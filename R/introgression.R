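# Gene-origin assignment by best local alignment score, and pan-genome
# gene-family presence/absence classification.

#' Alignment scoring scheme
#'
#' BLASTN-like defaults for the local aligner: match +1, mismatch -2, gap
#' open -5, gap extend -2 (a gap of length L costs
#' `|gap_open| + L * |gap_extend|`).
#'
#' @param match,mismatch,gap_open,gap_extend scoring parameters; `match`
#'   must be positive and the penalties non-positive.
#' @return named list.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap_open = -5,
                          gap_extend = -2) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

.align_submat <- function(scoring) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- scoring$match
  m["N", ] <- scoring$mismatch   # N matches nothing, not even N
  m[, "N"] <- scoring$mismatch
  m
}

.clean_dna <- function(x) {
  x <- toupper(as.character(x))
  gsub("[^ACGT]", "N", x)
}

#' Best local alignment score of two nucleotide sequences
#'
#' Smith-Waterman local alignment with affine gaps, computed with
#' \pkg{Biostrings}.  `N` scores as a mismatch against every base including
#' `N`.  The score is symmetric in its arguments and never negative (the
#' empty local alignment scores 0); an empty sequence scores 0.
#'
#' @param seq_a,seq_b character strings (or `DNAString`s) over `ACGTN`;
#'   other IUPAC codes are treated as `N`.
#' @param scoring an [align_scoring()] list.
#' @return integer-valued score.
#' @export
local_align_score <- function(seq_a, seq_b, scoring = align_scoring()) {
  a <- .clean_dna(seq_a)
  b <- .clean_dna(seq_b)
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = .align_submat(scoring),
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend),
    scoreOnly = TRUE)
  max(0, s)
}

#' Assign the origin species of one gene
#'
#' Scores the query against every candidate ortholog of every donor species
#' (per-species score = best over that species' sequences) and assigns the
#' species attaining the strict maximum, provided the best score reaches
#' `min_score` and beats the runner-up by at least `margin`; otherwise the
#' gene is `"ambiguous"`.  Exact ties are always ambiguous.
#'
#' @param query one nucleotide sequence (character or `DNAString`).
#' @param catalog named list: species -> character vector (or
#'   `DNAStringSet`) of candidate ortholog sequences.
#' @param min_score minimum best score required for an assignment
#'   (default 0).
#' @param margin minimum lead over the second-best species (default 0; with
#'   0, a strict maximum is still required).
#' @param scoring an [align_scoring()] list.
#' @return list with `assigned` (species name or `"ambiguous"`) and
#'   `scores` (named numeric, one per species).
#' @export
assign_gene_origin <- function(query, catalog, min_score = 0, margin = 0,
                               scoring = align_scoring()) {
  stopifnot(length(catalog) >= 1L, !is.null(names(catalog)))
  scores <- vapply(catalog, function(seqs) {
    max(vapply(as.character(seqs), local_align_score, numeric(1),
               seq_a = query, scoring = scoring))
  }, numeric(1))
  o <- order(scores, decreasing = TRUE)
  best <- scores[o[1]]
  second <- if (length(scores) > 1L) scores[o[2]] else -Inf
  assigned <- if (best >= min_score && best > second && best - second >= margin)
    names(scores)[o[1]] else "ambiguous"
  list(assigned = assigned, scores = scores)
}

#' Assign origins for a set of genes
#'
#' @param queries named character vector (or `DNAStringSet`) of query gene
#'   sequences.
#' @inheritParams assign_gene_origin
#' @return data.frame with `gene_id`, `assigned`, `best_score`, and one
#'   `score_<species>` column per donor species.
#' @export
assign_gene_origins <- function(queries, catalog, min_score = 0, margin = 0,
                                scoring = align_scoring()) {
  queries <- as.character(queries)
  if (is.null(names(queries)))
    names(queries) <- sprintf("g%04d", seq_along(queries))
  rows <- lapply(names(queries), function(id) {
    a <- assign_gene_origin(queries[[id]], catalog, min_score, margin, scoring)
    c(list(gene_id = id, assigned = a$assigned, best_score = max(a$scores)),
      stats::setNames(as.list(a$scores), paste0("score_", names(a$scores))))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Summarize origin assignments as per-species fractions
#'
#' @param assignments data.frame from [assign_gene_origins()] (needs an
#'   `assigned` column).
#' @return data.frame (`species`, `n`, `fraction`) including an
#'   `"ambiguous"` class; fractions sum to 1.
#' @export
summarize_origins <- function(assignments) {
  stopifnot(nrow(assignments) >= 1L)
  cls <- assignments$assigned
  lev <- c(setdiff(sort(unique(cls)), "ambiguous"), "ambiguous")
  tab <- table(factor(cls, levels = lev))
  data.frame(species = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify gene families by presence/absence across species
#'
#' Pan-genome classes: `core` = present in every species, `specific` =
#' present in exactly one, `dispensable` = anything in between.
#'
#' @param mat families x species matrix (or data.frame) of 0/1 or logical
#'   presence calls; at least two species columns, each family present
#'   somewhere.
#' @return list with `classes` (named character vector per family),
#'   `counts` (named vector `core`, `dispensable`, `specific`) and
#'   `specific_by_species` (named integer vector).
#' @export
classify_families <- function(mat) {
  m <- as.matrix(mat) > 0
  if (ncol(m) < 2L) stop("need at least 2 species columns")
  if (any(rowSums(m) == 0L)) stop("every family must be present in >= 1 species")
  if (is.null(rownames(m))) rownames(m) <- sprintf("fam%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("sp%d", seq_len(ncol(m)))
  ns <- rowSums(m)
  classes <- ifelse(ns == ncol(m), "core",
                    ifelse(ns == 1L, "specific", "dispensable"))
  names(classes) <- rownames(m)
  spec <- m[ns == 1L, , drop = FALSE]
  specific_by_species <- colSums(spec)
  counts <- c(core = sum(classes == "core"),
              dispensable = sum(classes == "dispensable"),
              specific = sum(classes == "specific"))
  list(classes = classes, counts = counts,
       specific_by_species = specific_by_species)
}

#' Read a presence/absence matrix from TSV
#'
#' Families in rows (first column = family id), species in columns, cells
#' 0/1.
#'
#' @param path file path.
#' @return integer matrix with family rownames.
#' @export
read_presence_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}
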