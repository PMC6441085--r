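# Codon-usage-bias statistics: Wright's effective number of codons (Nc)
# from within-family codon homozygosity, and the codon deviation
# coefficient (CDC) comparing observed usage with the usage expected from
# positional GC and purine contents alone.

#' Count sense codons in an in-frame sequence
#'
#' Codons containing `N` or gap characters are skipped; a terminal stop
#' codon is ignored; an internal stop codon is an error (QC upstream
#' should have rejected it).
#'
#' @param sequence nucleotide string (length divisible by 3) or a
#'   character vector of codons.
#' @return Named integer vector of counts over the 61 sense codons, with
#'   attribute `skipped` (codons containing N/gap).
#' @export
codon_counts <- function(sequence) {
  cods <- if (length(sequence) == 1L && nchar(sequence[1]) > 3L) {
    split_codons(toupper(sequence))
  } else {
    toupper(sequence)
  }
  n <- length(cods)
  if (n && cods[n] %in% STOP_CODONS) cods <- cods[-n]
  stop_at <- which(cods %in% STOP_CODONS)
  if (length(stop_at)) {
    stop("internal stop codon at codon index ", stop_at[1] - 1L,
         " (0-based)", call. = FALSE)
  }
  sp <- codon_space()
  idx <- match(cods, sp$codons)
  skipped <- sum(is.na(idx))
  counts <- tabulate(idx, nbins = 61L)
  names(counts) <- sp$codons
  attr(counts, "skipped") <- skipped
  counts
}

#' Wright's effective number of codons (Nc)
#'
#' Per amino acid with at least two observations, the codon homozygosity
#' is estimated as `F = (n * sum(p_i^2) - 1) / (n - 1)`; class means over
#' the degeneracy classes (2-fold: 9 amino acids; 3-fold: Ile; 4-fold: 5
#' amino acids; 6-fold: Leu, Ser, Arg) give
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. Nc runs from 20 (every amino
#' acid uses a single codon: maximal bias) to 61 (uniform synonymous
#' usage: no bias); finite-sample estimates above 61 are capped at 61.
#'
#' If the 3-fold class (Ile) is unobserved its mean is imputed as
#' `(F2 + F4) / 2`; a missing 2-, 4- or 6-fold class makes Nc `NA`.
#'
#' @param counts 61-vector of sense-codon counts (named or in
#'   lexicographic codon order).
#' @return Nc, or `NA` if undefined for these counts.
#' @export
effective_number_of_codons <- function(counts) {
  sp <- codon_space()
  if (length(counts) != 61L || any(counts < 0)) {
    stop("counts must be 61 non-negative values", call. = FALSE)
  }
  if (!is.null(names(counts))) counts <- counts[sp$codons]
  fam <- split(seq_len(61L), sp$aa)
  deg <- lengths(fam)
  f_hat <- deg_class <- numeric(0)
  for (a in names(fam)) {
    if (deg[[a]] < 2L) next                       # Met, Trp
    cts <- counts[fam[[a]]]
    n <- sum(cts)
    if (n < 2L) next
    p <- cts / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    f_hat <- c(f_hat, f)
    deg_class <- c(deg_class, deg[[a]])
  }
  if (length(f_hat) < 2L) return(NA_real_)
  cls_mean <- function(k) {
    v <- f_hat[deg_class == k]
    if (length(v)) mean(v) else NA_real_
  }
  f2 <- cls_mean(2L)
  f3 <- cls_mean(3L)
  f4 <- cls_mean(4L)
  f6 <- cls_mean(6L)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6))) return(NA_real_)
  if (any(c(f2, f3, f4, f6) <= 0)) return(NA_real_)
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(nc, 61)
}

#' Positional GC and purine contents
#'
#' Per codon position, the fraction of counted codons carrying G/C and the
#' fraction carrying a purine (A/G). Codons with N or gap are skipped.
#'
#' @param sequence nucleotide string or codon vector, in frame.
#' @return List with numeric vectors `gc` and `pur` (length 3 each) and
#'   `n_codons` counted; values are `NA` when no codon could be counted.
#' @export
positional_composition <- function(sequence) {
  cods <- if (length(sequence) == 1L && nchar(sequence[1]) > 3L) {
    split_codons(toupper(sequence))
  } else {
    toupper(sequence)
  }
  n0 <- length(cods)
  if (n0 && cods[n0] %in% STOP_CODONS) cods <- cods[-n0]
  cods <- cods[!grepl("[^ACGT]", cods)]
  if (!length(cods)) {
    return(list(gc = rep(NA_real_, 3), pur = rep(NA_real_, 3),
                n_codons = 0L))
  }
  gc <- pur <- numeric(3)
  for (p in 1:3) {
    nt <- substr(cods, p, p)
    gc[p] <- mean(nt %in% c("G", "C"))
    pur[p] <- mean(nt %in% PURINES)
  }
  list(gc = gc, pur = pur, n_codons = length(cods))
}

#' Expected codon usage from positional GC and purine contents
#'
#' Factorizes each position's nucleotide distribution as
#' `P(G) = gc * pur`, `P(C) = gc * (1 - pur)`, `P(A) = (1 - gc) * pur`,
#' `P(T) = (1 - gc) * (1 - pur)`; a codon's expectation is the product
#' over its three positions. Stop codons are dropped and the vector
#' renormalized over the 61 sense codons.
#'
#' @param gc,pur numeric length-3 vectors of positional GC and purine
#'   proportions (in `[0, 1]`).
#' @return Named 61-vector of expected sense-codon frequencies summing
#'   to 1.
#' @export
expected_codon_usage <- function(gc, pur) {
  stopifnot(length(gc) == 3L, length(pur) == 3L)
  if (any(gc < 0 | gc > 1 | pur < 0 | pur > 1)) {
    stop("gc and pur must lie in [0, 1]", call. = FALSE)
  }
  pos <- matrix(0, 3, 4, dimnames = list(NULL, NUCLEOTIDES))
  for (p in 1:3) {
    pos[p, "G"] <- gc[p] * pur[p]
    pos[p, "C"] <- gc[p] * (1 - pur[p])
    pos[p, "A"] <- (1 - gc[p]) * pur[p]
    pos[p, "T"] <- (1 - gc[p]) * (1 - pur[p])
  }
  sp <- codon_space()
  f <- pos[1L, sp$nuc[, 1L]] * pos[2L, sp$nuc[, 2L]] * pos[3L, sp$nuc[, 3L]]
  tot <- sum(f)
  if (tot <= 0) {
    stop("degenerate composition: every sense codon has expectation 0",
         call. = FALSE)
  }
  stats::setNames(f / tot, sp$codons)
}

#' Codon deviation coefficient (CDC)
#'
#' One minus the cosine similarity between the observed codon-frequency
#' vector and the expected vector over the 61 sense codons; 0 means
#' observed usage matches the composition-driven expectation (no
#' detectable selection on codon usage), 1 means maximal deviation.
#'
#' @param observed 61-vector of codon counts (positive total).
#' @param expected 61-vector of expected frequencies.
#' @return CDC in `[0, 1]`.
#' @export
codon_deviation_coefficient <- function(observed, expected) {
  stopifnot(length(observed) == 61L, length(expected) == 61L)
  sp <- codon_space()
  if (!is.null(names(observed))) observed <- observed[sp$codons]
  if (!is.null(names(expected))) expected <- expected[sp$codons]
  no <- sqrt(sum(observed^2))
  ne <- sqrt(sum(expected^2))
  if (no <= 0 || ne <= 0) {
    stop("zero-norm codon vector; CDC undefined", call. = FALSE)
  }
  cdc <- 1 - sum(observed * expected) / (no * ne)
  min(max(cdc, 0), 1)
}

#' Codon-usage-bias table for a set of alignments
#'
#' Per gene and species: counted codons, Nc, CDC (against the sequence's
#' own positional-composition expectation) and the positional GC/purine
#' contents. Gaps are removed per species before counting. Per-record
#' failures are logged as `NA` rows; the loop continues.
#'
#' @param alignments list of [codon_alignment] objects.
#' @param design optional [study_design]; if given, `mode` and `group`
#'   columns are attached.
#' @return Data frame with columns `gene`, `species`, `n_codons`, `nc`,
#'   `cdc`, `gc1..3`, `pur1..3` (and `mode`, `group` when `design` is
#'   given).
#' @export
cub_table <- function(alignments, design = NULL) {
  rows <- list()
  for (aln in alignments) {
    gene <- attr(aln, "gene_id")
    for (sp_name in names(aln)) {
      seq <- gsub("-", "", unclass(aln)[[sp_name]])
      rec <- tryCatch({
        seq_use <- substr(seq, 1L, (nchar(seq) %/% 3L) * 3L)
        counts <- codon_counts(seq_use)
        comp <- positional_composition(seq_use)
        cdc <- if (comp$n_codons > 0L) {
          codon_deviation_coefficient(
            counts, expected_codon_usage(comp$gc, comp$pur))
        } else NA_real_
        data.frame(gene = gene, species = sp_name,
                   n_codons = comp$n_codons,
                   nc = effective_number_of_codons(counts), cdc = cdc,
                   gc1 = comp$gc[1], gc2 = comp$gc[2], gc3 = comp$gc[3],
                   pur1 = comp$pur[1], pur2 = comp$pur[2],
                   pur3 = comp$pur[3], stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("cub_table: ", gene, "/", sp_name, ": ",
                conditionMessage(e), call. = FALSE)
        data.frame(gene = gene, species = sp_name, n_codons = NA_integer_,
                   nc = NA_real_, cdc = NA_real_, gc1 = NA_real_,
                   gc2 = NA_real_, gc3 = NA_real_, pur1 = NA_real_,
                   pur2 = NA_real_, pur3 = NA_real_,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(design)) {
    m <- match(out$species, design$meta$species)
    out$mode <- design$meta$mode[m]
    out$group <- design$meta$group[m]
  }
  out
}
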