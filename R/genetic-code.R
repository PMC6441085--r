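# Universal genetic code over the 61 sense codons plus the structural
# pairing tables (single-nucleotide neighbours, transition/transversion,
# synonymous/nonsynonymous) shared by the MG94 rate matrix, the sequence
# simulator and the codon-usage statistics.

NUCLEOTIDES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.purisel_cache <- new.env(parent = emptyenv())

#' Codon space of the universal genetic code
#'
#' Returns the cached description of the 61 sense codons: their order
#' (lexicographic in A < C < G < T), translations, per-position nucleotides,
#' and the pairwise structural matrices used by the substitution model
#' (single-nucleotide neighbourhood, transition vs. transversion,
#' synonymous vs. nonsynonymous).
#'
#' @return A list with elements `codons` (61 sense codons), `aa` (their
#'   amino acids, one-letter), `nuc` (61 x 3 character matrix),
#'   `one_diff`, `is_ts`, `is_syn` (61 x 61 logical matrices), and
#'   `aa64`/`codons64` covering the full code.
#' @keywords internal
codon_space <- function() {
  if (!is.null(.purisel_cache$space)) {
    return(.purisel_cache$space)
  }
  codons64 <- apply(expand.grid(NUCLEOTIDES, NUCLEOTIDES, NUCLEOTIDES,
                                stringsAsFactors = FALSE)[, 3:1],
                    1L, paste, collapse = "")
  aa64 <- vapply(codons64, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]])
  }, character(1))
  sense <- !(codons64 %in% STOP_CODONS)
  codons <- codons64[sense]
  aa <- aa64[sense]
  nuc <- t(vapply(strsplit(codons, ""), identity, character(3)))
  rownames(nuc) <- codons

  n <- length(codons)
  ndiff <- matrix(0L, n, n)
  is_ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    same <- outer(nuc[, p], nuc[, p], "==")
    ndiff <- ndiff + !same
    # transition iff both purines or both pyrimidines but unequal
    pur_i <- nuc[, p] %in% PURINES
    ts_p <- outer(pur_i, pur_i, "==") & !same
    is_ts <- is_ts | ts_p
  }
  one_diff <- ndiff == 1L
  is_ts <- is_ts & one_diff
  is_syn <- outer(aa, aa, "==") & one_diff
  dimnames(one_diff) <- dimnames(is_ts) <- dimnames(is_syn) <-
    list(codons, codons)

  .purisel_cache$space <- list(
    codons64 = codons64, aa64 = aa64,
    codons = codons, aa = aa, nuc = nuc,
    one_diff = one_diff, is_ts = is_ts, is_syn = is_syn
  )
  .purisel_cache$space
}

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons in lexicographic order.
#' @export
sense_codons <- function() codon_space()$codons

#' Translate codons to one-letter amino acids
#'
#' @param codons character vector of codons (uppercase ACGT triplets).
#' @return Character vector of one-letter amino acids; `"*"` for stop,
#'   `NA` for codons containing non-ACGT characters.
#' @export
translate_codons <- function(codons) {
  sp <- codon_space()
  out <- sp$aa64[match(codons, sp$codons64)]
  unname(out)
}

# split a nucleotide string into codon triplets
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# indices into the 61 sense codons; NA for codons containing N/gap or stops
codon_indices <- function(codons) {
  match(codons, codon_space()$codons)
}
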