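# Hydrophobicity scoring of amino-acid replacements: a symmetric 20x20
# score matrix in which 100 means identical hydrophobicity and lower
# values mean stronger hydrophobicity change (a proxy for the
# deleteriousness of the replacement); scores below the threshold
# (default 90) are called "dissimilar".

AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Default hydrophobicity scoring matrix
#'
#' `HS(a, b) = round(100 - 100 * |h(a) - h(b)| / (max h - min h))` on the
#' Kyte-Doolittle hydropathy scale: 100 on the diagonal, lower for pairs
#' of increasingly dissimilar hydrophobicity. The scale name is attached
#' as attribute `scale`.
#'
#' @return Symmetric 20 x 20 integer-valued matrix over the standard
#'   amino acids.
#' @export
default_hs_matrix <- function() {
  h <- KYTE_DOOLITTLE[AMINO_ACIDS]
  rng <- max(h) - min(h)
  m <- round(100 - 100 * abs(outer(h, h, "-")) / rng)
  dimnames(m) <- list(AMINO_ACIDS, AMINO_ACIDS)
  attr(m, "scale") <- "Kyte-Doolittle"
  m
}

#' Load (or build) a hydrophobicity scoring matrix
#'
#' @param path TSV with amino-acid row and column labels covering the 20
#'   standard amino acids; `NULL` (default) returns [default_hs_matrix()].
#' @return Validated symmetric matrix of class `hs_matrix` behaviourally
#'   (plain matrix with `scale` attribute).
#' @export
load_hs_matrix <- function(path = NULL) {
  if (is.null(path)) return(default_hs_matrix())
  raw <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(raw)
  if (!setequal(rownames(m), AMINO_ACIDS) ||
      !setequal(colnames(m), AMINO_ACIDS)) {
    stop("HS matrix must be labelled by the 20 standard amino acids",
         call. = FALSE)
  }
  m <- m[AMINO_ACIDS, AMINO_ACIDS]
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("HS matrix entries must be finite numbers", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-9) {
    stop("HS matrix must be symmetric", call. = FALSE)
  }
  attr(m, "scale") <- basename(path)
  m
}

#' Score amino-acid transitions by hydrophobicity change
#'
#' @param transitions data frame from [terminal_transitions()] (columns
#'   `ancestral_aa`, `derived_aa`; other columns carried through).
#' @param matrix HS matrix (default [default_hs_matrix()]).
#' @param threshold transitions with `hs < threshold` are flagged
#'   `dissimilar` (default 90).
#' @return The input records with `hs` and `dissimilar` columns appended;
#'   transitions involving nonstandard amino acids are dropped with a
#'   warning.
#' @export
score_transitions <- function(transitions, matrix = default_hs_matrix(),
                              threshold = 90) {
  stopifnot(is.data.frame(transitions))
  if (nrow(transitions) == 0L) {
    out <- transitions
    out$hs <- numeric(0)
    out$dissimilar <- logical(0)
    return(out)
  }
  ok <- transitions$ancestral_aa %in% AMINO_ACIDS &
        transitions$derived_aa %in% AMINO_ACIDS
  if (any(!ok)) {
    warning(sum(!ok), " transition(s) with nonstandard amino acids skipped",
            call. = FALSE)
  }
  out <- transitions[ok, , drop = FALSE]
  out$hs <- matrix[cbind(out$ancestral_aa, out$derived_aa)]
  out$dissimilar <- out$hs < threshold
  rownames(out) <- NULL
  out
}

#' Summarize hydrophobicity scores per reproductive mode
#'
#' @param records scored transitions from [score_transitions()].
#' @param design a [study_design] mapping species to modes.
#' @return List with `by_mode` (mode, n transitions, mean HS, percent
#'   dissimilar) and `by_species` (the same per species). Modes without
#'   transitions appear with `NA` summaries.
#' @export
summarize_hs <- function(records, design) {
  stopifnot(inherits(design, "study_design"))
  meta <- design$meta[!design$meta$outgroup, ]
  recs <- records[records$species %in% meta$species, , drop = FALSE]
  recs$mode <- meta$mode[match(recs$species, meta$species)]
  one <- function(d) {
    if (nrow(d) == 0L) {
      return(c(n = 0, mean_hs = NA_real_, pct_dissimilar = NA_real_))
    }
    c(n = nrow(d), mean_hs = mean(d$hs),
      pct_dissimilar = 100 * mean(d$dissimilar))
  }
  by_mode <- do.call(rbind, lapply(c("sexual", "asexual"), function(m) {
    data.frame(mode = m, t(one(recs[recs$mode == m, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  by_species <- do.call(rbind, lapply(meta$species, function(s) {
    data.frame(species = s,
               mode = meta$mode[meta$species == s],
               group = meta$group[meta$species == s],
               t(one(recs[recs$species == s, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  rownames(by_mode) <- rownames(by_species) <- NULL
  list(by_mode = by_mode, by_species = by_species)
}
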