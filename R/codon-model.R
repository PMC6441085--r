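# MG94 x HKY codon substitution model: equilibrium frequencies (F3x4),
# rate matrix construction, transition probabilities via eigendecomposition
# of the symmetrized reversible generator, and the synonymous /
# nonsynonymous flux decomposition that converts branch lengths into
# dN and dS.

#' Codon equilibrium frequencies from positional nucleotide compositions
#'
#' The F3x4 construction: the equilibrium frequency of a codon is the
#' product of its nucleotides' frequencies at the three codon positions;
#' stop codons are dropped and the vector renormalized over the 61 sense
#' codons.
#'
#' @param pos_comp 3 x 4 numeric matrix of nucleotide frequencies, rows =
#'   codon positions 1..3, columns named `A`, `C`, `G`, `T`. Rows are
#'   renormalized to sum to 1.
#' @return Named numeric vector of 61 sense-codon frequencies summing to 1.
#' @export
codon_freqs_f3x4 <- function(pos_comp) {
  stopifnot(is.matrix(pos_comp), nrow(pos_comp) == 3L, ncol(pos_comp) == 4L)
  if (is.null(colnames(pos_comp))) colnames(pos_comp) <- NUCLEOTIDES
  pos_comp <- pos_comp[, NUCLEOTIDES, drop = FALSE]
  if (any(pos_comp < 0) || any(rowSums(pos_comp) <= 0)) {
    stop("positional compositions must be non-negative with positive sums",
         call. = FALSE)
  }
  pos_comp <- pos_comp / rowSums(pos_comp)
  sp <- codon_space()
  f <- pos_comp[1L, sp$nuc[, 1L]] *
       pos_comp[2L, sp$nuc[, 2L]] *
       pos_comp[3L, sp$nuc[, 3L]]
  if (sum(f) <= 0) {
    stop("degenerate positional composition: all sense codons have ",
         "frequency 0", call. = FALSE)
  }
  stats::setNames(f / sum(f), sp$codons)
}

#' Construct an MG94 x HKY codon model
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param codon_freqs 61-vector of sense-codon equilibrium frequencies
#'   (renormalized); default uniform.
#' @return Object of class `codon_model` with elements `kappa` and `pi`.
#' @export
codon_model <- function(kappa = 2, codon_freqs = NULL) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  sp <- codon_space()
  if (is.null(codon_freqs)) {
    codon_freqs <- rep(1 / 61, 61)
  }
  if (length(codon_freqs) != 61L || any(codon_freqs < 0) ||
      sum(codon_freqs) <= 0) {
    stop("codon_freqs must be 61 non-negative values with a positive sum",
         call. = FALSE)
  }
  if (!is.null(names(codon_freqs))) {
    if (!setequal(names(codon_freqs), sp$codons)) {
      stop("codon_freqs names must be the 61 sense codons", call. = FALSE)
    }
    codon_freqs <- codon_freqs[sp$codons]
  } else {
    names(codon_freqs) <- sp$codons
  }
  structure(list(kappa = kappa, pi = codon_freqs / sum(codon_freqs)),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat("codon_model (MG94 x HKY): kappa =", signif(x$kappa, 4),
      "| pi: 61 sense codons, GC3 =",
      signif(sum(x$pi[codon_space()$nuc[, 3] %in% c("G", "C")]), 3), "\n")
  invisible(x)
}

#' Build the MG94 rate matrix for a given dN/dS
#'
#' Off-diagonal rate `q_ij` is nonzero only for single-nucleotide changes to
#' a sense codon: `q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]`.
#' With `scale = TRUE` the matrix is rescaled so the expected number of
#' substitutions per codon per unit time at equilibrium is 1.
#'
#' @param model a [codon_model].
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param scale rescale to one expected substitution per codon per unit
#'   branch length (default TRUE).
#' @return 61 x 61 rate matrix with zero row sums.
#' @export
build_rate_matrix <- function(model, omega, scale = TRUE) {
  stopifnot(inherits(model, "codon_model"))
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) ||
      omega < 0) {
    stop("omega must be a single non-negative number", call. = FALSE)
  }
  sp <- codon_space()
  q <- matrix(0, 61L, 61L, dimnames = list(sp$codons, sp$codons))
  q[sp$one_diff] <- rep(model$pi, each = 61L)[sp$one_diff]
  q[sp$is_ts] <- q[sp$is_ts] * model$kappa
  nonsyn <- sp$one_diff & !sp$is_syn
  q[nonsyn] <- q[nonsyn] * omega
  diag(q) <- -rowSums(q)
  if (scale) {
    mu <- -sum(model$pi * diag(q))
    if (mu > 0) q <- q / mu
  }
  q
}

# fraction of equilibrium substitution flux that is nonsynonymous
nonsyn_flux_fraction <- function(model, omega) {
  sp <- codon_space()
  q <- build_rate_matrix(model, omega, scale = FALSE)
  flux <- model$pi * q
  tot <- sum(flux[sp$one_diff])
  if (tot <= 0) return(NA_real_)
  sum(flux[sp$one_diff & !sp$is_syn]) / tot
}

# proportions of nonsynonymous / synonymous "sites" per codon, defined as
# the neutral (omega = 1) mutational-opportunity flux fractions
site_proportions <- function(model) {
  pn <- nonsyn_flux_fraction(model, 1)
  c(nonsyn = pn, syn = 1 - pn)
}

# eigendecomposition of the scaled reversible generator, reusable across
# branch lengths; P(t) = U diag(exp(vals t)) V
rate_decomp <- function(model, omega) {
  q <- build_rate_matrix(model, omega, scale = TRUE)
  pi <- model$pi
  sq <- sqrt(pi)
  b <- q * (sq %o% (1 / sq))        # symmetric for reversible q
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  list(vals = e$values,
       U = e$vectors / sq,          # diag(1/sq) %*% vectors
       V = t(e$vectors * sq))       # t(vectors) %*% diag(sq)
}

# transition probability matrix from a decomposition
pmat_from_decomp <- function(dec, t) {
  p <- dec$U %*% (exp(dec$vals * t) * dec$V)
  p[p < 0] <- 0
  p
}

#' Transition probability matrix of the codon model
#'
#' @param model a [codon_model].
#' @param omega branch dN/dS.
#' @param t branch length in expected substitutions per codon.
#' @return 61 x 61 stochastic matrix.
#' @export
transition_probabilities <- function(model, omega, t) {
  stopifnot(t >= 0)
  p <- pmat_from_decomp(rate_decomp(model, omega), t)
  dimnames(p) <- list(codon_space()$codons, codon_space()$codons)
  p
}

# Convert a fitted branch (t, omega) into CodeML-convention dN and dS:
# dN = t * rhoN(omega) / (3 * LN), dS = t * rhoS(omega) / (3 * LS), where
# rho* are the flux fractions under the branch's own omega and L* the
# neutral site proportions. The ratio dN/dS recovers omega exactly.
branch_dn_ds <- function(model, omega, t) {
  L <- site_proportions(model)
  rho_n <- nonsyn_flux_fraction(model, omega)
  if (is.na(rho_n)) return(c(dN = NA_real_, dS = NA_real_))
  dn <- t * rho_n / (3 * L[["nonsyn"]])
  ds <- t * (1 - rho_n) / (3 * L[["syn"]])
  c(dN = dn, dS = ds)
}
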