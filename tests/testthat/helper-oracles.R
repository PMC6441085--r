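# Independent oracles and small fixtures used across the suite. The
# oracles deliberately avoid the package's own code paths: brute-force
# enumeration for likelihoods and sign assignments, direct formula
# transcriptions for Nc and CDC.

# brute-force phylogenetic likelihood: enumerate all internal-node state
# combinations of an ape tree (any topology, <= 4 tips practical)
brute_force_loglik <- function(aln, tree, model, branch_omega,
                               branch_lengths = NULL) {
  if (is.null(branch_lengths)) branch_lengths <- tree$edge.length
  branch_omega <- rep_len(branch_omega, nrow(tree$edge))
  sp <- sense_codons()
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    transition_probabilities(model, branch_omega[e], branch_lengths[e])
  })
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  cods <- lapply(tree$tip.label, function(s) {
    v <- unclass(aln)[[s]]
    substring(v, seq(1, nchar(v), 3), seq(3, nchar(v), 3))
  })
  n_sites <- length(cods[[1]])
  total_ll <- 0
  combos <- as.matrix(expand.grid(rep(list(1:61), nnode)))
  for (s in seq_len(n_sites)) {
    tipidx <- vapply(cods, function(x) match(x[s], sp), 0L)
    lik <- 0
    for (r in seq_len(nrow(combos))) {
      states <- c(tipidx, combos[r, ])
      pr <- as.numeric(model$pi[combos[r, root - ntip]])
      for (e in seq_len(nrow(tree$edge))) {
        i <- states[tree$edge[e, 1L]]
        j <- states[tree$edge[e, 2L]]
        if (is.na(j)) next                    # missing tip codon
        pr <- pr * P[[e]][i, j]
        if (pr == 0) break
      }
      lik <- lik + pr
    }
    total_ll <- total_ll + log(lik)
  }
  total_ll
}

# direct transcription of Wright's Nc formula, coded independently of the
# package implementation (explicit amino-acid family lists)
oracle_nc <- function(counts) {
  sp <- sense_codons()
  aa <- purisel::translate_codons(sp)
  names(counts) <- sp
  fams <- split(sp, aa)
  fams <- fams[vapply(fams, length, 0L) >= 2L]
  F_by_deg <- list()
  for (f in names(fams)) {
    cts <- counts[fams[[f]]]
    n <- sum(cts)
    if (n < 2) next
    Fh <- (n * sum((cts / n)^2) - 1) / (n - 1)
    k <- as.character(length(fams[[f]]))
    F_by_deg[[k]] <- c(F_by_deg[[k]], Fh)
  }
  mean_or_na <- function(k) {
    if (is.null(F_by_deg[[k]])) NA_real_ else mean(F_by_deg[[k]])
  }
  f2 <- mean_or_na("2"); f3 <- mean_or_na("3")
  f4 <- mean_or_na("4"); f6 <- mean_or_na("6")
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6)) || any(c(f2, f3, f4, f6) <= 0)) {
    return(NA_real_)
  }
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# independent cosine-based CDC
oracle_cdc <- function(obs, expd) {
  o <- as.numeric(obs); e <- as.numeric(expd)
  1 - sum(o * e) / sqrt(sum(o^2) * sum(e^2))
}

# exact two-sided signed-rank p by complete enumeration of sign vectors
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Vs <- as.numeric(signs %*% r)
  tot <- sum(r)
  p_le <- mean(Vs <= V_obs + 1e-9)
  p_ge <- mean(Vs >= V_obs - 1e-9)
  list(V = V_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# neutral expectation of the nonsynonymous/synonymous event ratio under
# kappa = 1, omega = 1, uniform codon frequencies: enumerate all
# single-nucleotide sense-to-sense codon changes
oracle_neutral_ns_ratio <- function() {
  sp <- sense_codons()
  aa <- purisel::translate_codons(sp)
  nuc <- c("A", "C", "G", "T")
  n_syn <- 0L; n_non <- 0L
  for (i in seq_along(sp)) {
    for (pos in 1:3) {
      for (b in nuc) {
        cand <- sp[i]
        substr(cand, pos, pos) <- b
        if (cand == sp[i]) next
        j <- match(cand, sp)
        if (is.na(j)) next                    # stop codon
        if (aa[i] == aa[j]) n_syn <- n_syn + 1L else n_non <- n_non + 1L
      }
    }
  }
  n_non / n_syn
}

# small paired design (3 groups + outgroup, 7 tips) for fast model tests
small_design <- function() {
  tree <- ape::read.tree(text = paste0(
    "((g1_sex:0.2,g1_asex:0.25):0.05,((g2_sex:0.3,g2_asex:0.2):0.06,",
    "(g3_sex:0.25,g3_asex:0.3):0.05):0.04,OG:0.4);"))
  meta <- data.frame(
    species = c("g1_sex", "g1_asex", "g2_sex", "g2_asex", "g3_sex",
                "g3_asex", "OG"),
    mode = c("sexual", "asexual", "sexual", "asexual", "sexual",
             "asexual", "sexual"),
    group = c("g1", "g1", "g2", "g2", "g3", "g3", "og"),
    outgroup = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  study_design(tree, meta)
}

# random in-frame gap-free coding sequence (no stop codons)
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# response table with given genes for permutation tests (paired design)
null_response <- function(n_genes, design = NULL, sd = 1) {
  if (is.null(design)) design <- small_design()
  meta <- design$meta[!design$meta$outgroup, ]
  d <- expand.grid(gene = sprintf("g%02d", seq_len(n_genes)),
                   species = meta$species, stringsAsFactors = FALSE)
  d$mode <- meta$mode[match(d$species, meta$species)]
  d$group <- meta$group[match(d$species, meta$species)]
  d$value <- stats::rnorm(nrow(d), sd = sd)
  d
}
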