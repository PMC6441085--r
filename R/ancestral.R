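# Marginal ancestral codon reconstruction (inside/outside posterior per
# internal node and site) and the extraction of amino-acid transitions
# along terminal branches.

#' Marginal ancestral codon reconstruction
#'
#' Posterior codon distributions for every internal node and site under a
#' fitted free-ratio model, by the inside/outside form of the pruning
#' algorithm. The reported state is the posterior argmax codon, translated
#' to an amino acid. Sites with no data anywhere get a posterior equal to
#' the equilibrium frequencies and are flagged.
#'
#' For rooting, fit the tree rooted at the outgroup (the pipeline does
#' this); marginal posteriors at internal nodes other than the root are
#' invariant to root placement under this reversible model.
#'
#' @param fit a [fit_free_ratio()] result.
#' @param keep_posterior store the full 61-state posterior per node
#'   (default TRUE).
#' @return Object of class `ancestral_assignment`: `nodes` (internal node
#'   labels), `codon` / `aa` (node x site character matrices of argmax
#'   states), `pmax` (node x site matrix of maximum posterior
#'   probabilities), and, if kept, `posterior` (list of 61 x site
#'   matrices, one per internal node).
#' @export
reconstruct_ancestral <- function(fit, keep_posterior = TRUE) {
  stopifnot(inherits(fit, "free_ratio_fit"))
  ctx <- fit$ctx
  pat <- fit$pat
  model <- fit$model
  sp <- codon_space()
  plist <- edge_pmats(ctx, model, fit$edge_t, fit$edge_omega)
  inside <- inside_pass(ctx, plist, pat)
  outside <- outside_pass(ctx, plist, inside, model$pi)
  internal <- (ctx$ntip + 1L):(ctx$ntip + ctx$nnode)
  n_nodes <- length(internal)
  n_sites <- pat$n_sites
  codon <- aa <- matrix(NA_character_, n_nodes, n_sites)
  pmax_m <- matrix(NA_real_, n_nodes, n_sites)
  posterior <- if (keep_posterior) vector("list", n_nodes) else NULL
  for (k in seq_len(n_nodes)) {
    v <- internal[k]
    raw <- outside$O[[v]] * inside$L[[v]]
    tot <- colSums(raw)
    bad <- tot <= 0
    if (any(bad)) raw[, bad] <- model$pi
    post <- sweep(raw, 2L, colSums(raw), "/")
    post_sites <- post[, pat$map, drop = FALSE]
    arg <- max.col(t(post_sites), ties.method = "first")
    codon[k, ] <- sp$codons[arg]
    aa[k, ] <- sp$aa[arg]
    pmax_m[k, ] <- post_sites[cbind(arg, seq_len(n_sites))]
    if (keep_posterior) {
      rownames(post_sites) <- sp$codons
      posterior[[k]] <- post_sites
    }
  }
  labels <- ctx$node_label[internal]
  dimnames(codon) <- dimnames(aa) <- dimnames(pmax_m) <-
    list(labels, NULL)
  if (keep_posterior) names(posterior) <- labels
  structure(list(nodes = labels, codon = codon, aa = aa, pmax = pmax_m,
                 posterior = posterior, gene_id = fit$gene_id),
            class = "ancestral_assignment")
}

#' @export
print.ancestral_assignment <- function(x, ...) {
  cat("ancestral_assignment '", x$gene_id, "': ", length(x$nodes),
      " internal nodes x ", ncol(x$codon), " sites\n", sep = "")
  invisible(x)
}

#' Amino-acid transitions along terminal branches
#'
#' For every terminal branch, compares the observed tip amino acid at each
#' site with the reconstructed amino acid of the branch's parent node and
#' emits one record per site where they differ. Synonymous codon changes
#' produce no record. Sites whose parent reconstruction falls below the
#' posterior threshold, or where the tip codon is missing/ambiguous, are
#' skipped (counted in the `skipped` attribute).
#'
#' @param aln the [codon_alignment] the model was fitted to.
#' @param anc a [reconstruct_ancestral()] result.
#' @param fit the matching [fit_free_ratio()] result.
#' @param posterior_threshold minimum parent-node posterior for a site to
#'   be scored (default 0.5).
#' @return Data frame with columns `gene`, `branch`, `species`, `site`
#'   (0-based codon index), `ancestral_aa`, `derived_aa`; attribute
#'   `skipped` counts low-posterior or missing sites.
#' @export
terminal_transitions <- function(aln, anc, fit, posterior_threshold = 0.5) {
  stopifnot(inherits(anc, "ancestral_assignment"),
            inherits(fit, "free_ratio_fit"))
  ctx <- fit$ctx
  sp_names <- ctx$phy$tip.label
  out <- list()
  skipped <- 0L
  for (tip in seq_len(ctx$ntip)) {
    species <- ctx$node_label[tip]
    e <- ctx$parent_edge[tip]
    parent <- ctx$node_label[ctx$edge[e, 1L]]
    tip_cod <- split_codons(unclass(aln)[[species]])
    tip_aa <- translate_codons(tip_cod)      # NA for N/gap codons
    par_aa <- anc$aa[parent, ]
    par_ok <- anc$pmax[parent, ] >= posterior_threshold
    usable <- !is.na(tip_aa) & par_ok
    skipped <- skipped + sum(!usable)
    hit <- which(usable & tip_aa != par_aa)
    if (length(hit)) {
      out[[species]] <- data.frame(
        gene = fit$gene_id, branch = species, species = species,
        site = hit - 1L,
        ancestral_aa = par_aa[hit], derived_aa = tip_aa[hit],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(0), branch = character(0),
               species = character(0), site = integer(0),
               ancestral_aa = character(0), derived_aa = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
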