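# Felsenstein pruning over the 61 sense-codon states, with per-pattern
# scaling, plus the inside/outside ("two partials") machinery that lets a
# single branch's length or dN/dS be re-optimized by recomputing only that
# branch's transition matrix.

# normalized tree bookkeeping: postorder edge list, children per node
phylo_context <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  root <- ntip + 1L
  edge <- phy$edge
  child_edges <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1L]
    child_edges[[u]] <- c(child_edges[[u]], e)
  }
  node_label <- c(phy$tip.label,
                  if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
                    phy$node.label
                  else paste0("node", root:(ntip + nnode)))
  list(phy = phy, ntip = ntip, nnode = nnode, root = root, edge = edge,
       n_edge = nrow(edge), child_edges = child_edges,
       node_label = node_label,
       parent_edge = match(seq_len(ntip + nnode), edge[, 2L]))
}

# site-pattern compression: matrix of codon indices (tips x patterns, NA =
# missing/ambiguous codon) plus pattern weights
alignment_patterns <- function(aln, tip_labels) {
  miss <- setdiff(tip_labels, names(aln))
  if (length(miss)) {
    stop("alignment lacks sequences for tree tips: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cods <- vapply(unclass(aln)[tip_labels], split_codons,
                 character(attr(aln, "n_codons")))
  if (is.null(dim(cods))) cods <- matrix(cods, nrow = 1L)
  idx_full <- matrix(codon_indices(t(cods)), nrow = length(tip_labels))
  key <- apply(idx_full, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(idx = idx_full[, first, drop = FALSE],
       w = as.numeric(tabulate(map, sum(first))),
       map = map, n_sites = length(key))
}

# per-edge transition matrices; edge_omega recycled to n_edge
edge_pmats <- function(ctx, model, edge_t, edge_omega) {
  edge_omega <- rep_len(edge_omega, ctx$n_edge)
  edge_t <- rep_len(edge_t, ctx$n_edge)
  plist <- vector("list", ctx$n_edge)
  for (om in unique(edge_omega)) {
    dec <- rate_decomp(model, om)
    for (e in which(edge_omega == om)) {
      plist[[e]] <- pmat_from_decomp(dec, edge_t[e])
    }
  }
  plist
}

# P_e %*% L_child for a tip child: pick columns of P, missing codon -> 1
tip_contribution <- function(p, idx, npat) {
  m <- matrix(1, nrow(p), npat)
  ok <- which(!is.na(idx))
  m[, ok] <- p[, idx[ok]]
  m
}

# inside (postorder) pass; returns conditionals, per-edge contributions and
# cumulative log-scalers
inside_pass <- function(ctx, plist, pat) {
  npat <- ncol(pat$idx)
  nn <- ctx$ntip + ctx$nnode
  L <- vector("list", nn)
  ls <- matrix(0, nn, npat)
  C <- vector("list", ctx$n_edge)
  Cls <- matrix(0, ctx$n_edge, npat)
  for (e in seq_len(ctx$n_edge)) {
    v <- ctx$edge[e, 2L]
    u <- ctx$edge[e, 1L]
    if (v <= ctx$ntip) {
      C[[e]] <- tip_contribution(plist[[e]], pat$idx[v, ], npat)
    } else {
      C[[e]] <- plist[[e]] %*% L[[v]]
      Cls[e, ] <- ls[v, ]
    }
    if (is.null(L[[u]])) {
      L[[u]] <- C[[e]]
      ls[u, ] <- Cls[e, ]
    } else {
      L[[u]] <- L[[u]] * C[[e]]
      ls[u, ] <- ls[u, ] + Cls[e, ]
    }
    if (identical(ctx$child_edges[[u]][length(ctx$child_edges[[u]])], e)) {
      # all children folded in: rescale
      mx <- apply(L[[u]], 2L, max)
      mx[mx <= 0] <- 1
      L[[u]] <- sweep(L[[u]], 2L, mx, "/")
      ls[u, ] <- ls[u, ] + log(mx)
    }
  }
  list(L = L, ls = ls, C = C, Cls = Cls, npat = npat)
}

# outside (preorder) pass: O[[v]] is the partial likelihood of everything
# outside the subtree of v, seen at v, including the root frequencies
outside_pass <- function(ctx, plist, inside, pi) {
  npat <- inside$npat
  nn <- ctx$ntip + ctx$nnode
  O <- vector("list", nn)
  os <- matrix(0, nn, npat)
  O[[ctx$root]] <- matrix(pi, 61L, npat)
  for (e in rev(seq_len(ctx$n_edge))) {   # preorder
    u <- ctx$edge[e, 1L]
    v <- ctx$edge[e, 2L]
    out <- O[[u]]
    osum <- os[u, ]
    for (e2 in ctx$child_edges[[u]]) {
      if (e2 != e) {
        out <- out * inside$C[[e2]]
        osum <- osum + inside$Cls[e2, ]
      }
    }
    if (v > ctx$ntip) {
      ov <- crossprod(plist[[e]], out)
      mx <- apply(ov, 2L, max)
      mx[mx <= 0] <- 1
      O[[v]] <- sweep(ov, 2L, mx, "/")
      os[v, ] <- osum + log(mx)
    } else {
      O[[v]] <- out        # outside partial at the parent side of a tip edge
      os[v, ] <- osum
    }
  }
  list(O = O, os = os)
}

# log-likelihood from an inside pass
loglik_from_inside <- function(ctx, inside, pi, pat) {
  lik <- colSums(pi * inside$L[[ctx$root]])
  sum(pat$w * (log(lik) + inside$ls[ctx$root, ]))
}

# full pruning log-likelihood for given per-edge (t, omega)
loglik_edges <- function(ctx, model, edge_t, edge_omega, pat) {
  plist <- edge_pmats(ctx, model, edge_t, edge_omega)
  inside <- inside_pass(ctx, plist, pat)
  loglik_from_inside(ctx, inside, model$pi, pat)
}

# cheap per-edge log-likelihood: everything fixed except edge e's P matrix.
# out/osum come from the outside pass at edge e (the product over the
# parent's other children already folded in).
edge_loglik_factory <- function(ctx, inside, outside, pat, e) {
  u <- ctx$edge[e, 1L]
  v <- ctx$edge[e, 2L]
  out <- outside$O[[u]]
  osum <- outside$os[u, ]
  for (e2 in ctx$child_edges[[u]]) {
    if (e2 != e) {
      out <- out * inside$C[[e2]]
      osum <- osum + inside$Cls[e2, ]
    }
  }
  if (v <= ctx$ntip) {
    idx <- pat$idx[v, ]
    ok <- which(!is.na(idx))
    function(p) {
      lik <- colSums(out)           # missing tip codon: P row-sums to 1
      lik[ok] <- colSums(out[, ok, drop = FALSE] * p[, idx[ok], drop = FALSE])
      sum(pat$w * (log(lik) + osum))
    }
  } else {
    Lv <- inside$L[[v]]
    lsv <- inside$ls[v, ]
    function(p) {
      lik <- colSums(out * (p %*% Lv))
      sum(pat$w * (log(lik) + osum + lsv))
    }
  }
}

#' Pruning log-likelihood of a codon alignment on a tree
#'
#' Sites are independent; each branch carries its own length and dN/dS.
#' Codons containing `N` or gaps contribute partial likelihood 1 for every
#' state (missing data). The root is weighted by the model's equilibrium
#' frequencies; under this reversible model the value does not depend on
#' root placement.
#'
#' @param aln a [codon_alignment] covering all tree tips.
#' @param tree `ape::phylo`; `branch_lengths` defaults to its edge lengths.
#' @param model a [codon_model].
#' @param branch_omega scalar or per-edge vector of dN/dS, in the order of
#'   `tree$edge` rows.
#' @param branch_lengths optional scalar or per-edge vector overriding
#'   `tree$edge.length`, in the order of `tree$edge` rows.
#' @return Log-likelihood (single number).
#' @export
log_likelihood <- function(aln, tree, model, branch_omega = 1,
                           branch_lengths = NULL) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(model, "codon_model"))
  if (is.null(branch_lengths)) branch_lengths <- tree$edge.length
  if (is.null(branch_lengths)) {
    stop("tree has no edge lengths and branch_lengths not given",
         call. = FALSE)
  }
  if (any(branch_lengths < 0)) stop("negative branch length", call. = FALSE)
  branch_lengths <- rep_len(branch_lengths, nrow(tree$edge))
  branch_omega <- rep_len(branch_omega, nrow(tree$edge))
  ctx <- phylo_context(tree)
  # map user edge order (input tree) to postorder edge order
  key_in <- paste(tree$edge[, 1L], tree$edge[, 2L])
  key_po <- paste(ctx$edge[, 1L], ctx$edge[, 2L])
  ord <- match(key_po, key_in)
  pat <- alignment_patterns(aln, ctx$phy$tip.label)
  loglik_edges(ctx, model, branch_lengths[ord], branch_omega[ord], pat)
}
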