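# Maximum-likelihood fitting: a shared-omega fit for kappa and branch
# lengths (initialization stage), then per-branch "free ratio" dN/dS
# refinement, mirroring the fixed-topology branch-model workflow of
# codon-model packages. Branch lengths are in expected substitutions per
# codon under the branch's own omega (each branch's generator is rescaled
# to unit flux), so t and omega are cleanly separable.

OMEGA_BOUNDS <- c(1e-4, 20)
TLEN_BOUNDS <- c(1e-9, 20)

# one sweep of sequential single-branch optimization; fn_param builds the
# edge objective. Shared machinery for branch-length and (t, omega) sweeps.
sweep_branches <- function(ctx, model, edge_t, edge_omega, pat,
                           optimize_omega = FALSE) {
  edge_t <- rep_len(edge_t, ctx$n_edge)
  edge_omega <- rep_len(edge_omega, ctx$n_edge)
  for (e in seq_len(ctx$n_edge)) {
    plist <- edge_pmats(ctx, model, edge_t, edge_omega)
    inside <- inside_pass(ctx, plist, pat)
    outside <- outside_pass(ctx, plist, inside, model$pi)
    f_edge <- edge_loglik_factory(ctx, inside, outside, pat, e)
    # profile optimization: Brent on log t for a fixed omega (decomposition
    # reused across t evaluations), nested in Brent on log omega; brackets
    # are local around the current values and expanded if the optimum
    # lands on a bracket edge
    best_t <- function(om, t0) {
      dec <- rate_decomp(model, om)
      opt <- bracketed_brent(function(lt) {
        -f_edge(pmat_from_decomp(dec, exp(lt)))
      }, log(t0), log(TLEN_BOUNDS), half_width = log(8), tol = 1e-3)
      list(t = exp(opt$minimum), nll = opt$objective)
    }
    if (!optimize_omega) {
      edge_t[e] <- best_t(edge_omega[e], edge_t[e])$t
    } else {
      opt <- bracketed_brent(function(lo) {
        best_t(exp(lo), edge_t[e])$nll
      }, log(edge_omega[e]), log(OMEGA_BOUNDS), half_width = log(10),
      tol = 5e-3)
      edge_omega[e] <- exp(opt$minimum)
      edge_t[e] <- best_t(edge_omega[e], edge_t[e])$t
    }
  }
  list(edge_t = edge_t, edge_omega = edge_omega)
}

# Brent minimization on a local bracket around x0, expanding (up to
# max_expand times) when the optimum lands at a bracket edge
bracketed_brent <- function(f, x0, bounds, half_width, tol,
                            max_expand = 3L) {
  lo <- max(x0 - half_width, bounds[1])
  hi <- min(x0 + half_width, bounds[2])
  for (i in seq_len(max_expand + 1L)) {
    opt <- stats::optimize(f, lower = lo, upper = hi, tol = tol)
    at_lo <- opt$minimum - lo < 2 * tol && lo > bounds[1]
    at_hi <- hi - opt$minimum < 2 * tol && hi < bounds[2]
    if ((!at_lo && !at_hi) || i > max_expand) break
    if (at_lo) lo <- max(lo - 2 * half_width, bounds[1])
    if (at_hi) hi <- min(hi + 2 * half_width, bounds[2])
  }
  opt
}

# shared-omega stage: optimize kappa, omega and all branch lengths
fit_shared <- function(ctx, pat, pi, kappa0, omega0, max_rounds = 3,
                       tol = 1e-2, edge_t = rep(0.1, ctx$n_edge),
                       sweep_lengths = TRUE) {
  kappa <- kappa0
  omega <- omega0
  ll_old <- -Inf
  for (round in seq_len(max_rounds)) {
    model <- codon_model(kappa, pi)
    if (sweep_lengths) {
      sw <- sweep_branches(ctx, model, edge_t, omega, pat,
                           optimize_omega = FALSE)
      edge_t <- sw$edge_t
    }
    opt <- stats::optim(log(c(kappa, omega)), function(par) {
      m <- codon_model(exp(par[1]), pi)
      -loglik_edges(ctx, m, edge_t, exp(par[2]), pat)
    }, method = "Nelder-Mead",
    control = list(maxit = if (sweep_lengths) 50 else 25, reltol = 1e-7))
    kappa <- min(max(exp(opt$par[1]), 0.05), 50)
    omega <- min(max(exp(opt$par[2]), OMEGA_BOUNDS[1]), OMEGA_BOUNDS[2])
    ll <- -opt$value
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(kappa = kappa, omega = omega, edge_t = edge_t, loglik = ll)
}

#' Estimate branch lengths under a shared dN/dS
#'
#' Fixed-topology joint optimization of the transition/transversion ratio,
#' a single tree-wide dN/dS and all branch lengths under the MG94 model.
#' Serves both as a standalone estimator and as the initialization stage of
#' [fit_free_ratio()].
#'
#' @param aln a [codon_alignment].
#' @param tree `ape::phylo` with tips covered by the alignment.
#' @param model optional [codon_model] supplying equilibrium frequencies
#'   and the starting kappa; frequencies default to the alignment's own
#'   F3x4 composition.
#' @param omega_init starting shared dN/dS.
#' @return List with `tree` (edge lengths filled in), `kappa`, `omega`,
#'   `loglik`.
#' @export
estimate_branch_lengths <- function(aln, tree, model = NULL,
                                    omega_init = 0.2) {
  ctx <- phylo_context(tree)
  pat <- alignment_patterns(aln, ctx$phy$tip.label)
  pi <- if (is.null(model)) alignment_f3x4(aln) else model$pi
  kappa0 <- if (is.null(model)) 2 else model$kappa
  fit <- fit_shared(ctx, pat, pi, kappa0, omega_init)
  phy <- ctx$phy
  phy$edge.length <- fit$edge_t
  list(tree = phy, kappa = fit$kappa, omega = fit$omega,
       loglik = fit$loglik)
}

# empirical F3x4 frequencies of an alignment (gaps/N ignored)
alignment_f3x4 <- function(aln) {
  cods <- unlist(lapply(unclass(aln), split_codons), use.names = FALSE)
  cods <- cods[!grepl("[N-]", cods)]
  m <- matrix(0, 3, 4, dimnames = list(NULL, NUCLEOTIDES))
  for (p in 1:3) {
    tab <- table(factor(substr(cods, p, p), levels = NUCLEOTIDES))
    m[p, ] <- as.numeric(tab)
  }
  # light pseudocount keeps rare compositions off the boundary
  codon_freqs_f3x4(m + 0.5)
}

#' Fit the free-ratio branch model
#'
#' Estimates one dN/dS per branch of a fixed topology, along with the
#' transition/transversion ratio and branch lengths, by maximizing the
#' pruning likelihood. A shared-omega fit over a small deterministic grid
#' of starting values initializes the search; per-branch `(t, omega)` are
#' then refined by sequential profile-Brent sweeps (bounded searches on
#' log t nested in log omega, on expanding local brackets) until the
#' log-likelihood gain of a full sweep falls below `tol`.
#'
#' Per branch, dN and dS follow the flux convention: `dN = t * rhoN /
#' (3 LN)` and `dS = t * rhoS / (3 LS)` where `rhoN` is the nonsynonymous
#' fraction of substitution flux under the branch's fitted omega and
#' `LN`/`LS` are the neutral site proportions, so `dN/dS` equals the
#' fitted omega wherever `dS > 0`.
#'
#' @param aln a [codon_alignment].
#' @param tree `ape::phylo` (topology fixed; edge lengths, if any, ignored).
#' @param model_init optional [codon_model] (frequencies, starting kappa);
#'   defaults to the alignment's F3x4 composition.
#' @param gene_id gene label for the branch table; defaults to the
#'   alignment's.
#' @param max_sweeps maximum free-ratio refinement sweeps.
#' @param tol convergence threshold on the log-likelihood change.
#' @param starts matrix of (kappa, omega) starting pairs for the shared
#'   stage; rows are tried in order and the best kept.
#' @return Object of class `free_ratio_fit`: `table` (the per-branch rate
#'   table, see below), `model`, `loglik`, `tree` (with fitted lengths),
#'   plus internal state reused by [reconstruct_ancestral()] and
#'   [flag_positive_selection()]. The table has one row per branch with
#'   columns `gene`, `branch`, `parent`, `child`, `species`, `terminal`,
#'   `t`, `omega`, `dN`, `dS`, `excl_internal`, `excl_omega_gt1`,
#'   `flag_sat`.
#' @export
fit_free_ratio <- function(aln, tree, model_init = NULL, gene_id = NULL,
                           max_sweeps = 8, tol = 1e-2,
                           starts = cbind(kappa = c(2, 1, 4),
                                          omega = c(0.2, 0.05, 0.5))) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(tree$tip.label) < 3L) {
    stop("free-ratio fitting needs at least 3 tips", call. = FALSE)
  }
  if (is.null(gene_id)) gene_id <- attr(aln, "gene_id")
  ctx <- phylo_context(tree)
  pat <- alignment_patterns(aln, ctx$phy$tip.label)
  pi <- if (is.null(model_init)) alignment_f3x4(aln) else model_init$pi

  # stage 1: coarse shared-omega multistart (branch lengths fixed at the
  # common initial value), then full refinement of the winner
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    cand <- fit_shared(ctx, pat, pi, starts[s, 1], starts[s, 2],
                       max_rounds = 1, sweep_lengths = FALSE)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  best <- fit_shared(ctx, pat, pi, best$kappa, best$omega, max_rounds = 2)
  kappa <- best$kappa
  edge_t <- best$edge_t
  edge_omega <- rep(best$omega, ctx$n_edge)
  model <- codon_model(kappa, pi)
  ll <- loglik_edges(ctx, model, edge_t, edge_omega, pat)

  # stage 2: per-branch (t, omega) refinement
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    sw <- sweep_branches(ctx, model, edge_t, edge_omega, pat,
                         optimize_omega = TRUE)
    edge_t <- sw$edge_t
    edge_omega <- sw$edge_omega
    if (sweep == 1L) {
      # one kappa re-optimization under the free ratios
      opt <- stats::optimize(function(lk) {
        -loglik_edges(ctx, codon_model(exp(lk), pi), edge_t, edge_omega, pat)
      }, lower = log(0.2), upper = log(20), tol = 1e-4)
      kappa <- exp(opt$minimum)
      model <- codon_model(kappa, pi)
    }
    ll_new <- loglik_edges(ctx, model, edge_t, edge_omega, pat)
    if (abs(ll_new - ll) < max(tol, 1e-6)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  tab <- branch_rate_table(ctx, model, edge_t, edge_omega, gene_id)
  structure(list(table = tab, model = model, loglik = ll,
                 tree = within_tree(ctx, edge_t), converged = converged,
                 ctx = ctx, pat = pat, edge_t = edge_t,
                 edge_omega = edge_omega, gene_id = gene_id),
            class = "free_ratio_fit")
}

within_tree <- function(ctx, edge_t) {
  phy <- ctx$phy
  phy$edge.length <- edge_t
  phy
}

# assemble the per-branch rate table from fitted (t, omega)
branch_rate_table <- function(ctx, model, edge_t, edge_omega, gene_id) {
  n <- ctx$n_edge
  child <- ctx$edge[, 2L]
  parent <- ctx$edge[, 1L]
  terminal <- child <= ctx$ntip
  species <- ifelse(terminal, ctx$node_label[child], NA_character_)
  dn <- ds <- numeric(n)
  for (e in seq_len(n)) {
    v <- branch_dn_ds(model, edge_omega[e], edge_t[e])
    dn[e] <- v[["dN"]]
    ds[e] <- v[["dS"]]
  }
  omega_rep <- ifelse(ds > 1e-8, dn / ds, NA_real_)
  tab <- data.frame(
    gene = gene_id,
    branch = ctx$node_label[child],
    parent = ctx$node_label[parent],
    child = ctx$node_label[child],
    species = species,
    terminal = terminal,
    t = edge_t,
    omega = omega_rep,
    dN = dn,
    dS = ds,
    excl_internal = !terminal,
    excl_omega_gt1 = terminal & !is.na(omega_rep) & omega_rep > 1,
    flag_sat = ds > 3,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  tab
}

#' @export
print.free_ratio_fit <- function(x, ...) {
  cat("free_ratio_fit '", x$gene_id, "': logL = ", signif(x$loglik, 8),
      ", kappa = ", signif(x$model$kappa, 4), ", ",
      nrow(x$table), " branches (median omega ",
      signif(stats::median(x$table$omega, na.rm = TRUE), 3), ")\n",
      sep = "")
  invisible(x)
}

#' Flag a gene for positive selection
#'
#' A gene is flagged when some branch's fitted dN/dS exceeds 1 with
#' likelihood-ratio support: the branch is refit with its dN/dS capped at 1
#' (length re-optimized) and the gene is flagged if twice the
#' log-likelihood drop exceeds the one-sided 5% chi-square(1) threshold
#' 2.71. Genes so flagged are excluded from the downstream mode
#' comparisons.
#'
#' @param fit a [fit_free_ratio()] result.
#' @param threshold LRT threshold on `2 * delta logL` (default 2.71).
#' @return Logical scalar; attribute `detail` holds the per-branch LRT
#'   table for the tested branches.
#' @export
flag_positive_selection <- function(fit, threshold = 2.71) {
  stopifnot(inherits(fit, "free_ratio_fit"))
  cand <- which(fit$edge_omega > 1 & fit$table$dS > 1e-8)
  detail <- data.frame(branch = character(0), omega = numeric(0),
                       lrt = numeric(0), flagged = logical(0))
  flagged <- FALSE
  ctx <- fit$ctx
  model <- fit$model
  for (e in cand) {
    plist <- edge_pmats(ctx, model, fit$edge_t, fit$edge_omega)
    inside <- inside_pass(ctx, plist, fit$pat)
    outside <- outside_pass(ctx, plist, inside, model$pi)
    f_edge <- edge_loglik_factory(ctx, inside, outside, fit$pat, e)
    ll_free <- f_edge(plist[[e]])
    dec1 <- rate_decomp(model, 1)
    opt <- stats::optimize(function(lt) {
      -f_edge(pmat_from_decomp(dec1, exp(lt)))
    }, lower = log(TLEN_BOUNDS[1]), upper = log(TLEN_BOUNDS[2]), tol = 1e-6)
    lrt <- 2 * (ll_free - (-opt$objective))
    lrt <- max(lrt, 0)
    hit <- lrt > threshold
    detail <- rbind(detail, data.frame(
      branch = fit$table$branch[e], omega = fit$edge_omega[e],
      lrt = lrt, flagged = hit))
    flagged <- flagged || hit
  }
  structure(flagged, detail = detail)
}
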