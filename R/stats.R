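# Statistical comparisons between reproductive modes: branch filtering,
# permutation ANOVA (sequential sums of squares, response permuted
# wholesale), exact Wilcoxon signed-rank tests, per-group paired
# comparisons with Delta(sex - asex) reporting, and a paired sign-flip
# permutation test for per-species summaries.

#' Filter a branch rate table to the comparable terminal branches
#'
#' Keeps terminal branches only, drops branches with fitted dN/dS above 1
#' (putative positive selection) or with undefined dN/dS (dS numerically
#' zero), and attaches reproductive mode and group labels. Internal
#' branches are excluded because, in a paired design, they are not
#' attributable to either reproductive mode.
#'
#' @param table branch rate table from [fit_free_ratio()] (possibly
#'   row-bound over genes).
#' @param design a [study_design].
#' @param measure which column becomes `value`: `"omega"` (default),
#'   `"dS"` or `"dN"`.
#' @return Response data frame with columns `gene`, `species`, `mode`,
#'   `group`, `value`; attribute `n_removed` counts dropped rows.
#' @export
filter_branches <- function(table, design, measure = c("omega", "dS", "dN")) {
  measure <- match.arg(measure)
  stopifnot(is.data.frame(table), inherits(design, "study_design"))
  keep <- table$terminal &
    !is.na(table$omega) & table$omega <= 1 &
    table$dS > 0
  out <- table[keep, , drop = FALSE]
  meta <- design$meta
  m <- match(out$species, meta$species)
  res <- data.frame(gene = out$gene, species = out$species,
                    mode = meta$mode[m], group = meta$group[m],
                    value = out[[measure]], stringsAsFactors = FALSE)
  res <- res[!meta$outgroup[m], , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res) == 0L) {
    warning("no branches left after filtering", call. = FALSE)
  }
  attr(res, "n_removed") <- nrow(table) - nrow(res)
  res
}

#' Permutation ANOVA of a response over gene, mode and group
#'
#' Fits `value ~ gene + mode + group + mode:group` by least squares with
#' sequential (type I) sums of squares in that order, and obtains the
#' permutation null of each term's F statistic by permuting the response
#' vector wholesale `n_perm` times (`scheme = "raw"`, the default) or by
#' Freedman-Lane residual permutation under the reduced model for each
#' term (`scheme = "freedman_lane"`).  P-values use the add-one rule
#' `p = (1 + #[F* >= F]) / (1 + n_perm)`.
#'
#' @param table response table from [filter_branches()] (columns `gene`,
#'   `mode`, `group`, `value`).
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed (required for reproducibility).
#' @param scheme `"raw"` or `"freedman_lane"`.
#' @return Object of class `perm_anova`: data frame with one row per term
#'   (`gene`, `mode`, `group`, `mode:group`), columns `df`, `F`, `p`;
#'   attributes `n_perm`, `seed`, `scheme`.
#' @export
permutation_anova <- function(table, n_perm = 5000, seed = 1,
                              scheme = c("raw", "freedman_lane")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(table), n_perm >= 1)
  d <- data.frame(gene = factor(table$gene), mode = factor(table$mode),
                  group = factor(table$group), value = table$value)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  for (f in c("gene", "mode", "group")) {
    if (nlevels(droplevels(d[[f]])) < 2L) {
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  terms <- c("gene", "mode", "group", "mode:group")
  forms <- list(~gene, ~gene + mode, ~gene + mode + group,
                ~gene + mode + group + mode:group)
  X <- lapply(forms, function(f) stats::model.matrix(f, d))
  p_cum <- vapply(X, function(x) qr(x)$rank, 0L)
  df_term <- diff(c(1L, p_cum))
  if (any(df_term <= 0L)) {
    stop("rank-deficient design: term '",
         terms[which(df_term <= 0L)[1]], "' is aliased", call. = FALSE)
  }
  n <- nrow(d)
  df_res <- n - p_cum[4]
  if (df_res <= 0L) stop("no residual degrees of freedom", call. = FALSE)
  # orthonormal bases for the cumulative models
  Q <- lapply(X, function(x) qr.Q(qr(x)))
  ss_terms <- function(y) {
    tot <- sum(y^2) - length(y) * mean(y)^2
    cum <- vapply(Q, function(q) sum(crossprod(q, y)^2), 0)
    ss <- diff(c(length(y) * mean(y)^2, cum))
    c(ss, tot - sum(ss))
  }
  y <- d$value
  if (stats::var(y) == 0) {
    out <- data.frame(term = terms, df = df_term, F = 0, p = 1,
                      stringsAsFactors = FALSE)
    return(structure(out, n_perm = n_perm, seed = seed, scheme = scheme,
                     class = c("perm_anova", "data.frame")))
  }
  ss_obs <- ss_terms(y)
  F_obs <- (ss_obs[1:4] / df_term) / (ss_obs[5] / df_res)

  set.seed(seed)
  count_ge <- rep(0L, 4L)
  if (scheme == "raw") {
    # all permutations as one matrix; crossprod once per cumulative model
    block <- 1000L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      Y <- vapply(seq_len(b), function(i) sample(y), numeric(n))
      cum <- vapply(Q, function(q) colSums(crossprod(q, Y)^2),
                    numeric(b))
      if (b == 1L) cum <- matrix(cum, nrow = 1L)
      mean_ss <- n * colMeans(Y)^2
      tot <- colSums(Y^2) - mean_ss
      ss <- cbind(cum[, 1] - mean_ss, cum[, 2] - cum[, 1],
                  cum[, 3] - cum[, 2], cum[, 4] - cum[, 3])
      res <- tot - rowSums(ss)
      Fs <- sweep(ss, 2L, df_term, "/") / (res / df_res)
      count_ge <- count_ge +
        colSums(Fs >= matrix(F_obs, b, 4L, byrow = TRUE) - 1e-12)
      done <- done + b
    }
  } else {
    # Freedman-Lane: permute residuals of the reduced (previous) model
    for (k in seq_len(4L)) {
      qk <- Q[[k]]
      q_prev <- if (k == 1L) matrix(1 / sqrt(n), n, 1L) else Q[[k - 1L]]
      fit_prev <- q_prev %*% crossprod(q_prev, y)
      res_prev <- y - fit_prev
      for (b in seq_len(n_perm)) {
        ystar <- fit_prev + sample(res_prev)
        ss <- ss_terms(ystar)
        Fstar <- (ss[k] / df_term[k]) / (ss[5] / df_res)
        if (Fstar >= F_obs[k] - 1e-12) count_ge[k] <- count_ge[k] + 1L
      }
    }
  }
  p <- (1 + count_ge) / (1 + n_perm)
  out <- data.frame(term = terms, df = df_term, F = F_obs, p = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_perm = n_perm, seed = seed, scheme = scheme,
            class = c("perm_anova", "data.frame"))
}

#' Wilcoxon signed-rank test with exact tied-rank null
#'
#' Zero differences are discarded; tied absolute differences get
#' mid-ranks; `V` is the sum of ranks of positive differences. For up to
#' 15 nonzero pairs the two-sided p-value is exact, from the full
#' distribution of `V` over all sign assignments (computed by convolution,
#' equivalent to complete enumeration and correct under ties); beyond
#' that, a normal approximation with continuity and tie correction is
#' used.
#'
#' @param x,y paired observations, or `y = NULL` to treat `x` as
#'   differences.
#' @return List with `V`, `p`, `n` (nonzero pairs), `direction`
#'   (`"x_lower"`, `"y_lower"` or `"none"`), `method`, and `degenerate`
#'   (TRUE when all differences are zero: `V = 0`, `p = 1`).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(V = 0, p = 1, n = 0L, direction = "none",
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  tot <- sum(r)
  if (n <= 15L) {
    # distribution of V over all 2^n sign assignments via convolution on
    # doubled (hence integer) ranks
    r2 <- as.integer(round(2 * r))
    dist <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(length(dist) - ri)])
      dist <- dist + shifted
    }
    v2 <- round(2 * V)
    p_le <- sum(dist[seq_len(v2 + 1L)]) / 2^n
    p_ge <- sum(dist[(v2 + 1L):length(dist)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- tot / 2
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  direction <- if (V < tot / 2) "x_lower" else if (V > tot / 2) "y_lower"
               else "none"
  list(V = V, p = p, n = n, direction = direction, method = method,
       degenerate = FALSE)
}

#' Per-group paired comparison of modes
#'
#' Within each group, pairs each gene's sexual and asexual values and runs
#' a Wilcoxon signed-rank test; also emits the per-gene
#' `Delta = sexual - asexual` table used for distribution summaries.
#'
#' @param table response table from [filter_branches()].
#' @param min_pairs groups with fewer complete pairs are flagged `low_n`
#'   (default 5).
#' @return List with `tests` (group, n_pairs, V, p, direction, low_n) and
#'   `delta` (gene, group, sexual, asexual, delta).
#' @export
paired_mode_comparison_by_group <- function(table, min_pairs = 5) {
  stopifnot(is.data.frame(table))
  groups <- sort(unique(table$group))
  tests <- list()
  deltas <- list()
  for (g in groups) {
    d <- table[table$group == g, , drop = FALSE]
    sx <- d[d$mode == "sexual", c("gene", "value")]
    ax <- d[d$mode == "asexual", c("gene", "value")]
    merged <- merge(sx, ax, by = "gene", suffixes = c("_sex", "_asex"))
    merged <- merged[stats::complete.cases(merged), , drop = FALSE]
    n <- nrow(merged)
    if (n > 0L) {
      w <- wilcoxon_signed_rank(merged$value_sex, merged$value_asex)
      deltas[[g]] <- data.frame(
        gene = merged$gene, group = g, sexual = merged$value_sex,
        asexual = merged$value_asex,
        delta = merged$value_sex - merged$value_asex,
        stringsAsFactors = FALSE)
      dir <- switch(w$direction, x_lower = "sexual_lower",
                    y_lower = "asexual_lower", "none")
    } else {
      w <- list(V = NA_real_, p = NA_real_, n = 0L)
      dir <- "none"
    }
    tests[[g]] <- data.frame(group = g, n_pairs = n, V = w$V, p = w$p,
                             direction = dir, low_n = n < min_pairs,
                             stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  delta <- if (length(deltas)) do.call(rbind, deltas) else
    data.frame(gene = character(0), group = character(0),
               sexual = numeric(0), asexual = numeric(0),
               delta = numeric(0))
  rownames(tests) <- rownames(delta) <- NULL
  list(tests = tests, delta = delta)
}

#' Paired sign-flip permutation test across groups
#'
#' Tests whether per-species summaries differ between modes: the statistic
#' is the mean within-group (sexual - asexual) difference; the null is
#' built by flipping the sign of each group's difference. All `2^G` flips
#' are enumerated when feasible (`2^G <= n_perm`), otherwise `n_perm`
#' random flips are drawn; p-values are two-sided, with the add-one rule
#' in the sampled case.
#'
#' @param summaries data frame with columns `group`, `mode`, `value`
#'   (one row per species), e.g. `by_species` from [summarize_hs()] with
#'   `value = mean_hs`.
#' @param n_perm permutation budget (default 5000).
#' @param seed RNG seed for the sampled case.
#' @return List with `statistic` (observed mean difference), `p`,
#'   `n_groups`, `method`.
#' @export
paired_permutation_test <- function(summaries, n_perm = 5000, seed = 1) {
  stopifnot(is.data.frame(summaries),
            all(c("group", "mode", "value") %in% names(summaries)))
  sx <- summaries[summaries$mode == "sexual", c("group", "value")]
  ax <- summaries[summaries$mode == "asexual", c("group", "value")]
  merged <- merge(sx, ax, by = "group", suffixes = c("_sex", "_asex"))
  merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  diffs <- merged$value_sex - merged$value_asex
  G <- length(diffs)
  if (G < 2L) stop("need at least 2 groups with both modes", call. = FALSE)
  obs <- mean(diffs)
  if (all(diffs == 0)) {
    return(list(statistic = 0, p = 1, n_groups = G, method = "degenerate"))
  }
  if (2^G <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), G)))
    stats_null <- as.numeric(signs %*% diffs) / G
    p <- mean(abs(stats_null) >= abs(obs) - 1e-12)
    method <- "exact"
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      s <- sample(c(-1, 1), G, replace = TRUE)
      if (abs(mean(s * diffs)) >= abs(obs) - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    method <- "sampled"
  }
  list(statistic = obs, p = p, n_groups = G, method = method)
}
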