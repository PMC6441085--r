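# MG94 rate matrix structure, pruning likelihood against brute-force
# enumeration, and the small-scale behaviour of the fitting routines.

test_that("rate matrix has MG94 structure", {
  m <- codon_model(kappa = 3)
  q <- build_rate_matrix(m, omega = 0.4)
  expect_identical(q["ATT", "GGG"], 0)          # two positions differ
  expect_lt(max(abs(rowSums(q))), 1e-12)
  expect_equal(-sum(m$pi * diag(q)), 1, tolerance = 1e-12)
  # reversibility
  f <- m$pi * q
  expect_lt(max(abs(f - t(f))), 1e-15)
  # no rate into stop codons: TAA etc are absent from the state space
  expect_false(any(colnames(q) %in% c("TAA", "TAG", "TGA")))
  expect_error(build_rate_matrix(m, -0.1), "non-negative")

  # kappa = 1, omega = 1, uniform pi: all allowed entries equal (unscaled)
  q1 <- build_rate_matrix(codon_model(kappa = 1), 1, scale = FALSE)
  off <- q1[upper.tri(q1) | lower.tri(q1)]
  expect_identical(sort(unique(round(off[off > 0], 15))),
                   round(1 / 61, 15))
})

test_that("transition probabilities behave like a stochastic semigroup", {
  m <- codon_model(2, codon_freqs_f3x4(default_pos_composition()))
  p0 <- transition_probabilities(m, 0.3, 0)
  expect_equal(p0, diag(61), ignore_attr = TRUE, tolerance = 1e-12)
  p <- transition_probabilities(m, 0.3, 0.7)
  expect_equal(rowSums(p), rep(1, 61), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(p >= 0))
  # Chapman-Kolmogorov
  p2 <- transition_probabilities(m, 0.3, 0.35)
  expect_equal(p2 %*% p2, p, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("zero-length star tree gives the closed-form likelihood", {
  m <- codon_model(2, codon_freqs_f3x4(default_pos_composition()))
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  seq <- random_cds(20, seed = 5)
  aln <- codon_alignment(c(A = seq, B = seq, C = seq))
  idx <- match(substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3)),
               sense_codons())
  expect_equal(log_likelihood(aln, tr, m), sum(log(m$pi[idx])),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to rooting and tip order", {
  m <- codon_model(1.5, codon_freqs_f3x4(default_pos_composition()))
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.05):0.2);")
  set.seed(9)
  seqs <- vapply(1:4, function(i) random_cds(15), character(1))
  names(seqs) <- c("A", "B", "C", "D")
  aln <- codon_alignment(seqs)
  ll <- log_likelihood(aln, tr, m, branch_omega = 0.3)
  for (og in c("A", "C", "D")) {
    rerooted <- ape::root(tr, og, resolve.root = TRUE)
    expect_equal(log_likelihood(aln, rerooted, m, branch_omega = 0.3), ll,
                 tolerance = 1e-8)
  }
  aln_perm <- codon_alignment(seqs[c("D", "B", "A", "C")])
  expect_equal(log_likelihood(aln_perm, tr, m, branch_omega = 0.3), ll,
               tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(31)
  m <- codon_model(2.2, codon_freqs_f3x4(default_pos_composition()))
  cases <- list(
    list(tree = "(A:0.2,B:0.4,C:0.3);", tips = c("A", "B", "C")),
    list(tree = "((A:0.1,B:0.25):0.15,(C:0.3,D:0.1):0.2);",
         tips = c("A", "B", "C", "D")),
    list(tree = "(A:0.15,B:0.2,C:0.25,D:0.1);",
         tips = c("A", "B", "C", "D")))
  for (cs in cases) {
    tr <- ape::read.tree(text = cs$tree)
    for (nsites in c(1L, 3L)) {
      seqs <- vapply(cs$tips, function(s) random_cds(nsites), character(1))
      aln <- codon_alignment(seqs)
      om <- stats::runif(nrow(tr$edge), 0.05, 1.5)
      ll <- log_likelihood(aln, tr, m, branch_omega = om)
      bll <- brute_force_loglik(aln, tr, m, branch_omega = om)
      expect_equal(ll, bll, tolerance = 1e-8)
    }
  }
})

test_that("codons with N or gaps act as missing data", {
  m <- codon_model(2)
  tr <- ape::read.tree(text = "(A:0.2,B:0.4,C:0.3);")
  aln_full <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATGAAC"))
  aln_na <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATGNN-"))
  ll_na <- log_likelihood(aln_na, tr, m, branch_omega = 0.5)
  bll <- brute_force_loglik(aln_na, tr, m, branch_omega = 0.5)
  expect_equal(ll_na, bll, tolerance = 1e-8)
  expect_gt(ll_na, log_likelihood(aln_full, tr, m, branch_omega = 0.5))
})

test_that("branch lengths shrink to zero for invariant alignments", {
  seq <- random_cds(40, seed = 3)
  aln <- codon_alignment(c(A = seq, B = seq, C = seq, D = seq))
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  est <- estimate_branch_lengths(aln, tr)
  expect_lt(max(est$tree$edge.length), 1e-6)

  fit <- fit_free_ratio(aln, tr)
  expect_lt(max(fit$table$t), 1e-6)
  expect_lt(max(fit$table$dN), 1e-6)
  expect_lt(max(fit$table$dS), 1e-6)
  expect_true(all(is.na(fit$table$omega)))      # dS ~ 0: omega undefined
})

test_that("fitted branch length increases with simulated divergence", {
  design <- small_design()
  lens <- c(0.05, 0.2, 0.6)
  fitted <- vapply(seq_along(lens), function(i) {
    tr <- ape::read.tree(text = sprintf("(A:%g,B:%g,C:0.05);",
                                        lens[i] / 2, lens[i] / 2))
    m <- codon_model(2, codon_freqs_f3x4(default_pos_composition()))
    sc <- local({
      d <- design
      s <- build_scenario(d, omega = 0.2, n_genes = 1, n_codons = 250,
                          seed = 100 + i)
      s$tree <- tr
      s$branch_omega <- rep(0.2, nrow(tr$edge))
      s
    })
    g <- simulate_gene(sc, 1)
    est <- estimate_branch_lengths(g$alignment, tr)
    sum(est$tree$edge.length[tr$edge[, 2] <= 2])   # A-B path length
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("dN/dS bookkeeping is internally consistent", {
  sc <- build_scenario(small_design(), omega = 0.15, n_genes = 1,
                       n_codons = 150, seed = 21)
  g <- simulate_gene(sc, 1)
  fit <- fit_free_ratio(g$alignment, sc$tree)
  tab <- fit$table
  expect_true(all(tab$dN >= 0 & tab$dS >= 0))
  ok <- !is.na(tab$omega) & tab$dS > 1e-8
  expect_true(any(ok))
  expect_equal(tab$omega[ok], tab$dN[ok] / tab$dS[ok], tolerance = 1e-6)
  expect_identical(tab$excl_internal, !tab$terminal)
  expect_true(all(is.na(tab$species) == !tab$terminal))
})

test_that("genes without high-omega branches are not flagged", {
  sc <- build_scenario(small_design(), omega = 0.1, n_genes = 1,
                       n_codons = 120, seed = 34)
  g <- simulate_gene(sc, 1)
  fit <- fit_free_ratio(g$alignment, sc$tree)
  expect_true(all(fit$table$omega <= 1, na.rm = TRUE))
  flag <- flag_positive_selection(fit)
  expect_false(as.logical(flag))
  expect_identical(nrow(attr(flag, "detail")), 0L)
})

test_that("a strongly positively selected branch is flagged", {
  sc <- build_scenario(small_design(), omega = 0.15, n_genes = 1,
                       n_codons = 300, seed = 77)
  # put omega = 5 on one terminal branch
  tipedge <- which(sc$tree$edge[, 2] ==
                     match("g2_sex", sc$tree$tip.label))
  sc$branch_omega[tipedge] <- 5
  g <- simulate_gene(sc, 1)
  fit <- fit_free_ratio(g$alignment, sc$tree)
  flag <- flag_positive_selection(fit)
  expect_true(as.logical(flag))
  detail <- attr(flag, "detail")
  expect_true(all(detail$lrt >= 0))             # cap fit never beats free fit
  expect_true("g2_sex" %in% detail$branch[detail$flagged])
})
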