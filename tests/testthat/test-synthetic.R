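# Scenario construction, codon-level simulation (event counts, stop-free
# sequences, determinism), equilibrium behaviour and dataset writing.

test_that("scenarios resolve per-branch omegas from the design", {
  d <- default_design()
  sc <- build_scenario(d, omega = 0.03, meltdown = 1, n_genes = 1)
  expect_true(all(sc$branch_omega == 0.03))
  sc3 <- build_scenario(d, omega = 0.03, meltdown = 3, n_genes = 1)
  ntip <- length(sc3$tree$tip.label)
  tip_edges <- sc3$tree$edge[, 2] <= ntip
  labels <- sc3$tree$tip.label[sc3$tree$edge[tip_edges, 2]]
  asex <- d$meta$species[d$meta$mode == "asexual"]
  expect_equal(unique(sc3$branch_omega[tip_edges][labels %in% asex]), 0.09)
  expect_equal(unique(sc3$branch_omega[tip_edges][!labels %in% asex]), 0.03)
  expect_true(all(sc3$branch_omega[!tip_edges] == 0.03))

  expect_error(build_scenario(d, meltdown = 0.5), ">= 1")
  expect_error(build_scenario(d, omega = 0), "> 0")
  # metadata missing one tree tip is caught at design construction
  expect_error(study_design(d$tree, d$meta[-2, ]), "differ")
  # codon frequencies: 61 sense codons summing to 1
  expect_length(sc$codon_freqs, 61L)
  expect_equal(sum(sc$codon_freqs), 1, tolerance = 1e-12)
  expect_false(any(names(sc$codon_freqs) %in% c("TAA", "TAG", "TGA")))
})

test_that("zero-length branches copy the root; omega 0 stops
           nonsynonymous events", {
  d <- small_design()
  sc <- build_scenario(d, omega = 0.2, n_genes = 1, n_codons = 50,
                       seed = 5)
  sc$tree$edge.length[] <- 0
  g <- simulate_gene(sc, 1)
  expect_identical(length(unique(unclass(g$alignment))), 1L)
  expect_true(all(g$true_branch_events$n_syn == 0L))
  expect_true(all(g$true_branch_events$n_nonsyn == 0L))

  sc2 <- build_scenario(d, omega = 1, n_genes = 1, n_codons = 50, seed = 6)
  sc2$branch_omega[] <- 0                        # model limit
  sc2$tree$edge.length[] <- 1.5
  g2 <- simulate_gene(sc2, 1)
  expect_true(all(g2$true_branch_events$n_nonsyn == 0L))
  expect_gt(sum(g2$true_branch_events$n_syn), 0L)
})

test_that("no simulated sequence contains an in-frame stop codon", {
  sc <- build_scenario(small_design(), omega = 0.5, n_genes = 1,
                       n_codons = 80, seed = 17)
  for (g in 1:3) {
    sim <- simulate_gene(sc, g)
    for (s in unclass(sim$alignment)) {
      cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("recorded events are consistent with endpoint differences", {
  sc <- build_scenario(small_design(), omega = 0.4, n_genes = 1,
                       n_codons = 100, seed = 29)
  sim <- simulate_gene(sc, 1)
  ctx <- purisel:::phylo_context(sc$tree)
  node_seq <- function(label) {
    if (label %in% rownames(sim$true_ancestral)) {
      sim$true_ancestral[label, ]
    } else {
      purisel:::split_codons(unclass(sim$alignment)[[label]])
    }
  }
  ev <- sim$true_branch_events
  for (e in seq_len(ctx$n_edge)) {
    parent <- ctx$node_label[ctx$edge[e, 1]]
    child <- ctx$node_label[ctx$edge[e, 2]]
    ndiff <- sum(node_seq(parent) != node_seq(child))
    row <- ev[ev$branch == child, ]
    expect_gte(row$n_syn + row$n_nonsyn, ndiff)
    if (row$n_syn + row$n_nonsyn == 0L) expect_identical(ndiff, 0L)
  }
})

test_that("neutral event ratio matches the enumeration oracle", {
  m <- codon_model(kappa = 1, codon_freqs = rep(1 / 61, 61))
  q <- build_rate_matrix(m, omega = 1)
  set.seed(71)
  root <- sample.int(61, 3000, replace = TRUE)
  res <- purisel:::simulate_branch_gillespie(root, 1.0, q)
  expect_gt(res$n_syn, 300)
  ratio <- res$n_nonsyn / res$n_syn
  expect_equal(ratio, oracle_neutral_ns_ratio(), tolerance = 0.15)
})

test_that("kernel sampling converges to the equilibrium frequencies", {
  d <- small_design()
  sc <- build_scenario(d, omega = 1, kappa = 1, n_genes = 1,
                       n_codons = 10000, seed = 13)
  sc$codon_freqs <- setNames(rep(1 / 61, 61), sense_codons())
  tr <- ape::read.tree(text = "(g1_sex:25,g1_asex:25);")
  sc$tree <- tr
  sc$branch_omega <- c(1, 1)
  g <- simulate_gene(sc, 1, method = "kernel")
  tipseq <- unclass(g$alignment)[["g1_sex"]]
  counts <- codon_counts(tipseq)
  gof <- stats::chisq.test(counts, p = rep(1 / 61, 61))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulation is deterministic per (seed, gene) stream", {
  sc <- build_scenario(small_design(), n_genes = 2, n_codons = 40,
                       seed = 99)
  g1a <- simulate_gene(sc, 1)
  g1b <- simulate_gene(sc, 1)
  g2 <- simulate_gene(sc, 2)
  expect_identical(unclass(g1a$alignment), unclass(g1b$alignment))
  expect_identical(g1a$true_branch_events, g1b$true_branch_events)
  expect_false(identical(unclass(g1a$alignment), unclass(g2$alignment)))
  # meltdown = 1 equals the null scenario byte for byte
  sc_null <- build_scenario(small_design(), n_genes = 2, n_codons = 40,
                            seed = 99, meltdown = 1)
  expect_identical(unclass(simulate_gene(sc_null, 1)$alignment),
                   unclass(g1a$alignment))
})

test_that("study writer emits a complete, reproducible dataset", {
  sc <- build_scenario(small_design(), n_genes = 3, n_codons = 30,
                       seed = 42)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  simulate_study(sc, dir1)
  simulate_study(sc, dir2)
  fas <- list.files(file.path(dir1, "alignments"), pattern = "fasta$")
  expect_length(fas, 3L)
  for (f in c("tree.nwk", "metadata.tsv", "truth.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(dir1, f)))
  }
  # byte-identical rerun
  for (f in file.path("alignments", fas)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  expect_identical(readLines(file.path(dir1, "truth.tsv")),
                   readLines(file.path(dir2, "truth.tsv")))
  # dataset is readable back into a valid design + alignments
  dsn <- read_design(file.path(dir1, "tree.nwk"),
                     file.path(dir1, "metadata.tsv"))
  aln <- read_codon_fasta(file.path(dir1, "alignments", fas[1]))
  expect_setequal(names(aln), dsn$tree$tip.label)
})
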