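# Nc and CDC statistics against independent formula transcriptions,
# boundary cases, and structural invariances.

test_that("codon counting skips ambiguous codons and terminal stops", {
  cts <- codon_counts("ATGATG")
  expect_identical(unname(cts["ATG"]), 2L)
  expect_identical(sum(cts), 2L)

  cts2 <- codon_counts("ATGN-A")
  expect_identical(sum(cts2), 1L)
  expect_identical(attr(cts2, "skipped"), 1L)

  cts3 <- codon_counts("ATGAAATAA")      # terminal stop ignored
  expect_identical(sum(cts3), 2L)
  expect_error(codon_counts("ATGTAAAAA"), "internal stop")

  # conservation: counted + skipped = codons (after stop stripping)
  set.seed(8)
  seq <- random_cds(50)
  substr(seq, 4, 6) <- "NNN"
  cts4 <- codon_counts(seq)
  expect_identical(sum(cts4) + attr(cts4, "skipped"), 50L)
})

test_that("Nc hits its theoretical bounds at the usage extremes", {
  sp <- sense_codons()
  aa <- translate_codons(sp)
  # maximal bias: one codon per redundant amino acid, 10 counts each
  counts_biased <- setNames(integer(61), sp)
  for (a in unique(aa)) {
    counts_biased[sp[aa == a][1]] <- 10L
  }
  expect_identical(effective_number_of_codons(counts_biased), 20)
  # no bias: uniform usage of all 61 sense codons
  counts_uniform <- setNames(rep(1000L, 61), sp)
  expect_identical(effective_number_of_codons(counts_uniform), 61)
})

test_that("Nc matches an independent formula transcription", {
  set.seed(15)
  for (i in 1:20) {
    counts <- rpois(61, lambda = sample(c(0.5, 2, 10), 1))
    names(counts) <- sense_codons()
    expect_equal(effective_number_of_codons(counts), oracle_nc(counts),
                 tolerance = 1e-12)
  }
})

test_that("Nc is invariant to relabeling within a family and decreases
           with concentration", {
  sp <- sense_codons()
  aa <- translate_codons(sp)
  set.seed(4)
  counts <- rpois(61, 5) + 1L
  names(counts) <- sp
  base_nc <- effective_number_of_codons(counts)
  # permute counts within the Leu family
  leu <- sp[aa == "L"]
  counts2 <- counts
  counts2[leu] <- counts[sample(leu)]
  expect_equal(effective_number_of_codons(counts2), base_nc,
               tolerance = 1e-12)
  # concentrating a 2-fold family at fixed total lowers Nc
  twofold <- names(which(table(aa) == 2))
  fam <- sp[aa == twofold[1]]
  counts3 <- counts
  counts3[fam] <- c(sum(counts[fam]), 0L)
  expect_lt(effective_number_of_codons(counts3), base_nc)
})

test_that("Nc missing-class rules apply", {
  sp <- sense_codons()
  aa <- translate_codons(sp)
  set.seed(2)
  counts <- rpois(61, 4) + 1L
  names(counts) <- sp
  # remove isoleucine: imputed from 2- and 4-fold class means
  counts_noI <- counts
  counts_noI[sp[aa == "I"]] <- 0L
  expect_false(is.na(effective_number_of_codons(counts_noI)))
  # remove all 6-fold families: Nc undefined
  counts_no6 <- counts
  counts_no6[sp[aa %in% c("L", "S", "R")]] <- 0L
  expect_true(is.na(effective_number_of_codons(counts_no6)))
})

test_that("positional composition is a plain hand count", {
  pc <- positional_composition("GCG")
  expect_equal(pc$gc, c(1, 1, 1))
  expect_equal(pc$pur, c(1, 0, 1))
  # ATA TAT ATA TAT ... hand count: pos1 A,T,A,T -> gc 0, pur 0.5
  pc2 <- positional_composition("ATATATATATAT")
  expect_equal(pc2$gc, c(0, 0, 0))
  expect_equal(pc2$pur, c(0.5, 0.5, 0.5))
  expect_identical(pc2$n_codons, 4L)
  # bounds on random sequences
  set.seed(11)
  for (i in 1:5) {
    pc3 <- positional_composition(random_cds(30))
    expect_true(all(pc3$gc >= 0 & pc3$gc <= 1))
    expect_true(all(pc3$pur >= 0 & pc3$pur <= 1))
  }
})

test_that("expected usage factorizes positional composition", {
  e <- expected_codon_usage(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(unname(e), rep(1 / 61, 61), tolerance = 1e-12)
  e2 <- expected_codon_usage(c(1, 0.5, 0.5), c(0.5, 0.5, 0.5))
  sp <- sense_codons()
  first <- substr(sp, 1, 1)
  expect_true(all(e2[first %in% c("A", "T")] == 0))
  # construction oracle: a distribution built from its own marginals
  gc <- c(0.7, 0.4, 0.8); pur <- c(0.6, 0.5, 0.3)
  e3 <- expected_codon_usage(gc, pur)
  pos_p <- function(p, nt) {
    switch(nt, G = gc[p] * pur[p], C = gc[p] * (1 - pur[p]),
           A = (1 - gc[p]) * pur[p], T = (1 - gc[p]) * (1 - pur[p]))
  }
  manual <- vapply(sp, function(cd) {
    prod(vapply(1:3, function(p) pos_p(p, substr(cd, p, p)), 0))
  }, 0)
  expect_equal(unname(e3), unname(manual / sum(manual)), tolerance = 1e-12)
})

test_that("CDC is 0 at self-consistency, 1 at orthogonality", {
  e <- expected_codon_usage(c(0.6, 0.4, 0.7), c(0.5, 0.5, 0.4))
  expect_equal(codon_deviation_coefficient(e * 1000, e), 0,
               tolerance = 1e-12)
  # observed mass entirely on codons with zero expectation
  e2 <- expected_codon_usage(c(1, 0.5, 0.5), c(0.5, 0.5, 0.5))
  obs <- setNames(numeric(61), sense_codons())
  obs["AAA"] <- 50
  expect_identical(codon_deviation_coefficient(obs, e2), 1)
})

test_that("CDC matches a direct cosine and is scale-invariant in [0,1]", {
  set.seed(19)
  for (i in 1:20) {
    obs <- rpois(61, 3)
    if (sum(obs) == 0) obs[1] <- 1
    names(obs) <- sense_codons()
    e <- expected_codon_usage(runif(3), runif(3))
    cdc <- codon_deviation_coefficient(obs, e)
    expect_equal(cdc, max(0, min(1, oracle_cdc(obs, e))), tolerance = 1e-12)
    expect_gte(cdc, 0)
    expect_lte(cdc, 1)
    expect_equal(codon_deviation_coefficient(obs * 10L, e), cdc,
                 tolerance = 1e-12)
  }
})

test_that("cub_table assembles one record per gene and species", {
  sc <- build_scenario(small_design(), n_genes = 2, n_codons = 120,
                       seed = 3)
  alns <- lapply(1:2, function(g) simulate_gene(sc, g)$alignment)
  tab <- cub_table(alns, sc$design)
  expect_identical(nrow(tab), 2L * 7L)
  expect_true(all(c("nc", "cdc", "gc3", "mode", "group") %in% names(tab)))
  # GC3-rich simulation shows codon-usage bias
  expect_lt(mean(tab$nc, na.rm = TRUE), 59)
  expect_gt(mean(tab$gc3, na.rm = TRUE), 0.55)
})
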