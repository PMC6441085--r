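# Synthetic-data generator: codon alignments evolved along the fixed
# species tree under the same MG94 process the estimator assumes, with
# codon-usage bias from an unequal F3x4 composition, and an optional
# "meltdown" elevation of dN/dS on asexual terminal branches. Gillespie
# event simulation records the true per-branch substitution counts;
# exact transition-kernel sampling is retained as a cross-check mode.

#' Default positional nucleotide composition (GC3-rich)
#'
#' The default composition used by simulation scenarios: near-uniform
#' first and second codon positions, GC-rich third position, so simulated
#' sequences carry measurable codon-usage bias.
#'
#' @return 3 x 4 matrix (positions x `A C G T`).
#' @export
default_pos_composition <- function() {
  m <- rbind(c(0.28, 0.22, 0.30, 0.20),
             c(0.30, 0.22, 0.20, 0.28),
             c(0.12, 0.38, 0.32, 0.18))
  dimnames(m) <- list(paste0("pos", 1:3), NUCLEOTIDES)
  m
}

#' Packaged synthetic study design
#'
#' The paired study layout used throughout: eight groups, each contributing
#' one sexual and one asexual species as a cherry on a comb backbone, plus
#' a single outgroup. Topology and branch lengths are a synthetic stand-in
#' chosen to mirror that sampling design, not estimates for any real taxa.
#'
#' @return A [study_design].
#' @export
default_design <- function() {
  tree_path <- system.file("extdata", "synthetic_16taxa_tree.nwk",
                           package = "purisel")
  meta_path <- system.file("extdata", "synthetic_species_metadata.tsv",
                           package = "purisel")
  read_design(tree_path, meta_path)
}

#' Build a simulation scenario
#'
#' Resolves a study design plus process parameters into a fully specified
#' scenario: every branch carries its dN/dS (asexual terminal branches get
#' `omega * meltdown`), branch lengths are in expected substitutions per
#' codon under the branch's own dN/dS, and codon frequencies come from the
#' F3x4 construction.
#'
#' @param design a [study_design]; default [default_design()].
#' @param omega baseline dN/dS on every branch (default 0.03, the strong
#'   purifying selection regime the analysis targets).
#' @param kappa transition/transversion ratio (default 2).
#' @param pos_comp 3 x 4 positional nucleotide composition; default
#'   [default_pos_composition()].
#' @param n_genes number of genes (default 99).
#' @param n_codons codons per gene (default 300).
#' @param meltdown multiplier `>= 1` applied to the dN/dS of asexual
#'   terminal branches; 1 reproduces the null scenario exactly.
#' @param seed base seed; gene `i` uses an RNG stream derived from
#'   `(seed, i)`.
#' @return Object of class `sim_scenario`.
#' @export
build_scenario <- function(design = default_design(), omega = 0.03,
                           kappa = 2, pos_comp = default_pos_composition(),
                           n_genes = 99, n_codons = 300, meltdown = 1,
                           seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (!is.numeric(omega) || omega <= 0 || !is.finite(omega)) {
    stop("omega must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(kappa) || kappa <= 0) {
    stop("kappa must be > 0", call. = FALSE)
  }
  if (!is.numeric(meltdown) || meltdown < 1) {
    stop("meltdown factor must be >= 1", call. = FALSE)
  }
  stopifnot(n_genes >= 1, n_codons >= 1)
  tree <- design$tree
  if (is.null(tree$edge.length)) {
    stop("design tree must carry branch lengths for simulation",
         call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  asex <- design$meta$species[design$meta$mode == "asexual" &
                              !design$meta$outgroup]
  edge_omega <- rep(omega, nrow(tree$edge))
  tip_edges <- tree$edge[, 2L] <= ntip
  edge_label <- rep(NA_character_, nrow(tree$edge))
  edge_label[tip_edges] <- tree$tip.label[tree$edge[tip_edges, 2L]]
  edge_omega[tip_edges & edge_label %in% asex] <- omega * meltdown
  freqs <- codon_freqs_f3x4(pos_comp)
  structure(list(design = design, tree = tree, branch_omega = edge_omega,
                 kappa = kappa, codon_freqs = freqs, pos_comp = pos_comp,
                 n_genes = as.integer(n_genes),
                 n_codons = as.integer(n_codons),
                 meltdown = meltdown, omega = omega, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("sim_scenario:", length(x$tree$tip.label), "tips,", x$n_genes,
      "genes x", x$n_codons, "codons; omega =", x$omega,
      "kappa =", x$kappa, "meltdown =", x$meltdown, "\n")
  invisible(x)
}

# per-gene deterministic RNG stream (kept below 2^31)
gene_seed <- function(seed, gene_index) {
  as.integer((as.double(seed) + as.double(gene_index) * 1000003) %%
             2147483647)
}

# Gillespie simulation of one branch; returns final sequence and true
# synonymous / nonsynonymous event counts
simulate_branch_gillespie <- function(seq_idx, t, q) {
  sp <- codon_space()
  rates <- -diag(q)
  syn <- sp$is_syn
  n_syn <- 0L
  n_nonsyn <- 0L
  r <- rates[seq_idx]
  total <- sum(r)
  time <- 0
  repeat {
    if (total <= 0) break
    time <- time + stats::rexp(1L, total)
    if (time > t) break
    site <- sample.int(length(seq_idx), 1L, prob = r)
    i <- seq_idx[site]
    w <- q[i, ]
    w[i] <- 0
    j <- sample.int(61L, 1L, prob = w)
    if (syn[i, j]) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
    seq_idx[site] <- j
    total <- total - r[site]
    r[site] <- rates[j]
    total <- total + r[site]
  }
  list(seq = seq_idx, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

# exact-kernel simulation of one branch: sample each site from P(t)
simulate_branch_kernel <- function(seq_idx, p) {
  out <- seq_idx
  for (i in unique(seq_idx)) {
    at <- which(seq_idx == i)
    out[at] <- sample.int(61L, length(at), replace = TRUE, prob = p[i, ])
  }
  out
}

#' Simulate one gene along the scenario tree
#'
#' Draws the root codon sequence from the scenario's equilibrium
#' frequencies and evolves it branch by branch. The default Gillespie mode
#' simulates individual substitution events (yielding true per-branch
#' synonymous/nonsynonymous event counts); the kernel mode samples each
#' site's end state exactly from the branch transition matrix (event
#' counts then unavailable).
#'
#' @param scenario a [build_scenario()] result.
#' @param gene_index non-negative integer selecting the gene's RNG stream.
#' @param method `"gillespie"` (default) or `"kernel"`.
#' @return Object of class `simulated_gene`: `alignment` (a
#'   [codon_alignment] over the tips), `true_ancestral` (internal node x
#'   codon matrix of codon strings), `true_branch_events` (data frame:
#'   branch, species, t, omega, n_syn, n_nonsyn; counts `NA` in kernel
#'   mode).
#' @export
simulate_gene <- function(scenario, gene_index,
                          method = c("gillespie", "kernel")) {
  stopifnot(inherits(scenario, "sim_scenario"), gene_index >= 0)
  method <- match.arg(method)
  sp <- codon_space()
  model <- codon_model(scenario$kappa, scenario$codon_freqs)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(gene_seed(scenario$seed, gene_index))

  ctx <- phylo_context(scenario$tree)
  # map scenario edge order (input tree) to postorder
  key_in <- paste(scenario$tree$edge[, 1L], scenario$tree$edge[, 2L])
  key_po <- paste(ctx$edge[, 1L], ctx$edge[, 2L])
  ord <- match(key_po, key_in)
  edge_t <- scenario$tree$edge.length[ord]
  edge_omega <- scenario$branch_omega[ord]

  qs <- lapply(stats::setNames(nm = unique(edge_omega)), function(om) {
    build_rate_matrix(model, as.numeric(om), scale = TRUE)
  })
  ps <- if (method == "kernel") {
    lapply(stats::setNames(nm = unique(edge_omega)), function(om) {
      rate_decomp(model, as.numeric(om))
    })
  } else NULL

  n <- scenario$n_codons
  nn <- ctx$ntip + ctx$nnode
  seqs <- vector("list", nn)
  seqs[[ctx$root]] <- sample.int(61L, n, replace = TRUE,
                                 prob = model$pi)
  n_syn <- n_nonsyn <- rep(NA_integer_, ctx$n_edge)
  for (e in rev(seq_len(ctx$n_edge))) {   # preorder: parents before children
    u <- ctx$edge[e, 1L]
    v <- ctx$edge[e, 2L]
    om_key <- as.character(edge_omega[e])
    if (method == "gillespie") {
      res <- simulate_branch_gillespie(seqs[[u]], edge_t[e], qs[[om_key]])
      seqs[[v]] <- res$seq
      n_syn[e] <- res$n_syn
      n_nonsyn[e] <- res$n_nonsyn
    } else {
      p <- pmat_from_decomp(ps[[om_key]], edge_t[e])
      seqs[[v]] <- simulate_branch_kernel(seqs[[u]], p)
    }
  }

  to_string <- function(idx) paste(sp$codons[idx], collapse = "")
  tip_seqs <- vapply(seq_len(ctx$ntip), function(i) to_string(seqs[[i]]),
                     character(1))
  names(tip_seqs) <- ctx$node_label[seq_len(ctx$ntip)]
  gene_id <- sprintf("gene_%03d", gene_index)
  aln <- codon_alignment(tip_seqs, gene_id = gene_id)

  internal <- (ctx$ntip + 1L):nn
  anc <- t(vapply(internal, function(v) sp$codons[seqs[[v]]],
                  character(n)))
  rownames(anc) <- ctx$node_label[internal]

  child <- ctx$edge[, 2L]
  events <- data.frame(
    gene = gene_id,
    branch = ctx$node_label[child],
    species = ifelse(child <= ctx$ntip, ctx$node_label[child],
                     NA_character_),
    t = edge_t, omega = edge_omega,
    n_syn = n_syn, n_nonsyn = n_nonsyn,
    stringsAsFactors = FALSE)

  structure(list(alignment = aln, true_ancestral = anc,
                 true_branch_events = events, gene_id = gene_id),
            class = "simulated_gene")
}

#' @export
print.simulated_gene <- function(x, ...) {
  cat("simulated_gene '", x$gene_id, "': ", length(x$alignment),
      " tips x ", attr(x$alignment, "n_codons"), " codons; ",
      sum(x$true_branch_events$n_syn, na.rm = TRUE), " syn + ",
      sum(x$true_branch_events$n_nonsyn, na.rm = TRUE),
      " nonsyn true events\n", sep = "")
  invisible(x)
}

#' Simulate and write a complete study dataset
#'
#' Writes one FASTA per gene, the newick tree, the species metadata TSV, a
#' per-branch truth TSV (true dN/dS and event counts), and a JSON manifest
#' recording the seed and all scenario parameters. Outputs are
#' deterministic given the scenario (identical seed, identical bytes).
#'
#' @param scenario a [build_scenario()] result.
#' @param output_dir directory to create/populate.
#' @param method passed to [simulate_gene()].
#' @return Invisibly, the manifest list.
#' @export
simulate_study <- function(scenario, output_dir,
                           method = c("gillespie", "kernel")) {
  stopifnot(inherits(scenario, "sim_scenario"))
  method <- match.arg(method)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  }
  aln_dir <- file.path(output_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  truth <- vector("list", scenario$n_genes)
  for (g in seq_len(scenario$n_genes)) {
    sim <- simulate_gene(scenario, g, method = method)
    write_codon_fasta(sim$alignment,
                      file.path(aln_dir, paste0(sim$gene_id, ".fasta")))
    truth[[g]] <- sim$true_branch_events
  }
  ape::write.tree(scenario$tree, file.path(output_dir, "tree.nwk"))
  write_tables(scenario$design$meta, file.path(output_dir, "metadata.tsv"))
  write_tables(do.call(rbind, truth), file.path(output_dir, "truth.tsv"))
  manifest <- list(
    n_genes = scenario$n_genes, n_codons = scenario$n_codons,
    omega = scenario$omega, kappa = scenario$kappa,
    meltdown = scenario$meltdown, seed = scenario$seed,
    method = method,
    pos_composition = apply(scenario$pos_comp, 1L, as.list),
    species = scenario$design$meta$species)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
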