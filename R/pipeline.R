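# End-to-end orchestration: alignments -> curation -> free-ratio dN/dS
# (with positive-selection screening) -> ancestral reconstruction and
# hydrophobicity scoring -> codon-usage statistics -> mode comparisons,
# with an explicit gene-exclusion funnel and a reproducible manifest.

#' Assemble a pipeline run configuration
#'
#' @param alignment_dir directory of per-gene FASTA codon alignments.
#' @param tree_path newick species tree.
#' @param meta_path species metadata TSV.
#' @param out_dir output directory.
#' @param hs_matrix_path optional HS matrix TSV (default: built-in matrix).
#' @param max_gap_fraction codon-column curation threshold (default 0.2).
#' @param hs_threshold dissimilarity threshold on HS (default 90).
#' @param posterior_threshold minimum ancestral posterior for scoring a
#'   site (default 0.5).
#' @param n_perm permutation replicates (default 5000).
#' @param seed RNG seed for all resampling.
#' @return A validated `run_config` list.
#' @export
run_config <- function(alignment_dir, tree_path, meta_path, out_dir,
                       hs_matrix_path = NULL, max_gap_fraction = 0.2,
                       hs_threshold = 90, posterior_threshold = 0.5,
                       n_perm = 5000, seed = 1) {
  for (p in c(alignment_dir, tree_path, meta_path)) {
    if (!file.exists(p)) stop("no such path: ", p, call. = FALSE)
  }
  if (!is.null(hs_matrix_path) && !file.exists(hs_matrix_path)) {
    stop("no such path: ", hs_matrix_path, call. = FALSE)
  }
  stopifnot(n_perm >= 1, max_gap_fraction >= 0, max_gap_fraction <= 1,
            posterior_threshold >= 0, posterior_threshold <= 1)
  structure(list(alignment_dir = alignment_dir, tree_path = tree_path,
                 meta_path = meta_path, out_dir = out_dir,
                 hs_matrix_path = hs_matrix_path,
                 max_gap_fraction = max_gap_fraction,
                 hs_threshold = hs_threshold,
                 posterior_threshold = posterior_threshold,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: read design (rooting the tree at the outgroup when present);
#' per gene, read and curate the alignment, fit the free-ratio model, and
#' screen for positive selection; on the retained genes, reconstruct
#' ancestral codons and score terminal-branch amino-acid transitions by
#' hydrophobicity; compute codon-usage statistics; then run the
#' permutation ANOVA (for dN/dS, dS and CDC), the per-group paired
#' Wilcoxon tests, and the paired sign-flip test on per-species mean HS.
#' All result tables plus an exclusions TSV and a JSON manifest are
#' written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with all result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- read_design(config$tree_path, config$meta_path)
  og <- outgroup_species(design)
  tree <- design$tree
  if (!is.null(og) && !ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  }

  paths <- sort(list.files(config$alignment_dir,
                           pattern = "\\.(fa|fasta|fna)$",
                           full.names = TRUE))
  if (!length(paths)) {
    stop("no FASTA alignments under ", config$alignment_dir, call. = FALSE)
  }
  hs_mat <- load_hs_matrix(config$hs_matrix_path)

  exclusions <- list()
  branch_rows <- list()
  hs_rows <- list()
  kept_alns <- list()
  for (path in paths) {
    gene <- tools::file_path_sans_ext(basename(path))
    step <- function(stage, expr) {
      tryCatch(expr, error = function(e) {
        exclusions[[length(exclusions) + 1L]] <<- data.frame(
          gene = gene, stage = stage, reason = conditionMessage(e),
          stringsAsFactors = FALSE)
        NULL
      })
    }
    aln <- step("qc", read_codon_fasta(path, gene_id = gene))
    if (is.null(aln)) next
    aln <- step("curation", curate_alignment(aln, config$max_gap_fraction))
    if (is.null(aln)) next
    fit <- step("fit", fit_free_ratio(aln, tree, gene_id = gene))
    if (is.null(fit)) next
    flagged <- flag_positive_selection(fit)
    if (isTRUE(as.logical(flagged))) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        gene = gene, stage = "positive_selection",
        reason = paste0("branch dN/dS > 1 with LRT support (",
                        paste(attr(flagged, "detail")$branch[
                          attr(flagged, "detail")$flagged],
                          collapse = ","), ")"),
        stringsAsFactors = FALSE)
      next
    }
    branch_rows[[gene]] <- fit$table
    kept_alns[[gene]] <- aln
    anc <- reconstruct_ancestral(fit, keep_posterior = FALSE)
    trans <- terminal_transitions(aln, anc, fit,
                                  config$posterior_threshold)
    hs_rows[[gene]] <- score_transitions(trans, hs_mat,
                                         config$hs_threshold)
  }
  if (!length(branch_rows)) {
    stop("pipeline: no gene survived QC and screening", call. = FALSE)
  }
  branch_table <- do.call(rbind, branch_rows)
  rownames(branch_table) <- NULL
  hs_table <- do.call(rbind, hs_rows)
  rownames(hs_table) <- NULL
  cub <- cub_table(kept_alns, design)

  results <- list(branch_table = branch_table, hs_table = hs_table,
                  cub_table = cub)

  # mode comparisons per measure
  stats_out <- list()
  for (measure in c("omega", "dS")) {
    resp <- filter_branches(branch_table, design, measure = measure)
    stats_out[[paste0("anova_", measure)]] <-
      permutation_anova(resp, n_perm = config$n_perm, seed = config$seed)
    paired <- paired_mode_comparison_by_group(resp)
    stats_out[[paste0("paired_", measure)]] <- paired$tests
    stats_out[[paste0("delta_", measure)]] <- paired$delta
  }
  cdc_resp <- data.frame(gene = cub$gene, species = cub$species,
                         mode = cub$mode, group = cub$group,
                         value = cub$cdc, stringsAsFactors = FALSE)
  cdc_resp <- cdc_resp[!is.na(cdc_resp$mode) & !is.na(cdc_resp$value) &
                       cdc_resp$species %in%
                         design$meta$species[!design$meta$outgroup], ,
                       drop = FALSE]
  stats_out$anova_cdc <- permutation_anova(cdc_resp,
                                           n_perm = config$n_perm,
                                           seed = config$seed)
  paired_cdc <- paired_mode_comparison_by_group(cdc_resp)
  stats_out$paired_cdc <- paired_cdc$tests
  stats_out$delta_cdc <- paired_cdc$delta

  hs_sum <- summarize_hs(hs_table, design)
  stats_out$hs_by_mode <- hs_sum$by_mode
  stats_out$hs_by_species <- hs_sum$by_species
  hs_species <- hs_sum$by_species
  hs_species$value <- hs_species$mean_hs
  hs_perm <- tryCatch(
    paired_permutation_test(hs_species, n_perm = config$n_perm,
                            seed = config$seed),
    error = function(e) list(statistic = NA_real_, p = NA_real_,
                             n_groups = 0L, method = "failed"))
  stats_out$hs_mode_test <- data.frame(
    statistic = hs_perm$statistic, p = hs_perm$p,
    n_groups = hs_perm$n_groups, method = hs_perm$method)

  results <- c(results, stats_out)
  results$exclusions <- if (length(exclusions)) {
    do.call(rbind, exclusions)
  } else {
    data.frame(gene = character(0), stage = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }

  # write everything
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) {
      write_tables(as.data.frame(results[[nm]]),
                   file.path(config$out_dir, paste0(nm, ".tsv")))
    }
  }
  manifest <- list(
    n_genes_input = length(paths),
    n_genes_analysed = length(branch_rows),
    n_genes_excluded = length(paths) - length(branch_rows),
    seed = config$seed, n_perm = config$n_perm,
    max_gap_fraction = config$max_gap_fraction,
    hs_threshold = config$hs_threshold,
    posterior_threshold = config$posterior_threshold,
    hs_matrix = attr(hs_mat, "scale"))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Summarize a pipeline run directory
#'
#' Reads the result TSVs written by [run_pipeline()] and prints a compact
#' human-readable report: the gene funnel, per-measure permutation-ANOVA
#' tables, the per-group paired tests and the HS mode summary. Missing
#' tables produce warnings, not errors.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @param file connection or path for the report (default stdout).
#' @return Invisibly, the report lines.
#' @export
make_report <- function(out_dir, file = stdout()) {
  lines <- character(0)
  say <- function(...) lines <<- c(lines, paste0(...))
  grab <- function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    if (!file.exists(p)) {
      warning("missing table: ", nm, call. = FALSE)
      return(NULL)
    }
    utils::read.delim(p, stringsAsFactors = FALSE)
  }
  mani_p <- file.path(out_dir, "manifest.json")
  if (file.exists(mani_p)) {
    mani <- jsonlite::read_json(mani_p)
    say("Pipeline run: ", mani$n_genes_analysed, "/", mani$n_genes_input,
        " genes analysed (", mani$n_genes_excluded, " excluded); seed ",
        mani$seed, ", ", mani$n_perm, " permutations")
  }
  excl <- grab("exclusions")
  if (!is.null(excl) && nrow(excl)) {
    tab <- table(excl$stage)
    say("Exclusions: ", paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  for (m in c("omega", "dS", "cdc")) {
    an <- grab(paste0("anova_", m))
    if (!is.null(an)) {
      say("")
      say("Permutation ANOVA [", m, "]:")
      for (i in seq_len(nrow(an))) {
        say(sprintf("  %-11s F = %8.3f  p = %.4g", an$term[i], an$F[i],
                    an$p[i]))
      }
    }
    pr <- grab(paste0("paired_", m))
    if (!is.null(pr)) {
      say("Per-group Wilcoxon [", m, "]:")
      for (i in seq_len(nrow(pr))) {
        say(sprintf("  %-15s n = %3d  V = %7.1f  p = %.4g  (%s)%s",
                    pr$group[i], pr$n_pairs[i], pr$V[i], pr$p[i],
                    pr$direction[i],
                    if (isTRUE(pr$low_n[i])) " [low n]" else ""))
      }
    }
  }
  hs <- grab("hs_by_mode")
  if (!is.null(hs)) {
    say("")
    say("Hydrophobicity of terminal-branch replacements:")
    for (i in seq_len(nrow(hs))) {
      say(sprintf("  %-7s n = %5d  mean HS = %6.2f  %% dissimilar = %.2f",
                  hs$mode[i], hs$n[i], hs$mean_hs[i],
                  hs$pct_dissimilar[i]))
    }
  }
  hst <- grab("hs_mode_test")
  if (!is.null(hst)) {
    say(sprintf("  paired sign-flip test: mean d = %.4g, p = %.4g (%s)",
                hst$statistic[1], hst$p[1], hst$method[1]))
  }
  writeLines(lines, con = file)
  invisible(lines)
}
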