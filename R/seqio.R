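# Readers, writers and QC for the formats the pipeline touches:
# in-frame codon alignments (FASTA), the fixed species tree (newick) with
# its species metadata (TSV), and the codon-column curation filter.

#' Construct a validated codon alignment
#'
#' A codon alignment is a named character vector of equal-length, in-frame
#' nucleotide sequences (alphabet `A C G T N -`). Validation enforces the
#' invariants every downstream stage assumes: equal lengths divisible by 3,
#' unique species names, and no in-frame stop codon. A stop codon in the
#' final codon column (a retained ORF terminator) causes that column to be
#' dropped for all species, with a message.
#'
#' @param sequences named character vector, one nucleotide string per species.
#' @param gene_id identifier attached to the alignment.
#' @return An object of class `codon_alignment`: the uppercase sequences with
#'   attributes `gene_id` and `n_codons`.
#' @export
codon_alignment <- function(sequences, gene_id = "gene") {
  if (length(sequences) == 0L) {
    stop("alignment '", gene_id, "' contains no sequences", call. = FALSE)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stop("sequences must carry unique, non-empty species names", call. = FALSE)
  }
  sequences <- toupper(unlist(sequences))
  lens <- unname(nchar(sequences))
  if (length(unique(lens)) != 1L) {
    stop("unequal sequence lengths in '", gene_id, "': ",
         paste(sprintf("%s=%d", names(sequences), lens), collapse = ", "),
         call. = FALSE)
  }
  if (lens[1] == 0L) {
    stop("alignment '", gene_id, "' has zero-length sequences", call. = FALSE)
  }
  if (lens[1] %% 3L != 0L) {
    stop("alignment length ", lens[1], " of '", gene_id,
         "' is not a multiple of 3", call. = FALSE)
  }
  if (any(grepl("[^ACGTN-]", sequences))) {
    off <- names(sequences)[grepl("[^ACGTN-]", sequences)][1]
    stop("sequence '", off, "' in '", gene_id,
         "' contains characters outside A/C/G/T/N/-", call. = FALSE)
  }

  cods <- lapply(sequences, split_codons)
  n_codons <- lens[1] %/% 3L
  # strip a terminal stop column if any species ends in one
  last <- vapply(cods, function(x) x[n_codons], character(1))
  if (any(last %in% STOP_CODONS)) {
    message("alignment '", gene_id, "': terminal stop codon(s) stripped")
    sequences <- substr(sequences, 1L, lens[1] - 3L)
    cods <- lapply(cods, function(x) x[-n_codons])
    n_codons <- n_codons - 1L
    if (n_codons == 0L) {
      stop("alignment '", gene_id, "' is empty after stripping the ",
           "terminal stop column", call. = FALSE)
    }
  }
  for (sp in names(cods)) {
    hit <- which(cods[[sp]] %in% STOP_CODONS)
    if (length(hit)) {
      stop("in-frame stop codon in '", gene_id, "', species '", sp,
           "', codon index ", hit[1] - 1L, " (0-based)", call. = FALSE)
    }
  }
  structure(sequences, gene_id = gene_id, n_codons = n_codons,
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment '", attr(x, "gene_id"), "': ", length(x),
      " species x ", attr(x, "n_codons"), " codons\n", sep = "")
  invisible(x)
}

#' Read an in-frame codon alignment from FASTA
#'
#' Parses a (possibly gapped) FASTA alignment, uppercases it and validates
#' it as a codon alignment. Malformed input is rejected, not repaired.
#'
#' @param path FASTA file.
#' @param gene_id identifier; defaults to the file name without extension.
#' @return A [codon_alignment].
#' @export
read_codon_fasta <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(gene_id)) {
    gene_id <- tools::file_path_sans_ext(basename(path))
  }
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  codon_alignment(seqs, gene_id = gene_id)
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(aln, path) {
  seqinr::write.fasta(as.list(unclass(aln)), names = names(aln),
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Study design: species tree plus reproductive-mode metadata
#'
#' Binds the fixed species-tree topology to the species table (reproductive
#' mode, group, outgroup flag). The design emulated throughout is a paired
#' one: within each group one sexual and one asexual species, plus at most
#' one outgroup; departures from exact pairing produce a warning, not an
#' error.
#'
#' @param tree an `ape::phylo` tree whose tip labels are species names.
#' @param meta data frame with columns `species`, `mode` (`"sexual"` or
#'   `"asexual"`), `group`, `outgroup` (logical).
#' @return An object of class `study_design` with elements `tree` and `meta`.
#' @export
study_design <- function(tree, meta) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(meta))
  need <- c("species", "mode", "group", "outgroup")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  meta$species <- as.character(meta$species)
  meta$mode <- as.character(meta$mode)
  meta$group <- as.character(meta$group)
  meta$outgroup <- as.logical(meta$outgroup)
  bad_mode <- setdiff(unique(meta$mode), c("sexual", "asexual"))
  if (length(bad_mode)) {
    stop("mode must be 'sexual' or 'asexual'; found: ",
         paste(bad_mode, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(meta$species, tree$tip.label)
  miss <- setdiff(tree$tip.label, meta$species)
  if (length(extra) || length(miss)) {
    stop("tree tips and metadata species differ; only in metadata: {",
         paste(extra, collapse = ", "), "}; only in tree: {",
         paste(miss, collapse = ", "), "}", call. = FALSE)
  }
  if (anyDuplicated(meta$species)) {
    stop("duplicated species in metadata", call. = FALSE)
  }
  if (sum(meta$outgroup) > 1L) {
    stop("at most one outgroup species is supported", call. = FALSE)
  }
  core <- meta[!meta$outgroup, ]
  tab <- table(core$group, core$mode)
  if (!all(dim(tab) == c(length(unique(core$group)), 2L)) ||
      any(tab != 1L)) {
    warning("design is not one sexual + one asexual species per group",
            call. = FALSE)
  }
  structure(list(tree = tree, meta = meta), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", length(x$tree$tip.label), "species,",
      length(unique(x$meta$group[!x$meta$outgroup])), "groups,",
      sum(x$meta$outgroup), "outgroup\n")
  invisible(x)
}

#' Read a study design from newick + metadata TSV
#'
#' @param tree_path newick file (unrooted topologies accepted).
#' @param meta_path TSV with header `species mode group outgroup`.
#' @return A [study_design].
#' @export
read_design <- function(tree_path, meta_path) {
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stop("could not parse newick: ", tree_path, call. = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  study_design(tree, meta)
}

# species of the single outgroup, or NULL
outgroup_species <- function(design) {
  og <- design$meta$species[design$meta$outgroup]
  if (length(og)) og else NULL
}

#' Drop gap-heavy codon columns from an alignment
#'
#' Curation filter applied before model fitting: any codon column in which
#' the fraction of species with a gap or N character exceeds
#' `max_gap_fraction` is removed, triplet-wise, so the reading frame is
#' always preserved. Stands in for block-based alignment curation.
#'
#' @param aln a [codon_alignment].
#' @param max_gap_fraction columns with a strictly greater gap/N fraction
#'   are dropped; default 0.2.
#' @return The filtered [codon_alignment]; attribute `removed_columns`
#'   lists the removed codon columns (0-based indices, i.e. half-open
#'   `[i, i+1)` codon coordinates).
#' @export
curate_alignment <- function(aln, max_gap_fraction = 0.2) {
  stopifnot(inherits(aln, "codon_alignment"),
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  cods <- vapply(unclass(aln), split_codons,
                 character(attr(aln, "n_codons")))
  if (is.null(dim(cods))) cods <- matrix(cods, nrow = 1L,
                                         dimnames = list(NULL, names(aln)))
  # rows = codon columns, cols = species
  has_gap <- grepl("[N-]", cods)
  dim(has_gap) <- dim(cods)
  frac <- rowMeans(has_gap)
  drop <- frac > max_gap_fraction
  if (all(drop)) {
    stop("all ", length(drop), " codon columns exceed the gap threshold; ",
         "empty alignment", call. = FALSE)
  }
  kept <- cods[!drop, , drop = FALSE]
  seqs <- apply(kept, 2L, paste, collapse = "")
  out <- codon_alignment(seqs, gene_id = attr(aln, "gene_id"))
  attr(out, "removed_columns") <- which(drop) - 1L
  out
}

#' Write a results table as TSV
#'
#' Tab-separated, header included, no quoting or row names; numeric columns
#' serialized with 6 significant digits so reruns are byte-stable.
#'
#' @param records data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- signif(out[[j]], 6)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
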