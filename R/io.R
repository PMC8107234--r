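#' Read a FASTA file of nucleotide or protein sequences
#'
#' Sequences are uppercased.  For `kind = "nucleotide"`, any character
#' outside `{A,C,G,T,N}` is mapped to `N` (IUPAC ambiguity codes carry no
#' information for the k-mer and fragment statistics downstream).
#' Record IDs are the first whitespace-delimited token of each header and
#' must be unique within the file.
#'
#' @param path Path to a FASTA file.
#' @param kind `"nucleotide"` or `"protein"`.
#' @return A named character vector of sequences, in file order.
#' @export
read_genome_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  if (file.size(path) == 0) .stopf("FASTA file is empty: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) .stopf("FASTA file has no records: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    .stopf("duplicate sequence ID in %s: %s", path, dup[1])
  seqs <- toupper(as.character(set))
  if (kind == "nucleotide") seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA (80-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    .stopf("all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Construct a genome record
#'
#' The per-genome unit of the pipeline: assembly contigs, predicted
#' proteome, optional 16S rRNA sequences and an optional CheckM-style
#' quality triple.
#'
#' @param genome_id Unique genome identifier.
#' @param contigs Named character vector of nucleotide contigs.
#' @param proteins Named character vector of protein sequences (optional).
#' @param rrna_16s Named character vector of 16S sequences (optional).
#' @param quality Numeric vector `c(completeness, contamination,
#'   heterogeneity)` in percent, or `NULL`.
#' @param label Free-text species label as supplied.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, proteins = character(),
                          rrna_16s = character(), quality = NULL,
                          label = genome_id) {
  stopifnot(is.character(genome_id), length(genome_id) == 1, nzchar(genome_id))
  if (length(contigs) == 0 || any(!nzchar(contigs)))
    .stopf("genome %s: contigs must be non-empty sequences", genome_id)
  if (!is.null(quality)) {
    quality <- as.numeric(quality)
    if (length(quality) != 3 || anyNA(quality))
      .stopf("genome %s: quality must be (completeness, contamination, heterogeneity)",
             genome_id)
    names(quality) <- c("completeness", "contamination", "heterogeneity")
    if (quality[1] < 0 || quality[1] > 100 || any(quality[2:3] < 0))
      .stopf("genome %s: quality values out of range", genome_id)
  }
  structure(list(genome_id = genome_id, label = label, contigs = contigs,
                 proteins = proteins, rrna_16s = rrna_16s, quality = quality),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record %s: %d contig(s), %.1f kb, %d protein(s), %d 16S>\n",
              x$genome_id, length(x$contigs),
              sum(nchar(x$contigs)) / 1000, length(x$proteins),
              length(x$rrna_16s)))
  invisible(x)
}

#' Apply the dataset quality filter
#'
#' A genome is retained iff completeness >= `min_completeness` AND
#' contamination < `max_contamination` AND heterogeneity <
#' `max_heterogeneity` (completeness bound inclusive, the other two
#' strict, matching the usual "95% or higher" / "lower than 5%"
#' phrasing of high-quality-draft criteria).  Genomes without a quality
#' triple are retained with a warning.
#'
#' @param genomes List of [genome_record] objects.
#' @param min_completeness,max_contamination,max_heterogeneity Thresholds in %.
#' @return List with `retained` (genome records) and `rejected`
#'   (data.frame of `genome_id`, `reason`).
#' @export
filter_quality <- function(genomes, min_completeness = 95,
                           max_contamination = 5, max_heterogeneity = 5) {
  keep <- logical(length(genomes))
  reasons <- character(0); rejected_ids <- character(0)
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    q <- g$quality
    if (is.null(q)) {
      .warnf("genome %s has no quality metrics; retained unfiltered", g$genome_id)
      keep[i] <- TRUE
      next
    }
    if (q[["completeness"]] < min_completeness) {
      rejected_ids <- c(rejected_ids, g$genome_id); reasons <- c(reasons, "completeness")
    } else if (q[["contamination"]] >= max_contamination) {
      rejected_ids <- c(rejected_ids, g$genome_id); reasons <- c(reasons, "contamination")
    } else if (q[["heterogeneity"]] >= max_heterogeneity) {
      rejected_ids <- c(rejected_ids, g$genome_id); reasons <- c(reasons, "heterogeneity")
    } else keep[i] <- TRUE
  }
  list(retained = genomes[keep],
       rejected = data.frame(genome_id = rejected_ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Read a tab-separated quality table
#'
#' Expected header: `genome_id completeness contamination heterogeneity`.
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_quality_table <- function(path) {
  q <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("genome_id", "completeness", "contamination", "heterogeneity")
  if (!all(need %in% names(q)))
    .stopf("quality table %s must have columns: %s", path, paste(need, collapse = " "))
  q
}

#' Write a family-by-genome (or pair metric) matrix as a TSV table
#'
#' Rtab-style layout: first column holds the family/pair ID, remaining
#' columns one per genome.  Round-trips losslessly through
#' [read_matrix_table()].
#'
#' @param matrix Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Name for the first column.
#' @export
write_matrix_table <- function(matrix, path, id_column = "family") {
  if (is.null(dim(matrix)) || nrow(matrix) == 0 || ncol(matrix) == 0)
    .stopf("cannot write an empty matrix")
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix table written by [write_matrix_table()]
#' @param path Path to the TSV.
#' @return Numeric matrix with row names from the first column.
#' @export
read_matrix_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write Newick trees
#'
#' Thin wrappers around \pkg{ape} adding the validity checks the pipeline
#' relies on: balanced parentheses and unique leaf labels.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) .stopf("Newick file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close)
    .stopf("unbalanced parentheses in Newick file %s", path)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) .stopf("could not parse Newick file %s", path)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0) .stopf("duplicate leaf label in %s: %s", path, dup[1])
  tree
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a dataset manifest (YAML)
#'
#' @param manifest A list with elements `genomes` (data.frame with at least
#'   `genome_id`, `label`, `fna`, `faa`, optionally `rrna`) and
#'   `outgroup_id` (or `NULL`).
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  obj <- list(genomes = lapply(seq_len(nrow(manifest$genomes)), function(i)
                as.list(manifest$genomes[i, , drop = FALSE])),
              outgroup_id = manifest$outgroup_id)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a dataset manifest (YAML)
#' @param path Manifest path.
#' @return List with `genomes` data.frame and `outgroup_id`.
#' @export
read_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  genomes <- do.call(rbind, lapply(obj$genomes, function(g)
    as.data.frame(g, stringsAsFactors = FALSE)))
  if (is.null(genomes) || nrow(genomes) < 1) .stopf("manifest %s lists no genomes", path)
  out <- obj$outgroup_id
  if (!is.null(out) && !out %in% genomes$genome_id)
    .stopf("manifest outgroup %s is not among its genomes", out)
  list(genomes = genomes, outgroup_id = out)
}

#' Load genome records listed in a manifest
#'
#' @param manifest Manifest as returned by [read_manifest()].
#' @param base_dir Directory that relative paths in the manifest refer to.
#' @param quality Optional quality data.frame (see [read_quality_table()]).
#' @return Named list of [genome_record] objects.
#' @export
load_genomes <- function(manifest, base_dir = ".", quality = NULL) {
  recs <- lapply(seq_len(nrow(manifest$genomes)), function(i) {
    row <- manifest$genomes[i, ]
    contigs <- read_genome_fasta(file.path(base_dir, row$fna), "nucleotide")
    prots <- if (!is.null(row$faa) && !is.na(row$faa))
      read_genome_fasta(file.path(base_dir, row$faa), "protein") else character()
    rrna <- if (!is.null(row$rrna) && !is.na(row$rrna) && nzchar(row$rrna))
      read_genome_fasta(file.path(base_dir, row$rrna), "nucleotide") else character()
    q <- NULL
    if (!is.null(quality)) {
      hit <- quality[quality$genome_id == row$genome_id, ]
      if (nrow(hit) == 1)
        q <- c(hit$completeness, hit$contamination, hit$heterogeneity)
    }
    genome_record(row$genome_id, contigs, prots, rrna, q, label = row$label)
  })
  names(recs) <- manifest$genomes$genome_id
  recs
}
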