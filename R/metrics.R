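#' Fragment-based average nucleotide identity (ANI)
#'
#' Goris-style fragment ANI: each genome is cut into consecutive 1020-nt
#' fragments, fragments are placed on the other genome by shared-16-mer
#' seeding (best-voted diagonal) and aligned in a 64-column band
#' (match +1 / mismatch -1 / gap -2); a fragment is retained if its
#' identity is >= 30% over >= 70% of its length.  The directional ANI is
#' the mean identity of retained fragments and the reported ANI averages
#' the two directions, which makes the statistic symmetric.
#'
#' @param g1,g2 [genome_record] objects (or named character contig vectors).
#' @param frag_len Fragment length in nt.
#' @param min_identity,min_coverage Retention thresholds (fractions).
#' @param band Alignment band half-width.
#' @return List with `ani` (percent, `NA` with reason `"no homology"` if no
#'   fragment is retained in either direction) and `fragments` (total
#'   retained in both directions).
#' @export
compute_ani <- function(g1, g2, frag_len = 1020L, min_identity = 0.3,
                        min_coverage = 0.7, band = 64L) {
  c1 <- if (inherits(g1, "genome_record")) g1$contigs else g1
  c2 <- if (inherits(g2, "genome_record")) g2$contigs else g2
  if (sum(nchar(c1)) < 10000 || sum(nchar(c2)) < 10000)
    .warnf("ANI on genomes shorter than 10 kb is poorly determined")
  d12 <- cpp_ani_directional(c1, c2, frag_len, 16L, band, min_identity,
                             min_coverage)
  d21 <- cpp_ani_directional(c2, c1, frag_len, 16L, band, min_identity,
                             min_coverage)
  frags <- d12$n_retained + d21$n_retained
  if (d12$n_retained == 0 || d21$n_retained == 0) {
    return(structure(list(ani = NA_real_, fragments = frags),
                     reason = "no homology"))
  }
  ani <- 100 * mean(c(d12$sum_identity / d12$n_retained,
                      d21$sum_identity / d21$n_retained))
  list(ani = ani, fragments = frags)
}

#' Reciprocal-best-hit average amino-acid identity (AAI)
#'
#' Candidate hits are found via shared 5-mer amino-acid seeds; each query
#' keeps its best-identity banded BLOSUM62 alignment (gap open 11 /
#' extend 1) with identity >= 30% over >= 70% of the shorter sequence.
#' Reciprocal best hits define ortholog pairs and AAI is the mean of the
#' two directional identities over those pairs.
#'
#' @param g1,g2 [genome_record] objects (or named character protein vectors).
#' @param min_identity,min_coverage Hit thresholds (fractions).
#' @return List with `aai` (percent, `NA` with reason `"no homology"` when
#'   no reciprocal pair exists) and `rbh_pairs`.
#' @export
compute_aai <- function(g1, g2, min_identity = 0.3, min_coverage = 0.7) {
  p1 <- if (inherits(g1, "genome_record")) g1$proteins else g1
  p2 <- if (inherits(g2, "genome_record")) g2$proteins else g2
  if (length(p1) == 0 || length(p2) == 0)
    .stopf("AAI requires both genomes to have proteomes")
  h12 <- cpp_best_hits(p1, p2, 5L, min_identity, min_coverage)
  h21 <- cpp_best_hits(p2, p1, 5L, min_identity, min_coverage)
  rbh <- which(h12$target > 0 & h21$target[pmax(h12$target, 1L)] == seq_along(p1))
  if (length(rbh) == 0) {
    return(structure(list(aai = NA_real_, rbh_pairs = 0L),
                     reason = "no homology"))
  }
  ids <- (h12$identity[rbh] + h21$identity[h12$target[rbh]]) / 2
  list(aai = 100 * mean(ids), rbh_pairs = length(rbh))
}

#' 16S marker identity and coverages
#'
#' Global alignment with free end gaps; identity is matches over aligned
#' columns (terminal free gaps excluded, internal gaps counted) and each
#' coverage is the aligned span divided by that sequence's length.
#'
#' @param s1,s2 Nucleotide sequences (single strings).
#' @return Named numeric: `identity`, `query_coverage`, `target_coverage`
#'   (all percent).
#' @export
marker_identity <- function(s1, s2) {
  stopifnot(nchar(s1) > 0, nchar(s2) > 0)
  r <- cpp_align_pair(s1, s2, TRUE, 64L)
  if (r[["columns"]] == 0)
    return(c(identity = 0, query_coverage = 0, target_coverage = 0))
  c(identity = 100 * r[["matches"]] / r[["columns"]],
    query_coverage = 100 * (r[["a_end"]] - r[["a_start"]]) / nchar(s1),
    target_coverage = 100 * (r[["b_end"]] - r[["b_start"]]) / nchar(s2))
}

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "__")

#' Compute the full pairwise metric table
#'
#' ANI, TETRA and AAI for every unordered genome pair.  Tetranucleotide
#' profiles are computed once per genome.  With a `cache_dir`, finished
#' pairs are written as small TSV records and reused on rerun, making the
#' computation resumable.
#'
#' @param records Named list of [genome_record] objects (>= 2).
#' @param cache_dir Optional directory for per-pair cache files.
#' @param markers If `TRUE`, also report the best 16S marker identity and
#'   coverages per pair.
#' @param verbose Print progress.
#' @return A data.frame of class `pairwise_metrics` with columns
#'   `genome_a`, `genome_b`, `ani`, `ani_fragments`, `tetra`, `aai`,
#'   `rbh_pairs` (and marker columns when requested).
#' @export
compute_all_pairs <- function(records, cache_dir = NULL, markers = FALSE,
                              verbose = FALSE) {
  if (length(records) < 2) .stopf("need at least two genomes")
  ids <- vapply(records, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) .stopf("duplicate genome_id in dataset")
  names(records) <- ids
  if (!is.null(cache_dir)) dir.create(cache_dir, recursive = TRUE,
                                      showWarnings = FALSE)
  profiles <- lapply(records, compute_tetra_profile)
  pairs <- combn(sort(ids), 2)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0(.pair_key(a, b), ".tsv")) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[k]] <- read.delim(cache_file, stringsAsFactors = FALSE)
      next
    }
    if (verbose) message(sprintf("pair %d/%d: %s vs %s", k, ncol(pairs), a, b))
    ani <- compute_ani(records[[a]], records[[b]])
    aai <- compute_aai(records[[a]], records[[b]])
    tet <- tetra_correlation(profiles[[a]], profiles[[b]])
    row <- data.frame(genome_a = a, genome_b = b,
                      ani = ani$ani, ani_fragments = ani$fragments,
                      tetra = tet, aai = aai$aai, rbh_pairs = aai$rbh_pairs,
                      stringsAsFactors = FALSE)
    if (markers) {
      ra <- records[[a]]$rrna_16s; rb <- records[[b]]$rrna_16s
      if (length(ra) > 0 && length(rb) > 0) {
        best <- c(identity = -1, query_coverage = 0, target_coverage = 0)
        for (x in ra) for (y in rb) {
          m <- marker_identity(x, y)
          if (m[["identity"]] > best[["identity"]]) best <- m
        }
        row$marker_identity <- best[["identity"]]
        row$marker_query_coverage <- best[["query_coverage"]]
        row$marker_target_coverage <- best[["target_coverage"]]
      } else {
        row$marker_identity <- NA_real_
        row$marker_query_coverage <- NA_real_
        row$marker_target_coverage <- NA_real_
      }
    }
    if (!is.null(cache_file))
      write.table(row, cache_file, sep = "\t", quote = FALSE, row.names = FALSE)
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pairwise_metrics", "data.frame")
  out
}

#' Look up one pair in a metric table
#' @param table A `pairwise_metrics` data.frame.
#' @param a,b Genome IDs (order-free).
#' @return The matching row (or a zero-row data.frame).
#' @export
metric_pair <- function(table, a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  table[table$genome_a == lo & table$genome_b == hi, , drop = FALSE]
}
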