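#' Tetranucleotide z-score profile of a genome
#'
#' Counts all 2-, 3- and 4-mers over every contig and its reverse
#' complement (windows never cross contig ends; windows containing `N` are
#' not counted).  Expected 4-mer counts follow the maximal-order Markov
#' model `E(n1n2n3n4) = O(n1n2n3) * O(n2n3n4) / O(n2n3)` with variance
#' `V = E * (O(n2n3) - O(n1n2n3)) * (O(n2n3) - O(n2n3n4)) / O(n2n3)^2`,
#' and `z = (O - E) / sqrt(V)` (0 wherever `V` is 0).  The Pearson
#' correlation of two such profiles is the TETRA statistic used in the
#' species criterion.
#'
#' @param x A [genome_record], a named character vector of contigs, or a
#'   `Biostrings::DNAStringSet`.
#' @return An object of class `tetra_profile`: list with `z` (256 z-scores
#'   in lexicographic 4-mer order) and the underlying counts `o4`, `o3`,
#'   `o2` plus `e` and `v`.
#' @export
compute_tetra_profile <- function(x) {
  contigs <- if (inherits(x, "genome_record")) x$contigs else x
  if (!inherits(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (length(contigs) == 0 || sum(Biostrings::width(contigs)) == 0)
    .stopf("cannot compute a tetranucleotide profile of an empty genome")
  if (sum(Biostrings::width(contigs)) < 50000)
    .warnf("genome shorter than 50 kb; tetranucleotide z-scores will be noisy")
  both <- c(contigs, Biostrings::reverseComplement(contigs))
  o2 <- colSums(Biostrings::oligonucleotideFrequency(both, 2L))
  o3 <- colSums(Biostrings::oligonucleotideFrequency(both, 3L))
  o4 <- colSums(Biostrings::oligonucleotideFrequency(both, 4L))
  w <- names(o4)
  left3 <- substr(w, 1, 3); right3 <- substr(w, 2, 4); mid2 <- substr(w, 2, 3)
  om <- o2[mid2]
  e <- ifelse(om > 0, o3[left3] * o3[right3] / om, 0)
  v <- ifelse(om > 0, e * (om - o3[left3]) * (om - o3[right3]) / om^2, 0)
  z <- ifelse(v > 0, (o4 - e) / sqrt(v), 0)
  names(z) <- names(e) <- names(v) <- w
  structure(list(z = z, o4 = o4, o3 = o3, o2 = o2, e = e, v = v),
            class = "tetra_profile")
}

#' Correlation of two tetranucleotide profiles (TETRA)
#'
#' @param p1,p2 Profiles from [compute_tetra_profile()].
#' @return Pearson correlation of the 256 z-scores, in `[-1, 1]`.
#' @export
tetra_correlation <- function(p1, p2) {
  stopifnot(inherits(p1, "tetra_profile"), inherits(p2, "tetra_profile"),
            length(p1$z) == length(p2$z))
  if (stats::sd(p1$z) == 0 || stats::sd(p2$z) == 0)
    .stopf("TETRA undefined: a profile has zero variance")
  unname(cor(p1$z, p2$z))
}
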