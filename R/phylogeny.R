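#' Single-copy core families
#'
#' Families with occurrence count exactly 1 in every genome of the subset,
#' sorted by family ID — the raw material for the species tree.
#'
#' @param matrix Orthogroup occurrence matrix.
#' @param genomes Genome subset (default: all).
#' @return Character vector of family IDs.
#' @export
single_copy_core <- function(matrix, genomes = colnames(matrix)) {
  sub <- matrix[, genomes, drop = FALSE]
  fams <- rownames(sub)[rowSums(sub == 1) == length(genomes)]
  if (length(fams) == 0)
    .stopf("no single-copy core families; try a smaller genome subset")
  sort(fams)
}

#' Pairwise distance matrix from single-copy core families
#'
#' For each genome pair, every family's pair of sequences is aligned
#' globally (free end gaps); the distance is `1 -` the length-weighted
#' mean identity (weights = aligned columns).  These are p-distances:
#' triangle-inequality violations are possible and tolerated.
#'
#' @param families Family IDs (from [single_copy_core()]).
#' @param sequences Named list: family -> named character vector (one
#'   sequence per genome).
#' @param type `"protein"` or `"nucleotide"` (alignment scoring).
#' @return Symmetric numeric distance matrix over genomes.
#' @export
family_distance_matrix <- function(families, sequences,
                                   type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  dna <- type == "nucleotide"
  genomes <- sort(names(sequences[[families[1]]]))
  for (f in families) {
    missing <- setdiff(genomes, names(sequences[[f]]))
    if (length(missing) > 0)
      .stopf("family %s lacks a sequence for genome %s", f, missing[1])
  }
  n <- length(genomes)
  d <- matrix(0, n, n, dimnames = list(genomes, genomes))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      matches <- 0; columns <- 0
      for (f in families) {
        r <- cpp_align_pair(sequences[[f]][[genomes[i]]],
                            sequences[[f]][[genomes[j]]], dna, 48L)
        matches <- matches + r[["matches"]]
        columns <- columns + r[["columns"]]
      }
      d[i, j] <- d[j, i] <- if (columns > 0) 1 - matches / columns else NA_real_
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with the deficit shifted onto the sister branch so that
#' path lengths are preserved where possible.
#'
#' @param dist Symmetric distance matrix (>= 3 taxa) with zero diagonal.
#' @return Unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dist) {
  if (nrow(dist) < 3) .stopf("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(dist, t(dist))))
    .stopf("distance matrix must be symmetric")
  tree <- ape::nj(as.dist(dist))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    sib <- which(tree$edge[, 1] == tree$edge[e, 1] &
                   seq_len(nrow(tree$edge)) != e)
    if (length(sib) > 0)
      tree$edge.length[sib[1]] <- max(0, tree$edge.length[sib[1]] + deficit)
  }
  tree
}

#' Root a tree on an outgroup
#'
#' The root is placed at the midpoint of the outgroup's pendant edge and
#' internal nodes are relabeled `N1..Nk` in preorder.
#'
#' @param tree Unrooted (or rooted) `ape::phylo` tree.
#' @param outgroup_id Tip label of the outgroup.
#' @return Rooted `ape::phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  tip <- which(tree$tip.label == outgroup_id)
  if (length(tip) != 1) .stopf("outgroup %s is not a leaf of the tree", outgroup_id)
  pend <- which(tree$edge[, 2] == tip)
  half <- tree$edge.length[pend] / 2
  rooted <- phytools::reroot(tree, tip, position = half)
  rooted$node.label <- paste0("N", seq_len(rooted$Nnode))
  rooted
}

#' Robinson-Foulds distance
#'
#' Symmetric difference over non-trivial bipartitions (via \pkg{phangorn}).
#' @param t1,t2 Trees with identical leaf sets.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    .stopf("trees have different leaf sets")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}
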