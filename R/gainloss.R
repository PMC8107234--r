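#' Wagner-parsimony reconstruction of ancestral gene content
#'
#' Per family, a two-state (absent/present) Sankoff dynamic program over
#' the rooted tree with transition penalties `gain_penalty`
#' (absent -> present) and `loss_penalty` (present -> absent), followed by
#' a root-first traceback.  Presence at the root is charged one gain (the
#' family's origination), so an early gain followed by losses and later
#' independent gains are priced on the same scale.  Ties are broken toward
#' absence (configurable
#' to `"present"`), which delays gains: a pattern explicable either by an
#' early gain plus losses or by later independent gains at equal cost is
#' reconstructed as the later gains.  Occurrence counts are binarized
#' (>= 1 means present).
#'
#' @param tree Rooted `ape::phylo` with labeled internal nodes (leaves
#'   must appear among the matrix columns).
#' @param matrix Orthogroup occurrence matrix (families x genomes).
#' @param gain_penalty,loss_penalty Positive event penalties (the default
#'   1/1 weighs gains and losses equally).
#' @param ties `"absent"` (default) or `"present"`.
#' @return Object of class `gain_loss_reconstruction`: `tree`,
#'   `node_state` (logical matrix nodes x families), `branch_gains` /
#'   `branch_losses` (named lists per child-node label), `total_cost`.
#' @export
wagner_parsimony <- function(tree, matrix, gain_penalty = 1,
                             loss_penalty = 1, ties = c("absent", "present")) {
  ties <- match.arg(ties)
  stopifnot(gain_penalty > 0, loss_penalty > 0)
  if (!ape::is.rooted(tree)) .stopf("Wagner parsimony needs a rooted tree")
  missing <- setdiff(tree$tip.label, colnames(matrix))
  if (length(missing) > 0)
    .stopf("leaf %s is missing from the orthogroup matrix", missing[1])
  if (is.null(tree$node.label))
    tree$node.label <- paste0("N", seq_len(tree$Nnode))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  labels <- c(tree$tip.label, tree$node.label)
  fams <- rownames(matrix)
  nf <- length(fams)
  pres <- t(matrix[, tree$tip.label, drop = FALSE] > 0)  # tips x families
  BIG <- 1e9
  cost0 <- matrix(0, nnode, nf)
  cost1 <- matrix(0, nnode, nf)
  cost0[seq_len(ntip), ] <- ifelse(pres, BIG, 0)
  cost1[seq_len(ntip), ] <- ifelse(pres, 0, BIG)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    cost0[p, ] <- cost0[p, ] + pmin(cost0[ch, ], cost1[ch, ] + gain_penalty)
    cost1[p, ] <- cost1[p, ] + pmin(cost0[ch, ] + loss_penalty, cost1[ch, ])
  }
  root <- ntip + 1L
  prefer_present <- ties == "present"
  state <- matrix(FALSE, nnode, nf)
  # a family present at the root is charged one gain (its origination),
  # so "early gain + losses" and "independent later gains" price equally
  root_pres <- cost1[root, ] + gain_penalty
  state[root, ] <- if (prefer_present) root_pres <= cost0[root, ]
                   else root_pres < cost0[root, ]
  pre <- ape::reorder.phylo(tree, "cladewise")
  gains <- vector("list", nnode)
  losses <- vector("list", nnode)
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
    sp <- state[p, ]
    c_pres <- cost1[ch, ] + ifelse(sp, 0, gain_penalty)
    c_abs <- cost0[ch, ] + ifelse(sp, loss_penalty, 0)
    state[ch, ] <- if (prefer_present) c_pres <= c_abs else c_pres < c_abs
    gains[[ch]] <- fams[!sp & state[ch, ]]
    losses[[ch]] <- fams[sp & !state[ch, ]]
  }
  total <- sum(gain_penalty * lengths(gains[tree$edge[, 2]]),
               loss_penalty * lengths(losses[tree$edge[, 2]]),
               gain_penalty * sum(state[root, ]))
  min_root <- sum(pmin(cost0[root, ], cost1[root, ] + gain_penalty))
  if (abs(total - min_root) > 1e-6)
    .stopf("internal error: traceback cost %g != DP optimum %g", total, min_root)
  rownames(state) <- labels
  colnames(state) <- fams
  names(gains) <- labels; names(losses) <- labels
  structure(list(tree = tree,
                 node_state = state,
                 branch_gains = gains[tree$edge[, 2]],
                 branch_losses = losses[tree$edge[, 2]],
                 gain_penalty = gain_penalty, loss_penalty = loss_penalty,
                 total_cost = total),
            class = "gain_loss_reconstruction")
}

#' Per-branch gain/loss summary
#'
#' One row per branch: parent and child node labels, numbers of families
#' gained and lost on the branch, and the family-set size at the child.
#' The bookkeeping identity `|child| = |parent| + gains - losses` holds on
#' every branch.
#'
#' @param recon A [wagner_parsimony()] reconstruction.
#' @return data.frame `parent, child, n_gained, n_lost, n_present_child`.
#' @export
branch_summary <- function(recon) {
  tree <- recon$tree
  labels <- rownames(recon$node_state)
  sizes <- rowSums(recon$node_state)
  data.frame(parent = labels[tree$edge[, 1]],
             child = labels[tree$edge[, 2]],
             n_gained = unname(lengths(recon$branch_gains)),
             n_lost = unname(lengths(recon$branch_losses)),
             n_present_child = unname(sizes[tree$edge[, 2]]),
             stringsAsFactors = FALSE)
}

#' Ancestral family content at a node
#'
#' @param recon A [wagner_parsimony()] reconstruction.
#' @param node A node label, a leaf label, or a character vector of >= 2
#'   leaves (resolved to their last common ancestor).
#' @return Character vector of families present at that node.
#' @export
lca_content <- function(recon, node) {
  labels <- rownames(recon$node_state)
  if (length(node) > 1) {
    tips <- match(node, recon$tree$tip.label)
    if (anyNA(tips)) .stopf("unknown leaf: %s", node[which(is.na(tips))[1]])
    idx <- ape::getMRCA(recon$tree, tips)
  } else {
    idx <- match(node, labels)
    if (is.na(idx)) .stopf("unknown node: %s", node)
  }
  colnames(recon$node_state)[recon$node_state[idx, ]]
}

#' Functional category profile of a family set
#'
#' Percentages per category over the set, with unmapped families counted
#' as `"unassigned"`; percentages sum to 100.
#'
#' @param families Character vector of family IDs (non-empty).
#' @param annotation Named character vector: family -> category.
#' @return Named numeric vector of percentages (sorted decreasing, with
#'   `unassigned` last).
#' @export
category_profile <- function(families, annotation) {
  if (length(families) == 0) .stopf("empty family set")
  cats <- annotation[families]
  cats[is.na(cats)] <- "unassigned"
  pct <- 100 * table(cats) / length(families)
  pct <- c(sort(pct[names(pct) != "unassigned"], decreasing = TRUE),
           pct[names(pct) == "unassigned"])
  out <- as.numeric(pct)
  names(out) <- names(pct)
  out
}
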