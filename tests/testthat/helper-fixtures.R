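# Shared fixtures, built lazily once per test run, and independent oracles.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small clade for unit tests (~40 kb genomes, fast)
small_clade <- function() fixture("small_clade", function() {
  cfg <- simulation_config(seed = 11, n_species = 4, strains_per_species = 2,
                           root_family_count = 60, include_outgroup = TRUE)
  simulate_clade(cfg)
})

# the 8-species x 3-strain study condition (~200 kb genomes)
clade24 <- function() fixture("clade24", function() {
  cfg <- simulation_config(seed = 42, n_species = 8, strains_per_species = 3,
                           root_family_count = 220)
  simulate_clade(cfg)
})

metrics24 <- function() fixture("metrics24", function() {
  compute_all_pairs(clade24()$records)
})

# random DNA string, optionally with N's
rand_dna <- function(n, p_n = 0) {
  alpha <- c("A", "C", "G", "T")
  s <- sample(alpha, n, replace = TRUE)
  if (p_n > 0) s[runif(n) < p_n] <- "N"
  paste(s, collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# substitute exactly k positions of a DNA string with a different base
substitute_dna <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(seq_along(v), k)
  alpha <- c("A", "C", "G", "T")
  for (i in idx) v[i] <- sample(setdiff(alpha, v[i]), 1)
  paste(v, collapse = "")
}

# exhaustive window-enumeration k-mer counter over sequences + reverse
# complements, skipping windows with non-ACGT characters
oracle_kmer_counts <- function(contigs, k) {
  revcomp <- function(s) chartr("ACGTN", "TGCAN",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  alpha <- c("A", "C", "G", "T")
  words <- sort(apply(expand.grid(rep(list(alpha), k)), 1, paste, collapse = ""))
  counts <- setNames(integer(4^k), words)
  for (s in c(contigs, vapply(contigs, revcomp, ""))) {
    n <- nchar(s)
    if (n < k) next
    st <- seq_len(n - k + 1)
    w <- substring(s, st, st + k - 1)
    w <- w[!grepl("[^ACGT]", w)]
    tab <- table(factor(w, levels = words))
    counts <- counts + as.integer(tab)
  }
  counts
}

# vectorized brute-force Wagner parsimony over many patterns at once
oracle_wagner_costs <- function(tree, patterns, gain = 1, loss = 1) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- ntip + 1L
  pats <- patterns[, tree$tip.label, drop = FALSE]
  best <- rep(Inf, nrow(pats))
  for (mask in 0:(2^nint - 1)) {
    lab <- as.integer(intToBits(mask)[seq_len(nint)])
    st <- cbind(pats, matrix(rep(lab, each = nrow(pats)), nrow(pats)))
    cost <- gain * st[, root]
    for (e in seq_len(nrow(tree$edge))) {
      p <- st[, tree$edge[e, 1]]; ch <- st[, tree$edge[e, 2]]
      cost <- cost + gain * (p == 0 & ch == 1) + loss * (p == 1 & ch == 0)
    }
    best <- pmin(best, cost)
  }
  best
}

# brute-force Wagner parsimony: enumerate all internal labelings; root
# presence charged as one gain
oracle_wagner_cost <- function(tree, pattern, gain = 1, loss = 1) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- ntip + 1L
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    st <- c(pattern[tree$tip.label],
            as.integer(intToBits(mask)[seq_len(nint)]))
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- st[tree$edge[e, 1]]; ch <- st[tree$edge[e, 2]]
      if (p == 0 && ch == 1) cost <- cost + gain
      if (p == 1 && ch == 0) cost <- cost + loss
    }
    cost <- cost + gain * st[root]
    best <- min(best, cost)
  }
  best
}

# random additive (tree-metric) distance matrix from a random topology
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.05, 1))
  list(tree = tr, dist = ape::cophenetic.phylo(tr))
}

# truth presence/absence matrix at the leaves of a simulated clade
truth_leaf_matrix <- function(truth) {
  tips <- truth$tree$tip.label
  fams <- sort(unique(unlist(truth$node_families[tips])))
  m <- vapply(tips, function(g) as.integer(fams %in% truth$node_families[[g]]),
              integer(length(fams)))
  rownames(m) <- fams
  m
}
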