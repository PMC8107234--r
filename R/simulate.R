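#' Simulation configuration for a synthetic clade
#'
#' Defines the study conditions emulated by the generator: a pure-birth
#' species tree of `n_species` tips expanded into strains, gene repertoires
#' evolving by Poisson gain/loss along branches, Jukes-Cantor sequence
#' evolution, and a slowly evolving 16S-like marker.  Branch lengths are in
#' expected substitutions per site.
#'
#' `min_species_separation` is the smallest nucleotide divergence
#' (tip-to-tip path length) allowed between two species; the default 0.06
#' keeps every inter-species pair clearly outside the 95% ANI boundary
#' after Jukes-Cantor saturation (a nominal 0.05 path would sit exactly on
#' it), while `intra_species_divergence` 0.01 keeps strains of one species
#' at ~99% identity.
#'
#' @param seed Integer seed; the full dataset is a pure function of the
#'   configuration.
#' @param n_species Number of species in the clade (>= 2).
#' @param strains_per_species Strains per species (scalar or per-species).
#' @param tree_depth Root-to-species-tip depth, substitutions/site.
#' @param intra_species_divergence Pairwise divergence among strains of one
#'   species.
#' @param min_species_separation Minimum inter-species pairwise divergence.
#' @param root_family_count Gene families present at the root.
#' @param gain_rate,loss_rate Expected gene gains / losses per unit branch
#'   length.
#' @param mean_gene_length Mean gene length in nt (min 300, multiple of 3).
#' @param marker_length Length of the 16S-like marker gene.
#' @param marker_rate_scale Substitution-rate multiplier for the marker.
#' @param novel_pool `"infinite"` for globally unique gained families (open
#'   pangenome regime) or a positive integer pool size (closed regime).
#' @param include_outgroup Attach one deeper-branching outgroup genome.
#' @param outgroup_extra_depth Extra stem depth above the clade root for the
#'   outgroup split.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_species = 8L, strains_per_species = 3L,
                              tree_depth = 0.2, intra_species_divergence = 0.01,
                              min_species_separation = 0.06,
                              root_family_count = 2000L,
                              gain_rate = 150, loss_rate = 100,
                              mean_gene_length = 900L, marker_length = 1550L,
                              marker_rate_scale = 0.05,
                              novel_pool = "infinite",
                              include_outgroup = FALSE,
                              outgroup_extra_depth = 0.1) {
  stopifnot(n_species >= 2, root_family_count >= 1,
            gain_rate >= 0, loss_rate >= 0,
            intra_species_divergence < tree_depth,
            tree_depth > 0, marker_rate_scale >= 0)
  if (!identical(novel_pool, "infinite"))
    stopifnot(is.numeric(novel_pool), novel_pool >= 1)
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              strains_per_species = as.integer(strains_per_species),
              tree_depth = tree_depth,
              intra_species_divergence = intra_species_divergence,
              min_species_separation = min_species_separation,
              root_family_count = as.integer(root_family_count),
              gain_rate = gain_rate, loss_rate = loss_rate,
              mean_gene_length = as.integer(mean_gene_length),
              marker_length = as.integer(marker_length),
              marker_rate_scale = marker_rate_scale,
              novel_pool = novel_pool,
              include_outgroup = include_outgroup,
              outgroup_extra_depth = outgroup_extra_depth)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate the species/strain tree
#'
#' Pure-birth topology: split times are drawn uniformly on
#' `[0, tree_depth - min_species_separation/2]` and each split subdivides a
#' uniformly chosen extant lineage, giving an ultrametric species tree of
#' depth `tree_depth`.  Each species tip is then expanded into a star of
#' strain leaves at pairwise depth `intra_species_divergence`.  Internal
#' nodes are labeled `N1..Nk` in preorder.
#'
#' @param config A [simulation_config()].
#' @return A rooted `ape::phylo` tree whose tip labels are genome IDs.
#' @export
simulate_species_tree <- function(config) {
  if (config$n_species < 2) .stopf("n_species must be >= 2")
  set.seed(config$seed)
  n <- config$n_species
  D <- config$tree_depth
  sep2 <- config$min_species_separation / 2
  if (D <= sep2) .stopf("tree_depth must exceed min_species_separation/2")
  times <- c(0, sort(runif(max(0, n - 2), 0, D - sep2)))
  # lineage bookkeeping: negative ids = extant lineages, positive = nodes
  kids <- list(); node_time <- numeric(0)
  lin_parent <- new.env(parent = emptyenv())
  active <- -1L
  next_lin <- 2L
  root_node <- NA_integer_
  for (j in seq_len(n - 1)) {
    pick <- if (length(active) == 1) 1L else sample.int(length(active), 1)
    L <- active[pick]
    nid <- length(node_time) + 1L
    node_time[nid] <- times[j]
    c1 <- -next_lin; c2 <- -(next_lin + 1L); next_lin <- next_lin + 2L
    kids[[nid]] <- c(c1, c2)
    pl <- mget(as.character(L), envir = lin_parent,
               ifnotfound = list(NULL))[[1]]
    if (is.null(pl)) root_node <- nid
    else kids[[pl]][kids[[pl]] == L] <- nid
    assign(as.character(c1), nid, envir = lin_parent)
    assign(as.character(c2), nid, envir = lin_parent)
    active <- c(active[-pick], c1, c2)
  }
  spb <- config$strains_per_species
  if (length(spb) == 1) spb <- rep(spb, n)
  sp_counter <- 0L
  newick_of <- function(id, parent_time) {
    if (id > 0) {
      parts <- vapply(kids[[id]], newick_of, "", parent_time = node_time[id])
      sprintf("(%s):%.10f", paste(parts, collapse = ","),
              node_time[id] - parent_time)
    } else {
      sp_counter <<- sp_counter + 1L
      k <- spb[sp_counter]
      stem <- D - parent_time
      if (k == 1) {
        sprintf("s%02d_t01:%.10f", sp_counter, stem)
      } else {
        half <- config$intra_species_divergence / 2
        leaves <- sprintf("s%02d_t%02d:%.10f", sp_counter, seq_len(k), half)
        sprintf("(%s):%.10f", paste(leaves, collapse = ","), stem)
      }
    }
  }
  nwk <- sprintf("%s;", sub(":[0-9.]+$", "", newick_of(root_node, 0)))
  if (config$include_outgroup) {
    x <- config$outgroup_extra_depth
    inner <- sub(";$", "", nwk)
    nwk <- sprintf("(%s:%.10f,outgroup:%.10f);", inner, x, D + x)
  }
  tree <- ape::read.tree(text = nwk)
  tree$node.label <- paste0("N", seq_len(tree$Nnode))
  tree
}

#' Simulate gene content evolution along a tree
#'
#' The root carries families `F000001..F<K>`.  On each branch of length
#' `t`, `Poisson(gain_rate * t)` families are gained (fresh IDs under the
#' infinite-pool model, IDs drawn from a finite accessory pool otherwise)
#' and `Poisson(loss_rate * t)` uniformly chosen present families are lost
#' (capped at the number present).
#'
#' @param tree Rooted tree from [simulate_species_tree()].
#' @param config A [simulation_config()].
#' @return An object of class `clade_truth`: `tree`, `species_of` (named
#'   vector genome -> species index), `node_families` (named list of family
#'   sets per node label) and `branch_events` (list of per-branch gained /
#'   lost ID sets).
#' @export
simulate_gene_content <- function(tree, config) {
  if (!ape::is.rooted(tree)) .stopf("tree must be rooted")
  set.seed(config$seed + 1L)
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  root <- ntip + 1L
  root_fams <- sprintf("F%06d", seq_len(config$root_family_count))
  counter <- new.env(parent = emptyenv())
  counter$n <- config$root_family_count
  finite <- !identical(config$novel_pool, "infinite")
  pool <- if (finite) sprintf("P%05d", seq_len(as.integer(config$novel_pool)))
          else character(0)
  node_families <- vector("list", ntip + tree$Nnode)
  node_families[[root]] <- root_fams
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- tree$edge.length[match(paste(ord[, 1], ord[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  branch_events <- vector("list", nrow(ord))
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1]; ch <- ord[e, 2]; t <- lens[e]
    fams <- node_families[[p]]
    n_loss <- min(rpois(1, config$loss_rate * t), length(fams))
    lost <- if (n_loss > 0) sample(fams, n_loss) else character(0)
    n_gain <- rpois(1, config$gain_rate * t)
    if (n_gain > 0) {
      if (finite) {
        avail <- setdiff(pool, fams)
        gained <- if (length(avail) == 0) character(0)
                  else sample(avail, min(n_gain, length(avail)))
      } else {
        gained <- sprintf("F%06d", counter$n + seq_len(n_gain))
        counter$n <- counter$n + n_gain
      }
    } else gained <- character(0)
    node_families[[ch]] <- sort(union(setdiff(fams, lost), gained))
    branch_events[[e]] <- list(parent = labels[p], child = labels[ch],
                               gained = gained, lost = lost)
  }
  names(node_families) <- labels
  species_of <- vapply(tree$tip.label, function(l) {
    if (l == "outgroup") 0L else as.integer(sub("^s(\\d+)_t\\d+$", "\\1", l))
  }, integer(1))
  structure(list(tree = tree, species_of = species_of,
                 node_families = node_families,
                 branch_events = branch_events, config = config),
            class = "clade_truth")
}

.codons_nonstop <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# Jukes-Cantor branch substitution: each site changes with probability
# 3/4 * (1 - exp(-4/3 r t)) to a uniformly chosen different base, where r
# is the site's relative rate (1 for the rRNA-like marker).
.jc_mutate <- function(codes, t, rate = 1) {
  p <- 0.75 * (1 - exp(-4 / 3 * rate * t))
  hit <- which(runif(length(codes)) < p)
  if (length(hit) > 0)
    codes[hit] <- (codes[hit] + sample.int(3L, length(hit), replace = TRUE) - 1L) %% 4L + 1L
  codes
}

# Coding-sequence evolution with purifying selection: 1st/2nd codon
# positions mutate slowly (accepted missense), 3rd positions mutate fast
# but amino-acid-changing 3rd-position mutations are rejected with
# probability 1 - omega3.  The rates are chosen so the expected accepted
# nucleotide divergence equals the branch length in the linear regime
# ((2*r12 + r3*(syn3 + (1-syn3)*omega3)) / 3 = 1 with syn3 ~ 0.7), while
# amino-acid divergence stays far below nucleotide divergence, as in real
# genes.
.R12 <- 0.15
.R3 <- 3.7
.OMEGA3 <- 0.1

.codon_aa_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      bases <- c("A", "C", "G", "T")
      idx <- expand.grid(p3 = 0:3, p2 = 0:3, p1 = 0:3)  # code order below
      cods <- paste0(bases[idx$p1 + 1], bases[idx$p2 + 1], bases[idx$p3 + 1])
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(cods), no.init.codon = TRUE))
      tab <<- aa
    }
    tab
  }
})

.codon_index <- function(codes) {
  # codes: 1..4 vector, length multiple of 3 -> 1..64 per codon
  m <- matrix(codes - 1L, nrow = 3L)
  m[1, ] * 16L + m[2, ] * 4L + m[3, ] + 1L
}

.evolve_coding <- function(codes, t) {
  aa_tab <- .codon_aa_table()
  # positions 1 and 2: slow missense channel
  pos <- rep_len(c(1L, 2L, 3L), length(codes))
  p12 <- 0.75 * (1 - exp(-4 / 3 * .R12 * t))
  hit12 <- which(pos != 3L & runif(length(codes)) < p12)
  if (length(hit12) > 0)
    codes[hit12] <- (codes[hit12] + sample.int(3L, length(hit12), replace = TRUE) - 1L) %% 4L + 1L
  # position 3: fast, mostly synonymous channel
  p3 <- 0.75 * (1 - exp(-4 / 3 * .R3 * t))
  hit3 <- which(pos == 3L & runif(length(codes)) < p3)
  if (length(hit3) > 0) {
    old <- codes[hit3]
    prev_aa <- aa_tab[.codon_index(codes)]
    codes[hit3] <- (codes[hit3] + sample.int(3L, length(hit3), replace = TRUE) - 1L) %% 4L + 1L
    new_aa <- aa_tab[.codon_index(codes)]
    cod_of <- (hit3 - 1L) %/% 3L + 1L
    changed <- new_aa[cod_of] != prev_aa[cod_of]
    revert <- changed & runif(length(hit3)) >= .OMEGA3
    codes[hit3[revert]] <- old[revert]
  }
  codes
}

.fix_stops <- function(codes, nonstop_codons) {
  bases <- c("A", "C", "G", "T")
  ncod <- length(codes) %/% 3L
  cm <- matrix(bases[codes], nrow = 3L)
  cod <- paste0(cm[1, ], cm[2, ], cm[3, ])
  bad <- which(cod %in% c("TAA", "TAG", "TGA"))
  if (length(bad) > 0) {
    repl <- sample(nonstop_codons, length(bad), replace = TRUE)
    rm_ <- do.call(rbind, strsplit(repl, ""))
    for (j in seq_along(bad)) {
      codes[(bad[j] - 1L) * 3L + 1:3] <- match(rm_[j, ], bases)
    }
  }
  codes
}

#' Simulate sequences for a gene-content history
#'
#' Each family receives a random root coding sequence (length geometric
#' around `mean_gene_length`, minimum 300 nt, multiple of 3, stop-codon
#' free) at its point of origin and evolves along the tree by site-wise
#' Jukes-Cantor substitution at the branch's expected rate; codons mutated
#' into stops are re-drawn.  Proteins are direct translations, so AAI and
#' ANI stay coherently coupled.  One 16S-like marker of `marker_length` nt
#' evolves at `marker_rate_scale` times the branch rates and is attached to
#' every genome.  Leaf repertoires are concatenated into 1-10 contigs.
#'
#' @param truth A `clade_truth` from [simulate_gene_content()].
#' @param config The same [simulation_config()].
#' @return Named list of [genome_record] objects (quality 100/0/0).
#' @export
simulate_sequences <- function(truth, config) {
  set.seed(config$seed + 2L)
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  bases <- c("A", "C", "G", "T")
  nonstop <- .codons_nonstop()
  # clade-level compositional signature: all genes are drawn from one
  # order-3 Markov model (Dirichlet(1) transition rows), giving the genomes
  # the shared tetranucleotide signature real same-genus genomes carry
  trans <- matrix(rgamma(64L * 4L, shape = 1), 64L, 4L)
  trans <- trans / rowSums(trans)
  cum_trans <- t(apply(trans, 1, cumsum))
  gene_len <- function() {
    extra <- rgeom(1, prob = 3 / max(3, config$mean_gene_length - 300))
    300L + 3L * extra
  }
  new_gene <- function() {
    L <- gene_len()
    .fix_stops(cpp_markov_seq(cum_trans, L), nonstop)
  }
  root <- ntip + 1L
  seq_store <- vector("list", ntip + tree$Nnode)  # per node: list fam -> codes
  root_seqs <- lapply(truth$node_families[[root]], function(f) new_gene())
  names(root_seqs) <- truth$node_families[[root]]
  seq_store[[root]] <- root_seqs
  marker_store <- vector("list", ntip + tree$Nnode)
  marker_store[[root]] <- cpp_markov_seq(cum_trans, config$marker_length)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- tree$edge.length[match(paste(ord[, 1], ord[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  ev_by_child <- setNames(truth$branch_events,
                          vapply(truth$branch_events, `[[`, "", "child"))
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1]; ch <- ord[e, 2]; t <- lens[e]
    ev <- ev_by_child[[labels[ch]]]
    parent_seqs <- seq_store[[p]]
    fams <- truth$node_families[[ch]]
    child_seqs <- vector("list", length(fams)); names(child_seqs) <- fams
    for (f in fams) {
      if (!is.null(parent_seqs[[f]]) && !(f %in% ev$gained)) {
        child_seqs[[f]] <- .fix_stops(.evolve_coding(parent_seqs[[f]], t),
                                      nonstop)
      } else {
        child_seqs[[f]] <- new_gene()
      }
    }
    seq_store[[ch]] <- child_seqs
    marker_store[[ch]] <- .jc_mutate(marker_store[[p]],
                                     t * config$marker_rate_scale)
  }
  # free internal nodes' sequences as we only need leaves below
  records <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    gid <- tree$tip.label[i]
    fams <- truth$node_families[[i]]
    genes <- vapply(seq_store[[i]][fams],
                    function(cd) paste(bases[cd], collapse = ""), "")
    names(genes) <- paste0(gid, "_", fams)
    nc <- sample.int(10L, 1)
    nc <- min(nc, length(genes))
    breaks <- sort(c(0, sample.int(length(genes) - 1L,
                                   min(nc - 1L, length(genes) - 1L)),
                     length(genes)))
    contigs <- vapply(seq_len(length(breaks) - 1L), function(k)
      paste(genes[(breaks[k] + 1L):breaks[k + 1L]], collapse = ""), "")
    names(contigs) <- sprintf("%s_ctg%02d", gid, seq_along(contigs))
    prots <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(genes), no.init.codon = TRUE))
    names(prots) <- names(genes)
    marker <- paste(bases[marker_store[[i]]], collapse = "")
    names(marker) <- paste0(gid, "_16S")
    records[[i]] <- genome_record(gid, contigs, prots, marker,
                                  quality = c(100, 0, 0))
  }
  names(records) <- tree$tip.label
  records
}

#' Simulate a full synthetic clade in memory
#'
#' Convenience wrapper: tree, gene content, sequences.
#' @param config A [simulation_config()].
#' @return List with `records`, `truth`, `config`.
#' @export
simulate_clade <- function(config) {
  tree <- simulate_species_tree(config)
  truth <- simulate_gene_content(tree, config)
  records <- simulate_sequences(truth, config)
  list(records = records, truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits per-genome nucleotide, protein and marker FASTA files, a quality
#' table, the true tree (Newick), truth tables (species assignment and
#' per-branch events) and a YAML manifest referencing everything.
#'
#' @param records Genome records from [simulate_sequences()].
#' @param truth Matching `clade_truth`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
emit_dataset <- function(records, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("genomes", "proteins", "markers")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  rows <- lapply(records, function(r) {
    fna <- file.path("genomes", paste0(r$genome_id, ".fna"))
    faa <- file.path("proteins", paste0(r$genome_id, ".faa"))
    rrna <- file.path("markers", paste0(r$genome_id, ".16S.fna"))
    write_genome_fasta(r$contigs, file.path(out_dir, fna))
    write_genome_fasta(r$proteins, file.path(out_dir, faa))
    write_genome_fasta(r$rrna_16s, file.path(out_dir, rrna))
    data.frame(genome_id = r$genome_id, label = r$label, fna = fna,
               faa = faa, rrna = rrna, stringsAsFactors = FALSE)
  })
  genomes <- do.call(rbind, rows)
  qual <- data.frame(genome_id = genomes$genome_id, completeness = 100,
                     contamination = 0, heterogeneity = 0)
  write.table(qual, file.path(out_dir, "quality.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(truth$tree, file.path(out_dir, "tree.nwk"))
  sp <- data.frame(genome_id = names(truth$species_of),
                   species = unname(truth$species_of))
  write.table(sp, file.path(out_dir, "truth_species.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ev <- do.call(rbind, lapply(truth$branch_events, function(b)
    data.frame(parent = b$parent, child = b$child,
               gained = paste(b$gained, collapse = ","),
               lost = paste(b$lost, collapse = ","),
               stringsAsFactors = FALSE)))
  write.table(ev, file.path(out_dir, "truth_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- if ("outgroup" %in% genomes$genome_id) "outgroup" else NULL
  manifest <- list(genomes = genomes, outgroup_id = out)
  write_manifest(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
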