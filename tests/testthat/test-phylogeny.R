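test_that("single-copy core selection is exact", {
  m <- matrix(1L, 4, 3, dimnames = list(paste0("f", 1:4), paste0("g", 1:3)))
  m["f2", 2] <- 2L
  m["f3", 3] <- 0L
  expect_equal(single_copy_core(m), c("f1", "f4"))
  m0 <- m; m0[] <- 2L
  expect_error(single_copy_core(m0), "no single-copy")
})

test_that("family distances track substitution fractions", {
  set.seed(111)
  fams <- paste0("f", 1:20)
  seqs <- lapply(fams, function(f) {
    s <- rand_protein(300)
    v <- strsplit(s, "")[[1]]
    idx <- sample(300, 30)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in idx) v[i] <- sample(setdiff(aa, v[i]), 1)
    c(gA = s, gB = paste(v, collapse = ""), gC = s)
  })
  names(seqs) <- fams
  d <- family_distance_matrix(fams, seqs, "protein")
  expect_equal(unname(d["gA", "gC"]), 0)
  expect_lt(abs(d["gA", "gB"] - 0.10), 0.01)
  expect_equal(d, t(d))
})

test_that("neighbor joining recovers 3-taxon closed forms and additive splits", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(d3)
  # pendant lengths (d_AB + d_AC - d_BC)/2 etc.
  lens <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(lens["A"]), 1)
  expect_equal(unname(lens["B"]), 2)
  expect_equal(unname(lens["C"]), 3)

  # additive 4-taxon matrix with true split AB|CD
  tr4 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:1,D:3):0.5);")
  d4 <- ape::cophenetic.phylo(tr4)
  nj4 <- neighbor_joining(d4)
  expect_equal(rf_distance(nj4, tr4), 0L)

  expect_error(neighbor_joining(d3[1:2, 1:2]), "3 taxa")
})

test_that("NJ reconstructs 50 random additive 8-taxon matrices exactly", {
  set.seed(121)
  for (i in 1:50) {
    gen <- random_additive(8)
    nj <- neighbor_joining(gen$dist)
    expect_equal(rf_distance(nj, gen$tree), 0L)
    expect_true(all(nj$edge.length >= 0))
  }
})

test_that("outgroup rooting preserves leaves, adds one node and round-trips", {
  set.seed(131)
  gen <- random_additive(8)
  nj <- neighbor_joining(gen$dist)
  out <- nj$tip.label[1]
  rooted <- root_with_outgroup(nj, out)
  expect_true(ape::is.rooted(rooted))
  expect_setequal(rooted$tip.label, nj$tip.label)
  expect_equal(rooted$Nnode, nj$Nnode + 1L)
  # re-rooting after unrooting returns an RF-0 tree
  rerooted <- root_with_outgroup(ape::unroot(rooted), out)
  expect_equal(rf_distance(rerooted, rooted), 0L)
  expect_error(root_with_outgroup(nj, "nope"), "not a leaf")
})

test_that("RF distance identities", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(rf_distance(t1, t3), "leaf set")
})

test_that("the species tree is recovered from a simulated clade", {
  cfg <- simulation_config(seed = 77, n_species = 8, strains_per_species = 1,
                           root_family_count = 60, include_outgroup = TRUE,
                           gain_rate = 20, loss_rate = 10)
  sim <- simulate_clade(cfg)
  m <- cluster_orthogroups(sim$records)
  fams <- single_copy_core(m)
  expect_gt(length(fams), 10)
  gf <- attr(m, "gene_family")
  seqs <- lapply(fams, function(f) {
    genes <- names(gf)[gf == f]
    vapply(sim$records, function(r) {
      unname(r$proteins[names(r$proteins) %in% genes][1])
    }, "")
  })
  names(seqs) <- fams
  d <- family_distance_matrix(fams, seqs, "protein")
  nj <- neighbor_joining(d)
  rooted <- root_with_outgroup(nj, "outgroup")
  expect_equal(rf_distance(rooted, sim$truth$tree), 0L)
  # root bipartition: outgroup alone on one side
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  expect_true(match("outgroup", rooted$tip.label) %in% kids)
})
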