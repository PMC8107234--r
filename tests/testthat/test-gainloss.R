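test_that("forced optima and tie-breaking on the 4-leaf quartet", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  mk <- function(v) matrix(v, nrow = 1, dimnames = list("f1", c("A", "B", "C", "D")))

  r <- wagner_parsimony(tr, mk(c(1, 1, 0, 0)))
  expect_equal(r$total_cost, 1)
  expect_equal(sum(lengths(r$branch_gains)), 1L)
  expect_equal(sum(lengths(r$branch_losses)), 0L)

  r2 <- wagner_parsimony(tr, mk(c(1, 0, 1, 0)))
  expect_equal(r2$total_cost, 2)                 # two tip gains beat root gain + losses
  expect_equal(sum(lengths(r2$branch_gains)), 2L)
  expect_false(r2$node_state[5, 1])              # root absent

  r3 <- wagner_parsimony(tr, mk(c(1, 1, 1, 0)))  # cost-2 tie resolved to later gains
  expect_equal(r3$total_cost, 2)
  expect_false(r3$node_state[5, 1])
  expect_equal(sum(lengths(r3$branch_gains)), 2L)
  r3p <- wagner_parsimony(tr, mk(c(1, 1, 1, 0)), ties = "present")
  expect_true(r3p$node_state[5, 1])
})

test_that("total cost equals the enumeration oracle on random small trees", {
  set.seed(141)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)
    pats <- matrix(rbinom(20 * n, 1, 0.5), 20, n,
                   dimnames = list(paste0("f", 1:20), tr$tip.label))
    g <- sample(c(1, 1, 2), 1); l <- sample(c(1, 1, 2), 1)
    rec <- wagner_parsimony(tr, pats, g, l)
    oracle <- sum(vapply(seq_len(nrow(pats)), function(f)
      oracle_wagner_cost(tr, pats[f, ], g, l), 1))
    expect_equal(rec$total_cost, oracle)
  }
})

test_that("branch summaries satisfy the per-branch bookkeeping identity", {
  sim <- small_clade()
  m <- truth_leaf_matrix(sim$truth)
  rec <- wagner_parsimony(sim$truth$tree, m)
  bs <- branch_summary(rec)
  sizes <- rowSums(rec$node_state)
  for (i in seq_len(nrow(bs))) {
    expect_equal(bs$n_present_child[i],
                 unname(sizes[bs$parent[i]]) + bs$n_gained[i] - bs$n_lost[i])
  }
})

test_that("raising the loss penalty never increases inferred losses", {
  set.seed(151)
  tr <- ape::rtree(8)
  pats <- matrix(rbinom(100 * 8, 1, 0.4), 100, 8,
                 dimnames = list(paste0("f", 1:100), tr$tip.label))
  prev <- Inf
  for (l in c(0.5, 1, 2, 4)) {
    rec <- wagner_parsimony(tr, pats, gain_penalty = 1, loss_penalty = l)
    n_loss <- sum(lengths(rec$branch_losses))
    expect_lte(n_loss, prev)
    prev <- n_loss
  }
})

test_that("LCA content queries work for nodes, leaves and leaf pairs", {
  cfg <- simulation_config(seed = 33, n_species = 3, strains_per_species = 1,
                           root_family_count = 30, gain_rate = 0, loss_rate = 0)
  tr <- simulate_species_tree(cfg)
  truth <- simulate_gene_content(tr, cfg)
  m <- truth_leaf_matrix(truth)
  rec <- wagner_parsimony(tr, m)
  root_set <- truth$node_families[[length(tr$tip.label) + 1L]]
  expect_setequal(lca_content(rec, tr$tip.label), root_set)
  expect_setequal(lca_content(rec, "s01_t01"), root_set)  # zero-event clade
  expect_setequal(lca_content(rec, tr$tip.label[1:2]), root_set)
  expect_error(lca_content(rec, "nope"), "unknown")
})

test_that("category profiles always sum to 100 with unassigned remainder", {
  ann <- c(f1 = "Metabolism", f2 = "Metabolism", f3 = "Signaling")
  p <- category_profile(c("f1", "f2", "f3", "f4"), ann)
  expect_equal(sum(p), 100, tolerance = 1e-9)
  expect_equal(unname(p[["Metabolism"]]), 50)
  expect_equal(unname(p[["unassigned"]]), 25)
  p1 <- category_profile(c("f1", "f2"), ann)
  expect_equal(unname(p1[["Metabolism"]]), 100)
  expect_error(category_profile(character(0), ann), "empty")
})
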