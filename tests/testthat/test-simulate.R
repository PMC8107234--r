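test_that("species tree has the requested shape and is deterministic", {
  cfg2 <- simulation_config(seed = 3, n_species = 2, strains_per_species = 1)
  tr2 <- simulate_species_tree(cfg2)
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(tr2$Nnode, 1L)

  cfg <- simulation_config(seed = 3, n_species = 8, strains_per_species = 3)
  tr <- simulate_species_tree(cfg)
  expect_equal(length(tr$tip.label), 24L)
  expect_identical(ape::write.tree(simulate_species_tree(cfg)),
                   ape::write.tree(tr))
  expect_error(simulation_config(seed = 1, n_species = 1))
})

test_that("gene content respects degenerate rates and event bookkeeping", {
  cfg <- simulation_config(seed = 5, n_species = 4, strains_per_species = 2,
                           root_family_count = 50)
  tr <- simulate_species_tree(cfg)

  cfg0 <- cfg; cfg0$loss_rate <- 0
  tg <- simulate_gene_content(tr, cfg0)
  root_set <- tg$node_families[[length(tr$tip.label) + 1L]]
  for (tip in tr$tip.label)
    expect_true(all(root_set %in% tg$node_families[[tip]]))

  cfg00 <- cfg; cfg00$loss_rate <- 0; cfg00$gain_rate <- 0
  tg0 <- simulate_gene_content(tr, cfg00)
  for (tip in tr$tip.label)
    expect_setequal(tg0$node_families[[tip]], root_set)

  # bookkeeping: |child| = |parent| + gains - losses on every branch
  tg1 <- simulate_gene_content(tr, cfg)
  for (b in tg1$branch_events) {
    expect_equal(length(tg1$node_families[[b$child]]),
                 length(tg1$node_families[[b$parent]]) +
                   length(b$gained) - length(b$lost))
  }
})

test_that("branch gains are Poisson with the configured mean", {
  # 1000 one-unit branches at gain_rate 5: a two-leaf tree with depth-1 tips
  set.seed(1)
  cfg <- simulation_config(seed = 1, n_species = 2, strains_per_species = 1,
                           tree_depth = 1, min_species_separation = 0.01,
                           root_family_count = 1, gain_rate = 5, loss_rate = 0)
  gains <- integer(0)
  for (s in 1:500) {
    cfg$seed <- s
    tr <- simulate_species_tree(cfg)
    tg <- simulate_gene_content(tr, cfg)
    # both tip branches have length 1
    gains <- c(gains, vapply(tg$branch_events, function(b) length(b$gained), 1L))
  }
  expect_gt(mean(gains), 4.8)
  expect_lt(mean(gains), 5.2)
})

test_that("sequence evolution is calibrated: zero branches, intra divergence, marker", {
  # gain/loss off so strain genomes are positionally comparable
  cfg <- simulation_config(seed = 9, n_species = 2, strains_per_species = 2,
                           root_family_count = 120, gain_rate = 0, loss_rate = 0)
  sim <- simulate_clade(cfg)
  cat_genome <- function(r) paste(r$contigs, collapse = "")
  a <- strsplit(cat_genome(sim$records[["s01_t01"]]), "")[[1]]
  b <- strsplit(cat_genome(sim$records[["s01_t02"]]), "")[[1]]
  expect_equal(length(a), length(b))
  expect_gt(length(a), 100000)
  div <- mean(a != b)
  expect_lt(abs(div - 0.01), 0.002)

  # 16S-like marker divergence matches expected-substitution arithmetic:
  # JC change probability at path length x is 3/4 (1 - exp(-4/3 x))
  path <- ape::cophenetic.phylo(sim$truth$tree)["s01_t01", "s02_t01"]
  expected_id <- 100 * (1 - 0.75 * (1 - exp(-4 / 3 * 0.05 * path)))
  m <- marker_identity(sim$records[["s01_t01"]]$rrna_16s[[1]],
                       sim$records[["s02_t01"]]$rrna_16s[[1]])
  expect_lt(abs(m[["identity"]] - expected_id), 1.5)
  expect_gte(m[["identity"]], 97.5)

  # zero-length branch: identical sequences (strain star at divergence 0)
  cfg0 <- simulation_config(seed = 10, n_species = 2, strains_per_species = 2,
                            root_family_count = 10, gain_rate = 0, loss_rate = 0,
                            intra_species_divergence = 1e-12)
  sim0 <- simulate_clade(cfg0)
  expect_identical(paste(sim0$records[["s01_t01"]]$contigs, collapse = ""),
                   paste(sim0$records[["s01_t02"]]$contigs, collapse = ""))
})

test_that("emitted datasets round-trip and are byte-identical under one seed", {
  sim <- small_clade()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  man <- emit_dataset(sim$records, sim$truth, d1)
  expect_equal(nrow(man$genomes), length(sim$records))
  expect_equal(man$outgroup_id, "outgroup")
  qual <- read_quality_table(file.path(d1, "quality.tsv"))
  recs <- load_genomes(man, d1, qual)
  expect_identical(recs[[1]]$contigs, sim$records[[1]]$contigs)
  expect_identical(recs[[5]]$proteins, sim$records[[5]]$proteins)
  expect_equal(recs[[1]]$quality[["completeness"]], 100)

  emit_dataset(sim$records, sim$truth, d2)
  for (f in c("genomes/s01_t01.fna", "proteins/s03_t02.faa", "tree.nwk",
              "truth_events.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }

  # events table covers every edge and matches the in-memory truth
  ev <- read.delim(file.path(d1, "truth_events.tsv"))
  expect_equal(nrow(ev), nrow(sim$truth$tree$edge))
  ev_mem <- vapply(sim$truth$branch_events, function(b)
    paste(sort(b$gained), collapse = ","), "")
  names(ev_mem) <- vapply(sim$truth$branch_events, `[[`, "", "child")
  gained_disk <- vapply(strsplit(ev$gained, ","), function(x)
    paste(sort(x), collapse = ","), "")
  expect_identical(unname(gained_disk), unname(ev_mem[ev$child]))
})
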