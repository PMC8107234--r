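mk_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(genome_a = r[[1]], genome_b = r[[2]], ani = r[[3]],
               ani_fragments = 100L, tetra = r[[4]], aai = r[[5]],
               rbh_pairs = 100L, stringsAsFactors = FALSE)))
}

test_that("triple-condition edges require all three strict inequalities", {
  tab <- mk_table(list("a", "b", 98.0877, 0.99868, 97.61),
                  list("a", "c", 94.9, 0.995, 96.0),
                  list("b", "c", 95.0, 0.99, 95.0))
  g <- suppressWarnings(build_species_graph(tab))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$genome_a, "a")
  expect_equal(g$edges$genome_b, "b")
  ne <- g$non_edges
  expect_equal(ne$passed[ne$genome_a == "a" & ne$genome_b == "c"], "TETRA,AAI")
  expect_equal(ne$passed[ne$genome_a == "b" & ne$genome_b == "c"], "")
})

test_that("clusters are connected components with transitivity violations surfaced", {
  tab <- mk_table(list("A", "B", 97, 0.999, 97), list("B", "C", 97, 0.999, 97),
                  list("A", "C", 94, 0.999, 97))
  cl <- cluster_species(build_species_graph(tab))
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, c("A", "B", "C"))
  expect_equal(nrow(cl[[1]]$incomplete_pairs), 1L)
  expect_equal(cl[[1]]$incomplete_pairs$genome_a, "A")
  expect_equal(cl[[1]]$incomplete_pairs$genome_b, "C")

  tab5 <- mk_table(list("a", "b", 80, 0.9, 80), list("a", "c", 80, 0.9, 80),
                   list("a", "d", 80, 0.9, 80), list("a", "e", 80, 0.9, 80),
                   list("b", "c", 80, 0.9, 80), list("b", "d", 80, 0.9, 80),
                   list("b", "e", 80, 0.9, 80), list("c", "d", 80, 0.9, 80),
                   list("c", "e", 80, 0.9, 80), list("d", "e", 80, 0.9, 80))
  cl5 <- cluster_species(build_species_graph(tab5))
  expect_length(cl5, 5L)
  # partition property
  expect_setequal(unlist(lapply(cl5, `[[`, "members")), letters[1:5])
})

test_that("gray zones report partial criteria and the ANI discontinuity fraction", {
  tab <- mk_table(list("a", "b", 97, 0.999, 97),   # same cluster
                  list("a", "c", 94.2, 0.993, 94.8),
                  list("b", "c", 82, 0.9, 80))
  cl <- cluster_species(build_species_graph(tab))
  gz <- flag_gray_zones(tab, cl)
  expect_equal(nrow(gz$gray_pairs), 1L)
  expect_equal(gz$gray_pairs$passed, "TETRA")
  expect_equal(gz$discontinuity_fraction, 1 / 3)  # only the 94.2 pair in 83-95

  tab2 <- mk_table(list("a", "b", 97, 0.999, 97), list("a", "c", 70, 0.9, 60),
                   list("b", "c", 70, 0.9, 60))
  cl2 <- cluster_species(build_species_graph(tab2))
  expect_equal(flag_gray_zones(tab2, cl2)$discontinuity_fraction, 0)
})

test_that("raising thresholds never decreases the number of clusters", {
  set.seed(71)
  for (rep in 1:20) {
    n <- 8
    ids <- paste0("g", 1:n)
    pairs <- t(combn(ids, 2))
    tab <- data.frame(genome_a = pairs[, 1], genome_b = pairs[, 2],
                      ani = runif(nrow(pairs), 90, 100), ani_fragments = 10L,
                      tetra = runif(nrow(pairs), 0.98, 1),
                      aai = runif(nrow(pairs), 90, 100), rbh_pairs = 10L)
    n_prev <- -1
    for (ani_min in c(92, 94, 96, 98)) {
      th <- species_thresholds(ani_min = ani_min)
      ncl <- length(cluster_species(suppressWarnings(build_species_graph(tab, th))))
      expect_gte(ncl, n_prev)
      n_prev <- ncl
    }
  }
})

test_that("naming precedence: type strains, merges, 16S rules, unknown letters", {
  tab <- mk_table(list("g1", "g2", 97, 0.999, 97), list("g1", "g3", 80, 0.9, 80),
                  list("g2", "g3", 80, 0.9, 80), list("g1", "g4", 80, 0.9, 80),
                  list("g2", "g4", 80, 0.9, 80), list("g3", "g4", 80, 0.9, 80),
                  list("g1", "g5", 80, 0.9, 80), list("g2", "g5", 80, 0.9, 80),
                  list("g3", "g5", 80, 0.9, 80), list("g4", "g5", 80, 0.9, 80))
  cl <- cluster_species(build_species_graph(tab))

  set.seed(81)
  ref16 <- rand_dna(1500)
  near <- substitute_dna(ref16, 10)        # 99.33% identical
  far <- substitute_dna(ref16, 40)         # 97.3% identical, below 99
  short <- substr(substitute_dna(ref16, 2), 1, 1198)  # matching but too short
  refs <- data.frame(name = c("Species one", "Species two", "Species three"),
                     genome_id = c("g1", "g2", NA),
                     marker_seq = c(NA, NA, ref16), stringsAsFactors = FALSE)
  markers <- list(g1 = character(0), g2 = character(0),
                  g3 = near, g4 = short, g5 = far)
  named <- suppressWarnings(assign_names(cl, refs, markers))
  byrep <- setNames(named, vapply(named, `[[`, "", "representative"))
  # g1+g2 cluster carries both type-strain names (merge)
  expect_warning(assign_names(cl, refs, markers), "merge")
  expect_match(byrep[["g1"]]$name, "Species one / Species two")
  expect_equal(byrep[["g1"]]$evidence, "type_strain")
  # full-length matching 16S names its cluster
  expect_equal(byrep[["g3"]]$name, "Species three")
  expect_equal(byrep[["g3"]]$evidence, "marker_match")
  # 1198-nt marker is refused despite matching; 97.3% identity is below 99
  expect_match(byrep[["g4"]]$name, "unknown group")
  expect_match(byrep[["g5"]]$name, "unknown group")
  expect_equal(sort(c(byrep[["g4"]]$name, byrep[["g5"]]$name)),
               c("unknown group A", "unknown group B"))
})
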