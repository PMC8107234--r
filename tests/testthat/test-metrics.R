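test_that("ANI of a genome against an exact copy is 100", {
  set.seed(41)
  g <- rand_dna(30000)
  r <- compute_ani(g, g)
  expect_equal(r$ani, 100)
  expect_gt(r$fragments, 0)
})

test_that("ANI matches the Hamming oracle on a 2% substituted copy", {
  set.seed(42)
  g <- rand_dna(1e5)
  g2 <- substitute_dna(g, 2000)
  r <- compute_ani(g, g2)
  expect_lt(abs(r$ani - 98.0), 0.2)
})

test_that("ANI is symmetric and never increases with substitution fraction", {
  set.seed(43)
  g <- rand_dna(50000)
  prev <- 101
  for (f in seq(0, 0.10, by = 0.02)) {
    g2 <- if (f == 0) g else substitute_dna(g, round(f * nchar(g)))
    a <- compute_ani(g, g2)$ani
    b <- compute_ani(g2, g)$ani
    expect_equal(a, b)
    expect_lte(a, prev + 1e-9)
    prev <- a
  }
})

test_that("unrelated random sequences yield no ANI homology", {
  set.seed(44)
  r <- compute_ani(rand_dna(20000), rand_dna(20000))
  expect_true(is.na(r$ani))
  expect_equal(attr(r, "reason"), "no homology")
})

test_that("AAI identities: identical proteomes and 10% substituted copies", {
  set.seed(51)
  prot <- setNames(vapply(1:40, function(i) rand_protein(sample(200:400, 1)), ""),
                   paste0("p", 1:40))
  r <- compute_aai(prot, prot)
  expect_equal(r$aai, 100)
  expect_equal(r$rbh_pairs, 40L)

  subst_prot <- function(s, frac) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(v), round(frac * length(v)))
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in idx) v[i] <- sample(setdiff(aa, v[i]), 1)
    paste(v, collapse = "")
  }
  prot2 <- setNames(vapply(prot, subst_prot, "", frac = 0.10), names(prot))
  r2 <- compute_aai(prot, prot2)
  expect_lt(abs(r2$aai - 90.0), 0.5)
  r3 <- compute_aai(prot2, prot)
  expect_equal(r2$aai, r3$aai)
  expect_error(compute_aai(prot, character(0)), "proteome")
})

test_that("marker identity and coverages follow the free-end-gap contract", {
  set.seed(61)
  s <- rand_dna(1500)
  m <- marker_identity(s, s)
  expect_equal(unname(m), c(100, 100, 100))

  s2 <- substitute_dna(s, 15)
  expect_equal(marker_identity(s, s2)[["identity"]], 99.0)

  mid <- substr(s, 251, 1250)
  m3 <- marker_identity(s, mid)
  expect_equal(m3[["target_coverage"]], 100)
  expect_lt(abs(m3[["query_coverage"]] - 66.7), 0.5)
  expect_lt(m3[["query_coverage"]], 80)  # fails the 80% coverage rule
})

test_that("all-pairs tables cover n(n-1)/2 pairs and reruns reuse the cache", {
  sim <- small_clade()
  recs <- sim$records[1:4]
  cache <- withr::local_tempdir()
  t1 <- suppressWarnings(compute_all_pairs(recs, cache_dir = cache))
  expect_equal(nrow(t1), 6L)
  # poison one cached pair to prove the rerun reads the cache
  poison <- t1[1, ]; poison$ani <- 12.34
  write.table(poison, file.path(cache, paste0(poison$genome_a, "__",
                                              poison$genome_b, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  t2 <- suppressWarnings(compute_all_pairs(recs, cache_dir = cache))
  expect_equal(t2$ani[1], 12.34)
  expect_equal(t2[-1, ], t1[-1, ], ignore_attr = TRUE)
})
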