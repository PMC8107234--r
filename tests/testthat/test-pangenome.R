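test_that("orthogroup clustering handles identity, paralogs and input order", {
  set.seed(91)
  prots <- setNames(vapply(1:30, function(i) rand_protein(sample(150:350, 1)), ""),
                    sprintf("gA_p%02d", 1:30))
  protsB <- setNames(prots, sprintf("gB_p%02d", 1:30))
  m <- cluster_orthogroups(list(gA = prots, gB = protsB))
  expect_equal(nrow(m), 30L)
  expect_true(all(m == 1L))

  # an in-genome duplicate becomes occurrence count 2
  dup <- c(prots, setNames(prots[1], "gA_dup"))
  m2 <- cluster_orthogroups(list(gA = dup, gB = protsB))
  expect_equal(nrow(m2), 30L)
  expect_equal(sum(m2[, "gA"] == 2), 1L)

  # invariant to input order (canonical sort inside)
  m3 <- cluster_orthogroups(list(gB = protsB, gA = prots))
  expect_equal(m3[, c("gA", "gB")], m[, c("gA", "gB")], ignore_attr = TRUE)
  expect_equal(rownames(m3), rownames(m))
})

test_that("pangenome categories follow the thresholds and always sum to total", {
  m <- matrix(0L, 3, 10, dimnames = list(c("core", "shellf", "cloudf"),
                                         paste0("g", 1:10)))
  m["core", ] <- 1L
  m["shellf", 1:2] <- 1L
  m["cloudf", 1] <- 1L
  s <- categorize(m)
  expect_equal(s$core, 1L)
  expect_equal(s$shell, 1L)   # 2/10 = 0.20 >= 0.15
  expect_equal(s$cloud, 1L)   # 1/10 < 0.15
  expect_equal(s$core + s$soft_core + s$shell + s$cloud, s$total)

  set.seed(101)
  for (i in 1:10) {
    mm <- matrix(rbinom(20 * 12, 1, runif(1, 0.1, 0.9)), 20, 12)
    mm <- mm[rowSums(mm) > 0, , drop = FALSE]
    colnames(mm) <- paste0("g", 1:12); rownames(mm) <- paste0("f", seq_len(nrow(mm)))
    s2 <- categorize(mm)
    expect_equal(s2$core + s2$soft_core + s2$shell + s2$cloud, nrow(mm))
  }
})

test_that("rarefaction curves are monotone in every permutation and anchored", {
  sim <- small_clade()
  m <- truth_leaf_matrix(sim$truth)
  cv <- rarefaction(m, n_permutations = 50, seed = 5, keep_permutations = TRUE)
  pan <- attr(cv, "pan"); core <- attr(cv, "core")
  expect_true(all(pan[, -1] - pan[, -ncol(pan)] >= 0))
  expect_true(all(core[, -1] - core[, -ncol(core)] <= 0))
  expect_true(all(pan[, ncol(pan)] == nrow(m)))
  expect_equal(cv$core_median[1], cv$pan_median[1])
  sizes <- colSums(m > 0)
  expect_gte(cv$pan_median[1], min(sizes))
  expect_lte(cv$pan_median[1], max(sizes))

  # all genomes identical: flat curves
  flat <- matrix(1L, 7, 5, dimnames = list(paste0("f", 1:7), paste0("g", 1:5)))
  cvf <- rarefaction(flat, n_permutations = 20, seed = 1)
  expect_true(all(cvf$pan_median == 7))
  expect_true(all(cvf$core_median == 7))
})

test_that("openness fit recovers exact power laws to 1e-6", {
  N <- 1:40
  curves <- data.frame(N = N, new_median = 100 * N^-0.5)
  fit <- fit_openness(curves)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-6)
  expect_equal(fit$kappa, 100, tolerance = 1e-4)
  expect_true(fit$open)
  expect_error(fit_openness(data.frame(N = 1:5, new_median = 0)), "undefined")
})

test_that("per-genome rates mirror the curve arithmetic", {
  N <- 1:25
  curves <- data.frame(N = N, new_median = 100 * N^-0.5,
                       core_median = seq(500, by = -1, length.out = 25))
  fit <- fit_openness(curves)
  r <- per_genome_rates(curves, fit)
  expect_equal(unname(r[["pan_gain_per_genome"]]), 100 * 25^-0.5, tolerance = 1e-6)
  # core 500 at N=2 falling to 438 at N=102 gives 0.62/genome
  curves2 <- data.frame(N = c(2, 52, 102), new_median = c(70, 14, 7),
                        core_median = c(500, 470, 438))
  fit2 <- fit_openness(curves2)
  r2 <- per_genome_rates(curves2, fit2)
  expect_equal(unname(r2[["core_loss_per_genome"]]), 0.62)
})

test_that("frequency histogram conserves the family total and windows scale", {
  m <- matrix(0L, 6, 10, dimnames = list(paste0("f", 1:6), paste0("g", 1:10)))
  m[1:4, 1] <- 1L            # four singletons
  m[5:6, ] <- 1L             # two core families
  h <- frequency_histogram(m)
  expect_equal(unname(h$histogram[1]), 4L)
  expect_equal(unname(h$histogram[10]), 2L)
  expect_equal(sum(h$histogram), nrow(m))
  expect_equal(h$window, round(c(50, 200) / 224 * 10))
})

test_that("module completeness covers subset cores and filters below 50%", {
  m <- matrix(1L, 12, 4, dimnames = list(sprintf("f%02d", 1:12), paste0("g", 1:4)))
  m[10, 2] <- 0L   # f10 missing from one genome -> not core
  ann <- data.frame(family = sprintf("f%02d", 1:12),
                    step = paste0("K", 1:12), stringsAsFactors = FALSE)
  modules <- list(full = paste0("K", 1:5),
                  atp = paste0("K", c(1:7, 10, 11, 12))[1:10],
                  sparse = paste0("K", c(10, 20, 21, 22, 23, 24, 25, 26, 27, 28)))
  mc <- module_completeness(ann, modules, m)
  expect_equal(mc$completeness[mc$module == "full"], 100)
  expect_equal(mc$completeness[mc$module == "atp"], 90)  # K10 not core
  expect_false("sparse" %in% mc$module)                  # 0/10 < 50%
  expect_error(module_completeness(ann, list(bad = character(0)), m), "zero")
})
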