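#' Cluster proteomes into orthogroups
#'
#' Greedy length-sorted incremental clustering (CD-HIT-like): proteins are
#' sorted by length descending then gene ID, and each joins the
#' earliest-founded cluster whose representative it matches at >=
#' `identity_min` over >= `coverage_min` of the shorter sequence (seeded
#' banded BLOSUM62 alignment), else founds a new cluster.  The canonical
#' internal sort makes the result invariant to input order.
#'
#' @param proteomes Named list (genome_id -> named character vector of
#'   proteins) or a named list of [genome_record]s.
#' @param identity_min,coverage_min Match thresholds (fractions).
#' @return Integer matrix (families x genomes) of occurrence counts, with
#'   family IDs `OG00001..` as row names and attributes `representative`
#'   (founder gene ID per family) and `gene_family` (named vector gene ->
#'   family).
#' @export
cluster_orthogroups <- function(proteomes, identity_min = 0.8,
                                coverage_min = 0.8) {
  if (length(proteomes) == 0) .stopf("no proteomes supplied")
  if (inherits(proteomes[[1]], "genome_record"))
    proteomes <- setNames(lapply(proteomes, `[[`, "proteins"),
                          vapply(proteomes, `[[`, "", "genome_id"))
  if (any(lengths(proteomes) == 0)) .stopf("every genome needs a proteome")
  genome_of <- rep(names(proteomes), lengths(proteomes))
  seqs <- unlist(unname(proteomes))
  if (anyDuplicated(names(seqs))) .stopf("gene IDs must be globally unique")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]; genome_of <- genome_of[ord]
  assign <- cpp_greedy_cluster(seqs, 5L, identity_min, coverage_min)
  n_fam <- max(assign)
  fam_ids <- sprintf("OG%05d", seq_len(n_fam))
  m <- matrix(0L, nrow = n_fam, ncol = length(proteomes),
              dimnames = list(fam_ids, names(proteomes)))
  tab <- table(factor(assign, levels = seq_len(n_fam)),
               factor(genome_of, levels = names(proteomes)))
  m[] <- as.integer(tab)
  reps <- names(seqs)[match(seq_len(n_fam), assign)]
  attr(m, "representative") <- setNames(reps, fam_ids)
  attr(m, "gene_family") <- setNames(fam_ids[assign], names(seqs))
  m
}

#' Partition a pangenome into core / soft-core / shell / cloud
#'
#' Core families are present in 100% of genomes (strict definition);
#' soft-core in at least `soft_min` but not all; shell in at least
#' `shell_min`; the rest is cloud.  Counts always sum to the family total.
#'
#' @param matrix Orthogroup occurrence matrix (families x genomes).
#' @param soft_min,shell_min Category bounds as genome fractions.
#' @return List of class `pangenome_summary` with `core`, `soft_core`,
#'   `shell`, `cloud`, `total` counts and the thresholds used.
#' @export
categorize <- function(matrix, soft_min = 0.95, shell_min = 0.15) {
  if (nrow(matrix) == 0) .stopf("empty orthogroup matrix")
  g <- ncol(matrix)
  freq <- rowSums(matrix > 0) / g
  if (any(freq == 0)) .stopf("matrix contains all-zero family rows")
  core <- sum(freq == 1)
  soft <- sum(freq >= soft_min & freq < 1)
  shell <- sum(freq >= shell_min & freq < soft_min)
  cloud <- sum(freq < shell_min)
  structure(list(core = core, soft_core = soft, shell = shell, cloud = cloud,
                 total = nrow(matrix),
                 soft_min = soft_min, shell_min = shell_min),
            class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat(sprintf("pangenome: %d families (core %d, soft-core %d, shell %d, cloud %d)\n",
              x$total, x$core, x$soft_core, x$shell, x$cloud))
  invisible(x)
}

#' Rarefaction curves of the pangenome
#'
#' For each of `n_permutations` random genome orderings, computes the
#' cumulative distinct-family (pan), intersection (core) and newly seen
#' (new) family counts at each step, and summarises each curve by its
#' median and 2.5/97.5% quantiles.
#'
#' @param matrix Orthogroup occurrence matrix.
#' @param n_permutations Number of random orderings.
#' @param seed RNG seed (results are deterministic given the seed).
#' @param keep_permutations Attach the raw per-permutation curves as
#'   attributes `pan`, `core`, `new` (matrices permutations x N).
#' @return data.frame of class `rarefaction_curves` with one row per N:
#'   `N`, `pan_median`, `pan_lo`, `pan_hi`, `core_median`, `core_lo`,
#'   `core_hi`, `new_median`, `new_lo`, `new_hi`.
#' @export
rarefaction <- function(matrix, n_permutations = 1000L, seed = 1L,
                        keep_permutations = FALSE) {
  g <- ncol(matrix)
  if (g < 2) .stopf("rarefaction needs at least two genomes")
  set.seed(seed)
  pres <- matrix > 0
  pan <- matrix(0L, n_permutations, g)
  core <- matrix(0L, n_permutations, g)
  new <- matrix(0L, n_permutations, g)
  for (p in seq_len(n_permutations)) {
    ordr <- sample.int(g)
    pp <- pres[, ordr, drop = FALSE]
    first_present <- max.col(pp, ties.method = "first")
    n_absent <- g - rowSums(pp)
    first_absent <- ifelse(n_absent == 0, g + 1L,
                           max.col(!pp, ties.method = "first"))
    new[p, ] <- tabulate(first_present, g)
    pan[p, ] <- cumsum(new[p, ])
    core[p, ] <- nrow(pp) - cumsum(tabulate(first_absent, g + 1L))[seq_len(g)]
  }
  q <- function(m, probs) apply(m, 2, quantile, probs = probs, names = FALSE)
  out <- data.frame(N = seq_len(g),
                    pan_median = q(pan, 0.5), pan_lo = q(pan, 0.025),
                    pan_hi = q(pan, 0.975),
                    core_median = q(core, 0.5), core_lo = q(core, 0.025),
                    core_hi = q(core, 0.975),
                    new_median = q(new, 0.5), new_lo = q(new, 0.025),
                    new_hi = q(new, 0.975))
  class(out) <- c("rarefaction_curves", "data.frame")
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  if (keep_permutations) {
    attr(out, "pan") <- pan
    attr(out, "core") <- core
    attr(out, "new") <- new
  }
  out
}

#' Fit pangenome openness (power law on the new-genes curve)
#'
#' Least-squares fit of `log(median new(N)) = log(kappa) - alpha * log(N)`
#' over `N >= 2` (the first genome's whole repertoire is excluded).  An
#' `alpha < 1` indicates an open pangenome.
#'
#' @param curves Output of [rarefaction()] (or a data.frame with `N` and
#'   `new_median`).
#' @return List of class `openness_fit`: `kappa`, `alpha`, `open`,
#'   `n_points`.
#' @export
fit_openness <- function(curves) {
  keep <- curves$N >= 2 & curves$new_median > 0
  if (sum(keep) < 3)
    .stopf("openness fit undefined: fewer than 3 positive new-gene medians at N >= 2")
  x <- log(curves$N[keep]); y <- log(curves$new_median[keep])
  fit <- lm(y ~ x)
  kappa <- exp(unname(coef(fit)[1])); alpha <- -unname(coef(fit)[2])
  structure(list(kappa = kappa, alpha = alpha, open = alpha < 1,
                 n_points = sum(keep)),
            class = "openness_fit")
}

#' @export
print.openness_fit <- function(x, ...) {
  cat(sprintf("power-law fit: kappa = %.3g, alpha = %.4f -> %s pangenome\n",
              x$kappa, x$alpha, if (x$open) "open" else "closed"))
  invisible(x)
}

#' Per-genome pan gain and core loss rates
#'
#' Pan gain per added genome is the fitted power law evaluated at the full
#' dataset size (`kappa * N_max^-alpha`); core loss per genome is the
#' median core-curve drop between N = 2 and N = N_max divided by
#' `N_max - 2`.
#'
#' @param curves Output of [rarefaction()].
#' @param fit Output of [fit_openness()].
#' @return Named numeric: `pan_gain_per_genome`, `core_loss_per_genome`.
#' @export
per_genome_rates <- function(curves, fit) {
  n_max <- max(curves$N)
  if (n_max < 3) .stopf("need at least 3 genomes for per-genome rates")
  pan_gain <- fit$kappa * n_max^(-fit$alpha)
  core2 <- curves$core_median[curves$N == 2]
  coreN <- curves$core_median[curves$N == n_max]
  c(pan_gain_per_genome = pan_gain,
    core_loss_per_genome = (core2 - coreN) / (n_max - 2))
}

#' Gene-frequency histogram
#'
#' Families binned by the number of genomes containing them, plus the mean
#' number of families per frequency bin over an "accessory" window.  The
#' default window, 50-200 genomes in a 224-genome dataset, is rescaled
#' proportionally to the dataset at hand.
#'
#' @param matrix Orthogroup occurrence matrix.
#' @param window Integer bounds `c(lo, hi)` of the accessory window, or
#'   `NULL` for the proportional default.
#' @return List with `histogram` (named counts for frequencies `1..G`),
#'   `window`, `window_mean`.
#' @export
frequency_histogram <- function(matrix, window = NULL) {
  if (nrow(matrix) == 0) .stopf("empty orthogroup matrix")
  g <- ncol(matrix)
  freq <- rowSums(matrix > 0)
  h <- tabulate(freq, g)
  names(h) <- seq_len(g)
  if (is.null(window))
    window <- pmax(1L, pmin(g, round(c(50, 200) / 224 * g)))
  sel <- seq(window[1], window[2])
  list(histogram = h, window = window, window_mean = mean(h[sel]))
}

#' Metabolic module completeness over a genome subset's core
#'
#' A step is covered when some family present in every genome of the
#' subset is annotated with it; module completeness is the percentage of
#' required steps covered.  Only modules at or above `min_completeness`
#' are reported.
#'
#' @param annotations data.frame with columns `family` and `step` (one row
#'   per family-step assignment), or a named character vector family ->
#'   step.
#' @param modules Named list: module -> character vector of required steps.
#' @param matrix Orthogroup occurrence matrix.
#' @param genomes Genome subset (default: all columns).
#' @param min_completeness Reporting threshold in percent.
#' @return data.frame `module`, `completeness`, `covered`, `required`.
#' @export
module_completeness <- function(annotations, modules, matrix,
                                genomes = colnames(matrix),
                                min_completeness = 50) {
  if (length(modules) == 0) .stopf("no module definitions supplied")
  if (is.character(annotations) && !is.null(names(annotations)))
    annotations <- data.frame(family = names(annotations),
                              step = unname(annotations),
                              stringsAsFactors = FALSE)
  if (any(lengths(modules) == 0)) .stopf("module with zero required steps")
  sub <- matrix[, genomes, drop = FALSE]
  core_fams <- rownames(sub)[rowSums(sub > 0) == length(genomes)]
  covered_steps <- unique(annotations$step[annotations$family %in% core_fams])
  rows <- lapply(names(modules), function(mod) {
    req <- unique(modules[[mod]])
    cov <- sum(req %in% covered_steps)
    data.frame(module = mod, completeness = 100 * cov / length(req),
               covered = cov, required = length(req),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$completeness >= min_completeness, , drop = FALSE]
}
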