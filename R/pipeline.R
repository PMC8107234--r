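#' Pipeline configuration
#'
#' @param manifest Path to a dataset manifest (YAML) or a manifest list.
#' @param out_dir Output directory.
#' @param seed Seed recorded in every output header and used for the
#'   rarefaction permutations.
#' @param n_permutations Rarefaction permutations.
#' @param thresholds A [species_thresholds()].
#' @param identity_min,coverage_min Orthogroup clustering thresholds.
#' @param gain_penalty,loss_penalty Wagner parsimony penalties.
#' @param references Optional naming references (see [assign_names()]).
#' @param stages Stages to run, a subset of
#'   `c("filter", "metrics", "delineate", "pangenome", "tree", "gainloss")`.
#' @param plots Write PNG plots with the report.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, out_dir, seed = 1L,
                            n_permutations = 200L,
                            thresholds = species_thresholds(),
                            identity_min = 0.8, coverage_min = 0.8,
                            gain_penalty = 1, loss_penalty = 1,
                            references = NULL,
                            stages = c("filter", "metrics", "delineate",
                                       "pangenome", "tree", "gainloss"),
                            plots = FALSE) {
  structure(list(manifest = manifest, out_dir = out_dir, seed = as.integer(seed),
                 n_permutations = as.integer(n_permutations),
                 thresholds = thresholds, identity_min = identity_min,
                 coverage_min = coverage_min, gain_penalty = gain_penalty,
                 loss_penalty = loss_penalty, references = references,
                 stages = stages, plots = plots),
            class = "pipeline_config")
}

.write_tsv <- function(df, path, seed, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# panclade %s  seed=%d",
                       as.character(utils::packageVersion("panclade")), seed),
               extra), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline end-to-end
#'
#' Executes the requested stages in dependency order (quality filter ->
#' metrics -> delineation; proteomes -> pangenome -> phylogeny ->
#' gain/loss), writing TSV artifacts under `out_dir`.  Pairwise metrics
#' are cached per pair and reused on rerun.  Everything downstream of the
#' seed is deterministic, so two runs with the same configuration produce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stages <- config$stages
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- if (is.character(config$manifest)) {
    base <- dirname(config$manifest)
    m <- read_manifest(config$manifest)
    attr(m, "base_dir") <- base
    m
  } else config$manifest
  base_dir <- attr(manifest, "base_dir") %||% "."
  qual_path <- file.path(base_dir, "quality.tsv")
  quality <- if (file.exists(qual_path)) read_quality_table(qual_path) else NULL
  records <- load_genomes(manifest, base_dir, quality)
  res <- list(manifest = manifest)

  if ("filter" %in% stages) {
    fq <- filter_quality(records)
    records <- fq$retained
    names(records) <- vapply(records, `[[`, "", "genome_id")
    if (nrow(fq$rejected) > 0)
      .write_tsv(fq$rejected, file.path(out, "rejected_genomes.tsv"), config$seed)
    res$rejected <- fq$rejected
  }
  res$records <- records

  if ("metrics" %in% stages) {
    table <- compute_all_pairs(records,
                               cache_dir = file.path(out, "metrics_cache"),
                               markers = TRUE)
    .write_tsv(table, file.path(out, "metrics.tsv"), config$seed)
    res$metrics <- table
  }

  if ("delineate" %in% stages) {
    if (is.null(res$metrics)) .stopf("delineation needs the metrics stage")
    graph <- build_species_graph(res$metrics, config$thresholds)
    clusters <- cluster_species(graph)
    markers <- lapply(records, `[[`, "rrna_16s")
    clusters <- assign_names(clusters, config$references, markers,
                             config$thresholds)
    gray <- flag_gray_zones(res$metrics, clusters, config$thresholds)
    .write_tsv(cluster_table(clusters), file.path(out, "clusters.tsv"),
               config$seed)
    .write_tsv(gray$gray_pairs, file.path(out, "gray_zones.tsv"), config$seed,
               sprintf("# ANI discontinuity-zone fraction: %.6f",
                       gray$discontinuity_fraction))
    res$clusters <- clusters
    res$gray <- gray
  }

  if (any(c("pangenome", "tree", "gainloss") %in% stages)) {
    matrix <- cluster_orthogroups(records, config$identity_min,
                                  config$coverage_min)
    write_matrix_table(matrix, file.path(out, "gene_content.Rtab"))
    res$matrix <- matrix
  }

  if ("pangenome" %in% stages) {
    summary <- categorize(res$matrix)
    curves <- rarefaction(res$matrix, config$n_permutations, config$seed)
    fit <- tryCatch(fit_openness(curves), error = function(e) NULL)
    rates <- if (!is.null(fit)) per_genome_rates(curves, fit) else NULL
    hist <- frequency_histogram(res$matrix)
    .write_tsv(data.frame(core = summary$core, soft_core = summary$soft_core,
                          shell = summary$shell, cloud = summary$cloud,
                          total = summary$total),
               file.path(out, "pangenome_summary.tsv"), config$seed)
    .write_tsv(as.data.frame(curves), file.path(out, "rarefaction.tsv"),
               config$seed,
               if (!is.null(fit))
                 sprintf("# power law: kappa=%.6g alpha=%.6f (%s)",
                         fit$kappa, fit$alpha,
                         if (fit$open) "open" else "closed") else character())
    res$pangenome <- list(summary = summary, curves = curves, fit = fit,
                          rates = rates, histogram = hist)
  }

  if (any(c("tree", "gainloss") %in% stages)) {
    fams <- single_copy_core(res$matrix)
    gene_family <- attr(res$matrix, "gene_family")
    seqs <- lapply(fams, function(f) {
      genes <- names(gene_family)[gene_family == f]
      gid <- vapply(records, function(r) {
        hit <- genes[genes %in% names(r$proteins)]
        r$proteins[[hit[1]]]
      }, "")
      gid
    })
    names(seqs) <- fams
    d <- family_distance_matrix(fams, seqs, "protein")
    tree <- neighbor_joining(d)
    if (!is.null(manifest$outgroup_id))
      tree <- root_with_outgroup(tree, manifest$outgroup_id)
    else {
      tree <- phytools::midpoint.root(tree)
      tree$node.label <- paste0("N", seq_len(tree$Nnode))
    }
    write_newick(tree, file.path(out, "core_tree.nwk"))
    res$tree <- tree
    res$core_families <- fams
  }

  if ("gainloss" %in% stages) {
    recon <- wagner_parsimony(res$tree, res$matrix,
                              config$gain_penalty, config$loss_penalty)
    bs <- branch_summary(recon)
    .write_tsv(bs, file.path(out, "gain_loss_branches.tsv"), config$seed)
    res$gainloss <- recon
    res$branch_summary <- bs
  }
  saved <- file.path(out, "run_report.md")
  pipeline_report(res, config, saved)
  invisible(res)
}

#' Write a human-readable run report
#'
#' Markdown summary of whatever stages ran: species clusters (Table-1
#' style), pangenome category counts, openness, the core tree and the
#' per-branch gain/loss table.  Sections for stages that did not run are
#' marked "not run".
#'
#' @param res Stage results from [run_pipeline()].
#' @param config The [pipeline_config()] used.
#' @param path Output path of the Markdown report.
#' @return The path, invisibly.
#' @export
pipeline_report <- function(res, config, path) {
  lines <- c("# panclade run report", "",
             sprintf("- seed: %d", config$seed),
             sprintf("- genomes analysed: %d", length(res$records)), "")
  lines <- c(lines, "## Genomic species", "")
  if (!is.null(res$clusters)) {
    tab <- cluster_table(res$clusters)
    lines <- c(lines, sprintf("%d clusters over %d genomes",
                              length(res$clusters), nrow(tab)), "")
    for (cl in res$clusters)
      lines <- c(lines, sprintf("- %s: %s (%d genomes, evidence: %s)",
                                cl$cluster_id, cl$name, length(cl$members),
                                cl$evidence))
    lines <- c(lines, "",
               sprintf("ANI discontinuity-zone fraction: %.4f",
                       res$gray$discontinuity_fraction),
               sprintf("gray-zone pairs: %d", nrow(res$gray$gray_pairs)), "")
  } else lines <- c(lines, "not run", "")
  lines <- c(lines, "## Pangenome", "")
  if (!is.null(res$pangenome)) {
    s <- res$pangenome$summary
    lines <- c(lines, sprintf(
      "families: %d (core %d, soft-core %d, shell %d, cloud %d)",
      s$total, s$core, s$soft_core, s$shell, s$cloud))
    if (!is.null(res$pangenome$fit)) {
      f <- res$pangenome$fit
      lines <- c(lines, sprintf(
        "power-law fit: kappa = %.4g, alpha = %.4f -> %s pangenome",
        f$kappa, f$alpha, if (f$open) "open" else "closed"))
      r <- res$pangenome$rates
      lines <- c(lines, sprintf(
        "pan gain %.2f families/genome; core loss %.3f families/genome",
        r[["pan_gain_per_genome"]], r[["core_loss_per_genome"]]))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "not run", "")
  lines <- c(lines, "## Core-genome tree", "")
  if (!is.null(res$tree)) {
    lines <- c(lines, sprintf("%d single-copy core families; %d leaves",
                              length(res$core_families),
                              length(res$tree$tip.label)), "")
  } else lines <- c(lines, "not run", "")
  lines <- c(lines, "## Gene gain/loss", "")
  if (!is.null(res$branch_summary)) {
    bs <- res$branch_summary
    lines <- c(lines, sprintf("total gains %d, total losses %d, cost %g",
                              sum(bs$n_gained), sum(bs$n_lost),
                              res$gainloss$total_cost), "",
               paste(capture.output(print(bs, row.names = FALSE)),
                     collapse = "\n"), "")
  } else lines <- c(lines, "not run", "")
  writeLines(lines, path)
  if (isTRUE(config$plots) && !is.null(res$pangenome)) {
    try({
      png_path <- file.path(dirname(path), "rarefaction.png")
      grDevices::png(png_path, width = 900, height = 450)
      cv <- res$pangenome$curves
      graphics::par(mfrow = c(1, 2))
      graphics::plot(cv$N, cv$pan_median, type = "l", xlab = "genomes",
                     ylab = "pan families", main = "Pangenome rarefaction")
      graphics::lines(cv$N, cv$pan_lo, lty = 2)
      graphics::lines(cv$N, cv$pan_hi, lty = 2)
      graphics::plot(cv$N, cv$core_median, type = "l", xlab = "genomes",
                     ylab = "core families", main = "Core rarefaction")
      graphics::lines(cv$N, cv$core_lo, lty = 2)
      graphics::lines(cv$N, cv$core_hi, lty = 2)
      grDevices::dev.off()
    }, silent = TRUE)
  }
  invisible(path)
}
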