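#' Thresholds of the genomic species criterion
#'
#' Defaults follow the conventional intra-species boundaries: ANI > 95%,
#' TETRA > 0.99 and AAI > 95% (all strict), with 16S naming requiring
#' >= 99% identity, both coverages >= 80% and marker length > 1400 nt.
#'
#' @param ani_min,tetra_min,aai_min Metric thresholds (strict `>`).
#' @param marker_identity_min,marker_coverage_min 16S naming thresholds (%).
#' @param marker_length_min Minimum 16S length (nt, strict `>`).
#' @return A list of class `species_thresholds`.
#' @export
species_thresholds <- function(ani_min = 95, tetra_min = 0.99, aai_min = 95,
                               marker_identity_min = 99,
                               marker_coverage_min = 80,
                               marker_length_min = 1400) {
  stopifnot(ani_min >= 0, ani_min <= 100, aai_min >= 0, aai_min <= 100,
            tetra_min >= -1, tetra_min <= 1)
  structure(list(ani_min = ani_min, tetra_min = tetra_min, aai_min = aai_min,
                 marker_identity_min = marker_identity_min,
                 marker_coverage_min = marker_coverage_min,
                 marker_length_min = marker_length_min),
            class = "species_thresholds")
}

.criteria_passed <- function(row, th) {
  passed <- character(0)
  if (!is.na(row$ani) && row$ani > th$ani_min) passed <- c(passed, "ANI")
  if (!is.na(row$tetra) && row$tetra > th$tetra_min) passed <- c(passed, "TETRA")
  if (!is.na(row$aai) && row$aai > th$aai_min) passed <- c(passed, "AAI")
  passed
}

#' Build the triple-condition species graph
#'
#' Two genomes are connected iff ANI > `ani_min` AND TETRA > `tetra_min`
#' AND AAI > `aai_min` (strict inequalities; an undefined metric fails its
#' criterion).  Every non-edge is annotated with the subset of criteria it
#' did pass, which feeds the gray-zone report.
#'
#' @param table A `pairwise_metrics` data.frame covering all pairs.
#' @param th A [species_thresholds()].
#' @return List of class `species_graph`: `graph` (igraph), `genomes`,
#'   `edges` and `non_edges` data.frames (the latter with a `passed`
#'   column), `thresholds`.
#' @export
build_species_graph <- function(table, th = species_thresholds()) {
  genomes <- sort(unique(c(table$genome_a, table$genome_b)))
  n_expected <- choose(length(genomes), 2)
  if (nrow(table) < n_expected)
    .warnf("metric table has %d of %d pairs; missing pairs count as no-edge",
           nrow(table), n_expected)
  passed_list <- lapply(seq_len(nrow(table)), function(i)
    .criteria_passed(table[i, ], th))
  is_edge <- vapply(passed_list, length, 1L) == 3L
  boundary <- !is.na(table$ani) & table$ani == th$ani_min |
    !is.na(table$tetra) & table$tetra == th$tetra_min |
    !is.na(table$aai) & table$aai == th$aai_min
  if (any(boundary))
    .warnf("%d pair(s) sit exactly on a threshold (strict rule excludes them)",
           sum(boundary))
  ann <- data.frame(genome_a = table$genome_a, genome_b = table$genome_b,
                    passed = vapply(passed_list, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    ann[is_edge, c("genome_a", "genome_b"), drop = FALSE],
    directed = FALSE, vertices = genomes)
  structure(list(graph = g, genomes = genomes,
                 edges = ann[is_edge, , drop = FALSE],
                 non_edges = ann[!is_edge, , drop = FALSE],
                 thresholds = th),
            class = "species_graph")
}

#' Cluster genomes into genomic species
#'
#' Genomic species = connected components of the triple-condition graph.
#' Transitivity violations (member pairs inside one component that fail
#' the full criterion) are surfaced in `incomplete_pairs`, never silently
#' merged away or split.  Clusters are ordered by size (descending) then
#' representative ID; the representative is the lexicographically first
#' member.
#'
#' @param graph A `species_graph` from [build_species_graph()].
#' @return List of `species_cluster` objects (fields: `cluster_id`,
#'   `members`, `representative`, `name`, `evidence`, `incomplete_pairs`).
#' @export
cluster_species <- function(graph) {
  comp <- igraph::components(graph$graph)
  member_of <- split(names(comp$membership), comp$membership)
  reps <- vapply(member_of, function(m) sort(m)[1], "")
  ord <- order(-lengths(member_of), reps)
  bad <- graph$non_edges
  clusters <- lapply(seq_along(ord), function(i) {
    m <- sort(member_of[[ord[i]]])
    inc <- bad[bad$genome_a %in% m & bad$genome_b %in% m, , drop = FALSE]
    structure(list(cluster_id = sprintf("C%02d", i), members = m,
                   representative = m[1], name = NA_character_,
                   evidence = "unnamed",
                   incomplete_pairs = inc),
              class = "species_cluster")
  })
  clusters
}

#' Gray zones and the ANI discontinuity zone
#'
#' Reports every inter-cluster pair that passes at least one but not all
#' criteria (ambiguous species boundaries), plus the fraction of all pairs
#' whose ANI falls in the sparsely populated 83-95% "discontinuity zone".
#'
#' @param table A `pairwise_metrics` data.frame.
#' @param clusters Clusters from [cluster_species()].
#' @param th A [species_thresholds()].
#' @param zone ANI bounds of the discontinuity zone.
#' @return List with `gray_pairs` data.frame (`genome_a`, `genome_b`,
#'   `cluster_a`, `cluster_b`, `passed`) and `discontinuity_fraction`.
#' @export
flag_gray_zones <- function(table, clusters, th = species_thresholds(),
                            zone = c(83, 95)) {
  cl_of <- unlist(lapply(clusters, function(cl)
    setNames(rep(cl$cluster_id, length(cl$members)), cl$members)))
  rows <- list()
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    ca <- cl_of[[row$genome_a]]; cb <- cl_of[[row$genome_b]]
    if (identical(ca, cb)) next
    passed <- .criteria_passed(row, th)
    if (length(passed) >= 1 && length(passed) < 3) {
      rows[[length(rows) + 1]] <-
        data.frame(genome_a = row$genome_a, genome_b = row$genome_b,
                   cluster_a = ca, cluster_b = cb,
                   passed = paste(passed, collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  gray <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(genome_a = character(), genome_b = character(),
               cluster_a = character(), cluster_b = character(),
               passed = character(), stringsAsFactors = FALSE)
  in_zone <- !is.na(table$ani) & table$ani >= zone[1] & table$ani <= zone[2]
  list(gray_pairs = gray,
       discontinuity_fraction = sum(in_zone) / nrow(table))
}

#' Assign species names to clusters
#'
#' Precedence: (1) a cluster containing a reference type-strain genome
#' takes that species name (several type strains in one cluster are all
#' reported, as a merge); (2) otherwise a member 16S longer than
#' `marker_length_min` matching a reference 16S at >=
#' `marker_identity_min` with both coverages >= `marker_coverage_min`
#' names the cluster with evidence `"marker_match"`; (3) otherwise the
#' cluster becomes "unknown group A", "B", ... in cluster order.
#'
#' @param clusters Clusters from [cluster_species()].
#' @param references data.frame with columns `name`, `genome_id` (NA if the
#'   reference has no genome here) and `marker_seq` (16S sequence or NA).
#' @param markers Named list: genome_id -> character vector of its 16S
#'   sequences.
#' @param th A [species_thresholds()].
#' @return The clusters, with `name` and `evidence` filled in.
#' @export
assign_names <- function(clusters, references = NULL, markers = NULL,
                         th = species_thresholds()) {
  letter_seq <- c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))
  next_letter <- 1L
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    name <- NULL; evidence <- NULL
    if (!is.null(references) && nrow(references) > 0) {
      hit <- references[!is.na(references$genome_id) &
                          references$genome_id %in% cl$members, , drop = FALSE]
      if (nrow(hit) > 0) {
        name <- paste(sort(unique(hit$name)), collapse = " / ")
        evidence <- "type_strain"
        if (nrow(hit) > 1)
          .warnf("cluster %s merges type strains: %s", cl$cluster_id, name)
      }
    }
    if (is.null(name) && !is.null(references) && !is.null(markers)) {
      refs <- references[!is.na(references$marker_seq), , drop = FALSE]
      best_name <- NULL; best_id <- -1
      for (m in cl$members) {
        for (s in markers[[m]] %||% character(0)) {
          if (nchar(s) <= th$marker_length_min) next
          for (r in seq_len(nrow(refs))) {
            res <- marker_identity(s, refs$marker_seq[r])
            if (res[["identity"]] >= th$marker_identity_min &&
                res[["query_coverage"]] >= th$marker_coverage_min &&
                res[["target_coverage"]] >= th$marker_coverage_min &&
                res[["identity"]] > best_id) {
              best_id <- res[["identity"]]; best_name <- refs$name[r]
            }
          }
        }
      }
      if (!is.null(best_name)) { name <- best_name; evidence <- "marker_match" }
    }
    if (is.null(name)) {
      name <- paste("unknown group", letter_seq[next_letter])
      next_letter <- next_letter + 1L
      evidence <- "unnamed"
    }
    clusters[[i]]$name <- name
    clusters[[i]]$evidence <- evidence
  }
  clusters
}

#' Flat cluster table
#' @param clusters Clusters (named or not).
#' @return data.frame `cluster_id, genome_id, name, evidence`.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id, genome_id = cl$members,
               name = cl$name, evidence = cl$evidence,
               stringsAsFactors = FALSE)))
}
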