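# End-to-end orchestration: intergenomic -> protclust -> pangenome -> taxa
# -> phylo, with a single classed result object and artifact/report output.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full comparative-genomics pipeline
#'
#' Computes the intergenomic similarity matrix, clusters proteins, builds
#' the presence/absence matrix and pangenome summary, detects clades and
#' their signature clusters, computes Jaccard shared-cluster similarity and
#' group statistics, delineates species/genus ranks, and builds the
#' midpoint-rooted core-genome NJ tree with cluster-resampling support and a
#' single-marker congruence check. Deterministic for fixed inputs and seed.
#'
#' @param genomes Named character vector of genome sequences (>= 3).
#' @param proteins Protein table (`genome_id`, `gene_id`, `aa`, optional
#'   `label`).
#' @param metadata Optional metadata `data.frame` with `genome_id` and
#'   `year`/`tissue`/`cultivar` columns.
#' @param min_identity,min_coverage,coverage_mode Clustering thresholds
#'   (defaults 0.70 / 0.50 / `"both"`, the within-genus tier; use
#'   0.50 / 0.50 for a family-wide tier).
#' @param species_thr,genus_thr Intergenomic demarcation thresholds
#'   (defaults 95 and 70 percent).
#' @param n_reps Resampling replicates for core-tree support (default 200).
#' @param seed Integer seed for resampling.
#' @param align_params Optional list of [seed_extend_align()] parameters.
#' @return Object of class `phagepan_analysis`; see [print.phagepan_analysis()].
#' @export
phagepan_run <- function(genomes, proteins, metadata = NULL,
                         min_identity = 0.70, min_coverage = 0.50,
                         coverage_mode = "both",
                         species_thr = 95, genus_thr = 70,
                         n_reps = 200L, seed = 1L,
                         align_params = list()) {
  if (length(genomes) < 3L) stop("need at least 3 genomes")
  ids <- names(genomes)
  sim <- stage("intergenomic", do.call(similarity_matrix,
                                       c(list(genomes), align_params)))
  clustering <- stage("protclust", greedy_cluster(
    proteins, min_identity = min_identity, min_coverage = min_coverage,
    coverage_mode = coverage_mode))
  pa <- stage("pangenome", make_pa_matrix(clustering, ids))
  core <- core_clusters(pa)
  summary_pg <- upset_intersections(pa)
  jac <- stage("taxa", jaccard_matrix(pa))
  ranks <- delineate_ranks(sim, species_thr, genus_thr)
  clades <- detect_clades(sim)
  signatures <- NULL
  if (length(unique(clades)) >= 2L) {
    signatures <- lapply(sort(unique(clades)), function(cl) {
      signature_clusters(pa, ids[clades == cl], ids[clades != cl])
    })
    names(signatures) <- sort(unique(clades))
  }
  clade_stats <- group_stats(jac, clades)

  cpd <- stage("phylo", cluster_pair_distances(clustering, proteins, core,
                                               ids))
  core_dist <- pair_means_to_matrix(colMeans(cpd$per_cluster), cpd$pairs, ids)
  core_tree <- stage("phylo", resample_support(cpd, n_reps = n_reps,
                                               seed = seed))
  marker_id <- core[1L]
  mtree <- stage("phylo", marker_tree(marker_id, clustering, proteins, ids))
  congruence <- list(marker = marker_id,
                     rf = rf_distance(core_tree, mtree),
                     shared_fraction = shared_bipartitions(core_tree, mtree))

  concordance <- NULL
  if (!is.null(metadata) && "year" %in% names(metadata))
    concordance <- clade_metadata_concordance(clades, metadata, "year")

  structure(list(
    genome_ids = ids,
    similarity = sim,
    clustering = clustering,
    pa = pa,
    core = core,
    pangenome = summary_pg,
    jaccard = jac,
    ranks = ranks,
    clades = clades,
    signatures = signatures,
    clade_stats = clade_stats,
    core_distance = core_dist,
    core_tree = core_tree,
    marker_tree = mtree,
    congruence = congruence,
    concordance = concordance,
    provenance = list(
      package = "phagepan",
      version = as.character(utils::packageVersion("phagepan")),
      n_genomes = length(ids),
      min_identity = min_identity, min_coverage = min_coverage,
      coverage_mode = coverage_mode,
      species_thr = species_thr, genus_thr = genus_thr,
      n_reps = n_reps, seed = seed,
      align_params = utils::modifyList(default_align_params(),
                                       align_params))),
    class = "phagepan_analysis")
}

#' Cross-tabulate a clade partition against a metadata field
#'
#' Years are binned (default: up to 2013 versus 2020 and later, anything in
#' between its own bin); categorical fields are used as-is. Purity is the
#' fraction of genomes falling in their clade's majority bin. Genomes with
#' missing field values are excluded with a warning and reported.
#'
#' @param clades Named character vector `genome_id -> clade`.
#' @param metadata Metadata `data.frame` with `genome_id` and the field.
#' @param field One of `"year"`, `"tissue"`, `"cultivar"`.
#' @param year_breaks Two cutpoints for year binning (default `c(2013, 2020)`).
#' @return List: `table` (clade x bin contingency), `purity`, `n_missing`.
#' @export
clade_metadata_concordance <- function(clades, metadata,
                                       field = c("year", "tissue",
                                                 "cultivar"),
                                       year_breaks = c(2013, 2020)) {
  field <- match.arg(field)
  ids <- names(clades)
  if (!all(ids %in% metadata$genome_id))
    stop("metadata does not cover: ",
         paste(setdiff(ids, metadata$genome_id), collapse = ", "))
  v <- metadata[[field]][match(ids, metadata$genome_id)]
  miss <- is.na(v)
  if (any(miss))
    warning(sum(miss), " genome(s) with missing ", field, " excluded")
  ids <- ids[!miss]; v <- v[!miss]
  bin <- if (field == "year") {
    ifelse(v <= year_breaks[1L], paste0("<=", year_breaks[1L]),
           ifelse(v >= year_breaks[2L], paste0(">=", year_breaks[2L]),
                  "intermediate"))
  } else as.character(v)
  tab <- table(clade = clades[ids], bin = bin)
  purity <- sum(apply(tab, 1L, max)) / sum(tab)
  list(table = tab, purity = purity, n_missing = sum(miss))
}

#' @export
print.phagepan_analysis <- function(x, ...) {
  cat("phagepan analysis of", length(x$genome_ids), "genomes\n")
  cat(sprintf("  intergenomic similarity: %.1f-%.1f%% (off-diagonal)\n",
              min(x$similarity[upper.tri(x$similarity)]),
              max(x$similarity[upper.tri(x$similarity)])))
  cat(sprintf("  protein clusters: %d (%d core, %d accessory)\n",
              x$pangenome$total, x$pangenome$n_core, x$pangenome$n_accessory))
  cat(sprintf("  ranks: %d species (thr %.0f), %d genera (thr %.0f)\n",
              length(unique(x$ranks$species)), x$ranks$species_thr,
              length(unique(x$ranks$genus)), x$ranks$genus_thr))
  cat(sprintf("  clades: %d detected\n", length(unique(x$clades))))
  if (!is.null(x$signatures))
    cat("  signature clusters per clade:",
        paste(sprintf("%s=%d", names(x$signatures), lengths(x$signatures)),
              collapse = ", "), "\n")
  cat(sprintf("  core tree vs marker '%s': RF %d, shared bipartitions %.2f\n",
              x$congruence$marker, x$congruence$rf,
              x$congruence$shared_fraction))
  if (!is.null(x$concordance))
    cat(sprintf("  clade/year concordance purity: %.2f\n",
                x$concordance$purity))
  invisible(x)
}

#' @method summary phagepan_analysis
#' @export
summary.phagepan_analysis <- function(object, ...) {
  print(object)
  cat("\nclade sizes:\n")
  print(table(object$clades))
  cat("\nintra/inter-clade shared-cluster statistics (Jaccard %):\n")
  print(object$clade_stats, digits = 3)
  invisible(object)
}

#' Heatmap of the intergenomic similarity matrix, ordered by clade
#'
#' @param x A `phagepan_analysis`.
#' @param which `"intergenomic"` (default) or `"jaccard"`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @method plot phagepan_analysis
#' @export
plot.phagepan_analysis <- function(x, which = c("intergenomic", "jaccard"),
                                   ...) {
  which <- match.arg(which)
  m <- if (which == "intergenomic") x$similarity else x$jaccard
  ord <- order(x$clades, rownames(m))
  m <- m[ord, ord]
  n <- nrow(m)
  op <- par(mar = c(6, 6, 3, 1))
  on.exit(par(op))
  image(seq_len(n), seq_len(n), t(m[n:1, ]), col = hcl.colors(64, "YlOrRd",
                                                              rev = TRUE),
        axes = FALSE, xlab = "", ylab = "")
  axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.7)
  axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.7)
  title(sprintf("%s similarity (%%)", which))
  invisible(x)
}

#' Write all pipeline artifacts and a JSON report
#'
#' Emits the similarity and Jaccard matrices, PA matrix, cluster membership,
#' rank assignment TSVs, Newick trees and a self-contained `report.json`
#' carrying summaries and full parameter provenance.
#'
#' @param x A `phagepan_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "phagepan_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(x$similarity, file.path(dir, "intergenomic_similarity.tsv"))
  write_matrix_tsv(x$jaccard, file.path(dir, "jaccard_similarity.tsv"))
  write_pa_tsv(x$pa, file.path(dir, "pa_matrix.tsv"))
  write_clusters_tsv(x$clustering, file.path(dir, "clusters.tsv"))
  ranks_df <- data.frame(genome_id = x$genome_ids,
                         species = x$ranks$species[x$genome_ids],
                         genus = x$ranks$genus[x$genome_ids],
                         clade = x$clades[x$genome_ids])
  utils::write.table(ranks_df, file.path(dir, "ranks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(x$core_tree, file.path(dir, "core_tree.nwk"))
  ape::write.tree(x$marker_tree, file.path(dir, "marker_tree.nwk"))
  report <- list(
    n_genomes = length(x$genome_ids),
    genome_ids = x$genome_ids,
    n_clusters = x$pangenome$total,
    n_core = x$pangenome$n_core,
    n_accessory = x$pangenome$n_accessory,
    core_clusters = x$core,
    clades = as.list(x$clades),
    species = as.list(x$ranks$species),
    genus = as.list(x$ranks$genus),
    signatures = x$signatures,
    congruence = x$congruence,
    concordance = if (!is.null(x$concordance))
      list(purity = x$concordance$purity,
           n_missing = x$concordance$n_missing),
    artifacts = c("intergenomic_similarity.tsv", "jaccard_similarity.tsv",
                  "pa_matrix.tsv", "clusters.tsv", "ranks.tsv",
                  "core_tree.nwk", "marker_tree.nwk"),
    provenance = x$provenance)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
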