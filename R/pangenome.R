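# Presence/absence matrix construction, core/accessory partitioning,
# upset-style exclusive intersections and clade-signature identification.

#' Build a cluster-by-genome presence/absence matrix
#'
#' Entry is `TRUE` iff the cluster has at least one member protein in that
#' genome (paralogs booleanize to a single `TRUE`). Rows are ordered by
#' descending prevalence, then cluster id.
#'
#' @param clustering A `protein_clusters` object from [greedy_cluster()], or
#'   a cluster-by-genome count matrix.
#' @param genome_ids Ordered genome ids (columns). Must include every genome
#'   referenced by a cluster member.
#' @return Logical matrix, clusters x genomes (class `pa_matrix`).
#' @export
make_pa_matrix <- function(clustering, genome_ids = NULL) {
  counts <- if (is.matrix(clustering)) clustering
            else cluster_counts_matrix(clustering, genome_ids)
  pa <- counts > 0L
  if (any(rowSums(pa) == 0L)) stop("cluster with no members in PA matrix")
  ord <- order(-rowSums(pa), rownames(pa))
  pa <- pa[ord, , drop = FALSE]
  class(pa) <- c("pa_matrix", class(pa))
  pa
}

#' Core clusters at a prevalence threshold
#'
#' @param pa Presence/absence matrix from [make_pa_matrix()].
#' @param min_prevalence Fraction of genomes a cluster must be present in;
#'   the default 1.0 requires strictly all genomes. A cluster qualifies when
#'   present in at least `ceiling(min_prevalence * n_genomes)` genomes.
#' @return Character vector of core cluster ids.
#' @export
core_clusters <- function(pa, min_prevalence = 1.0) {
  need <- ceiling(min_prevalence * ncol(pa))
  rownames(pa)[rowSums(pa) >= need]
}

#' Exclusive pangenome intersections (upset-style summary)
#'
#' Each cluster contributes to exactly one subset signature: the exact set of
#' genomes containing it. Intersections are sorted by count, descending.
#'
#' @param pa Presence/absence matrix.
#' @return List of class `pangenome_summary`: `n_core`, `n_accessory`,
#'   `intersections` (data.frame `signature` (genome ids joined by `&`),
#'   `n_genomes`, `count`), `unique_per_genome` (named counts of
#'   single-genome clusters), `total`.
#' @export
upset_intersections <- function(pa) {
  sig <- apply(pa, 1L, function(r) paste(colnames(pa)[r], collapse = "&"))
  tb <- table(sig)
  inter <- data.frame(signature = names(tb),
                      n_genomes = lengths(strsplit(names(tb), "&",
                                                   fixed = TRUE)),
                      count = as.integer(tb), stringsAsFactors = FALSE)
  inter <- inter[order(-inter$count, inter$signature), ]
  rownames(inter) <- NULL
  n_core <- sum(rowSums(pa) == ncol(pa))
  uniq <- integer(ncol(pa))
  names(uniq) <- colnames(pa)
  solo <- rowSums(pa) == 1L
  if (any(solo)) {
    cnt <- table(colnames(pa)[apply(pa[solo, , drop = FALSE], 1L, which)])
    uniq[names(cnt)] <- as.integer(cnt)
  }
  structure(list(n_core = n_core, n_accessory = nrow(pa) - n_core,
                 intersections = inter, unique_per_genome = uniq,
                 total = nrow(pa)),
            class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat(sprintf("pangenome: %d clusters (%d core, %d accessory)\n",
              x$total, x$n_core, x$n_accessory))
  cat("largest exclusive intersections:\n")
  print(utils::head(x$intersections, 6L))
  invisible(x)
}

#' Clade-signature clusters: present throughout one group, absent from another
#'
#' @param pa Presence/absence matrix.
#' @param group_a,group_b Disjoint, nonempty genome id sets (columns of `pa`).
#' @return Character vector of cluster ids present in every genome of
#'   `group_a` and in no genome of `group_b`.
#' @export
signature_clusters <- function(pa, group_a, group_b) {
  stopifnot(length(group_a) > 0L, length(group_b) > 0L)
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups overlap: ", paste(intersect(group_a, group_b),
                                   collapse = ", "))
  missing <- setdiff(c(group_a, group_b), colnames(pa))
  if (length(missing) > 0L)
    stop("genomes absent from PA matrix: ", paste(missing, collapse = ", "))
  in_all_a <- rowSums(pa[, group_a, drop = FALSE]) == length(group_a)
  in_no_b <- rowSums(pa[, group_b, drop = FALSE]) == 0L
  rownames(pa)[in_all_a & in_no_b]
}

#' Per-taxon unique-core counts for a grouping
#'
#' For each taxon: clusters present in all of its members and absent from
#' every non-member ([signature_clusters()] applied taxon vs rest). Also
#' reports the set-wide core (clusters present in every genome).
#'
#' @param pa Presence/absence matrix.
#' @param grouping Named character vector: `genome_id -> taxon label`,
#'   covering all genomes in `pa`.
#' @return List: `per_taxon` (data.frame `taxon`, `n_genomes`,
#'   `n_unique_core`), `unique_core` (list of cluster-id vectors per taxon),
#'   `global_core` (cluster ids present in all genomes).
#' @export
rank_core_table <- function(pa, grouping) {
  gn <- colnames(pa)
  if (!all(gn %in% names(grouping)))
    stop("grouping does not cover genomes: ",
         paste(setdiff(gn, names(grouping)), collapse = ", "))
  grouping <- grouping[gn]
  taxa <- unique(grouping)
  if (any(!nzchar(taxa)) || anyNA(taxa)) stop("empty taxon label")
  uc <- lapply(taxa, function(tx) {
    inside <- gn[grouping == tx]
    outside <- setdiff(gn, inside)
    if (length(outside) == 0L) return(core_clusters(pa))
    signature_clusters(pa, inside, outside)
  })
  names(uc) <- taxa
  list(per_taxon = data.frame(taxon = taxa,
                              n_genomes = as.integer(table(grouping)[taxa]),
                              n_unique_core = lengths(uc),
                              stringsAsFactors = FALSE),
       unique_core = uc,
       global_core = core_clusters(pa))
}

#' Write a presence/absence matrix as 0/1 TSV
#'
#' @param pa Presence/absence matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pa_tsv <- function(pa, path) {
  m <- matrix(as.numeric(pa), nrow(pa), ncol(pa), dimnames = dimnames(pa))
  write_matrix_tsv(m, path)
}
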