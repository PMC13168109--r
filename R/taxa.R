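# Shared-protein-cluster similarity, intra/inter-group statistics and
# threshold-based rank delineation.

#' Jaccard similarity matrix over shared protein clusters (percent)
#'
#' `entry(i, j) = 100 * |clusters in both| / |clusters in either|`.
#'
#' @param pa Presence/absence matrix from [make_pa_matrix()].
#' @return Symmetric percent matrix, diagonal 100, genome ids as dimnames.
#' @export
jaccard_matrix <- function(pa) {
  m <- matrix(as.numeric(pa), nrow(pa), ncol(pa), dimnames = dimnames(pa))
  sizes <- colSums(m)
  if (any(sizes == 0))
    stop("genome with zero clusters: ",
         paste(colnames(pa)[sizes == 0], collapse = ", "))
  shared <- crossprod(m)
  un <- outer(sizes, sizes, "+") - shared
  j <- 100 * shared / un
  diag(j) <- 100
  j
}

#' Percent shared protein clusters between two genomes
#'
#' @param pa Presence/absence matrix.
#' @param i,j Genome ids or column indices (`i != j`).
#' @param mode `"jaccard"` (default; shared / union) or `"of_smaller"`
#'   (shared / size of the smaller repertoire).
#' @return Percent in `[0, 100]`.
#' @export
shared_pc_percent <- function(pa, i, j, mode = c("jaccard", "of_smaller")) {
  mode <- match.arg(mode)
  ci <- pa[, i]; cj <- pa[, j]
  if (identical(i, j)) stop("i and j must differ")
  shared <- sum(ci & cj)
  if (mode == "jaccard") 100 * shared / sum(ci | cj)
  else 100 * shared / min(sum(ci), sum(cj))
}

#' Intra- and inter-taxon similarity statistics
#'
#' Five-number summaries of a pairwise similarity matrix within each taxon
#' (unordered pairs, self-pairs excluded) and between each taxon pair.
#' Singleton taxa yield an intra row with `n_pairs = 0` and `NA` statistics.
#'
#' @param sim Symmetric similarity matrix with genome ids as dimnames.
#' @param grouping Named character vector `genome_id -> taxon`, covering all
#'   labels of `sim`.
#' @return `data.frame`: `taxon_a`, `taxon_b` (equal for intra rows),
#'   `n_pairs`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
group_stats <- function(sim, grouping) {
  ids <- rownames(sim)
  if (!all(ids %in% names(grouping)))
    stop("grouping does not cover: ",
         paste(setdiff(ids, names(grouping)), collapse = ", "))
  grouping <- grouping[ids]
  taxa <- sort(unique(grouping))
  rows <- list(); n <- 0L
  for (a in seq_along(taxa)) {
    for (b in a:length(taxa)) {
      ga <- ids[grouping == taxa[a]]
      gb <- ids[grouping == taxa[b]]
      if (a == b) {
        v <- if (length(ga) >= 2L) sim[ga, ga][upper.tri(sim[ga, ga])]
             else numeric()
      } else {
        v <- as.vector(sim[ga, gb, drop = FALSE])
      }
      q <- if (length(v) > 0L) unname(quantile(v, c(0, .25, .5, .75, 1)))
           else rep(NA_real_, 5L)
      n <- n + 1L
      rows[[n]] <- data.frame(taxon_a = taxa[a], taxon_b = taxa[b],
                              n_pairs = length(v), min = q[1L], q1 = q[2L],
                              median = q[3L], q3 = q[4L], max = q[5L],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# connected components of the graph with edges sim >= thr (single linkage);
# labels are assigned in first-genome order.
threshold_components <- function(sim, thr) {
  n <- nrow(sim)
  comp <- integer(n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(sim[v, ] >= thr & comp == 0L)
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  setNames(comp, rownames(sim))
}

#' Threshold-based species and genus demarcation
#'
#' Single-linkage connected components of the similarity graph with edges
#' `sim >= threshold`, at the species and genus thresholds. Because
#' `species_thr >= genus_thr`, every species component nests within exactly
#' one genus component.
#'
#' @param sim Intergenomic similarity matrix (percent).
#' @param species_thr Species demarcation threshold (default 95, the ICTV
#'   convention for phage species).
#' @param genus_thr Genus demarcation threshold (default 70).
#' @return List of class `rank_assignment`: `species` and `genus`, each a
#'   named character vector `genome_id -> label` (`species_1`, `genus_1`,
#'   ... numbered in first-genome order), plus the thresholds used.
#' @export
delineate_ranks <- function(sim, species_thr = 95, genus_thr = 70) {
  if (species_thr < genus_thr)
    stop("species_thr must be >= genus_thr")
  sp <- threshold_components(sim, species_thr)
  ge <- threshold_components(sim, genus_thr)
  structure(list(species = setNames(paste0("species_", sp), names(sp)),
                 genus = setNames(paste0("genus_", ge), names(ge)),
                 species_thr = species_thr, genus_thr = genus_thr),
            class = "rank_assignment")
}

#' @export
print.rank_assignment <- function(x, ...) {
  cat(sprintf("rank assignment: %d species (thr %.1f), %d genera (thr %.1f)\n",
              length(unique(x$species)), x$species_thr,
              length(unique(x$genus)), x$genus_thr))
  invisible(x)
}

#' Detect clade substructure from a similarity matrix
#'
#' Average-linkage hierarchical clustering of `100 - sim`, cut inside the
#' largest gap between successive merge heights. When no gap reaches
#' `min_gap` (percentage points) the genomes form a single clade.
#'
#' @param sim Similarity matrix (percent).
#' @param k Number of clades; `NULL` (default) selects it by the largest
#'   merge-height gap.
#' @param min_gap Smallest merge-height gap treated as clade structure
#'   (default 0.5 percentage points).
#' @return Named character vector `genome_id -> clade_i`, clades numbered in
#'   first-genome order.
#' @export
detect_clades <- function(sim, k = NULL, min_gap = 0.5) {
  n <- nrow(sim)
  hc <- hclust(as.dist(100 - sim), method = "average")
  if (is.null(k)) {
    gaps <- diff(hc$height)
    k <- if (length(gaps) == 0L || max(gaps) < min_gap ||
             max(hc$height) < min_gap) 1L
         else n - which.max(gaps)
  }
  ct <- stats::cutree(hc, k = k)
  # renumber in first-appearance order
  remap <- setNames(seq_along(unique(ct[rownames(sim)])),
                    unique(ct[rownames(sim)]))
  setNames(paste0("clade_", remap[as.character(ct)]), names(ct))
}
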