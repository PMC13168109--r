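# Core-genome distance phylogeny, marker trees, cluster-resampling support
# and Robinson-Foulds congruence. Trees are ape "phylo" objects throughout;
# Newick I/O goes through ape::read.tree / ape::write.tree.

# choose one member per genome for each universal cluster:
# paralog ties resolved by longest protein, then lexicographic gene_id
pick_cluster_members <- function(clustering, proteins, cluster_ids,
                                 genome_ids) {
  aa_key <- paste(proteins$genome_id, proteins$gene_id, sep = "|")
  mem <- clustering$members
  out <- list()
  for (cid in cluster_ids) {
    m <- mem[mem$cluster_id == cid, ]
    if (!all(genome_ids %in% m$genome_id))
      stop("cluster ", cid, " missing genome(s): ",
           paste(setdiff(genome_ids, m$genome_id), collapse = ", "),
           " (not a core cluster)")
    sel <- vapply(genome_ids, function(g) {
      rows <- m[m$genome_id == g, ]
      key <- paste(rows$genome_id, rows$gene_id, sep = "|")
      aa <- proteins$aa[match(key, aa_key)]
      key[order(-nchar(aa), rows$gene_id)][1L]
    }, character(1L))
    out[[cid]] <- setNames(proteins$aa[match(sel, aa_key)], genome_ids)
  }
  out
}

#' Per-cluster pairwise protein distances for a set of universal clusters
#'
#' For every cluster (one chosen member per genome) and every genome pair,
#' distance = 1 - identity from [pairwise_protein_identity()]. This is the
#' reusable kernel behind [core_distance_matrix()] and [resample_support()].
#'
#' @param clustering A `protein_clusters` object.
#' @param proteins Protein table with `genome_id`, `gene_id`, `aa`.
#' @param cluster_ids Universal (core) cluster ids to use.
#' @param genome_ids Ordered genome ids.
#' @return List: `per_cluster` numeric matrix (clusters x genome pairs),
#'   `pairs` 2-column matrix of genome-id pairs, `genome_ids`.
#' @export
cluster_pair_distances <- function(clustering, proteins, cluster_ids,
                                   genome_ids) {
  seqs <- pick_cluster_members(clustering, proteins, cluster_ids, genome_ids)
  n <- length(genome_ids)
  pairs <- t(utils::combn(genome_ids, 2L))
  d <- matrix(NA_real_, length(cluster_ids), nrow(pairs),
              dimnames = list(cluster_ids, NULL))
  for (ci in seq_along(cluster_ids)) {
    aa <- seqs[[ci]]
    col <- 0L
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      idm <- batch_protein_identity(aa[rest], aa[[i]])
      d[ci, col + seq_along(rest)] <- 1 - idm[, "identity"]
      col <- col + length(rest)
    }
  }
  list(per_cluster = d, pairs = pairs, genome_ids = genome_ids)
}

pair_means_to_matrix <- function(values, pairs, genome_ids) {
  m <- matrix(0, length(genome_ids), length(genome_ids),
              dimnames = list(genome_ids, genome_ids))
  for (p in seq_len(nrow(pairs))) {
    m[pairs[p, 1L], pairs[p, 2L]] <- values[p]
    m[pairs[p, 2L], pairs[p, 1L]] <- values[p]
  }
  m
}

#' Core-genome protein distance matrix
#'
#' Genome-pair distance is the unweighted mean over core clusters of
#' `1 - identity` between the chosen members (values in `[0, 1]`).
#'
#' @inheritParams cluster_pair_distances
#' @return Symmetric distance matrix with zero diagonal.
#' @export
core_distance_matrix <- function(clustering, proteins, cluster_ids,
                                 genome_ids) {
  cpd <- cluster_pair_distances(clustering, proteins, cluster_ids, genome_ids)
  pair_means_to_matrix(colMeans(cpd$per_cluster, na.rm = FALSE),
                       cpd$pairs, genome_ids)
}

# clamp negative branch lengths to zero, transferring the deficit to the
# sister edge (same parent) so path lengths through the parent are preserved
clamp_negative_edges <- function(tree) {
  el <- tree$edge.length
  for (i in seq_along(el)) {
    if (el[i] < 0) {
      sisters <- which(tree$edge[, 1L] == tree$edge[i, 1L] &
                       seq_along(el) != i)
      if (length(sisters) > 0L)
        el[sisters[1L]] <- el[sisters[1L]] + el[i]
      el[i] <- 0
    }
  }
  el[el < 0] <- 0
  tree$edge.length <- el
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (which recovers additive matrices exactly),
#' with negative branch lengths clamped to zero and the deficit transferred
#' to the sister edge.
#'
#' @param d Symmetric distance matrix (labels as dimnames) or `dist` object,
#'   over at least 3 taxa.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  clamp_negative_edges(ape::nj(as.dist(d)))
}

#' Midpoint-root a tree
#'
#' Root at the midpoint of the longest leaf-to-leaf path. A tree whose
#' branch lengths are all zero is rooted at a deterministic arbitrary edge,
#' with a warning.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) == 2L) {
    half <- sum(tree$edge.length) / 2
    tree$edge.length <- rep(half, length(tree$edge.length))
    tree$root.edge <- NULL
    return(tree)
  }
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; rooting at the first tip edge")
    return(ape::root(tree, outgroup = sort(tree$tip.label)[1L],
                     resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

# canonical string signatures of the nontrivial bipartitions of an unrooted
# tree: for each internal edge, the leaf side NOT containing the
# alphabetically smallest label, sorted and joined
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sigs <- character(0)
  for (p in pp) {
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2L && length(side) <= n - 2L)
      sigs <- c(sigs, paste(sort(side), collapse = "|"))
  }
  unique(sigs)
}

#' Robinson-Foulds distance between two trees
#'
#' Unrooted Robinson-Foulds count (number of bipartitions present in exactly
#' one tree). Zero iff the unrooted topologies are identical.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  d <- setdiff(t1$tip.label, t2$tip.label)
  d2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(d) > 0L || length(d2) > 0L)
    stop("leaf sets differ: only in t1 {", paste(d, collapse = ","),
         "}; only in t2 {", paste(d2, collapse = ","), "}")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Fraction of internal bipartitions shared by two trees
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Fraction in `[0, 1]`: `2 * shared / (b1 + b2)` over nontrivial
#'   bipartitions; defined as 1 when neither tree has any (star trees).
#' @export
shared_bipartitions <- function(t1, t2) {
  d <- union(setdiff(t1$tip.label, t2$tip.label),
             setdiff(t2$tip.label, t1$tip.label))
  if (length(d) > 0L) stop("leaf sets differ: ", paste(d, collapse = ", "))
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  if (length(b1) + length(b2) == 0L) return(1)
  2 * length(intersect(b1, b2)) / (length(b1) + length(b2))
}

#' Cluster-resampling support for a core-genome tree
#'
#' Resamples core clusters with replacement, rebuilds the mean distance
#' matrix and NJ tree for each replicate, and reports for every internal
#' bipartition of the base tree the percentage of replicates containing it
#' (a gene-jackknife-style analogue of bootstrap support). Reproducible for
#' a fixed seed.
#'
#' @param cpd Per-cluster distances from [cluster_pair_distances()].
#' @param n_reps Number of replicates (default 200).
#' @param seed Integer seed for the resampling RNG.
#' @return The midpoint-rooted base tree with node labels set to support
#'   percentages, plus attribute `support` (data.frame `bipartition`,
#'   `support`).
#' @export
resample_support <- function(cpd, n_reps = 200L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  nclust <- nrow(cpd$per_cluster)
  if (nclust < 1L) stop("no clusters to resample")
  base_d <- pair_means_to_matrix(colMeans(cpd$per_cluster), cpd$pairs,
                                 cpd$genome_ids)
  base <- nj_tree(base_d)
  base_bip <- tree_bipartitions(base)
  counts <- setNames(numeric(length(base_bip)), base_bip)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    take <- sample.int(nclust, nclust, replace = TRUE)
    d <- pair_means_to_matrix(
      colMeans(cpd$per_cluster[take, , drop = FALSE]), cpd$pairs,
      cpd$genome_ids)
    bip <- tree_bipartitions(nj_tree(d))
    hit <- base_bip %in% bip
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  rooted <- midpoint_root(base)
  rooted <- label_nodes_with_support(rooted, support)
  attr(rooted, "support") <- data.frame(bipartition = names(support),
                                        support = unname(support),
                                        stringsAsFactors = FALSE)
  rooted
}

# write support values onto the internal nodes of a rooted tree whose
# bipartitions match the given signatures
label_nodes_with_support <- function(tree, support) {
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  node_lab <- rep("", tree$Nnode)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    sig <- paste(sort(side), collapse = "|")
    if (sig %in% names(support))
      node_lab[i] <- sprintf("%.0f", support[[sig]])
  }
  tree$node.label <- node_lab
  tree
}

#' Single-marker tree from one universal protein cluster
#'
#' Distance matrix from that cluster alone, then NJ and midpoint rooting.
#'
#' @param cluster_id Cluster id; must be present in every genome.
#' @inheritParams cluster_pair_distances
#' @return Midpoint-rooted `phylo` tree.
#' @export
marker_tree <- function(cluster_id, clustering, proteins, genome_ids) {
  cpd <- cluster_pair_distances(clustering, proteins, cluster_id, genome_ids)
  midpoint_root(nj_tree(pair_means_to_matrix(
    colMeans(cpd$per_cluster), cpd$pairs, genome_ids)))
}
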