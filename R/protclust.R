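# Greedy centroid protein clustering (CD-HIT style) with exact local
# alignments, reproducing an MMSeqs2 clustering step at desk scale.
# Scoring: BLOSUM62, gap open 11 / extend 1 (BLAST defaults); identity counts
# gap columns in the denominator.

blosum62 <- function() {
  # lazy data() load into a private environment
  if (is.null(.pc_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pc_env$BLOSUM62 <- e$BLOSUM62
  }
  .pc_env$BLOSUM62
}
.pc_env <- new.env(parent = emptyenv())

#' Pairwise local-alignment identity and coverage between two proteins
#'
#' Smith-Waterman local alignment under BLOSUM62 with gap open 11 / extend 1.
#' Identity is matches divided by alignment columns (gap columns included);
#' coverage of each sequence is the aligned span divided by its full length.
#'
# 0-based residue encoding into the BLOSUM62 alphabet (unknowns -> X)
aa_encode <- function(aa) {
  alpha <- rownames(blosum62())
  v <- match(strsplit(aa, "", fixed = TRUE)[[1L]], alpha)
  v[is.na(v)] <- match("X", alpha)
  v - 1L
}

sw_stats <- function(pe, qe) {
  sw_align_stats(pe, qe, blosum62(), 11, 1)
}

#' @param p,q Amino-acid strings.
#' @return Named numeric vector: `identity`, `coverage_p`, `coverage_q`.
#' @export
pairwise_protein_identity <- function(p, q) {
  stopifnot(nchar(p) > 0L, nchar(q) > 0L)
  a <- sw_stats(aa_encode(p), aa_encode(q))
  if (a$columns == 0L)
    return(c(identity = 0, coverage_p = 0, coverage_q = 0))
  c(identity = a$matches / a$columns,
    coverage_p = (a$p_end - a$p_start + 1L) / nchar(p),
    coverage_q = (a$q_end - a$q_start + 1L) / nchar(q))
}

# many patterns vs one subject; returns matrix [n, 3]
batch_protein_identity <- function(ps, q) {
  qe <- aa_encode(q)
  m <- t(vapply(ps, function(p)
    pairwise_protein_identity_enc(aa_encode(p), qe, nchar(p), nchar(q)),
    numeric(3L), USE.NAMES = FALSE))
  colnames(m) <- c("identity", "coverage_p", "coverage_q")
  m
}

pairwise_protein_identity_enc <- function(pe, qe, lp, lq) {
  a <- sw_stats(pe, qe)
  if (a$columns == 0L)
    return(c(identity = 0, coverage_p = 0, coverage_q = 0))
  c(identity = a$matches / a$columns,
    coverage_p = (a$p_end - a$p_start + 1L) / lp,
    coverage_q = (a$q_end - a$q_start + 1L) / lq)
}

coverage_ok <- function(covp, covq, lp, lq, min_cov, mode) {
  switch(mode,
         both = covp >= min_cov & covq >= min_cov,
         shorter = ifelse(lp <= lq, covp, covq) >= min_cov,
         target = covq >= min_cov)
}

# can a pair possibly satisfy the coverage rule given lengths alone?
coverage_feasible <- function(lp, lq, min_cov, mode) {
  span_max <- pmin(lp, lq)  # an aligned span cannot exceed either length
  switch(mode,
         both = span_max / pmax(lp, lq) >= min_cov,
         shorter = TRUE,
         target = span_max / lq >= min_cov)
}

# integer-coded 4-mer set of a protein, for the zero-overlap prescreen
aa_kmer_set <- function(aa) {
  n <- nchar(aa)
  if (n < 4L) return(integer())
  v <- match(strsplit(aa, "", fixed = TRUE)[[1L]],
             c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
               "P","S","T","W","Y","V","X","B","Z","U","*"))
  v[is.na(v)] <- 21L
  k <- v[1:(n - 3L)] + 26L * v[2:(n - 2L)] + 676L * v[3:(n - 1L)] +
    17576L * v[4:n]
  unique(k)
}

#' Greedy centroid clustering of proteins at identity/coverage thresholds
#'
#' Proteins are sorted by (length descending, genome id, gene id) and each is
#' assigned to the first existing cluster (in founding order) whose
#' representative it matches at `min_identity` and the coverage criterion;
#' otherwise it founds a new cluster with itself as representative. The
#' result is deterministic and invariant to input order.
#'
#' @param proteins Protein table (`genome_id`, `gene_id`, `aa`, optional
#'   `label`), e.g. from [read_protein_fasta()] or [read_genbank_cds()].
#'   Rows with `flagged = TRUE` (internal stops) are excluded.
#' @param min_identity Minimum identity fraction in (0, 1] (default 0.7).
#' @param min_coverage Minimum coverage fraction in (0, 1] (default 0.5).
#' @param coverage_mode One of `"both"` (default; both sequences must be
#'   covered, mirroring MMSeqs2 cov-mode 0), `"shorter"`, `"target"`.
#' @return Object of class `protein_clusters`: a list with
#'   `clusters` (data.frame: `cluster_id`, `rep_genome`, `rep_gene`,
#'   `n_members`, `label`), `members` (data.frame: `cluster_id`, `genome_id`,
#'   `gene_id`, `is_representative`) and `params`. Clusters are ordered by
#'   descending member count, then cluster id.
#' @export
greedy_cluster <- function(proteins, min_identity = 0.7, min_coverage = 0.5,
                           coverage_mode = c("both", "shorter", "target")) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1, nrow(proteins) >= 1L)
  if (!is.null(proteins$flagged)) proteins <- proteins[!proteins$flagged, ]
  key <- paste(proteins$genome_id, proteins$gene_id, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (genome_id, gene_id): ", key[duplicated(key)][1L])
  len <- nchar(proteins$aa)
  ord <- order(-len, proteins$genome_id, proteins$gene_id)
  proteins <- proteins[ord, ]
  len <- len[ord]
  n <- nrow(proteins)
  kms <- lapply(proteins$aa, aa_kmer_set)
  enc <- lapply(proteins$aa, aa_encode)

  assign <- integer(n)
  rep_idx <- integer(0)   # row index of each cluster representative
  for (i in seq_len(n)) {
    placed <- FALSE
    if (length(rep_idx) > 0L) {
      feas <- coverage_feasible(len[i], len[rep_idx], min_coverage,
                                coverage_mode)
      cand <- which(feas)
      for (cl in cand) {
        r <- rep_idx[cl]
        if (!any(kms[[i]] %in% kms[[r]])) next  # no shared 4-mer: cannot pass
        v <- pairwise_protein_identity_enc(enc[[i]], enc[[r]], len[i], len[r])
        if (v[["identity"]] >= min_identity &&
            coverage_ok(v[["coverage_p"]], v[["coverage_q"]], len[i], len[r],
                        min_coverage, coverage_mode)) {
          assign[i] <- cl
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- length(rep_idx)
    }
  }

  ids <- sprintf("PC%04d", seq_along(rep_idx))
  counts <- tabulate(assign, nbins = length(rep_idx))
  labels <- vapply(seq_along(rep_idx), function(cl) {
    if (is.null(proteins$label)) return(NA_character_)
    labs <- proteins$label[assign == cl]
    labs <- labs[!is.na(labs) & !grepl("hypothetical", labs,
                                       ignore.case = TRUE)]
    if (length(labs) == 0L) {
      rl <- proteins$label[rep_idx[cl]]
      return(if (is.null(rl)) NA_character_ else rl)
    }
    tb <- sort(table(labs), decreasing = TRUE)
    if (sum(tb == tb[1L]) > 1L) {
      rl <- proteins$label[rep_idx[cl]]
      if (!is.na(rl) && rl %in% names(tb)[tb == tb[1L]]) return(rl)
    }
    names(tb)[1L]
  }, character(1L))

  out_order <- order(-counts, ids)
  members <- data.frame(
    cluster_id = ids[assign],
    genome_id = proteins$genome_id,
    gene_id = proteins$gene_id,
    is_representative = seq_len(n) %in% rep_idx,
    stringsAsFactors = FALSE)
  members <- members[order(match(members$cluster_id, ids[out_order]),
                           members$genome_id, members$gene_id), ]
  rownames(members) <- NULL
  clusters <- data.frame(
    cluster_id = ids[out_order],
    rep_genome = proteins$genome_id[rep_idx][out_order],
    rep_gene = proteins$gene_id[rep_idx][out_order],
    n_members = counts[out_order],
    label = labels[out_order],
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, members = members,
                 params = list(min_identity = min_identity,
                               min_coverage = min_coverage,
                               coverage_mode = coverage_mode)),
            class = "protein_clusters")
}

#' @export
print.protein_clusters <- function(x, ...) {
  cat(sprintf(
    "protein_clusters: %d clusters over %d proteins (id >= %.2f, cov >= %.2f, mode %s)\n",
    nrow(x$clusters), nrow(x$members), x$params$min_identity,
    x$params$min_coverage, x$params$coverage_mode))
  cat("largest clusters:\n")
  print(utils::head(x$clusters, 5L))
  invisible(x)
}

#' Cluster-by-genome count matrix
#'
#' Entry = number of member proteins of that cluster in that genome, so
#' column sums equal per-genome protein counts.
#'
#' @param clustering A `protein_clusters` object from [greedy_cluster()].
#' @param genome_ids Ordered genome ids to use as columns (default: all
#'   genomes seen among members, in order of first appearance).
#' @return Integer matrix, clusters x genomes.
#' @export
cluster_counts_matrix <- function(clustering, genome_ids = NULL) {
  mem <- clustering$members
  if (is.null(genome_ids)) genome_ids <- unique(mem$genome_id)
  unknown <- setdiff(unique(mem$genome_id), genome_ids)
  if (length(unknown) > 0L)
    stop("cluster member references unknown genome: ",
         paste(unknown, collapse = ", "))
  cl_ids <- clustering$clusters$cluster_id
  m <- table(factor(mem$cluster_id, levels = cl_ids),
             factor(mem$genome_id, levels = genome_ids))
  m <- matrix(as.integer(m), nrow = length(cl_ids),
              dimnames = list(cl_ids, genome_ids))
  m
}

#' Write cluster membership to TSV
#'
#' @param clustering A `protein_clusters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clustering, path) {
  utils::write.table(clustering$members, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
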