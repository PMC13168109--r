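# Shared fixtures, built in code. The default community and its full
# pipeline run are expensive, so they are computed lazily once per session.

.fixtures <- new.env(parent = emptyenv())

# the study-condition community: 2 clades (9 + 6), 63 core families,
# 4 + 3 signature clusters, 0.5% / 4% divergence (package defaults)
default_community <- function() {
  if (is.null(.fixtures$community))
    .fixtures$community <- generate_community(community_config(seed = 101L))
  .fixtures$community
}

default_analysis <- function() {
  if (is.null(.fixtures$analysis)) {
    cm <- default_community()
    .fixtures$analysis <- phagepan_run(cm$genomes, cm$proteins, cm$metadata,
                                       n_reps = 200L, seed = 7L)
  }
  .fixtures$analysis
}

# a small, fast community for unit tests
small_config <- function(...) {
  defaults <- list(genomes_per_clade = c(3L, 3L), n_core_families = 12L,
                   n_signature_families = c(1L, 2L),
                   n_accessory_families = 2L, accessory_rate = 0.3,
                   gene_length_aa = c(60L, 120L),
                   small_gene_length_aa = c(40L, 80L),
                   seed = 5L)
  do.call(community_config, utils::modifyList(defaults, list(...)))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions of a protein with different residues
mutate_protein <- function(aa, k) {
  v <- strsplit(aa, "", fixed = TRUE)[[1L]]
  pos <- sample(length(v), k)
  alpha <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
             "P","S","T","W","Y","V")
  for (i in pos) v[i] <- sample(setdiff(alpha, v[i]), 1L)
  paste(v, collapse = "")
}

protein_df <- function(aa, genome_id = NULL, gene_id = NULL) {
  n <- length(aa)
  data.frame(genome_id = genome_id %||% paste0("G", seq_len(n)),
             gene_id = gene_id %||% paste0("p", seq_len(n)),
             aa = aa, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# measured nucleotide difference fraction between equal-length strings
diff_fraction <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca != cb)
}

# map a cluster id to the planted families of its members
cluster_families <- function(community, clustering, cluster_id) {
  tr <- community$truth$genes
  fam_of <- setNames(tr$family, paste(tr$genome_id, tr$gene_id, sep = "|"))
  m <- clustering$members[clustering$members$cluster_id == cluster_id, ]
  unique(unname(fam_of[paste(m$genome_id, m$gene_id, sep = "|")]))
}
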