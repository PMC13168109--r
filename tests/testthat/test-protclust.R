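test_that("pairwise identity and coverage behave on forced constructions", {
  set.seed(4)
  p <- random_protein(100)
  v <- pairwise_protein_identity(p, p)
  expect_equal(unname(v), c(1, 1, 1))

  q <- substr(p, 1, 40)  # containment
  v <- pairwise_protein_identity(p, q)
  expect_equal(v[["identity"]], 1)
  expect_equal(v[["coverage_p"]], 0.4)
  expect_equal(v[["coverage_q"]], 1)
})

test_that("identity agrees with the Biostrings DP oracle on homologous pairs", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(8)
  for (rep in 1:8) {
    p <- random_protein(100)
    q <- mutate_protein(p, 20)
    mine <- pairwise_protein_identity(p, q)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p), Biostrings::AAString(q), type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
    cols <- nchar(as.character(Biostrings::pattern(aln)))
    expect_equal(mine[["identity"]], Biostrings::nmatch(aln) / cols,
                 tolerance = 0.02)
    # when the full-length alignment is optimal, identity is exactly 0.80
    if (cols == 100L) expect_equal(mine[["identity"]], 0.80)
  }
})

test_that("greedy clustering handles the canonical threshold cases", {
  set.seed(10)
  a <- random_protein(100)
  three <- protein_df(rep(a, 3))
  cl <- greedy_cluster(three)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n_members, 3L)

  unrelated <- protein_df(c(random_protein(80), random_protein(80)))
  expect_equal(nrow(greedy_cluster(unrelated)$clusters), 2L)

  # A; B = A with 20 substitutions (identity ~0.80 >= 0.70);
  # C = first 40 aa of A (coverage 0.40 < 0.50 under mode = both)
  b <- mutate_protein(a, 20)
  idb <- pairwise_protein_identity(a, b)[["identity"]]
  expect_gte(idb, 0.70)  # construction check against the DP kernel
  cc <- substr(a, 1, 40)
  cl <- greedy_cluster(protein_df(c(a, b, cc)), 0.70, 0.50, "both")
  expect_equal(nrow(cl$clusters), 2L)
  expect_equal(sort(cl$clusters$n_members), c(1L, 2L))
  big <- cl$members$cluster_id[cl$members$gene_id == "p1"]
  expect_setequal(cl$members$gene_id[cl$members$cluster_id == big],
                  c("p1", "p2"))

  # under mode = shorter, C's full self-coverage lets it join
  cl2 <- greedy_cluster(protein_df(c(a, b, cc)), 0.70, 0.50, "shorter")
  expect_equal(nrow(cl2$clusters), 1L)

  expect_error(greedy_cluster(protein_df(c(a, a), genome_id = c("G", "G"),
                                         gene_id = c("p", "p"))),
               "duplicate")
})

test_that("clustering is permutation-invariant and partitions the input", {
  set.seed(12)
  fams <- lapply(1:5, function(i) random_protein(sample(60:120, 1)))
  aa <- unlist(lapply(fams, function(f)
    c(f, mutate_protein(f, 5), mutate_protein(f, 8))))
  pr <- protein_df(aa, genome_id = paste0("G", rep(1:3, 5)),
                   gene_id = paste0("p", seq_along(aa)))
  cl <- greedy_cluster(pr)
  perm <- pr[sample(nrow(pr)), ]
  cl2 <- greedy_cluster(perm)
  expect_identical(cl$clusters, cl2$clusters)
  expect_identical(cl$members, cl2$members)
  # partition: every protein in exactly one cluster
  expect_equal(nrow(cl$members), nrow(pr))
  expect_false(anyDuplicated(paste(cl$members$genome_id,
                                   cl$members$gene_id)) > 0)
  expect_equal(sum(cl$clusters$n_members), nrow(pr))
})

test_that("greedy clusters refine threshold-graph components (<= 30 proteins)", {
  set.seed(14)
  for (rep in 1:4) {
    fams <- lapply(1:4, function(i) random_protein(sample(50:100, 1)))
    aa <- unlist(lapply(fams, function(f) {
      n <- sample(2:5, 1)
      c(f, vapply(seq_len(n - 1), function(i)
        mutate_protein(f, sample(0:25, 1)), ""))
    }))
    aa <- utils::head(aa, 30)
    pr <- protein_df(aa, genome_id = paste0("G", seq_along(aa)),
                     gene_id = paste0("p", seq_along(aa)))
    cl <- greedy_cluster(pr, 0.70, 0.50)
    # oracle: connected components of the all-pairs >= threshold graph
    n <- nrow(pr)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- pairwise_protein_identity(pr$aa[i], pr$aa[j])
      adj[i, j] <- adj[j, i] <- v[["identity"]] >= 0.70 &&
        v[["coverage_p"]] >= 0.5 && v[["coverage_q"]] >= 0.5
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    key <- paste(pr$genome_id, pr$gene_id, sep = "|")
    mem_comp <- comp[match(paste(cl$members$genome_id, cl$members$gene_id,
                                 sep = "|"), key)]
    # every greedy cluster lies inside one component
    expect_true(all(tapply(mem_comp, cl$members$cluster_id,
                           function(x) length(unique(x))) == 1L))
  }
})

test_that("raising the identity threshold never merges clusters", {
  set.seed(16)
  f1 <- random_protein(90)
  aa <- c(f1, mutate_protein(f1, 10), mutate_protein(f1, 25),
          random_protein(90), random_protein(70))
  pr <- protein_df(aa)
  n_prev <- 0L
  for (thr in c(0.4, 0.6, 0.8, 0.95)) {
    n <- nrow(greedy_cluster(pr, thr, 0.5)$clusters)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("count matrix reflects paralogs and per-genome totals", {
  set.seed(18)
  a <- random_protein(100)
  pr <- protein_df(c(a, a, a, mutate_protein(a, 3)),
                   genome_id = c("G1", "G2", "G3", "G3"),
                   gene_id = c("p1", "p1", "p1", "p2"))
  cl <- greedy_cluster(pr)
  m <- cluster_counts_matrix(cl, c("G1", "G2", "G3"))
  expect_equal(dim(m), c(1L, 3L))
  expect_equal(unname(m[1, ]), c(1L, 1L, 2L))  # paralog counted twice
  expect_equal(unname(colSums(m)), c(1L, 1L, 2L))
  expect_error(cluster_counts_matrix(cl, c("G1", "G2")), "unknown genome")
})

test_that("cluster labels take the majority non-hypothetical annotation", {
  set.seed(20)
  a <- random_protein(80)
  pr <- protein_df(c(a, a, a))
  pr$label <- c("hypothetical protein", "portal protein", "portal protein")
  cl <- greedy_cluster(pr)
  expect_equal(cl$clusters$label, "portal protein")
})
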