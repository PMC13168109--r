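dist_mat <- function(v, ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- v
  m + t(m)
}

test_that("3-taxon NJ solves the closed-form leaf edges", {
  d <- dist_mat(c(2, 3, 4), c("t1", "t2", "t3"))  # d12=2, d13=3, d23=4
  tr <- nj_tree(d)
  el <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(el[["t1"]], 0.5)
  expect_equal(el[["t2"]], 1.5)
  expect_equal(el[["t3"]], 2.5)
  expect_error(nj_tree(dist_mat(1, c("a", "b"))), "at least 3")
})

test_that("NJ exactly recovers random additive trees (n <= 12)", {
  set.seed(30)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    d <- cophenetic(gen)  # path-length oracle on the generating tree
    tr <- nj_tree(d)
    expect_equal(rf_distance(tr, gen), 0L)
    # branch lengths: path lengths between all leaf pairs match
    expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("negative NJ edges are clamped with deficit transfer", {
  # a non-additive matrix known to produce a negative NJ edge
  d <- dist_mat(c(5, 9, 10, 8, 9, 7), c("a", "b", "c", "d"))
  raw <- ape::nj(as.dist(d))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  # total tree length preserved by clamp-and-transfer
  expect_equal(sum(tr$edge.length), sum(raw$edge.length))
})

test_that("midpoint rooting places the root on the longest path", {
  # two-leaf tree with total length 4: root 2 from each tip
  two <- ape::read.tree(text = "(a:1,b:3);")
  r2 <- midpoint_root(two)
  expect_equal(sort(r2$edge.length), c(2, 2))

  # perfectly balanced quartet: root on the central edge
  q <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  rq <- midpoint_root(q)
  splits <- phagepan:::tree_bipartitions(rq)
  expect_true(paste(sort(c("c", "d")), collapse = "|") %in% splits)
  depths <- ape::node.depth.edgelength(rq)
  expect_equal(max(depths[1:4]), 2)  # root equidistant from farthest tips

  # caterpillar with one long terminal edge: root lands on that edge
  cat_tree <- ape::read.tree(text = "(((a:0.1,b:0.1):0.1,c:0.1):0.1,d:10);")
  rc <- midpoint_root(cat_tree)
  root_children <- rc$edge[rc$edge[, 1] == ape::Ntip(rc) + 1L, 2]
  expect_true(which(rc$tip.label == "d") %in% root_children)

  # all-zero branch lengths: deterministic arbitrary root with warning
  z <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  expect_warning(rz <- midpoint_root(z), "zero")
  expect_warning(rz2 <- midpoint_root(z), "zero")
  expect_equal(ape::write.tree(rz), ape::write.tree(rz2))
})

test_that("RF distance is zero on self, 2 on opposite quartets, a metric", {
  q1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  q2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  expect_equal(rf_distance(q1, q1), 0L)
  expect_equal(shared_bipartitions(q1, q1), 1)
  expect_equal(rf_distance(q1, q2), 2L)
  expect_equal(shared_bipartitions(q1, q2), 0)

  t3 <- ape::read.tree(text = "((a:1,e:1):1,(c:1,d:1):1);")
  expect_error(rf_distance(q1, t3), "differ")

  # metric spot-check for n = 5 against the phangorn oracle
  set.seed(32)
  trees <- lapply(1:6, function(i) ape::rtree(5, tip.label = letters[1:5]))
  for (i in 1:6) for (j in 1:6) {
    rf <- rf_distance(trees[[i]], trees[[j]])
    expect_equal(rf, as.integer(phangorn::RF.dist(trees[[i]], trees[[j]])))
    expect_equal(rf, rf_distance(trees[[j]], trees[[i]]))
    for (k in 1:6)
      expect_lte(rf, rf_distance(trees[[i]], trees[[k]]) +
                   rf_distance(trees[[k]], trees[[j]]))
  }
})

test_that("core distances average per-cluster identities", {
  set.seed(34)
  base <- random_protein(80)
  base2 <- random_protein(80)
  # two genomes, two clusters with identities ~0.9 and ~0.8
  p <- protein_df(c(base, mutate_protein(base, 8),
                    base2, mutate_protein(base2, 16)),
                  genome_id = c("G1", "G2", "G1", "G2"),
                  gene_id = c("x", "x", "y", "y"))
  # build clustering by hand through greedy_cluster at a permissive threshold
  cl <- greedy_cluster(p, 0.5, 0.5)
  expect_equal(nrow(cl$clusters), 2L)
  d <- core_distance_matrix(cl, p, cl$clusters$cluster_id, c("G1", "G2"))
  ids <- vapply(cl$clusters$cluster_id, function(cid) {
    m <- cl$members[cl$members$cluster_id == cid, ]
    aa <- p$aa[match(paste(m$genome_id, m$gene_id),
                     paste(p$genome_id, p$gene_id))]
    pairwise_protein_identity(aa[1], aa[2])[["identity"]]
  }, 0)
  expect_equal(d["G1", "G2"], mean(1 - ids))
  expect_equal(diag(d), c(G1 = 0, G2 = 0))

  # identical proteins everywhere: zero matrix and a star marker tree
  p0 <- protein_df(rep(base, 3), genome_id = paste0("G", 1:3),
                   gene_id = rep("x", 3))
  cl0 <- greedy_cluster(p0)
  d0 <- core_distance_matrix(cl0, p0, cl0$clusters$cluster_id,
                             paste0("G", 1:3))
  expect_true(all(d0 == 0))
  expect_warning(mt <- marker_tree(cl0$clusters$cluster_id[1], cl0, p0,
                                   paste0("G", 1:3)), "zero")
  expect_true(all(mt$edge.length == 0))
})

test_that("cluster resampling is reproducible and certain for one cluster", {
  cm <- generate_community(small_config())
  cl <- greedy_cluster(cm$proteins, 0.70, 0.50)
  pa <- make_pa_matrix(cl, names(cm$genomes))
  core <- core_clusters(pa)
  cpd <- cluster_pair_distances(cl, cm$proteins, core, names(cm$genomes))

  # single-cluster input: every replicate identical, all supports 100
  one <- cluster_pair_distances(cl, cm$proteins, core[1], names(cm$genomes))
  t1 <- resample_support(one, n_reps = 25L, seed = 3L)
  expect_true(all(attr(t1, "support")$support == 100))

  # fixed seed reproduces; different seeds keep the clade bipartition
  ta <- resample_support(cpd, n_reps = 50L, seed = 11L)
  tb <- resample_support(cpd, n_reps = 50L, seed = 11L)
  expect_identical(attr(ta, "support"), attr(tb, "support"))
  tc_ <- resample_support(cpd, n_reps = 50L, seed = 12L)
  expect_equal(rf_distance(ta, tc_), 0L)

  clade2 <- sort(names(cm$genomes)[cm$truth$clades == "clade_2"])
  sig <- paste(clade2, collapse = "|")
  sup <- attr(ta, "support")
  expect_gte(sup$support[sup$bipartition == sig], 95)
  expect_error(resample_support(cpd, n_reps = 0L), "n_reps")
})

test_that("marker trees are congruent unless a transfer is planted", {
  cfg <- small_config()
  cm <- generate_community(cfg)
  cl <- greedy_cluster(cm$proteins, 0.70, 0.50)
  pa <- make_pa_matrix(cl, names(cm$genomes))
  core <- core_clusters(pa)
  ids <- names(cm$genomes)
  core_tree <- midpoint_root(nj_tree(core_distance_matrix(cl, cm$proteins,
                                                          core, ids)))
  clade_sig <- paste(sort(ids[cm$truth$clades == "clade_2"]), collapse = "|")

  # concordant marker: the clade bipartition is present in both trees
  mt <- marker_tree(core[2], cl, cm$proteins, ids)
  expect_true(clade_sig %in% phagepan:::tree_bipartitions(mt))
  expect_true(clade_sig %in% phagepan:::tree_bipartitions(core_tree))

  # discordant marker (simulated transfer of the first core family)
  cfg_d <- small_config(discordant_marker = TRUE)
  cmd <- generate_community(cfg_d)
  cld <- greedy_cluster(cmd$proteins, 0.70, 0.50)
  pad <- make_pa_matrix(cld, names(cmd$genomes))
  cored <- core_clusters(pad)
  idsd <- names(cmd$genomes)
  # find the cluster holding the transferred family
  disc_cl <- Filter(function(cid)
    "core_001" %in% cluster_families(cmd, cld, cid), cored)[[1]]
  tree_core <- midpoint_root(nj_tree(core_distance_matrix(
    cld, cmd$proteins, setdiff(cored, disc_cl), idsd)))
  tree_disc <- marker_tree(disc_cl, cld, cmd$proteins, idsd)
  sig_d <- paste(sort(idsd[cmd$truth$clades == "clade_2"]), collapse = "|")
  expect_true(sig_d %in% phagepan:::tree_bipartitions(tree_core))
  # zero-length tie edges carry no signal; collapse them before comparing
  disc_resolved <- ape::di2multi(tree_disc, tol = 1e-10)
  expect_false(sig_d %in% phagepan:::tree_bipartitions(disc_resolved))
  expect_gt(rf_distance(tree_core, disc_resolved), 0L)
  # the transferred genomes sit with the donor clade in marker distances
  cpd_d <- cluster_pair_distances(cld, cmd$proteins, disc_cl, idsd)
  dm <- phagepan:::pair_means_to_matrix(colMeans(cpd_d$per_cluster),
                                        cpd_d$pairs, idsd)
  donors <- idsd[cmd$truth$clades == "clade_1"]
  moved <- cmd$truth$discordant_genomes
  kept <- setdiff(idsd[cmd$truth$clades == "clade_2"], moved)
  expect_lt(max(dm[moved, donors]), min(dm[moved, kept]))

  expect_error(marker_tree("PC9999", cl, cm$proteins, ids), "missing|core")
})

test_that("Newick round-trip preserves topology and support labels", {
  cm <- generate_community(small_config())
  cl <- greedy_cluster(cm$proteins, 0.70, 0.50)
  core <- core_clusters(make_pa_matrix(cl, names(cm$genomes)))
  cpd <- cluster_pair_distances(cl, cm$proteins, core, names(cm$genomes))
  tr <- resample_support(cpd, n_reps = 20L, seed = 2L)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_equal(rf_distance(tr, back), 0L)
  expect_setequal(setdiff(back$node.label, ""), setdiff(tr$node.label, ""))
})
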