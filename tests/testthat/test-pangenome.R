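pa_from_profiles <- function(profiles, genomes) {
  m <- do.call(rbind, profiles)
  dimnames(m) <- list(names(profiles), genomes)
  counts <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  make_pa_matrix(counts)
}

test_that("PA matrix booleanizes counts and orders by prevalence", {
  counts <- matrix(c(1L, 1L, 1L, 1L,   # present everywhere
                     0L, 2L, 0L, 0L,   # paralog in one genome
                     1L, 0L, 1L, 1L),
                   3, 4, byrow = TRUE,
                   dimnames = list(c("c1", "c2", "c3"), paste0("G", 1:4)))
  pa <- make_pa_matrix(counts)
  expect_type(pa[1, 1], "logical")
  expect_equal(rownames(pa), c("c1", "c3", "c2"))  # prevalence then id
  expect_equal(unname(pa["c2", ]), c(FALSE, TRUE, FALSE, FALSE))
  # booleanization is idempotent
  expect_equal(make_pa_matrix(matrix(as.integer(pa), nrow(pa), ncol(pa),
                                     dimnames = dimnames(pa))), pa)
  bad <- counts; bad["c2", ] <- 0L
  expect_error(make_pa_matrix(bad), "no members")
})

test_that("core extraction respects the prevalence threshold edge", {
  pa <- pa_from_profiles(list(c1 = rep(TRUE, 4), c2 = rep(TRUE, 4),
                              c3 = rep(TRUE, 4)), paste0("G", 1:4))
  expect_setequal(core_clusters(pa), c("c1", "c2", "c3"))

  profiles <- c(list(absent1 = c(FALSE, rep(TRUE, 14))),
                lapply(1:3, function(i) rep(TRUE, 15)))
  names(profiles)[2:4] <- paste0("full", 1:3)
  pa <- pa_from_profiles(profiles, paste0("G", 1:15))
  expect_false("absent1" %in% core_clusters(pa, 1.0))
  expect_true("absent1" %in% core_clusters(pa, 0.9))  # ceil(.9*15)=14
})

test_that("upset intersections are exclusive and partition the clusters", {
  pa <- pa_from_profiles(list(c1 = c(TRUE, TRUE), c2 = c(TRUE, FALSE),
                              c3 = c(FALSE, TRUE)), c("A", "B"))
  s <- upset_intersections(pa)
  expect_equal(sort(s$intersections$count), c(1L, 1L, 1L))
  expect_setequal(s$intersections$signature, c("A&B", "A", "B"))
  expect_equal(s$n_core, 1L)
  expect_equal(unname(s$unique_per_genome), c(1L, 1L))

  all_core <- pa_from_profiles(lapply(setNames(1:5, paste0("c", 1:5)),
                                      function(i) rep(TRUE, 3)),
                               paste0("G", 1:3))
  s2 <- upset_intersections(all_core)
  expect_equal(nrow(s2$intersections), 1L)
  expect_equal(s2$intersections$count, 5L)
  # partition property
  expect_equal(sum(s$intersections$count), s$total)
  expect_equal(sum(s2$intersections$count), s2$total)
})

test_that("signature clusters require presence in all of A and none of B", {
  pa <- pa_from_profiles(list(core = rep(TRUE, 4),
                              sigA = c(TRUE, TRUE, FALSE, FALSE),
                              partA = c(TRUE, FALSE, FALSE, FALSE),
                              sigB = c(FALSE, FALSE, TRUE, TRUE)),
                         paste0("G", 1:4))
  A <- c("G1", "G2"); B <- c("G3", "G4")
  expect_equal(signature_clusters(pa, A, B), "sigA")
  expect_equal(signature_clusters(pa, B, A), "sigB")
  # disjointness property
  expect_length(intersect(signature_clusters(pa, A, B),
                          signature_clusters(pa, B, A)), 0L)
  # identical presence profiles across groups: empty
  pa_same <- pa_from_profiles(list(c1 = c(TRUE, TRUE), c2 = c(TRUE, TRUE)),
                              c("G1", "G2"))
  expect_length(signature_clusters(pa_same, "G1", "G2"), 0L)
  expect_error(signature_clusters(pa, c("G1", "G2"), c("G2", "G3")),
               "overlap")
})

test_that("per-taxon unique-core counts recover block designs", {
  profiles <- c(lapply(setNames(1:5, paste0("x", 1:5)),
                       function(i) c(rep(TRUE, 3), rep(FALSE, 4))),
                lapply(setNames(1:7, paste0("y", 1:7)),
                       function(i) c(rep(FALSE, 3), rep(TRUE, 4))))
  pa <- pa_from_profiles(profiles, paste0("G", 1:7))
  grouping <- setNames(c(rep("tx", 3), rep("ty", 4)), paste0("G", 1:7))
  rc <- rank_core_table(pa, grouping)
  expect_equal(rc$per_taxon$n_unique_core[rc$per_taxon$taxon == "tx"], 5L)
  expect_equal(rc$per_taxon$n_unique_core[rc$per_taxon$taxon == "ty"], 7L)
  expect_length(rc$global_core, 0L)

  # one-taxon grouping: unique-core equals the global core
  pa2 <- pa_from_profiles(list(a = rep(TRUE, 3), b = c(TRUE, TRUE, FALSE)),
                          paste0("G", 1:3))
  rc2 <- rank_core_table(pa2, setNames(rep("t", 3), paste0("G", 1:3)))
  expect_equal(rc2$unique_core$t, rc2$global_core)
  expect_error(rank_core_table(pa, grouping[1:5]), "cover")
})

test_that("adding a genome can only shrink or preserve the core", {
  set.seed(22)
  for (rep in 1:5) {
    m <- matrix(runif(60) < 0.7, 10, 6,
                dimnames = list(paste0("c", 1:10), paste0("G", 1:6)))
    m[1, ] <- TRUE  # keep at least one core row so PA invariants hold
    keep <- rowSums(m) > 0
    m <- m[keep, , drop = FALSE]
    pa_small <- make_pa_matrix(matrix(as.integer(m[, 1:5]), nrow(m), 5,
                                      dimnames = list(rownames(m),
                                                      paste0("G", 1:5))))
    pa_full <- make_pa_matrix(matrix(as.integer(m), nrow(m), 6,
                                     dimnames = dimnames(m)))
    expect_true(all(core_clusters(pa_full) %in% core_clusters(pa_small)))
  }
})

test_that("planted pangenome structure is recovered from the generator", {
  cm <- generate_community(small_config())
  cl <- greedy_cluster(cm$proteins, 0.70, 0.50)
  pa <- make_pa_matrix(cl, names(cm$genomes))
  expect_equal(length(core_clusters(pa)), 12L)

  ids <- names(cm$genomes)
  tc <- cm$truth$clades
  sig2 <- signature_clusters(pa, ids[tc == "clade_2"], ids[tc == "clade_1"])
  sig1 <- signature_clusters(pa, ids[tc == "clade_1"], ids[tc == "clade_2"])
  expect_length(sig2, 2L)
  expect_length(sig1, 1L)
  expect_setequal(unlist(lapply(sig2, cluster_families, community = cm,
                                clustering = cl)),
                  cm$truth$signature_families$clade_2)
  expect_setequal(unlist(lapply(sig1, cluster_families, community = cm,
                                clustering = cl)),
                  cm$truth$signature_families$clade_1)

  # count matrix row sums equal planted family sizes over genomes
  counts <- cluster_counts_matrix(cl, ids)
  fam_sizes <- table(cm$truth$genes$family)
  for (cid in rownames(counts)) {
    fams <- cluster_families(cm, cl, cid)
    if (length(fams) == 1L)
      expect_lte(sum(counts[cid, ]), fam_sizes[[fams]])
  }
})
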