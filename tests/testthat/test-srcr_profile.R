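test_that("homology graph edges follow the positives threshold", {
  s <- paste(rep("MKWVTFISLLFLFSSAYS", 3), collapse = "")  # 54 residues
  seqs <- c(a = s, b = s, c = paste(rep("GGGGGPPPPP", 6), collapse = ""))
  g <- homology_graph(seqs)
  expect_gt(g$adjacency["a", "b"], 0)    # identical pair, positives 1.0
  expect_equal(g$adjacency["a", "c"], 0)
  expect_true(all(g$nodes == c("a", "b", "c")))  # isolated node kept

  # threshold 0 (and no length floor): complete graph on positive-score pairs
  seqs2 <- c(x = "MKWVTF", y = "MKWVTF", z = "MKWCCF")
  g0 <- homology_graph(seqs2, positives_threshold = 0, min_aligned = 0)
  expect_true(all(g0$adjacency[upper.tri(g0$adjacency)] > 0))
})

test_that("homology edges are monotone in the positives threshold", {
  s <- gen_srcr_sequences(srcr_spec(n_clusters = 2, seed = 13))
  g_strict <- homology_graph(s$seqs, positives_threshold = 0.95)
  g_loose <- homology_graph(s$seqs, positives_threshold = 0.85)
  expect_true(all((g_strict$adjacency > 0) <= (g_loose$adjacency > 0)))
})

test_that("generated clusters yield no between-cluster homology edges", {
  s <- gen_srcr_sequences(srcr_spec(n_clusters = 2, seed = 17))
  g <- homology_graph(s$seqs)
  cl_of <- setNames(s$truth$cluster, s$truth$id)
  idx <- which(g$adjacency > 0, arr.ind = TRUE)
  expect_true(all(cl_of[g$nodes[idx[, 1]]] == cl_of[g$nodes[idx[, 2]]]))
  # within-cluster support is dense enough for clustering
  expect_gt(sum(g$adjacency > 0) / 2, 0.5 * 2 * choose(10, 2))
})

test_that("cluster_srcr retains size-filtered clusters and reports the rest", {
  s <- gen_srcr_sequences(srcr_spec(
    n_clusters = 3, members_per_species = c(SC = 4, XT = 3, AQ = 3), seed = 19))
  # shrink the third cluster to 3 members
  keep <- s$truth$cluster != 3 | s$truth$id %in% s$truth$id[s$truth$cluster == 3][1:3]
  seqs <- s$seqs[keep]
  cs <- cluster_srcr(seqs, min_cluster_size = 5)
  expect_equal(lengths(cs$clusters), c(10L, 10L))
  expect_equal(sum(lengths(cs$small)), 3L)
  truth <- setNames(s$truth$cluster[keep], s$truth$id[keep])
  expect_equal(adjusted_rand(c(cs$clusters, cs$small), truth), 1.0)
})

test_that("conservation profiles report per-column frequencies that sum to 1", {
  aln <- c(m1 = "CAC-", m2 = "CSCA", m3 = "CACA", m4 = "CACA", m5 = "CACA",
           m6 = "CACA", m7 = "CACA", m8 = "CACA", m9 = "CACA", m10 = "CSCA")
  prof <- conservation_profile(aln)
  expect_equal(prof$cysteine_conservation[[1]], 1.0)
  expect_equal(prof$cysteine_conservation[[2]], 0)
  expect_equal(prof$conservation[[2]], 0.8)          # A x8, S x2
  expect_equal(unname(colSums(prof$frequencies)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(prof$frequencies["-", 4]), 0.1)
  expect_error(conservation_profile(c("AC", "A")), "length")
})

test_that("cysteine retention is recovered from generated clusters", {
  spec <- srcr_spec(n_clusters = 4, cysteine_retention = 0.95, seed = 23)
  s <- gen_srcr_sequences(spec)
  cys <- c()
  for (cl in unique(s$truth$cluster)) {
    msa <- progressive_msa(s$seqs[s$truth$cluster == cl])
    prof <- conservation_profile(msa)
    cys <- c(cys, prof$cysteine_conservation[spec$cysteine_positions])
  }
  expect_gt(mean(cys), 0.95 - 0.03)
  expect_lt(mean(cys), 0.95 + 0.03)
})

test_that("lineage expansion tables count members per species", {
  clusters <- list(c(sprintf("SC|P%04d|SRCR|1", 1:8), sprintf("AQ|P%04d|SRCR|1", 1:2)),
                   c(sprintf("SC|P%04d|SRCR|1", 9:13), sprintf("XT|P%04d|SRCR|1", 1:5)))
  tab <- lineage_expansion(clusters)
  expect_equal(tab$SC, c(8L, 5L))
  expect_equal(tab$dominant[1], "SC")
  expect_true(is.na(tab$dominant[2]))          # 5/5 tie: no dominant species
  expect_equal(colSums(tab[c("AQ", "SC", "XT")]),
               c(AQ = 2L, SC = 13L, XT = 5L))  # conservation over clusters
})
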