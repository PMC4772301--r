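test_that("MCL recovers cliques, singletons and weakly bridged cliques", {
  adj <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1; diag(adj) <- 0
  cl <- mcl_cluster(adj, inflation = 2)
  expect_true(cl$converged)
  expect_true(same_partition(cl$clusters, list(letters[1:4], letters[5:8])))

  single <- matrix(0, 1, 1, dimnames = list("x", "x"))
  expect_equal(mcl_cluster(single)$clusters, list("x"))

  # two 5-cliques joined by a weak bridge split at the bridge
  adj2 <- matrix(0, 10, 10, dimnames = list(letters[1:10], letters[1:10]))
  adj2[1:5, 1:5] <- 1; adj2[6:10, 6:10] <- 1; diag(adj2) <- 0
  adj2[5, 6] <- adj2[6, 5] <- 0.01
  cl2 <- mcl_cluster(adj2, inflation = 2)
  expect_true(same_partition(cl2$clusters, list(letters[1:5], letters[6:10])))
})

test_that("MCL is deterministic and validates its input", {
  withr::local_seed(31)
  adj <- matrix(runif(49), 7, 7); adj <- adj + t(adj); diag(adj) <- 0
  dimnames(adj) <- list(letters[1:7], letters[1:7])
  expect_identical(mcl_cluster(adj, 2)$clusters, mcl_cluster(adj, 2)$clusters)
  bad <- adj; bad[1, 2] <- -1
  expect_error(mcl_cluster(bad, 2), "negative")
  asym <- adj; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mcl_cluster(asym, 2), "symmetric")
})

test_that("MCL clusters refine connected components", {
  withr::local_seed(32)
  for (rep in 1:5) {
    n <- sample(10:25, 1)
    adj <- matrix(0, n, n, dimnames = list(sprintf("n%02d", 1:n),
                                           sprintf("n%02d", 1:n)))
    m <- sample(5:(2 * n), 1)
    for (k in seq_len(m)) {
      ij <- sample(n, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- runif(1, 0.5, 2)
    }
    comp <- connected_components(adj)$clusters
    comp_of <- setNames(rep(seq_along(comp), lengths(comp)), unlist(comp))
    for (cl in mcl_cluster(adj, inflation = 2)$clusters) {
      expect_equal(length(unique(comp_of[cl])), 1L)
    }
  }
})

test_that("connected components match the igraph oracle", {
  expect_equal(length(connected_components(matrix(0, 5, 5))$clusters), 5)
  path <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  path[cbind(1:3, 2:4)] <- 1; path <- path + t(path)
  expect_equal(length(connected_components(path)$clusters), 1)

  withr::local_seed(33)
  for (rep in 1:5) {
    n <- sample(8:30, 1)
    adj <- matrix(0, n, n, dimnames = list(sprintf("n%02d", 1:n),
                                           sprintf("n%02d", 1:n)))
    for (k in seq_len(sample(3:25, 1))) {
      ij <- sample(n, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- 1
    }
    mine <- connected_components(adj)$clusters
    ig <- igraph::components(igraph::graph_from_adjacency_matrix(
      adj > 0, mode = "undirected"))
    ref <- split(names(ig$membership), ig$membership)
    expect_true(same_partition(mine, unname(ref)))
  }
})

test_that("clusters are ranked by size with deterministic tie-breaks", {
  adj <- matrix(0, 7, 7, dimnames = list(letters[1:7], letters[1:7]))
  adj[1:2, 1:2] <- 1; adj[3:5, 3:5] <- 1; adj[6:7, 6:7] <- 1; diag(adj) <- 0
  cl <- mcl_cluster(adj, 2)$clusters
  expect_equal(lengths(cl), c(3L, 2L, 2L))
  expect_equal(cl[[2]], c("a", "b"))  # size tie broken by smallest member id
})

test_that("cluster files round-trip through the mcl dump format", {
  cl <- mcl_cluster(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  path <- withr::local_tempfile()
  write_clusters(cl, path)
  expect_equal(read_clusters(path)$clusters, cl$clusters)
})
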