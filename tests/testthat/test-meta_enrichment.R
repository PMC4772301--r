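test_that("rRNA filter removes reads at or above both thresholds", {
  a <- data.frame(read_id = sprintf("r%d", 1:4),
                  identity = c(0.92, 0.80, 0.90, 0.89),
                  coverage = c(0.95, 0.95, 0.90, 0.95))
  out <- rrna_filter(a)
  expect_setequal(out$read_id, c("r2", "r4"))   # r1 removed; r3 boundary removed
  expect_error(rrna_filter(transform(a, identity = NA)), "missing")
})

test_that("read counts aggregate by homology group and conserve totals", {
  groups <- c(r1 = "g1", r2 = "g2")
  a <- data.frame(read_id = sprintf("x%d", 1:4),
                  sample_id = c("s1", "s1", "s1", "s2"),
                  best_hit = c("r1", "r1", "r2", "r9"))
  expect_warning(res <- aggregate_counts(a, groups, samples = c("s1", "s2", "s3")),
                 "unassigned")
  expect_equal(res$counts["g1", "s1"], 2L)
  expect_equal(res$counts["g2", "s1"], 1L)
  expect_true(all(res$counts[, "s3"] == 0))     # empty sample: zero column
  expect_equal(sum(res$counts) + sum(res$unassigned), nrow(a))
})

test_that("homology groups delegate to MCL and keep references unique", {
  edges <- data.frame(from = c("r1", "r2", "r4"), to = c("r2", "r3", "r5"),
                      weight = c(50, 60, 45))
  cl <- build_homology_groups(edges)
  expect_true(same_partition(cl$clusters, list(c("r1", "r2", "r3"), c("r4", "r5"))))
  expect_equal(sort(unlist(cl$clusters)), sprintf("r%d", 1:5))
  expect_identical(cl$clusters, build_homology_groups(edges)$clusters)
})

test_that("quantile normalisation equalises sample distributions", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  q <- quantile_normalize(m)
  expect_equal(unname(q[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, 2]), c(2.5, 3.5, 4.5))

  withr::local_seed(51)
  # continuous values: tie-free, where sorted-column identity is exact
  x <- matrix(rlnorm(300, 3, 1), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  q1 <- quantile_normalize(x)
  srt <- apply(q1, 2, sort)
  expect_lt(max(abs(srt - srt[, 1])), 1e-12)     # identical sorted columns
  expect_lt(max(abs(quantile_normalize(q1) - q1)), 1e-9)  # idempotent

  same <- cbind(a = c(3, 1, 7), b = c(3, 1, 7))
  expect_equal(quantile_normalize(same), same)   # fixed point

  # ties share the mean of the reference values over their rank range
  tie <- cbind(a = c(2, 2, 9), b = c(1, 5, 7))
  qt <- quantile_normalize(tie)
  ref <- rowMeans(apply(tie, 2, sort))
  expect_equal(unname(qt[, 1]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("quantile normalisation matches the limma reference on tie-free data", {
  skip_if_not_installed("limma")
  withr::local_seed(52)
  x <- matrix(rnorm(200), ncol = 4)   # continuous: ties almost surely absent
  expect_equal(unname(quantile_normalize(x)),
               unname(limma::normalizeQuantiles(x)), tolerance = 1e-10)
})

test_that("the binomial DE test matches its exact tail behaviour", {
  # g3 balances g2 so the two library sizes are equal
  counts <- rbind(g1 = c(100L, 100L), g2 = c(400L, 50L), g3 = c(50L, 400L),
                  g0 = c(0L, 0L))
  colnames(counts) <- c("s1", "s2")
  de <- call_differential(counts, c("sponge1", "sponge2"), method = "binomial")
  expect_false("g0" %in% de$group)               # all-zero group excluded
  expect_false(de$de[de$group == "g1"])
  expect_true(de$de[de$group == "g2"])
  expect_lt(de$pvalue[de$group == "g2"], 1e-10)
  expect_equal(de$direction[de$group == "g2"], "sponge1")
})

test_that("the default DE caller is calibrated on replicated null data", {
  m <- gen_meta_counts(meta_spec(n_groups = 300, n_de = 0, seed = 53))
  de <- call_differential(m$counts, m$samples$community)
  expect_lte(mean(de$de), 0.02)
  m2 <- gen_meta_counts(meta_spec(n_groups = 300, n_de = 30, seed = 54))
  de2 <- call_differential(m2$counts, m2$samples$community)
  expect_gte(mean(m2$truth$de_groups %in% de2$group[de2$de]), 0.9)
})

test_that("hypergeometric enrichment equals the closed form and brute force", {
  gd <- c(lapply(1:5, function(i) "PF1"), lapply(6:10, function(i) character(0)))
  names(gd) <- sprintf("g%02d", 1:10)
  gd <- lapply(gd, unlist)
  # universe "all": N=10, K=5, n=4, k=4
  res <- domain_enrichment(sprintf("g%02d", c(1, 2, 3, 4)), gd, universe = "all")
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res[c("N", "K", "n", "k")], data.frame(N = 10L, K = 5L, n = 4L, k = 4L),
               ignore_attr = TRUE)

  withr::local_seed(55)
  for (rep in 1:20) {
    N <- sample(4:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 brute_hyper_tail(N, K, n, k), tolerance = 1e-12,
                 info = paste(N, K, n, k))
  }
})

test_that("enrichment handles degenerate tails and orders q by p-rank", {
  gd <- list(g1 = "PF1", g2 = "PF1", g3 = character(0), g4 = "PF2",
             g5 = "PF2", g6 = "PF2")
  # k = 0 for PF1 would mean PF1 absent from DE groups: untested; p for k=0 is 1
  expect_equal(phyper(-1, 3, 3, 2, lower.tail = FALSE), 1)
  # K = N saturation: every universe group carries the domain
  sat <- domain_enrichment(c("g1", "g2"), list(g1 = "PF1", g2 = "PF1", g3 = "PF1"))
  expect_equal(sat$p, 1)

  m <- gen_meta_counts(meta_spec(n_groups = 120, n_de = 25, seed = 56))
  res <- domain_enrichment(m$truth$de_groups, m$group_domains)
  expect_true(all(diff(res$q) >= -1e-12))        # BH q monotone in p-rank
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(res$k <= pmin(res$K, res$n)))
})

test_that("log2 heat-map matrix transforms and restricts rows", {
  m <- matrix(c(0, 7, 3, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  h <- log2_heatmap_matrix(m)
  expect_equal(h["g1", "s1"], 0)
  expect_equal(h["g2", "s1"], 3)
  expect_true(all(log2_heatmap_matrix(m + 5) > h))  # monotone

  enr <- data.frame(domain = c("PF1", "PF2"), enriched = c(TRUE, FALSE))
  gd <- list(g1 = "PF2", g2 = "PF1")
  h2 <- log2_heatmap_matrix(m, enrichment = enr, group_domains = gd)
  expect_equal(rownames(h2), "g2")               # only enriched-domain carriers
})
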