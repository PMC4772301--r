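# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive (enumeration, union-find, closed forms) and never
# share code with the implementation paths they check.

# Optimal local alignment score by exhaustive enumeration over all
# strictly increasing matchings of residue positions.  Gap of length g
# between consecutive aligned pairs costs gap_open + g * gap_extend per
# gapped sequence.  Feasible for sequences up to ~8 residues.
brute_local_score <- function(s1, s2, sub, gap_open = 11, gap_extend = 1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  m <- length(a); n <- length(b)
  gap_costs <- function(sets) {
    # per column of a combn matrix: affine cost of the internal gaps
    if (nrow(sets) == 1) return(numeric(ncol(sets)))
    d <- sets[-1, , drop = FALSE] - sets[-nrow(sets), , drop = FALSE] - 1L
    colSums((d > 0) * gap_open + d * gap_extend)
  }
  best <- 0
  bcode <- match(b, colnames(sub))
  for (k in seq_len(min(m, n))) {
    i_sets <- utils::combn(m, k)
    j_sets <- utils::combn(n, k)
    gj <- gap_costs(j_sets)
    gi <- gap_costs(i_sets)
    cj <- ncol(j_sets)
    jj_flat <- cbind(rep(seq_len(k), cj), bcode[as.vector(j_sets)])
    for (ci in seq_len(ncol(i_sets))) {
      S <- sub[a[i_sets[, ci]], , drop = FALSE]  # k x alphabet
      subsums <- colSums(matrix(S[jj_flat], nrow = k))
      cand <- max(subsums - gj) - gi[ci]
      if (cand > best) best <- cand
    }
  }
  best
}

# Upper-tail hypergeometric probability by enumerating every possible
# draw of n from N (membership-matrix method); exact for N <= 12.
brute_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  in_k <- draws <= K  # elements 1..K carry the domain
  mean(colSums(in_k) >= k)
}

# Adjusted Rand index between a list-of-members partition and a named
# truth vector.
adjusted_rand <- function(partition, truth) {
  lab <- rep(seq_along(partition), lengths(partition))
  names(lab) <- unlist(partition)
  tab <- table(lab[names(truth)], truth)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  e <- b * cc / nn
  (a - e) / ((b + cc) / 2 - e)
}

# Brute-force co-occurrence weights: enumerate, per protein, every
# unordered pair of distinct subset domains it contains.
brute_cooccurrence <- function(table, domains) {
  t <- table[table$domain_id %in% domains, , drop = FALSE]
  out <- list()
  for (p in unique(t$protein_id)) {
    ds <- sort(unique(t$domain_id[t$protein_id == p]))
    if (length(ds) < 2) next
    for (x in seq_len(length(ds) - 1)) {
      for (y in seq.int(x + 1, length(ds))) {
        key <- paste(ds[x], ds[y], sep = "|")
        out[[key]] <- (out[[key]] %||% 0L) + 1L
      }
    }
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random protein-domain table for property tests.
random_domain_table <- function(species, n_proteins = 20, domain_pool = LETTERS[1:6],
                                max_per_protein = 4) {
  rows <- list()
  for (p in seq_len(n_proteins)) {
    nd <- sample.int(max_per_protein, 1)
    ds <- sample(domain_pool, nd, replace = TRUE)
    for (i in seq_along(ds)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = sprintf("p%03d", p), domain_id = ds[i],
        start = (i - 1L) * 50L, end = (i - 1L) * 50L + 40L)
    }
  }
  rec <- unique(do.call(rbind, rows))
  domain_table(rec, species)
}

# Random clique-union graph: each component is a clique with unit
# weights.  Returns the adjacency matrix and the true component labels.
random_clique_graph <- function(n_nodes, max_clique = 8) {
  sizes <- c()
  while (sum(sizes) < n_nodes) {
    sizes <- c(sizes, sample.int(max_clique, 1))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_nodes)
  sizes <- sizes[sizes > 0]
  ids <- sprintf("n%03d", seq_len(n_nodes))
  adj <- matrix(0, n_nodes, n_nodes, dimnames = list(ids, ids))
  start <- 1L
  labels <- integer(n_nodes)
  for (ci in seq_along(sizes)) {
    idx <- seq.int(start, start + sizes[ci] - 1L)
    adj[idx, idx] <- 1
    labels[idx] <- ci
    start <- start + sizes[ci]
  }
  diag(adj) <- 0
  list(adjacency = adj, labels = setNames(labels, ids))
}

# Partition equality up to ordering.
same_partition <- function(p1, p2) {
  c1 <- sort(vapply(p1, function(x) paste(sort(x), collapse = ","), ""))
  c2 <- sort(vapply(p2, function(x) paste(sort(x), collapse = ","), ""))
  identical(c1, c2)
}
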