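#' Remove rRNA reads by alignment identity and coverage
#'
#' A read is removed iff its best alignment against an rRNA reference
#' reaches both thresholds (inclusive), mirroring an rRNA screen at
#' 90% coverage and 90% identity.  Reads whose `identity` or
#' `coverage` is missing are an error.
#'
#' @param assignments data.frame with at least numeric columns
#'   `identity` and `coverage` in `[0, 1]` (the best rRNA alignment per
#'   read; use 0 for reads with no rRNA hit).
#' @param coverage_threshold,identity_threshold inclusive removal
#'   thresholds (defaults 0.90).
#' @return The retained rows of `assignments`.
#' @export
rrna_filter <- function(assignments, coverage_threshold = 0.90,
                        identity_threshold = 0.90) {
  assignments <- as.data.frame(assignments)
  stopifnot(all(c("identity", "coverage") %in% names(assignments)))
  idn <- assignments$identity; cov <- assignments$coverage
  if (anyNA(idn) || anyNA(cov)) stop("missing identity/coverage values")
  stopifnot(all(idn >= 0 & idn <= 1), all(cov >= 0 & cov <= 1))
  removed <- cov >= coverage_threshold & idn >= identity_threshold
  out <- assignments[!removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster reference sequences into homology groups
#'
#' Markov clustering of the pairwise-similarity graph among best-hit
#' reference sequences, with the inflation used for metatranscriptome
#' homology groups (3.6) and all other parameters at their defaults.
#' Every reference belongs to exactly one group.
#'
#' @param graph similarity edges (`similarity_graph`, symmetric matrix
#'   or `from`/`to`/`weight` data.frame).
#' @param inflation MCL inflation (default 3.6).
#' @param ... other [mcl_cluster()] parameters.
#' @return A `clustering`.
#' @export
build_homology_groups <- function(graph, inflation = 3.6, ...) {
  mcl_cluster(graph, inflation = inflation, ...)
}

#' Aggregate read counts over homology groups
#'
#' Sums, per sample, the reads whose best hit belongs to each homology
#' group.  Reads whose best hit is in no group go into an `unassigned`
#' bucket that is reported, so total retained reads are conserved:
#' assigned + unassigned = input reads.
#'
#' @param assignments data.frame with columns `read_id`, `sample_id`,
#'   `best_hit`.
#' @param groups a `clustering` (reference ids per group) or a named
#'   character vector mapping reference id -> group id.
#' @param samples optional character vector of all sample ids, so that
#'   samples with no retained reads still get an all-zero column.
#' @return List with `counts` (group x sample integer matrix) and
#'   `unassigned` (named integer vector per sample).
#' @export
aggregate_counts <- function(assignments, groups, samples = NULL) {
  assignments <- as.data.frame(assignments)
  stopifnot(all(c("read_id", "sample_id", "best_hit") %in% names(assignments)))
  if (inherits(groups, "clustering")) {
    membership <- rep(sprintf("HG%04d", seq_along(groups$clusters)),
                      lengths(groups$clusters))
    names(membership) <- unlist(groups$clusters)
  } else {
    membership <- groups
  }
  if (anyDuplicated(names(membership))) {
    stop("a reference sequence belongs to more than one group")
  }
  samples <- sort(unique(c(samples, assignments$sample_id)))
  grp <- membership[assignments$best_hit]
  unassigned_rows <- is.na(grp)
  group_ids <- sort(unique(membership))
  counts <- matrix(0L, length(group_ids), length(samples),
                   dimnames = list(group_ids, samples))
  if (any(!unassigned_rows)) {
    tab <- table(grp[!unassigned_rows], assignments$sample_id[!unassigned_rows])
    counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  unassigned <- setNames(rep(0L, length(samples)), samples)
  if (any(unassigned_rows)) {
    tab <- table(assignments$sample_id[unassigned_rows])
    unassigned[names(tab)] <- as.integer(tab)
    warning(sum(unassigned_rows), " read(s) with best hits outside any group ",
            "counted as unassigned")
  }
  list(counts = counts, unassigned = unassigned)
}

#' Quantile-normalise a count table across samples
#'
#' Forces every sample to share one empirical distribution: each
#' sample's values are ranked, and the value at each rank is replaced
#' by the cross-sample mean of the sorted values at that rank.  Ties
#' within a sample all receive the mean of the reference values over
#' their tied rank range.  Afterwards every sample's sorted vector is
#' identical, and the transform is idempotent.
#'
#' @param table numeric matrix, rows = homology groups, columns =
#'   samples (>= 2 samples; a single sample is returned unchanged with
#'   a warning).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(table) {
  stopifnot(is.matrix(table), is.numeric(table))
  if (ncol(table) < 2) {
    warning("single sample: quantile normalisation is the identity")
    return(table)
  }
  ref <- rowMeans(apply(table, 2, sort))
  out <- table
  for (j in seq_len(ncol(table))) {
    x <- table[, j]
    ord <- order(x)
    val <- numeric(length(x))
    i <- 1L
    while (i <= length(x)) {
      run <- i
      while (run < length(x) && x[ord[run + 1L]] == x[ord[i]]) run <- run + 1L
      val[ord[i:run]] <- mean(ref[i:run])
      i <- run + 1L
    }
    out[, j] <- val
  }
  out
}

#' Call differentially expressed homology groups between two communities
#'
#' Substitute for an external differential-expression tool, fully
#' specified so it can be calibrated: group counts are compared between
#' the two host communities with an exact conditional test and the
#' p-values are Benjamini-Hochberg corrected; a group is called DE iff
#' its adjusted p-value is at most `fdr_threshold`.  Two tests are
#' available:
#'
#' * `"nb_exact"` (default): edgeR's exact negative-binomial test
#'   conditioned on the group total, with tagwise dispersion estimated
#'   from the within-community replicates.  Falls back to the binomial
#'   test when either community lacks replicates.
#' * `"binomial"`: the Poisson-rate limit — community counts are summed
#'   and the community-1 sum is tested against the library-size split
#'   with an exact two-sided binomial test.  Exact under
#'   Poisson sampling, anti-conservative when counts are
#'   overdispersed.
#'
#' The reported `log2fc` and `direction` come from quantile-normalised
#' community means (pseudocount 1).  Groups with zero counts in both
#' communities are excluded from testing.
#'
#' @param counts group x sample integer matrix of raw read counts.
#' @param communities character vector (length `ncol(counts)`) giving
#'   each sample's community; exactly two communities required.
#' @param fdr_threshold BH-adjusted significance threshold (default 0.05).
#' @param method test to use, see above.
#' @return data.frame with one row per tested group: `group`,
#'   `log2fc` (community 1 over community 2), `pvalue`, `qvalue`, `de`,
#'   `direction`.
#' @export
call_differential <- function(counts, communities, fdr_threshold = 0.05,
                              method = c("nb_exact", "binomial")) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts), length(communities) == ncol(counts))
  comm <- unique(communities)
  if (length(comm) != 2) stop("exactly two communities are required")
  tested <- rowSums(counts) > 0
  x <- counts[tested, , drop = FALSE]
  norm <- quantile_normalize(counts)
  m1 <- rowMeans(norm[tested, communities == comm[1], drop = FALSE])
  m2 <- rowMeans(norm[tested, communities == comm[2], drop = FALSE])
  lfc <- log2((m1 + 1) / (m2 + 1))
  has_reps <- all(table(communities) >= 2)
  if (method == "nb_exact" && has_reps) {
    d <- edgeR::DGEList(counts = x, group = factor(communities, levels = comm))
    d <- edgeR::calcNormFactors(d)
    d <- edgeR::estimateCommonDisp(d)
    d <- edgeR::estimateTagwiseDisp(d)
    et <- edgeR::exactTest(d, pair = comm)
    pvalue <- et$table$PValue
  } else {
    s1 <- rowSums(x[, communities == comm[1], drop = FALSE])
    s2 <- rowSums(x[, communities == comm[2], drop = FALSE])
    l1 <- sum(counts[, communities == comm[1], drop = FALSE])
    l2 <- sum(counts[, communities == comm[2], drop = FALSE])
    prob <- l1 / (l1 + l2)
    pvalue <- vapply(seq_along(s1), function(i) {
      binom_two_sided(s1[i], s1[i] + s2[i], prob)
    }, numeric(1))
  }
  qvalue <- p.adjust(pvalue, method = "BH")
  data.frame(group = rownames(x),
             log2fc = unname(lfc),
             pvalue = pvalue, qvalue = qvalue,
             de = qvalue <= fdr_threshold,
             direction = ifelse(lfc >= 0, comm[1], comm[2]),
             stringsAsFactors = FALSE)
}

# Exact two-sided binomial p-value by the minimum-likelihood method
# (sum of all outcome probabilities not exceeding the observed one).
binom_two_sided <- function(x, n, prob) {
  if (n == 0) return(1)
  d <- dbinom(0:n, n, prob)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

#' Hypergeometric domain enrichment among DE homology groups
#'
#' For each domain found in at least one differentially expressed
#' group, tests whether DE groups are enriched for the domain with the
#' upper-tail (cumulative) hypergeometric distribution:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)` with `N`
#' universe groups, `K` carrying the domain, `n` DE groups and `k` DE
#' groups carrying it.  P-values are BH-corrected and a domain is
#' enriched iff `q <= fdr_threshold`.  The `de_groups` argument is a
#' plain id vector, so DE calls produced by an external tool can be
#' supplied directly in place of [call_differential()] output.
#'
#' @param de_groups character vector of DE group ids.
#' @param group_domains named list mapping every group in the universe
#'   to its (possibly empty) character vector of domain ids.
#' @param fdr_threshold BH threshold (default 0.05).
#' @param universe `"annotated"` (default: only groups with at least
#'   one domain form the universe) or `"all"` (every group in
#'   `group_domains`).
#' @return data.frame sorted by p-value with columns `domain`, `N`,
#'   `K`, `n`, `k`, `p`, `q`, `enriched`.
#' @export
domain_enrichment <- function(de_groups, group_domains, fdr_threshold = 0.05,
                              universe = c("annotated", "all")) {
  universe <- match.arg(universe)
  stopifnot(is.list(group_domains), !is.null(names(group_domains)))
  univ <- if (universe == "annotated") {
    names(group_domains)[lengths(group_domains) > 0]
  } else {
    names(group_domains)
  }
  de <- intersect(de_groups, univ)
  N <- length(univ); n <- length(de)
  if (n > N) stop("more DE groups than universe groups")
  domains <- sort(unique(unlist(group_domains[de])))
  if (length(domains) == 0) {
    return(data.frame(domain = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), p = numeric(),
                      q = numeric(), enriched = logical()))
  }
  res <- do.call(rbind, lapply(domains, function(d) {
    carriers <- univ[vapply(group_domains[univ], function(ds) d %in% ds,
                            logical(1))]
    K <- length(carriers)
    k <- length(intersect(de, carriers))
    if (k > K || n > N) stop("inconsistent enrichment contingency")
    data.frame(domain = d, N = N, K = K, n = n, k = k,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  res$enriched <- res$q <= fdr_threshold
  res <- res[order(res$p, res$domain), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Log2 expression matrix for heat-map display
#'
#' Elementwise `log2(normalised count + pseudocount)`.  When an
#' enrichment table is supplied, rows are restricted to the groups
#' carrying significantly enriched domains and ordered domain by
#' domain (a group already shown under an earlier domain is not
#' repeated).
#'
#' @param table normalised group x sample matrix.
#' @param pseudocount added before the log (default 1).
#' @param enrichment optional [domain_enrichment()] result.
#' @param group_domains named list mapping group -> domains (required
#'   with `enrichment`).
#' @return Numeric matrix.
#' @export
log2_heatmap_matrix <- function(table, pseudocount = 1, enrichment = NULL,
                                group_domains = NULL) {
  stopifnot(is.matrix(table), pseudocount >= 0)
  m <- log2(table + pseudocount)
  if (!is.null(enrichment)) {
    stopifnot(!is.null(group_domains))
    sig <- enrichment$domain[enrichment$enriched]
    rows <- character(0)
    for (d in sig) {
      carriers <- names(group_domains)[vapply(group_domains, function(ds)
        d %in% ds, logical(1))]
      rows <- c(rows, setdiff(intersect(carriers, rownames(m)), rows))
    }
    m <- m[rows, , drop = FALSE]
  }
  m
}
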