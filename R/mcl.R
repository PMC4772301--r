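#' Construct a similarity graph from a weighted edge list
#'
#' @param edges data.frame with columns `from`, `to`, `weight`
#'   (weights must be non-negative; the graph is undirected, so an
#'   edge listed once counts in both directions and conflicting
#'   duplicate weights are an error).
#' @param nodes optional character vector of node ids (to include
#'   isolated nodes).
#' @return A `similarity_graph`: list with `nodes` and `adjacency`
#'   (symmetric numeric matrix).
#' @export
similarity_graph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (any(edges$weight < 0)) stop("negative edge weight")
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    f <- edges$from[i]; t <- edges$to[i]; w <- edges$weight[i]
    if (f == t) next
    if ((adj[f, t] != 0 && adj[f, t] != w)) {
      stop("conflicting duplicate weights for edge ", f, " -- ", t)
    }
    adj[f, t] <- w
    adj[t, f] <- w
  }
  structure(list(nodes = nodes, adjacency = adj), class = "similarity_graph")
}

as_similarity_graph <- function(x) {
  if (inherits(x, "similarity_graph")) return(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      dimnames(x) <- list(as.character(seq_len(nrow(x))),
                          as.character(seq_len(nrow(x))))
    }
    if (any(x < 0)) stop("negative edge weight")
    if (!isTRUE(all.equal(x, t(x)))) stop("adjacency matrix must be symmetric")
    return(structure(list(nodes = rownames(x), adjacency = x),
                     class = "similarity_graph"))
  }
  similarity_graph(x)
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Dense-matrix implementation of the Markov Cluster algorithm.  Self
#' loops are added with weight equal to each node's maximum incident
#' edge weight (1 for isolated nodes), the matrix is column-normalised
#' to a stochastic flow matrix, and the iteration alternates expansion
#' (`e`-th matrix power), inflation (elementwise power `r` followed by
#' column renormalisation) and pruning of entries below
#' `prune_threshold`, until the matrix changes by less than
#' `tolerance` or `max_iterations` is reached.  Clusters are read off
#' the limit matrix as attractor systems together with the nodes they
#' attract; a node attracted to several systems is assigned to the one
#' holding its largest-probability attractor, ties broken by the
#' smallest node id, which makes the output deterministic.
#'
#' @param graph a `similarity_graph`, symmetric adjacency matrix, or
#'   edge data.frame.
#' @param inflation inflation exponent r > 1 (granularity knob; 2 is
#'   the canonical default, 3.6 is used for metatranscriptome homology
#'   groups).
#' @param expansion integer matrix-power e >= 2.
#' @param prune_threshold entries below this are zeroed each cycle.
#' @param max_iterations iteration cap.
#' @param tolerance convergence threshold on the max absolute change.
#' @return A `clustering`: list with `clusters` (list of character
#'   vectors, sorted by decreasing size, ties by smallest member id),
#'   `converged`, `iterations`.
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2L,
                        prune_threshold = 1e-5, max_iterations = 200L,
                        tolerance = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2)
  g <- as_similarity_graph(graph)
  n <- length(g$nodes)
  if (n == 0) stop("empty graph")
  adj <- g$adjacency
  loop <- apply(adj, 1, max)
  loop[loop == 0] <- 1
  diag(adj) <- loop
  M <- sweep(adj, 2, colSums(adj), "/")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    prev <- M
    for (k in seq_len(expansion - 1L)) M <- M %*% prev  # expansion: M^e
    M <- M^inflation
    M[M < prune_threshold] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - prev)) < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iterations, " iterations; ",
            "interpreting the current matrix")
  }
  cl <- interpret_mcl(M, g$nodes)
  structure(list(clusters = cl, converged = converged, iterations = iter),
            class = "clustering")
}

# Read clusters off an (approximately) idempotent MCL limit matrix.
interpret_mcl <- function(M, nodes, eps = 1e-6) {
  n <- length(nodes)
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0) attractors <- seq_len(n)  # degenerate safety
  # attractor systems: weakly connected components of the attractor submatrix
  sub <- (M[attractors, attractors, drop = FALSE] > eps) |
         t(M[attractors, attractors, drop = FALSE] > eps)
  sys_id <- components_from_adjacency(sub)
  assignment <- integer(n)
  for (j in seq_len(n)) {
    probs <- M[attractors, j]
    cand <- which(probs > eps)
    if (j %in% attractors) {
      assignment[j] <- sys_id[match(j, attractors)]
    } else if (length(cand) == 0) {
      assignment[j] <- 0L  # unattracted; becomes a singleton
    } else {
      best <- cand[probs[cand] == max(probs[cand])]
      assignment[j] <- sys_id[min(best)]  # largest probability, then smallest id
    }
  }
  k <- max(assignment)
  cl <- lapply(seq_len(k), function(s) nodes[assignment == s])
  for (j in which(assignment == 0L)) cl <- c(cl, list(nodes[j]))
  cl <- cl[lengths(cl) > 0]
  sort_clusters(cl)
}

components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  id <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (id[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    id[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & id == 0L)
      id[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  id
}

sort_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  ord <- order(-lengths(cl), vapply(cl, `[`, "", 1))
  cl[ord]
}

#' Weakly connected components of a similarity graph
#'
#' Union-find implementation; used both on its own and as the limiting
#' reference behaviour of [mcl_cluster()] on graphs whose components
#' are cliques.
#'
#' @inheritParams mcl_cluster
#' @return A `clustering` (see [mcl_cluster()]).
#' @export
connected_components <- function(graph) {
  g <- as_similarity_graph(graph)
  n <- length(g$nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(g$adjacency > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    a <- find(idx[k, 1]); b <- find(idx[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- split(g$nodes, roots)
  structure(list(clusters = sort_clusters(unname(cl)), converged = TRUE,
                 iterations = 0L),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat("Clustering with ", length(x$clusters), " clusters (sizes: ",
      paste(utils::head(lengths(x$clusters), 10), collapse = ", "),
      if (length(x$clusters) > 10) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Read/write clusters in mcl dump format (one cluster per line,
#' tab-separated member ids)
#'
#' @param clustering a `clustering` object.
#' @param path file path.
#' @export
write_clusters <- function(clustering, path) {
  writeLines(vapply(clustering$clusters, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  cl <- strsplit(readLines(path), "\t", fixed = TRUE)
  structure(list(clusters = cl, converged = NA, iterations = NA_integer_),
            class = "clustering")
}
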