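#' Build the per-species domain co-occurrence network
#'
#' Nodes are domains from the supplied subset (typically the
#' keyword-selected immune set); for each species, every protein
#' contributes exactly 1 to the weight of each unordered pair of
#' distinct domains it contains.  Counting is presence-based: a protein
#' with three copies of A and one of B still contributes 1 to
#' w(A, B), matching the notion of "number of proteins in which the two
#' domains co-occur".  Self-pairs are excluded.
#'
#' @param tables list of [domain_table()] objects, one per species.
#' @param domains character vector of domain ids to restrict to.
#' @return A `cooccurrence_graph`: list with `edges` (data.frame
#'   `d1`, `d2` plus one weight column per species), `species`, and
#'   `node_size` (named integer vector, number of incident edges).
#' @export
build_cooccurrence <- function(tables, domains) {
  stopifnot(all(vapply(tables, inherits, logical(1), "domain_table")))
  species <- vapply(tables, attr, character(1), "species_id")
  pair_key <- function(d1, d2) paste(pmin(d1, d2), pmax(d1, d2), sep = "\r")
  weights <- list()
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    t <- t[t$domain_id %in% domains, , drop = FALSE]
    w <- new.env(parent = emptyenv())
    if (nrow(t) > 0) {
      per_prot <- split(t$domain_id, t$protein_id)
      for (ds in per_prot) {
        ds <- unique(ds)
        if (length(ds) < 2) next
        prs <- combn(sort(ds), 2)
        for (k in seq_len(ncol(prs))) {
          key <- pair_key(prs[1, k], prs[2, k])
          w[[key]] <- (if (is.null(w[[key]])) 0L else w[[key]]) + 1L
        }
      }
    }
    weights[[species[i]]] <- w
  }
  keys <- sort(unique(unlist(lapply(weights, ls))))
  edges <- data.frame(d1 = character(0), d2 = character(0))
  if (length(keys) > 0) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.frame(d1 = vapply(parts, `[`, "", 1),
                        d2 = vapply(parts, `[`, "", 2),
                        stringsAsFactors = FALSE)
    for (sp in species) {
      edges[[sp]] <- vapply(keys, function(k) {
        v <- weights[[sp]][[k]]
        if (is.null(v)) 0L else v
      }, integer(1), USE.NAMES = FALSE)
    }
  }
  rownames(edges) <- NULL
  g <- structure(list(edges = edges, species = species), class = "cooccurrence_graph")
  g$node_size <- node_degrees(g)
  g
}

node_degrees <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0) return(setNames(integer(0), character(0)))
  tab <- table(c(e$d1, e$d2))
  setNames(as.integer(tab), names(tab))
}

#' Filter co-occurrence edges by per-species support
#'
#' An edge is retained iff its weight reaches `min_count` in at least
#' `min_species` species (the network figure rule: pairs observed
#' >= 5 times in >= 1 species).  Node sizes are recomputed on the
#' retained edges and isolated nodes are dropped.
#'
#' @param graph a `cooccurrence_graph`.
#' @param min_count minimum per-species weight (>= 1; default 5).
#' @param min_species minimum number of supporting species (default 1).
#' @return Filtered `cooccurrence_graph`.
#' @export
filter_edges <- function(graph, min_count = 5, min_species = 1) {
  stopifnot(inherits(graph, "cooccurrence_graph"),
            min_count >= 1, min_species >= 1)
  e <- graph$edges
  if (nrow(e) > 0) {
    w <- as.matrix(e[, graph$species, drop = FALSE])
    keep <- rowSums(w >= min_count) >= min_species
    e <- e[keep, , drop = FALSE]
    rownames(e) <- NULL
  }
  out <- structure(list(edges = e, species = graph$species),
                   class = "cooccurrence_graph")
  out$node_size <- node_degrees(out)
  out
}

#' Export a co-occurrence graph
#'
#' `write_cooccurrence_tsv` writes the edge list with one weight column
#' per species; `cooccurrence_igraph` converts to an igraph object
#' (e.g. for GraphML export with `igraph::write_graph`).
#'
#' @param graph a `cooccurrence_graph`.
#' @param path output TSV path.
#' @export
write_cooccurrence_tsv <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cooccurrence_tsv
#' @export
cooccurrence_igraph <- function(graph) {
  e <- graph$edges
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  igraph::V(g)$size <- graph$node_size[igraph::V(g)$name]
  g
}
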