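#' All-vs-all homology graph over domain sequences
#'
#' Aligns every pair of sequences with exact local alignment and draws
#' an edge when the fraction of positive-scoring aligned residue pairs
#' reaches `positives_threshold` (the >= 90% positives homology
#' criterion).  Edge weights are alignment bit scores, the similarity
#' metric fed to Markov clustering.  Exact Smith-Waterman is symmetric,
#' so each pair is aligned once.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param positives_threshold minimum positives fraction for an edge
#'   (default 0.90).
#' @param denominator `"aligned"` (default: positives divided by
#'   aligned residue-residue columns, the BLAST "Positives"
#'   convention) or `"shorter"` (divided by the shorter sequence
#'   length).
#' @param min_aligned minimum number of aligned residue-residue
#'   columns for an edge (default 30).  Optimal local alignments of
#'   unrelated sequences are often tiny (a handful of residues) yet
#'   trivially reach any positives fraction; a heuristic search would
#'   never seed such alignments, and a domain-scale homology criterion
#'   presumes the alignment spans a substantial part of the domain.
#' @inheritParams local_align
#' @return A `similarity_graph` over all sequence ids (sequences with
#'   no edge remain as isolated nodes).
#' @export
homology_graph <- function(seqs, positives_threshold = 0.90,
                           denominator = c("aligned", "shorter"),
                           min_aligned = 30,
                           matrix = blosum62_matrix(),
                           gap_open = 11, gap_extend = 1) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)),
            positives_threshold >= 0, positives_threshold <= 1)
  denominator <- match.arg(denominator)
  ids <- names(seqs)
  from <- character(0); to <- character(0); weight <- numeric(0)
  for (i in seq_len(length(seqs) - 1L)) {
    for (j in seq.int(i + 1L, length(seqs))) {
      al <- local_align(seqs[[i]], seqs[[j]], matrix, gap_open, gap_extend)
      if (al$n_aligned < max(min_aligned, 1) || al$score <= 0) next
      pf <- if (denominator == "aligned") al$positives_fraction
            else al$positives_fraction * al$n_aligned /
                 min(nchar(seqs[[i]]), nchar(seqs[[j]]))
      if (pf >= positives_threshold) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
        weight <- c(weight, al$bit_score)
      }
    }
  }
  similarity_graph(data.frame(from = from, to = to, weight = weight,
                              stringsAsFactors = FALSE),
                   nodes = ids)
}

species_of <- function(ids) sub("\\|.*$", "", ids)

#' Cluster SRCR-like domain sequences into families
#'
#' Builds the >= 90% positives homology graph, clusters it with MCL on
#' bit scores, and splits the result into retained clusters (size >=
#' `min_cluster_size`, ordered by decreasing size with ties broken by
#' smallest member id) and smaller clusters, which are reported rather
#' than silently dropped.  Sequence ids are expected to follow the
#' `species|protein|domain|index` convention; the species prefix feeds
#' [lineage_expansion()].
#'
#' @inheritParams homology_graph
#' @param inflation MCL inflation (default 2).
#' @param min_cluster_size minimum retained cluster size (default 5).
#' @param ... passed on to [homology_graph()].
#' @return A `domain_cluster_set`: list with `clusters` (retained),
#'   `small`, `seqs`, and the underlying `clustering`.
#' @export
cluster_srcr <- function(seqs, inflation = 2, min_cluster_size = 5,
                         positives_threshold = 0.90, ...) {
  graph <- homology_graph(seqs, positives_threshold = positives_threshold, ...)
  clustering <- mcl_cluster(graph, inflation = inflation)
  big <- lengths(clustering$clusters) >= min_cluster_size
  structure(list(clusters = clustering$clusters[big],
                 small = clustering$clusters[!big],
                 seqs = seqs, clustering = clustering),
            class = "domain_cluster_set")
}

#' @export
print.domain_cluster_set <- function(x, ...) {
  cat("SRCR-like domain cluster set: ", length(x$clusters),
      " retained cluster(s) (sizes: ",
      paste(lengths(x$clusters), collapse = ", "), "), ",
      length(x$small), " below-threshold cluster(s)\n", sep = "")
  invisible(x)
}

#' Centre-star progressive multiple alignment
#'
#' The centre is the member with the maximal summed pairwise global
#' alignment score against all others (ties broken by input order);
#' every other member is aligned to the centre pairwise, and the
#' pairwise alignments are merged under the "once a gap, always a gap"
#' rule, so all rows have equal length.  Adequate for the short,
#' high-identity domain instances produced by family clustering.
#'
#' @param seqs named character vector (cluster members).
#' @inheritParams local_align
#' @return Named character vector of gapped rows of equal length, in
#'   the input order.
#' @export
progressive_msa <- function(seqs, matrix = blosum62_matrix(),
                            gap_open = 11, gap_extend = 1) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1) return(seqs)
  n <- length(seqs)
  scores <- matrix(0, n, n)
  aln <- vector("list", n * n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      g <- global_align(seqs[[i]], seqs[[j]], matrix, gap_open, gap_extend)
      scores[i, j] <- scores[j, i] <- g$score
    }
  }
  center <- which.max(rowSums(scores))
  rows <- list(strsplit(seqs[[center]], "")[[1]])
  row_ids <- names(seqs)[center]
  master <- rows[[1]]  # gapped centre row
  for (k in setdiff(seq_len(n), center)) {
    g <- global_align(seqs[[center]], seqs[[k]], matrix, gap_open, gap_extend)
    ac <- strsplit(g$aligned1, "")[[1]]
    am <- strsplit(g$aligned2, "")[[1]]
    merged <- merge_into_master(master, rows, ac, am)
    master <- merged$master
    rows <- merged$rows
    row_ids <- c(row_ids, names(seqs)[k])
  }
  out <- setNames(vapply(rows, paste, "", collapse = ""), row_ids)
  out[names(seqs)]
}

# Merge a (centre, member) pairwise alignment into the running MSA.
# `master` is the gapped centre row accumulated so far; `ac`/`am` are
# the centre/member rows of the new pairwise alignment.  Gap columns
# already in the master are kept (once a gap, always a gap) and new
# insertion columns from the member are spliced into every row.
merge_into_master <- function(master, rows, ac, am) {
  i <- 1L; j <- 1L
  nm <- length(master); na <- length(ac)
  new_rows <- lapply(rows, function(r) character(0))
  new_master <- character(0)
  new_member <- character(0)
  while (i <= nm || j <= na) {
    if (i <= nm && master[i] == "-") {
      # existing insertion column: member gets a gap
      new_master <- c(new_master, "-")
      for (r in seq_along(rows)) new_rows[[r]] <- c(new_rows[[r]], rows[[r]][i])
      new_member <- c(new_member, "-")
      i <- i + 1L
    } else if (j <= na && ac[j] == "-") {
      # new insertion column: existing rows get gaps
      new_master <- c(new_master, "-")
      for (r in seq_along(rows)) new_rows[[r]] <- c(new_rows[[r]], "-")
      new_member <- c(new_member, am[j])
      j <- j + 1L
    } else {
      # both carry the same centre residue
      new_master <- c(new_master, master[i])
      for (r in seq_along(rows)) new_rows[[r]] <- c(new_rows[[r]], rows[[r]][i])
      new_member <- c(new_member, am[j])
      i <- i + 1L
      j <- j + 1L
    }
  }
  list(master = new_master, rows = c(new_rows, list(new_member)))
}

#' Per-column conservation profile of a multiple alignment
#'
#' Computes the residue (and gap) frequency at every aligned position.
#' `conservation` is the most frequent amino acid's share (gaps
#' excluded from the maximum but included in the denominator), and
#' `cysteine_conservation` is the frequency of `C` — the statistic
#' behind the conserved-cysteine scaffold signature of SRCR-like
#' clusters.
#'
#' @param alignment named character vector of equal-length gapped rows.
#' @return A `cluster_profile`: list with `frequencies`
#'   ((residues + gap) x columns matrix, columns summing to 1),
#'   `conservation`, `cysteine_conservation`, `n_members`.
#' @export
conservation_profile <- function(alignment) {
  stopifnot(length(alignment) >= 1)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1) stop("alignment rows differ in length")
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  symbols <- c(AA_ALPHABET, "-")
  freq <- apply(chars, 2, function(col) {
    tab <- table(factor(col, levels = symbols))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- symbols
  structure(list(frequencies = freq,
                 conservation = apply(freq[AA_ALPHABET, , drop = FALSE], 2, max),
                 cysteine_conservation = freq["C", ],
                 n_members = length(alignment)),
            class = "cluster_profile")
}

#' Lineage-specific expansion table of a cluster set
#'
#' Counts cluster members per species; a cluster's dominant species is
#' flagged when it contributes more than half the members (ties leave
#' the flag empty).
#'
#' @param cluster_set a `domain_cluster_set` (or plain list of member
#'   id vectors, ids prefixed `species|...`).
#' @return data.frame with one row per cluster: `cluster`, `size`, one
#'   count column per species, `dominant` (`NA` when no species holds
#'   a majority).
#' @export
lineage_expansion <- function(cluster_set) {
  clusters <- if (inherits(cluster_set, "domain_cluster_set"))
    cluster_set$clusters else cluster_set
  stopifnot(length(clusters) >= 1)
  species <- sort(unique(species_of(unlist(clusters))))
  counts <- do.call(rbind, lapply(clusters, function(cl) {
    as.integer(table(factor(species_of(cl), levels = species)))
  }))
  colnames(counts) <- species
  share <- counts / rowSums(counts)
  dominant <- apply(share, 1, function(s) {
    if (max(s) > 0.5) species[which.max(s)] else NA_character_
  })
  data.frame(cluster = seq_along(clusters), size = lengths(clusters),
             counts, dominant = dominant, stringsAsFactors = FALSE)
}
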