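#' Construct a per-species protein domain table
#'
#' A domain table is the catalogue of domain occurrences for one
#' species: one row per (protein, domain, start, end) record.
#' Coordinates are 0-based half-open internally, so `end - start` is
#' the occurrence length.
#'
#' @param records data.frame with columns `protein_id`, `domain_id`,
#'   `start`, `end` (0-based half-open).
#' @param species_id short species label (e.g. `"SC"`).
#' @return A `domain_table`: a data.frame with a `species_id` attribute.
#' @export
domain_table <- function(records, species_id) {
  stopifnot(is.character(species_id), length(species_id) == 1L, nzchar(species_id))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("protein_id", "domain_id", "start", "end")
  if (!all(needed %in% names(records))) {
    stop("records must have columns ", paste(needed, collapse = ", "))
  }
  records <- records[needed]
  if (nrow(records) > 0) {
    if (any(!nzchar(records$protein_id)) || any(!nzchar(records$domain_id))) {
      stop("protein_id and domain_id must be non-empty")
    }
    if (any(records$start >= records$end)) {
      stop("every record must satisfy start < end")
    }
    if (anyDuplicated(records)) {
      stop("duplicate (protein, domain, start, end) records")
    }
  }
  rownames(records) <- NULL
  structure(records, species_id = species_id,
            class = c("domain_table", "data.frame"))
}

#' @export
print.domain_table <- function(x, ...) {
  cat("Domain table for species ", attr(x, "species_id"), ": ",
      nrow(x), " records, ", length(unique(x$protein_id)), " proteins, ",
      length(unique(x$domain_id)), " domains\n", sep = "")
  invisible(x)
}

#' Read an InterProScan-style domain annotation TSV
#'
#' Expects at least five tab-separated columns: protein id, domain
#' accession, description, start, end.  File coordinates are 1-based
#' inclusive (the InterProScan convention) and are converted to the
#' internal 0-based half-open convention.  Malformed lines (too few
#' fields, non-numeric or inverted coordinates) are dropped with a
#' warning, as are duplicated records.
#'
#' @param path path to the TSV file.
#' @param species_id species label to attach; defaults to the file stem.
#' @return A [domain_table()].
#' @export
read_domain_tsv <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("cannot read domain TSV: ", path)
  if (is.null(species_id)) {
    species_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("no records in ", path)
    return(domain_table(data.frame(protein_id = character(), domain_id = character(),
                                   start = integer(), end = integer()),
                        species_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_bad <- 0L
  rows <- lapply(fields, function(f) {
    if (length(f) < 5L) return(NULL)
    start <- suppressWarnings(as.integer(f[[4]]))
    end <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(start) || is.na(end) || end < start) return(NULL)
    data.frame(protein_id = f[[1]], domain_id = f[[2]],
               start = start - 1L, end = end, stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  n_bad <- sum(!keep)
  if (n_bad > 0) {
    warning(n_bad, " malformed line(s) dropped from ", path)
  }
  rec <- do.call(rbind, rows[keep])
  if (is.null(rec)) {
    rec <- data.frame(protein_id = character(), domain_id = character(),
                      start = integer(), end = integer())
  }
  dup <- duplicated(rec)
  if (any(dup)) {
    warning(sum(dup), " duplicate record(s) collapsed in ", path)
    rec <- rec[!dup, , drop = FALSE]
  }
  domain_table(rec, species_id)
}

#' Tag genes as eukaryotic, prokaryotic or unknown
#'
#' Applies the gene-origin rule used to separate bona fide host genes
#' from symbiont contamination: a gene is tagged `E` if any eukaryotic
#' hit falls below the e-value threshold, `P` if it has a significant
#' prokaryotic hit but no significant eukaryotic one, and `X` if it has
#' no significant hit at all.
#'
#' @param hits data.frame with columns `query_id`,
#'   `subject_taxon_class` (`"eukaryote"` or `"prokaryote"`; other
#'   classes are dropped with a warning) and `e_value`.
#' @param e_threshold significance threshold on the e-value (default
#'   `1e-4`); a hit is significant when `e_value < e_threshold`.
#' @return Named character vector of tags, one per distinct `query_id`.
#' @export
#' @examples
#' hits <- data.frame(
#'   query_id = c("g1", "g1", "g2"),
#'   subject_taxon_class = c("eukaryote", "prokaryote", "prokaryote"),
#'   e_value = c(1e-5, 1e-9, 1e-6))
#' tag_gene_origin(hits)  # g1 = "E", g2 = "P"
tag_gene_origin <- function(hits, e_threshold = 1e-4) {
  stopifnot(is.numeric(e_threshold), e_threshold > 0)
  hits <- as.data.frame(hits)
  needed <- c("query_id", "subject_taxon_class", "e_value")
  stopifnot(all(needed %in% names(hits)))
  if (any(hits$e_value < 0)) stop("negative e-value in hit table")
  known <- hits$subject_taxon_class %in% c("eukaryote", "prokaryote")
  if (any(!known)) {
    warning(sum(!known), " hit(s) to taxa outside the eukaryote/prokaryote ",
            "split dropped")
  }
  queries <- unique(hits$query_id)
  hits <- hits[known, , drop = FALSE]
  sig <- hits[hits$e_value < e_threshold, , drop = FALSE]
  euk <- unique(sig$query_id[sig$subject_taxon_class == "eukaryote"])
  prok <- unique(sig$query_id[sig$subject_taxon_class == "prokaryote"])
  tags <- setNames(rep("X", length(queries)), queries)
  tags[queries %in% prok] <- "P"
  tags[queries %in% euk] <- "E"
  tags
}

#' Read and write protein FASTA files
#'
#' Thin wrappers over Biostrings that represent a sequence set as a
#' named character vector (ids must be unique, sequences non-empty).
#' `write_fasta` followed by `read_fasta` is the identity up to line
#' wrapping.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  seqs <- setNames(as.character(ss), ids)
  if (any(!nzchar(seqs))) stop("empty sequence(s) in ", path)
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)), all(nzchar(seqs)))
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write gene-origin tags as a two-column TSV
#'
#' @param tags named character vector from [tag_gene_origin()].
#' @param path output path.
#' @export
write_tags <- function(tags, path) {
  write.table(data.frame(gene_id = names(tags), tag = unname(tags)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
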