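#' Count domain occurrences and domain-bearing genes per species
#'
#' The primary repertoire statistic is the number of times a domain
#' occurs in each genome; the number of distinct proteins containing
#' the domain is carried as a secondary statistic (gene counts can
#' never exceed occurrence counts).
#'
#' @param tables list of [domain_table()] objects, one per species.
#' @return A `domain_count_matrix`: list with integer matrices `counts`
#'   and `gene_counts`, both species x domain.
#' @export
count_domains <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "domain_table")))
  species <- vapply(tables, attr, character(1), "species_id")
  if (anyDuplicated(species)) stop("duplicate species ids among tables")
  domains <- sort(unique(unlist(lapply(tables, function(t) t$domain_id))))
  counts <- matrix(0L, length(species), length(domains),
                   dimnames = list(species, domains))
  gene_counts <- counts
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    if (nrow(t) == 0) next
    occ <- table(t$domain_id)
    counts[i, names(occ)] <- as.integer(occ)
    gen <- table(unique(t[c("protein_id", "domain_id")])$domain_id)
    gene_counts[i, names(gen)] <- as.integer(gen)
  }
  structure(list(counts = counts, gene_counts = gene_counts),
            class = "domain_count_matrix")
}

#' Select domains whose annotation matches any keyword
#'
#' A domain is selected iff any keyword is a case-insensitive substring
#' of any of its annotation strings (description and GO term names
#' concatenated by the caller).  The default keywords are the four used
#' to pick host-microbe interaction domains: "symbio", "innate
#' immunity", "antimicrobial peptides" and "antibacterial".
#'
#' @param annotations named list (or named character vector): domain id
#'   -> annotation string(s).
#' @param keywords character vector of non-empty keywords.
#' @return Character vector of selected domain ids.
#' @export
select_keyword_domains <- function(annotations,
                                   keywords = c("symbio", "innate immunity",
                                                "antimicrobial peptides",
                                                "antibacterial")) {
  stopifnot(length(annotations) > 0, !is.null(names(annotations)),
            length(keywords) > 0)
  if (any(!nzchar(keywords))) stop("empty keyword")
  hit <- vapply(annotations, function(ann) {
    ann <- tolower(paste(unlist(ann), collapse = " "))
    any(vapply(tolower(keywords), grepl, logical(1), x = ann, fixed = TRUE))
  }, logical(1))
  names(annotations)[hit]
}

#' Call domain expansions between two species by fold change
#'
#' A domain is reported as expanded towards species `a` when
#' `count_a >= fold_threshold * count_b`, and symmetrically towards
#' `b`.  The inequality form avoids division: any positive count
#' against zero is an expansion, while a domain absent from both
#' species is never reported.
#'
#' @param counts a `domain_count_matrix` from [count_domains()] (or a
#'   bare species x domain matrix).
#' @param a,b species ids present in the matrix.
#' @param fold_threshold fold-change threshold (> 1; default 1.5).
#' @return data.frame with columns `domain`, `direction` (`a` or `b`
#'   species id), `count_a`, `count_b`.
#' @export
fold_change_selection <- function(counts, a, b, fold_threshold = 1.5) {
  m <- if (inherits(counts, "domain_count_matrix")) counts$counts else counts
  stopifnot(fold_threshold > 1, a %in% rownames(m), b %in% rownames(m))
  xa <- m[a, ]; xb <- m[b, ]
  nonzero <- xa > 0 | xb > 0
  up_a <- nonzero & (xa >= fold_threshold * xb)
  up_b <- nonzero & (xb >= fold_threshold * xa)
  mk <- function(sel, dir) {
    if (!any(sel)) return(NULL)
    data.frame(domain = colnames(m)[sel], direction = dir,
               count_a = unname(xa[sel]), count_b = unname(xb[sel]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(up_a, a), mk(up_b, b))
  if (is.null(out)) {
    out <- data.frame(domain = character(), direction = character(),
                      count_a = integer(), count_b = integer())
  }
  rownames(out) <- NULL
  out[order(out$domain), , drop = FALSE]
}

#' Rank domain over/under-representation with background Z-scores
#'
#' For each domain the focal count is compared with its distribution
#' across a background panel of species:
#' `z = (x - mean) / sd`, with the sample (n - 1) standard deviation.
#' Domains with a constant background (sd 0) or absent from the panel
#' are flagged unscorable rather than given infinite scores.  The
#' result is sorted by decreasing z (over-represented first),
#' unscorable domains last.
#'
#' @param x named numeric vector of focal-species domain counts.
#' @param background domain x species numeric matrix of panel counts
#'   (>= 2 species per scored domain).
#' @return data.frame with columns `domain`, `x`, `mu`, `sigma`, `z`,
#'   `scorable`.
#' @export
zscore_representation <- function(x, background) {
  stopifnot(!is.null(names(x)), is.matrix(background),
            ncol(background) >= 2)
  domains <- names(x)
  mu <- sigma <- z <- rep(NA_real_, length(domains))
  in_bg <- domains %in% rownames(background)
  mu[in_bg] <- rowMeans(background[domains[in_bg], , drop = FALSE])
  sigma[in_bg] <- apply(background[domains[in_bg], , drop = FALSE], 1, sd)
  scorable <- in_bg & !is.na(sigma) & sigma > 0
  z[scorable] <- (x[scorable] - mu[scorable]) / sigma[scorable]
  out <- data.frame(domain = domains, x = unname(x), mu = mu, sigma = sigma,
                    z = z, scorable = scorable, stringsAsFactors = FALSE)
  out[order(-xtfrm(out$z), out$domain, na.last = TRUE), , drop = FALSE]
}

#' Pearson correlation of two species' domain repertoires
#'
#' @param counts a `domain_count_matrix` or species x domain matrix.
#' @param a,b species ids.
#' @param domains domain subset to correlate over (>= 3 domains).
#' @return Pearson product-moment correlation of the two count vectors.
#' @export
correlate_species <- function(counts, a, b, domains) {
  m <- if (inherits(counts, "domain_count_matrix")) counts$counts else counts
  stopifnot(a %in% rownames(m), b %in% rownames(m),
            length(domains) >= 3, all(domains %in% colnames(m)))
  xa <- m[a, domains]; xb <- m[b, domains]
  if (sd(xa) == 0 || sd(xb) == 0) {
    stop("correlation undefined: zero variance in a count vector")
  }
  cor(xa, xb)
}
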