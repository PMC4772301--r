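#' Specification for a synthetic domain-count panel
#'
#' Describes a panel of focal species plus a multi-species background,
#' with per-domain negative-binomial occurrence counts
#' (`var = mu + dispersion * mu^2`; `dispersion = 0` is the
#' deterministic limit where every count equals the rounded mean) and
#' optional planted lineage-specific expansions that multiply the mean
#' of one (species, domain) cell.
#'
#' @param n_species number of focal species (default 3, labelled
#'   `SC`, `XT`, `AQ` in that order).
#' @param n_domains number of domains in the panel.
#' @param n_background number of background species used for Z-scores.
#' @param baseline_mean,baseline_dispersion negative-binomial baseline
#'   per domain (recycled if scalar).
#' @param planted_expansions data.frame with columns `species_id`,
#'   `domain_id`, `fold` (all folds must be >= 1), or `NULL` for none.
#' @param seed integer RNG seed; the generator is a pure function of
#'   the spec including the seed.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_species = 3, n_domains = 300, n_background = 30,
                       baseline_mean = 200, baseline_dispersion = 0.01,
                       planted_expansions = NULL, seed = 1L) {
  stopifnot(n_species >= 1, n_domains >= 1, n_background >= 2,
            all(baseline_mean > 0), all(baseline_dispersion >= 0))
  species_ids <- if (n_species <= 3) c("SC", "XT", "AQ")[seq_len(n_species)]
                 else sprintf("S%02d", seq_len(n_species))
  domain_ids <- sprintf("SSF%04d", seq_len(n_domains))
  if (!is.null(planted_expansions)) {
    planted_expansions <- as.data.frame(planted_expansions)
    stopifnot(all(c("species_id", "domain_id", "fold") %in% names(planted_expansions)))
    if (any(planted_expansions$fold < 1)) stop("planted folds must be >= 1")
    if (!all(planted_expansions$species_id %in% species_ids) ||
        !all(planted_expansions$domain_id %in% domain_ids)) {
      stop("planted expansion ids must be resolvable within the panel")
    }
  }
  structure(list(species_ids = species_ids, domain_ids = domain_ids,
                 n_background = n_background,
                 baseline_mean = rep_len(baseline_mean, n_domains),
                 baseline_dispersion = rep_len(baseline_dispersion, n_domains),
                 planted_expansions = planted_expansions,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a synthetic domain-count panel with planted expansions
#'
#' Draws occurrence counts for the focal species and for a background
#' panel of eukaryote-like species from the spec's negative-binomial
#' baseline; planted (species, domain) cells have their mean multiplied
#' by the planted fold, so their expected count is `fold * baseline`.
#'
#' @param spec a [panel_spec()].
#' @return List with `counts` (focal species x domain integer matrix),
#'   `background` (domain x background-species matrix) and `truth`
#'   (the planted expansion table).
#' @export
gen_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    nsp <- length(spec$species_ids)
    nd <- length(spec$domain_ids)
    mu <- matrix(rep(spec$baseline_mean, each = nsp), nrow = nsp,
                 dimnames = list(spec$species_ids, spec$domain_ids))
    pl <- spec$planted_expansions
    if (!is.null(pl)) {
      for (i in seq_len(nrow(pl))) {
        mu[pl$species_id[i], pl$domain_id[i]] <-
          mu[pl$species_id[i], pl$domain_id[i]] * pl$fold[i]
      }
    }
    counts <- matrix(0L, nsp, nd, dimnames = dimnames(mu))
    for (d in seq_len(nd)) {
      counts[, d] <- rnbinom_disp(nsp, mu[, d], spec$baseline_dispersion[d])
    }
    bg <- matrix(0L, nd, spec$n_background,
                 dimnames = list(spec$domain_ids,
                                 sprintf("BG%03d", seq_len(spec$n_background))))
    for (d in seq_len(nd)) {
      bg[d, ] <- rnbinom_disp(spec$n_background, spec$baseline_mean[d],
                              spec$baseline_dispersion[d])
    }
    list(counts = counts, background = bg,
         truth = if (is.null(pl)) {
           data.frame(species_id = character(), domain_id = character(),
                      fold = numeric())
         } else pl)
  })
}

#' Specification for synthetic SRCR-like domain sequence clusters
#'
#' Each cluster is built on a shared scaffold: fixed cysteine columns
#' that every member retains with probability `cysteine_retention`, and
#' variable columns whose residue distribution is drawn per cluster
#' from a Dirichlet centred on a cluster consensus.
#' `variable_column_concentration` is the Dirichlet weight on the
#' consensus residue (the 18 other non-cysteine residues share weight
#' 0.1 each): larger values give more conserved clusters, and
#' `Inf` makes every member identical to the consensus.  Variable
#' columns never use cysteine, so cysteine conservation is an unambiguous
#' scaffold signature.
#'
#' @param n_clusters number of planted clusters.
#' @param members_per_species named integer vector: members contributed
#'   per species to every cluster (names are species ids).
#' @param scaffold_length sequence length in residues.
#' @param cysteine_positions 1-based column indices of the conserved
#'   cysteines; must lie within the scaffold.
#' @param cysteine_retention probability each member keeps each
#'   scaffold cysteine (default 0.95).
#' @param variable_column_concentration Dirichlet weight on the
#'   consensus residue of each variable column (default 60).
#' @param seed integer RNG seed.
#' @return An `srcr_spec` list.
#' @export
srcr_spec <- function(n_clusters = 5,
                      members_per_species = c(SC = 4, XT = 3, AQ = 3),
                      scaffold_length = 100,
                      cysteine_positions = c(8, 20, 33, 47, 59, 74, 88, 96),
                      cysteine_retention = 0.95,
                      variable_column_concentration = 60,
                      seed = 1L) {
  stopifnot(n_clusters >= 1, all(members_per_species >= 0),
            sum(members_per_species) >= 1,
            !is.null(names(members_per_species)),
            scaffold_length >= 1,
            cysteine_retention > 0, cysteine_retention <= 1,
            variable_column_concentration > 0)
  cysteine_positions <- as.integer(cysteine_positions)
  if (length(cysteine_positions) > scaffold_length ||
      any(cysteine_positions < 1) || any(cysteine_positions > scaffold_length)) {
    stop("cysteine_positions must fit within the scaffold")
  }
  structure(list(n_clusters = n_clusters,
                 members_per_species = members_per_species,
                 scaffold_length = scaffold_length,
                 cysteine_positions = cysteine_positions,
                 cysteine_retention = cysteine_retention,
                 variable_column_concentration = variable_column_concentration,
                 seed = as.integer(seed)),
            class = "srcr_spec")
}

# One Dirichlet draw via normalised gamma variates.
rdirichlet1 <- function(alpha) {
  if (any(!is.finite(alpha))) {
    p <- as.numeric(!is.finite(alpha))
    return(p / sum(p))
  }
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate synthetic SRCR-like domain sequences with known clusters
#'
#' @param spec an [srcr_spec()].
#' @return List with `seqs` (named character vector; ids follow the
#'   `species|protein|domain|index` convention and carry no cluster
#'   information) and `truth` (data.frame `id`, `species`, `cluster`).
#' @export
gen_srcr_sequences <- function(spec) {
  stopifnot(inherits(spec, "srcr_spec"))
  with_seed(spec$seed, {
    non_cys <- setdiff(AA_ALPHABET[1:20], "C")
    var_cols <- setdiff(seq_len(spec$scaffold_length), spec$cysteine_positions)
    ids <- character(0); seqs <- character(0)
    species <- character(0); cluster <- integer(0)
    counter <- setNames(rep(0L, length(spec$members_per_species)),
                        names(spec$members_per_species))
    for (cl in seq_len(spec$n_clusters)) {
      # per-cluster column distributions over the 19 non-cysteine residues
      consensus <- sample(non_cys, length(var_cols), replace = TRUE)
      probs <- lapply(seq_along(var_cols), function(j) {
        alpha <- rep(0.1, length(non_cys))
        alpha[match(consensus[j], non_cys)] <- spec$variable_column_concentration
        rdirichlet1(alpha)
      })
      for (sp in names(spec$members_per_species)) {
        for (m in seq_len(spec$members_per_species[[sp]])) {
          counter[sp] <- counter[sp] + 1L
          res <- character(spec$scaffold_length)
          for (j in seq_along(var_cols)) {
            res[var_cols[j]] <- sample(non_cys, 1, prob = probs[[j]])
          }
          keep <- runif(length(spec$cysteine_positions)) <= spec$cysteine_retention
          res[spec$cysteine_positions] <- ifelse(
            keep, "C", sample(non_cys, length(keep), replace = TRUE))
          ids <- c(ids, sprintf("%s|P%04d|SRCR|1", sp, counter[sp]))
          seqs <- c(seqs, paste(res, collapse = ""))
          species <- c(species, sp)
          cluster <- c(cluster, cl)
        }
      }
    }
    list(seqs = setNames(seqs, ids),
         truth = data.frame(id = ids, species = species, cluster = cluster,
                            stringsAsFactors = FALSE))
  })
}

#' Specification for a synthetic symbiont metatranscriptome count table
#'
#' Homology-group read counts for two host communities with biological
#' replicates, negative-binomial noise, planted differentially
#' expressed (DE) groups and planted enriched domains.  Group baseline
#' means vary log-normally around `mean` to mimic the skewed abundance
#' of real homology groups.  A planted `log2_fold` is split
#' symmetrically: community 1 gets `2^(lfc/2)` times the baseline,
#' community 2 `2^(-lfc/2)`.  Planted enriched domains are attached to
#' DE groups with probability `enriched_rate` and to all other groups
#' with probability `background_rate`; every other domain uses
#' `background_rate` throughout.
#'
#' @param n_groups number of homology groups.
#' @param n_samples samples per community (scalar or length 2).
#' @param mean baseline mean read count per group per sample.
#' @param dispersion negative-binomial dispersion.
#' @param n_de number of planted DE groups (0 for a null dataset).
#' @param log2_fold planted absolute log2 fold change.
#' @param n_domains number of domains in the annotation vocabulary.
#' @param n_enriched number of planted enriched domains.
#' @param enriched_rate,background_rate domain attachment probabilities.
#' @param seed integer RNG seed.
#' @return A `meta_spec` list.
#' @export
meta_spec <- function(n_groups = 500, n_samples = 3, mean = 200,
                      dispersion = 0.1, n_de = 50, log2_fold = 3,
                      n_domains = 40, n_enriched = 3,
                      enriched_rate = 0.8, background_rate = 0.1,
                      seed = 1L) {
  n_samples <- rep_len(as.integer(n_samples), 2L)
  stopifnot(n_groups >= 1, all(n_samples >= 1), mean > 0, dispersion >= 0,
            n_de >= 0, n_de <= n_groups, is.finite(log2_fold),
            n_domains >= 1, n_enriched >= 0, n_enriched <= n_domains,
            enriched_rate >= 0, enriched_rate <= 1,
            background_rate >= 0, background_rate <= 1)
  structure(list(n_groups = n_groups, n_samples = n_samples, mean = mean,
                 dispersion = dispersion, n_de = n_de, log2_fold = log2_fold,
                 n_domains = n_domains, n_enriched = n_enriched,
                 enriched_rate = enriched_rate, background_rate = background_rate,
                 seed = as.integer(seed)),
            class = "meta_spec")
}

#' Generate synthetic homology-group counts with planted DE and enrichment
#'
#' @param spec a [meta_spec()].
#' @return List with `counts` (group x sample integer matrix), `samples`
#'   (data.frame `sample_id`, `community`), `group_domains` (named list
#'   mapping each group to its domain ids) and `truth` (list with
#'   `de_groups`, `enriched_domains` and the per-group signed
#'   `log2_fold`).
#' @export
gen_meta_counts <- function(spec) {
  stopifnot(inherits(spec, "meta_spec"))
  with_seed(spec$seed, {
    groups <- sprintf("HG%04d", seq_len(spec$n_groups))
    communities <- c("sponge1", "sponge2")
    sample_id <- c(sprintf("sp1_r%d", seq_len(spec$n_samples[1])),
                   sprintf("sp2_r%d", seq_len(spec$n_samples[2])))
    community <- rep(communities, spec$n_samples)
    # log-normal spread of group abundances, expectation = spec$mean
    base_mu <- stats::rlnorm(spec$n_groups, meanlog = log(spec$mean) - 0.5,
                             sdlog = 1)
    de_groups <- if (spec$n_de > 0) sort(sample(groups, spec$n_de)) else character(0)
    lfc <- setNames(rep(0, spec$n_groups), groups)
    if (spec$n_de > 0) {
      lfc[de_groups] <- sample(c(-1, 1), spec$n_de, replace = TRUE) * spec$log2_fold
    }
    mu1 <- base_mu * 2^(lfc / 2)
    mu2 <- base_mu * 2^(-lfc / 2)
    counts <- matrix(0L, spec$n_groups, length(sample_id),
                     dimnames = list(groups, sample_id))
    for (j in seq_along(sample_id)) {
      mu <- if (community[j] == "sponge1") mu1 else mu2
      counts[, j] <- rnbinom_disp(spec$n_groups, mu, spec$dispersion)
    }
    domains <- sprintf("PF%05d", seq_len(spec$n_domains))
    enriched <- domains[seq_len(spec$n_enriched)]
    rate <- matrix(spec$background_rate, spec$n_groups, spec$n_domains,
                   dimnames = list(groups, domains))
    rate[de_groups, enriched] <- spec$enriched_rate
    present <- matrix(runif(length(rate)) < rate, nrow = spec$n_groups)
    group_domains <- lapply(seq_len(spec$n_groups),
                            function(i) domains[present[i, ]])
    names(group_domains) <- groups
    list(counts = counts,
         samples = data.frame(sample_id = sample_id, community = community,
                              stringsAsFactors = FALSE),
         group_domains = group_domains,
         truth = list(de_groups = de_groups, enriched_domains = enriched,
                      log2_fold = lfc))
  })
}
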