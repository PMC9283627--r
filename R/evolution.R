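#' Co-conservation of a gene pair across a phylum panel
#'
#' A pair is evolutionarily co-conserved only when both genes are present
#' in every phylum of the panel (the all-phyla rule). The panel defaults to
#' all profile columns; restricting it (e.g. to a single phylum) relaxes
#' the rule monotonically.
#'
#' @param profiles Tibble from [simulate_phylo_profiles()] or
#'   [read_phylo_profiles()]: `gene_id` plus one 0/1 column per phylum.
#' @param gene_a,gene_b Gene identifiers.
#' @param panel Optional character vector of phylum columns to consider.
#' @return Logical scalar.
#' @export
co_conserved <- function(profiles, gene_a, gene_b, panel = NULL) {
  panel <- panel %||% setdiff(names(profiles), "gene_id")
  miss <- setdiff(c(gene_a, gene_b), profiles$gene_id)
  if (length(miss) > 0) {
    abort(sprintf("no phylogenetic profile for gene(s): %s",
                  paste(miss, collapse = ", ")),
          class = "giscreen_lookup_error")
  }
  pa <- unlist(profiles[profiles$gene_id == gene_a, panel])
  pb <- unlist(profiles[profiles$gene_id == gene_b, panel])
  all(pa == 1) && all(pb == 1)
}

# Internal: logical vector over profile rows, TRUE where a gene is present
# in every phylum of the panel.
fully_conserved <- function(profiles, panel = NULL) {
  panel <- panel %||% setdiff(names(profiles), "gene_id")
  mat <- as.matrix(profiles[, panel, drop = FALSE])
  setNames(rowSums(mat == 1) == length(panel), profiles$gene_id)
}

#' Permutation enrichment of co-conserved interactions per process pair
#'
#' Counts, for every bioprocess pair, the significant interactions whose
#' two genes are both conserved across all phyla of the panel, and compares
#' each count with a null obtained by shuffling the profile-to-gene
#' assignment `n_perm` times. `Z = (observed - mean_null) / sd_null`;
#' enrichment at `Z >= z_cut` (default 2). Degenerate permutation SDs give
#' a flagged missing Z.
#'
#' @param network A called network.
#' @param profiles Phylogenetic profile tibble.
#' @param genes Annotation tibble (major bioprocess membership).
#' @param n_perm Number of permutations (default 1000).
#' @param z_cut Z threshold (default 2).
#' @param seed Integer seed.
#' @param panel Optional phylum column subset.
#' @return Tibble per process pair: `process_a`, `process_b`,
#'   `observed_count`, `perm_mean`, `perm_sd`, `Z`, `degenerate`,
#'   `significant`.
#' @export
conservation_enrichment <- function(network, profiles, genes,
                                    n_perm = 1000L, z_cut = 2.0, seed = 1L,
                                    panel = NULL) {
  if (n_perm < 1L) abort("n_perm must be >= 1", class = "giscreen_config_error")
  edges <- network_pairs(network) %>% filter(.data$significant)
  if (nrow(edges) == 0L) {
    abort("network has no significant interactions", class = "giscreen_data_error")
  }
  conserved <- fully_conserved(profiles, panel)
  missing <- setdiff(unique(c(edges$donor, edges$recipient)), names(conserved))
  if (length(missing) > 0) {
    abort(sprintf("no phylogenetic profile for gene(s): %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "giscreen_lookup_error")
  }

  membership <- gene_memberships(genes, "major")
  expanded <- edges %>%
    mutate(edge_id = row_number()) %>%
    inner_join(membership %>% rename(donor = "gene_id", process_a = "process"),
               by = "donor", relationship = "many-to-many") %>%
    inner_join(membership %>% rename(recipient = "gene_id", process_b = "process"),
               by = "recipient", relationship = "many-to-many") %>%
    mutate(pa = pmin(.data$process_a, .data$process_b),
           pb = pmax(.data$process_a, .data$process_b)) %>%
    distinct(.data$edge_id, .data$donor, .data$recipient, .data$pa, .data$pb)

  pp <- expanded %>% distinct(.data$pa, .data$pb) %>% arrange(.data$pa, .data$pb)
  key <- match(paste(expanded$pa, expanded$pb),
               paste(pp$pa, pp$pb))
  nk <- nrow(pp)

  ids <- names(conserved)
  di <- match(expanded$donor, ids)
  ri <- match(expanded$recipient, ids)
  cons_vec <- unname(conserved)

  count_fn <- function(flags) {
    keep <- flags[di] & flags[ri]
    tabulate(key[keep], nbins = nk)
  }
  observed <- count_fn(cons_vec)
  perm_counts <- withr::with_seed(derive_seed(seed, "conservation_perm"), {
    vapply(seq_len(n_perm), function(i) {
      count_fn(cons_vec[sample.int(length(cons_vec))])
    }, numeric(nk))
  })
  pm <- rowMeans(perm_counts)
  psd <- apply(perm_counts, 1, sd)

  pp %>%
    mutate(process_a = .data$pa, process_b = .data$pb,
           observed_count = observed,
           perm_mean = pm, perm_sd = psd,
           degenerate = psd == 0,
           Z = if_else(.data$degenerate, NA_real_,
                       (observed - pm) / psd),
           significant = !is.na(.data$Z) & .data$Z >= z_cut) %>%
    select("process_a", "process_b", "observed_count", "perm_mean",
           "perm_sd", "Z", "degenerate", "significant")
}

#' Filter alignment hits to putative paralog pairs
#'
#' A pair is retained when, in at least one alignment direction, coverage
#' is at least 50% of the query length, the E-value is at most 5e-2, and
#' amino-acid identity is at least 30% (all boundaries inclusive). Output
#' is deduplicated to unordered pairs and sorted lexicographically.
#'
#' @param hits Tibble of alignment hits: `query_id`, `subject_id`,
#'   `coverage` (0-1), `e_value`, `identity` (0-1).
#' @param min_coverage,max_evalue,min_identity The three criteria.
#' @return Tibble of unordered pairs `gene_a`, `gene_b`.
#' @export
paralog_filter <- function(hits, min_coverage = 0.5, max_evalue = 5e-2,
                           min_identity = 0.30) {
  if (nrow(hits) == 0L) {
    return(tibble(gene_a = character(0), gene_b = character(0)))
  }
  hits %>%
    filter(.data$query_id != .data$subject_id,
           .data$coverage >= min_coverage,
           .data$e_value <= max_evalue,
           .data$identity >= min_identity) %>%
    transmute(gene_a = pmin(.data$query_id, .data$subject_id),
              gene_b = pmax(.data$query_id, .data$subject_id)) %>%
    distinct() %>%
    arrange(.data$gene_a, .data$gene_b)
}

#' Aggravating-interaction bias among paralog pairs
#'
#' Tests whether paralogous gene pairs are aggravating more often than
#' random non-paralog pairs from the same network. The observed statistic
#' is the aggravating fraction among the scorable paralog pairs; the null
#' resamples equal-sized sets of scorable non-paralog pairs `n_perm` times.
#' Reports the permutation mean/SD, `Z`, and the add-one-smoothed
#' one-sided empirical P.
#'
#' @param network A called network.
#' @param paralog_pairs Tibble of unordered pairs (`gene_a`, `gene_b`) from
#'   [paralog_filter()].
#' @param n_perm Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `n_paralog_pairs`, `observed_fraction`,
#'   `perm_mean`, `perm_sd`, `Z`, `p_value`.
#' @export
paralog_gi_bias <- function(network, paralog_pairs, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) abort("n_perm must be >= 1", class = "giscreen_config_error")
  pairs <- network_pairs(network)
  key <- paste(pmin(pairs$donor, pairs$recipient),
               pmax(pairs$donor, pairs$recipient))
  par_key <- paste(pmin(paralog_pairs$gene_a, paralog_pairs$gene_b),
                   pmax(paralog_pairs$gene_a, paralog_pairs$gene_b))
  is_par <- key %in% par_key
  if (!any(is_par)) {
    abort("no paralog pair is scorable in this network",
          class = "giscreen_data_error")
  }
  agg <- pairs$class == "aggravating"
  n_par <- sum(is_par)
  obs <- mean(agg[is_par])

  pool <- which(!is_par)
  perm <- withr::with_seed(derive_seed(seed, "paralog_bias"), {
    vapply(seq_len(n_perm), function(i) {
      mean(agg[sample(pool, n_par)])
    }, numeric(1))
  })
  psd <- sd(perm)
  tibble(n_paralog_pairs = n_par,
         observed_fraction = obs,
         perm_mean = mean(perm),
         perm_sd = psd,
         Z = if (psd == 0) NA_real_ else (obs - mean(perm)) / psd,
         p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}
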