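#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric with population size `N` containing `M`
#' successes, drawing `n`. This is the enrichment P-value for observing `k`
#' significant interactions between two categories out of `n` possible,
#' when the network holds `M` significant interactions among `N` possible.
#'
#' @param k Observed successes in the draw.
#' @param n Draw size (possible interactions between the two categories).
#' @param M Successes in the population (significant interactions in the
#'   network).
#' @param N Population size (possible interactions in the network).
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, n, M, N) {
  ok <- k >= 0 & k <= pmin(n, M) & n <= N & M <= N & n >= 0 & M >= 0 & N >= 0
  if (any(!ok)) {
    abort("hypergeometric parameters must satisfy 0 <= k <= min(n, M), n <= N, M <= N",
          class = "giscreen_domain_error")
  }
  phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted values
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param p_values Numeric vector of raw P-values in (0, 1].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort("p_values must lie in (0, 1]", class = "giscreen_domain_error")
  }
  p.adjust(p_values, method = "BH")
}

# Internal: turn a network-ish object into (pairs universe, significance).
# Accepts gi_static_network, gi_differential_network, or a tibble with
# donor/recipient and a class-like column.
network_pairs <- function(network,
                          direction = c("any", "aggravating", "alleviating")) {
  direction <- match.arg(direction)
  if (inherits(network, "gi_static_network")) {
    tab <- network$scores %>% select("donor", "recipient", "class")
  } else if (inherits(network, "gi_differential_network")) {
    tab <- network$records %>%
      filter(!.data$incomplete) %>%
      select("donor", "recipient", class = "diff_class")
  } else {
    cls_col <- intersect(c("class", "diff_class"), names(network))[1]
    if (is.na(cls_col)) {
      abort("network table must have a 'class' or 'diff_class' column",
            class = "giscreen_data_error")
    }
    tab <- network %>% select("donor", "recipient", class = all_of(cls_col))
  }
  tab %>%
    mutate(significant = .data$class != "neutral" &
             (direction == "any" | .data$class == direction))
}

#' Process-crosstalk enrichment between bioprocess categories
#'
#' For every unordered pair of categories (including self-pairs, which
#' measure intraconnectivity), counts the significant interactions between
#' them (`k`) among the possible interactions between them (`n`) against
#' the network totals (`M` significant of `N` possible) and computes the
#' exact hypergeometric upper tail with Benjamini-Hochberg adjustment
#' across all tested category pairs. Membership may be fuzzy: a gene pair
#' contributes once to every category pair it instantiates, and `N` and `M`
#' are totals over the same fuzzy universe so the four parameters stay
#' consistent.
#'
#' @param network A called network (`gi_static_network`,
#'   `gi_differential_network`, or a tibble with `donor`, `recipient` and a
#'   class column).
#' @param genes Annotation tibble; category membership is taken from the
#'   `major_bioprocesses` list-column (`annotation = "major"`) or the
#'   `minor_bioprocess` column (`"minor"`).
#' @param direction Count all significant interactions (`"any"`) or only
#'   one sign.
#' @param annotation Which category universe to use.
#' @param config An [analysis_config()] (supplies the FDR level).
#' @return Tibble with one row per tested category pair: `process_a`,
#'   `process_b`, `k`, `n`, `M`, `N`, `P`, `q`, `direction`.
#' @export
process_crosstalk <- function(network, genes,
                              direction = c("any", "aggravating", "alleviating"),
                              annotation = c("major", "minor"),
                              config = analysis_config()) {
  direction <- match.arg(direction)
  annotation <- match.arg(annotation)
  pairs <- network_pairs(network, direction)

  membership <- gene_memberships(genes, annotation)
  unknown <- setdiff(unique(c(pairs$donor, pairs$recipient)),
                     membership$gene_id)
  if (length(unknown) > 0) {
    abort(sprintf("unannotated gene(s) in network: %s",
                  paste(head(unknown, 5), collapse = ", ")),
          class = "giscreen_lookup_error")
  }

  expanded <- pairs %>%
    mutate(pair_id = row_number()) %>%
    inner_join(membership %>% rename(donor = "gene_id", process_a = "process"),
               by = "donor", relationship = "many-to-many") %>%
    inner_join(membership %>% rename(recipient = "gene_id", process_b = "process"),
               by = "recipient", relationship = "many-to-many") %>%
    mutate(pa = pmin(.data$process_a, .data$process_b),
           pb = pmax(.data$process_a, .data$process_b)) %>%
    distinct(.data$pair_id, .data$significant, .data$pa, .data$pb)

  counts <- expanded %>%
    group_by(process_a = .data$pa, process_b = .data$pb) %>%
    summarise(k = sum(.data$significant), n = n(), .groups = "drop")

  N <- sum(counts$n)
  M <- sum(counts$k)
  counts %>%
    mutate(M = M, N = N,
           P = hypergeom_upper_tail(.data$k, .data$n, M, N),
           q = bh_fdr(.data$P),
           direction = direction) %>%
    arrange(.data$P)
}

gene_memberships <- function(genes, annotation) {
  if (annotation == "major") {
    genes %>%
      select("gene_id", process = "major_bioprocesses") %>%
      tidyr::unnest(cols = "process") %>%
      distinct()
  } else {
    genes %>%
      select("gene_id", process = "minor_bioprocess") %>%
      filter(!is.na(.data$process)) %>%
      distinct()
  }
}

#' Permutation test of module-crosstalk enrichment
#'
#' Counts observed significant interactions between every unordered pair of
#' functional modules, then builds a null by randomly reassigning the
#' gene-to-module labels (preserving module sizes) `n_perm` times and
#' recounting. The observed count is transformed to
#' `Z = (observed - mean_null) / sd_null`; a module pair is significant at
#' `Z >= z_cut` (default 1.65, the one-sided 5% normal point). Degenerate
#' permutation SDs yield a flagged missing Z rather than an infinity.
#'
#' @param network A called network (see [process_crosstalk()]).
#' @param modules Tibble with columns `gene_id` and `module`; each module
#'   should contain at least two genes.
#' @param n_perm Number of permutations (default 1000).
#' @param z_cut One-sided Z threshold (default 1.65).
#' @param seed Integer seed.
#' @param inter_only Restrict results to inter-module pairs (default TRUE).
#' @return Tibble per module pair: `module_a`, `module_b`,
#'   `observed_count`, `perm_mean`, `perm_sd`, `Z`, `degenerate`,
#'   `significant`, `n_perm`.
#' @export
module_crosstalk_permutation <- function(network, modules, n_perm = 1000L,
                                         z_cut = 1.65, seed = 1L,
                                         inter_only = TRUE) {
  if (n_perm < 1L) abort("n_perm must be >= 1", class = "giscreen_config_error")
  sizes <- modules %>% count(.data$module)
  if (any(sizes$n < 2L)) {
    warn("module(s) with fewer than 2 genes present")
  }
  pairs <- network_pairs(network) %>% filter(.data$significant)
  mod <- setNames(modules$module, modules$gene_id)
  edges <- pairs %>%
    filter(.data$donor %in% names(mod), .data$recipient %in% names(mod))
  if (nrow(edges) == 0L) {
    abort("no significant interactions between genes with module assignments",
          class = "giscreen_data_error")
  }

  mods <- sort(unique(modules$module))
  nm <- length(mods)
  gene_ids <- modules$gene_id
  lab <- match(mod[gene_ids], mods)
  di <- match(edges$donor, gene_ids)
  ri <- match(edges$recipient, gene_ids)

  pair_key <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    (lo - 1L) * nm + hi
  }
  count_keys <- function(a, b) {
    tabulate(pair_key(a, b), nbins = nm * nm)
  }

  observed <- count_keys(lab[di], lab[ri])
  perm_counts <- withr::with_seed(derive_seed(seed, "module_perm"), {
    vapply(seq_len(n_perm), function(i) {
      pl <- lab[sample.int(length(lab))]
      count_keys(pl[di], pl[ri])
    }, numeric(nm * nm))
  })
  pm <- rowMeans(perm_counts)
  psd <- apply(perm_counts, 1, sd)

  grid <- tidyr::expand_grid(a = seq_len(nm), b = seq_len(nm)) %>%
    filter(.data$a <= .data$b) %>%
    mutate(key = (.data$a - 1L) * nm + .data$b)

  out <- grid %>%
    mutate(module_a = mods[.data$a], module_b = mods[.data$b],
           observed_count = observed[.data$key],
           perm_mean = pm[.data$key],
           perm_sd = psd[.data$key],
           degenerate = .data$perm_sd == 0,
           Z = if_else(.data$degenerate, NA_real_,
                       (.data$observed_count - .data$perm_mean) / .data$perm_sd),
           significant = !is.na(.data$Z) & .data$Z >= z_cut,
           n_perm = n_perm) %>%
    select("module_a", "module_b", "observed_count", "perm_mean", "perm_sd",
           "Z", "degenerate", "significant", "n_perm")
  if (inter_only) out <- out %>% filter(.data$module_a != .data$module_b)
  out
}

# Internal: gene x partner matrix of interaction scores. A gene's profile
# holds its score against every partner it was scored with, in either
# orientation (averaged when both orientations were screened).
profile_matrix <- function(scores) {
  long <- bind_rows(
    scores %>% select(gene = "donor", partner = "recipient", S = "S"),
    scores %>% select(gene = "recipient", partner = "donor", S = "S")) %>%
    group_by(.data$gene, .data$partner) %>%
    summarise(S = mean(.data$S), .groups = "drop")
  genes <- sort(unique(long$gene))
  partners <- sort(unique(long$partner))
  m <- matrix(NA_real_, length(genes), length(partners),
              dimnames = list(genes, partners))
  m[cbind(match(long$gene, genes), match(long$partner, partners))] <- long$S
  m
}

#' Correlation of two genes' interaction profiles
#'
#' Pearson correlation of the interaction scores of `gene_a` and `gene_b`
#' over the partners both were scored against, excluding the two genes
#' themselves and missing values. Suppressed (zero-row result with a
#' message) when fewer than `min_shared` partners are shared.
#'
#' @param scores Score tibble for one network/condition with `donor`,
#'   `recipient`, `S` (e.g. a static network's edges or all scores with
#'   `S = S_gp`).
#' @param gene_a,gene_b Gene identifiers.
#' @param min_shared Minimum shared partners (default 30).
#' @return Tibble with `gene_a`, `gene_b`, `r`, `n_shared`.
#' @export
profile_correlation <- function(scores, gene_a, gene_b, min_shared = 30L) {
  m <- profile_matrix(scores)
  miss <- setdiff(c(gene_a, gene_b), rownames(m))
  if (length(miss) > 0) {
    abort(sprintf("gene(s) not scored in this network: %s",
                  paste(miss, collapse = ", ")),
          class = "giscreen_lookup_error")
  }
  pa <- m[gene_a, ]
  pb <- m[gene_b, ]
  keep <- !is.na(pa) & !is.na(pb) &
    !(colnames(m) %in% c(gene_a, gene_b))
  n_shared <- sum(keep)
  if (n_shared < min_shared) {
    inform(sprintf("profile_correlation: %s-%s suppressed (%d shared partners < %d)",
                   gene_a, gene_b, n_shared, min_shared))
    return(tibble(gene_a = character(0), gene_b = character(0),
                  r = numeric(0), n_shared = integer(0)))
  }
  tibble(gene_a = gene_a, gene_b = gene_b,
         r = cor(pa[keep], pb[keep]), n_shared = n_shared)
}

#' Cross-condition autocorrelation of interaction profiles
#'
#' For each gene scored in both conditions, the Pearson correlation between
#' its RM and MM interaction profiles over shared partners. Genes are
#' partitioned into high (`r >= autocorr_cut`, boundary inclusive) and low
#' autocorrelation classes; low autocorrelation marks genes whose
#' interaction pattern is rewired by the growth condition.
#'
#' @param rm_scores,mm_scores Score tibbles (`donor`, `recipient`, `S`) for
#'   the two conditions.
#' @param gene Optional single gene id; default computes all genes scored
#'   in both conditions.
#' @param config An [analysis_config()] (`autocorr_cut`, `min_shared`).
#' @return Tibble with `gene`, `r`, `n_shared`, `autocorr_class`.
#' @export
autocorrelation <- function(rm_scores, mm_scores, gene = NULL,
                            config = analysis_config()) {
  m_rm <- profile_matrix(rm_scores)
  m_mm <- profile_matrix(mm_scores)
  genes <- intersect(rownames(m_rm), rownames(m_mm))
  if (!is.null(gene)) {
    if (!gene %in% genes) {
      abort(sprintf("gene '%s' is not scored in both conditions", gene),
            class = "giscreen_lookup_error")
    }
    genes <- gene
  }
  partners <- intersect(colnames(m_rm), colnames(m_mm))
  res <- purrr::map_dfr(genes, function(g) {
    pa <- m_rm[g, partners]
    pb <- m_mm[g, partners]
    keep <- !is.na(pa) & !is.na(pb) & partners != g
    if (sum(keep) < config$min_shared) {
      return(tibble(gene = character(0), r = numeric(0), n_shared = integer(0)))
    }
    tibble(gene = g, r = cor(pa[keep], pb[keep]), n_shared = sum(keep))
  })
  res %>%
    mutate(autocorr_class = if_else(.data$r >= config$autocorr_cut,
                                    "high", "low"))
}

#' Per-gene degree statistics, hubs and class summaries
#'
#' Degree is the number of significant interactions incident to a gene;
#' hubs carry at least `hub_min_degree` (default 100). The
#' aggravating-to-alleviating ratio is reported as missing when a gene has
#' no alleviating interactions. Summaries count edges by regulator-scope
#' pairing (local-local vs local-global vs global-global) and by
#' orphan/annotated pairing.
#'
#' @param network A called network.
#' @param genes Annotation tibble with `regulator_scope` and `is_orphan`.
#' @param config An [analysis_config()].
#' @return List of class `gi_degree_stats`: `per_gene` tibble (`gene`,
#'   `degree`, `n_aggravating`, `n_alleviating`, `ratio`, `hub`,
#'   `regulator_scope`, `is_orphan`), `by_scope` and `by_orphan` edge-count
#'   tibbles.
#' @export
degree_stats <- function(network, genes, config = analysis_config()) {
  edges <- network_pairs(network) %>% filter(.data$significant)
  incid <- bind_rows(
    edges %>% select(gene = "donor", "class"),
    edges %>% select(gene = "recipient", "class"))
  per_gene <- incid %>%
    group_by(.data$gene) %>%
    summarise(degree = n(),
              n_aggravating = sum(.data$class == "aggravating"),
              n_alleviating = sum(.data$class == "alleviating"),
              .groups = "drop") %>%
    mutate(ratio = if_else(.data$n_alleviating == 0, NA_real_,
                           .data$n_aggravating / .data$n_alleviating),
           hub = .data$degree >= config$hub_min_degree) %>%
    left_join(genes %>% select(gene = "gene_id", "regulator_scope", "is_orphan"),
              by = "gene")

  scope <- setNames(genes$regulator_scope, genes$gene_id)
  orphan <- setNames(genes$is_orphan, genes$gene_id)
  by_scope <- edges %>%
    mutate(pairing = paste(pmin(scope[.data$donor], scope[.data$recipient]),
                           pmax(scope[.data$donor], scope[.data$recipient]),
                           sep = "-")) %>%
    count(.data$pairing, .data$class, name = "n_edges")
  by_orphan <- edges %>%
    mutate(pairing = case_when(
      orphan[.data$donor] & orphan[.data$recipient] ~ "orphan-orphan",
      !orphan[.data$donor] & !orphan[.data$recipient] ~ "annotated-annotated",
      TRUE ~ "orphan-annotated")) %>%
    count(.data$pairing, .data$class, name = "n_edges")

  structure(list(per_gene = per_gene, by_scope = by_scope,
                 by_orphan = by_orphan),
            class = "gi_degree_stats")
}

#' @export
print.gi_degree_stats <- function(x, ...) {
  cat(sprintf("Degree statistics for %d genes; %d hub(s)\n",
              nrow(x$per_gene), sum(x$per_gene$hub)))
  invisible(x)
}

#' @export
tidy.gi_degree_stats <- function(x, ...) x$per_gene
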