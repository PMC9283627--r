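#' Simulate a two-condition double-mutant colony screen
#'
#' Generates seeded synthetic conjugation-screen data with known ground
#' truth. Expected colony size for a pair (d, r) is
#' `baseline * W_d * W_r`, plus a planted epistatic effect when the pair
#' carries an interaction in that condition, plus additive per-plate
#' row/column offsets, a constant edge bonus on border positions, and
#' i.i.d. Gaussian replicate noise truncated at zero. Planted interactions
#' are negative (aggravating) or positive (alleviating) deviations of
#' `effect_size * noise_sd` intensity units; a deterministic share of them
#' (`rewired_fraction`, per sign, split evenly between conditions) exists in
#' exactly one growth condition, providing ground truth for differential
#' calling.
#'
#' Replicate layout mirrors arrayed screening practice: recipients occupy
#' fixed grid positions, and each (donor, replicate, condition) is pinned on
#' its own plate(s).
#'
#' @param config A [screen_config()].
#' @return An object of class `gi_sim`: a list with
#'   * `screens` — named list (`RM`, `MM`) of colony tibbles with columns
#'     `donor`, `recipient`, `replicate`, `plate`, `row`, `col`, `size`;
#'   * `truth` — list with `planted` (one row per pair x condition with
#'     `sign` and `effect`), `rewired` (pairs present in one condition, with
#'     that condition), and `fitness` (per-gene relative fitness `W`,
#'     identical across conditions);
#'   * `config` — the input configuration.
#' @examples
#' sim <- simulate_screen(screen_config(n_donors = 6, n_recipients = 8,
#'                                      n_replicates = 4, seed = 1))
#' sim$screens$RM
#' @export
simulate_screen <- function(config = screen_config()) {
  validate_screen_config(config)
  donors <- sprintf("d%03d", seq_len(config$n_donors))
  recipients <- sprintf("r%03d", seq_len(config$n_recipients))

  fitness <- withr::with_seed(derive_seed(config$seed, "fitness"), {
    tibble(gene_id = c(donors, recipients),
           W = rtruncnorm(length(donors) + length(recipients),
                          config$fitness_mean, config$fitness_sd,
                          lower = 0, upper = 1.2))
  })

  truth <- plant_interactions(config, donors, recipients)

  screens <- lapply(c(RM = "RM", MM = "MM"), function(cond) {
    simulate_condition(config, cond, donors, recipients, fitness, truth)
  })

  structure(list(screens = screens,
                 truth = list(planted = truth$planted,
                              rewired = truth$rewired,
                              fitness = fitness),
                 config = config),
            class = "gi_sim")
}

# inverse-CDF truncated normal: exact and vectorised, no rejection loop
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Choose planted pairs and their condition memberships. Counts are exact:
# round(fraction * n_pairs) pairs per sign; round(rewired_fraction * n_sign)
# of those live in one condition only, alternately RM / MM.
plant_interactions <- function(config, donors, recipients) {
  n_pairs <- config$n_donors * config$n_recipients
  n_agg <- round(config$planted_fraction_aggravating * n_pairs)
  n_all <- round(config$planted_fraction_alleviating * n_pairs)

  withr::with_seed(derive_seed(config$seed, "plant"), {
    idx <- if (n_agg + n_all > 0) sample.int(n_pairs, n_agg + n_all) else integer(0)
    sign_lab <- rep(c("aggravating", "alleviating"), c(n_agg, n_all))
    d_idx <- ((idx - 1L) %% config$n_donors) + 1L
    r_idx <- ((idx - 1L) %/% config$n_donors) + 1L
    base <- tibble(donor = donors[d_idx], recipient = recipients[r_idx],
                   sign = sign_lab)

    assign_conditions <- function(block) {
      m <- nrow(block)
      n_rw <- round(config$rewired_fraction * m)
      cond_only <- rep(NA_character_, m)
      if (n_rw > 0) {
        rw <- sample.int(m, n_rw)
        cond_only[rw] <- rep(c("RM", "MM"), length.out = n_rw)
      }
      block$condition_only <- cond_only
      block
    }
    base <- base %>%
      group_by(.data$sign) %>%
      dplyr::group_modify(~assign_conditions(.x)) %>%
      ungroup()
  })

  effect <- config$effect_size * config$noise_sd
  planted <- base %>%
    mutate(conds = purrr::map(.data$condition_only,
                              ~ if (is.na(.x)) c("RM", "MM") else .x)) %>%
    tidyr::unnest(cols = "conds") %>%
    transmute_planted(effect)

  rewired <- base %>%
    filter(!is.na(.data$condition_only)) %>%
    select("donor", "recipient", "sign", condition = "condition_only")

  list(planted = planted, rewired = rewired)
}

transmute_planted <- function(x, effect) {
  x %>%
    mutate(condition = .data$conds,
           effect = if_else(.data$sign == "aggravating", -effect, effect)) %>%
    select("donor", "recipient", "condition", "sign", "effect") %>%
    arrange(.data$condition, .data$donor, .data$recipient)
}

simulate_condition <- function(config, cond, donors, recipients, fitness, truth) {
  nd <- config$n_donors
  nr <- config$n_recipients
  nrep <- config$n_replicates
  W <- setNames(fitness$W, fitness$gene_id)

  # long layout: recipient index varies fastest, then donor, then replicate
  grid <- tidyr::expand_grid(replicate = seq_len(nrep),
                             donor = donors,
                             recipient = recipients)

  cap <- config$plate_rows * config$plate_cols
  r_idx <- match(grid$recipient, recipients)
  d_idx <- match(grid$donor, donors)
  n_slots <- nr * nrep
  # each donor's recipient x replicate colonies fill its plate set densely,
  # with positions randomized within the set (spatial randomization): plate
  # rows and columns then mix many gene pairs, so positional artifacts are
  # identifiable and decorrelate from any one pair
  i0 <- (r_idx - 1L) * nrep + (grid$replicate - 1L)
  perm <- withr::with_seed(derive_seed(config$seed, paste0("layout_", cond)), {
    matrix(unlist(lapply(seq_len(nd), function(d) sample.int(n_slots))),
           nrow = n_slots)
  })
  slot <- perm[cbind(i0 + 1L, d_idx)] - 1L
  plate_of <- (slot %/% cap) + 1L
  pos <- slot %% cap
  grid$row <- (pos %/% config$plate_cols) + 1L
  grid$col <- (pos %% config$plate_cols) + 1L
  grid$plate <- sprintf("%s_%s_p%d", cond, grid$donor, plate_of)

  expected <- config$baseline_colony_size * W[grid$donor] * W[grid$recipient]

  pl <- truth$planted %>% filter(.data$condition == cond)
  eff <- numeric(nrow(grid))
  if (nrow(pl) > 0) {
    key <- paste(grid$donor, grid$recipient)
    pe <- setNames(pl$effect, paste(pl$donor, pl$recipient))
    hit <- match(key, names(pe))
    eff[!is.na(hit)] <- pe[hit[!is.na(hit)]]
  }

  withr::with_seed(derive_seed(config$seed, paste0("screen_", cond)), {
    plates <- unique(grid$plate)
    row_off <- matrix(rnorm(length(plates) * config$plate_rows,
                            0, config$row_effect_sd),
                      nrow = length(plates), dimnames = list(plates, NULL))
    col_off <- matrix(rnorm(length(plates) * config$plate_cols,
                            0, config$col_effect_sd),
                      nrow = length(plates), dimnames = list(plates, NULL))
    pi_ <- match(grid$plate, plates)
    edge <- (grid$row == 1L | grid$row == config$plate_rows |
               grid$col == 1L | grid$col == config$plate_cols) *
      config$edge_effect
    noise <- rnorm(nrow(grid), 0, config$noise_sd)
    size <- pmax(0, expected + eff +
                   row_off[cbind(pi_, grid$row)] +
                   col_off[cbind(pi_, grid$col)] +
                   edge + noise)
    if (config$missing_fraction > 0) {
      miss <- runif(nrow(grid)) < config$missing_fraction
      size[miss] <- NA_real_
    }
    grid$size <- size
  })

  grid %>%
    mutate(condition = cond) %>%
    select("condition", "donor", "recipient", "replicate",
           "plate", "row", "col", "size")
}

#' @export
print.gi_sim <- function(x, ...) {
  cat("Synthetic double-mutant screen\n")
  cat(sprintf("  %d donors x %d recipients x %d replicates, conditions RM/MM\n",
              x$config$n_donors, x$config$n_recipients, x$config$n_replicates))
  cat(sprintf("  planted interactions: %d (pair x condition rows), rewired pairs: %d\n",
              nrow(x$truth$planted), nrow(x$truth$rewired)))
  invisible(x)
}

#' Simulate gene annotations for a screen
#'
#' Assigns each gene a uniform locus on the circular chromosome, one to
#' three of thirteen major bioprocess categories (fuzzy membership), one of
#' 41 minor categories, a transcription-factor family label, and orphan /
#' global-regulator / essential-hypomorph flags. Flag counts are assigned by
#' deterministic quota — exactly `round(fraction * n)` genes per flag — so
#' marginal fractions are exact.
#'
#' @param config A [screen_config()]; provides the gene universe, genome
#'   length and root seed.
#' @param orphan_fraction Fraction of genes lacking functional annotation
#'   (default 72/304, the share of uncharacterized transcription factors in
#'   the *E. coli* candidate set).
#' @param global_fraction Fraction of global regulators (default 14/304).
#' @param hypomorph_fraction Fraction of essential-gene hypomorphic alleles.
#' @return A tibble of gene records with list-column `major_bioprocesses`.
#' @export
simulate_annotations <- function(config = screen_config(),
                                 orphan_fraction = 72 / 304,
                                 global_fraction = 14 / 304,
                                 hypomorph_fraction = 7 / 302) {
  stopifnot(orphan_fraction >= 0, orphan_fraction <= 1,
            global_fraction >= 0, global_fraction <= 1)
  genes <- c(sprintf("d%03d", seq_len(config$n_donors)),
             sprintf("r%03d", seq_len(config$n_recipients)))
  n <- length(genes)

  quota_flag <- function(n, frac, order) {
    k <- round(frac * n)
    flag <- logical(n)
    if (k > 0) flag[order[seq_len(k)]] <- TRUE
    flag
  }

  withr::with_seed(derive_seed(config$seed, "annotations"), {
    locus <- sample.int(config$genome_length, n, replace = TRUE) - 1L
    n_major <- sample(1:3, n, replace = TRUE, prob = c(0.55, 0.3, 0.15))
    major <- purrr::map(n_major, ~ sort(sample(bioprocess_labels(), .x)))
    minor <- sample(sprintf("minor_%02d", 1:41), n, replace = TRUE)
    family <- sample(tf_family_labels(), n, replace = TRUE)
    orphan <- quota_flag(n, orphan_fraction, sample.int(n))
    global <- quota_flag(n, global_fraction, sample.int(n))
    hypo <- quota_flag(n, hypomorph_fraction, sample.int(n))
  })

  tibble(gene_id = genes,
         locus_position = locus,
         is_orphan = orphan,
         regulator_scope = if_else(global, "global", "local"),
         is_essential_hypomorph = hypo,
         major_bioprocesses = major,
         minor_bioprocess = minor,
         family = family)
}

#' The thirteen major bioprocess categories
#' @return Character vector of category labels.
#' @export
bioprocess_labels <- function() {
  c("metabolism", "transport", "stress response", "gene regulation",
    "envelope biogenesis", "cell division/shape", "flagellar motility",
    "translation", "genome integrity", "signal transduction",
    "nucleoid organization", "energy production", "unknown function")
}

tf_family_labels <- function() {
  c("LysR", "TetR/AcrR", "AraC/XylS", "GntR", "LuxR", "OmpR", "MarR",
    "GalR-LacI", "Crp-Fnr", "DeoR", "AsnC", "IclR", "MerR", "ArsR",
    "Fis", "HTH-other")
}

#' Simulate phylogenetic ortholog-presence profiles
#'
#' Each gene receives a binary presence vector over a panel of bacterial
#' phyla (default 17). Genes listed in `coconserved_pairs` receive
#' correlated vectors: each of their phylum entries is forced present with
#' probability `coconservation_boost`, so a boost of 1 makes designated
#' pairs co-conserved under the all-phyla rule.
#'
#' @param genes Annotation tibble (or character vector of gene ids).
#' @param n_phyla Number of phyla in the panel (default 17).
#' @param presence_prob Baseline per-phylum presence probability.
#' @param coconservation_boost Probability that a designated gene's entry is
#'   forced to presence (default 1).
#' @param coconserved_pairs Optional tibble with columns `gene_a`, `gene_b`
#'   naming pairs to make co-conserved.
#' @param seed Integer seed.
#' @return Tibble with `gene_id` and one 0/1 column per phylum.
#' @export
simulate_phylo_profiles <- function(genes, n_phyla = 17L,
                                    presence_prob = 0.4,
                                    coconservation_boost = 1,
                                    coconserved_pairs = NULL,
                                    seed = 1L) {
  stopifnot(n_phyla >= 1L)
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  panel <- phylum_labels(n_phyla)
  boosted <- unique(c(coconserved_pairs$gene_a, coconserved_pairs$gene_b))

  withr::with_seed(derive_seed(seed, "phylo"), {
    pres <- matrix(as.integer(runif(length(ids) * n_phyla) < presence_prob),
                   nrow = length(ids))
    if (length(boosted) > 0) {
      bi <- match(intersect(boosted, ids), ids)
      force_on <- matrix(runif(length(bi) * n_phyla) < coconservation_boost,
                         nrow = length(bi))
      pres[bi, ][force_on] <- 1L
    }
  })

  out <- as_tibble(as.data.frame(pres))
  names(out) <- panel
  bind_cols(tibble(gene_id = ids), out)
}

phylum_labels <- function(n_phyla = 17L) {
  full <- c("Proteobacteria", "Firmicutes", "Actinobacteria", "Bacteroidetes",
            "Cyanobacteria", "Spirochaetes", "Tenericutes", "Chlamydiae",
            "Chlorobi", "Chloroflexi", "Deinococcus_Thermus", "Fusobacteria",
            "Planctomycetes", "Thermotogae", "Verrucomicrobia",
            "Acidobacteria", "Aquificae")
  if (n_phyla <= length(full)) full[seq_len(n_phyla)]
  else c(full, sprintf("phylum_%02d", seq_len(n_phyla - length(full))))
}

#' Simulate protein-alignment hits for paralog detection
#'
#' Designates `n_paralog_pairs` gene pairs as true paralogs whose alignment
#' statistics satisfy the paralog criteria (coverage >= 0.5, E-value <=
#' 5e-2, identity >= 0.30) and emits an equal number of decoy hits that each
#' fail at least one criterion.
#'
#' @param genes Annotation tibble or character vector of gene ids.
#' @param n_paralog_pairs Number of true paralog pairs to plant.
#' @param n_decoys Number of decoy hits (default equal to the paralog count).
#' @param seed Integer seed.
#' @return Tibble of hits: `query_id`, `subject_id`, `coverage`, `e_value`,
#'   `identity`, and logical ground-truth column `planted`.
#' @export
simulate_alignment_hits <- function(genes, n_paralog_pairs,
                                    n_decoys = n_paralog_pairs, seed = 1L) {
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  n_possible <- choose(length(ids), 2)
  stopifnot(n_paralog_pairs + n_decoys <= n_possible)

  withr::with_seed(derive_seed(seed, "paralogs"), {
    total <- n_paralog_pairs + n_decoys
    pairs <- sample_unordered_pairs(ids, total)
    planted <- c(rep(TRUE, n_paralog_pairs), rep(FALSE, n_decoys))
    coverage <- ifelse(planted, runif(total, 0.5, 1), runif(total, 0.5, 1))
    e_value <- ifelse(planted, 10^runif(total, -30, log10(5e-2)),
                      10^runif(total, -30, log10(5e-2)))
    identity <- ifelse(planted, runif(total, 0.30, 0.95), runif(total, 0.30, 0.95))
    if (n_decoys > 0) {
      fail_mode <- sample(1:3, n_decoys, replace = TRUE)
      di <- which(!planted)
      coverage[di][fail_mode == 1] <- runif(sum(fail_mode == 1), 0, 0.4999)
      e_value[di][fail_mode == 2] <- 10^runif(sum(fail_mode == 2), log10(5e-2) + 0.01, 2)
      identity[di][fail_mode == 3] <- runif(sum(fail_mode == 3), 0, 0.2999)
    }
  })

  tibble(query_id = pairs$a, subject_id = pairs$b,
         coverage = coverage, e_value = e_value, identity = identity,
         planted = planted)
}

# distinct unordered pairs, uniformly without replacement
sample_unordered_pairs <- function(ids, k) {
  n <- length(ids)
  idx <- sample.int(choose(n, 2), k)
  # map linear index to (i, j), i < j, column-major over the upper triangle
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  # guard against floating-point error at triangle boundaries
  over <- i > j - 1
  j[over] <- j[over] + 1L
  i[over] <- idx[over] - (j[over] - 1) * (j[over] - 2) / 2
  under <- i < 1
  j[under] <- j[under] - 1L
  i[under] <- idx[under] - (j[under] - 1) * (j[under] - 2) / 2
  list(a = ids[i], b = ids[j])
}
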