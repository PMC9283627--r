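#' Configuration of a synthetic double-mutant screen
#'
#' Defaults emulate a transcription-factor epistasis screen in *E. coli*:
#' 278 conjugation donors crossed against 300 arrayed recipients with eight
#' replicate colonies per pair on 16 x 24 plates, a circular 4.6 Mb
#' chromosome, and planted aggravating/alleviating epistasis at 5% + 5% of
#' pairs with an effect of six replicate-noise standard deviations.
#'
#' @param n_donors,n_recipients Number of donor (query) and recipient (array)
#'   genes. Donor and recipient gene sets are disjoint.
#' @param n_replicates Replicate colonies per gene pair (default 8).
#' @param genome_length Circular chromosome length in base pairs.
#' @param plate_rows,plate_cols Colony grid dimensions of one plate.
#' @param baseline_colony_size Expected colony size (arbitrary intensity
#'   units) for a pair of fully fit single mutants.
#' @param fitness_mean,fitness_sd Location and scale of the single-mutant
#'   relative-fitness distribution; fitness is drawn from a normal truncated
#'   to (0, 1.2].
#' @param planted_fraction_aggravating,planted_fraction_alleviating Fractions
#'   of gene pairs receiving a planted negative/positive interaction.
#' @param effect_size Magnitude of the planted deviation from the
#'   multiplicative expectation, in units of `noise_sd`.
#' @param rewired_fraction Fraction of planted pairs (per sign) whose
#'   interaction exists in exactly one growth condition.
#' @param noise_sd Replicate noise standard deviation (intensity units).
#' @param row_effect_sd,col_effect_sd Per-plate row/column offset SDs.
#' @param edge_effect Constant size bonus for border positions of a plate.
#' @param missing_fraction Fraction of colonies set missing at random.
#' @param linkage_window Genomic linkage window in base pairs; pairs closer
#'   than this on the circular chromosome are removed before scoring.
#' @param seed Integer root seed. All generator sub-streams derive child
#'   seeds from it by fixed labels.
#'
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_donors = 278L,
                          n_recipients = 300L,
                          n_replicates = 8L,
                          genome_length = 4600000L,
                          plate_rows = 16L,
                          plate_cols = 24L,
                          baseline_colony_size = 100,
                          fitness_mean = 0.95,
                          fitness_sd = 0.1,
                          planted_fraction_aggravating = 0.05,
                          planted_fraction_alleviating = 0.05,
                          effect_size = 6,
                          rewired_fraction = 0.3,
                          noise_sd = 10,
                          row_effect_sd = 2,
                          col_effect_sd = 2,
                          edge_effect = 5,
                          missing_fraction = 0.02,
                          linkage_window = 30000L,
                          seed = 1L) {
  cfg <- list(
    n_donors = as.integer(n_donors),
    n_recipients = as.integer(n_recipients),
    n_replicates = as.integer(n_replicates),
    genome_length = as.integer(genome_length),
    plate_rows = as.integer(plate_rows),
    plate_cols = as.integer(plate_cols),
    baseline_colony_size = baseline_colony_size,
    fitness_mean = fitness_mean,
    fitness_sd = fitness_sd,
    planted_fraction_aggravating = planted_fraction_aggravating,
    planted_fraction_alleviating = planted_fraction_alleviating,
    effect_size = effect_size,
    rewired_fraction = rewired_fraction,
    noise_sd = noise_sd,
    row_effect_sd = row_effect_sd,
    col_effect_sd = col_effect_sd,
    edge_effect = edge_effect,
    missing_fraction = missing_fraction,
    linkage_window = as.integer(linkage_window),
    seed = as.integer(seed)
  )
  validate_screen_config(cfg)
  structure(cfg, class = "screen_config")
}

validate_screen_config <- function(cfg) {
  if (cfg$n_donors < 1L || cfg$n_recipients < 1L) {
    abort("screen dimensions must be positive", class = "giscreen_config_error")
  }
  if (cfg$n_replicates < 2L) {
    abort("n_replicates must be >= 2", class = "giscreen_config_error")
  }
  fr <- cfg$planted_fraction_aggravating + cfg$planted_fraction_alleviating
  if (cfg$planted_fraction_aggravating < 0 || cfg$planted_fraction_alleviating < 0 ||
      fr > 0.4) {
    abort("planted fractions must be non-negative and sum to at most 0.4",
          class = "giscreen_config_error")
  }
  sds <- c(cfg$noise_sd, cfg$row_effect_sd, cfg$col_effect_sd, cfg$edge_effect,
           cfg$effect_size, cfg$fitness_sd)
  if (any(sds < 0)) {
    abort("effect and SD parameters must be >= 0", class = "giscreen_config_error")
  }
  if (cfg$rewired_fraction < 0 || cfg$rewired_fraction > 1) {
    abort("rewired_fraction must lie in [0, 1]", class = "giscreen_config_error")
  }
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1) {
    abort("missing_fraction must lie in [0, 1)", class = "giscreen_config_error")
  }
  if (cfg$plate_rows < 1L || cfg$plate_cols < 1L) {
    abort("plate dimensions must be positive", class = "giscreen_config_error")
  }
  invisible(cfg)
}

#' Normalization settings
#'
#' @param correct_row_col Remove per-plate row/column trends by one round of
#'   median polish on log colony sizes (default `TRUE`).
#' @param linkage_window Linkage window in base pairs (default 30,000).
#' @param min_replicates Minimum non-missing replicates for a pair or gene to
#'   be scorable (default 4).
#' @param missing_policy How scoring treats pairs with too few replicates:
#'   drop them (`"drop_pair"`) or impute the pair median (`"impute_median"`).
#'
#' @return A list of class `normalization_config`.
#' @export
normalization_config <- function(correct_row_col = TRUE,
                                 linkage_window = 30000L,
                                 min_replicates = 4L,
                                 missing_policy = c("drop_pair", "impute_median")) {
  missing_policy <- match.arg(missing_policy)
  if (linkage_window < 0) abort("linkage_window must be >= 0",
                                class = "giscreen_config_error")
  if (min_replicates < 2L) abort("min_replicates must be >= 2",
                                 class = "giscreen_config_error")
  structure(list(reference_statistic = "plate_median",
                 correct_row_col = isTRUE(correct_row_col),
                 linkage_window = as.integer(linkage_window),
                 min_replicates = as.integer(min_replicates),
                 missing_policy = missing_policy),
            class = "normalization_config")
}

#' Static-interaction calling thresholds
#'
#' The default score cuts are the published two-standard-deviation neutral
#' bands of each scoring model per growth condition: multiplicative RM
#' (-0.3, 1.8) and MM (-1.4, 3.0); Gaussian-process RM (-0.9, 1.3) and MM
#' (-2.3, 1.9). A pair is non-neutral when its score falls at or outside the
#' band, its |Z| is at least `z_cut` and its P at most `p_cut`. All
#' comparisons are inclusive.
#'
#' @param mult,gp Named lists with elements `RM` and `MM`, each a numeric
#'   `c(lower, upper)` neutral band (lower < 0 < upper).
#' @param z_cut Absolute standardized-score threshold (default 2.0).
#' @param p_cut Tail-probability threshold (default 0.05).
#' @param require_sign_agreement Require both models to agree on the
#'   interaction sign (default `TRUE`) rather than mere co-significance.
#'
#' @return A list of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(mult = list(RM = c(-0.3, 1.8), MM = c(-1.4, 3.0)),
                               gp = list(RM = c(-0.9, 1.3), MM = c(-2.3, 1.9)),
                               z_cut = 2.0,
                               p_cut = 0.05,
                               require_sign_agreement = TRUE) {
  for (model in list(mult, gp)) {
    for (cond in names(model)) {
      cut <- model[[cond]]
      if (length(cut) != 2L || !(cut[1] < 0 && cut[2] > 0)) {
        abort("each threshold band must satisfy lower < 0 < upper",
              class = "giscreen_config_error")
      }
    }
  }
  structure(list(mult = mult, gp = gp, z_cut = z_cut, p_cut = p_cut,
                 require_sign_agreement = isTRUE(require_sign_agreement)),
            class = "scoring_thresholds")
}

#' Differential-network thresholds
#'
#' Defaults are the published cuts: a differential score S_DF = S_MM - S_RM
#' is called aggravating at S_DF <= -2.6 and alleviating at S_DF >= 1.7,
#' both with empirical P <= 0.05; gain/loss classification is restricted to
#' |S_DF| >= 5.0.
#'
#' @param lower_diff_cut,upper_diff_cut Neutral band on S_DF.
#' @param p_cut Empirical tail-probability threshold.
#' @param gainloss_magnitude Minimum |S_DF| for gain/loss classification.
#'
#' @return A list of class `differential_thresholds`.
#' @export
differential_thresholds <- function(lower_diff_cut = -2.6,
                                    upper_diff_cut = 1.7,
                                    p_cut = 0.05,
                                    gainloss_magnitude = 5.0) {
  if (!(lower_diff_cut < 0 && upper_diff_cut > 0)) {
    abort("differential band must satisfy lower < 0 < upper",
          class = "giscreen_config_error")
  }
  structure(list(lower_diff_cut = lower_diff_cut,
                 upper_diff_cut = upper_diff_cut,
                 p_cut = p_cut,
                 gainloss_magnitude = gainloss_magnitude),
            class = "differential_thresholds")
}

#' Downstream network-analysis settings
#'
#' @param hub_min_degree Minimum significant-interaction count for a hub
#'   (default 100).
#' @param autocorr_cut Boundary between high and low cross-condition profile
#'   autocorrelation (default 0.25; the boundary itself is "high").
#' @param min_shared Minimum shared scored partners for a profile
#'   correlation (default 30).
#' @param fdr_alpha Benjamini-Hochberg FDR level (default 0.05).
#' @param enrichment_p_cut Raw-P threshold reported alongside the FDR for
#'   process-crosstalk enrichment (default 0.008).
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(hub_min_degree = 100L,
                            autocorr_cut = 0.25,
                            min_shared = 30L,
                            fdr_alpha = 0.05,
                            enrichment_p_cut = 0.008) {
  vals <- c(hub_min_degree, autocorr_cut, min_shared, fdr_alpha, enrichment_p_cut)
  if (any(vals <= 0)) abort("analysis settings must be positive",
                            class = "giscreen_config_error")
  structure(list(hub_min_degree = as.integer(hub_min_degree),
                 autocorr_cut = autocorr_cut,
                 min_shared = as.integer(min_shared),
                 fdr_alpha = fdr_alpha,
                 enrichment_p_cut = enrichment_p_cut),
            class = "analysis_config")
}

#' Gaussian-process scorer settings
#'
#' @param fit_cap Maximum number of gene pairs conditioning the predictive
#'   distribution; larger screens are represented by a fixed-seed subsample
#'   and all pairs are predicted from it.
#' @param opt_cap Maximum number of pairs (drawn from the conditioning
#'   subsample) used for marginal-likelihood hyperparameter optimisation.
#' @param restarts Number of fixed hyperparameter starting points for the
#'   marginal-likelihood optimisation.
#' @param subsample_seed Seed for the fit subsample; fixed so the fit is a
#'   deterministic function of the data.
#' @param jitter Numerical ridge added to the kernel diagonal.
#' @param trim_iters Outlier-trimming passes: after each fit, training
#'   points whose standardized residual exceeds `trim_z` are dropped and
#'   the hyperparameters refit (warm-started), so strong epistatic outliers
#'   do not inflate the fitted noise term. 0 disables trimming.
#' @param trim_z Residual threshold for trimming (default 3).
#'
#' @return A list of class `gp_control`.
#' @export
gp_control <- function(fit_cap = 500L, opt_cap = 250L, restarts = 2L,
                       subsample_seed = 101L, jitter = 1e-8,
                       trim_iters = 2L, trim_z = 3) {
  structure(list(fit_cap = as.integer(fit_cap),
                 opt_cap = as.integer(opt_cap),
                 restarts = as.integer(restarts),
                 subsample_seed = as.integer(subsample_seed),
                 jitter = jitter,
                 trim_iters = as.integer(trim_iters),
                 trim_z = trim_z),
            class = "gp_control")
}

# Deterministic child seed from a root seed and a stream label, so adding a
# generator never perturbs the draws of existing ones. Rolling polynomial
# hash of the label, folded with the seed; always < 2^31.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000003
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + h) %% 2147483647)
}
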