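# shared fixture builders; everything is generated in code at test time

# a single-condition screen tibble built by hand: one row per colony
flat_screen <- function(sizes, plate_rows = 4L, plate_cols = 6L,
                        donors = "dA", recipients = NULL,
                        condition = "RM", plate = "p1") {
  cap <- plate_rows * plate_cols
  n <- length(sizes)
  stopifnot(n <= cap)
  recipients <- recipients %||% sprintf("r%02d", seq_len(n))
  pos <- seq_len(n) - 1L
  tibble::tibble(condition = condition,
                 donor = donors,
                 recipient = recipients,
                 replicate = 1L,
                 plate = plate,
                 row = pos %/% plate_cols + 1L,
                 col = pos %% plate_cols + 1L,
                 size = sizes)
}

# manual fitness object for scoring tests with controlled W values
manual_fitness <- function(W, reference_size) {
  tab <- tibble::tibble(gene_id = names(W), role = "donor", W = unname(W),
                        n_obs = 100L, excluded = FALSE)
  structure(list(table = tab, reference_size = reference_size),
            class = "gi_fitness")
}

# standardized score table built directly (bypasses standardize_scores) so
# calling-rule tests can place S, Z, P exactly where they want them
manual_scores <- function(donor, recipient, condition, S, Z = NULL, P = NULL) {
  Z <- Z %||% S
  P <- P %||% (2 * stats::pnorm(-abs(Z)))
  tibble::tibble(donor = donor, recipient = recipient,
                 condition = condition, n_obs = 8L,
                 mean_size = NA_real_, expected = NA_real_,
                 S = S, Z = Z, P = P)
}

# minimal static-network stand-in: only $edges is consulted by
# classify_gain_loss
manual_static_net <- function(donor, recipient, class = "alleviating",
                              condition = "RM") {
  edges <- tibble::tibble(donor = donor, recipient = recipient,
                          condition = condition, S = NA_real_, Z = NA_real_,
                          P = NA_real_, n_obs = 8L, class = class)
  structure(list(condition = condition, scores = edges, edges = edges,
                 thresholds = scoring_thresholds()),
            class = "gi_static_network")
}

# run normalize + dual-model scoring + calling for one condition
call_condition <- function(screen, thresholds = scoring_thresholds()) {
  scr <- normalize_screen(screen)
  fit <- estimate_fitness(scr)
  mult <- standardize_scores(score_multiplicative(scr, fit))
  gp <- standardize_scores(score_gaussian_process(scr, fit))
  call_static_network(mult, gp, thresholds)
}

pair_key <- function(d, r) paste(d, r)
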