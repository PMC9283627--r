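#' Differential interaction scores between conditions
#'
#' For every gene pair scored in both growth conditions, the differential
#' score is `S_DF = S_MM - S_RM`, computed on robust-standardized
#' Gaussian-process static scores: within each condition the scores are
#' centred by their median and scaled by their MAD. The per-condition
#' transformation brings the two conditions onto a common scale before
#' differencing — without it, any difference between the conditions' score
#' scales would masquerade as rewiring for every strong interaction — and
#' the robust scale estimate calibrates that common scale to the neutral
#' background rather than letting strong interactions stretch it. Pairs
#' scored in only one condition are kept with missing `S_DF` and flagged
#' `incomplete`; they are excluded from significance calling.
#'
#' @param rm,mm `gi_static_network` objects (their GP score column is
#'   robust-standardized) or score tibbles with columns `donor`,
#'   `recipient`, `S` already on a common scale, for the RM and MM
#'   conditions.
#' @return Tibble with `donor`, `recipient`, `S_RM`, `S_MM`, `S_DF`,
#'   `incomplete`.
#' @export
compute_differential <- function(rm, mm) {
  grab <- function(x) {
    if (inherits(x, "gi_static_network")) {
      x$scores %>%
        transmute(donor = .data$donor, recipient = .data$recipient,
                  S = (.data$S_gp - median(.data$S_gp)) / mad(.data$S_gp))
    } else {
      x %>% select("donor", "recipient", S = "S")
    }
  }
  full_join(grab(rm) %>% rename(S_RM = "S"),
            grab(mm) %>% rename(S_MM = "S"),
            by = c("donor", "recipient")) %>%
    mutate(S_DF = .data$S_MM - .data$S_RM,
           incomplete = is.na(.data$S_RM) | is.na(.data$S_MM))
}

#' Empirical null distribution of score differences
#'
#' Builds the no-rewiring null for differential calling by split-half
#' resampling: within each condition the replicates are randomly split into
#' two halves, each half is scored independently through the supplied
#' scoring pipeline, and the within-condition difference of half scores is
#' pooled across conditions and splits. These differences carry the full
#' scoring noise of the pipeline but, being computed within a condition,
#' contain no condition effect.
#'
#' @param rm_screen,mm_screen Normalized colony tibbles with at least four
#'   replicates each.
#' @param scorer Function `screen -> tibble(donor, recipient, S)`. The
#'   default re-estimates fitness on each half, applies the
#'   Gaussian-process scorer and standardizes within the half, matching the
#'   static scoring path on the Z scale used for differencing.
#' @param n_splits Number of random replicate splits (default 20).
#' @param seed Integer seed; the null is deterministic given it.
#' @param half_scale Factor applied to the half-score differences (default
#'   `sqrt(2)`). Each half holds half the replicates, and the half scores
#'   are standardized against their own (noisier) background, which would
#'   otherwise cancel the extra split noise; the factor restores the
#'   variance ratio between a split half and the full screen, keeping the
#'   null conservative on the full-replicate scale.
#' @return Numeric vector of null score differences.
#' @export
difference_null <- function(rm_screen, mm_screen, scorer = NULL,
                            n_splits = 20L, seed = 1L,
                            half_scale = sqrt(2)) {
  if (n_splits < 1L) {
    abort("n_splits must be at least 1", class = "giscreen_config_error")
  }
  scorer <- scorer %||% function(screen) {
    fit <- estimate_fitness(screen, min_replicates = 2L)
    score_gaussian_process(screen, fit, min_replicates = 2L) %>%
      standardize_scores(robust = TRUE) %>%
      mutate(S = .data$Z)
  }
  screens <- list(rm_screen, mm_screen)
  for (s in screens) {
    if (length(unique(s$replicate)) < 4L) {
      abort("cannot form split halves: fewer than 4 replicates",
            class = "giscreen_data_error")
    }
  }

  out <- vector("list", 2L * n_splits)
  k <- 0L
  for (ci in seq_along(screens)) {
    screen <- screens[[ci]]
    reps <- sort(unique(screen$replicate))
    half <- length(reps) %/% 2L
    for (split in seq_len(n_splits)) {
      split_seed <- derive_seed(seed, sprintf("null_c%d_s%d", ci, split))
      ra <- withr::with_seed(split_seed, sample(reps, half))
      sa <- scorer(screen %>% filter(.data$replicate %in% ra))
      sb <- scorer(screen %>% filter(!(.data$replicate %in% ra)))
      d <- inner_join(sa %>% select("donor", "recipient", S_a = "S"),
                      sb %>% select("donor", "recipient", S_b = "S"),
                      by = c("donor", "recipient"))
      k <- k + 1L
      out[[k]] <- half_scale * (d$S_a - d$S_b)
    }
  }
  unlist(out)
}

#' Assign empirical differential P-values
#'
#' Two-sided empirical tail probability of each differential score against
#' the null sample, with add-one smoothing so P is never zero:
#' `P_DF = (1 + #\{|null| >= |S_DF|\}) / (m + 1)`.
#'
#' @param records Differential records from [compute_differential()].
#' @param null_sample Numeric vector of null score differences (length >=
#'   100 recommended).
#' @return `records` with column `P_DF`; missing `S_DF` yields missing
#'   `P_DF`.
#' @export
assign_differential_p <- function(records, null_sample) {
  m <- length(null_sample)
  if (m == 0L) {
    abort("empty null sample", class = "giscreen_data_error")
  }
  absnull <- sort(abs(null_sample))
  # #{|null| >= |s|} = m - #{|null| < |s|}, via binary search on sorted |null|
  cnt <- m - findInterval(abs(records$S_DF), absnull, left.open = TRUE)
  records %>%
    mutate(P_DF = if_else(is.na(.data$S_DF), NA_real_, (1 + cnt) / (m + 1)))
}

#' Call the differential interaction network
#'
#' A pair is differentially aggravating when `S_DF <= lower_diff_cut` and
#' `P_DF <= p_cut`, differentially alleviating when `S_DF >=
#' upper_diff_cut` and `P_DF <= p_cut`, and neutral otherwise; boundary
#' values are significant. Incomplete records (unscored in one condition)
#' stay neutral.
#'
#' @param records Differential records with `P_DF` assigned.
#' @param thresholds A [differential_thresholds()].
#' @return Object of class `gi_differential_network`: list with `records`
#'   (column `diff_class` added) and `thresholds`.
#' @export
call_differential <- function(records, thresholds = differential_thresholds()) {
  records <- records %>%
    mutate(diff_class = case_when(
      is.na(.data$S_DF) | is.na(.data$P_DF) ~ "neutral",
      .data$S_DF <= thresholds$lower_diff_cut & .data$P_DF <= thresholds$p_cut ~
        "aggravating",
      .data$S_DF >= thresholds$upper_diff_cut & .data$P_DF <= thresholds$p_cut ~
        "alleviating",
      TRUE ~ "neutral"))
  structure(list(records = records, thresholds = thresholds),
            class = "gi_differential_network")
}

#' Classify gain and loss of interaction
#'
#' Restricted to differential records with `P_DF <= p_cut` and
#' `|S_DF| >= gainloss_magnitude`: a pair neutral in the static RM network
#' but significant in MM is a gain of interaction; significant in RM but
#' neutral in MM is a loss. Pairs significant in both conditions (or in
#' neither) are labelled by the dominant shift: gain when `|S_MM| >
#' |S_RM|`, loss otherwise. Qualifying records are ordered by
#' average-linkage hierarchical clustering of the `(S_RM, S_MM)` vectors
#' with Euclidean distance (column `cluster_order`; ties broken by the
#' deterministic input order of pair ids).
#'
#' @param diff_net A `gi_differential_network` (or its records tibble with
#'   `diff_class` and `P_DF`).
#' @param rm_net,mm_net Static `gi_static_network` objects providing the
#'   per-condition significance calls.
#' @param thresholds A [differential_thresholds()].
#' @return Records tibble with columns `gain_loss` (`"gain"`, `"loss"`,
#'   `"none"`) and `cluster_order` (rank in the clustering leaf order; NA
#'   for non-qualifying rows).
#' @export
classify_gain_loss <- function(diff_net, rm_net, mm_net,
                               thresholds = differential_thresholds()) {
  records <- if (inherits(diff_net, "gi_differential_network")) {
    diff_net$records
  } else {
    diff_net
  }
  sig_key <- function(net) {
    paste(net$edges$donor, net$edges$recipient)
  }
  rm_sig <- sig_key(rm_net)
  mm_sig <- sig_key(mm_net)
  key <- paste(records$donor, records$recipient)
  in_rm <- key %in% rm_sig
  in_mm <- key %in% mm_sig

  qualifies <- !is.na(records$S_DF) & !is.na(records$P_DF) &
    records$P_DF <= thresholds$p_cut &
    abs(records$S_DF) >= thresholds$gainloss_magnitude

  records$gain_loss <- dplyr::case_when(
    !qualifies ~ "none",
    !in_rm & in_mm ~ "gain",
    in_rm & !in_mm ~ "loss",
    abs(records$S_MM) > abs(records$S_RM) ~ "gain",
    TRUE ~ "loss")

  records$cluster_order <- NA_integer_
  qi <- which(qualifies)
  if (length(qi) >= 3L) {
    ord <- order(records$donor[qi], records$recipient[qi])
    qi <- qi[ord]  # deterministic input order by pair id
    hc <- hclust(dist(cbind(records$S_RM[qi], records$S_MM[qi])),
                 method = "average")
    records$cluster_order[qi[hc$order]] <- seq_along(qi)
  } else if (length(qi) > 0L) {
    records$cluster_order[qi] <- seq_along(qi)
  }
  records
}

#' @export
print.gi_differential_network <- function(x, ...) {
  r <- x$records
  cat("Differential genetic-interaction network (S_MM - S_RM)\n")
  cat(sprintf("  %d pairs (%d incomplete), %d aggravating, %d alleviating\n",
              nrow(r), sum(r$incomplete),
              sum(r$diff_class == "aggravating"),
              sum(r$diff_class == "alleviating")))
  invisible(x)
}

#' Tidy the records of a differential network
#' @param x A `gi_differential_network`.
#' @param ... Unused.
#' @export
tidy.gi_differential_network <- function(x, ...) x$records

#' One-row summary of a differential network
#' @param x A `gi_differential_network`.
#' @param ... Unused.
#' @export
glance.gi_differential_network <- function(x, ...) {
  r <- x$records
  tibble(n_pairs = nrow(r),
         n_incomplete = sum(r$incomplete),
         n_aggravating = sum(r$diff_class == "aggravating"),
         n_alleviating = sum(r$diff_class == "alleviating"),
         frac_called = mean(r$diff_class != "neutral"))
}

#' @export
autoplot.gi_differential_network <- function(object, ...) {
  ggplot2::ggplot(object$records %>% filter(!.data$incomplete),
                  ggplot2::aes(x = .data$S_RM, y = .data$S_MM,
                               colour = .data$diff_class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(aggravating = "#c0392b",
                                            alleviating = "#2471a3",
                                            neutral = "grey70")) +
    ggplot2::labs(x = "S (rich medium)", y = "S (minimal medium)") +
    ggplot2::theme_minimal()
}

#' Heatmap of gain/loss-classified differential pairs
#'
#' Displays the `(S_RM, S_MM)` score pair of every gain/loss record in
#' hierarchical-clustering order.
#'
#' @param records Output of [classify_gain_loss()].
#' @return A ggplot object.
#' @export
plot_gain_loss <- function(records) {
  x <- records %>%
    filter(.data$gain_loss != "none") %>%
    arrange(.data$cluster_order) %>%
    mutate(pos = row_number()) %>%
    tidyr::pivot_longer(cols = c("S_RM", "S_MM"),
                        names_to = "condition", values_to = "S")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$condition, y = .data$pos,
                                  fill = .data$S)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#c0392b", mid = "white",
                                  high = "#2471a3", midpoint = 0) +
    ggplot2::facet_wrap(~gain_loss, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "gene pairs (clustering order)") +
    ggplot2::theme_minimal()
}
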