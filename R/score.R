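#' Score gene pairs under the multiplicative fitness model
#'
#' For each donor-recipient pair the expected double-mutant colony size is
#' `E = reference * W_d * W_r`. The score is a t-like statistic: the
#' deviation of the replicate mean from `E` divided by its standard error,
#' `S = (mean(obs) - E) / (s / sqrt(n))`, where `s` is a moderated replicate
#' SD: the per-pair sample variance is shrunk toward the median per-pair
#' variance with `moderation_df` pseudo-replicates
#' (`s^2 <- (d * s^2 + moderation_df * s0^2) / (d + moderation_df)`, with
#' `d = n - 1` and `s0` the screen-wide median SD), and then floored (by
#' default at the 5th percentile of all per-pair SDs). Moderation stabilises
#' the denominator of well-replicated pairs exactly as pooled-variance
#' scoring does in epistatic-miniarray practice; the floor prevents
#' blow-ups for pairs with near-identical replicates. Negative scores flag
#' aggravating (worse than expected) pairs, positive scores alleviating
#' ones.
#'
#' @param screen Normalized colony tibble for one condition.
#' @param fitness A [estimate_fitness()] result for the same screen.
#' @param min_replicates Minimum non-missing replicates per pair; pairs
#'   below it are skipped (reported via message).
#' @param s_floor Optional explicit variance floor for the replicate SD;
#'   default `NULL` uses the 5th percentile of all per-pair SDs.
#' @param moderation_df Prior degrees of freedom for variance moderation
#'   (default 50); 0 disables moderation and leaves the pure
#'   floored-SD statistic.
#' @return Tibble with one row per scorable pair: `donor`, `recipient`,
#'   `condition`, `n_obs`, `mean_size`, `expected`, `S`.
#' @export
score_multiplicative <- function(screen, fitness, min_replicates = 4L,
                                 s_floor = NULL, moderation_df = 50) {
  cond <- screen_condition(screen)
  W <- fitness_lookup(fitness)
  ref <- fitness$reference_size

  per_pair <- screen %>%
    group_by(.data$donor, .data$recipient) %>%
    summarise(n_obs = sum(!is.na(.data$size)),
              mean_size = mean(.data$size, na.rm = TRUE),
              s = sd(.data$size, na.rm = TRUE),
              .groups = "drop")

  excluded <- fitness$table$gene_id[fitness$table$excluded]
  scorable <- per_pair %>%
    filter(.data$n_obs >= min_replicates,
           !(.data$donor %in% excluded), !(.data$recipient %in% excluded))
  n_skip <- nrow(per_pair) - nrow(scorable)
  if (n_skip > 0) {
    inform(sprintf("score_multiplicative: %d pair(s) skipped (insufficient replicates or excluded gene)",
                   n_skip))
  }

  floor_val <- s_floor %||% quantile(scorable$s, 0.05, na.rm = TRUE, names = FALSE)
  s0sq <- median(scorable$s, na.rm = TRUE)^2
  scorable %>%
    mutate(condition = cond,
           expected = ref * unname(W[.data$donor] * W[.data$recipient]),
           s_mod = sqrt(((.data$n_obs - 1) * .data$s^2 + moderation_df * s0sq) /
                          (.data$n_obs - 1 + moderation_df)),
           s_used = pmax(.data$s_mod, floor_val, 1e-12),
           dev = .data$mean_size - .data$expected,
           S = if_else(.data$dev == 0, 0,
                       .data$dev / (.data$s_used / sqrt(.data$n_obs)))) %>%
    select("donor", "recipient", "condition", "n_obs", "mean_size",
           "expected", "S")
}

screen_condition <- function(screen) {
  if ("condition" %in% names(screen)) {
    cond <- unique(screen$condition)
    if (length(cond) != 1L) {
      abort("screen must contain a single condition", class = "giscreen_data_error")
    }
    cond
  } else {
    NA_character_
  }
}

fitness_lookup <- function(fitness) {
  tab <- fitness$table
  # a gene screened in both roles keeps its per-role estimate; scoring looks
  # up donors and recipients separately through the combined map
  W <- setNames(tab$W, tab$gene_id)
  W
}

#' Score gene pairs with a Gaussian-process surface model
#'
#' Fits, per condition, a Gaussian-process regression of the per-pair mean
#' colony size on the two single-mutant fitness values (W_d, W_r), using a
#' squared-exponential kernel plus observation noise with hyperparameters
#' chosen by marginal-likelihood optimisation from a fixed set of starting
#' points. The observation noise is heteroscedastic and largely known: each
#' pair's mean carries sampling variance `s_mod^2 / n` from its own
#' (moderated) replicate SD, and the optimiser adds only a shared extra
#' white-noise term on top. The GP captures smooth non-multiplicative
#' trends in the fitness-fitness plane; the score of a pair is its
#' standardized residual,
#' `S = (observed mean - posterior mean) / posterior predictive SD`, where
#' the predictive SD includes that pair's own observation noise. For
#' screens larger than `gp_config$fit_cap` pairs, hyperparameters and the
#' predictive conditioning set come from a fixed-seed subsample and all
#' pairs are predicted from it. The fit is deterministic given the data and
#' `gp_config`.
#'
#' If the predictor matrix is degenerate (all fitness values identical) the
#' function falls back to multiplicative scoring with a warning.
#'
#' @inheritParams score_multiplicative
#' @param gp_config A [gp_control()].
#' @return Tibble like [score_multiplicative()] with score column `S`.
#' @export
score_gaussian_process <- function(screen, fitness, min_replicates = 4L,
                                   gp_config = gp_control(),
                                   moderation_df = 50) {
  cond <- screen_condition(screen)
  W <- fitness_lookup(fitness)
  excluded <- fitness$table$gene_id[fitness$table$excluded]

  per_pair <- screen %>%
    group_by(.data$donor, .data$recipient) %>%
    summarise(n_obs = sum(!is.na(.data$size)),
              mean_size = mean(.data$size, na.rm = TRUE),
              s = sd(.data$size, na.rm = TRUE),
              .groups = "drop") %>%
    filter(.data$n_obs >= min_replicates,
           !(.data$donor %in% excluded), !(.data$recipient %in% excluded))

  X <- cbind(unname(W[per_pair$donor]), unname(W[per_pair$recipient]))
  y <- per_pair$mean_size
  if (nrow(per_pair) < 5L) {
    abort("too few scorable pairs for Gaussian-process scoring",
          class = "giscreen_data_error")
  }
  if (sd(X[, 1]) < 1e-12 && sd(X[, 2]) < 1e-12) {
    warn("degenerate predictor matrix (all fitness values identical); falling back to multiplicative scoring")
    return(score_multiplicative(screen, fitness, min_replicates))
  }

  s0sq <- median(per_pair$s, na.rm = TRUE)^2
  s_mod <- sqrt(((per_pair$n_obs - 1) * per_pair$s^2 + moderation_df * s0sq) /
                  (per_pair$n_obs - 1 + moderation_df))
  noise_var <- pmax(s_mod^2 / per_pair$n_obs, 1e-12)

  # the GP models smooth deviations from the multiplicative expectation:
  # the multiplicative surface is the parametric mean function, so where
  # data or kernel support is thin the prediction reverts to it instead of
  # extrapolating freely
  mult_expected <- fitness$reference_size * X[, 1] * X[, 2]
  resid <- y - mult_expected

  # pre-screen the training set with multiplicative-model residuals: unlike
  # the GP's own leave-in residuals, these cannot absorb a strong epistatic
  # pair at a high-leverage position, so such pairs never enter the fit
  pre_z <- resid / sqrt(noise_var)
  train_ok <- abs(pre_z) <= gp_config$trim_z | !is.finite(pre_z)
  if (sum(train_ok) < 20L) train_ok <- rep(TRUE, length(train_ok))

  # predictive SDs below 1e-6 of the colony-size scale are numerically
  # indistinguishable from zero (relevant only for noise-free inputs)
  fit <- gp_fit_predict(X, resid, noise_var, gp_config, train_ok = train_ok,
                        sd_floor = 1e-6 * max(sd(y), 1e-12))
  per_pair %>%
    mutate(condition = cond,
           expected = mult_expected + fit$mu,
           S = (.data$mean_size - .data$expected) / fit$sd) %>%
    select("donor", "recipient", "condition", "n_obs", "mean_size",
           "expected", "S")
}

# Squared-exponential GP regression with heteroscedastic observation noise.
# `noise_var` holds each observation's known sampling variance (original y
# units); the optimiser adds a shared extra white-noise term. Standardizes
# X and y internally; returns predictive mean and per-point predictive SD
# on the original y scale, the latter including each point's own noise.
gp_fit_predict <- function(X, y, noise_var, ctrl = gp_control(),
                           train_ok = NULL, sd_floor = 0) {
  n <- nrow(X)
  xm <- colMeans(X); xs <- pmax(apply(X, 2, sd), 1e-12)
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y); ys <- max(sd(y), 1e-12)
  yz <- (y - ym) / ys
  nv <- noise_var / ys^2

  pool <- which(train_ok %||% rep(TRUE, n))
  fit_idx <- if (length(pool) > ctrl$fit_cap) {
    withr::with_seed(ctrl$subsample_seed,
                     sort(pool[sample.int(length(pool), ctrl$fit_cap)]))
  } else {
    pool
  }

  optimise_gp <- function(Xf, yf, nvf, starts) {
    m <- length(yf)
    D <- sq_dist(Xf, Xf)
    nll <- function(theta) {
      ell <- exp(theta[1]); sf2 <- exp(2 * theta[2]); sn2 <- exp(2 * theta[3])
      K <- sf2 * exp(-0.5 * D / ell^2)
      diag(K) <- diag(K) + sn2 + nvf + ctrl$jitter
      L <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(L)) return(1e10)
      alpha <- backsolve(L, forwardsolve(t(L), yf))
      sum(log(diag(L))) + 0.5 * sum(yf * alpha) + 0.5 * m * log(2 * pi)
    }
    best <- NULL
    for (s in starts) {
      opt <- tryCatch(
        optim(s, nll, method = "L-BFGS-B",
              lower = c(log(1e-3), log(1e-3), log(1e-5)),
              upper = c(log(1e3), log(1e2), log(1e1)),
              control = list(maxit = 80, factr = 1e9)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
    if (is.null(best)) {
      abort("Gaussian-process hyperparameter optimisation failed",
            class = "giscreen_fit_error")
    }
    best$par
  }

  fit_resid_z <- function(Xf, yf, nvf, theta) {
    ell <- exp(theta[1]); sf2 <- exp(2 * theta[2]); sn2 <- exp(2 * theta[3])
    K <- sf2 * exp(-0.5 * sq_dist(Xf, Xf) / ell^2)
    noise <- sn2 + nvf + ctrl$jitter
    diag(K) <- diag(K) + noise
    L <- chol(K)
    alpha <- backsolve(L, forwardsolve(t(L), yf))
    # leave-in posterior mean is fine for flagging gross outliers
    mu <- drop((K - diag(noise, length(yf))) %*% alpha)
    (yf - mu) / sqrt(sn2 + nvf)
  }

  starts <- list(c(log(0.5), log(1), log(0.3)),
                 c(log(2), log(1), log(0.05)),
                 c(log(0.2), log(0.5), log(0.5)))
  starts <- starts[seq_len(min(ctrl$restarts + 1L, length(starts)))]

  Xf <- Xs[fit_idx, , drop = FALSE]
  yf <- yz[fit_idx]
  nvf <- nv[fit_idx]
  # hyperparameters are fit on a smaller subsample of the conditioning set;
  # the conditioning set itself drives prediction
  opt_of <- function(Xf, yf, nvf) {
    if (length(yf) > ctrl$opt_cap) {
      oi <- withr::with_seed(ctrl$subsample_seed + 1L,
                             sort(sample.int(length(yf), ctrl$opt_cap)))
      list(X = Xf[oi, , drop = FALSE], y = yf[oi], nv = nvf[oi])
    } else {
      list(X = Xf, y = yf, nv = nvf)
    }
  }
  os <- opt_of(Xf, yf, nvf)
  theta <- optimise_gp(os$X, os$y, os$nv, starts)

  # trim strong epistatic outliers from the training set so they do not
  # inflate the fitted noise; refits warm-start from the previous optimum
  for (it in seq_len(ctrl$trim_iters)) {
    z <- fit_resid_z(Xf, yf, nvf, theta)
    keep <- abs(z) <= ctrl$trim_z
    if (all(keep) || sum(keep) < 20L) break
    Xf <- Xf[keep, , drop = FALSE]
    yf <- yf[keep]
    nvf <- nvf[keep]
    os <- opt_of(Xf, yf, nvf)
    theta <- optimise_gp(os$X, os$y, os$nv, list(theta))
  }

  ell <- exp(theta[1]); sf2 <- exp(2 * theta[2]); sn2 <- exp(2 * theta[3])
  K <- sf2 * exp(-0.5 * sq_dist(Xf, Xf) / ell^2)
  diag(K) <- diag(K) + sn2 + nvf + ctrl$jitter
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yf))

  mu <- numeric(n); var <- numeric(n)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / 2000))
  for (b in blocks) {
    Ks <- sf2 * exp(-0.5 * sq_dist(Xf, Xs[b, , drop = FALSE]) / ell^2)
    mu[b] <- drop(crossprod(Ks, alpha))
    V <- forwardsolve(t(L), Ks)
    var[b] <- pmax(sf2 + sn2 + nv[b] - colSums(V^2), 1e-12)
  }
  list(mu = mu * ys + ym, sd = pmax(sqrt(var) * ys, sd_floor),
       hyper = c(lengthscale = ell, signal_var = sf2, extra_noise_var = sn2))
}

sq_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

#' Standardize interaction scores to Z and P
#'
#' Within each condition, `Z = (S - mean(S)) / sd(S)` over all scored pairs
#' and `P = 2 * (1 - pnorm(|Z|))`, the two-sided standard-normal tail. The
#' two-standard-deviation calling threshold |Z| >= 2 therefore corresponds
#' to P <= 0.0455. A robust variant standardizes by median and MAD.
#'
#' @param scores A score tibble with columns `condition` and `S`.
#' @param robust Use median/MAD instead of mean/SD (default `FALSE`).
#' @return `scores` with columns `Z` and `P` added.
#' @export
standardize_scores <- function(scores, robust = FALSE) {
  if (nrow(scores) < 30L) {
    abort("at least 30 scored pairs are required for standardization",
          class = "giscreen_data_error")
  }
  centre <- if (robust) median else mean
  spread <- if (robust) mad else sd
  scores %>%
    group_by(.data$condition) %>%
    mutate(.mu = centre(.data$S), .sigma = spread(.data$S)) %>%
    ungroup() %>%
    { if (any(.$.sigma == 0)) abort("degenerate score distribution",
                                    class = "giscreen_data_error") else . } %>%
    mutate(Z = (.data$S - .data$.mu) / .data$.sigma,
           P = 2 * pnorm(-abs(.data$Z))) %>%
    select(-".mu", -".sigma")
}

#' Call the static interaction network with dual-model agreement
#'
#' A pair enters the significant network only when both scoring models call
#' it non-neutral with the same sign. Non-neutral under a model means the
#' score falls at or outside that model's neutral band for the condition
#' (aggravating at `S <= lower`, alleviating at `S >= upper`), with
#' `|Z| >= z_cut` and `P <= p_cut`; all comparisons are inclusive. Edges
#' retain the Gaussian-process score as their weight, following the
#' convention that downstream analyses use the machine-learning score.
#'
#' @param mult,gp Standardized score tibbles (see [standardize_scores()])
#'   from the two models, covering the same pairs and condition.
#' @param thresholds A [scoring_thresholds()].
#' @return Object of class `gi_static_network`: list with `condition`,
#'   `scores` (all pairs with per-model columns and `class`), `edges` (the
#'   significant subset weighted by the GP score), `thresholds`.
#' @export
call_static_network <- function(mult, gp, thresholds = scoring_thresholds()) {
  cond <- unique(c(mult$condition, gp$condition))
  if (length(cond) != 1L) {
    abort("score tables must share a single condition",
          class = "giscreen_data_error")
  }
  if (!cond %in% names(thresholds$mult)) {
    abort(sprintf("no thresholds for condition '%s'", cond),
          class = "giscreen_config_error")
  }

  joined <- inner_join(
    mult %>% select("donor", "recipient", "n_obs",
                    S_mult = "S", Z_mult = "Z", P_mult = "P"),
    gp %>% select("donor", "recipient",
                  S_gp = "S", Z_gp = "Z", P_gp = "P"),
    by = c("donor", "recipient"))

  cls <- function(S, Z, P, band) {
    case_when(
      S <= band[1] & abs(Z) >= thresholds$z_cut & P <= thresholds$p_cut ~ "aggravating",
      S >= band[2] & abs(Z) >= thresholds$z_cut & P <= thresholds$p_cut ~ "alleviating",
      TRUE ~ "neutral")
  }
  joined <- joined %>%
    mutate(class_mult = cls(.data$S_mult, .data$Z_mult, .data$P_mult,
                            thresholds$mult[[cond]]),
           class_gp = cls(.data$S_gp, .data$Z_gp, .data$P_gp,
                          thresholds$gp[[cond]]),
           class = if (thresholds$require_sign_agreement) {
             if_else(.data$class_mult == .data$class_gp, .data$class_gp, "neutral")
           } else {
             if_else(.data$class_mult != "neutral" & .data$class_gp != "neutral",
                     .data$class_gp, "neutral")
           },
           condition = cond)

  edges <- joined %>%
    filter(.data$class != "neutral") %>%
    transmute(donor = .data$donor, recipient = .data$recipient,
              condition = cond, S = .data$S_gp, Z = .data$Z_gp,
              P = .data$P_gp, n_obs = .data$n_obs, class = .data$class)

  structure(list(condition = cond, scores = joined, edges = edges,
                 thresholds = thresholds),
            class = "gi_static_network")
}

#' @export
print.gi_static_network <- function(x, ...) {
  cat(sprintf("Static genetic-interaction network (%s)\n", x$condition))
  cat(sprintf("  %d scored pairs, %d significant edges (%d aggravating, %d alleviating)\n",
              nrow(x$scores), nrow(x$edges),
              sum(x$edges$class == "aggravating"),
              sum(x$edges$class == "alleviating")))
  invisible(x)
}

#' Tidy the significant edges of a static network
#' @param x A `gi_static_network`.
#' @param ... Unused.
#' @return Tibble of significant edges.
#' @export
tidy.gi_static_network <- function(x, ...) x$edges

#' One-row summary of a static network
#' @param x A `gi_static_network`.
#' @param ... Unused.
#' @export
glance.gi_static_network <- function(x, ...) {
  tibble(condition = x$condition,
         n_pairs = nrow(x$scores),
         n_edges = nrow(x$edges),
         n_aggravating = sum(x$edges$class == "aggravating"),
         n_alleviating = sum(x$edges$class == "alleviating"),
         frac_called = nrow(x$edges) / max(nrow(x$scores), 1L))
}

#' @export
autoplot.gi_static_network <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$S_mult, y = .data$S_gp,
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(aggravating = "#c0392b",
                                            alleviating = "#2471a3",
                                            neutral = "grey70")) +
    ggplot2::labs(x = "multiplicative score", y = "Gaussian-process score",
                  title = sprintf("Static network, %s", object$condition)) +
    ggplot2::theme_minimal()
}
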