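test_that("multiplicative score is zero when observations match expectation", {
  scr <- flat_screen(rep(100, 12))
  scr <- dplyr::bind_rows(lapply(1:4, function(r) {
    x <- scr; x$replicate <- r
    x$plate <- sprintf("p%d", r)
    x
  }))
  fit <- estimate_fitness(scr)
  sc <- score_multiplicative(scr, fit)
  expect_true(all(sc$S == 0))
})

test_that("multiplicative score matches hand arithmetic with an explicit floor", {
  # W_d = 0.8, W_r = 0.9, reference 100 -> E = 72; four replicates of 62
  # with SD floor 2: S = (62 - 72) / (2 / sqrt(4)) = -10
  fit <- manual_fitness(c(dX = 0.8, rY = 0.9), reference_size = 100)
  scr <- tibble::tibble(condition = "RM", donor = "dX", recipient = "rY",
                        replicate = 1:4, plate = "p1", row = 1L, col = 1:4,
                        size = rep(62, 4))
  sc <- score_multiplicative(scr, fit, s_floor = 2, moderation_df = 0)
  expect_equal(sc$expected, 72)
  expect_equal(sc$S, -10)
})

test_that("scores are covariant under global rescaling", {
  cfg <- screen_config(n_donors = 8, n_recipients = 10, n_replicates = 6,
                       seed = 19)
  scr <- normalize_screen(simulate_screen(cfg)$screens$RM)
  fit <- estimate_fitness(scr)
  s1 <- score_multiplicative(scr, fit)
  scr2 <- scr %>% dplyr::mutate(size = size * 2)
  s2 <- score_multiplicative(scr2, estimate_fitness(scr2))
  expect_equal(s1$S, s2$S, tolerance = 1e-9)
})

test_that("pairs below the replicate minimum are skipped", {
  cfg <- screen_config(n_donors = 5, n_recipients = 8, n_replicates = 6,
                       missing_fraction = 0, seed = 23)
  scr <- simulate_screen(cfg)$screens$RM
  scr$size[scr$donor == "d001" & scr$recipient == "r001" &
             scr$replicate > 2] <- NA_real_
  fit <- estimate_fitness(scr)
  expect_message(sc <- score_multiplicative(scr, fit, min_replicates = 4),
                 "skipped")
  expect_false(any(sc$donor == "d001" & sc$recipient == "r001"))
  expect_true(all(sc$n_obs >= 4))
})

test_that("GP scores are null on noise-free multiplicative data", {
  cfg <- screen_config(n_donors = 30, n_recipients = 40, n_replicates = 4,
                       noise_sd = 0, row_effect_sd = 0, col_effect_sd = 0,
                       edge_effect = 0, missing_fraction = 0,
                       planted_fraction_aggravating = 0,
                       planted_fraction_alleviating = 0, seed = 7)
  scr <- simulate_screen(cfg)$screens$RM
  fit <- estimate_fitness(scr)
  # noise-free data leaves no sampling variance to absorb interpolation
  # error, so every pair conditions the posterior directly
  gp <- score_gaussian_process(scr, fit, min_replicates = 2,
                               gp_config = gp_control(fit_cap = 1200))
  expect_gte(mean(abs(gp$S) < 0.5), 0.99)
})

test_that("GP detects planted aggravating pairs at six noise SDs", {
  cfg <- screen_config(n_donors = 40, n_recipients = 50, n_replicates = 8,
                       effect_size = 6, seed = 7)
  sim <- simulate_screen(cfg)
  scr <- normalize_screen(sim$screens$RM)
  fit <- estimate_fitness(scr)
  gp <- score_gaussian_process(scr, fit)
  agg <- sim$truth$planted %>%
    dplyr::filter(condition == "RM", sign == "aggravating")
  hit <- gp %>% dplyr::semi_join(agg, by = c("donor", "recipient"))
  expect_gte(nrow(hit), nrow(agg) * 0.95)  # a few pairs lose replicates
  expect_true(all(hit$S < -2))
})

test_that("degenerate predictors fall back to multiplicative scoring", {
  scr <- dplyr::bind_rows(lapply(1:4, function(r) {
    x <- flat_screen(90 + seq(-5, 6), plate = sprintf("p%d", r))
    x$replicate <- r
    x
  }))
  fit <- estimate_fitness(scr)
  fit$table$W <- 1  # identical fitness everywhere
  expect_warning(gp <- score_gaussian_process(scr, fit, min_replicates = 2),
                 "degenerate predictor")
  mult <- score_multiplicative(scr, fit, min_replicates = 2)
  expect_equal(gp$S, mult$S)
})

test_that("standardization maps scores to normal-tail probabilities", {
  # symmetric design with sample mean 0 and sample sd exactly 1, containing
  # the values -2, 0 and 2: entries +/-2, two zeros, and 16 pairs +/-a with
  # a chosen so that (8 + 2 * 16 * a^2) / 35 = 1
  k <- 16
  a <- sqrt((2 * k - 5) / (2 * k))
  z <- c(-2, 2, 0, 0, rep(c(a, -a), k))
  stopifnot(abs(mean(z)) < 1e-12, abs(sd(z) - 1) < 1e-12)
  scores <- tibble::tibble(condition = "RM", S = 5 + 3 * z)
  out <- standardize_scores(scores)
  expect_equal(out$Z, z, tolerance = 1e-12)
  expect_equal(out$P[3], 1)  # score at the distribution mean
  # |Z| = 2 corresponds to the two-sided normal tail 0.0455
  expect_equal(out$P[2], 2 * (1 - pnorm(2)), tolerance = 1e-12)
  expect_equal(out$P[2], 0.0455, tolerance = 1e-3)

  # adding a constant to all scores leaves Z unchanged
  shifted <- standardize_scores(scores %>% dplyr::mutate(S = S + 42))
  expect_equal(shifted$Z, out$Z, tolerance = 1e-12)
})

test_that("standardization rejects degenerate inputs", {
  expect_error(standardize_scores(tibble::tibble(condition = "RM", S = 1:10)),
               class = "giscreen_data_error")
  expect_error(
    standardize_scores(tibble::tibble(condition = "RM", S = rep(1, 40))),
    "degenerate score distribution")
})

test_that("dual-model agreement rule calls edges at the printed cuts", {
  th <- scoring_thresholds()
  # both models alleviating in MM, above their cuts (1.9 and 3.0)
  mult <- manual_scores("d1", "r1", "MM", S = 3.5, Z = 2.5)
  gp <- manual_scores("d1", "r1", "MM", S = 2.5, Z = 2.5)
  net <- call_static_network(mult, gp, th)
  expect_equal(net$edges$class, "alleviating")
  expect_equal(net$edges$S, 2.5)  # the GP score is the edge weight

  # agreement failure: GP aggravating but multiplicative neutral
  mult2 <- manual_scores("d1", "r1", "RM", S = 0, Z = 0)
  gp2 <- manual_scores("d1", "r1", "RM", S = -1.5, Z = -2.5)
  net2 <- call_static_network(mult2, gp2, th)
  expect_equal(nrow(net2$edges), 0)
  expect_equal(net2$scores$class, "neutral")

  # inclusive boundary: GP S_RM exactly 1.3, multiplicative exactly 1.8
  mult3 <- manual_scores("d1", "r1", "RM", S = 1.8, Z = 2)
  gp3 <- manual_scores("d1", "r1", "RM", S = 1.3, Z = 2)
  net3 <- call_static_network(mult3, gp3, th)
  expect_equal(net3$edges$class, "alleviating")

  # sign disagreement is neutral under the agreement rule
  mult4 <- manual_scores("d1", "r1", "MM", S = 3.5, Z = 2.5)
  gp4 <- manual_scores("d1", "r1", "MM", S = -2.5, Z = -2.5)
  expect_equal(nrow(call_static_network(mult4, gp4, th)$edges), 0)
})

test_that("condition mismatch between model tables is an error", {
  mult <- manual_scores("d1", "r1", "RM", S = 1)
  gp <- manual_scores("d1", "r1", "MM", S = 1)
  expect_error(call_static_network(mult, gp), class = "giscreen_data_error")
})

test_that("the two scoring models agree strongly on planted screens", {
  cfg <- screen_config(n_donors = 30, n_recipients = 40, n_replicates = 8,
                       seed = 29)
  scr <- normalize_screen(simulate_screen(cfg)$screens$RM)
  fit <- estimate_fitness(scr)
  mult <- score_multiplicative(scr, fit)
  gp <- score_gaussian_process(scr, fit)
  j <- dplyr::inner_join(mult, gp, by = c("donor", "recipient"))
  expect_gte(cor(j$S.x, j$S.y), 0.8)
})
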