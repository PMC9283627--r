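# combinatorial oracle for the hypergeometric upper tail: sum the pmf
# written directly in binomial coefficients
hyper_tail_oracle <- function(k, n, M, N) {
  js <- k:min(n, M)
  sum(choose(M, js) * choose(N - M, n - js)) / choose(N, n)
}

test_that("hypergeometric upper tail is exact", {
  expect_equal(hypergeom_upper_tail(0, 3, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(3, 3, 3, 3), 1)  # forced draw
  # 120 equally likely draws of 3 from 10 with 5 successes
  expect_equal(hypergeom_upper_tail(2, 3, 5, 10), 0.5)
  expect_equal(hyper_tail_oracle(2, 3, 5, 10), 0.5)

  expect_error(hypergeom_upper_tail(4, 3, 5, 10),
               class = "giscreen_domain_error")
  expect_error(hypergeom_upper_tail(1, 3, 11, 10),
               class = "giscreen_domain_error")
})

test_that("hypergeometric tail matches the combinatorial oracle for all N <= 12", {
  worst <- 0
  for (N in 1:12) for (M in 0:N) for (n in 0:N) for (k in 0:min(n, M)) {
    worst <- max(worst, abs(hypergeom_upper_tail(k, n, M, N) -
                              hyper_tail_oracle(k, n, M, N)))
  }
  expect_lt(worst, 1e-12)
})

# direct step-up definition: adjusted_i = min over j >= rank(i) of p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), class = "giscreen_domain_error")

  withr::with_seed(41, {
    for (i in 1:50) {
      p <- runif(sample(3:40, 1))
      got <- bh_fdr(p)
      expect_equal(got, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(got <= 1))
    }
  })
})

# small fully annotated network: genes in two processes, significant edges
# planted only between procA and procB
crosstalk_fixture <- function() {
  genes <- tibble::tibble(
    gene_id = c(sprintf("dA%d", 1:3), sprintf("dC%d", 1:3),
                sprintf("rB%d", 1:3), sprintf("rD%d", 1:3)),
    locus_position = 0L, is_orphan = FALSE, regulator_scope = "local",
    is_essential_hypomorph = FALSE,
    major_bioprocesses = c(rep(list("procA"), 3), rep(list("procC"), 3),
                           rep(list("procB"), 3), rep(list("procD"), 3)),
    minor_bioprocess = NA_character_, family = NA_character_)
  pairs <- tidyr::expand_grid(donor = genes$gene_id[1:6],
                              recipient = genes$gene_id[7:12]) %>%
    dplyr::mutate(class = dplyr::if_else(grepl("dA", donor) & grepl("rB", recipient),
                                         "aggravating", "neutral"))
  list(genes = genes, pairs = pairs)
}

test_that("process crosstalk singles out the enriched process pair", {
  fx <- crosstalk_fixture()
  out <- process_crosstalk(fx$pairs, fx$genes)
  top <- out[which.min(out$P), ]
  expect_equal(c(top$process_a, top$process_b), c("procA", "procB"))
  expect_equal(top$k, 9)
  expect_equal(top$n, 9)
  expect_equal(top$M, 9)
  expect_equal(top$N, 36)
  expect_equal(top$P, hyper_tail_oracle(9, 9, 9, 36))

  # with no significant edges every k is 0 and every P is 1
  nul <- process_crosstalk(fx$pairs %>% dplyr::mutate(class = "neutral"),
                           fx$genes)
  expect_true(all(nul$k == 0))
  expect_true(all(nul$P == 1))

  # direction filter: no alleviating edges exist
  alv <- process_crosstalk(fx$pairs, fx$genes, direction = "alleviating")
  expect_true(all(alv$k == 0))

  expect_error(process_crosstalk(fx$pairs, fx$genes[-1, ]),
               class = "giscreen_lookup_error")
})

test_that("the minor-category universe yields the expected pair counts", {
  n_cat <- 53
  cats <- sprintf("cat%02d", seq_len(n_cat))
  genes <- tibble::tibble(
    gene_id = c(sprintf("d%02d", seq_len(n_cat)), sprintf("r%02d", seq_len(n_cat))),
    major_bioprocesses = rep(list("x"), 2 * n_cat),
    minor_bioprocess = rep(cats, 2))
  pairs <- tidyr::expand_grid(donor = genes$gene_id[seq_len(n_cat)],
                              recipient = genes$gene_id[n_cat + seq_len(n_cat)]) %>%
    dplyr::mutate(class = "neutral")
  out <- process_crosstalk(pairs, genes, annotation = "minor")
  expect_equal(nrow(out), n_cat * (n_cat + 1) / 2)  # 1431
  expect_equal(nrow(out), 1431)

  # one more category makes 1485 testable pairs
  genes54 <- genes %>%
    dplyr::bind_rows(tibble::tibble(gene_id = c("d99", "r99"),
                                    major_bioprocesses = list("x", "x"),
                                    minor_bioprocess = "cat99"))
  pairs54 <- tidyr::expand_grid(donor = genes54$gene_id[c(seq_len(n_cat), 107)],
                                recipient = genes54$gene_id[c(n_cat + seq_len(n_cat), 108)]) %>%
    dplyr::mutate(class = "neutral")
  expect_equal(nrow(process_crosstalk(pairs54, genes54, annotation = "minor")),
               54 * 55 / 2)
})

test_that("module crosstalk permutation flags planted inter-module excess", {
  # modules X and Y joined by many significant edges; Z stays disconnected
  genes <- c(sprintf("x%d", 1:6), sprintf("y%d", 1:6), sprintf("z%d", 1:6))
  modules <- tibble::tibble(gene_id = genes,
                            module = rep(c("X", "Y", "Z"), each = 6))
  pairs <- tidyr::expand_grid(donor = genes[1:6], recipient = genes[7:12]) %>%
    dplyr::mutate(class = "aggravating") %>%
    dplyr::bind_rows(tidyr::expand_grid(donor = genes[1:12],
                                        recipient = genes[13:18]) %>%
                       dplyr::mutate(class = "neutral"))
  out <- module_crosstalk_permutation(pairs, modules, n_perm = 200, seed = 2)
  xy <- out[out$module_a == "X" & out$module_b == "Y", ]
  expect_true(xy$significant)
  expect_equal(xy$observed_count, 36)
  expect_gte(xy$Z, 1.65)
  expect_equal(unique(out$n_perm), 200)

  expect_error(module_crosstalk_permutation(pairs, modules, n_perm = 0),
               class = "giscreen_config_error")
})

test_that("degenerate permutation spread yields a flagged missing Z", {
  # complete graph: every gene pair is a significant edge, so the
  # inter-module count equals the product of module sizes under any
  # relabelling and the permutation spread is exactly zero
  genes <- c("a1", "a2", "b1", "b2")
  modules <- tibble::tibble(gene_id = genes, module = c("A", "A", "B", "B"))
  pairs <- t(combn(genes, 2)) %>%
    `colnames<-`(c("donor", "recipient")) %>%
    tibble::as_tibble() %>%
    dplyr::mutate(class = "aggravating")
  out <- suppressWarnings(
    module_crosstalk_permutation(pairs, modules, n_perm = 50, seed = 1))
  ab <- out[out$module_a == "A" & out$module_b == "B", ]
  expect_equal(ab$observed_count, 4)
  expect_true(ab$degenerate)
  expect_true(is.na(ab$Z))
  expect_false(ab$significant)
})

test_that("profile correlations behave like Pearson correlation", {
  partners <- sprintf("p%02d", 1:8)
  prof <- function(gene, values) {
    tibble::tibble(donor = gene, recipient = partners, S = values)
  }
  v <- c(1.2, -0.5, 0.8, 2.0, -1.4, 0.3, -0.9, 1.1)
  scores <- dplyr::bind_rows(prof("gA", v), prof("gB", v), prof("gC", -v),
                             prof("gD", c(1, 0, 1, 0, 1, 0, 1, 0)),
                             prof("gE", c(1, 1, 0, 0, 1, 1, 0, 0)))
  expect_equal(profile_correlation(scores, "gA", "gB", min_shared = 5)$r, 1)
  expect_equal(profile_correlation(scores, "gA", "gC", min_shared = 5)$r, -1)
  expect_equal(profile_correlation(scores, "gD", "gE", min_shared = 5)$r, 0)

  # symmetry is exact
  expect_equal(profile_correlation(scores, "gA", "gD", min_shared = 5)$r,
               profile_correlation(scores, "gD", "gA", min_shared = 5)$r)

  # too few shared partners: suppressed with a message
  expect_message(
    none <- profile_correlation(scores, "gA", "gB", min_shared = 30),
    "suppressed")
  expect_equal(nrow(none), 0)

  expect_error(profile_correlation(scores, "gA", "nope", min_shared = 2),
               class = "giscreen_lookup_error")
})

test_that("autocorrelation classifies the 0.25 boundary as high", {
  partners <- sprintf("p%02d", 1:40)
  withr::with_seed(15, {
    x <- rnorm(40)
    e <- rnorm(40)
  })
  zx <- (x - mean(x)) / sd(x)
  # Gram-Schmidt: component of e orthogonal to zx, standardized
  ez <- e - zx * sum(e * zx) / sum(zx * zx)
  ez <- (ez - mean(ez)) / sd(ez)
  r0 <- 0.25
  y <- r0 * zx + sqrt(1 - r0^2) * ez
  rm_scores <- tibble::tibble(donor = "g", recipient = partners, S = zx)
  mm_scores <- tibble::tibble(donor = "g", recipient = partners, S = y)
  out <- autocorrelation(rm_scores, mm_scores,
                         config = analysis_config(min_shared = 30))
  out <- out[out$gene == "g", ]
  expect_equal(out$r, 0.25, tolerance = 1e-9)
  # the boundary is assigned to the high class: a cut placed exactly at the
  # observed correlation still classifies the gene as high
  boundary <- autocorrelation(rm_scores, mm_scores,
                              config = analysis_config(autocorr_cut = out$r,
                                                       min_shared = 30))
  expect_equal(boundary$autocorr_class[boundary$gene == "g"], "high")

  ident <- autocorrelation(rm_scores, rm_scores, gene = "g",
                           config = analysis_config(min_shared = 30))
  expect_equal(ident$r, 1)
  expect_equal(ident$autocorr_class, "high")
})

test_that("independent profiles rarely show high autocorrelation", {
  n_genes <- 200
  partners <- sprintf("p%03d", 1:300)
  withr::with_seed(3, {
    rm_scores <- tidyr::expand_grid(donor = sprintf("g%03d", 1:n_genes),
                                    recipient = partners) %>%
      dplyr::mutate(S = rnorm(dplyr::n()))
    mm_scores <- rm_scores %>% dplyr::mutate(S = rnorm(dplyr::n()))
  })
  out <- autocorrelation(rm_scores, mm_scores)
  # every gene and every partner carries a profile in both conditions
  expect_equal(nrow(out), n_genes + length(partners))
  expect_gte(mean(abs(out$r) < 0.2), 0.95)
})

test_that("degree statistics report hubs at the inclusive threshold", {
  hub_gene <- "hub"
  partners <- sprintf("p%03d", 1:100)
  genes <- tibble::tibble(gene_id = c(hub_gene, "mid", partners),
                          regulator_scope = c("global", rep("local", 101)),
                          is_orphan = c(FALSE, TRUE, rep(FALSE, 100)))
  pairs <- dplyr::bind_rows(
    tibble::tibble(donor = hub_gene, recipient = partners,
                   class = rep(c("aggravating", "alleviating"), 50)),
    tibble::tibble(donor = "mid", recipient = partners[1:99],
                   class = "aggravating"))
  out <- degree_stats(pairs, genes)
  pg <- out$per_gene
  expect_true(pg$hub[pg$gene == hub_gene])        # exactly 100 edges
  expect_false(pg$hub[pg$gene == "mid"])          # 99 edges is not a hub
  expect_equal(pg$degree[pg$gene == hub_gene], 100)
  expect_equal(pg$ratio[pg$gene == hub_gene], 1)
  expect_true(is.na(pg$ratio[pg$gene == "mid"]))  # no alleviating edges

  empty <- degree_stats(pairs %>% dplyr::mutate(class = "neutral"), genes)
  expect_equal(nrow(empty$per_gene), 0)
})
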