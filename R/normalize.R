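#' Normalize colony sizes within one condition
#'
#' Two-step normalization of a colony screen for experimental variation.
#' First, if `config$correct_row_col` is set, one round of median polish on
#' log colony sizes removes per-plate row and column trends (pinning-gradient
#' and edge artifacts); fitted row/column effects are subtracted on the log
#' scale and sizes re-exponentiated. Second, every plate is rescaled so its
#' median non-missing colony size equals the condition-wide median of plate
#' medians. Missing entries are preserved; zero sizes pass through the
#' row/column correction unchanged.
#'
#' The operation is idempotent: renormalizing a normalized screen returns it
#' unchanged (to numerical tolerance).
#'
#' @param screen Colony tibble (`donor`, `recipient`, `replicate`, `plate`,
#'   `row`, `col`, `size`; an optional `condition` column partitions the
#'   reference statistic).
#' @param config A [normalization_config()].
#' @return The screen tibble with normalized `size`.
#' @export
normalize_screen <- function(screen, config = normalization_config()) {
  stopifnot(all(c("plate", "row", "col", "size") %in% names(screen)))
  by_cond <- if ("condition" %in% names(screen)) "condition" else character(0)

  out <- screen
  if (config$correct_row_col) {
    out <- out %>%
      group_by(.data$plate) %>%
      mutate(size = polish_plate(.data$size, .data$row, .data$col)) %>%
      ungroup()
  }

  scale_tbl <- out %>%
    group_by(across(all_of(c(by_cond, "plate")))) %>%
    summarise(plate_median = median(.data$size, na.rm = TRUE), .groups = "drop_last") %>%
    mutate(reference = median(.data$plate_median, na.rm = TRUE)) %>%
    ungroup() %>%
    mutate(scale = .data$reference / .data$plate_median)

  if (any(!is.finite(scale_tbl$scale))) {
    bad <- scale_tbl$plate[!is.finite(scale_tbl$scale)]
    warn(sprintf("%d plate(s) with no usable colonies left unscaled (e.g. %s)",
                 length(bad), bad[1]))
    scale_tbl$scale[!is.finite(scale_tbl$scale)] <- 1
  }

  out %>%
    left_join(scale_tbl %>% select(all_of(c(by_cond, "plate", "scale"))),
              by = c(by_cond, "plate")) %>%
    mutate(size = .data$size * .data$scale) %>%
    select(-"scale")
}

# One-plate median polish on the log scale; returns corrected sizes.
# Only row and column effects are removed (overall + residual kept), so the
# plate's location is untouched up to polish bookkeeping. Zeros and missing
# values are left as-is. Iterates to machine-level convergence so that
# renormalizing a normalized screen is a no-op.
polish_plate <- function(size, row, col, eps = 1e-13, maxiter = 500L) {
  ok <- !is.na(size) & size > 0
  # too sparse a plate cannot support row/column estimates
  if (sum(ok) < 9L || length(unique(row[ok])) < 3L ||
      length(unique(col[ok])) < 3L) {
    return(size)
  }
  ri <- match(row, sort(unique(row)))
  ci <- match(col, sort(unique(col)))
  m <- matrix(NA_real_, max(ri), max(ci))
  m[cbind(ri[ok], ci[ok])] <- log(size[ok])

  eff <- polish_effects(m, eps, maxiter)
  # centre the effects so the overall level stays with the plate
  reff <- eff$row - median(eff$row)
  ceff <- eff$col - median(eff$col)
  # an already-polished plate (effects below 1e-6 log units, i.e. well under
  # any measurable artifact) is left untouched, making the step idempotent
  if (max(abs(reff)) < 1e-6 && max(abs(ceff)) < 1e-6) return(size)
  out <- size
  out[ok] <- exp(log(size[ok]) - reff[ri[ok]] - ceff[ci[ok]])
  # a sparse incidence pattern can make row + column effects unidentifiable
  if (any(!is.finite(out[ok]))) return(size)
  out
}

#' Remove genomically linked gene pairs
#'
#' Drops pairs whose circular-chromosome distance is within the linkage
#' window (inclusive), where recombination frequencies are too low for
#' reliable double-mutant construction. Distance between loci `p` and `q` on
#' a circular chromosome of length `L` is `min(|p - q|, L - |p - q|)`.
#'
#' @param pairs Tibble with columns `donor` and `recipient` (extra columns
#'   are kept; row order is preserved).
#' @param genes Annotation tibble with `gene_id` and `locus_position`.
#' @param window Linkage window in base pairs (default 30,000).
#' @param genome_length Circular chromosome length in base pairs.
#' @return `pairs` with linked rows removed.
#' @export
filter_linked_pairs <- function(pairs, genes, window = 30000,
                                genome_length = 4600000) {
  pos <- setNames(genes$locus_position, genes$gene_id)
  missing <- setdiff(unique(c(pairs$donor, pairs$recipient)), names(pos))
  if (length(missing) > 0) {
    abort(sprintf("no locus for gene id(s): %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "giscreen_lookup_error")
  }
  d <- abs(pos[pairs$donor] - pos[pairs$recipient])
  circ <- pmin(d, genome_length - d)
  pairs[circ > window, , drop = FALSE]
}

#' Estimate single-mutant relative fitness from a normalized screen
#'
#' The marginal fitness of a donor is the median of its colony sizes across
#' all recipients and replicates divided by the condition-wide median colony
#' size (the reference); recipient fitness is defined analogously across
#' donors. Medians ignore missing values. Genes observed in fewer than
#' `min_replicates` non-missing colonies are flagged `excluded` and are
#' skipped by the scoring functions.
#'
#' @param screen Normalized colony tibble for one condition.
#' @param min_replicates Minimum non-missing observations per gene.
#' @return Object of class `gi_fitness`: list with `table` (columns `gene_id`,
#'   `role`, `W`, `n_obs`, `excluded`) and `reference_size`.
#' @export
estimate_fitness <- function(screen, min_replicates = 4L) {
  reference <- median(screen$size, na.rm = TRUE)
  if (!is.finite(reference) || reference <= 0) {
    abort("screen has no usable colony sizes", class = "giscreen_data_error")
  }
  marg <- function(role) {
    screen %>%
      group_by(gene_id = .data[[role]]) %>%
      summarise(W = median(.data$size, na.rm = TRUE) / reference,
                n_obs = sum(!is.na(.data$size)), .groups = "drop") %>%
      mutate(role = role,
             excluded = .data$n_obs < min_replicates | !is.finite(.data$W) |
               .data$W <= 0)
  }
  tab <- bind_rows(marg("donor"), marg("recipient")) %>%
    select("gene_id", "role", "W", "n_obs", "excluded")
  structure(list(table = tab, reference_size = reference),
            class = "gi_fitness")
}

#' @export
print.gi_fitness <- function(x, ...) {
  cat(sprintf("Single-mutant fitness table: %d genes, reference size %.3g\n",
              nrow(x$table), x$reference_size))
  if (any(x$table$excluded)) {
    cat(sprintf("  %d gene(s) excluded (< min replicates or degenerate)\n",
                sum(x$table$excluded)))
  }
  invisible(x)
}

#' @export
#' @rdname estimate_fitness
#' @param x A `gi_fitness` object.
#' @param ... Unused.
tidy.gi_fitness <- function(x, ...) x$table

#' @export
autoplot.gi_fitness <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$W, fill = .data$role)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "single-mutant relative fitness W", y = "genes") +
    ggplot2::theme_minimal()
}
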