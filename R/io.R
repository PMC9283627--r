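#' Write a table as headered TSV
#'
#' All package outputs share one plain-text format: UTF-8 TSV with '.'
#' decimal separator, 'NA' for missing values, and '#'-prefixed header
#' lines carrying the package version, the seed and a configuration hash.
#' Files ending in `.gz` are compressed.
#'
#' @param x A data frame. List-columns are collapsed with ';'.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @param config Optional configuration object; a hash of it is recorded.
#' @return `path`, invisibly.
#' @export
write_gi_tsv <- function(x, path, seed = NULL, config = NULL) {
  x <- x %>%
    mutate(across(tidyselect::where(is.list),
                  ~ purrr::map_chr(.x, paste, collapse = ";")))
  header <- c(
    sprintf("# giscreen %s", as.character(packageVersion("giscreen"))),
    if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed)),
    if (!is.null(config)) sprintf("# config_hash=%s", rlang::hash(config)))
  readr::write_lines(c(header, readr::format_tsv(x)), path)
  invisible(path)
}

#' @rdname write_gi_tsv
#' @param screen A colony screen tibble.
#' @export
write_screen_tsv <- function(screen, path, seed = NULL, config = NULL) {
  write_gi_tsv(screen, path, seed = seed, config = config)
}

#' Read a headered TSV written by the package
#'
#' @param path Input path (optionally gzipped).
#' @return A tibble; '#' header lines are skipped.
#' @export
read_gi_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname read_gi_tsv
#' @export
read_screen_tsv <- function(path) {
  out <- read_gi_tsv(path)
  needed <- c("donor", "recipient", "replicate", "plate", "row", "col", "size")
  missing <- setdiff(needed, names(out))
  if (length(missing) > 0) {
    abort(sprintf("screen file lacks column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "giscreen_schema_error")
  }
  out
}

#' Read a phylogenetic-profile table
#'
#' @param path TSV with a `gene_id` column and one 0/1 column per phylum.
#' @return A tibble.
#' @export
read_phylo_profiles <- function(path) {
  out <- read_gi_tsv(path)
  if (!"gene_id" %in% names(out)) {
    abort("phylogenetic profile table needs a 'gene_id' column",
          class = "giscreen_schema_error")
  }
  panel <- setdiff(names(out), "gene_id")
  vals <- unlist(out[, panel])
  if (!all(vals %in% c(0L, 1L))) {
    abort("profile entries must be 0 or 1", class = "giscreen_schema_error")
  }
  out
}

#' Read a typed edge list with schema validation
#'
#' Reads a TSV edge list (for example a deposited interaction table) and
#' validates it against a schema of required columns and types. Header
#' matching is case-insensitive and order-free. Rows whose numeric fields
#' fail to parse are dropped with a warning that reports their line
#' numbers; the count of rejected rows is attached as attribute
#' `n_rejected`.
#'
#' @param path Input path.
#' @param schema Named character vector mapping required column names to
#'   types: `"c"` (character), `"d"` (double), `"i"` (integer).
#' @return Tibble with the schema's columns (in schema order) plus any
#'   extra file columns.
#' @export
read_edge_list <- function(path,
                           schema = c(donor = "c", recipient = "c", S = "d")) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "giscreen_io_error")
  }
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  lower <- tolower(names(raw))
  idx <- match(tolower(names(schema)), lower)
  if (anyNA(idx)) {
    abort(sprintf("missing required column(s): %s",
                  paste(names(schema)[is.na(idx)], collapse = ", ")),
          class = "giscreen_schema_error")
  }
  names(raw)[idx] <- names(schema)

  bad <- rep(FALSE, nrow(raw))
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("d", "i")) {
      parsed <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- bad | (is.na(parsed) & !is.na(raw[[col]]) &
                      toupper(raw[[col]]) != "NA")
      raw[[col]] <- if (type == "i") as.integer(round(parsed)) else parsed
    }
  }
  if (any(bad)) {
    warn(sprintf("read_edge_list: rejected %d malformed row(s) (data rows: %s)",
                 sum(bad), paste(head(which(bad), 10), collapse = ", ")))
  }
  out <- raw[!bad, c(names(schema), setdiff(names(raw), names(schema)))]
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Read a deposited differential-network table
#'
#' Parses a differential edge list into the package's differential-record
#' schema, accepting common column aliases for the static and differential
#' scores.
#'
#' @param path Input path.
#' @return Tibble with `donor`, `recipient`, `S_RM`, `S_MM`, `S_DF` and,
#'   when present, `P_DF`.
#' @export
read_differential_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  nm <- tolower(names(raw))
  alias <- function(cands) {
    hit <- match(cands, nm)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  cols <- c(donor = alias(c("donor", "query", "gene_a", "gene1")),
            recipient = alias(c("recipient", "array", "gene_b", "gene2")),
            S_RM = alias(c("s_rm", "srm", "score_rm")),
            S_MM = alias(c("s_mm", "smm", "score_mm")),
            S_DF = alias(c("s_df", "sdf", "score_df", "diff_score")))
  if (anyNA(cols)) {
    abort(sprintf("differential table lacks recognizable column(s): %s",
                  paste(names(cols)[is.na(cols)], collapse = ", ")),
          class = "giscreen_schema_error")
  }
  out <- raw[, cols]
  names(out) <- names(cols)
  p_idx <- alias(c("p_df", "pdf", "p", "p_value", "pvalue"))
  if (!is.na(p_idx)) out$P_DF <- raw[[p_idx]]
  out %>% mutate(incomplete = is.na(.data$S_RM) | is.na(.data$S_MM))
}

#' Recount a differential table at the published cut-offs
#'
#' Applies the differential calling rule and the gain/loss magnitude filter
#' to a differential-record table and returns the headline counts:
#' aggravating and alleviating differential interactions, pairs passing the
#' |S_DF| magnitude cut, and their gain/loss split (by the sign of the
#' shift when static calls are not supplied).
#'
#' @param records Differential records (e.g. from
#'   [read_differential_table()]), with `P_DF` if available; when absent,
#'   only the score cuts are applied.
#' @param thresholds A [differential_thresholds()].
#' @return One-row tibble of counts: `n_aggravating`, `n_alleviating`,
#'   `n_magnitude`, `n_gain`, `n_loss`.
#' @export
recount_differential <- function(records,
                                 thresholds = differential_thresholds()) {
  has_p <- "P_DF" %in% names(records) && !all(is.na(records$P_DF))
  p_ok <- if (has_p) records$P_DF <= thresholds$p_cut else TRUE
  s <- records$S_DF
  agg <- !is.na(s) & s <= thresholds$lower_diff_cut & p_ok
  all_ <- !is.na(s) & s >= thresholds$upper_diff_cut & p_ok
  magn <- !is.na(s) & abs(s) >= thresholds$gainloss_magnitude & p_ok
  gain <- magn & !is.na(records$S_MM) & !is.na(records$S_RM) &
    abs(records$S_MM) > abs(records$S_RM)
  tibble(n_aggravating = sum(agg),
         n_alleviating = sum(all_),
         n_magnitude = sum(magn),
         n_gain = sum(gain),
         n_loss = sum(magn) - sum(gain))
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the output/seed settings used
#' by [run_pipeline()].
#'
#' @param screen A [screen_config()].
#' @param normalization A [normalization_config()].
#' @param static_thresholds A [scoring_thresholds()].
#' @param diff_thresholds A [differential_thresholds()].
#' @param analysis An [analysis_config()].
#' @param gp A [gp_control()].
#' @param n_null_splits Split-half resamples for the differential null.
#' @param n_perm Permutations for the module/conservation tests.
#' @param n_paralog_pairs Planted paralog pairs in the synthetic annexes.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(screen = screen_config(),
                            normalization = normalization_config(),
                            static_thresholds = scoring_thresholds(),
                            diff_thresholds = differential_thresholds(),
                            analysis = analysis_config(),
                            gp = gp_control(),
                            n_null_splits = 10L,
                            n_perm = 200L,
                            n_paralog_pairs = 30L) {
  structure(list(screen = screen, normalization = normalization,
                 static_thresholds = static_thresholds,
                 diff_thresholds = diff_thresholds,
                 analysis = analysis, gp = gp,
                 n_null_splits = as.integer(n_null_splits),
                 n_perm = as.integer(n_perm),
                 n_paralog_pairs = as.integer(n_paralog_pairs)),
            class = "pipeline_config")
}

#' Run the full screening pipeline end to end
#'
#' Simulates a two-condition screen, normalizes it, removes linked pairs,
#' scores both models, calls the static networks, builds the differential
#' network with its empirical null, classifies gain/loss, and runs the
#' downstream statistics (process crosstalk, module permutation test,
#' autocorrelation, degree/hubs, co-conservation, paralog bias). Every
#' output file carries a header with the package version, seed, and a
#' configuration hash; the returned manifest lists files with MD5
#' checksums, so identical configurations reproduce identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory `results` and the
#'   `manifest` tibble (`file`, `md5`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("gi_run_")) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (file.access(out_dir, 2) != 0) {
    abort(sprintf("output directory is not writable: %s", out_dir),
          class = "giscreen_io_error")
  }
  seed <- config$screen$seed
  emit <- function(x, name) {
    write_gi_tsv(x, file.path(out_dir, name), seed = seed, config = config)
  }

  sim <- simulate_screen(config$screen)
  genes <- simulate_annotations(config$screen)
  emit(sim$truth$planted, "truth_planted.tsv")
  emit(genes, "gene_annotations.tsv")

  linked_ok <- function(scores) {
    filter_linked_pairs(scores, genes,
                        window = config$normalization$linkage_window,
                        genome_length = config$screen$genome_length)
  }

  nets <- list(); norm <- list()
  for (cond in c("RM", "MM")) {
    scr <- normalize_screen(sim$screens[[cond]], config$normalization)
    norm[[cond]] <- scr
    fit <- estimate_fitness(scr, config$normalization$min_replicates)
    mult <- score_multiplicative(scr, fit, config$normalization$min_replicates) %>%
      linked_ok() %>% standardize_scores()
    gp <- score_gaussian_process(scr, fit, config$normalization$min_replicates,
                                 config$gp) %>%
      linked_ok() %>% standardize_scores()
    nets[[cond]] <- call_static_network(mult, gp, config$static_thresholds)
    emit(nets[[cond]]$scores, sprintf("static_scores_%s.tsv", cond))
    emit(nets[[cond]]$edges, sprintf("static_edges_%s.tsv", cond))
  }

  diff <- compute_differential(nets$RM, nets$MM)
  null <- difference_null(norm$RM, norm$MM, n_splits = config$n_null_splits,
                          seed = derive_seed(seed, "pipeline_null"))
  diff_net <- diff %>%
    assign_differential_p(null) %>%
    call_differential(config$diff_thresholds)
  diff_net$records <- classify_gain_loss(diff_net, nets$RM, nets$MM,
                                         config$diff_thresholds)
  emit(diff_net$records, "differential_network.tsv")

  crosstalk <- process_crosstalk(nets$RM, genes, config = config$analysis)
  emit(crosstalk, "process_crosstalk_RM.tsv")

  modules <- genes %>% select(gene_id = "gene_id", module = "minor_bioprocess")
  modperm <- module_crosstalk_permutation(diff_net, modules,
                                          n_perm = config$n_perm,
                                          seed = derive_seed(seed, "modperm"))
  emit(modperm, "module_crosstalk.tsv")

  gp_scores <- function(net) net$scores %>%
    select("donor", "recipient", S = "S_gp")
  autoc <- autocorrelation(gp_scores(nets$RM), gp_scores(nets$MM),
                           config = config$analysis)
  emit(autoc, "autocorrelation.tsv")

  degs <- degree_stats(diff_net, genes, config$analysis)
  emit(degs$per_gene, "degree_stats.tsv")

  profiles <- simulate_phylo_profiles(genes, seed = derive_seed(seed, "phylo"))
  consv <- conservation_enrichment(nets$RM, profiles, genes,
                                   n_perm = config$n_perm,
                                   seed = derive_seed(seed, "consperm"))
  emit(consv, "conservation_enrichment.tsv")

  hits <- simulate_alignment_hits(genes, config$n_paralog_pairs,
                                  seed = derive_seed(seed, "hits"))
  paralogs <- paralog_filter(hits)
  bias <- paralog_gi_bias(nets$MM, paralogs, n_perm = config$n_perm,
                          seed = derive_seed(seed, "bias"))
  emit(paralogs, "paralog_pairs.tsv")
  emit(bias, "paralog_bias.tsv")

  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  emit_manifest <- file.path(out_dir, "manifest.tsv")
  readr::write_lines(readr::format_tsv(manifest), emit_manifest)

  invisible(list(results = list(sim = sim, genes = genes, static = nets,
                                differential = diff_net,
                                crosstalk = crosstalk,
                                module_permutation = modperm,
                                autocorrelation = autoc,
                                degree = degs,
                                conservation = consv,
                                paralog_bias = bias),
                 manifest = manifest))
}
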