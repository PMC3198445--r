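#' Run a full validation campaign
#'
#' End-to-end orchestration: builds interpolated profiles from raw
#' recordings, enumerates the transcription-degradation family (from the
#' target table and TF configuration) and the translation-inhibition
#' families (from the per-protein candidate lists), fits every
#' architecture, and aggregates network validations into per-pair
#' verdicts and summary tables. Deterministic for fixed inputs and
#' configuration.
#'
#' @param recordings Raw recording data frame (or a prebuilt
#'   `profile_set`).
#' @param target_table miRNA target prediction table.
#' @param tf_config TF configuration for the Transcr.Degr. genes (may be
#'   empty).
#' @param ti_spec Data frame (gene, protein, max_combo) for the
#'   Transl.Inhib. families (may be `NULL`).
#' @param config Campaign configuration.
#' @return List with `profiles`, `architectures`, `fits`, `fit_table`,
#'   `verdicts` and `summary`.
#' @export
run_campaign <- function(recordings, target_table, tf_config = list(),
                         ti_spec = NULL, config = campaign_config()) {
  profiles <- if (inherits(recordings, "profile_set")) recordings
              else build_profiles(recordings)
  target_table <- validate_target_table(target_table)

  archs <- list()
  if (length(tf_config) > 0L) {
    pairs <- filter_target_pairs(unique(target_table$mirna_id),
                                 names(tf_config), target_table)
    archs <- c(archs, build_transcr_degr_family(pairs, tf_config))
  }
  if (!is.null(ti_spec) && nrow(ti_spec) > 0L) {
    for (i in seq_len(nrow(ti_spec))) {
      cands <- target_table$mirna_id[target_table$gene_id == ti_spec$gene[i]]
      mc <- ti_spec$max_combo[i] %||% config$max_combo
      archs <- c(archs, build_transl_inhib_family(
        ti_spec$gene[i], ti_spec$protein[i], cands, max_combo = mc))
    }
  }

  fits <- fit_campaign(archs, profiles, config)
  list(profiles = profiles, architectures = archs, fits = fits,
       fit_table = if (length(fits)) fit_results_table(fits) else
         data.frame(),
       verdicts = validate_pairs(fits, threshold = config$threshold),
       summary = summarize_campaign(fits, threshold = config$threshold))
}

#' Simulate a campaign to disk
#'
#' Writes the simulated recordings, target table, TF configuration,
#' Transl.Inhib. specification and ground truth of a synthetic campaign
#' into a directory, in the same delimited-text formats the fitting
#' command reads.
#'
#' @param spec A [sim_spec()].
#' @param out_dir Output directory (created if missing).
#' @return Invisible named vector of written paths.
#' @export
cmd_simulate <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_downstream(spec)
  paths <- c(
    recordings = file.path(out_dir, "recordings.csv"),
    target_table = file.path(out_dir, "target_table.csv"),
    tf_config = file.path(out_dir, "tf_config.yaml"),
    ti_spec = file.path(out_dir, "ti_spec.csv"),
    truth = file.path(out_dir, "truth.csv"))
  write_expression_table(sim$recordings, paths[["recordings"]])
  if (!is.null(sim$target_table)) {
    write_target_table(sim$target_table, paths[["target_table"]])
  }
  if (length(spec$tf_config) > 0L) {
    write_tf_config(spec$tf_config, paths[["tf_config"]])
  }
  if (!is.null(spec$ti_spec)) {
    utils::write.table(spec$ti_spec, paths[["ti_spec"]], sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  utils::write.table(sim$truth$values, paths[["truth"]], sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Fit a campaign from files on disk
#'
#' Reads the recordings, target table, TF configuration and
#' Transl.Inhib. specification from a directory (as written by
#' [cmd_simulate()]), runs the campaign and writes the fit table, the
#' per-pair verdicts and the summary tables.
#'
#' @param data_dir Directory with `recordings.csv`, `target_table.csv`
#'   and optionally `tf_config.yaml` / `ti_spec.csv`.
#' @param out_dir Output directory.
#' @param config Campaign configuration.
#' @return The [run_campaign()] result, invisibly.
#' @export
cmd_fit <- function(data_dir, out_dir, config = campaign_config()) {
  recordings <- read_expression_table(file.path(data_dir, "recordings.csv"))
  target_table <- read_target_table(file.path(data_dir, "target_table.csv"))
  tf_path <- file.path(data_dir, "tf_config.yaml")
  tf_config <- if (file.exists(tf_path)) read_tf_config(tf_path) else list()
  ti_path <- file.path(data_dir, "ti_spec.csv")
  ti_spec <- if (file.exists(ti_path)) {
    utils::read.table(ti_path, header = TRUE, sep = ",",
                      stringsAsFactors = FALSE)
  } else NULL

  res <- run_campaign(recordings, target_table, tf_config, ti_spec, config)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$fit_table, file.path(out_dir, "fits.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(res$verdicts, file.path(out_dir, "verdicts.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(res$summary$counts, file.path(out_dir, "summary.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(res$summary$validated_pairs,
                     file.path(out_dir, "validated_pairs.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(res)
}

#' Summarize an existing fit table
#'
#' Rebuilds the per-gene summary and validated-pair list from a fits
#' table written by [cmd_fit()], without refitting.
#'
#' @param fits_path Path to `fits.csv`.
#' @param threshold Validation threshold in percent.
#' @return List with `counts` and `validated_pairs` data frames.
#' @export
cmd_report <- function(fits_path, threshold = 10) {
  ft <- utils::read.table(fits_path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(ft))) {
    for (m in strsplit(ft$mirnas[i], ";", fixed = TRUE)[[1L]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, gene_id = ft$gene[i], kind = ft$kind[i],
        objective = ft$objective[i],
        validated = ft$objective[i] < threshold, stringsAsFactors = FALSE)
    }
  }
  pr <- do.call(rbind, rows)
  counts <- do.call(rbind, lapply(split(pr, paste(pr$gene_id, pr$kind)),
    function(s) data.frame(
      gene_id = s$gene_id[1L], kind = s$kind[1L],
      n_targeting = length(unique(s$mirna_id)),
      n_validated = length(unique(s$mirna_id[s$validated])),
      stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  agg <- stats::aggregate(validated ~ mirna_id + gene_id, data = pr, FUN = any)
  validated_pairs <- agg[agg$validated, , drop = FALSE]
  validated_pairs <- validated_pairs[order(validated_pairs$gene_id,
                                           validated_pairs$mirna_id), ]
  rownames(validated_pairs) <- NULL
  list(counts = counts, validated_pairs = validated_pairs)
}
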