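#' Smoothed relative error of prediction at one time point
#'
#' The plain relative error `|pred - obs| / obs` becomes meaninglessly
#' large when the observation approaches zero; the smoothed form floors
#' the denominator at the profile mean: `|pred - obs| / max(obs, mean_obs)`.
#'
#' @param pred Predicted value(s), >= 0.
#' @param obs Observed value(s), >= 0.
#' @param mean_obs Mean of the observed profile over the grid (> 0).
#' @return Nonnegative smoothed relative error(s).
#' @export
#' @examples
#' smoothed_relative_error(0.5, 0, 1)  # 0.5, not Inf
smoothed_relative_error <- function(pred, obs, mean_obs) {
  if (any(mean_obs <= 0)) {
    stop("degenerate-profile error: the observed profile mean must be > 0")
  }
  abs(pred - obs) / pmax(obs, mean_obs)
}

#' Global error of prediction between two profiles
#'
#' Aggregates the per-point smoothed relative errors over the 19 grid
#' points into a percentage (arithmetic mean by default, root mean square
#' optionally). Invariant under joint positive rescaling of both profiles.
#'
#' @param pred Predicted profile on the common grid.
#' @param obs Observed profile on the same grid.
#' @param aggregation `"mean"` or `"rms"`.
#' @return Global error of prediction in percent.
#' @export
#' @examples
#' errpred_global(1.1 * rep(2, 19), rep(2, 19))  # 10
errpred_global <- function(pred, obs, aggregation = c("mean", "rms")) {
  aggregation <- match.arg(aggregation)
  if (length(pred) != length(obs)) {
    stop("alignment error: predicted and observed profiles differ in length")
  }
  e <- smoothed_relative_error(pred, obs, mean(obs))
  100 * if (aggregation == "mean") mean(e) else sqrt(mean(e^2))
}

#' Validate one fitted network against the error threshold
#'
#' A network is validated when the global error of prediction is strictly
#' below the threshold in every scored condition (a single condition
#' suffices when the design records only one, e.g. the knocked-out
#' protein's own profile).
#'
#' @param fit A `fit_result`.
#' @param threshold Threshold in percent (default 10).
#' @return Logical.
#' @export
validate_network <- function(fit, threshold = 10) {
  all(fit$errpred < threshold)
}

#' Rank validated networks by reliability
#'
#' Ascending worst-condition error of prediction; ties broken by parameter
#' parsimony (fewer fitted parameters first), then by architecture id.
#'
#' @param fits List of `fit_result` objects.
#' @return The list reordered.
#' @export
rank_networks <- function(fits) {
  if (length(fits) == 0L) return(fits)
  obj <- vapply(fits, `[[`, numeric(1L), "objective")
  np <- vapply(fits, `[[`, integer(1L), "n_params")
  ids <- vapply(fits, `[[`, character(1L), "arch_id")
  fits[order(obj, np, ids)]
}

#' Aggregate fitted networks into per-pair verdicts
#'
#' A miRNA-mRNA pair is validated if and only if at least one fitted
#' network containing the pair is validated. The verdict records which
#' architecture kinds validated it and the ranked best networks.
#'
#' @param fits List of `fit_result` objects.
#' @param threshold Validation threshold in percent.
#' @return Data frame with one row per (mirna, gene) pair: `mirna_id`,
#'   `gene_id`, `validated`, `mode` (`Transcr.Degr.`, `Transl.Inhib.`,
#'   `both`, or `none`), `n_networks`, `best_errpred`, `best_arch`.
#' @export
validate_pairs <- function(fits, threshold = 10) {
  if (length(fits) == 0L) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      validated = logical(), mode = character(),
                      n_networks = integer(), best_errpred = numeric(),
                      best_arch = character(), stringsAsFactors = FALSE))
  }
  pair_rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
    p <- arch_pairs(fits[[i]]$arch)
    p$fit_idx <- i
    p
  }))
  keys <- unique(pair_rows[, c("mirna_id", "gene_id")])
  keys <- keys[order(keys$gene_id, keys$mirna_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(keys)), function(r) {
    sel <- pair_rows$mirna_id == keys$mirna_id[r] &
      pair_rows$gene_id == keys$gene_id[r]
    idx <- pair_rows$fit_idx[sel]
    sub <- fits[idx]
    ok <- vapply(sub, validate_network, logical(1L), threshold = threshold)
    kinds_ok <- unique(pair_rows$kind[sel][ok])
    mode <- if (length(kinds_ok) == 0L) "none"
    else if (length(kinds_ok) == 2L) "both" else kinds_ok
    ranked <- rank_networks(sub[ok])
    data.frame(
      mirna_id = keys$mirna_id[r], gene_id = keys$gene_id[r],
      validated = any(ok), mode = mode, n_networks = length(sub),
      best_errpred = if (length(ranked)) ranked[[1L]]$objective else NA_real_,
      best_arch = if (length(ranked)) ranked[[1L]]$arch_id else NA_character_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a validation campaign
#'
#' Per gene and architecture kind: how many distinct miRNAs target it in
#' the fitted families and how many were validated; plus the flat list of
#' validated pairs.
#'
#' @param fits List of `fit_result` objects.
#' @param threshold Validation threshold in percent.
#' @return List with `counts` (gene x kind table) and `validated_pairs`
#'   (flat data frame).
#' @export
summarize_campaign <- function(fits, threshold = 10) {
  verdicts_by_kind <- function(kind_label) {
    sel <- vapply(fits, function(f) {
      (f$kind == "TD") == (kind_label == "Transcr.Degr.")
    }, logical(1L))
    validate_pairs(fits[sel], threshold = threshold)
  }
  counts <- list()
  for (kind_label in c("Transcr.Degr.", "Transl.Inhib.")) {
    v <- verdicts_by_kind(kind_label)
    if (nrow(v) == 0L) next
    for (g in sort(unique(v$gene_id))) {
      sub <- v[v$gene_id == g, ]
      counts[[length(counts) + 1L]] <- data.frame(
        gene_id = g, kind = kind_label,
        n_targeting = length(unique(sub$mirna_id)),
        n_validated = length(unique(sub$mirna_id[sub$validated])),
        stringsAsFactors = FALSE)
    }
  }
  counts <- if (length(counts)) do.call(rbind, counts) else
    data.frame(gene_id = character(), kind = character(),
               n_targeting = integer(), n_validated = integer())
  all_verdicts <- validate_pairs(fits, threshold = threshold)
  list(counts = counts,
       validated_pairs = all_verdicts[all_verdicts$validated, , drop = FALSE],
       verdicts = all_verdicts)
}
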