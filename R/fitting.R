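#' Campaign configuration
#'
#' Collects every tunable constant of the enumeration, fitting and
#' validation stages. Defaults follow the study conditions: a strict 10%
#' validation threshold, at most 4 binding sites per regulator, a coarse
#' factor grid 0.1..0.9 with one local refinement at resolution 0.01, and
#' at most 3 miRNAs per translation-inhibition architecture (1 for
#' proteins recorded in a single condition).
#'
#' @param threshold Validation threshold on the global error of prediction,
#'   in percent (strict inequality).
#' @param c_max Maximum number of binding sites per regulator.
#' @param factor_grid Coarse grid of saturating-factor values, strictly
#'   inside (0, 1).
#' @param refine Whether to refine the factor grid once around the
#'   incumbent.
#' @param refine_halfwidth,refine_step Geometry of the refinement grid.
#' @param max_combo Maximum miRNAs per Transl.Inhib. architecture.
#' @param max_combo_single_condition Same bound for downstream proteins
#'   recorded in only one condition (the knocked-out protein).
#' @param rate_solver Rate-constant solver; only `"nnls"` (nonnegative
#'   least squares) is implemented.
#' @param errpred_aggregation Aggregation of per-point smoothed errors into
#'   the global error of prediction: `"mean"` (default) or `"rms"`.
#' @param residual_scheme Discretization of the CKE residuals:
#'   `"trapezoid"` (second-order, default) or `"forward"` (first-order
#'   forward difference).
#' @param step RK4 integration step in days.
#' @param max_candidates Budget on the number of grid-search candidates per
#'   architecture; exceeding it is an error.
#' @param k_degp Optional fixed protein decay rate (1/day) overriding the
#'   pre-estimation from data; either a single value or a named vector per
#'   condition.
#' @param k_degp_per_condition Estimate the protein decay rate separately
#'   per condition instead of sharing one value.
#' @param knockout Named list condition -> molecule ids with level
#'   identically zero in that condition.
#' @param audit Record every evaluated candidate's objective in the fit
#'   result (for auditing that the returned optimum is the evaluated
#'   minimum).
#' @return A `campaign_config` list.
#' @export
campaign_config <- function(threshold = 10, c_max = 4L,
                            factor_grid = seq(0.1, 0.9, by = 0.1),
                            refine = TRUE, refine_halfwidth = 0.05,
                            refine_step = 0.01,
                            max_combo = 3L, max_combo_single_condition = 1L,
                            rate_solver = c("nnls", "l1_lp"),
                            errpred_aggregation = c("mean", "rms"),
                            residual_scheme = c("trapezoid", "forward"),
                            step = 1 / 30, max_candidates = 1e5,
                            k_degp = NULL, k_degp_per_condition = FALSE,
                            knockout = list(KO = "GCNF"),
                            audit = FALSE) {
  rate_solver <- match.arg(rate_solver)
  if (rate_solver == "l1_lp") {
    stop("rate_solver 'l1_lp' is not implemented; use 'nnls'")
  }
  stopifnot(threshold > 0, c_max >= 1L, max_combo >= 1L,
            all(factor_grid > 0), all(factor_grid < 1))
  structure(list(threshold = threshold, c_max = as.integer(c_max),
                 factor_grid = sort(factor_grid), refine = refine,
                 refine_halfwidth = refine_halfwidth,
                 refine_step = refine_step,
                 max_combo = as.integer(max_combo),
                 max_combo_single_condition = as.integer(max_combo_single_condition),
                 rate_solver = rate_solver,
                 errpred_aggregation = match.arg(errpred_aggregation),
                 residual_scheme = match.arg(residual_scheme),
                 step = step, max_candidates = max_candidates,
                 k_degp = k_degp,
                 k_degp_per_condition = k_degp_per_condition,
                 knockout = knockout, audit = audit),
            class = "campaign_config")
}

#' Invert a saturating factor into an affinity constant
#'
#' The grid search explores values of the saturating factor
#' `f = a / (1 + a)`, `a = (gamma * level)^sites`, at a key instant where
#' the regulator's level is known; this inversion recovers the affinity
#' constant: `gamma = (f / (1 - f))^(1/sites) / level`.
#'
#' @param factor Saturating factor strictly inside (0, 1).
#' @param level Positive regulator level at the key instant.
#' @param sites Number of binding sites.
#' @return Affinity constant `gamma`.
#' @export
#' @examples
#' hill_from_factor(0.5, 1, 1)  # 1
hill_from_factor <- function(factor, level, sites) {
  if (any(factor <= 0) || any(factor >= 1)) {
    stop("factor must lie strictly inside (0, 1)")
  }
  if (any(level <= 0)) {
    stop("inversion error: regulator level is zero at the key instant; ",
         "the regulator cannot be calibrated there")
  }
  (factor / (1 - factor))^(1 / sites) / level
}

# --- fit preparation -------------------------------------------------------

.downstream_id <- function(arch) {
  if (inherits(arch, "transcr_degr_arch")) arch$gene else arch$protein
}

.regulator_ids <- function(arch) {
  if (inherits(arch, "transcr_degr_arch")) {
    c(arch$rep_proteins, arch$act_proteins)
  } else {
    arch$mirnas
  }
}

.regulator_roles <- function(arch) {
  if (inherits(arch, "transcr_degr_arch")) {
    c(rep("repressor", length(arch$rep_proteins)),
      rep("activator", length(arch$act_proteins)))
  } else {
    rep("mirna", length(arch$mirnas))
  }
}

# Pairwise interval combination of a 19-point series according to the
# residual scheme: trapezoid averages consecutive points, forward takes
# the left point.
.interval_op <- function(v, scheme) {
  n <- length(v)
  if (scheme == "trapezoid") (v[-n] + v[-1L]) / 2 else v[-n]
}

#' Estimate a protein's decay rate from its own declining profile
#'
#' Log-linear least-squares fit of `log(value)` against day over the
#' maximal strictly decreasing suffix of the averaged knot values. When no
#' such suffix with at least two positive points exists, the rate is 0 and
#' the result is flagged.
#'
#' @param day Recording days.
#' @param value Averaged (actin-normalized) protein values at `day`.
#' @return Decay rate in 1/day with attribute `n_points` (number of points
#'   used; < 2 means the estimate is a degenerate fallback of 0).
#' @export
estimate_protein_decay <- function(day, value) {
  o <- order(day)
  day <- day[o]; value <- value[o]
  n <- length(value)
  start <- n
  while (start > 1L && value[start - 1L] > value[start]) start <- start - 1L
  d <- day[start:n]; v <- value[start:n]
  keep <- v > 0
  d <- d[keep]; v <- v[keep]
  if (length(v) < 2L) {
    return(structure(0, n_points = length(v)))
  }
  slope <- stats::coef(stats::lm(log(v) ~ d))[[2L]]
  structure(max(0, -slope), n_points = length(v))
}

# Decay rate(s) for a TI fit: configured value, or estimated from the
# downstream protein's averaged knots (per condition or pooled).
.resolve_kdegp <- function(arch, profiles, conds, config) {
  if (!is.null(config$k_degp)) {
    k <- config$k_degp
    if (is.null(names(k))) k <- stats::setNames(rep(k[[1L]], length(conds)), conds)
    return(k[conds])
  }
  knots <- profiles$knots
  est_one <- function(cond) {
    if (!is.null(knots)) {
      s <- knots[knots$molecule_id == arch$protein & knots$condition == cond, ]
      if (nrow(s) >= 2L) return(as.numeric(estimate_protein_decay(s$day, s$value)))
    }
    v <- profile_values(profiles, arch$protein, cond)
    as.numeric(estimate_protein_decay(profiles$grid, v))
  }
  ests <- vapply(conds, est_one, numeric(1L))
  if (!config$k_degp_per_condition) {
    ests[] <- mean(ests)
  }
  ests
}

# Everything about (arch, data) that does not depend on the Hill
# candidate: observed series, fixed design columns, fine-time upstream
# levels, key-instant levels for the factor inversion.
.fit_prep <- function(arch, profiles, config) {
  grid <- profiles$grid
  dt <- grid[2L] - grid[1L]
  downstream <- .downstream_id(arch)
  conds_all <- intersect(c("WT", "KO"), unique(profiles$data$condition))
  if (length(conds_all) == 0L) conds_all <- unique(profiles$data$condition)
  have_obs <- vapply(conds_all, function(cc) {
    nrow(profiles$data[profiles$data$molecule_id == downstream &
                         profiles$data$condition == cc, ]) > 0L
  }, logical(1L))
  conds <- conds_all[have_obs]
  obs <- lapply(conds, function(cc) profile_values(profiles, downstream, cc))
  names(obs) <- conds
  scored <- conds[vapply(obs, function(v) mean(v) > 0, logical(1L))]
  if (length(scored) == 0L) {
    stop("degenerate-profile error: downstream '", downstream,
         "' is identically zero in every condition")
  }
  obs <- obs[scored]

  times <- .fine_times(config$step)
  n_sub <- round(dt / config$step)
  grid_idx <- 1L + n_sub * (seq_along(grid) - 1L)
  scheme <- config$residual_scheme
  regs <- .regulator_ids(arch)
  roles <- .regulator_roles(arch)
  kind <- if (inherits(arch, "transcr_degr_arch")) "TD" else "TI"

  per_cond <- lapply(scored, function(cc) {
    lev19 <- function(id) .upstream_values(profiles, id, cc, config$knockout)
    levfine <- function(v) .profile_at(grid, v, times)
    D <- obs[[cc]]
    dD <- diff(D) / dt
    reg19 <- do.call(rbind, lapply(regs, lev19))
    regfine <- if (length(regs)) t(apply(reg19, 1L, levfine)) else NULL
    out <- list(obs = D, dD = dD, reg19 = reg19, regfine = regfine)
    if (kind == "TD") {
      M19 <- 0
      for (m in arch$mirnas) M19 <- M19 + lev19(m)
      out$M19 <- M19
      out$Mfine <- levfine(M19)
      # fixed design columns: -(G*M) and -G, interval-combined
      out$colGM <- -.interval_op(D * M19, scheme)
      out$colG <- -.interval_op(D, scheme)
    } else {
      G19 <- lev19(arch$gene)
      out$G19 <- G19
      out$Gfine <- levfine(G19)
      out$colP <- .interval_op(D, scheme)
    }
    out
  })
  names(per_cond) <- scored

  # key instant per regulator: time of its maximum observed level in the
  # reference condition (WT when available)
  ref <- if ("WT" %in% scored) "WT" else scored[1L]
  ref_levels <- per_cond[[ref]]$reg19
  key_level <- if (length(regs)) apply(ref_levels, 1L, max) else numeric()
  if (any(key_level <= 0)) {
    bad <- regs[key_level <= 0][1L]
    stop("inversion error: regulator '", bad,
         "' has an identically zero reference profile and cannot be calibrated")
  }

  kdegp <- if (kind == "TI") .resolve_kdegp(arch, profiles, scored, config) else NULL

  list(arch = arch, kind = kind, regs = regs, roles = roles,
       key_level = key_level, conds = scored, per_cond = per_cond,
       grid = grid, dt = dt, grid_idx = grid_idx, kdegp = kdegp,
       scheme = scheme)
}

# --- rate solve and candidate scoring --------------------------------------

# Design matrix and response of the rate-linear residual system for fixed
# Hill parameters (gamma, sites per regulator). Returns the stacked system
# over scored conditions, including one zero initial-condition row per
# condition (the discretized system has 19 rows per condition).
.rate_system <- function(prep, sites, gamma) {
  A_rows <- list(); b_rows <- list()
  for (cc in prep$conds) {
    pc <- prep$per_cond[[cc]]
    if (prep$kind == "TD") {
      rep_idx <- which(prep$roles == "repressor")
      act_idx <- which(prep$roles == "activator")
      REP <- .impact_rows(pc$reg19, rep_idx, sites, gamma)
      ACT <- .impact_rows(pc$reg19, act_idx, sites, gamma)
      F19 <- committed_fraction(REP, ACT, has_activators = length(act_idx) > 0L)
      A <- cbind(.interval_op(F19, prep$scheme), pc$colGM, pc$colG)
      b <- pc$dD
    } else {
      REP <- .impact_rows(pc$reg19, seq_along(prep$regs), sites, gamma)
      u <- pc$G19 / (1 + REP)
      A <- cbind(.interval_op(u, prep$scheme))
      b <- pc$dD + prep$kdegp[[cc]] * pc$colP
    }
    A_rows[[cc]] <- rbind(A, matrix(0, 1L, ncol(A)))  # initial-condition row
    b_rows[[cc]] <- c(b, 0)
  }
  list(A = do.call(rbind, A_rows), b = unlist(b_rows, use.names = FALSE))
}

.impact_rows <- function(levels, idx, sites, gamma) {
  if (length(idx) == 0L) return(numeric(ncol(levels)))
  acc <- 0
  for (i in idx) acc <- acc + (gamma[i] * levels[i, ])^sites[i]
  acc
}

.nnls_rates <- function(A, b) {
  nz <- colSums(abs(A)) > 0
  x <- numeric(ncol(A))
  if (any(nz)) {
    x[nz] <- pracma::lsqnonneg(A[, nz, drop = FALSE], b)$x
  }
  list(rates = x, degenerate = !nz)
}

#' Solve the rate constants by nonnegative least squares
#'
#' With the Hill parameters fixed, the discretized CKE residuals are
#' linear in the rate constants (`k_transcr`, `k_react`, `k_deg` for a
#' transcription-degradation architecture; `k_transl` for a
#' translation-inhibition architecture). This solves the resulting
#' nonnegative least-squares problem over both conditions pooled.
#' Regressor columns that are identically zero are flagged and their rate
#' fixed to 0.
#'
#' @param arch A `cke_arch` object.
#' @param hill Hill-parameter table with fixed `sites` and `gamma`.
#' @param profiles `profile_set` with the data of both conditions.
#' @param config Campaign configuration.
#' @return List with `rates` (named), `degenerate` (logical per rate) and
#'   the residual sum of squares `rss`.
#' @export
solve_rates <- function(arch, hill, profiles, config = campaign_config()) {
  prep <- .fit_prep(arch, profiles, config)
  ord <- match(prep$regs, hill$regulator)
  if (anyNA(ord)) stop("hill table does not cover every regulator")
  sys <- .rate_system(prep, hill$sites[ord], hill$gamma[ord])
  sol <- .nnls_rates(sys$A, sys$b)
  nm <- if (prep$kind == "TD") c("k_transcr", "k_react", "k_deg") else "k_transl"
  resid <- sys$b - as.vector(sys$A %*% sol$rates)
  list(rates = stats::setNames(sol$rates, nm),
       degenerate = stats::setNames(sol$degenerate, nm),
       rss = sum(resid^2))
}

#' Discretized residual system of a parameterized CKE
#'
#' Evaluates the residuals of the discretized kinetic equation at the
#' supplied parameters over every scored condition: 18 interval residuals
#' plus one initial-condition residual per condition (38 in total for two
#' conditions on the 19-point grid).
#'
#' @param arch A `cke_arch` object.
#' @param params `td_params` or `ti_params` (the decay rate of `ti_params`
#'   is taken as given).
#' @param profiles `profile_set` with the observed data.
#' @param config Campaign configuration (controls the residual scheme).
#' @return List with `residuals` (numeric vector) and `n_unknowns`.
#' @export
discretize_residuals <- function(arch, params, profiles,
                                 config = campaign_config()) {
  prep <- .fit_prep(arch, profiles, config)
  if (prep$kind == "TI" && inherits(params, "ti_params")) {
    kdp <- params$k_degp
    if (is.null(names(kdp))) kdp <- stats::setNames(rep(kdp[[1L]], length(prep$conds)), prep$conds)
    prep$kdegp <- kdp[prep$conds]
  }
  ord <- match(prep$regs, params$hill$regulator)
  if (anyNA(ord)) stop("hill table does not cover every regulator")
  sys <- .rate_system(prep, params$hill$sites[ord], params$hill$gamma[ord])
  rates <- if (prep$kind == "TD") {
    c(params$k_transcr, params$k_react, params$k_deg)
  } else {
    params$k_transl
  }
  list(residuals = sys$b - as.vector(sys$A %*% rates),
       n_unknowns = n_params(arch))
}

# Score one Hill candidate: NNLS rates, RK4 prediction per condition,
# global error of prediction, objective = worst condition.
.score_candidate <- function(prep, sites, gamma, config) {
  sys <- .rate_system(prep, sites, gamma)
  sol <- .nnls_rates(sys$A, sys$b)
  rates <- sol$rates
  errs <- numeric(length(prep$conds))
  names(errs) <- prep$conds
  preds <- list()
  h <- config$step
  for (ci in seq_along(prep$conds)) {
    cc <- prep$conds[ci]
    pc <- prep$per_cond[[cc]]
    if (prep$kind == "TD") {
      rep_idx <- which(prep$roles == "repressor")
      act_idx <- which(prep$roles == "activator")
      REPf <- .impact_rows(pc$regfine, rep_idx, sites, gamma)
      ACTf <- .impact_rows(pc$regfine, act_idx, sites, gamma)
      Ff <- committed_fraction(REPf, ACTf,
                               has_activators = length(act_idx) > 0L)
      a <- rates[1L] * Ff
      b <- rates[2L] * pc$Mfine + rates[3L]
    } else {
      REPf <- .impact_rows(pc$regfine, seq_along(prep$regs), sites, gamma)
      a <- rates[1L] * pc$Gfine / (1 + REPf)
      b <- rep(prep$kdegp[[cc]], length(a))
    }
    sol_ode <- .rk4_linear(a, b, pc$obs[1L], h)
    pred <- sol_ode$values[prep$grid_idx]
    preds[[cc]] <- pred
    errs[ci] <- errpred_global(pred, pc$obs,
                               aggregation = config$errpred_aggregation)
  }
  list(objective = max(errs), errpred = errs, rates = rates,
       degenerate = sol$degenerate, preds = preds)
}

# candidate comparison with the parsimony tie-break: smaller objective,
# then fewer total binding sites, then lexicographically smaller gammas
.better_candidate <- function(cand, best, tol = 1e-12) {
  if (is.null(best)) return(TRUE)
  if (cand$objective < best$objective - tol) return(TRUE)
  if (cand$objective > best$objective + tol) return(FALSE)
  cs <- sum(cand$sites); bs <- sum(best$sites)
  if (cs != bs) return(cs < bs)
  d <- sign(cand$gamma - best$gamma)
  d <- d[d != 0]
  length(d) > 0L && d[1L] < 0
}

#' Fit a single architecture's kinetic parameters
#'
#' The dedicated estimator: for every regulator, candidate binding-site
#' counts 1..`c_max` and saturating-factor values on the coarse grid are
#' enumerated as a full product; each candidate's factor is inverted into
#' an affinity constant at the regulator's key instant (the time of its
#' maximum observed level in the reference condition), the rate constants
#' are solved by nonnegative least squares, the CKE is integrated, and the
#' candidate is scored by the worst-condition global error of prediction.
#' The factor grid is then refined once around the incumbent. Ties are
#' broken by parameter parsimony (fewer total binding sites, then
#' lexicographically smallest affinity vector). The procedure is fully
#' deterministic.
#'
#' @param arch A `cke_arch` object.
#' @param profiles `profile_set` with observed data for the conditions.
#' @param config Campaign configuration.
#' @return A `fit_result`: architecture, fitted `params`, per-condition
#'   `errpred` (percent), `objective` (worst condition), `n_params`,
#'   `validated` flag, predicted profiles, and optionally the audit table
#'   of every evaluated candidate.
#' @export
fit_architecture <- function(arch, profiles, config = campaign_config()) {
  prep <- .fit_prep(arch, profiles, config)
  R <- length(prep$regs)
  c_vals <- seq_len(config$c_max)
  n_coarse <- (length(c_vals) * length(config$factor_grid))^R
  if (n_coarse > config$max_candidates) {
    stop(sprintf(
      "budget error: architecture %s with %d regulators requires %g coarse candidates (> %g allowed)",
      arch_id(arch), R, n_coarse, config$max_candidates))
  }

  per_reg <- expand.grid(sites = c_vals, factor = config$factor_grid,
                         KEEP.OUT.ATTRS = FALSE)
  audit <- if (config$audit) list() else NULL
  best <- NULL

  eval_assignment <- function(idx_rows, best) {
    # idx_rows: list of per-regulator data.frames to take the product over
    combos <- expand.grid(lapply(idx_rows, function(d) seq_len(nrow(d))),
                          KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(combos))) {
      sites <- integer(R); fac <- numeric(R)
      for (j in seq_len(R)) {
        row <- idx_rows[[j]][combos[r, j], ]
        sites[j] <- row$sites; fac[j] <- row$factor
      }
      gamma <- hill_from_factor(fac, prep$key_level, sites)
      sc <- .score_candidate(prep, sites, gamma, config)
      cand <- c(sc, list(sites = sites, factor = fac, gamma = gamma))
      if (config$audit) {
        audit[[length(audit) + 1L]] <<- data.frame(
          objective = sc$objective, sites = paste(sites, collapse = "+"),
          factor = paste(fac, collapse = "+"))
      }
      if (.better_candidate(cand, best)) best <- cand
    }
    best
  }

  best <- eval_assignment(rep(list(per_reg), R), best)

  if (isTRUE(config$refine)) {
    refine_rows <- lapply(seq_len(R), function(j) {
      f <- seq(best$factor[j] - config$refine_halfwidth,
               best$factor[j] + config$refine_halfwidth,
               by = config$refine_step)
      f <- f[f > 0 & f < 1]
      data.frame(sites = best$sites[j], factor = f)
    })
    n_ref <- prod(vapply(refine_rows, nrow, integer(1L)))
    if (n_ref <= config$max_candidates) {
      best <- eval_assignment(refine_rows, best)
    } else {
      # coordinate-wise refinement: sweep one regulator at a time
      for (j in seq_len(R)) {
        rows <- lapply(seq_len(R), function(k) {
          if (k == j) refine_rows[[j]]
          else data.frame(sites = best$sites[k], factor = best$factor[k])
        })
        best <- eval_assignment(rows, best)
      }
    }
  }

  hill <- hill_params(prep$regs, prep$roles, best$sites, best$gamma)
  hill$factor <- best$factor
  params <- if (prep$kind == "TD") {
    td_params(hill, best$rates[1L], best$rates[2L], best$rates[3L])
  } else {
    ti_params(hill, best$rates[1L], prep$kdegp)
  }
  res <- structure(list(
    arch = arch, arch_id = arch_id(arch), kind = prep$kind,
    params = params, errpred = best$errpred,
    objective = best$objective, n_params = n_params(arch),
    rates_degenerate = best$degenerate,
    validated = all(best$errpred < config$threshold),
    threshold = config$threshold,
    predictions = best$preds,
    observations = lapply(prep$per_cond, `[[`, "obs")),
    class = "fit_result")
  if (config$audit) res$audit <- do.call(rbind, audit)
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(x$arch_id, "\n  ErrPred:",
      paste(sprintf("%s=%.2f%%", names(x$errpred), x$errpred), collapse = " "),
      "\n  parameters:", x$n_params,
      "| validated:", x$validated, "\n")
  invisible(x)
}

#' Fit every architecture of a campaign
#'
#' @param archs List of `cke_arch` objects.
#' @param profiles `profile_set` with the observed data.
#' @param config Campaign configuration.
#' @return List of `fit_result` objects, one per architecture, in input
#'   order.
#' @export
fit_campaign <- function(archs, profiles, config = campaign_config()) {
  lapply(archs, fit_architecture, profiles = profiles, config = config)
}

#' Flatten fit results into a delimited-text-ready table
#'
#' One row per architecture: id, kind, gene, miRNAs, parameter count,
#' per-condition errors of prediction, the worst-condition objective, the
#' validation flag and a compact parameter string.
#'
#' @param fits List of `fit_result` objects.
#' @return Data frame.
#' @export
fit_results_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    p <- f$params
    hill_str <- paste(sprintf("%s:c=%d:gamma=%.6g", p$hill$regulator,
                              p$hill$sites, p$hill$gamma), collapse = ";")
    rate_str <- if (f$kind == "TD") {
      sprintf("k_transcr=%.6g;k_react=%.6g;k_deg=%.6g",
              p$k_transcr, p$k_react, p$k_deg)
    } else {
      sprintf("k_transl=%.6g;k_degp=%s", p$k_transl,
              paste(sprintf("%.6g", p$k_degp), collapse = "/"))
    }
    data.frame(
      arch_id = f$arch_id, kind = f$kind, gene = f$arch$gene,
      mirnas = paste(f$arch$mirnas, collapse = ";"),
      n_params = f$n_params,
      errpred_WT = if ("WT" %in% names(f$errpred)) f$errpred[["WT"]] else NA_real_,
      errpred_KO = if ("KO" %in% names(f$errpred)) f$errpred[["KO"]] else NA_real_,
      objective = f$objective, validated = f$validated,
      params = paste(hill_str, rate_str, sep = "|"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
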