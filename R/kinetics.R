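#' Hill-type impact of a single regulator
#'
#' The individual impact of a regulator at expression level `level` with
#' `sites` binding sites and affinity constant `gamma` is
#' `a = (gamma * level)^sites`. The associated saturating factor
#' `a / (1 + a)` always lies in `[0, 1)`.
#'
#' @param level Nonnegative expression level (vectorized).
#' @param sites Positive integer number of binding sites.
#' @param gamma Positive affinity constant (1/intensity).
#' @return Nonnegative impact value(s).
#' @export
#' @examples
#' hill_impact(2, sites = 2, gamma = 1)        # 4
#' a <- hill_impact(2, 2, 1); a / (1 + a)       # saturating factor 0.8
hill_impact <- function(level, sites, gamma) {
  stopifnot(sites >= 1, gamma > 0)
  if (any(level < 0)) stop("expression level must be nonnegative")
  (gamma * level)^sites
}

#' Hill-parameter table for an architecture
#'
#' One row per regulator: its id, role (`"repressor"`, `"activator"` for
#' transcription factors, `"mirna"` for translation inhibitors), binding
#' site count and affinity constant.
#'
#' @param regulator Character vector of regulator ids.
#' @param role Character vector of roles.
#' @param sites Integer vector of binding-site counts (>= 1).
#' @param gamma Numeric vector of affinity constants (> 0).
#' @return Data frame of Hill parameters.
#' @export
hill_params <- function(regulator, role, sites, gamma) {
  h <- data.frame(regulator = as.character(regulator),
                  role = as.character(role),
                  sites = as.integer(sites), gamma = as.numeric(gamma),
                  stringsAsFactors = FALSE)
  if (any(h$sites < 1L)) stop("binding-site counts must be >= 1")
  if (any(h$gamma <= 0)) stop("affinity constants must be > 0")
  if (!all(h$role %in% c("repressor", "activator", "mirna"))) {
    stop("regulator role must be repressor, activator or mirna")
  }
  h
}

#' Kinetic parameters of a transcription-degradation equation
#'
#' @param hill Hill-parameter table ([hill_params()]) for the repressor and
#'   activator proteins.
#' @param k_transcr Transcription rate of the gene (intensity/day).
#' @param k_react Reaction rate between the mRNA and its miRNA(s)
#'   (1/(intensity day)).
#' @param k_deg First-order degradation rate of the mRNA (1/day).
#' @return Object of class `td_params`.
#' @export
td_params <- function(hill, k_transcr, k_react, k_deg) {
  stopifnot(k_transcr >= 0, k_react >= 0, k_deg >= 0)
  if (!all(hill$role %in% c("repressor", "activator"))) {
    stop("td_params: hill roles must be repressor/activator")
  }
  structure(list(hill = hill, k_transcr = k_transcr, k_react = k_react,
                 k_deg = k_deg),
            class = "td_params")
}

#' Kinetic parameters of a translation-inhibition equation
#'
#' @param hill Hill-parameter table for the inhibiting miRNAs
#'   (role `"mirna"`).
#' @param k_transl Translation rate (1/day).
#' @param k_degp Protein degradation rate (1/day); pre-estimated from the
#'   protein's own decay, not fitted. May be a single value or a named
#'   vector per condition.
#' @return Object of class `ti_params`.
#' @export
ti_params <- function(hill, k_transl, k_degp) {
  stopifnot(k_transl >= 0, all(k_degp >= 0))
  if (!all(hill$role == "mirna")) stop("ti_params: hill roles must be 'mirna'")
  structure(list(hill = hill, k_transl = k_transl, k_degp = k_degp),
            class = "ti_params")
}

#' Synthetic repressive and activating impacts
#'
#' Sums the individual Hill impacts of the repressors and of the
#' activators at given expression levels.
#'
#' @param rep_levels Numeric vector (or matrix, regulators in rows) of
#'   repressor levels.
#' @param act_levels Numeric vector/matrix of activator levels.
#' @param hill Hill-parameter table with roles `repressor`/`activator`,
#'   rows aligned with `c(rownames(rep), rownames(act))` order: repressor
#'   rows first.
#' @return List with elements `REP` and `ACT` (each a scalar, or a vector
#'   when level matrices are supplied).
#' @export
synthetic_impacts <- function(rep_levels, act_levels, hill) {
  sum_impacts <- function(levels, pars) {
    if (nrow(pars) == 0L) {
      if (is.matrix(levels)) return(numeric(ncol(levels))) else return(0)
    }
    if (!is.matrix(levels)) levels <- matrix(levels, nrow = nrow(pars))
    acc <- 0
    for (i in seq_len(nrow(pars))) {
      acc <- acc + hill_impact(levels[i, ], pars$sites[i], pars$gamma[i])
    }
    acc
  }
  rep_pars <- hill[hill$role == "repressor", , drop = FALSE]
  act_pars <- hill[hill$role == "activator", , drop = FALSE]
  list(REP = sum_impacts(rep_levels, rep_pars),
       ACT = sum_impacts(act_levels, act_pars))
}

#' Fraction of DNA templates committed to transcription
#'
#' With activators present: `F = ACT / ((1 + ACT) (1 + REP))`; without
#' activators: `F = 1 / (1 + REP)`. F lies in `[0, 1]`, decreases in the
#' repressive impact and increases in the activating impact.
#'
#' @param REP Nonnegative synthetic repressive impact (vectorized).
#' @param ACT Nonnegative synthetic activating impact (vectorized).
#' @param has_activators Whether the architecture has activator proteins.
#' @return Committed fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' committed_fraction(1, 0, has_activators = FALSE)  # 0.5
#' committed_fraction(0, 3, has_activators = TRUE)   # 0.75
committed_fraction <- function(REP, ACT = 0, has_activators = length(ACT) > 0 && any(ACT > 0)) {
  if (any(REP < 0) || any(ACT < 0)) stop("impacts must be nonnegative")
  if (has_activators) {
    ACT / ((1 + ACT) * (1 + REP))
  } else {
    1 / (1 + REP)
  }
}

#' Right-hand side of the transcription-degradation CKE
#'
#' `dG/dt = k_transcr * F - k_react * G * M - k_deg * G`: synthesis from
#' the committed template fraction, elimination by the miRNA reaction, and
#' first-order decay.
#'
#' @param G mRNA expression level.
#' @param M miRNA expression level (sum over the architecture's miRNAs).
#' @param F Committed transcription fraction in `[0, 1]`.
#' @param k_transcr,k_react,k_deg Nonnegative rate constants.
#' @return Rate of change of G.
#' @export
transcr_degr_rhs <- function(G, M, F, k_transcr, k_react, k_deg) {
  k_transcr * F - k_react * G * M - k_deg * G
}

#' Right-hand side of the translation-inhibition CKE
#'
#' `dP/dt = k_transl * G / (1 + REP_mir) - k_degp * P`: the fraction
#' `1 / (1 + REP_mir)` of mRNA molecules remains committed to translation
#' under the aggregate miRNA impact `REP_mir`, and the protein decays at
#' rate `k_degp`.
#'
#' @param P Protein expression level.
#' @param G mRNA expression level.
#' @param REP_mir Aggregate Hill impact of the inhibiting miRNAs.
#' @param k_transl,k_degp Nonnegative rate constants.
#' @return Rate of change of P.
#' @export
transl_inhib_rhs <- function(P, G, REP_mir, k_transl, k_degp) {
  k_transl * G / (1 + REP_mir) - k_degp * P
}

# Times at half-step resolution for an RK4 integration of [0, 6] with the
# given step; grid points must land on integration steps.
.fine_times <- function(step = 1 / 30, t_end = 6) {
  n_steps <- round(t_end / step)
  if (abs(n_steps * step - t_end) > 1e-9) {
    stop("integration step must divide the 6-day span")
  }
  seq(0, t_end, length.out = 2L * n_steps + 1L)
}

# Evaluate a 19-point profile at arbitrary times by PCHIP.
.profile_at <- function(grid, values, times) {
  pmax(pracma::pchip(grid, values, pmin(pmax(times, min(grid)), max(grid))), 0)
}

# Explicit RK4 for the scalar linear ODE y' = a(t) - b(t) y, with a and b
# sampled at half-step resolution (length 2N+1 for N steps). The RK4
# update for a linear ODE collapses to y_{n+1} = A_n y_n + B_n with
# vectorizable coefficients. Transient negative values are clamped to 0;
# the largest clamped deficit is returned for the caller to police.
.rk4_linear <- function(a, b, y0, h) {
  m <- length(a)
  n <- (m - 1L) %/% 2L
  i1 <- seq(1L, m - 2L, by = 2L)
  i2 <- seq(2L, m - 1L, by = 2L)
  i3 <- seq(3L, m, by = 2L)
  a1 <- a[i1]; a2 <- a[i2]; a3 <- a[i3]
  b1 <- b[i1]; b2 <- b[i2]; b3 <- b[i3]
  q1 <- b1
  q2 <- b2 * (1 - h / 2 * q1)
  q3 <- b2 * (1 - h / 2 * q2)
  q4 <- b3 * (1 - h * q3)
  p1 <- a1
  p2 <- a2 - h / 2 * b2 * p1
  p3 <- a2 - h / 2 * b2 * p2
  p4 <- a3 - h * b3 * p3
  A <- 1 - h / 6 * (q1 + 2 * q2 + 2 * q3 + q4)
  B <- h / 6 * (p1 + 2 * p2 + 2 * p3 + p4)
  y <- numeric(n + 1L)
  y[1L] <- y0
  clamp <- 0
  yy <- y0
  for (j in seq_len(n)) {
    yy <- A[j] * yy + B[j]
    if (yy < 0) {
      if (-yy > clamp) clamp <- -yy
      yy <- 0
    }
    y[j + 1L] <- yy
  }
  list(values = y, max_clamp = clamp)
}

# Level of one upstream molecule in one condition, honoring knocked-out
# molecules (level identically zero when listed in `knockout`).
.upstream_values <- function(profiles, id, condition, knockout = list()) {
  d <- profiles$data
  i <- which(d$molecule_id == id & d$condition == condition)
  if (length(i) > 0L) {
    return(as.numeric(d[i[1L], paste0("t", seq_along(profiles$grid) - 1L)]))
  }
  if (id %in% (knockout[[condition]] %||% character())) {
    return(numeric(length(profiles$grid)) * 0)
  }
  stop("dependency error: upstream molecule '", id,
       "' has no profile in condition '", condition, "'")
}

# Aggregate Hill impact of a set of regulators at sampled levels.
# levels: matrix (regulators x times); pars: hill table rows aligned.
.aggregate_impact <- function(levels, pars) {
  if (nrow(pars) == 0L) return(numeric(ncol(levels)))
  acc <- 0
  for (i in seq_len(nrow(pars))) {
    acc <- acc + (pars$gamma[i] * levels[i, ])^pars$sites[i]
  }
  acc
}

# Drives a(t), b(t) of the linear-in-state CKE for one architecture,
# sampled at the given times.
.cke_drives <- function(arch, params, profiles, condition, times,
                        knockout = list()) {
  grid <- profiles$grid
  lev <- function(id) {
    .profile_at(grid, .upstream_values(profiles, id, condition, knockout),
                times)
  }
  if (inherits(arch, "transcr_degr_arch")) {
    stopifnot(inherits(params, "td_params"))
    M <- 0
    for (m in arch$mirnas) M <- M + lev(m)
    h <- params$hill
    rep_pars <- h[h$role == "repressor", , drop = FALSE]
    act_pars <- h[h$role == "activator", , drop = FALSE]
    rep_levels <- do.call(rbind, lapply(rep_pars$regulator, lev))
    act_levels <- do.call(rbind, lapply(act_pars$regulator, lev))
    REP <- if (nrow(rep_pars)) .aggregate_impact(rep_levels, rep_pars) else numeric(length(times))
    ACT <- if (nrow(act_pars)) .aggregate_impact(act_levels, act_pars) else numeric(length(times))
    F <- committed_fraction(REP, ACT,
                            has_activators = length(arch$act_proteins) > 0L)
    list(a = params$k_transcr * F, b = params$k_react * M + params$k_deg)
  } else if (inherits(arch, "transl_inhib_arch")) {
    stopifnot(inherits(params, "ti_params"))
    h <- params$hill
    mir_levels <- do.call(rbind, lapply(h$regulator, lev))
    REP <- .aggregate_impact(mir_levels, h)
    G <- lev(arch$gene)
    kdp <- params$k_degp
    if (!is.null(names(kdp)) && condition %in% names(kdp)) {
      kdp <- kdp[[condition]]
    } else {
      kdp <- kdp[[1L]]
    }
    list(a = params$k_transl * G / (1 + REP),
         b = rep(kdp, length(times)))
  } else {
    stop("not a cke_arch object")
  }
}

#' Predict a downstream profile by integrating a parameterized CKE
#'
#' Numerically integrates the architecture's kinetic equation over the
#' six-day course with an explicit fixed-step 4th-order Runge-Kutta scheme
#' (default step 1/30 day, ten substeps per grid interval). Upstream
#' expression levels are evaluated at substep times by PCHIP interpolation
#' of their 19-point profiles. The prediction starts from the observed
#' downstream value at t = 0 (or a supplied initial value) and is returned
#' at the 19 grid points.
#'
#' @param arch A `cke_arch` object.
#' @param params Matching `td_params` or `ti_params`.
#' @param profiles `profile_set` holding every upstream molecule (and the
#'   downstream molecule, unless `initial_value` is given).
#' @param condition Condition to predict (`"WT"` or `"KO"`).
#' @param initial_value Downstream level at t = 0; defaults to the observed
#'   value.
#' @param step Integration step in days; must divide 6.
#' @param knockout Named list condition -> molecule ids whose level is
#'   identically zero in that condition (e.g. the knocked-out gene).
#' @param clamp_tol Relative tolerance for transient negative states;
#'   deficits beyond `clamp_tol * max(1, initial_value)` abort with an
#'   error (model misuse rather than roundoff).
#' @return Numeric vector of 19 predicted downstream values (all >= 0).
#' @export
predict_downstream <- function(arch, params, profiles, condition,
                               initial_value = NULL, step = 1 / 30,
                               knockout = list(), clamp_tol = 1e-9) {
  grid <- profiles$grid
  downstream <- if (inherits(arch, "transcr_degr_arch")) arch$gene else arch$protein
  if (is.null(initial_value)) {
    initial_value <- profile_values(profiles, downstream, condition)[1L]
  }
  times <- .fine_times(step)
  dr <- .cke_drives(arch, params, profiles, condition, times, knockout)
  sol <- .rk4_linear(dr$a, dr$b, initial_value, step)
  if (sol$max_clamp > clamp_tol * max(1, abs(initial_value))) {
    stop(sprintf(
      "integration of %s drove the state negative by %.3g (beyond roundoff)",
      arch_id(arch), sol$max_clamp))
  }
  n_sub <- round((grid[2L] - grid[1L]) / step)
  idx <- 1L + n_sub * (seq_along(grid) - 1L)
  sol$values[idx]
}
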