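# Build a profile_set directly from named per-condition value vectors:
# mols = list(id = list(kind = "...", WT = values19, KO = values19))
make_profile_set <- function(mols, grid = time_grid()) {
  rows <- list()
  for (id in names(mols)) {
    for (cc in setdiff(names(mols[[id]]), "kind")) {
      v <- mols[[id]][[cc]]
      stopifnot(length(v) == length(grid))
      rows[[length(rows) + 1L]] <- as.data.frame(
        c(list(molecule_id = id, kind = mols[[id]]$kind, condition = cc),
          stats::setNames(as.list(v), paste0("t", seq_along(grid) - 1L))),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(grid = grid, data = do.call(rbind, rows), knots = NULL),
            class = "profile_set")
}

# A small single-repressor transcription-degradation test system with
# smooth upstream profiles.
td_test_system <- function(seed = 42L) {
  set.seed(seed)
  grid <- time_grid()
  m <- pmax(0, 1000 * exp(-0.4 * grid) + stats::rnorm(19, 0, 20))
  p <- 500 + 400 * sin(grid / 2) + stats::rnorm(19, 0, 10)
  arch <- transcr_degr_arch("G", "M1", rep_proteins = "R1")
  list(grid = grid, m = m, p = p, arch = arch,
       hill = hill_params("R1", "repressor", 2L, 1 / 800))
}

# Minimal fit_result stub for validation-stage tests.
stub_fit <- function(arch, errpred, n_par = n_params(arch)) {
  structure(list(arch = arch, arch_id = arch_id(arch),
                 kind = if (inherits(arch, "transcr_degr_arch")) "TD" else "TI",
                 errpred = errpred, objective = max(errpred),
                 n_params = n_par, validated = all(errpred < 10)),
            class = "fit_result")
}

# Raw recording rows in long format.
recording_rows <- function(id, kind, condition, days, replicates, values) {
  g <- expand.grid(day = days, replicate = seq_len(replicates))
  data.frame(molecule_id = id, kind = kind, condition = condition,
             day = g$day, replicate = g$replicate,
             value = rep(values, times = replicates),
             stringsAsFactors = FALSE)
}
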