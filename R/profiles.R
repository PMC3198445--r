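#' The common interpolation time grid
#'
#' All expression profiles are interpolated onto a shared grid of 19 time
#' points spanning the six-day differentiation course: t = 0, 1/3, ..., 6
#' days (uniform spacing of 1/3 day).
#'
#' @return Numeric vector of 19 strictly increasing time values in days.
#' @export
#' @examples
#' time_grid()
time_grid <- function() {
  seq(0, 6, length.out = 19L)
}

.kinds <- c("miRNA", "mRNA", "protein")
.conditions <- c("WT", "KO")
.recording_cols <- c("molecule_id", "kind", "condition", "day", "replicate", "value")

#' Validate a table of raw expression recordings
#'
#' Checks the schema and invariants of a long-format recording table:
#' required columns, known molecule kinds and conditions, days within
#' \[0, 6\], positive integer replicate indices, nonnegative intensities,
#' and uniqueness of (molecule_id, condition, day, replicate).
#'
#' @param recordings Data frame of raw recordings.
#' @return The validated data frame, invisibly coerced to canonical column
#'   types.
#' @export
validate_recordings <- function(recordings) {
  stopifnot(is.data.frame(recordings))
  missing_cols <- setdiff(.recording_cols, names(recordings))
  if (length(missing_cols) > 0L) {
    stop("recording table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  recordings$molecule_id <- as.character(recordings$molecule_id)
  recordings$kind <- as.character(recordings$kind)
  recordings$condition <- as.character(recordings$condition)
  recordings$day <- as.numeric(recordings$day)
  recordings$replicate <- as.integer(recordings$replicate)
  recordings$value <- as.numeric(recordings$value)

  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0L) {
      stop(sprintf("%s at row %d (line %d of the data file)",
                   what, idx[1L], idx[1L] + 1L))
    }
  }
  bad(!recordings$kind %in% .kinds, "unknown molecule kind")
  bad(!recordings$condition %in% .conditions, "unknown condition")
  bad(is.na(recordings$day) | recordings$day < 0 | recordings$day > 6,
      "day outside [0, 6]")
  bad(is.na(recordings$replicate) | recordings$replicate < 1L,
      "replicate index must be a positive integer")
  bad(is.na(recordings$value) | recordings$value < 0,
      "negative or missing intensity value")
  key <- paste(recordings$molecule_id, recordings$condition,
               recordings$day, recordings$replicate, sep = "\r")
  bad(duplicated(key), "duplicated (molecule, condition, day, replicate) key")
  recordings
}

.delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

#' Read raw expression recordings from a delimited text file
#'
#' The file must have header columns `molecule_id`, `kind`, `condition`,
#' `day`, `replicate`, `value`. Comma- versus tab-separation is inferred
#' from the file extension (`.csv` is comma, anything else tab).
#'
#' @param path Path to the delimited file.
#' @return Validated data frame of recordings.
#' @seealso [write_expression_table()], [validate_recordings()]
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                         stringsAsFactors = FALSE)
  validate_recordings(x)
}

#' Write raw expression recordings to a delimited text file
#'
#' @param recordings Data frame of recordings (validated before writing).
#' @param path Output path; `.csv` extension selects comma separation,
#'   anything else tab.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(recordings, path) {
  recordings <- validate_recordings(recordings)
  utils::write.table(recordings[.recording_cols], path,
                     sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Average replicate recordings per molecule, condition and day
#'
#' Replicates are synthesized by the plain arithmetic mean; recordings that
#' are absent simply do not contribute (no imputation, no outlier
#' rejection).
#'
#' @param recordings Data frame of raw recordings.
#' @return Data frame with one row per (molecule_id, kind, condition, day)
#'   and the replicate mean in `value`, ordered by molecule, condition, day.
#' @export
average_replicates <- function(recordings) {
  recordings <- validate_recordings(recordings)
  if (nrow(recordings) == 0L) {
    stop("empty replicate set: no recordings to average")
  }
  agg <- stats::aggregate(
    value ~ molecule_id + kind + condition + day,
    data = recordings, FUN = mean
  )
  agg <- agg[order(agg$molecule_id, agg$condition, agg$day), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Normalize a Western-blot intensity by its actin loading control
#'
#' @param intensity Nonnegative recorded intensity (vectorized).
#' @param actin Positive actin intensity from the same lane (vectorized).
#' @return `intensity / actin`.
#' @export
#' @examples
#' normalize_by_actin(10, 2)
normalize_by_actin <- function(intensity, actin) {
  if (any(is.na(actin)) || any(actin <= 0)) {
    stop("invalid actin control: actin intensity must be > 0")
  }
  if (any(is.na(intensity)) || any(intensity < 0)) {
    stop("protein intensity must be nonnegative")
  }
  intensity / actin
}

#' Normalize protein recordings lane-by-lane against actin
#'
#' Every protein recording is divided by the actin recording sharing its
#' (condition, day, replicate) lane; the actin rows themselves are removed
#' from the returned table. Non-protein recordings pass through untouched.
#'
#' @param recordings Data frame of raw recordings including actin rows.
#' @param actin_id Molecule id of the actin loading control.
#' @return Recording data frame with normalized protein values and no
#'   actin rows.
#' @export
normalize_protein_recordings <- function(recordings, actin_id = "actin") {
  recordings <- validate_recordings(recordings)
  actin <- recordings[recordings$molecule_id == actin_id, , drop = FALSE]
  if (nrow(actin) == 0L) {
    return(recordings)
  }
  lane_key <- function(x) paste(x$condition, x$day, x$replicate, sep = "\r")
  actin_lookup <- stats::setNames(actin$value, lane_key(actin))
  is_prot <- recordings$kind == "protein" & recordings$molecule_id != actin_id
  if (any(is_prot)) {
    lanes <- lane_key(recordings[is_prot, , drop = FALSE])
    matched <- actin_lookup[lanes]
    if (anyNA(matched)) {
      miss <- which(is.na(matched))[1L]
      stop("no actin lane recorded for protein measurement (condition ",
           recordings$condition[is_prot][miss], ", day ",
           recordings$day[is_prot][miss], ", replicate ",
           recordings$replicate[is_prot][miss], ")")
    }
    recordings$value[is_prot] <- normalize_by_actin(
      recordings$value[is_prot], unname(matched))
  }
  recordings <- recordings[recordings$molecule_id != actin_id, , drop = FALSE]
  rownames(recordings) <- NULL
  recordings
}

#' Monotone piecewise cubic Hermite interpolation of a profile
#'
#' Interpolates averaged knot values onto the common time grid with the
#' shape-preserving PCHIP scheme: the interpolant reproduces the knots
#' exactly, preserves monotone runs, and never overshoots the enclosing
#' knot values. With exactly two knots the interpolant degenerates to the
#' straight line through them.
#'
#' @param knot_days Strictly increasing recording days spanning the grid.
#' @param knot_values Nonnegative values at `knot_days`.
#' @param grid Evaluation grid, by default [time_grid()].
#' @return Numeric vector of interpolated values, one per grid point.
#' @export
#' @examples
#' interpolate_profile(c(0, 3, 6), c(0, 3, 6))[7]  # exact on linear data
interpolate_profile <- function(knot_days, knot_values, grid = time_grid()) {
  if (length(knot_days) < 2L) {
    stop("insufficient data: at least 2 knots are required for interpolation")
  }
  if (length(knot_days) != length(knot_values)) {
    stop("knot_days and knot_values must have equal length")
  }
  if (any(diff(knot_days) <= 0)) {
    stop("knot days must be strictly increasing")
  }
  if (any(knot_values < 0)) {
    stop("knot values must be nonnegative")
  }
  tol <- 1e-9
  if (min(grid) < min(knot_days) - tol || max(grid) > max(knot_days) + tol) {
    stop("extrapolation error: knot days [", min(knot_days), ", ",
         max(knot_days), "] do not cover the requested grid")
  }
  g <- pmin(pmax(grid, min(knot_days)), max(knot_days))
  if (length(knot_days) == 2L) {
    out <- stats::approx(knot_days, knot_values, xout = g)$y
  } else {
    out <- pracma::pchip(knot_days, knot_values, g)
  }
  pmax(out, 0)
}

#' Build interpolated expression profiles from raw recordings
#'
#' The full preprocessing path: protein recordings are normalized by their
#' actin lanes (when an actin molecule is present), replicates are averaged
#' per day, and each molecule/condition series is PCHIP-interpolated onto
#' the common 19-point grid. The recorded day grid may differ by molecule
#' kind (it is inferred from the data, never assumed).
#'
#' @param recordings Data frame of raw recordings.
#' @param grid Target time grid, by default [time_grid()].
#' @param actin_id Molecule id of the actin loading control, if any.
#' @return A `profile_set` object: list with the `grid`, a wide `data`
#'   frame (one row per molecule and condition, columns `t0`...`t18`), and
#'   the averaged `knots` table.
#' @export
build_profiles <- function(recordings, grid = time_grid(), actin_id = "actin") {
  recordings <- normalize_protein_recordings(recordings, actin_id = actin_id)
  knots <- average_replicates(recordings)
  series <- split(knots, paste(knots$molecule_id, knots$condition, sep = "\r"))
  rows <- lapply(series, function(s) {
    s <- s[order(s$day), , drop = FALSE]
    vals <- interpolate_profile(s$day, s$value, grid)
    c(list(molecule_id = s$molecule_id[1L], kind = s$kind[1L],
           condition = s$condition[1L]),
      stats::setNames(as.list(vals), paste0("t", seq_along(vals) - 1L)))
  })
  data <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  data <- data[order(data$molecule_id, data$condition), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(grid = grid, data = data, knots = knots),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("profile_set:", nrow(x$data), "profiles on a", length(x$grid),
      "point grid [", min(x$grid), ",", max(x$grid), "] days\n")
  tab <- table(x$data$kind, x$data$condition)
  print(tab)
  invisible(x)
}

#' Extract one molecule's interpolated profile
#'
#' @param profiles A `profile_set`.
#' @param molecule_id Molecule identifier.
#' @param condition Experimental condition (`"WT"` or `"KO"`).
#' @return Numeric vector of values aligned to the profile grid.
#' @export
profile_values <- function(profiles, molecule_id, condition) {
  stopifnot(inherits(profiles, "profile_set"))
  d <- profiles$data
  i <- which(d$molecule_id == molecule_id & d$condition == condition)
  if (length(i) == 0L) {
    stop("dependency error: no profile recorded for molecule '", molecule_id,
         "' in condition '", condition, "'")
  }
  as.numeric(d[i[1L], paste0("t", seq_along(profiles$grid) - 1L)])
}

#' List the molecules available in a profile set
#'
#' @param profiles A `profile_set`.
#' @return Data frame with columns molecule_id, kind, condition.
#' @export
profile_index <- function(profiles) {
  profiles$data[, c("molecule_id", "kind", "condition")]
}

#' Write interpolated profiles as a wide delimited table
#'
#' One row per molecule and condition with columns `t0`...`t18`.
#'
#' @param profiles A `profile_set`.
#' @param path Output path (`.csv` comma-separated, else tab).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "profile_set"))
  utils::write.table(profiles$data, path, sep = .delim_for(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read profiles written by [write_profiles()]
#'
#' @param path Path to the wide profile table.
#' @return A `profile_set` (without the averaged knot table, which is not
#'   serialized).
#' @export
read_profiles <- function(path) {
  data <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                            stringsAsFactors = FALSE)
  tcols <- grep("^t[0-9]+$", names(data), value = TRUE)
  grid <- seq(0, 6, length.out = length(tcols))
  structure(list(grid = grid, data = data, knots = NULL),
            class = "profile_set")
}
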