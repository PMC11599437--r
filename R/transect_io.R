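#' Read otolith transects from CSV
#'
#' Reads a core-to-edge transect file with one row per measurement point.
#' Required columns: `fish_id`, `distance_um`, `annulus`, `sr_ca`, `d18o`.
#' `d18o` may be empty on rows where only the elemental channel was measured
#' (the isotope channel is typically sampled at a coarser spatial resolution);
#' missing `sr_ca` is not legal. Annulus indices are 1-based; distances are in
#' micrometres from the core and must be strictly increasing within a fish.
#'
#' @param path path to a UTF-8, comma-separated, dot-decimal CSV file.
#' @return A named list of transects (class `transect_set`), one per fish, in
#'   order of first appearance. Each transect is a data frame with columns
#'   `fish_id`, `distance_um`, `annulus`, `sr_ca`, `d18o`, sorted by distance.
#' @export
read_transects <- function(path) {
  if (!file.exists(path)) stop_named("path", paste("file not found:", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("fish_id", "distance_um", "annulus", "sr_ca", "d18o")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_named("columns", paste("missing required column(s):",
                                paste(missing_cols, collapse = ", ")))
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(!is.finite(df$distance_um) | !is.finite(df$annulus) |
                 !is.finite(df$sr_ca) | df$sr_ca < 0 | df$annulus < 1)
  if (length(bad) > 0)
    stop_named("rows", paste("malformed row(s) at line(s):",
                             paste(df$.line[bad], collapse = ", ")))
  out <- list()
  for (id in unique(df$fish_id)) {
    tr <- df[df$fish_id == id, , drop = FALSE]
    if (is.unsorted(tr$distance_um, strictly = TRUE)) {
      dec <- which(diff(tr$distance_um) <= 0)[1]
      stop_named("distance_um",
                 sprintf("non-monotone distances for fish '%s' at line %d",
                         id, tr$.line[dec + 1]))
    }
    if (is.unsorted(tr$annulus))
      stop_named("annulus", sprintf("non-monotone annulus indices for fish '%s'", id))
    if (!any(tr$annulus == 1))
      stop_named("annulus", sprintf("fish '%s' has no annulus 1", id))
    tr$.line <- NULL
    rownames(tr) <- NULL
    out[[as.character(id)]] <- structure(tr, class = c("transect", "data.frame"))
  }
  structure(out, class = "transect_set")
}

#' Read per-fish metadata from CSV
#'
#' Columns: `fish_id`, `sex` (F/M), `age` (years), `total_length_mm`,
#' `capture_location`, `capture_habitat` (lagoon/tributary),
#' `capture_season` (spawning/non_spawning).
#'
#' @param path CSV path.
#' @return Data frame of fish records, validated against the closed
#'   vocabularies.
#' @export
read_fish_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("fish_id", "sex", "age", "total_length_mm",
                "capture_location", "capture_habitat", "capture_season")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_named("columns", paste("missing:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$fish_id)) stop_named("fish_id", "duplicate fish id")
  if (!all(df$sex %in% c("F", "M"))) stop_named("sex", "must be F or M")
  if (!all(df$age >= 1)) stop_named("age", "must be >= 1")
  if (!all(df$capture_habitat %in% c("lagoon", "tributary")))
    stop_named("capture_habitat", "must be lagoon or tributary")
  if (!all(df$capture_season %in% c("spawning", "non_spawning")))
    stop_named("capture_season", "must be spawning or non_spawning")
  df
}

#' Pair the isotope channel with the elemental channel
#'
#' The two channels of an otolith transect are usually measured at different
#' spatial resolutions (e.g. delta-18O spots every 35 um, Sr:Ca spots every
#' 5.5 um). This pairs each delta-18O spot with the mean Sr:Ca of elemental
#' points lying within plus/minus half the median delta-18O spot spacing of
#' its position. The output series lives on the delta-18O spot positions;
#' pairing never invents positions. Spots with no elemental point in the
#' window are flagged (`paired = FALSE`) and later excluded from the
#' salinity-correction regression.
#'
#' @param transect a `transect` data frame as returned by [read_transects()].
#' @return The transect restricted to rows with observed `d18o`, with
#'   `sr_ca` replaced by the window-averaged value and a logical `paired`
#'   column.
#' @export
pair_channels <- function(transect) {
  has_iso <- is.finite(transect$d18o)
  if (!any(has_iso)) stop_named("d18o", "no delta-18O points in transect")
  iso <- transect[has_iso, , drop = FALSE]
  pos_el <- transect$distance_um[is.finite(transect$sr_ca)]
  val_el <- transect$sr_ca[is.finite(transect$sr_ca)]
  spacing <- if (nrow(iso) > 1) median(diff(iso$distance_um)) else
    diff(range(transect$distance_um))
  half <- spacing / 2
  sr_paired <- numeric(nrow(iso))
  ok <- logical(nrow(iso))
  for (i in seq_len(nrow(iso))) {
    sel <- abs(pos_el - iso$distance_um[i]) <= half + 1e-9
    if (any(sel)) {
      sr_paired[i] <- mean(val_el[sel])
      ok[i] <- TRUE
    } else {
      sr_paired[i] <- NA_real_
    }
  }
  iso$sr_ca <- sr_paired
  iso$paired <- ok
  rownames(iso) <- NULL
  structure(iso, class = c("transect", "data.frame"))
}

#' Salinity correction of the delta-18O temperature proxy
#'
#' delta-18O in otolith carbonate covaries with ambient salinity, which the
#' co-located Sr:Ca channel records. To isolate the thermal signal, a single
#' ordinary least squares regression of delta-18O on paired Sr:Ca is fitted
#' over all paired points of all fish pooled, and the per-point residual is
#' stored as `d18o_res`. Residuals have mean zero and zero sample covariance
#' with Sr:Ca by OLS orthogonality. Re-running replaces (never stacks)
#' residuals. With `per_fish = TRUE` the regression is stratified by fish.
#'
#' @param transects a `transect_set` (paired, see [pair_channels()]) or a
#'   list of paired transects.
#' @param per_fish fit one regression per fish instead of pooling (default
#'   `FALSE`: pooled).
#' @return The transect set with a `d18o_res` column on every paired point;
#'   the fitted regression is attached as attribute `correction_fit`
#'   (coefficients, n).
#' @export
correct_temperature_proxy <- function(transects, per_fish = FALSE) {
  if (inherits(transects, "data.frame")) transects <- list(transects)
  pooled <- do.call(rbind, lapply(transects, function(tr) {
    ok <- if ("paired" %in% names(tr)) tr$paired else is.finite(tr$sr_ca)
    tr[ok & is.finite(tr$d18o), c("fish_id", "distance_um", "sr_ca", "d18o")]
  }))
  if (nrow(pooled) < 3) stop_named("transects", "need >= 3 paired points overall")
  fit_one <- function(d) {
    if (sd(d$sr_ca) == 0)
      stop_named("sr_ca", "constant Sr:Ca: singular regression design")
    lm(d18o ~ sr_ca, data = d)
  }
  if (per_fish) {
    fits <- lapply(split(pooled, pooled$fish_id), fit_one)
  } else {
    fit <- fit_one(pooled)
  }
  out <- lapply(transects, function(tr) {
    tr$d18o_res <- NA_real_
    ok <- (if ("paired" %in% names(tr)) tr$paired else TRUE) &
      is.finite(tr$d18o) & is.finite(tr$sr_ca)
    if (any(ok)) {
      f <- if (per_fish) fits[[as.character(tr$fish_id[1])]] else fit
      pred <- coef(f)[1] + coef(f)[2] * tr$sr_ca[ok]
      tr$d18o_res[ok] <- tr$d18o[ok] - pred
    }
    tr
  })
  cf <- if (per_fish) lapply(fits, coef) else coef(fit)
  structure(out, class = "transect_set",
            correction_fit = list(coefficients = cf, n = nrow(pooled),
                                  per_fish = per_fish))
}

#' Per-annulus means of Sr:Ca and delta-18O residual
#'
#' Arithmetic mean over the points of each annulus; one row per annulus with
#' at least one point (empty annuli are absent from the output, with a
#' message). Input should be paired and salinity-corrected.
#'
#' @param transect a single corrected transect.
#' @return Data frame with columns `fish_id`, `annulus`, `sr_ca`, `d18o_res`,
#'   `n_points`.
#' @export
annual_means <- function(transect) {
  ok <- is.finite(transect$sr_ca)
  tr <- transect[ok, , drop = FALSE]
  if (nrow(tr) == 0) stop_named("transect", "no usable points")
  full <- seq_len(max(tr$annulus))
  absent <- setdiff(full, unique(tr$annulus))
  if (length(absent) > 0)
    message(sprintf("fish %s: annulus/annuli %s have no points, omitted",
                    tr$fish_id[1], paste(absent, collapse = ",")))
  res <- if ("d18o_res" %in% names(tr)) tr$d18o_res else rep(NA_real_, nrow(tr))
  agg <- aggregate(cbind(sr_ca = tr$sr_ca, d18o_res = res),
                   by = list(annulus = tr$annulus), FUN = mean, na.rm = TRUE)
  data.frame(fish_id = tr$fish_id[1], annulus = agg$annulus,
             sr_ca = agg$sr_ca, d18o_res = agg$d18o_res,
             n_points = as.vector(table(tr$annulus)[as.character(agg$annulus)]),
             stringsAsFactors = FALSE)
}

#' Annual means for all fish, with grand Sr:Ca z-score
#'
#' Stacks [annual_means()] over a transect set and adds `srca_z`, the Sr:Ca
#' annual mean z-scored against the grand mean and standard deviation over
#' all fish-years (denominator n-1). This is the salinity covariate of the
#' increment growth model.
#'
#' @param transects corrected `transect_set`.
#' @return One data frame of fish-year rows with an `srca_z` column.
#' @export
annual_means_table <- function(transects) {
  tab <- do.call(rbind, lapply(transects, annual_means))
  rownames(tab) <- NULL
  tab$srca_z <- as.vector(scale(tab$sr_ca))
  tab
}

#' Life-stage summaries of a fish's annual means
#'
#' Collapses annual means into natal (first year), early (second year) and
#' later life (unweighted mean over annual means of years >= 3) values of
#' Sr:Ca and delta-18O residual — six features per fish. Stages that do not
#' exist for young fish are flagged `NA` (never imputed): an age-1 fish has
#' no early or later stage, an age-2 fish no later stage.
#'
#' @param annual data frame from [annual_means()] or [annual_means_table()]
#'   (one or several fish).
#' @return Data frame with one row per fish: `fish_id`, `natal_sr`,
#'   `natal_d18o`, `early_sr`, `early_d18o`, `later_sr`, `later_d18o`.
#' @export
stage_features <- function(annual) {
  one <- function(d) {
    stage <- function(sel, col) if (any(sel)) mean(d[[col]][sel]) else NA_real_
    data.frame(
      fish_id = d$fish_id[1],
      natal_sr = stage(d$annulus == 1, "sr_ca"),
      natal_d18o = stage(d$annulus == 1, "d18o_res"),
      early_sr = stage(d$annulus == 2, "sr_ca"),
      early_d18o = stage(d$annulus == 2, "d18o_res"),
      later_sr = stage(d$annulus >= 3, "sr_ca"),
      later_d18o = stage(d$annulus >= 3, "d18o_res"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(annual, annual$fish_id), one))
  rownames(out) <- NULL
  if (any(is.na(out$natal_sr))) stop_named("annual", "natal stage must be defined")
  out[match(unique(annual$fish_id), out$fish_id), , drop = FALSE]
}
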