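# Therapy-outcome analysis: caliper tumor volumes, growth normalization,
# humane-endpoint detection and product-limit survival.

CALIPER_COLUMNS <- c("animal_id", "group", "day", "length_mm", "width_mm")

#' Ellipsoid-approximation tumor volume from caliper dimensions
#'
#' V = length x width^2 / 2 (mm^3), the standard xenograft formula.
#' Arguments are canonicalized so that length >= width before applying the
#' asymmetric formula; the result is therefore invariant to argument order.
#'
#' @param length_mm,width_mm caliper dimensions in mm (vectorized, >= 0).
#' @return Volumes in mm^3.
#' @examples
#' tumor_volume(12, 12)  # 864
#' tumor_volume(8, 10)   # 320, same as tumor_volume(10, 8)
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm < 0) || any(width_mm < 0))
    stop_domain("caliper dimensions must be finite and >= 0")
  l <- pmax(length_mm, width_mm)
  w <- pmin(length_mm, width_mm)
  l * w^2 / 2
}

#' Read caliper measurements from a delimited text file
#'
#' Expects columns `animal_id`, `group`, `day`, `length_mm`, `width_mm`.
#' Dimensions are canonicalized (length >= width) and the derived
#' `volume_mm3` column is appended; a volume column in the file is ignored,
#' never read.
#'
#' @param path file path (comma- or tab-separated, auto-detected).
#' @return data.frame of class `tumor_measurements`.
#' @export
read_caliper <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  tumor_measurements(df)
}

#' Validate and canonicalize a caliper table
#'
#' @param df data.frame with the caliper columns.
#' @return data.frame of class `tumor_measurements` with `volume_mm3`.
#' @export
tumor_measurements <- function(df) {
  missing_cols <- setdiff(CALIPER_COLUMNS, names(df))
  if (length(missing_cols))
    stop_parse("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("day", "length_mm", "width_mm")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]]))
      stop_parse("column '", col, "' must be numeric without missing values")
  }
  l <- pmax(df$length_mm, df$width_mm)
  w <- pmin(df$length_mm, df$width_mm)
  df$length_mm <- l
  df$width_mm <- w
  df$volume_mm3 <- tumor_volume(l, w)
  class(df) <- c("tumor_measurements", "data.frame")
  df
}

#' Tumor volume normalized to the animal's own baseline
#'
#' V(day) / V(baseline), with the baseline the day-0 measurement (or the
#' nearest measurement within `baseline_window_d` of day 0).
#'
#' @param series one animal's measurements (`tumor_measurements` rows).
#' @param day day at which to evaluate the normalized volume.
#' @param baseline_day nominal baseline day (default 0).
#' @param baseline_window_d how far from `baseline_day` a measurement may
#'   be and still serve as baseline (default 0 = exact).
#' @return Single normalized volume (fraction of baseline).
#' @export
normalized_volume <- function(series, day, baseline_day = 0,
                              baseline_window_d = 0) {
  series <- series[order(series$day), , drop = FALSE]
  i <- which(abs(series$day - baseline_day) <= baseline_window_d)
  if (!length(i))
    stop_domain("no baseline measurement within ", baseline_window_d,
                " d of day ", baseline_day)
  i <- i[which.min(abs(series$day[i] - baseline_day))]
  v0 <- series$volume_mm3[i]
  if (v0 <= 0) stop_domain("baseline volume must be > 0")
  j <- match(day, series$day)
  if (is.na(j)) stop_domain("no measurement at day ", day)
  series$volume_mm3[j] / v0
}

#' Time to the humane-endpoint diameter
#'
#' The event time is the first measurement day on which the tumor diameter
#' reaches `endpoint_diameter_mm`; an animal whose tumor never reaches it
#' is censored at the earlier of its last measurement and
#' `observation_end_d`. "Diameter" is `max(length, width)` by default;
#' `"mean"` of the two dimensions is available as an alternative reading.
#' No interpolation between discrete measurement days.
#'
#' @param series one animal's measurements, days increasing.
#' @param endpoint_diameter_mm humane-endpoint diameter (default 12 mm).
#' @param observation_end_d end of the observation period (default 56 d).
#' @param diameter `"max"` (default) or `"mean"`.
#' @return One-row data.frame: `animal_id`, `group`, `time_d`, `event`.
#' @export
endpoint_time <- function(series, endpoint_diameter_mm = 12,
                          observation_end_d = 56,
                          diameter = c("max", "mean")) {
  diameter <- match.arg(diameter)
  if (nrow(series) == 0L) stop_domain("empty measurement series")
  series <- series[order(series$day), , drop = FALSE]
  d <- switch(diameter,
              max = pmax(series$length_mm, series$width_mm),
              mean = (series$length_mm + series$width_mm) / 2)
  hit <- which(d >= endpoint_diameter_mm)
  if (length(hit)) {
    time_d <- series$day[hit[1]]
    event <- TRUE
  } else {
    time_d <- min(max(series$day), observation_end_d)
    event <- FALSE
  }
  data.frame(animal_id = series$animal_id[1], group = series$group[1],
             time_d = time_d, event = event)
}

#' Endpoint survival records for every animal in a caliper table
#'
#' @param measurements `tumor_measurements` table.
#' @inheritParams endpoint_time
#' @return data.frame of class `survival_records`: one row per animal.
#' @export
survival_records <- function(measurements, endpoint_diameter_mm = 12,
                             observation_end_d = 56,
                             diameter = c("max", "mean")) {
  diameter <- match.arg(diameter)
  out <- do.call(rbind, lapply(
    split(measurements, measurements$animal_id), endpoint_time,
    endpoint_diameter_mm = endpoint_diameter_mm,
    observation_end_d = observation_end_d, diameter = diameter))
  out <- out[order(out$group, out$animal_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("survival_records", "data.frame")
  out
}

#' Product-limit (Kaplan-Meier) endpoint-survival curve for one group
#'
#' Fraction of animals below the humane endpoint as a right-continuous
#' step function of time. With no censoring before events this equals
#' 1 minus the cumulative event fraction. Backed by
#' [survival::survfit()].
#'
#' @param records `survival_records` rows for a single group.
#' @return data.frame of class `surv_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`; evaluate it with [surv_at()].
#' @export
survival_curve <- function(records) {
  if (nrow(records) == 0L) stop_domain("no survival records")
  if (length(unique(records$group)) > 1L)
    stop_domain("records must come from one group; got: ",
                paste(unique(records$group), collapse = ", "))
  fit <- survival::survfit(
    survival::Surv(records$time_d, records$event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("surv_curve", "data.frame")
  out
}

#' Evaluate a survival step function
#'
#' Right-continuous: `surv_at(curve, t)` is the surviving fraction just
#' after time `t`; before the first event it is 1.
#'
#' @param curve a `surv_curve`.
#' @param t times (vectorized).
#' @return Surviving fractions in [0, 1].
#' @export
surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, numeric(1))
}

#' Relative body-weight change from day 0
#'
#' weight(day) / weight(day 0) - 1 for every measurement day.
#'
#' @param series data.frame with `day` and `weight_g`; must contain day 0.
#' @return data.frame `day`, `rel_change`.
#' @export
body_weight_change <- function(series) {
  i0 <- match(0, series$day)
  if (is.na(i0)) stop_domain("series lacks a day-0 weight")
  w0 <- series$weight_g[i0]
  if (w0 <= 0) stop_domain("day-0 weight must be > 0")
  data.frame(day = series$day, rel_change = series$weight_g / w0 - 1)
}
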