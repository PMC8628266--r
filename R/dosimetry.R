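# Internal dosimetry: time-integrated activity from a surrogate-nuclide
# %ID/g curve and absorbed dose via the mean energy emitted per transition.
#
# Model: the biological kinetics measured with the imaging surrogate are
# assumed decay-corrected and identical for the therapy conjugate, so the
# therapy nuclide's physical decay e^(-lambda t) is applied inside the
# integral. Self-dose only: all emitted beta energy is absorbed locally.

#' Injected-activity specification
#'
#' @param activity_bq injected activity A0 in Bq (> 0).
#' @param nuclide therapy nuclide (a [nuclide()]); must carry the mean
#'   energy per transition Delta to be usable in [absorbed_dose()].
#' @return Object of class `injection_spec`.
#' @export
injection_spec <- function(activity_bq, nuclide) {
  check_number(activity_bq, "activity_bq", lower = 0, strict = TRUE)
  stopifnot(inherits(nuclide, "nuclide"))
  structure(list(activity_bq = activity_bq, nuclide = nuclide),
            class = "injection_spec")
}

# Exact integral of (a + b*t) * exp(-lambda*t) over [t1, t2], where the
# linear piece interpolates (t1, f1) -> (t2, f2). Times in seconds.
# Reduces to the trapezoid rule when lambda = 0.
segment_integral <- function(t1, t2, f1, f2, lambda) {
  # closed form cancels catastrophically when lambda*(t2-t1) is tiny;
  # there the trapezoid on the product is exact to O((lambda dt)^2)
  if (lambda * (t2 - t1) < 1e-8)
    return((f1 * exp(-lambda * t1) + f2 * exp(-lambda * t2)) / 2 *
             (t2 - t1))
  b <- (f2 - f1) / (t2 - t1)
  a <- f1 - b * t1
  g <- function(t, f) (f / lambda + b / lambda^2) * exp(-lambda * t)
  g(t1, a + b * t1) - g(t2, a + b * t2)
}

#' Time-integrated activity per unit tissue mass
#'
#' Computes \eqn{\tilde A = A_0 \times 10 \times \int_0^\infty f(t)
#' e^{-\lambda t} dt} in Bq s kg\eqn{^{-1}}, where f(t) is the organ's
#' %ID/g curve interpolated piecewise-linearly between measured times
#' (the factor 10 converts %ID/g to fraction of injected dose per kg) and
#' \eqn{\lambda} is the therapy nuclide's physical decay constant. Each
#' linear segment of f times the exponential is integrated in closed form.
#'
#' Handling of the unmeasured ends of the curve is explicit:
#' \describe{
#'   \item{t0_mode}{`"zero"` ramps from (0, 0) to the first measurement;
#'     `"hold_first"` holds the first measured value back to t = 0;
#'     `"auto"` (default) uses hold_first for blood -- the antibody is
#'     intravascular at injection -- and zero for everything else.}
#'   \item{tail_mode}{beyond the last measurement, `"physical"` (default)
#'     keeps the last %ID/g value and lets only physical decay act
#'     (conservative when biological clearance is slow compared with the
#'     beta decay); `"terminal_slope"` continues the log-linear biological
#'     slope fitted to the last two points; `"truncate"` stops the
#'     integral at the last measurement.}
#' }
#'
#' @param curve single-organ curve: data.frame with `time_h`, `mean_pidg`
#'   (a `tac` from [get_curve()]), strictly increasing times.
#' @param injection an [injection_spec()] carrying A0 and the nuclide.
#' @param tail_mode tail extrapolation rule (see Details).
#' @param t0_mode pre-first-measurement rule (see Details).
#' @param method `"analytic"` closed-form segment integration (default) or
#'   `"trapezoid"`, the plain trapezoid rule on the product f(t)e^(-lambda t)
#'   at the measured nodes (cross-check option).
#' @return Object of class `tia`: list with `organ`, `group`, `value`
#'   (Bq s/kg), `window_end_h`, `tail_mode`, `t0_mode`.
#' @export
time_integrated_activity <- function(curve, injection,
                                     tail_mode = c("physical",
                                                   "terminal_slope",
                                                   "truncate"),
                                     t0_mode = c("auto", "zero",
                                                 "hold_first"),
                                     method = c("analytic", "trapezoid")) {
  tail_mode <- tryCatch(match.arg(tail_mode),
                        error = function(e) stop_config(
                          "unknown tail_mode '", tail_mode[1], "'"))
  t0_mode <- tryCatch(match.arg(t0_mode),
                      error = function(e) stop_config(
                        "unknown t0_mode '", t0_mode[1], "'"))
  method <- match.arg(method)
  stopifnot(inherits(injection, "injection_spec"))
  if (nrow(curve) < 1L) stop_domain("curve needs at least one time point")
  if (any(curve$mean_pidg < 0)) stop_domain("curve has negative %ID/g")
  if (is.unsorted(curve$time_h, strictly = TRUE))
    stop_domain("curve times must be strictly increasing")

  organ <- if ("organ" %in% names(curve)) curve$organ[1] else NA_character_
  if (t0_mode == "auto")
    t0_mode <- if (identical(organ, "blood")) "hold_first" else "zero"

  lambda <- injection$nuclide$decay_constant_per_s
  t_s <- curve$time_h * HOUR_S
  f <- curve$mean_pidg
  if (t_s[1] > 0) {
    f0 <- if (t0_mode == "hold_first") f[1] else 0
    t_s <- c(0, t_s); f <- c(f0, f)
  }
  n <- length(t_s)
  if (n >= 2L) {
    if (method == "analytic") {
      integral <- sum(vapply(seq_len(n - 1L), function(i)
        segment_integral(t_s[i], t_s[i + 1L], f[i], f[i + 1L], lambda),
        numeric(1)))
    } else {
      g <- f * exp(-lambda * t_s)
      integral <- sum((g[-1] + g[-n]) / 2 * diff(t_s))
    }
  } else integral <- 0

  tl <- t_s[n]; fl <- f[n]
  tail_value <- switch(tail_mode,
    truncate = 0,
    physical = if (lambda > 0) fl * exp(-lambda * tl) / lambda else
      stop_domain("physical tail diverges for a stable nuclide"),
    terminal_slope = {
      if (n < 2L || f[n - 1L] <= 0 || fl <= 0) {
        # cannot fit a log-linear slope; fall back to physical persistence
        if (lambda > 0) fl * exp(-lambda * tl) / lambda else
          stop_domain("terminal-slope tail undefined")
      } else {
        kb <- log(f[n - 1L] / fl) / (tl - t_s[n - 1L])  # biological rate, /s
        if (lambda + kb <= 0)
          stop_domain("terminal slope rises faster than physical decay; ",
                      "tail integral diverges")
        fl * exp(-lambda * tl) / (lambda + kb)
      }
    })

  structure(list(
    organ = organ,
    group = if ("group" %in% names(curve)) curve$group[1] else NA_character_,
    value = injection$activity_bq * 10 * (integral + tail_value),
    window_end_h = tl / HOUR_S,
    tail_mode = tail_mode, t0_mode = t0_mode
  ), class = "tia")
}

#' Absorbed dose from a time-integrated activity
#'
#' Self-dose approximation for a pure beta emitter: D = Delta x Atilde,
#' with Delta the mean energy emitted per transition in
#' Gy kg (Bq s)^-1 and Atilde in Bq s/kg.
#'
#' @param tia a `tia` object from [time_integrated_activity()].
#' @param nuclide therapy nuclide carrying Delta.
#' @return Object of class `dose_estimate`: list with `organ`, `group`,
#'   `activity_bq` (NA when unknown), `absorbed_dose_gy`.
#' @export
absorbed_dose <- function(tia, nuclide) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (is.null(nuclide$delta_gy_kg_per_bq_s))
    stop_config("nuclide '", nuclide$name, "' carries no mean energy per ",
                "transition (Delta); it cannot be used as a dose emitter")
  structure(list(
    organ = tia$organ, group = tia$group,
    absorbed_dose_gy = nuclide$delta_gy_kg_per_bq_s * tia$value
  ), class = "dose_estimate")
}

#' Dose table across groups, organs and injected activities
#'
#' For each curve in a `tac_table` and each injected activity, integrates
#' the group-mean curve and multiplies by Delta -- the computation behind a
#' per-organ absorbed-dose table for a therapy nuclide substituted for the
#' imaging surrogate. Doses are exactly linear in activity; values are kept
#' at full precision here, display rounding happens only at serialization.
#'
#' @param curves `tac_table` from [summarize_curves()].
#' @param activities_bq vector of injected activities A0 in Bq (all > 0).
#' @param nuclide therapy nuclide carrying Delta.
#' @inheritParams time_integrated_activity
#' @return data.frame of class `dose_table`: `group`, `organ`,
#'   `activity_bq`, `dose_gy`.
#' @export
dose_table <- function(curves, activities_bq, nuclide,
                       tail_mode = "physical", t0_mode = "auto",
                       method = "analytic") {
  if (length(activities_bq) == 0L)
    stop_domain("activities_bq must be non-empty")
  for (a in activities_bq) check_number(a, "activity", lower = 0,
                                        strict = TRUE)
  combos <- unique(as.data.frame(curves)[, c("group", "organ")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    cv <- get_curve(curves, combos$group[i], combos$organ[i])
    # Atilde is linear in A0: integrate once at unit activity and scale.
    tia1 <- time_integrated_activity(
      cv, injection_spec(1, nuclide),
      tail_mode = tail_mode, t0_mode = t0_mode, method = method)
    d1 <- absorbed_dose(tia1, nuclide)$absorbed_dose_gy
    rows[[i]] <- data.frame(group = combos$group[i], organ = combos$organ[i],
                            activity_bq = activities_bq,
                            dose_gy = d1 * activities_bq)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dose_table", "data.frame")
  out
}

#' Serialize / read a dose table
#'
#' `write_dose_table()` writes the long format (group, organ, activity_bq,
#' dose_gy) at full precision so that reading it back reproduces the
#' estimates. `format_dose_table_wide()` renders the report layout --
#' rows = organs, columns = group x activity -- with doses rounded to
#' `rounding_gy` for display.
#'
#' @param doses a `dose_table`.
#' @param path output file.
#' @export
write_dose_table <- function(doses, path) {
  df <- as.data.frame(doses)
  df$dose_gy <- sprintf("%.10g", df$dose_gy)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_table
#' @export
read_dose_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("dose_table", "data.frame")
  out
}

#' @rdname write_dose_table
#' @param rounding_gy display rounding step in Gy (default 0.1).
#' @export
format_dose_table_wide <- function(doses, rounding_gy = 0.1) {
  df <- as.data.frame(doses)
  df$dose_gy <- round(df$dose_gy / rounding_gy) * rounding_gy
  df$col <- paste0(df$group, "_", df$activity_bq / 1e6, "MBq")
  wide <- stats::reshape(df[, c("organ", "col", "dose_gy")],
                         idvar = "organ", timevar = "col",
                         direction = "wide")
  names(wide) <- sub("^dose_gy\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Check the imaging-to-therapy nuclide substitution
#'
#' When doses for a therapy nuclide are predicted from a surrogate's
#' biodistribution, the physical decay weighting inside the integral uses
#' the therapy nuclide's half-life. This reports the half-life ratio
#' (imaging / therapy) and the maximal relative discrepancy of the decay
#' weight over the measurement window had the imaging nuclide's decay been
#' used instead, and warns when the ratio deviates from 1 by more than
#' `threshold`.
#'
#' @param imaging,therapy `nuclide` objects.
#' @param window_h measurement window in hours (default 168).
#' @param threshold relative half-life deviation triggering a warning
#'   (default 0.25).
#' @return List of class `substitution_check`: `half_life_ratio`,
#'   `max_decay_discrepancy`, `window_h`, `warning` flag.
#' @export
surrogate_substitution_check <- function(imaging, therapy, window_h = 168,
                                         threshold = 0.25) {
  stopifnot(inherits(imaging, "nuclide"), inherits(therapy, "nuclide"))
  ratio <- imaging$half_life_h / therapy$half_life_h
  dl <- imaging$decay_constant_per_s - therapy$decay_constant_per_s
  # |e^(-li t)/e^(-lt t) - 1| is monotone in t: max at window end
  disc <- abs(exp(-dl * window_h * HOUR_S) - 1)
  warn <- abs(ratio - 1) > threshold
  if (warn)
    warning(sprintf(
      "half-life ratio %s/%s = %.3f deviates from 1 by more than %g%%; %s",
      imaging$name, therapy$name, ratio, 100 * threshold,
      "surrogate kinetics may misrepresent the therapy nuclide's decay"),
      call. = FALSE)
  structure(list(half_life_ratio = ratio, max_decay_discrepancy = disc,
                 window_h = window_h, warning = warn),
            class = "substitution_check")
}

#' @export
print.substitution_check <- function(x, ...) {
  cat(sprintf(paste0("<substitution check> half-life ratio %.4f, max decay",
                     "-weight discrepancy %.3g over %g h%s\n"),
              x$half_life_ratio, x$max_decay_discrepancy, x$window_h,
              if (x$warning) " [WARNING]" else ""))
  invisible(x)
}
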