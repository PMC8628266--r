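# Radionuclide physics: half-lives, decay constants, and the mean energy
# emitted per transition (Delta) used for self-dose estimation.

#' Construct a radionuclide
#'
#' A nuclide is described by its physical half-life and, for nuclides used
#' as dose emitters, the mean energy emitted per transition
#' \eqn{\Delta} in Gy kg (Bq s)\eqn{^{-1}}. The decay constant
#' \eqn{\lambda = \ln 2 / t_{1/2}} is stored in s\eqn{^{-1}}; half-lives are
#' given in hours at the interface and converted to seconds once, internally.
#'
#' @param name nuclide identifier, e.g. `"Y-90"`.
#' @param half_life_h physical half-life in hours (> 0).
#' @param delta_gy_kg_per_bq_s mean energy emitted per transition in
#'   Gy kg (Bq s)^-1, or `NULL` for nuclides not used as dose emitters.
#' @return An object of class `nuclide` with fields `name`, `half_life_h`,
#'   `decay_constant_per_s`, and `delta_gy_kg_per_bq_s`.
#' @examples
#' y90 <- nuclide("Y-90", 64.1, 1.495e-13)
#' y90$decay_constant_per_s * 64.1 * 3600  # = log(2)
#' @export
nuclide <- function(name, half_life_h, delta_gy_kg_per_bq_s = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  check_number(half_life_h, "half_life_h", lower = 0, strict = TRUE)
  if (!is.null(delta_gy_kg_per_bq_s))
    check_number(delta_gy_kg_per_bq_s, "delta_gy_kg_per_bq_s",
                 lower = 0, strict = TRUE)
  structure(list(
    name = name,
    half_life_h = half_life_h,
    decay_constant_per_s = log(2) / (half_life_h * HOUR_S),
    delta_gy_kg_per_bq_s = delta_gy_kg_per_bq_s
  ), class = "nuclide")
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide %s> t1/2 = %g h, lambda = %.6g /s", x$name,
              x$half_life_h, x$decay_constant_per_s))
  if (!is.null(x$delta_gy_kg_per_bq_s))
    cat(sprintf(", Delta = %g Gy kg/(Bq s)", x$delta_gy_kg_per_bq_s))
  cat("\n")
  invisible(x)
}

#' Default nuclide registry
#'
#' Ships the imaging/therapy pair used throughout: In-111 (gamma emitter,
#' t1/2 = 67.4 h, imaging surrogate, no Delta) and Y-90 (beta emitter,
#' t1/2 = 64.1 h, Delta = 1.495e-13 Gy kg (Bq s)^-1). Additional or
#' replacement entries can be supplied as a list of
#' `list(name=, half_life_h=, delta_gy_kg_per_bq_s=)`, e.g. from a run
#' configuration.
#'
#' @param overrides optional list of nuclide definitions to add or replace.
#' @return Named list of `nuclide` objects.
#' @export
nuclide_registry <- function(overrides = NULL) {
  reg <- list(
    "In-111" = nuclide("In-111", half_life_h = 67.4),
    "Y-90"   = nuclide("Y-90", half_life_h = 64.1,
                       delta_gy_kg_per_bq_s = 1.495e-13)
  )
  for (ov in overrides) {
    n <- nuclide(ov$name, ov$half_life_h,
                 ov$delta_gy_kg_per_bq_s %||% NULL)
    reg[[n$name]] <- n
  }
  reg
}

#' Look up a built-in (or registered) nuclide by name
#'
#' @param name nuclide identifier.
#' @param registry registry as returned by [nuclide_registry()].
#' @return A `nuclide` object.
#' @examples
#' builtin_nuclide("Y-90")$half_life_h  # 64.1
#' @export
builtin_nuclide <- function(name, registry = nuclide_registry()) {
  if (!name %in% names(registry))
    stop_config("unknown nuclide '", name, "'; registered: ",
                paste(names(registry), collapse = ", "))
  registry[[name]]
}

#' Physical decay factor
#'
#' Fraction of activity remaining after `t_h` hours: \eqn{e^{-\lambda t}}.
#'
#' @param nuclide a `nuclide` object.
#' @param t_h elapsed time in hours (vectorized, all >= 0).
#' @return Numeric vector in (0, 1].
#' @examples
#' decay_factor(builtin_nuclide("Y-90"), 64.1)  # 0.5
#' @export
decay_factor <- function(nuclide, t_h) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (any(!is.finite(t_h)) || any(t_h < 0))
    stop_domain("t_h must be finite and >= 0")
  exp(-nuclide$decay_constant_per_s * t_h * HOUR_S)
}
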