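# Fixtures built in code: small record tables, temp files, and the
# brute-force integration / survival oracles used across test files.

y90 <- builtin_nuclide("Y-90")
in111 <- builtin_nuclide("In-111")

make_biodist_df <- function() {
  data.frame(
    animal_id = rep(c("m1", "m2", "m3"), each = 2),
    group = "saline",
    organ = rep(c("tumor", "liver"), 3),
    time_h = 1,
    percent_id_per_g = c(1.7, 5.0, 3.2, 6.0, 4.7, 7.0),
    body_weight_g = 20
  )
}

write_temp_table <- function(df, sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# random piecewise-linear %ID/g curve on [0, 168] h
random_pl_curve <- function(n_pts = NULL) {
  n_pts <- n_pts %||% sample(3:8, 1)
  times <- sort(runif(n_pts, 0, 168))
  data.frame(organ = "x", group = "g", time_h = times,
             mean_pidg = runif(n_pts, 0, 50))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force fine-grid integral of interp(f)(t) * exp(-lambda*t) over the
# measured window (times in hours, integral in seconds); truncated tail
grid_integral <- function(curve, lambda_per_s, steps = 1e5) {
  t_s <- curve$time_h * 3600
  grid <- seq(min(t_s), max(t_s), length.out = steps + 1)
  f <- approx(t_s, curve$mean_pidg, xout = grid)$y
  g <- f * exp(-lambda_per_s * grid)
  sum((g[-1] + g[-length(g)]) / 2) * (grid[2] - grid[1])
}

# day-by-day counting oracle for the product-limit curve: walk forward in
# time, remove censored animals after their censor day, and multiply the
# surviving fraction by (at risk - events)/(at risk) on each event day
counting_survival <- function(time_d, event, eval_t) {
  stopifnot(length(time_d) == length(event))
  s <- 1
  for (d in sort(unique(time_d[event]))) {
    if (d > eval_t) break
    at_risk <- sum(time_d >= d)
    s <- s * (at_risk - sum(time_d == d & event)) / at_risk
  }
  s
}
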