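# lambda for Y-90 in 1/s, used throughout
lam <- log(2) / (64.1 * 3600)

flat_curve <- function(pidg = 100)
  data.frame(organ = "x", group = "g", time_h = 0, mean_pidg = pidg)

test_that("constant curve with physical tail matches the 1/lambda closed form", {
  tia <- time_integrated_activity(flat_curve(100), injection_spec(1e6, y90),
                                  tail_mode = "physical")
  expect_equal(tia$value, 1e6 * 1000 / lam, tolerance = 1e-9)
  d <- absorbed_dose(tia, y90)
  expect_equal(d$absorbed_dose_gy, 1.495e-13 * 1e6 * 1000 / lam,
               tolerance = 1e-9)   # ~49.77 Gy
  zero <- time_integrated_activity(flat_curve(0), injection_spec(1e6, y90))
  expect_equal(zero$value, 0)
  expect_equal(absorbed_dose(zero, y90)$absorbed_dose_gy, 0)
})

test_that("triangle ramp with negligible decay reproduces the area oracle", {
  # near-stable emitter: lambda ~ 2e-19 /s, e^(-lambda t) = 1 over 1 s
  stable <- nuclide("quasi-stable", 1e12)
  ramp <- data.frame(organ = "x", group = "g",
                     time_h = c(0, 1 / 3600), mean_pidg = c(0, 100))
  tia <- time_integrated_activity(ramp, injection_spec(2e6, stable),
                                  tail_mode = "truncate")
  expect_equal(tia$value, 2e6 * 10 * 50, tolerance = 1e-9)
})

test_that("absorbed_dose scales by Delta and requires it", {
  tia <- structure(list(organ = "x", group = "g", value = 1,
                        window_end_h = 0, tail_mode = "truncate",
                        t0_mode = "zero"), class = "tia")
  expect_equal(absorbed_dose(tia, y90)$absorbed_dose_gy, 1.495e-13)
  expect_error(absorbed_dose(tia, in111), "no mean energy")
})

test_that("analytic segment integration agrees with a fine-grid oracle", {
  set.seed(11)
  for (i in 1:25) {
    cv <- random_pl_curve()
    tia <- time_integrated_activity(cv, injection_spec(1, y90),
                                    tail_mode = "truncate",
                                    t0_mode = "zero")
    # window integral only: subtract nothing, compare to grid on same window
    ref <- grid_integral(cv, lam) +
      # include the t0 ramp the pipeline adds before the first time point
      grid_integral(data.frame(time_h = c(0, cv$time_h[1]),
                               mean_pidg = c(0, cv$mean_pidg[1])), lam)
    expect_equal(tia$value, 10 * ref, tolerance = 1e-6)
  }
})

test_that("trapezoid cross-check method converges to the analytic value", {
  cv <- data.frame(organ = "x", group = "g",
                   time_h = seq(0, 2000, length.out = 1e5 + 1),
                   mean_pidg = rep(100, 1e5 + 1))
  a <- time_integrated_activity(cv, injection_spec(1e6, y90),
                                method = "analytic")
  tr <- time_integrated_activity(cv, injection_spec(1e6, y90),
                                 method = "trapezoid")
  expect_equal(tr$value, a$value, tolerance = 1e-3)
  expect_equal(a$value, 1e6 * 1000 / lam, tolerance = 1e-9)
})

test_that("dose is exactly linear in injected activity", {
  curves <- summarize_curves(biodistribution_records(make_biodist_df()))
  dt <- dose_table(curves, c(1e6, 2e6, 4e6), y90)
  for (org in unique(dt$organ)) {
    d <- dt$dose_gy[dt$organ == org]
    expect_identical(d[2], d[1] * 2)
    expect_identical(d[3], d[1] * 4)
  }
  expect_error(dose_table(curves, numeric(0), y90), "non-empty")
  expect_error(dose_table(curves, c(1e6, -1), y90), "activity")
})

test_that("longer half-life (same Delta) yields a larger dose", {
  cv <- random_pl_curve(5)
  slow <- nuclide("slow", 128.2, 1.495e-13)
  d_fast <- absorbed_dose(time_integrated_activity(
    cv, injection_spec(1e6, y90)), y90)$absorbed_dose_gy
  d_slow <- absorbed_dose(time_integrated_activity(
    cv, injection_spec(1e6, slow)), slow)$absorbed_dose_gy
  expect_gt(d_slow, d_fast)
})

test_that("tail modes are ordered: truncate <= terminal_slope <= physical", {
  # declining terminal segment -> negative biological slope
  cv <- data.frame(organ = "x", group = "g", time_h = c(24, 96, 168),
                   mean_pidg = c(30, 20, 10))
  v <- vapply(c("truncate", "terminal_slope", "physical"), function(m)
    time_integrated_activity(cv, injection_spec(1, y90),
                             tail_mode = m)$value, numeric(1))
  expect_lt(v["truncate"], v["terminal_slope"])
  expect_lt(v["terminal_slope"], v["physical"])
})

test_that("t0 handling: blood holds its first value, organs ramp from zero", {
  blood <- data.frame(organ = "blood", group = "g", time_h = c(1, 6),
                      mean_pidg = c(20, 15))
  tumor <- data.frame(organ = "tumor", group = "g", time_h = c(1, 6),
                      mean_pidg = c(20, 15))
  tb <- time_integrated_activity(blood, injection_spec(1, y90),
                                 tail_mode = "truncate", t0_mode = "auto")
  tt <- time_integrated_activity(tumor, injection_spec(1, y90),
                                 tail_mode = "truncate", t0_mode = "auto")
  expect_equal(tb$t0_mode, "hold_first")
  expect_equal(tt$t0_mode, "zero")
  expect_gt(tb$value, tt$value)  # held plateau beats the ramp
  expect_error(time_integrated_activity(
    tumor, injection_spec(1, y90), tail_mode = "banana"), "tail_mode")
  expect_error(time_integrated_activity(
    tumor, injection_spec(1, y90), t0_mode = "banana"), "t0_mode")
  neg <- tumor; neg$mean_pidg[1] <- -2
  expect_error(time_integrated_activity(neg, injection_spec(1, y90)),
               "negative")
})

test_that("surrogate substitution check reports ratio and discrepancy", {
  chk <- surrogate_substitution_check(in111, y90)
  expect_equal(chk$half_life_ratio, 67.4 / 64.1, tolerance = 1e-12)
  expect_false(chk$warning)
  expect_gt(chk$max_decay_discrepancy, 0)

  ident <- surrogate_substitution_check(y90, y90)
  expect_equal(ident$half_life_ratio, 1)
  expect_equal(ident$max_decay_discrepancy, 0)

  short <- nuclide("X", 6)
  expect_warning(chk2 <- surrogate_substitution_check(short, y90),
                 "half-life ratio")
  expect_true(chk2$warning)
})

test_that("dose tables round-trip through serialization", {
  curves <- summarize_curves(biodistribution_records(make_biodist_df()))
  dt <- dose_table(curves, c(0.925e6, 1.85e6, 3.7e6), y90)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_table(dt, path)
  back <- read_dose_table(path)
  expect_equal(back$dose_gy, dt$dose_gy, tolerance = 1e-9)
  wide <- format_dose_table_wide(dt)
  expect_equal(nrow(wide), length(unique(dt$organ)))
  expect_equal(ncol(wide), 1 + 3)  # organ + one group x three activities
})
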