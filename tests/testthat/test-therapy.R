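make_series <- function(id, days, diam, group = "g") {
  data.frame(animal_id = id, group = group, day = days,
             length_mm = diam, width_mm = diam)
}

test_that("tumor volume is length x width^2 / 2 with canonicalized order", {
  expect_equal(tumor_volume(12, 12), 864)
  expect_equal(tumor_volume(10, 8), 320)
  expect_equal(tumor_volume(8, 10), 320)   # argument order irrelevant
  expect_equal(tumor_volume(15, 0), 0)
  expect_error(tumor_volume(-1, 5), "dimensions")
  # strictly increasing in each dimension
  expect_gt(tumor_volume(10.5, 8), tumor_volume(10, 8))
  expect_gt(tumor_volume(10, 8.5), tumor_volume(10, 8))
})

test_that("caliper ingestion derives volumes and never reads them", {
  df <- make_series("m1", c(0, 7), c(8, 10))
  df$volume_mm3 <- c(-999, -999)  # must be ignored
  path <- write_temp_table(df)
  meas <- read_caliper(path)
  expect_equal(meas$volume_mm3, c(256, 500))
  expect_error(read_caliper(write_temp_table(df[, 1:4])),
               "missing column")
})

test_that("normalized volume uses the animal's own day-0 baseline", {
  s <- tumor_measurements(make_series("m1", c(0, 28),
                                      c((2 * 200)^(1/3), (2 * 700)^(1/3))))
  expect_equal(normalized_volume(s, 28), 3.5, tolerance = 1e-12)
  expect_equal(normalized_volume(s, 0), 1)
  no_base <- tumor_measurements(make_series("m1", c(3, 28), c(8, 10)))
  expect_error(normalized_volume(no_base, 28), "baseline")
  # nearest-within-window relaxation
  expect_equal(normalized_volume(no_base, 28, baseline_window_d = 3),
               tumor_volume(10, 10) / tumor_volume(8, 8))
  zero <- tumor_measurements(make_series("m1", c(0, 28), c(0, 10)))
  expect_error(normalized_volume(zero, 28), "> 0")
})

test_that("endpoint detection: first crossing day, else censoring", {
  s <- tumor_measurements(make_series("m1", c(0, 10, 20), c(8, 10, 12)))
  r <- endpoint_time(s)
  expect_true(r$event)
  expect_equal(r$time_d, 20)

  never <- tumor_measurements(make_series("m2", seq(0, 56, 7), 11))
  r2 <- endpoint_time(never)
  expect_false(r2$event)
  expect_equal(r2$time_d, 56)

  immediate <- tumor_measurements(make_series("m3", c(0, 7), c(12, 13)))
  expect_equal(endpoint_time(immediate)$time_d, 0)

  # mean-diameter reading crosses later than max for elongated tumors
  elong <- tumor_measurements(data.frame(
    animal_id = "m4", group = "g", day = c(0, 10),
    length_mm = c(12, 14), width_mm = c(6, 8)))
  expect_equal(endpoint_time(elong, diameter = "max")$time_d, 0)
  expect_equal(endpoint_time(elong, diameter = "mean")$time_d, 10)

  expect_error(endpoint_time(never[0, ]), "empty")
})

test_that("endpoint_time is monotone under uniform enlargement", {
  set.seed(3)
  for (i in 1:10) {
    d <- sort(sample(0:56, 8))
    diam <- cumsum(runif(8, 0, 2)) + 6
    s <- tumor_measurements(make_series("m", d, diam))
    bigger <- tumor_measurements(make_series("m", d, diam * 1.2))
    t1 <- endpoint_time(s); t2 <- endpoint_time(bigger)
    if (t1$event) expect_true(t2$event && t2$time_d <= t1$time_d)
  }
})

test_that("survival curve reproduces the counting oracle on a 3/2 arm", {
  recs <- data.frame(animal_id = paste0("m", 1:5), group = "g",
                     time_d = c(35, 40, 45, 56, 56),
                     event = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  class(recs) <- c("survival_records", "data.frame")
  cv <- survival_curve(recs)
  expect_equal(surv_at(cv, 34), 1)
  expect_equal(surv_at(cv, 35), 0.8)
  expect_equal(surv_at(cv, 56), 0.4)

  all_cens <- recs; all_cens$event <- FALSE
  expect_equal(surv_at(survival_curve(all_cens), c(0, 56)), c(1, 1))

  all_day1 <- recs; all_day1$time_d <- 1; all_day1$event <- TRUE
  expect_equal(surv_at(survival_curve(all_day1), 1), 0)

  expect_error(survival_curve(recs[0, ]), "no survival records")
  two <- recs; two$group[1] <- "other"
  expect_error(survival_curve(two), "one group")
})

test_that("product-limit curve equals exhaustive counting on <=6 records", {
  times_grid <- c(10, 20, 20, 30, 40, 56)
  set.seed(9)
  # all event/censor flag arrangements at fixed times, plus shuffles
  for (mask in 0:63) {
    ev <- as.logical(bitwAnd(mask, 2^(0:5)))
    perm <- sample(6)
    recs <- data.frame(animal_id = paste0("m", 1:6), group = "g",
                       time_d = times_grid[perm], event = ev[perm])
    class(recs) <- c("survival_records", "data.frame")
    cv <- survival_curve(recs)
    for (tt in c(0, 10, 15, 20, 30, 40, 56))
      expect_equal(surv_at(cv, tt),
                   counting_survival(recs$time_d, recs$event, tt),
                   tolerance = 1e-12)
    # non-increasing step function starting at 1
    expect_true(all(diff(cv$surv) <= 1e-12))
    expect_lte(max(cv$surv), 1)
  }
})

test_that("body-weight change is relative to day 0", {
  s <- data.frame(day = c(0, 3, 7), weight_g = c(20, 18, 20))
  expect_equal(body_weight_change(s)$rel_change, c(0, -0.10, 0))
  expect_equal(body_weight_change(
    data.frame(day = c(0, 5), weight_g = c(20, 20)))$rel_change, c(0, 0))
  expect_error(body_weight_change(
    data.frame(day = c(1, 5), weight_g = c(20, 20))), "day-0")
})
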