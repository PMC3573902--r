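test_that("period labels are half-open and day-indexed at light-on", {
  sch <- light_schedule(8, 20)
  # clock 07:59, 08:00, 20:00 on the first day (start at light-on)
  lab <- partition_periods(c(23 + 59 / 60, 24, 36), 8, sch)
  expect_equal(as.character(lab$period), c("nocturnal", "diurnal", "nocturnal"))
  expect_equal(lab$day, c(1L, 2L, 2L))
  # day increments exactly at each light-on
  lab2 <- partition_periods(seq(0, 47.9, by = 0.5), 8, sch)
  expect_equal(max(lab2$day), 2L)
  expect_true(all(diff(lab2$day) >= 0))
  # exhaustive and exclusive for any admissible schedule
  for (sch2 in list(light_schedule(6, 22), light_schedule(20, 8))) {
    labx <- partition_periods(seq(0, 24, by = 0.25), 3, sch2)
    expect_false(anyNA(labx$period))
  }
  expect_error(light_schedule(8, 8), class = "phytoflow_validation_error")
})

test_that("period means aggregate piecewise-constant series exactly", {
  sch <- light_schedule(8, 20)
  t_h <- seq(0.25, 23.75, by = 0.5)
  lab <- partition_periods(t_h, 8, sch)
  vals <- ifelse(lab$period == "nocturnal", 0.3, 0.1)
  pm <- period_mean(vals, lab)
  expect_equal(pm$mean[pm$period == "nocturnal"], 0.3)
  expect_equal(pm$mean[pm$period == "diurnal"], 0.1)
  # constant series: both means equal the constant
  pmc <- period_mean(rep(2.5, length(t_h)), lab)
  expect_true(all(pmc$mean == 2.5))
  # a single-sample period still yields that sample as its mean
  lab1 <- partition_periods(c(1, 13), 8, sch)
  pm1 <- period_mean(c(0.7, 0.2), lab1)
  expect_equal(pm1$mean[pm1$period == "diurnal"], 0.7)
  expect_equal(pm1$mean[pm1$period == "nocturnal"], 0.2)
})

test_that("daily normalisation yields exact shares", {
  expect_equal(normalize_daily(1, 1), data.frame(diurnal_share = 50,
                                                 nocturnal_share = 50))
  sh <- normalize_daily(0.1, 0.3)  # nocturnal = 3x diurnal
  expect_equal(sh$nocturnal_share, 75)
  expect_equal(sh$diurnal_share, 25)
  sh2 <- normalize_daily(0.3, 0.7)
  expect_equal(sh2$nocturnal_share, 70)
  expect_true(is.na(normalize_daily(0, 0)$diurnal_share))
  expect_error(normalize_daily(-1, 2), class = "phytoflow_validation_error")
  # shares always sum to exactly 100 where defined
  set.seed(3)
  a <- runif(50); b <- runif(50)
  sh3 <- normalize_daily(a, b)
  expect_true(all(sh3$diurnal_share + sh3$nocturnal_share == 100))
})

test_that("replicate standard error matches the direct formula", {
  expect_equal(replicate_sem(c(1, 1, 1)), 0)
  expect_equal(replicate_sem(c(0, 2)), 1.0)
  expect_equal(replicate_sem(c(0.5, 0.6, 0.7)), 0.1 / sqrt(3),
               tolerance = 1e-12)
  expect_true(is.na(replicate_sem(5)))
})

test_that("treatment effects are percent changes per cell", {
  ctl <- data.frame(day = 1, period = c("diurnal", "nocturnal"),
                    mean = c(0.6, 0.6))
  cool <- data.frame(day = 1, period = c("diurnal", "nocturnal"),
                     mean = c(0.3, 0.3))
  ill <- data.frame(day = 1, period = c("diurnal", "nocturnal"),
                    mean = c(0.4, 0.4))
  expect_equal(treatment_effect(ctl, cool)$percent_change, c(-50, -50))
  expect_equal(treatment_effect(ctl, ill)$percent_change,
               c(-100 / 3, -100 / 3))
  expect_equal(treatment_effect(ctl, ctl)$percent_change, c(0, 0))
})

test_that("the partition -> mean -> normalise chain is exact in closed form", {
  # night value a, day value b under a 12/12 schedule
  sch <- light_schedule(8, 20)
  t_h <- seq(0.125, 23.875, by = 0.25)
  lab <- partition_periods(t_h, 8, sch)
  for (ab in list(c(0.9, 0.3), c(3, 1), c(0.123, 0.456))) {
    a <- ab[1]; b <- ab[2]
    vals <- ifelse(lab$period == "nocturnal", a, b)
    pm <- period_mean(vals, lab)
    sh <- normalize_daily(pm$mean[pm$period == "diurnal"],
                          pm$mean[pm$period == "nocturnal"])
    expect_equal(sh$nocturnal_share, 100 * a / (a + b), tolerance = 1e-14)
    expect_equal(sh$diurnal_share, 100 * b / (a + b), tolerance = 1e-14)
  }
})

test_that("diel summaries pool replicates with SE and shares", {
  sch <- light_schedule(8, 20)
  t_h <- seq(0.25, 23.75, by = 0.5)
  mk <- function(night, day) {
    lab <- partition_periods(t_h, 8, sch)
    data.frame(elapsed_h = t_h,
               value = ifelse(lab$period == "nocturnal", night, day))
  }
  reps <- list(mk(0.30, 0.10), mk(0.32, 0.12), mk(0.28, 0.08))
  sm <- diel_summary(reps, 8, sch)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$n, c(3, 3))
  expect_equal(sm$mean[sm$period == "nocturnal"], 0.30)
  expect_equal(sm$mean[sm$period == "diurnal"], 0.10)
  expect_equal(sm$sem[sm$period == "nocturnal"], sd(c(0.30, 0.32, 0.28)) / sqrt(3))
  expect_equal(sum(sm$share_pct), 100)
  # single replicate: SE undefined, not zero
  sm1 <- diel_summary(reps[1], 8, sch)
  expect_true(all(is.na(sm1$sem)))
})
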