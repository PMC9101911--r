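test_that("the reference oral scenario places doses at 8/12/18 h daily", {
  sim <- oral_2day_coarse()
  expect_equal(sim$schedule$events$start_h, c(8, 12, 18, 32, 36, 42))
  expect_equal(sim$schedule$events$amount_mg[sim$schedule$events$start_h == 36],
               0.8)
})

test_that("bolus dosing yields one liver peak per meal, largest mid-day", {
  sim <- oral_2day_coarse()
  pk <- organ_peaks(sim, "liver", "DEHP")
  expect_equal(nrow(pk), 6)
  # each peak follows its dose within an hour
  expect_true(all(pk$time_h - c(8, 12, 18, 32, 36, 42) > 0))
  expect_true(all(pk$time_h - c(8, 12, 18, 32, 36, 42) < 1))
  # the largest day-2 peak follows the 36-h (largest) dose
  day2 <- pk[pk$time_h > 24, ]
  expect_true(day2$time_h[which.max(day2$conc_ug_mL)] > 36 &&
                day2$time_h[which.max(day2$conc_ug_mL)] < 38)
  expect_error(organ_peaks(sim, "gallbladder"), "unknown organ")
})

test_that("continuous dosing gives a monotone rise to a flagged plateau", {
  sim <- dermal_2day_coarse()
  expect_equal(nrow(organ_peaks(sim, "endocrine", "DEHP")), 0)
  eq <- equilibrium_concentration(sim, "endocrine", "DEHP")
  expect_true(eq$converged)
  expect_gt(eq$value, 0)
  # periodic bolus dosing must not report a silent equilibrium
  eq_oral <- equilibrium_concentration(oral_2day_coarse(), "liver", "DEHP")
  expect_false(eq_oral$converged)
  expect_true(is.na(eq_oral$value))
  # zero dose equilibrates at zero
  sim0 <- simulate(default_model(), schedule = NULL, t_end = 24, dt = 1)
  eq0 <- equilibrium_concentration(sim0, "liver", "DEHP")
  expect_true(eq0$converged)
  expect_equal(eq0$value, 0)
  expect_equal(nrow(organ_peaks(sim0, "liver", "DEHP")), 0)
})

test_that("combined endocrine concentration is volume-weighted", {
  sim <- dermal_2day_coarse()
  sp <- get_concentration(sim, "spleen", "DEHP")
  pa <- get_concentration(sim, "pancreas", "DEHP")
  comb <- get_concentration(sim, "endocrine", "DEHP")
  expect_equal(comb, (sp * 192 + pa * 77) / (192 + 77), tolerance = 1e-12)
})

test_that("day-over-day burden deltas shrink and demand 48 h of data", {
  sim <- cached("oral_3day", simulate(default_model(),
                                      schedule = oral_schedule(days = 3),
                                      t_end = 72, dt = 0.1))
  d <- day_over_day_delta(sim)
  expect_length(d, 2)
  expect_true(all(d > 0))
  expect_true(all(diff(d) < 0))
  one_day <- simulate(default_model(), schedule = oral_schedule(days = 1),
                      t_end = 24, dt = 1)
  expect_error(day_over_day_delta(one_day), "48 h")
})
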