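test_that("the daily oral schedule splits meals in the stated ratios", {
  sched <- oral_schedule(days = 2)
  ev <- sched$events
  expect_equal(nrow(ev), 6)
  expect_equal(ev$start_h, c(8, 12, 18, 32, 36, 42))
  expect_equal(ev$amount_mg, rep(c(0.5, 0.8, 0.65), 2))
  expect_equal(ev$amount_mg[ev$start_h == 36], 0.8)
  expect_equal(unname(schedule_totals(sched)[["oral"]]), 2 * 1.95)
  expect_equal(nrow(oral_schedule(days = 0)$events), 0)
  expect_error(oral_schedule(meal_times = c(8, 12, 25)), "\\[0, 24\\)")
})

test_that("continuous infusions integrate to rate x duration", {
  expect_equal(unname(schedule_totals(continuous_dose("dermal", 0.68, 48))[["dermal"]]),
               0.68 * 48)  # 32.64 mg
  expect_equal(unname(schedule_totals(continuous_dose("inhalation", 0.53, 24))[["inhalation"]]),
               0.53 * 24)  # 12.72 mg
  expect_equal(unname(schedule_totals(continuous_dose("dermal", 0, 24))[["dermal"]]),
               0)
  expect_error(continuous_dose("dermal", -1, 24), "non-negative")
})

test_that("input rates are piecewise constant on half-open intervals", {
  sched <- oral_schedule(days = 1)
  expect_equal(unname(input_rate(sched, 8.25)[["oral"]]), 0.5 / 0.5)  # 1 mg/h
  expect_equal(unname(input_rate(sched, 10)[["oral"]]), 0)
  expect_equal(unname(input_rate(sched, 8)[["oral"]]), 1)    # closed start
  expect_equal(unname(input_rate(sched, 8.5)[["oral"]]), 0)  # open end
})

test_that("cumulative input matches declared totals and quadrature", {
  sched <- combine_schedules(oral_schedule(days = 2),
                             continuous_dose("dermal", 0.68, 48),
                             continuous_dose("inhalation", 0.53, 48))
  totals <- schedule_totals(sched)
  cum <- cumulative_input(sched, 48)
  expect_equal(cum, totals, tolerance = 1e-12)
  # midpoint quadrature of the rate function agrees with the exact integral
  # (the grid is aligned with every event boundary, so the rule is exact)
  h <- 0.0125
  mids <- seq(h / 2, 48 - h / 2, by = h)
  rates <- vapply(mids, function(t) input_rate(sched, t), numeric(3))
  for (r in c("oral", "dermal", "inhalation")) {
    expect_equal(sum(rates[r, ]) * h, unname(totals[[r]]), tolerance = 1e-9)
  }
  # rates are sums: event order cannot matter
  shuffled <- sched
  shuffled$events <- shuffled$events[rev(seq_len(nrow(shuffled$events))), ]
  expect_equal(input_rate(shuffled, 8.25), input_rate(sched, 8.25))
})
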