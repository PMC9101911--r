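test_that("the Michaelis-Menten rate law obeys its defining identities", {
  expect_equal(michaelis_menten_rate(100, vmax_scaled = 50, km = 100), 25)
  expect_equal(michaelis_menten_rate(1e12, vmax_scaled = 50, km = 100), 50,
               tolerance = 1e-9)
  expect_equal(michaelis_menten_rate(0, vmax_scaled = 50, km = 100), 0)
  expect_equal(michaelis_menten_rate(123, vmax_scaled = 0, km = 0), 0)
})

test_that("the integrator matches the one-compartment analytic solution", {
  # constant infusion R into volume V with first-order loss k:
  # C(t) = (R / (k V)) (1 - exp(-k t))
  R <- 120; k <- 0.8; V <- 5
  rhs_factory <- function(t_mid) function(t, y, parms) list(R - k * y)
  times <- seq(0, 20, by = 0.1)
  out <- dehptk:::integrate_segments(c(A = 0), times, breaks = c(0, 20),
                                     rhs_factory, rtol = 1e-10, atol = 1e-12)
  C_num <- out[, "A"] / V
  C_ref <- (R / (k * V)) * (1 - exp(-k * times))
  rel <- abs(C_num[-1] - C_ref[-1]) / C_ref[-1]
  expect_lt(max(rel), 1e-6)
})

test_that("zero input leaves the state identically zero", {
  sim <- simulate(default_model(), schedule = NULL, t_end = 12, dt = 0.5)
  expect_true(all(sim$amounts == 0))
  expect_equal(mass_balance(sim)$worst_residual, 0)
})

test_that("disabling sinks reduces the system to its conservation limits", {
  mod <- default_model()
  sched <- oral_schedule(days = 1)
  # no metabolism: DEHP mass in body equals cumulative input, no MEHP forms
  sim <- simulate(mod, schedule = sched, t_end = 24, dt = 0.5,
                  metabolism = FALSE)
  dehp_cols <- grep("^DEHP_", colnames(sim$amounts), value = TRUE)
  total_dehp <- rowSums(sim$amounts[, dehp_cols]) + sim$amounts[, "lumen_DEHP"]
  input_ug <- rowSums(cumulative_input(sched, sim$time)) * 1000
  expect_equal(total_dehp, input_ug, tolerance = 1e-8)
  expect_true(all(sim$amounts[, grep("^MEHP_", colnames(sim$amounts))] == 0))
  # no urinary elimination: urine stays empty while metabolism proceeds
  sim2 <- simulate(mod, schedule = sched, t_end = 24, dt = 0.5,
                   urinary_elimination = FALSE)
  expect_true(all(sim2$amounts[, "urine_MEHP"] == 0))
  expect_gt(utils::tail(sim2$amounts[, "sink_MEHP"], 1), 0)
})

test_that("a dosed run conserves moles and stays non-negative", {
  sim <- oral_2day_coarse()
  mb <- mass_balance(sim)
  expect_lt(mb$worst_residual, 1e-6)
  expect_true(all(sim$amounts >= -1e-9))
  sim_d <- dermal_2day_coarse()
  expect_lt(mass_balance(sim_d)$worst_residual, 1e-6)
  expect_true(all(sim_d$amounts >= -1e-9))
})

test_that("frozen-arterial tissues equilibrate to Kp times arterial conc", {
  mod <- default_model()
  c_art <- c(DEHP = 0.5, MEHP = 2)
  sim <- simulate(mod, schedule = NULL, t_end = 100, dt = 2,
                  metabolism = FALSE, urinary_elimination = FALSE,
                  frozen_arterial = c_art)
  for (sp in c("DEHP", "MEHP")) {
    for (o in mod$organs[[sp]]) {
      expect_equal(utils::tail(get_concentration(sim, o, sp), 1),
                   mod$kp[[sp]][[o]] * c_art[[sp]], tolerance = 1e-3)
    }
  }
})
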