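test_that("tabulated parameter medians are returned verbatim", {
  chem <- default_chemistry()
  expect_equal(chem$species$DEHP$molecular_weight, 391)
  expect_equal(chem$species$DEHP$logKow, 7.6)
  expect_equal(unname(chem$species$DEHP$kp[c("gut", "liver", "fat", "rest")]),
               c(12.86, 10.16, 188, 6.24))
  expect_equal(unname(chem$species$MEHP$kp[c("liver", "fat", "rest")]),
               c(1.7, 0.12, 0.38))
  expect_equal(chem$species$MEHP$fup, 0.007)
  expect_equal(chem$kinetics$kgut, 7)
  expect_equal(chem$kinetics$kurine, 0.35)
  rx <- chem$reactions
  expect_equal(rx$km[rx$id == "liver_M2"], 7980.4)
  expect_equal(rx$vmax[rx$id == "gut_M3"], 0)
  expect_equal(rx$km[rx$id == "gut_M3"], 0)
  expect_equal(rx$vmax[rx$id == "gut_M5"], 0.285)
  # deuterated bookkeeping is opt-in
  expect_equal(default_chemistry(mehp_mw = 281)$species$MEHP$molecular_weight,
               281)
  # unlisted organs fall back to the species rest-of-body Kp
  expect_equal(partition_coefficient(chem, "DEHP", "kidney"), 6.24)
  expect_equal(partition_coefficient(chem, "MEHP", "gut"), 0.38)
})

test_that("invalid parameter sets are rejected at load time", {
  chem <- default_chemistry()
  chem$reactions$km[chem$reactions$id == "gut_M3"] <- 0
  chem$reactions$vmax[chem$reactions$id == "gut_M3"] <- 1  # Km 0, Vmax > 0
  expect_error(validate_chemistry(chem), "Km = 0")
  chem2 <- default_chemistry()
  chem2$species$MEHP$fup <- 1.5
  expect_error(validate_chemistry(chem2), "fup")
})

test_that("whole-organ Vmax scaling follows the protein-mass chain", {
  chem <- default_chemistry()
  phys <- build_default_physiology()
  vmax <- scale_metabolic_capacity(chem, phys)
  # per-mg rate x 60 min/h x mg protein per g x organ grams
  expect_equal(vmax[["liver_msp_M1"]], 0.112 * 60 * 40 * 1690)
  expect_equal(vmax[["gut_msp_M1"]], 0.11 * 60 * 3 * 1650)
  expect_equal(vmax[["gut_M3"]], 0)
  phys2 <- build_default_physiology(overrides = list(liver =
                                                       list(volume_mL = 3380)))
  vmax2 <- scale_metabolic_capacity(chem, phys2)
  expect_equal(vmax2[["liver_msp_M1"]], 2 * vmax[["liver_msp_M1"]])
  chem_bad <- chem
  chem_bad$protein <- chem$protein[c("liver_msp", "liver_cyt")]
  expect_error(scale_metabolic_capacity(chem_bad, phys), "gut")
})

test_that("the parameter set round-trips through serialization exactly", {
  chem <- default_chemistry()
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(reactions = chem$reactions,
                            kinetics = chem$kinetics,
                            lognormal = chem$lognormal),
                       path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$reactions$vmax, chem$reactions$vmax)
  expect_identical(back$reactions$km, chem$reactions$km)
  expect_equal(back$kinetics$kgut, chem$kinetics$kgut)
  expect_identical(back$lognormal$median, chem$lognormal$median)
})

test_that("lognormal sampler honours medians, truncation and the seed", {
  chem <- default_chemistry()
  draws <- sample_parameters(chem, n = 20000, seed = 42)
  expect_equal(nrow(draws), 20000)
  med <- apply(draws, 2, median)
  spec <- chem$lognormal
  expect_true(all(abs(med - spec$median) / spec$median < 0.03))
  # all draws inside the +/-1.5 geometric-SD truncation range
  for (j in seq_len(nrow(spec))) {
    lo <- spec$median[j] * spec$sd_factor[j]^-1.5
    hi <- spec$median[j] * spec$sd_factor[j]^1.5
    expect_true(all(draws[, j] >= lo & draws[, j] <= hi))
  }
  expect_true(all(draws > 0))
  expect_identical(sample_parameters(chem, n = 50, seed = 7),
                   sample_parameters(chem, n = 50, seed = 7))
  # degenerate dispersion collapses every draw onto the median
  chem$lognormal$sd_factor[] <- 1
  flat <- sample_parameters(chem, n = 10, seed = 1)
  expect_equal(unname(flat), matrix(rep(chem$lognormal$median, each = 10),
                                    nrow = 10), tolerance = 1e-12)
  expect_error(sample_parameters(chem, n = 0), "positive")
})
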