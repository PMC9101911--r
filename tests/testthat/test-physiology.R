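test_that("default physiology carries the reference organ volumes", {
  phys <- build_default_physiology()
  vol <- setNames(phys$compartments$volume_mL, phys$compartments$name)
  expect_equal(vol[["liver"]], 1690)
  expect_equal(vol[["venous_blood"]], 3396)
  expect_equal(vol[["thymus"]], 29)
  expect_equal(vol[["urine"]], 1)
  expect_equal(vol[["muscle"]], 35000)
  expect_equal(sum(vol), 108903)
  expect_true(all(vol > 0))
})

test_that("perfused-organ flow fractions sum to one and the graph balances", {
  phys <- build_default_physiology()
  comp <- phys$compartments
  perfused <- comp$name %in% setdiff(comp$name[comp$flow_fraction > 0 |
                                                 comp$name == "lungs"],
                                     "lungs")
  expect_equal(sum(comp$flow_fraction), 1, tolerance = 1e-12)
  top <- validate_topology(phys)
  expect_true(top$ok)
  expect_equal(unname(top$residuals), c(0, 0, 0))
})

test_that("a mutated gut flow surfaces as the liver-node residual", {
  phys <- build_default_physiology()
  q_gut <- phys$cardiac_output *
    phys$compartments$flow_fraction[phys$compartments$name == "gut"]
  phys$compartments$flow_fraction[phys$compartments$name == "gut"] <-
    2 * phys$compartments$flow_fraction[phys$compartments$name == "gut"]
  top <- validate_topology(phys)
  expect_false(top$ok)
  expect_equal(unname(top$residuals[["liver"]]), q_gut)
})

test_that("missing venous drainage is a topology error naming the organ", {
  phys <- build_default_physiology()
  phys$drains_to <- phys$drains_to[names(phys$drains_to) != "kidney"]
  expect_error(validate_topology(phys), "kidney")
})

test_that("overrides are schema-checked and body-weight scaling is linear", {
  expect_error(build_default_physiology(overrides = list(gallbladder =
                                                           list(volume_mL = 10))),
               "gallbladder")
  expect_error(build_default_physiology(overrides = list(liver =
                                                           list(vol = 10))),
               "vol")
  phys <- build_default_physiology(overrides = list(liver =
                                                      list(volume_mL = 2000)))
  expect_equal(phys$compartments$volume_mL[phys$compartments$name == "liver"],
               2000)
  scaled <- build_default_physiology(body_weight = 90, scale_volumes = TRUE)
  expect_equal(scaled$compartments$volume_mL[scaled$compartments$name == "liver"],
               1690 * 90 / 60)
  # the urine accumulator stays at 1 mL regardless of body size
  expect_equal(scaled$compartments$volume_mL[scaled$compartments$name == "urine"],
               1)
})
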