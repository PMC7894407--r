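test_that("exchange flux matches the hand-computed chamber mass balance", {
  # Delta VMR = 2 ppbv, Q = 20 L/min, LA = 0.1 m2, 298 K, 101325 Pa:
  # air molar flow 0.01363 mol/s -> |flux| = 0.273 nmol m-2 s-1
  sc <- quiet_scenario(temperature = 298)
  ser <- gen_enclosure_series(sc)
  col <- "vmr_ISOPOOH_12"
  bg <- mean(ser[[col]][ser$phase == "background"])
  ser[[col]][ser$phase == "plant"] <- bg - 2
  fl <- compute_flux(ser, "ISOPOOH_12")
  expect_equal(fl$flux, c(-0.2726, -0.2726), tolerance = 1e-3)

  # outlet equal to background -> zero flux
  ser[[col]][ser$phase == "plant"] <- bg
  expect_equal(compute_flux(ser, "ISOPOOH_12")$flux, c(0, 0))

  # halving the leaf area doubles |flux|
  ser2 <- ser
  ser2[[col]][ser2$phase == "plant"] <- bg - 2
  ser3 <- ser2
  ser3$leaf_area <- ser3$leaf_area / 2
  expect_equal(compute_flux(ser3, "ISOPOOH_12")$flux,
               2 * compute_flux(ser2, "ISOPOOH_12")$flux)

  expect_error(compute_flux(ser[ser$phase != "background", ], "ISOPOOH_12"),
               "background")
})

test_that("deposition velocity is -flux/concentration with the right sign", {
  # mass-unit view: -0.12 ug cm-2 s-1 over 1 ug cm-3 -> 0.12 cm s-1
  expect_equal(compute_deposition_velocity(-0.12, 1, units = "mass_cgs"),
               0.12)
  expect_equal(compute_deposition_velocity(0, 1), 0)
  expect_error(compute_deposition_velocity(-1, 0), "undefined")

  # deposition => flux < 0 and vd > 0 simultaneously, every phase
  ser <- gen_enclosure_series(enclosure_scenario(noise_cv = 0.02, seed = 4))
  fl <- compute_flux(ser, "ISOPOOH_12")
  vd <- enclosure_vd(ser, "ISOPOOH_12")
  expect_true(all(fl$flux < 0))
  expect_true(all(vd$vd > 0))
})

test_that("enclosure pipeline recovers the generator's deposition velocities", {
  # noise-free consistency to 1e-6 relative (no wall loss)
  ser0 <- gen_enclosure_series(quiet_scenario())
  vd0 <- enclosure_vd(ser0, "ISOPOOH_12")
  expect_equal(vd0$vd[vd0$condition == "light"], 0.79, tolerance = 1e-6)
  expect_equal(vd0$vd[vd0$condition == "dark"], 0.12, tolerance = 1e-6)

  # measured-noise conditions: within 5% of truth
  ser <- gen_enclosure_series(enclosure_scenario(noise_cv = 0.02,
                                                 n_replicates = 5, seed = 2))
  vd <- enclosure_vd(ser, "ISOPOOH_12")
  expect_equal(vd$vd[vd$condition == "light"], 0.79, tolerance = 0.05)
  expect_equal(vd$vd[vd$condition == "dark"], 0.12, tolerance = 0.05)
})

test_that("conversion yields are recovered, scale-invariant, and guarded", {
  ser <- gen_enclosure_series(enclosure_scenario(noise_cv = 0.02, seed = 8))
  y_mvk <- estimate_conversion_yield(ser, "ISOPOOH_12", "MVK", "light")
  y_mek <- estimate_conversion_yield(ser, "ISOPOOH_12", "MEK", "light")
  expect_equal(y_mvk$yield, 0.5, tolerance = 0.05)
  expect_equal(y_mek$yield, 0.5, tolerance = 0.05)

  # multiplying every mixing ratio by a constant leaves yields unchanged
  ser2 <- ser
  for (cl in grep("^vmr_", names(ser2), value = TRUE))
    ser2[[cl]] <- ser2[[cl]] * 3.7
  y2 <- estimate_conversion_yield(ser2, "ISOPOOH_12", "MVK", "light")
  expect_equal(y2$yield, y_mvk$yield, tolerance = 1e-12)

  # 4,3-isomer scenario: MACR produced, no MEK
  sc43 <- enclosure_scenario(parent = "ISOPOOH_43",
                             yield_map = c(MACR = 1.0, MEK = 0.0),
                             noise_cv = 0.02, seed = 9)
  ser43 <- gen_enclosure_series(sc43)
  # noise can push a complete-conversion estimate above 1; it is flagged
  y_macr <- suppressWarnings(
    estimate_conversion_yield(ser43, "ISOPOOH_43", "MACR", "light"))
  y_mek43 <- estimate_conversion_yield(ser43, "ISOPOOH_43", "MEK", "light")
  expect_equal(y_macr$yield, 1.0, tolerance = 0.05)
  expect_equal(y_mek43$yield, 0, tolerance = 0.01)

  # a non-depositing parent has no defined yield
  serf <- gen_enclosure_series(quiet_scenario(true_vd_day = 0,
                                              true_vd_night = 0))
  expect_error(estimate_conversion_yield(serf, "ISOPOOH_12", "MVK"),
               "net-deposit")
})

test_that("estimator bias is below 2% of truth at measurement noise", {
  sc <- enclosure_scenario(noise_cv = 0.02, n_replicates = 200, seed = 42)
  ser <- gen_enclosure_series(sc)
  vd <- enclosure_vd(ser, "ISOPOOH_12")
  expect_lt(abs(vd$vd[vd$condition == "light"] - 0.79) / 0.79, 0.02)
  expect_lt(abs(vd$vd[vd$condition == "dark"] - 0.12) / 0.12, 0.02)
  y <- estimate_conversion_yield(ser, "ISOPOOH_12", "MVK", "light")
  expect_lt(abs(y$yield - 0.5) / 0.5, 0.02)
})

test_that("box statistics use linear quantile interpolation", {
  s <- summarize_boxstats(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  s4 <- summarize_boxstats(c(1, 2, 3, 4))
  expect_equal(s4$q25, 1.75)
  expect_equal(s4$q75, 3.25)
  s1 <- summarize_boxstats(7)
  expect_true(all(unlist(s1) == 7))
  expect_error(summarize_boxstats(numeric(0)), "empty")
})
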