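test_that("generators are deterministic per seed", {
  a <- gen_enclosure_series(enclosure_scenario(seed = 12))
  b <- gen_enclosure_series(enclosure_scenario(seed = 12))
  c <- gen_enclosure_series(enclosure_scenario(seed = 13))
  expect_identical(a, b)
  expect_false(identical(a$vmr_ISOPOOH_12, c$vmr_ISOPOOH_12))

  e1 <- gen_ec_series(ec_scenario(seed = 3))
  e2 <- gen_ec_series(ec_scenario(seed = 3))
  expect_identical(e1, e2)

  t1 <- gen_assay_traces(small_assay(seed = 5))
  t2 <- gen_assay_traces(small_assay(seed = 5))
  expect_identical(t1, t2)

  g1 <- gen_budget_fields(4, 5, budget_inputs(), seed = 6)
  g2 <- gen_budget_fields(4, 5, budget_inputs(), seed = 6)
  expect_identical(g1, g2)
})

test_that("enclosure generator respects the chamber mass balance", {
  # zero deposition, zero noise: plant outlet equals background outlet
  ser <- gen_enclosure_series(quiet_scenario(true_vd_day = 0,
                                             true_vd_night = 0))
  bg <- mean(ser$vmr_ISOPOOH_12[ser$phase == "background"])
  expect_equal(ser$vmr_ISOPOOH_12[ser$phase == "plant"],
               rep(bg, sum(ser$phase == "plant")))

  # steady state is independent of the chamber volume at fixed flow and vd
  s1 <- gen_enclosure_series(quiet_scenario(chamber_volume = 45))
  s2 <- gen_enclosure_series(quiet_scenario(chamber_volume = 90))
  expect_equal(s1$vmr_ISOPOOH_12, s2$vmr_ISOPOOH_12)

  # conservation at zero noise: parent moles lost = product gained / yield
  ser0 <- gen_enclosure_series(quiet_scenario())
  bg0 <- mean(ser0$vmr_ISOPOOH_12[ser0$phase == "background"])
  for (cond in c("dark", "light")) {
    sel <- ser0$phase == "plant" & ser0$light == cond
    lost <- bg0 - mean(ser0$vmr_ISOPOOH_12[sel])
    gained_mvk <- mean(ser0$vmr_MVK[sel])
    gained_mek <- mean(ser0$vmr_MEK[sel])
    expect_equal(gained_mvk / 0.5, lost, tolerance = 1e-6)
    expect_equal(gained_mek / 0.5, lost, tolerance = 1e-6)
  }

  # all generated mixing ratios finite and nonnegative
  sern <- gen_enclosure_series(enclosure_scenario(noise_cv = 0.05, seed = 1))
  vmrs <- unlist(sern[grep("^vmr_", names(sern))])
  expect_true(all(is.finite(vmrs) & vmrs >= 0))

  expect_error(enclosure_scenario(flow = -1), "> 0")
  expect_error(enclosure_scenario(yield_map = c(MVK = 0.7, MEK = 0.7)),
               "sum")
})

test_that("EC generator embeds the prescribed covariance and lag", {
  # zero flux: covariance of w and c is zero within 3 standard errors
  sc0 <- ec_scenario(true_flux = c(isoprene = 0),
                     mean_vmr = c(isoprene = 2), seed = 21)
  s0 <- gen_ec_series(sc0)
  n <- nrow(s0)
  cv <- stats::cov(s0$w, s0$vmr_isoprene)
  se <- stats::sd(s0$w) * stats::sd(s0$vmr_isoprene) / sqrt(n / 20)
  expect_lt(abs(cv), 3 * se)

  # wind is zero-mean with the requested standard deviation
  sc <- ec_scenario(duration = 3600, seed = 22)
  s <- gen_ec_series(sc)
  expect_lt(abs(mean(s$w)), 0.05)
  expect_equal(stats::sd(s$w), 0.3, tolerance = 0.1)

  # constructed shift is recovered exactly at zero noise
  scl <- ec_scenario(true_flux = c(isoprene = 10),
                     mean_vmr = c(isoprene = 2), lag_samples = 15L,
                     noise_cv = 0, seed = 23)
  sl <- gen_ec_series(scl)
  expect_identical(find_lag(sl$w, sl$vmr_isoprene, max_lag = 50)$lag, 15L)

  expect_error(ec_scenario(duration = 1, lag_samples = 100L), "lag")
})

test_that("assay generator produces the prescribed initial slopes", {
  # vmax = 0: flat traces before noise
  tr0 <- gen_assay_traces(small_assay(vmax = 0, absorbance_noise_sd = 0))
  by_trace <- split(tr0, tr0$trace_id)
  expect_true(all(vapply(by_trace, function(d)
    diff(range(d$absorbance)) == 0, logical(1))))

  # saturation limit: slope -> -eps * vmax * path
  trs <- gen_assay_traces(small_assay(vmax = 0.02, substrate_grid = 1e6,
                                      cofactor_grid = 1e6,
                                      absorbance_noise_sd = 0))
  d <- trs[trs$trace_id == 1, ]
  slope <- stats::coef(stats::lm(absorbance ~ time, d))[2]
  expect_equal(unname(slope), -6.22 * 0.02, tolerance = 1e-4)

  expect_error(assay_scenario(km_mvk = -1), "> 0")
})

test_that("gridded deposition fields sum exactly to the requested totals", {
  bi <- budget_inputs(dep_mvk = 3.7, dep_isopooh = 8.8)
  g1 <- gen_budget_fields(1, 1, bi, seed = 2)
  expect_equal(g1$dep_mvk, 3.7)
  expect_equal(g1$dep_isopooh, 8.8)

  g <- gen_budget_fields(4, 5, bi, seed = 2)
  expect_equal(nrow(g), 20)
  expect_true(all(g$dep_mvk >= 0 & g$dep_isopooh >= 0))
  expect_equal(sum(g$dep_mvk), 3.7, tolerance = 1e-12)
  expect_equal(sum(g$dep_isopooh), 8.8, tolerance = 1e-12)

  expect_error(gen_budget_fields(0, 1, bi), ">= 1")
})
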