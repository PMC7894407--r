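test_that("leaf box conserves carbon and shuts exchange off without pathways", {
  p <- leaf_box_params()
  st <- leafbox_init(c(ISOPOOH_12 = 8), p)
  c0 <- leafbox_carbon_inventory(st, p)
  r <- leafbox_step(st, p, light = TRUE, duration = 3600)
  expect_lt(abs(leafbox_carbon_inventory(r$state, p) - c0) / abs(c0), 1e-6)
  # carry on in the dark: still closed
  r2 <- leafbox_step(r$state, p, light = FALSE, duration = 3600)
  expect_lt(abs(leafbox_carbon_inventory(r2$state, p) - c0) / abs(c0), 1e-6)

  # no stomatal or cuticular pathway: outlet equals inlet, vd = 0
  p0 <- leaf_box_params(gs_day = 0, gs_night = 0, g_cuticle = 0)
  ser <- simulate_fumigation(p0, light_program = data.frame(
    light = c("dark", "light"), duration = c(3600, 3600)))
  vd <- enclosure_vd(ser, "ISOPOOH_12")
  expect_equal(vd$vd, c(0, 0), tolerance = 1e-8)
})

test_that("a conservative tracer equilibrates and net uptake decays", {
  # reactions off: ISOPOOH accumulates toward Henry equilibrium and the
  # aqueous phase approaches c_aq = H* p at steady state
  p <- leaf_box_params(k_fenton = 0,
                       aor = kinetic_parameters(vmax = 0),
                       apoplast_volume_per_area = 1e-5)
  st <- leafbox_init(c(ISOPOOH_12 = 8), p)
  r <- leafbox_step(st, p, inlet_vmr = c(ISOPOOH_12 = 8), light = TRUE,
                    duration = 2e5, dt_out = 5e3)
  gas <- r$state[["gas_ISOPOOH_12"]]
  aq_molar <- r$state[["aq_ISOPOOH_12"]] / 1000        # mM -> M
  p_atm <- gas * 8.31446 * p$temperature / 101325
  expect_equal(aq_molar / (1.7e6 * p_atm), 1, tolerance = 1e-3)
  # net uptake has collapsed: late outlet is close to the inlet
  late <- utils::tail(r$outlet_vmr$ISOPOOH_12, 1)
  expect_equal(late, 8, tolerance = 0.01)
})

test_that("integration errors surface rather than clamping", {
  p <- leaf_box_params()
  st <- leafbox_init(c(ISOPOOH_12 = 8), p)
  st[["gas_ISOPOOH_12"]] <- -1
  expect_error(suppressWarnings(leafbox_step(st, p, duration = 10)),
               "negative|failed")
  expect_error(leafbox_step(leafbox_init(params = p), p, duration = -5),
               "> 0")
})

test_that("solubility asymmetry: ISOPOOH barely re-volatilises, MVK does", {
  p <- leaf_box_params(k_fenton = 0.02,
                       aor = kinetic_parameters(vmax = 80))
  ser <- simulate_fumigation(p, light_program = data.frame(
    light = "light", duration = 7200))
  st <- attr(ser, "final_state")
  reg <- species_registry(c("ISOPOOH_12", "MVK"))
  g <- (p$gs_day + p$g_cuticle) / 100
  ceq <- function(sp, h) st[[paste0("aq_", sp)]] / 1000 / h *
    101325 / (8.31446 * p$temperature)
  revol_iso <- g * ceq("ISOPOOH_12", 1.7e6)
  uptake_iso <- g * (st[["gas_ISOPOOH_12"]] - ceq("ISOPOOH_12", 1.7e6))
  revol_mvk <- g * ceq("MVK", 44)
  expect_lt(revol_iso / uptake_iso, 0.01)
  # MVK re-volatilisation carries a substantial share of the Fenton output
  fenton <- p$k_fenton * st[["aq_ISOPOOH_12"]] *
    p$apoplast_volume_per_area * p$leaf_area * 1e-3
  expect_gt(revol_mvk * p$leaf_area / fenton, 0.2)
})

test_that("exchange is monotone in the controlling parameters", {
  base <- leaf_box_params(k_fenton = 0.02,
                          aor = kinetic_parameters(vmax = 80))
  tgt <- function(p) ovocflux:::.leafbox_forward_targets(
    p, phase_s = 5400, dt_out = 180)
  t_base <- tgt(base)
  # vd(ISOPOOH) nondecreasing in stomatal conductance
  hi_gs <- base; hi_gs$gs_day <- base$gs_day * 2
  expect_gt(tgt(hi_gs)[["vd_day"]], t_base[["vd_day"]])
  # MEK yield nondecreasing in AOR vmax
  hi_v <- base
  hi_v$aor <- kinetic_parameters(160, base$aor$km_mvk, base$aor$km_nadph)
  expect_gt(tgt(hi_v)[["yield_mek"]], t_base[["yield_mek"]])
  # forcing a zero MEK target drives the calibrated vmax toward zero
  lo_v <- base
  lo_v$aor <- kinetic_parameters(1e-6, base$aor$km_mvk, base$aor$km_nadph)
  expect_lt(tgt(lo_v)[["yield_mek"]], 0.01)
})

test_that("stomatal stress closure reproduces the qualitative enclosure pattern", {
  aor <- kinetic_parameters(vmax = 80)
  off <- leaf_box_params(k_fenton = 0.02, aor = aor)
  inert <- leaf_box_params(k_fenton = 0.02, aor = aor,
                           stress = list(threshold = Inf, floor = 0.1,
                                         hill = 4))
  floor_on <- leaf_box_params(k_fenton = 0.02, aor = aor,
                              stress = list(threshold = 0, floor = 0.1,
                                            hill = 4))
  st <- leafbox_init(c(ISOPOOH_12 = 8), off)
  r_off <- leafbox_step(st, off, light = TRUE, duration = 3600)
  r_inf <- leafbox_step(st, inert, light = TRUE, duration = 3600)
  expect_equal(r_inf$state, r_off$state, tolerance = 1e-10)

  # threshold 0: stomata at the floor throughout, vd near cuticular-only
  ser0 <- simulate_fumigation(floor_on, light_program = data.frame(
    light = "light", duration = 5400))
  vd0 <- enclosure_vd(ser0, "ISOPOOH_12")
  expect_lt(vd0$vd, (0.1 * off$gs_day + off$g_cuticle) * 1.2)

  # default threshold: outlet dips with uptake, then rises upon closure
  mid <- leaf_box_params(k_fenton = 0.02, aor = aor,
                         stress = list(threshold = 2, floor = 0.05,
                                       hill = 4))
  r_mid <- leafbox_step(leafbox_init(c(ISOPOOH_12 = 8), mid), mid,
                        light = TRUE, duration = 2e4, dt_out = 100)
  traj <- r_mid$outlet_vmr$ISOPOOH_12
  i_min <- which.min(traj)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(traj))
  expect_gt(utils::tail(traj, 1), min(traj) + 0.1)
})

test_that("calibration reproduces its own forward targets", {
  cal <- calibrate_leafbox(targets = c(vd_day = 0.5, vd_night = 0.08,
                                       yield_mvk = 0.6, yield_mek = 0.4),
                           maxit = 120)
  expect_lt(cal$residual, 1e-4)
  expect_true(cal$feasible)
  expect_error(calibrate_leafbox(targets = c(vd_day = 0.1, vd_night = 0.5,
                                             yield_mvk = 0.5,
                                             yield_mek = 0.5)),
               "vd_day")
})
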