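# Dynamic two-compartment leaf box model: well-mixed chamber gas phase and
# leaf apoplast liquid phase, coupled by stomatal + cuticular conductance
# and Henry's-law partitioning. In the liquid, 1,2-ISOPOOH decomposes by a
# first-order Fenton-type step to MVK (+ HCHO, retained), and AOR reduces
# MVK to MEK with NADPH-limited Michaelis-Menten kinetics. Integrated with
# deSolve (stiff-capable lsoda).

.LB_SPECIES <- c("ISOPOOH_12", "MVK", "MEK")   # gas-exchanged species
# carbon atoms per molecule, for the conservation oracle
.LB_CARBON <- c(ISOPOOH_12 = 5, MVK = 4, MEK = 4, HCHO = 1)

#' Leaf box model parameters
#'
#' @param chamber_volume enclosure volume, L.
#' @param flow through-flow, L min-1.
#' @param leaf_area single-sided leaf area, m2.
#' @param apoplast_volume_per_area apoplast water volume per leaf area,
#'   L m-2.
#' @param gs_day,gs_night stomatal conductance by light state, cm s-1.
#' @param g_cuticle cuticular conductance (parallel pathway), cm s-1.
#' @param k_fenton first-order Fenton-type ISOPOOH -> MVK + HCHO rate in
#'   the liquid, s-1.
#' @param aor a [kinetic_parameters()] object for the MVK -> MEK step
#'   (vmax in mM min-1 of apoplast liquid).
#' @param nadph_day,nadph_night NADPH pool by light state, mM (held
#'   constant; dark default 0 switches the AOR step off).
#' @param temperature leaf/chamber temperature, K.
#' @param stress optional stomatal stress-closure feature: a list with
#'   `threshold` (accumulated apoplast ISOPOOH dose, mM s, beyond which
#'   stomata close; oxidative damage integrates rather than tracking the
#'   instantaneous load), `floor` (residual fraction of gs, in \[0,1\])
#'   and `hill` (steepness exponent). `NULL` disables the feature.
#' @return object of class `leaf_box_params`.
#' @export
leaf_box_params <- function(chamber_volume = 45, flow = 20, leaf_area = 0.1,
                            apoplast_volume_per_area = 0.05,
                            gs_day = 0.67, gs_night = 0, g_cuticle = 0.12,
                            k_fenton = 0.01,
                            aor = kinetic_parameters(vmax = 150),
                            nadph_day = 0.15, nadph_night = 0,
                            temperature = 298.15, stress = NULL) {
  if (chamber_volume <= 0 || flow <= 0 || leaf_area < 0 ||
      apoplast_volume_per_area <= 0)
    stop("volumes, flow and areas must be positive")
  if (gs_day < 0 || gs_night < 0 || g_cuticle < 0)
    stop("conductances must be >= 0")
  if (k_fenton < 0) stop("k_fenton must be >= 0")
  stopifnot(inherits(aor, "kinetic_parameters"))
  if (!is.null(stress)) {
    stopifnot(is.list(stress),
              all(c("threshold", "floor", "hill") %in% names(stress)))
    if (stress$floor < 0 || stress$floor > 1)
      stop("stress floor must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "leaf_box_params")
}

# stomatal closure factor in [floor, 1], smooth in the accumulated
# apoplast ISOPOOH dose (oxidative damage integrates; closure does not
# reverse when the instantaneous load falls)
.stress_factor <- function(dose, stress) {
  if (is.null(stress)) return(1)
  if (!is.finite(stress$threshold)) return(1)
  if (stress$threshold <= 0) return(stress$floor)
  x <- (max(dose, 0) / stress$threshold)^stress$hill
  stress$floor + (1 - stress$floor) / (1 + x)
}

# derivative function; state units: gas mol m-3, aqueous mol m-3 (== mM),
# cumulative mol, dose mM s. 'light' fixed per phase.
.leafbox_deriv <- function(t, y, p) {
  gas <- y[1:3]; aq <- y[4:6]; aq_hcho <- y[7]
  V <- p$chamber_volume * 1e-3            # m3
  Q <- p$flow / 1000 / 60                 # m3 s-1
  Vaq <- p$apoplast_volume_per_area * p$leaf_area * 1e-3  # m3
  gs <- (if (p$light) p$gs_day else p$gs_night) / 100     # m s-1
  gs <- gs * .stress_factor(y[14], p$stress)
  g <- gs + p$g_cuticle / 100             # total conductance, m s-1
  # gas-phase concentration in equilibrium with the liquid:
  # p_atm = c_aq[M] / H*;  c_eq = p_atm * 101325 / (R T)
  c_eq <- (aq / 1000) / p$henry * .ATM_PA / (.R_GAS * p$temperature)
  uptake <- g * p$leaf_area * (gas - c_eq)          # mol s-1, into the leaf
  dgas <- (Q * (p$c_in - gas) - uptake) / V
  fenton <- p$k_fenton * aq[1]                      # mol m-3 s-1
  nadph <- if (p$light) p$nadph_day else p$nadph_night
  aor <- aor_rate(p$aor, mvk = aq[2], nadph = nadph,
                  temperature = p$temperature - 273.15) / 60  # mM/min -> mM/s
  daq <- uptake / Vaq + c(-fenton, fenton - aor, aor)
  daq_hcho <- fenton
  dcum_in <- Q * p$c_in
  dcum_out <- Q * gas
  ddose <- aq[1]                                    # mM s accumulated
  list(c(dgas, daq, daq_hcho, dcum_in, dcum_out, ddose))
}

#' Advance the leaf box model
#'
#' Integrates the coupled chamber/apoplast mass balance over `duration`
#' seconds at a fixed light state. The chamber balance is
#' \eqn{V\,dC/dt = Q(c_{in} - C) - g A (C - C_{eq})} with
#' \eqn{C_{eq} = c_{aq}/H^*} (converted through the ideal-gas law); the
#' liquid balance carries the uptake, the first-order Fenton conversion
#' (ISOPOOH -> MVK + HCHO, 1:1:1 molar), the AOR reduction (MVK -> MEK,
#' zero in the dark through the NADPH pool) and re-volatilisation.
#' Cumulative inflow and outflow moles are carried so mass closure can be
#' audited.
#'
#' @param state named state as returned by [leafbox_init()] or a previous
#'   call; gas mixing ratios internal units are mol m-3.
#' @param params a [leaf_box_params()].
#' @param inlet_vmr named inlet mixing ratios, ppbv (names among
#'   `ISOPOOH_12`, `MVK`, `MEK`; absent = 0).
#' @param light logical, stomata open / NADPH available.
#' @param duration integration time, s.
#' @param dt_out output time step, s.
#' @param rtol,atol integration tolerances.
#' @return list: `state` (final state vector), `times`, `trajectory`
#'   (deSolve matrix), `outlet_vmr` (data.frame of outlet ppbv per output
#'   time).
#' @export
leafbox_step <- function(state, params, inlet_vmr = c(ISOPOOH_12 = 8),
                         light = TRUE, duration = 3600, dt_out = 60,
                         rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "leaf_box_params"))
  if (duration <= 0) stop("duration must be > 0")
  reg <- species_registry(.LB_SPECIES)
  c_in <- vapply(.LB_SPECIES, function(sp) {
    v <- if (sp %in% names(inlet_vmr)) inlet_vmr[[sp]] else 0
    vmr_to_concentration(v, params$temperature, .ATM_PA)$mol_m3
  }, numeric(1))
  p <- c(params, list(henry = reg$henry_eff, c_in = c_in, light = light))
  times <- seq(0, duration, by = dt_out)
  sol <- deSolve::lsoda(y = state, times = times, func = .leafbox_deriv,
                        parms = p, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("leaf box integration failed (lsoda istate ",
         attr(sol, "istate")[1], ")")
  final <- sol[nrow(sol), -1]
  if (any(final < -1e4 * atol))
    stop("integration produced a negative state; reduce the step or ",
         "tolerances")
  outlet <- as.data.frame(sol[, 2:4])
  names(outlet) <- .LB_SPECIES
  for (sp in .LB_SPECIES)
    outlet[[sp]] <- concentration_to_vmr(outlet[[sp]], params$temperature)
  list(state = final, times = times, trajectory = sol, outlet_vmr = outlet)
}

#' Initial leaf box state
#'
#' @param gas_vmr named initial chamber mixing ratios, ppbv.
#' @param params a [leaf_box_params()] (for the temperature).
#' @return named state vector (gas mol m-3; aqueous mM; cumulative mol).
#' @export
leafbox_init <- function(gas_vmr = c(ISOPOOH_12 = 0), params) {
  gas <- vapply(.LB_SPECIES, function(sp) {
    v <- if (sp %in% names(gas_vmr)) gas_vmr[[sp]] else 0
    vmr_to_concentration(v, params$temperature)$mol_m3
  }, numeric(1))
  stats::setNames(
    c(gas, rep(0, 4), rep(0, 6), 0),
    c(paste0("gas_", .LB_SPECIES), paste0("aq_", .LB_SPECIES), "aq_HCHO",
      paste0("cumin_", .LB_SPECIES), paste0("cumout_", .LB_SPECIES),
      "stress_dose"))
}

#' Carbon-mole closure of a leaf box run
#'
#' Total carbon in the chamber gas, the apoplast liquid and the net
#' through-flow must be constant: the Fenton step splits one ISOPOOH (5 C)
#' into MVK (4 C) + HCHO (1 C) and the AOR step converts MVK to MEK
#' (4 C -> 4 C), so carbon moles are the conserved currency.
#'
#' @param state a leaf box state vector.
#' @param params the [leaf_box_params()] used.
#' @return carbon moles: gas + liquid + cumulative outflow - cumulative
#'   inflow.
#' @export
leafbox_carbon_inventory <- function(state, params) {
  V <- params$chamber_volume * 1e-3
  Vaq <- params$apoplast_volume_per_area * params$leaf_area * 1e-3
  cw <- .LB_CARBON
  gas_c <- sum(state[paste0("gas_", .LB_SPECIES)] * V * cw[.LB_SPECIES])
  aq_c <- sum(state[paste0("aq_", .LB_SPECIES)] * Vaq * cw[.LB_SPECIES]) +
    state[["aq_HCHO"]] * Vaq * cw[["HCHO"]]
  flow_c <- sum((state[paste0("cumout_", .LB_SPECIES)] -
                 state[paste0("cumin_", .LB_SPECIES)]) * cw[.LB_SPECIES])
  unname(gas_c + aq_c + flow_c)
}

#' Simulate a full fumigation experiment with the leaf box model
#'
#' Runs [leafbox_step()] over a program of light/dark phases (carrying the
#' state across phases), prepends inlet and empty-enclosure background
#' phases, and emits the result in the enclosure-series schema so the
#' enclosure estimators ([compute_flux()], [enclosure_vd()],
#' [estimate_conversion_yield()]) consume it directly. Only the final
#' `record_frac` of each plant phase is recorded, emulating sampling after
#' chamber equilibration.
#'
#' @param params a [leaf_box_params()].
#' @param inlet_vmr named inlet mixing ratios, ppbv.
#' @param light_program data.frame with columns `light`
#'   (`"light"`/`"dark"`) and `duration` (s), executed in order.
#' @param dt_out output step, s.
#' @param record_frac fraction of each phase (from the end) recorded as
#'   sampled observations.
#' @param replicate replicate id stamped on the output.
#' @return enclosure-series data.frame; attribute `final_state` holds the
#'   end state and `params` the parameter object.
#' @export
simulate_fumigation <- function(params, inlet_vmr = c(ISOPOOH_12 = 8),
                                light_program = data.frame(
                                  light = c("dark", "light"),
                                  duration = c(7200, 7200)),
                                dt_out = 60, record_frac = 0.25,
                                replicate = 1L) {
  stopifnot(inherits(params, "leaf_box_params"))
  stopifnot(all(light_program$light %in% c("light", "dark")),
            all(light_program$duration > 0))
  n_in <- 5L
  mk_rows <- function(time, phase, light, vmr_mat) {
    df <- data.frame(time = time, phase = phase, light = light,
                     replicate = replicate, stringsAsFactors = FALSE)
    for (sp in .LB_SPECIES) df[[paste0("vmr_", sp)]] <- vmr_mat[[sp]]
    df
  }
  inlet_full <- stats::setNames(lapply(.LB_SPECIES, function(sp)
    rep(if (sp %in% names(inlet_vmr)) inlet_vmr[[sp]] else 0, n_in)),
    .LB_SPECIES)
  rows <- list(
    mk_rows(seq_len(n_in) * dt_out, "inlet", "dark", inlet_full),
    # conditioned empty enclosure: outlet equals inlet at steady state
    mk_rows(n_in * dt_out + seq_len(n_in) * dt_out, "background", "dark",
            inlet_full))
  t0 <- 2 * n_in * dt_out
  state <- leafbox_init(gas_vmr = inlet_vmr, params = params)
  for (i in seq_len(nrow(light_program))) {
    ph <- light_program[i, ]
    res <- leafbox_step(state, params, inlet_vmr = inlet_vmr,
                        light = ph$light == "light",
                        duration = ph$duration, dt_out = dt_out)
    state <- res$state
    keep <- res$times >= (1 - record_frac) * ph$duration
    rows[[length(rows) + 1L]] <-
      mk_rows(t0 + res$times[keep], "plant", ph$light,
              lapply(res$outlet_vmr[keep, , drop = FALSE], identity))
    t0 <- t0 + ph$duration
  }
  out <- do.call(rbind, rows)
  out$flow <- params$flow
  out$leaf_area <- params$leaf_area
  out$temperature <- params$temperature
  out$pressure <- .ATM_PA
  attr(out, "final_state") <- state
  attr(out, "params") <- params
  out
}

# forward targets (vd day/night, ISOPOOH->MVK and ->MEK daytime yields)
# computed through the full simulate + estimate pipeline
.leafbox_forward_targets <- function(params, inlet_vmr = c(ISOPOOH_12 = 8),
                                     phase_s = 7200, dt_out = 120) {
  series <- simulate_fumigation(
    params, inlet_vmr = inlet_vmr,
    light_program = data.frame(light = c("dark", "light"),
                               duration = c(phase_s, phase_s)),
    dt_out = dt_out, record_frac = 0.2)
  vd <- enclosure_vd(series, "ISOPOOH_12")
  y_mvk <- estimate_conversion_yield(series, "ISOPOOH_12", "MVK", "light")
  y_mek <- estimate_conversion_yield(series, "ISOPOOH_12", "MEK", "light")
  c(vd_day = vd$vd[vd$condition == "light"],
    vd_night = vd$vd[vd$condition == "dark"],
    yield_mvk = y_mvk$yield, yield_mek = y_mek$yield)
}

#' Calibrate the leaf box model to measured exchange targets
#'
#' Inverse problem over the four measured quantities: daytime and dark
#' deposition velocities of 1,2-ISOPOOH and its daytime molar conversion
#' yields to MVK and MEK. Free parameters are the daytime stomatal
#' conductance, the cuticular conductance, the Fenton rate constant and
#' the AOR `vmax`; they are optimised (Nelder-Mead on log parameters,
#' derivative-free and bound-safe) to minimise the summed squared relative
#' mismatch of the targets computed through the full
#' simulate-then-estimate pipeline. Identifiability is partial by design:
#' the forward targets, not the parameters, are the calibration contract.
#'
#' @param targets named numeric: `vd_day`, `vd_night` (cm s-1),
#'   `yield_mvk`, `yield_mek` (molar fractions).
#' @param params_init starting [leaf_box_params()]; fixed entries (chamber
#'   geometry, AOR Km values, NADPH pools, temperature) are kept.
#' @param maxit optimiser iteration budget.
#' @param tol_rel per-target relative mismatch above which the result is
#'   flagged infeasible (diagnostic, not an error).
#' @param phase_s,dt_out forward-simulation phase length and output step, s.
#' @return list of class `leafbox_calibration`: `params`, `achieved`
#'   (forward targets at the optimum), `targets`, `residual` (objective),
#'   `rel_error` (per target), `feasible`, `optim` (the optim object).
#' @export
calibrate_leafbox <- function(targets = c(vd_day = 0.79, vd_night = 0.12,
                                          yield_mvk = 0.5, yield_mek = 0.5),
                              params_init = leaf_box_params(),
                              maxit = 150, tol_rel = 0.05,
                              phase_s = 7200, dt_out = 120) {
  need <- c("vd_day", "vd_night", "yield_mvk", "yield_mek")
  stopifnot(all(need %in% names(targets)))
  targets <- targets[need]
  if (targets[["vd_day"]] < targets[["vd_night"]] || any(targets < 0))
    stop("targets must satisfy vd_day >= vd_night >= 0 and be nonnegative")
  if (targets[["yield_mvk"]] + targets[["yield_mek"]] > 1 + 1e-9)
    stop("yields must sum to <= 1")

  p0 <- params_init
  # physically-informed starting point
  gcut0 <- max(targets[["vd_night"]], 1e-3)
  gs0 <- max(targets[["vd_day"]] - gcut0, 1e-3)
  k_volat_mvk <- ((gs0 + gcut0) / 100) * p0$leaf_area * .ATM_PA /
    (1000 * species_properties("MVK")$henry_eff * .R_GAS * p0$temperature *
       (p0$apoplast_volume_per_area * p0$leaf_area * 1e-3))
  f_n <- p0$nadph_day / (p0$aor$km_nadph + p0$nadph_day)
  ratio <- if (targets[["yield_mvk"]] > 0)
    targets[["yield_mek"]] / targets[["yield_mvk"]] else 10
  vmax0 <- max(ratio * k_volat_mvk * 60 * p0$aor$km_mvk / f_n, 1e-6)
  x0 <- log(c(gs0, gcut0, p0$k_fenton, vmax0))

  build <- function(x) {
    v <- exp(x)
    p <- p0
    p$gs_day <- v[1]; p$g_cuticle <- v[2]; p$k_fenton <- v[3]
    p$aor <- kinetic_parameters(v[4], p0$aor$km_mvk, p0$aor$km_nadph,
                                p0$aor$t_opt, p0$aor$t_width)
    p
  }
  obj <- function(x) {
    ach <- tryCatch(
      .leafbox_forward_targets(build(x), phase_s = phase_s, dt_out = dt_out),
      error = function(e) NULL)
    if (is.null(ach)) return(1e6)
    sum(((ach - targets) / targets)^2)
  }
  opt <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  params <- build(opt$par)
  achieved <- .leafbox_forward_targets(params, phase_s = phase_s,
                                       dt_out = dt_out)
  rel <- abs(achieved - targets) / targets
  feasible <- all(rel < tol_rel)
  if (!feasible)
    message("calibration residual above tolerance: max relative error ",
            format(max(rel), digits = 3), " (targets may be infeasible)")
  structure(list(params = params, achieved = achieved, targets = targets,
                 residual = opt$value, rel_error = rel, feasible = feasible,
                 optim = opt),
            class = "leafbox_calibration")
}
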