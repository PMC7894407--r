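# Synthetic-data generators: enclosure fumigation series, high-frequency
# eddy-covariance series, enzyme assay traces and gridded deposition fields,
# each with prescribed ground truth recorded in attributes.

#' Define an enclosure fumigation scenario
#'
#' Ground truth for the well-mixed chamber generator: prescribed day/night
#' deposition velocities of the fumigated parent, molar conversion yields of
#' the emitted products, and the chamber operating conditions.
#'
#' @param parent fumigated species name (registry entry).
#' @param true_vd_day,true_vd_night prescribed deposition velocities, cm s-1.
#' @param yield_map named numeric: molar fraction of deposited parent
#'   re-emitted as each product; values in \[0,1\], sum <= 1.
#' @param inlet_vmr inlet mixing ratio of the parent, ppbv.
#' @param flow chamber through-flow, L min-1.
#' @param leaf_area single-sided leaf area, m2.
#' @param chamber_volume chamber volume, L (sets the residence time only;
#'   the recorded quasi-steady samples do not depend on it).
#' @param photoperiod_hours nominal light period, h (metadata).
#' @param noise_cv relative SD of the multiplicative lognormal mixing-ratio
#'   noise.
#' @param n_replicates number of independent plant replicates.
#' @param residual_loss_frac residual wall loss of the conditioned empty
#'   enclosure, as a fraction of the through-flow (small, nonzero).
#' @param temperature,pressure chamber air state, K and Pa.
#' @param samples_per_phase recorded samples per phase after equilibration.
#' @param seed integer RNG seed.
#' @return object of class `enclosure_scenario`.
#' @export
enclosure_scenario <- function(parent = "ISOPOOH_12",
                               true_vd_day = 0.79, true_vd_night = 0.12,
                               yield_map = c(MVK = 0.5, MEK = 0.5),
                               inlet_vmr = 8, flow = 20, leaf_area = 0.1,
                               chamber_volume = 45, photoperiod_hours = 12,
                               noise_cv = 0.02, n_replicates = 5,
                               residual_loss_frac = 0.005,
                               temperature = 298.15, pressure = 101325,
                               samples_per_phase = 30, seed = 1L) {
  if (flow <= 0 || leaf_area <= 0 || chamber_volume <= 0)
    stop("flow, leaf_area and chamber_volume must be > 0")
  if (true_vd_day < 0 || true_vd_night < 0)
    stop("deposition velocities must be >= 0")
  if (length(yield_map) && (any(yield_map < 0) || any(yield_map > 1)))
    stop("yields must lie in [0, 1]")
  if (sum(yield_map) > 1 + 1e-12)
    stop("yields of one parent must sum to <= 1")
  if (inlet_vmr < 0 || noise_cv < 0 || residual_loss_frac < 0)
    stop("inlet_vmr, noise_cv and residual_loss_frac must be >= 0")
  if (n_replicates < 1 || samples_per_phase < 1)
    stop("n_replicates and samples_per_phase must be >= 1")
  species_registry(c(parent, names(yield_map)))  # validates names
  structure(as.list(environment()), class = "enclosure_scenario")
}

# multiplicative lognormal noise with unit mean and relative SD cv
.mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate enclosure fumigation time series
#'
#' Emulates the fumigation protocol on a well-mixed chamber: an inlet
#' sampling phase, an empty-enclosure background phase (conditioned
#' surfaces, small residual wall loss), and a plant phase cycling dark and
#' light stomatal states. Outlet mixing ratios are the analytic quasi-steady
#' states of the chamber mass balance
#' \eqn{V\,dc/dt = Q(c_{in} - c) - (k_{bg} + v_d A)\,c}; product species
#' appear at the scenario's molar yields of the parent deposition. Samples
#' carry multiplicative lognormal noise; everything is reproducible from the
#' scenario seed.
#'
#' @param scenario an [enclosure_scenario()].
#' @return data.frame in the enclosure-series schema (see [compute_flux()]),
#'   with attribute `truth` holding the prescribed deposition velocities and
#'   yields and attribute `scenario` the scenario itself.
#' @export
gen_enclosure_series <- function(scenario) {
  stopifnot(inherits(scenario, "enclosure_scenario"))
  s <- scenario
  set.seed(s$seed)
  q <- s$flow / 1000 / 60                       # m3 s-1
  k_bg <- s$residual_loss_frac * q              # m3 s-1 volumetric wall sink
  vd <- c(dark = s$true_vd_night, light = s$true_vd_day) / 100  # m s-1
  species <- c(s$parent, names(s$yield_map))
  n <- s$samples_per_phase

  c_bg <- s$inlet_vmr * q / (q + k_bg)
  rows <- list()
  t0 <- 0
  add_phase <- function(phase, light, rep_id, vmrs, t0) {
    tt <- t0 + seq_len(n) * 10
    df <- data.frame(time = tt, phase = phase, light = light,
                     replicate = rep_id, stringsAsFactors = FALSE)
    for (sp in species) {
      v <- vmrs[[sp]]
      df[[paste0("vmr_", sp)]] <- v * .mult_noise(n, s$noise_cv)
    }
    df
  }

  # inlet and shared background (measured once per experiment)
  vm_in <- stats::setNames(as.list(c(s$inlet_vmr, rep(0, length(s$yield_map)))),
                           species)
  vm_bg <- vm_in; vm_bg[[s$parent]] <- c_bg
  rows[[1]] <- add_phase("inlet", "dark", 1L, vm_in, t0); t0 <- t0 + n * 10
  rows[[2]] <- add_phase("background", "dark", 1L, vm_bg, t0); t0 <- t0 + n * 10

  for (r in seq_len(s$n_replicates)) {
    for (cond in c("dark", "light")) {
      c_out <- s$inlet_vmr * q / (q + k_bg + vd[[cond]] * s$leaf_area)
      dep <- vd[[cond]] * s$leaf_area * c_out     # ppbv * m3 s-1 deposited
      vm <- list()
      vm[[s$parent]] <- c_out
      for (p in names(s$yield_map)) vm[[p]] <- s$yield_map[[p]] * dep / q
      rows[[length(rows) + 1L]] <- add_phase("plant", cond, r, vm, t0)
      t0 <- t0 + n * 10
    }
  }
  out <- do.call(rbind, rows)
  out$flow <- s$flow
  out$leaf_area <- s$leaf_area
  out$temperature <- s$temperature
  out$pressure <- s$pressure
  attr(out, "truth") <- list(vd_day = s$true_vd_day,
                             vd_night = s$true_vd_night,
                             yield_map = s$yield_map)
  attr(out, "scenario") <- s
  out
}

#' Define an eddy-covariance scenario
#'
#' @param true_flux named numeric, prescribed kinematic flux per species,
#'   nmol m-2 s-1.
#' @param sigma_w standard deviation of vertical wind, m s-1.
#' @param lag_samples integer delay of the scalar series behind the wind
#'   (tubing/instrument lag), samples.
#' @param sample_rate Hz.
#' @param duration record length, s; must satisfy
#'   `duration * sample_rate >= 2 * abs(lag_samples)`.
#' @param mean_vmr named numeric, mean mixing ratio per species, ppbv.
#' @param noise_cv relative SD of additive scalar noise (of the mean VMR).
#' @param ar_coef AR(1) coefficient of the wind series at the sample rate.
#' @param temperature,pressure air state for the ppbv/molar conversion.
#' @param seed integer RNG seed.
#' @return object of class `ec_scenario`.
#' @export
ec_scenario <- function(true_flux = c(isoprene = 10, MEK = 0.09),
                        sigma_w = 0.3, lag_samples = 0L, sample_rate = 10,
                        duration = 1800,
                        mean_vmr = c(isoprene = 2, MEK = 0.5),
                        noise_cv = 0.02, ar_coef = 0.95,
                        temperature = 298.15, pressure = 101325,
                        seed = 1L) {
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (duration * sample_rate < 2 * abs(lag_samples))
    stop("duration * sample_rate must be >= 2 * |lag_samples|")
  if (sigma_w <= 0) stop("sigma_w must be > 0")
  if (!all(names(true_flux) %in% names(mean_vmr)))
    stop("every species in true_flux needs a mean_vmr")
  if (abs(ar_coef) >= 1) stop("ar_coef must lie in (-1, 1)")
  structure(as.list(environment()), class = "ec_scenario")
}

#' Generate a high-frequency eddy-covariance series
#'
#' Vertical wind is a zero-mean AR(1) process with exact stationary SD
#' `sigma_w`; each scalar mixing-ratio series is constructed so that its
#' covariance with the wind equals the prescribed flux (after the ideal-gas
#' ppbv-to-molar conversion) and is delayed by `lag_samples`, plus additive
#' Gaussian noise.
#'
#' @param scenario an [ec_scenario()].
#' @return data.frame: `time`, `w` (m s-1), one `vmr_<species>` column
#'   (ppbv) per species, `air_temperature`, `pressure`; attribute `truth`
#'   holds the prescribed fluxes and lag.
#' @export
gen_ec_series <- function(scenario) {
  stopifnot(inherits(scenario, "ec_scenario"))
  s <- scenario
  set.seed(s$seed)
  n <- round(s$duration * s$sample_rate)
  lag <- as.integer(s$lag_samples)
  ntot <- n + abs(lag)
  innov_sd <- s$sigma_w * sqrt(1 - s$ar_coef^2)
  w_full <- as.numeric(stats::arima.sim(list(ar = s$ar_coef), ntot,
                                        sd = innov_sd))
  # scalar at t responds to wind at t - lag
  idx_c <- if (lag >= 0) seq_len(n) else seq_len(n) + abs(lag)
  idx_w <- if (lag >= 0) seq_len(n) + lag else seq_len(n)
  w <- w_full[idx_w]
  n_air <- s$pressure / (.R_GAS * s$temperature)   # mol m-3
  out <- data.frame(time = (seq_len(n) - 1) / s$sample_rate, w = w)
  for (sp in names(s$true_flux)) {
    cov_needed <- s$true_flux[[sp]] / n_air        # (m s-1 . ppbv)
    a <- cov_needed / s$sigma_w^2
    noise_sd <- s$noise_cv * s$mean_vmr[[sp]]
    out[[paste0("vmr_", sp)]] <- s$mean_vmr[[sp]] +
      a * w_full[idx_c] + stats::rnorm(n, 0, noise_sd)
  }
  out$air_temperature <- s$temperature
  out$pressure <- s$pressure
  attr(out, "truth") <- list(flux = s$true_flux, lag_samples = lag,
                             sample_rate = s$sample_rate)
  attr(out, "scenario") <- s
  out
}

#' Define an enzyme assay scenario
#'
#' @param vmax maximal velocity, mM min-1.
#' @param km_mvk,km_nadph Michaelis constants, mM.
#' @param t_opt temperature optimum, degrees C.
#' @param t_width breadth of the temperature response, degrees C.
#' @param substrate_grid MVK concentrations assayed, mM.
#' @param cofactor_grid NADPH concentrations assayed, mM.
#' @param temperatures assay temperatures, degrees C.
#' @param absorbance_noise_sd additive Gaussian noise on A340, AU.
#' @param epsilon_nadph NADPH molar absorptivity at 340 nm, AU mM-1 cm-1.
#' @param path_length cuvette path, cm.
#' @param duration_min,dt_min trace length and sampling step, min.
#' @param seed integer RNG seed.
#' @return object of class `assay_scenario`.
#' @export
assay_scenario <- function(vmax = 0.02, km_mvk = 14.15, km_nadph = 0.049,
                           t_opt = 35, t_width = 10,
                           substrate_grid = c(2, 5, 10, 20, 40, 80),
                           cofactor_grid = c(0.01, 0.025, 0.05, 0.1, 0.2),
                           temperatures = 35,
                           absorbance_noise_sd = 0.002,
                           epsilon_nadph = 6.22, path_length = 1,
                           duration_min = 2, dt_min = 0.1, seed = 1L) {
  if (any(c(substrate_grid, cofactor_grid) < 0))
    stop("concentrations must be >= 0")
  if (km_mvk <= 0 || km_nadph <= 0) stop("Km values must be > 0")
  if (vmax < 0) stop("vmax must be >= 0")
  if (t_width <= 0) stop("t_width must be > 0")
  structure(as.list(environment()), class = "assay_scenario")
}

#' Generate enzyme assay absorbance traces
#'
#' One trace per (substrate, cofactor, temperature) grid point: a declining
#' A340 series whose slope is \eqn{-\varepsilon \cdot v(S, N, T) \cdot
#' \ell}, the initial-rate segment of NADPH consumption, with additive
#' Gaussian noise. The initial absorbance is that of the supplied NADPH.
#'
#' @param scenario an [assay_scenario()].
#' @return data.frame: `trace_id`, `time` (min), `absorbance` (AU),
#'   `mvk_conc`, `nadph_conc` (mM), `temperature` (C), `path_length`,
#'   `epsilon_nadph`; attribute `truth` holds the kinetic parameters.
#' @export
gen_assay_traces <- function(scenario) {
  stopifnot(inherits(scenario, "assay_scenario"))
  s <- scenario
  set.seed(s$seed)
  pars <- kinetic_parameters(s$vmax, s$km_mvk, s$km_nadph, s$t_opt, s$t_width)
  grid <- expand.grid(mvk = s$substrate_grid, nadph = s$cofactor_grid,
                      temp = s$temperatures)
  tt <- seq(0, s$duration_min, by = s$dt_min)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    slope <- assay_slope(pars, g$mvk, g$nadph, g$temp,
                         epsilon_nadph = s$epsilon_nadph,
                         path_length = s$path_length)
    a0 <- s$epsilon_nadph * s$path_length * g$nadph
    data.frame(trace_id = i, time = tt,
               absorbance = a0 + slope * tt +
                 stats::rnorm(length(tt), 0, s$absorbance_noise_sd),
               mvk_conc = g$mvk, nadph_conc = g$nadph, temperature = g$temp,
               path_length = s$path_length, epsilon_nadph = s$epsilon_nadph)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- pars
  attr(out, "scenario") <- s
  out
}

#' Generate gridded annual deposition fields with exact global totals
#'
#' Distributes the requested global deposition totals of MVK and
#' 1,2-ISOPOOH over an `n_lat` by `n_lon` grid with random nonnegative
#' weights normalised to sum to one, so the global sums equal the totals to
#' machine precision.
#'
#' @param n_lat,n_lon grid dimensions, >= 1.
#' @param totals a [budget_inputs()] object (its `dep_mvk` and
#'   `dep_isopooh` are the global totals, Tg yr-1).
#' @param seed integer RNG seed.
#' @return data.frame: `lat`, `lon`, `dep_mvk`, `dep_isopooh` (Tg yr-1 per
#'   cell).
#' @export
gen_budget_fields <- function(n_lat, n_lon, totals, seed = 1L) {
  stopifnot(inherits(totals, "budget_inputs"))
  if (n_lat < 1 || n_lon < 1) stop("n_lat and n_lon must be >= 1")
  if (totals$dep_mvk < 0 || totals$dep_isopooh < 0)
    stop("deposition totals must be >= 0")
  set.seed(seed)
  ncell <- n_lat * n_lon
  w1 <- stats::runif(ncell); w1 <- w1 / sum(w1)
  w2 <- stats::runif(ncell); w2 <- w2 / sum(w2)
  grid <- expand.grid(lat = seq(-90 + 90 / n_lat, 90 - 90 / n_lat,
                                length.out = n_lat),
                      lon = seq(-180 + 180 / n_lon, 180 - 180 / n_lon,
                                length.out = n_lon))
  grid$dep_mvk <- w1 * totals$dep_mvk
  grid$dep_isopooh <- w2 * totals$dep_isopooh
  grid
}
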