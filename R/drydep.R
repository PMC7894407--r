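# Resistance-in-series (Wesely-type) dry deposition: species-scaled
# surface resistances from H* and f0, total deposition velocity with
# stomatal-fraction diagnostics, and the prescribed land day/night
# constants for 1,2-ISOPOOH and MVK.

#' Species-scaled surface resistances
#'
#' Scales the base (water-vapour / ozone reference) surface resistances of
#' the Wesely resistance-in-series scheme to a target gas using its
#' effective Henry constant \eqn{H^*} and reactivity factor \eqn{f_0}:
#' \deqn{r_m = 1/(H^*/3000 + 100 f_0), \quad
#'       r_{lu} = r_{lu,base}/(10^{-5} H^* + f_0),}
#' with the lower-canopy and ground resistances scaled by the same
#' \eqn{(10^{-5} H^* + f_0)} solubility-reactivity factor. The stomatal
#' resistance is scaled by the molecular diffusivity ratio
#' \eqn{\sqrt{M/M_{H_2O}}}. An `NA`/absent base resistance is treated as an
#' open circuit (pathway missing).
#'
#' @param species species name in [species_registry()].
#' @param env named list/vector of base resistances, s m-1: `rs_base`
#'   (stomatal, water vapour), `rlu_base` (upper-canopy cuticle),
#'   `rcl_base` (lower canopy), `rgs_base` (ground surface), `rac`
#'   (in-canopy aerodynamic), `rdc` (buoyant-convection). Missing entries
#'   are open circuits.
#' @return object of class `resistance_set`: named list of `ra`-ready
#'   surface components `rs`, `rm`, `rlu`, `rdc`, `rcl`, `rac`, `rgs`.
#' @export
surface_resistance <- function(species,
                               env = c(rs_base = 100, rlu_base = 2000,
                                       rcl_base = 1000, rgs_base = 500,
                                       rac = 100, rdc = 100)) {
  sp <- species_properties(species)
  if (sp$henry_eff <= 0) stop("H* must be > 0")
  env <- as.list(env)
  get <- function(nm) if (!is.null(env[[nm]]) && is.finite(env[[nm]]))
    env[[nm]] else NA_real_
  if (any(unlist(env) < 0, na.rm = TRUE))
    stop("base resistances must be >= 0")
  scale_sr <- 1e-5 * sp$henry_eff + sp$f0     # solubility-reactivity factor
  rs <- get("rs_base") * sqrt(sp$molar_mass / 18.015)
  rm <- 1 / (sp$henry_eff / 3000 + 100 * sp$f0)
  rlu <- if (scale_sr > 0) get("rlu_base") / scale_sr else Inf
  rcl <- if (scale_sr > 0) get("rcl_base") / scale_sr else Inf
  rgs <- if (scale_sr > 0) get("rgs_base") / scale_sr else Inf
  structure(list(species = species, rs = rs, rm = rm, rlu = rlu,
                 rdc = get("rdc"), rcl = rcl, rac = get("rac"), rgs = rgs),
            class = "resistance_set")
}

#' Total deposition velocity from a resistance network
#'
#' Combines the surface branches in parallel,
#' \deqn{1/r_c = 1/(r_s + r_m) + 1/r_{lu} + 1/(r_{dc} + r_{cl}) +
#'       1/(r_{ac} + r_{gs}),}
#' over the branches present (an `NA` component opens its branch), and
#' returns \eqn{v_d = 1/(r_a + r_b + r_c)} in cm s-1 together with the
#' stomatal fraction (conductance of the stomatal+mesophyll branch over
#' the total surface conductance). If every branch is absent the velocity
#' is 0 and the result is flagged.
#'
#' @param ra aerodynamic resistance, s m-1.
#' @param rb quasi-laminar boundary-layer resistance, s m-1.
#' @param rc_set a [surface_resistance()] result (or compatible named
#'   list).
#' @return list of class `deposition_result`: `vd` (cm s-1), `rc` (s m-1),
#'   `stomatal_fraction`, `no_surface_pathway` flag.
#' @export
total_vd <- function(ra, rb, rc_set) {
  if (ra < 0 || rb < 0) stop("ra and rb must be >= 0")
  branch <- function(...) {
    r <- c(...)
    if (any(is.na(r))) return(0)       # open circuit
    if (sum(r) <= 0) return(Inf)       # zero resistance: perfect sink
    1 / sum(r)
  }
  g_st <- branch(rc_set$rs, rc_set$rm)
  g_lu <- branch(rc_set$rlu)
  g_lc <- branch(rc_set$rdc, rc_set$rcl)
  g_gr <- branch(rc_set$rac, rc_set$rgs)
  g_tot <- g_st + g_lu + g_lc + g_gr
  if (g_tot == 0)
    return(structure(list(vd = 0, rc = Inf, stomatal_fraction = NA_real_,
                          no_surface_pathway = TRUE),
                     class = "deposition_result"))
  rc <- 1 / g_tot
  structure(list(vd = 100 / (ra + rb + rc), rc = rc,
                 stomatal_fraction = g_st / g_tot,
                 no_surface_pathway = FALSE),
            class = "deposition_result")
}

#' Prescribed land deposition velocities for 1,2-ISOPOOH and MVK
#'
#' The measured constant daytime (nighttime) land deposition velocities:
#' 0.79 (0.12) cm s-1 for 1,2-ISOPOOH and 0.22 (0.044) cm s-1 for MVK.
#' Over the ocean no constant applies and a delegation marker is returned
#' instructing the caller to fall back to the resistance scheme.
#'
#' @param species `"ISOPOOH_12"` or `"MVK"`.
#' @param is_day logical.
#' @param is_land logical; `FALSE` returns the delegation marker.
#' @return deposition velocity in cm s-1, or an object of class
#'   `drydep_delegation` over the ocean.
#' @export
prescribed_vd <- function(species, is_day, is_land = TRUE) {
  tab <- list(ISOPOOH_12 = c(day = 0.79, night = 0.12),
              MVK = c(day = 0.22, night = 0.044))
  if (!species %in% names(tab))
    stop("no prescribed deposition velocity for species: ", species)
  if (!is_land)
    return(structure(list(species = species,
                          use = "resistance_scheme"),
                     class = "drydep_delegation"))
  unname(tab[[species]][if (is_day) "day" else "night"])
}

#' Time-weighted day/night mean deposition velocity
#'
#' @param vd_day,vd_night deposition velocities, cm s-1.
#' @param day_fraction fraction of time in daylight, in \[0,1\].
#' @return cm s-1.
#' @export
daynight_average <- function(vd_day, vd_night, day_fraction) {
  if (any(day_fraction < 0) || any(day_fraction > 1))
    stop("day_fraction must lie in [0, 1]")
  day_fraction * vd_day + (1 - day_fraction) * vd_night
}
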