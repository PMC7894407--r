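# Enclosure mass-balance estimation: exchange fluxes, deposition velocities
# and in-leaf conversion yields from inlet/background/plant outlet series.

.check_enclosure_series <- function(series, species) {
  need <- c("time", "phase", "light", "replicate", "flow", "leaf_area",
            "temperature", "pressure")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("series lacks columns: ", paste(miss, collapse = ", "))
  col <- paste0("vmr_", species)
  if (!col %in% names(series))
    stop("series has no column ", col, " for species ", species)
  if (!"plant" %in% series$phase)
    stop("series has no 'plant' phase")
  if (!"background" %in% series$phase)
    stop("series has no 'background' phase for the plant phase to pair with")
  col
}

#' Exchange flux of a species from an enclosure series
#'
#' Computes the leaf-area-normalised exchange flux from the difference in
#' outlet molar flows between the planted and the empty (background)
#' enclosure, per light condition and replicate:
#' \deqn{\Phi = (\dot n_{out} - \dot n_{out,BG}) / LA}
#' where \eqn{\dot n = \chi \cdot 10^{-9}\, pQ/(RT)} is the species molar
#' flow at the outlet. Deposition (outlet deficit) yields \eqn{\Phi < 0};
#' emission yields \eqn{\Phi > 0}. The reported estimate is the mean across
#' replicates and the uncertainty their standard deviation.
#'
#' @param series an enclosure series data.frame as produced by
#'   [gen_enclosure_series()] or [simulate_fumigation()]: columns `time`,
#'   `phase` (`inlet`/`background`/`plant`), `light` (`dark`/`light`),
#'   `replicate`, `flow` (L min-1), `leaf_area` (m2), `temperature` (K),
#'   `pressure` (Pa) and one `vmr_<species>` column (ppbv) per species.
#' @param species species name, e.g. `"ISOPOOH_12"`.
#' @return data.frame with one row per light condition: `species`,
#'   `condition`, `flux` (nmol m-2 s-1), `uncertainty`, `n`.
#' @export
compute_flux <- function(series, species) {
  col <- .check_enclosure_series(series, species)
  la <- series$leaf_area[series$phase == "plant"][1]
  if (!is.finite(la) || la <= 0) stop("leaf_area must be > 0")
  per_rep <- .flux_per_replicate(series, col, la)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep$condition), function(d) {
    data.frame(species = species, condition = d$condition[1],
               flux = mean(d$flux),
               uncertainty = if (nrow(d) > 1) stats::sd(d$flux) else 0,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

# per-replicate, per-light-condition flux (nmol m-2 s-1)
.flux_per_replicate <- function(series, col, la) {
  plant <- series[series$phase == "plant", ]
  bg <- series[series$phase == "background", ]
  out <- list()
  for (rep_id in unique(plant$replicate)) {
    p_r <- plant[plant$replicate == rep_id, ]
    b_r <- bg[bg$replicate == rep_id, ]
    if (!nrow(b_r)) b_r <- bg  # shared background across replicates
    vmr_bg <- mean(b_r[[col]])
    for (cond in unique(p_r$light)) {
      p_c <- p_r[p_r$light == cond, ]
      ndot_air <- .air_molar_flow(p_c$flow[1], p_c$temperature[1],
                                  p_c$pressure[1])
      # ppbv difference * mol/s air * 1e-9 -> mol/s, /LA, *1e9 -> nmol m-2 s-1
      flux <- (mean(p_c[[col]]) - vmr_bg) * ndot_air / la
      out[[length(out) + 1L]] <- data.frame(
        replicate = rep_id, condition = cond, flux = flux,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Deposition velocity from a flux and an ambient concentration
#'
#' Implements \eqn{v_d = -\Phi / c}: positive for deposition
#' (deposition-negative flux convention). Two unit systems are supported:
#' `"molar_si"` takes the flux in nmol m-2 s-1 and the concentration in
#' mol m-3; `"mass_cgs"` takes ug cm-2 s-1 and ug cm-3. Both return cm s-1.
#'
#' @param flux exchange flux (negative = deposition).
#' @param ambient_conc ambient (enclosure outlet) concentration, > 0.
#' @param units `"molar_si"` (default) or `"mass_cgs"`.
#' @return deposition velocity, cm s-1 (vectorised).
#' @export
compute_deposition_velocity <- function(flux, ambient_conc,
                                        units = c("molar_si", "mass_cgs")) {
  units <- match.arg(units)
  if (any(ambient_conc <= 0))
    stop("ambient_conc must be > 0: deposition velocity undefined")
  if (units == "molar_si") {
    -flux * 1e-9 / ambient_conc * 100   # (nmol -> mol) m s-1 -> cm s-1
  } else {
    -flux / ambient_conc                # ug cm-2 s-1 / ug cm-3 = cm s-1
  }
}

#' Deposition velocities from an enclosure series
#'
#' Runs [compute_flux()] and divides by the mean plant-phase outlet
#' concentration per light condition (the ambient concentration the leaf
#' sees in a well-mixed chamber). Replicate spread is propagated into the
#' uncertainty by applying the estimator per replicate.
#'
#' @inheritParams compute_flux
#' @return data.frame: `species`, `condition`, `vd` (cm s-1),
#'   `uncertainty`, `n`.
#' @export
enclosure_vd <- function(series, species) {
  col <- .check_enclosure_series(series, species)
  la <- series$leaf_area[series$phase == "plant"][1]
  if (!is.finite(la) || la <= 0) stop("leaf_area must be > 0")
  per_rep <- .flux_per_replicate(series, col, la)
  plant <- series[series$phase == "plant", ]
  rows <- lapply(seq_len(nrow(per_rep)), function(i) {
    r <- per_rep[i, ]
    p <- plant[plant$replicate == r$replicate & plant$light == r$condition, ]
    conc <- vmr_to_concentration(mean(p[[col]]), p$temperature[1],
                                 p$pressure[1])$mol_m3
    r$vd <- compute_deposition_velocity(r$flux, conc)
    r
  })
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep$condition), function(d) {
    data.frame(species = species, condition = d$condition[1],
               vd = mean(d$vd),
               uncertainty = if (nrow(d) > 1) stats::sd(d$vd) else 0,
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' In-leaf conversion yield of a deposited parent into an emitted product
#'
#' Molar yield = (molar emission flux of the product) / (molar deposition
#' flux of the parent), per light condition, estimated per replicate and
#' aggregated as mean and standard deviation. Yields above 1 are reported
#' as-is with `exceeds_unity = TRUE`.
#'
#' @inheritParams compute_flux
#' @param parent deposited parent species (must net-deposit).
#' @param product emitted product species (must not net-deposit).
#' @param condition optional light condition filter (`"light"`/`"dark"`);
#'   default: all conditions present.
#' @return data.frame: `parent`, `product`, `condition`, `yield`,
#'   `uncertainty`, `n`, `exceeds_unity`.
#' @export
estimate_conversion_yield <- function(series, parent, product,
                                      condition = NULL) {
  pcol <- .check_enclosure_series(series, parent)
  qcol <- .check_enclosure_series(series, product)
  la <- series$leaf_area[series$phase == "plant"][1]
  par_flux <- .flux_per_replicate(series, pcol, la)
  prod_flux <- .flux_per_replicate(series, qcol, la)
  m <- merge(par_flux, prod_flux, by = c("replicate", "condition"),
             suffixes = c("_parent", "_product"))
  if (!is.null(condition)) m <- m[m$condition %in% condition, ]
  if (!nrow(m)) stop("no matching replicate/condition rows")
  agg <- do.call(rbind, lapply(split(m, m$condition), function(d) {
    dep <- -d$flux_parent
    if (mean(dep) <= .Machine$double.eps^0.5 * max(abs(d$flux_product), 1))
      stop("parent '", parent, "' does not net-deposit in condition '",
           d$condition[1], "': yield undefined")
    y <- d$flux_product / dep
    yy <- mean(y)
    over <- yy > 1 + 1e-6
    if (over)
      warning("estimated yield exceeds 1 for ", parent, " -> ", product)
    data.frame(parent = parent, product = product,
               condition = d$condition[1], yield = yy,
               uncertainty = if (nrow(d) > 1) stats::sd(y) else 0,
               n = nrow(d), exceeds_unity = over,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Box-plot summary statistics
#'
#' Median, quartiles (linear interpolation, R type 7) and extrema of a set
#' of replicate values, matching the box-plot convention (median line,
#' 25th/75th percentile box, min/max whiskers).
#'
#' @param values numeric vector, length >= 1.
#' @return named list: `median`, `q25`, `q75`, `min`, `max`.
#' @export
summarize_boxstats <- function(values) {
  if (!length(values)) stop("empty input")
  if (anyNA(values)) stop("values contain NA")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3],
       min = min(values), max = max(values))
}
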