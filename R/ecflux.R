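# Eddy-covariance flux processing: MAD despiking, lag determination by
# cross-covariance maximisation, block-mean-detrended covariance fluxes,
# and emission-ratio summaries.

#' Despike a series by the median-absolute-deviation rule
#'
#' Splits the series into consecutive windows; within each window, points
#' farther than `mad_threshold` scaled MADs from the window median are
#' replaced by that median and flagged. A zero MAD (constant window)
#' flags nothing.
#'
#' @param x numeric series.
#' @param mad_threshold spike threshold in MAD units.
#' @param window window length, samples (> 10).
#' @return list: `x` (despiked series), `flags` (logical), `n_flagged`.
#' @export
despike <- function(x, mad_threshold = 6, window = 600) {
  if (window <= 10) stop("window length must exceed 10 samples")
  n <- length(x)
  flags <- logical(n)
  out <- x
  starts <- seq(1, n, by = window)
  for (s in starts) {
    idx <- s:min(s + window - 1, n)
    med <- stats::median(x[idx])
    md <- stats::mad(x[idx])
    if (md > 0) {
      bad <- abs(x[idx] - med) > mad_threshold * md
      out[idx][bad] <- med
      flags[idx][bad] <- TRUE
    }
  }
  list(x = out, flags = flags, n_flagged = sum(flags))
}

#' Find the scalar lag by cross-covariance maximisation
#'
#' Searches lags in `[-max_lag, max_lag]` for the maximum absolute
#' cross-covariance between the vertical wind and the scalar (positive lag
#' = scalar delayed behind the wind, the tubing-delay convention); ties go
#' to the smallest |lag|. Significance is judged against the spread of the
#' cross-covariance function away from the peak: a peak below
#' `sig_factor` times that spread is flagged low-confidence.
#'
#' @param w vertical wind series.
#' @param c scalar series, same length.
#' @param max_lag maximum lag searched, samples; series must be longer
#'   than `4 * max_lag`.
#' @param sig_factor significance multiple of the off-peak spread.
#' @return list: `lag` (samples), `significant` (logical), `peak_cov`.
#' @export
find_lag <- function(w, c, max_lag = 100, sig_factor = 3) {
  stopifnot(length(w) == length(c))
  if (length(w) <= 4 * max_lag)
    stop("series must be longer than 4 * max_lag")
  lags <- -max_lag:max_lag
  n <- length(w)
  wd <- w - mean(w); cd <- c - mean(c)
  cc <- vapply(lags, function(L) {
    if (L >= 0) mean(wd[1:(n - L)] * cd[(1 + L):n])
    else mean(wd[(1 - L):n] * cd[1:(n + L)])
  }, numeric(1))
  best <- which(abs(cc) == max(abs(cc)))
  best <- best[which.min(abs(lags[best]))]          # ties -> smallest |lag|
  off <- abs(lags - lags[best]) > max(5, max_lag %/% 10)
  baseline <- stats::sd(cc[off])
  significant <- is.finite(baseline) && baseline > 0 &&
    abs(cc[best]) > sig_factor * baseline
  list(lag = lags[best], significant = significant, peak_cov = cc[best])
}

# shift scalar forward by 'lag' samples to re-align with the wind
.align_lag <- function(w, c, lag) {
  n <- length(w)
  if (lag == 0) return(list(w = w, c = c))
  if (lag > 0) list(w = w[1:(n - lag)], c = c[(1 + lag):n])
  else list(w = w[(1 - lag):n], c = c[1:(n + lag)])
}

#' Eddy-covariance flux of a species
#'
#' Splits the record into averaging windows; per window, despikes wind
#' and scalar, determines the instrument lag by cross-covariance
#' maximisation, removes block means, and computes
#' \eqn{F = \overline{w'c'} \cdot p/(RT)} converting the kinematic
#' (m s-1 ppbv) covariance to nmol m-2 s-1 through the ideal-gas molar
#' density. Windows with less than half their samples valid are skipped
#' with a QC flag.
#'
#' @param series data.frame in the [gen_ec_series()] schema: `time`, `w`,
#'   `vmr_<species>`, `air_temperature`, `pressure`.
#' @param species species name.
#' @param window averaging window, s.
#' @param max_lag lag search half-width, samples.
#' @param apply_despike logical.
#' @param mad_threshold despiking threshold.
#' @return data.frame, one row per window: `species`, `window_start`,
#'   `flux` (nmol m-2 s-1), `lag`, `lag_significant`, `n_spikes_w`,
#'   `n_spikes_c`, `qc_ok`.
#' @export
covariance_flux <- function(series, species, window = 1800, max_lag = 100,
                            apply_despike = TRUE, mad_threshold = 6) {
  col <- paste0("vmr_", species)
  if (!col %in% names(series)) stop("series has no column ", col)
  dt <- stats::median(diff(series$time))
  nwin <- max(1L, round(window / dt))
  n <- nrow(series)
  n_air <- series$pressure[1] / (.R_GAS * series$air_temperature[1])
  starts <- seq(1, n, by = nwin)
  rows <- lapply(starts, function(s) {
    idx <- s:min(s + nwin - 1, n)
    ok_frac <- mean(is.finite(series$w[idx]) & is.finite(series[[col]][idx]))
    if (length(idx) < nwin / 2 || ok_frac < 0.5)
      return(data.frame(species = species,
                        window_start = series$time[idx[1]],
                        flux = NA_real_, lag = NA_integer_,
                        lag_significant = FALSE, n_spikes_w = NA_integer_,
                        n_spikes_c = NA_integer_, qc_ok = FALSE))
    w <- series$w[idx]; cvec <- series[[col]][idx]
    nsw <- nsc <- 0L
    if (apply_despike) {
      dw <- despike(w, mad_threshold, window = min(600, length(idx)))
      dc <- despike(cvec, mad_threshold, window = min(600, length(idx)))
      w <- dw$x; cvec <- dc$x
      nsw <- dw$n_flagged; nsc <- dc$n_flagged
    }
    lg <- find_lag(w, cvec, max_lag = min(max_lag, (length(idx) - 1) %/% 4))
    al <- .align_lag(w, cvec, lg$lag)
    wp <- al$w - mean(al$w)
    cp <- al$c - mean(al$c)
    data.frame(species = species, window_start = series$time[idx[1]],
               flux = mean(wp * cp) * n_air, lag = lg$lag,
               lag_significant = lg$significant, n_spikes_w = nsw,
               n_spikes_c = nsc, qc_ok = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emission ratio of two species from windowed fluxes
#'
#' Ratio of the window-mean flux of species A to that of species B,
#' expressed in percent, with the uncertainty propagated from the
#' window-to-window spread (delta method on the ratio of means). Windows
#' failing QC in either species are dropped; the denominator must be
#' significantly positive.
#'
#' @param flux_a,flux_b [covariance_flux()] results for the numerator and
#'   denominator species (matched by `window_start`).
#' @return list: `ratio_percent`, `uncertainty_percent`, `n_windows`.
#' @export
emission_ratio <- function(flux_a, flux_b) {
  m <- merge(flux_a[flux_a$qc_ok, c("window_start", "flux")],
             flux_b[flux_b$qc_ok, c("window_start", "flux")],
             by = "window_start", suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no overlapping valid windows")
  mb <- mean(m$flux_b)
  nb <- nrow(m)
  se_b <- if (nb > 1) stats::sd(m$flux_b) / sqrt(nb) else 0
  if (mb <= 0 || (nb > 1 && mb < 2 * se_b))
    stop("denominator flux not significantly positive: ratio undefined")
  ma <- mean(m$flux_a)
  se_a <- if (nb > 1) stats::sd(m$flux_a) / sqrt(nb) else 0
  r <- ma / mb
  se_r <- if (nb > 1) sqrt((se_a / mb)^2 + (ma * se_b / mb^2)^2) else 0
  list(ratio_percent = 100 * r,
       uncertainty_percent = 100 * se_r,
       n_windows = nb)
}
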