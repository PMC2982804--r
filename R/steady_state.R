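#' Steady-state summary of a trajectory
#'
#' Computes post-burn-in statistics of cell length (twice the half-cell
#' boundary position) and of the cortical contact count, with an automated
#' check that the retained window shows no meaningful linear trend in
#' length (the 95\% confidence interval of the OLS slope contains 0, or
#' the total drift over the window is below one standard deviation of
#' length; a failed check is reported, not an error, since runaway regimes
#' are a legitimate object of study).
#'
#' @param traj an \code{\link{simulate_cell}} trajectory.
#' @param burn_in initial transient to discard, min.
#' @return An object of class \code{mt_steady_state}: burn_in, mean_length,
#'   sd_length, cv_length, mean_n_B, n_samples, trend_slope,
#'   trend_stationary.
#' @export
summarize_steady_state <- function(traj, burn_in = 500) {
  stopifnot(inherits(traj, "mt_trajectory"))
  s <- traj$series
  keep <- s$time_min >= burn_in
  if (!any(keep)) {
    stop("burn_in leaves no samples: trajectory ends at ",
         max(s$time_min), " min", call. = FALSE)
  }
  len <- s$cell_length_um[keep]
  tt <- s$time_min[keep]
  m <- mean(len)
  sdl <- stats::sd(len)
  if (is.na(sdl)) sdl <- 0
  trend_slope <- NA_real_
  stationary <- NA
  if (length(len) >= 10 && sdl > 0) {
    fit <- stats::lm(len ~ tt)
    ci <- stats::confint(fit)["tt", ]
    trend_slope <- unname(stats::coef(fit)["tt"])
    # stationary if the slope CI contains 0, or the total drift over the
    # window is below one sd of length (long autocorrelated series make
    # negligible slopes formally "significant")
    drift <- abs(trend_slope) * diff(range(tt))
    stationary <- (ci[1] <= 0 && ci[2] >= 0) || drift < sdl
  }
  structure(list(
    burn_in = burn_in,
    mean_length = m,
    sd_length = sdl,
    cv_length = if (m > 0) sdl / m else NA_real_,
    mean_n_B = mean(s$n_B[keep]),
    n_samples = sum(keep),
    trend_slope = trend_slope,
    trend_stationary = unname(stationary)),
    class = "mt_steady_state")
}

#' @export
print.mt_steady_state <- function(x, ...) {
  cat(sprintf(
    "Steady state (burn-in %g min, %d samples):\n", x$burn_in, x$n_samples))
  cat(sprintf("  cell length %.2f +/- %.2f um (CV %.3f)\n",
              x$mean_length, x$sd_length, x$cv_length))
  cat(sprintf("  mean cortical contacts n_B = %.2f\n", x$mean_n_B))
  if (isFALSE(x$trend_stationary)) {
    cat(sprintf("  warning: post-burn-in length trend %.3g um/min (not stationary)\n",
                x$trend_slope))
  }
  invisible(x)
}

# deterministic per-cell seed below 2^31, derived from a master seed and
# grid coordinates so sweep cells are independent and reproducible
derive_seed <- function(master, i, j = 0L) {
  as.integer((as.numeric(master) * 48271 + i * 7919 + j * 104729 + 12345) %%
               2147483647)
}

#' Homeostasis map over nucleation-site count and cooperation constant
#'
#' Runs one independently seeded simulation per (N_m, alpha) grid cell and
#' records the post-burn-in standard deviation of cell length, the measure
#' of homeostasis used throughout: low sd means the length is homeostatic,
#' large sd means control is lost (e.g. runaway elongation at alpha = 0).
#'
#' @param N_m_values,alpha_values grid axes.
#' @param params baseline \code{\link{mt_params}} (its seed acts as the
#'   master seed).
#' @param duration simulated time per cell, min.
#' @param burn_in discarded transient, min.
#' @param record_interval recording cadence, min.
#' @return An object of class \code{homeostasis_map} with matrices
#'   \code{sd_length} and \code{mean_length} (rows = N_m, cols = alpha).
#' @export
homeostasis_map <- function(N_m_values, alpha_values, params = mt_params(),
                            duration = 10000, burn_in = 500,
                            record_interval = 1) {
  stopifnot(length(N_m_values) > 0, length(alpha_values) > 0)
  if (duration < 10 * burn_in) {
    stop("duration must be at least 10 * burn_in", call. = FALSE)
  }
  sdm <- matrix(NA_real_, length(N_m_values), length(alpha_values),
                dimnames = list(N_m = N_m_values, alpha = alpha_values))
  mlm <- sdm
  for (i in seq_along(N_m_values)) {
    for (j in seq_along(alpha_values)) {
      p <- tryCatch(
        mt_params(modifyList(unclass(params), list(
          N_m = N_m_values[i], alpha = alpha_values[j],
          seed = derive_seed(params$seed, i, j)))),
        error = function(e) {
          stop(sprintf("grid cell (N_m = %s, alpha = %s): %s",
                       N_m_values[i], alpha_values[j], conditionMessage(e)),
               call. = FALSE)
        })
      tr <- simulate_cell(p, duration, record_interval)
      ss <- summarize_steady_state(tr, burn_in)
      sdm[i, j] <- ss$sd_length
      mlm[i, j] <- ss$mean_length
    }
  }
  structure(list(N_m_values = N_m_values, alpha_values = alpha_values,
                 sd_length = sdm, mean_length = mlm,
                 duration = duration, burn_in = burn_in),
            class = "homeostasis_map")
}

#' @export
print.homeostasis_map <- function(x, ...) {
  cat(sprintf("Homeostasis map: %d x %d grid, %g min per cell\n",
              length(x$N_m_values), length(x$alpha_values), x$duration))
  cat("sd of cell length (um):\n")
  print(round(x$sd_length, 2))
  invisible(x)
}

#' @export
plot.homeostasis_map <- function(x, ...) {
  graphics::image(x$N_m_values, x$alpha_values, x$sd_length,
                  xlab = "N_m", ylab = "alpha",
                  main = "sd of cell length (um)", ...)
  invisible(x)
}

#' Mid-run parameter perturbation protocol
#'
#' Simulates with the baseline parameters until \code{t_switch}, then
#' continues the very same microtubule/boundary state (and RNG stream) with
#' selected parameters multiplied by the given factors; used to emulate,
#' e.g., a microtubule-polymerisation inhibitor as a drop in \code{v_g} or
#' loss of cortical catastrophe as a drop in \code{c_B}.
#'
#' @param params baseline \code{\link{mt_params}}.
#' @param t_switch switch time, min (< duration).
#' @param factors named list/vector of positive multipliers for parameter
#'   fields; empty means no perturbation.
#' @param duration total simulated time, min.
#' @param record_interval recording cadence, min.
#' @return an \code{mt_trajectory} spanning the full run, with attribute
#'   \code{switch_time} and the perturbed parameter set in
#'   \code{attr(, "params_after")}.
#' @export
perturb_parameter <- function(params, t_switch, factors, duration,
                              record_interval = 1) {
  stopifnot(inherits(params, "mt_params"))
  if (t_switch >= duration) stop("t_switch must be < duration", call. = FALSE)
  factors <- as.list(factors)
  if (length(factors) && any(unlist(factors) <= 0)) {
    stop("perturbation factors must be > 0", call. = FALSE)
  }
  unknown <- setdiff(names(factors), names(unclass(params)))
  if (length(unknown)) {
    stop("unknown parameter field(s) in factors: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(params$seed)
  tr1 <- simulate_cell(params, t_switch, record_interval, reseed = FALSE)
  p2 <- unclass(params)
  for (f in names(factors)) p2[[f]] <- p2[[f]] * factors[[f]]
  p2 <- mt_params(p2)  # re-validates the scaled set
  tr2 <- simulate_cell(p2, duration - t_switch, record_interval,
                       init = list(lengths = tr1$final$lengths,
                                   boundary = tr1$final$boundary,
                                   t0 = tr1$final$t),
                       reseed = FALSE)
  series <- rbind(tr1$series, tr2$series[-1L, ])
  rownames(series) <- NULL
  out <- structure(list(series = series, params = params,
                        final = tr2$final),
                   class = "mt_trajectory")
  attr(out, "switch_time") <- t_switch
  attr(out, "params_after") <- p2
  attr(out, "factors") <- factors
  out
}

#' Time-averaged microtubule occupancy along the cell axis
#'
#' Takes ensemble snapshots at a fixed cadence after burn-in and computes,
#' on a 0-100\% axis of the instantaneous half-cell length, the expected
#' number of microtubules overlapping each position (a microtubule of tip
#' position L overlaps all positions <= L). Occupancy is N_m at the centre
#' and decreases towards the edge; the model predicts an approximately
#' linear decline.
#'
#' @param params an \code{\link{mt_params}} object.
#' @param duration total simulated time, min.
#' @param n_snapshots number of post-burn-in snapshots to average.
#' @param burn_in transient to discard before snapshots begin, min.
#' @param positions percentage positions (0-100) at which to evaluate.
#' @return An object of class \code{density_profile} with \code{positions}
#'   (\%) and \code{occupancy} (mean microtubule count).
#' @export
density_profile <- function(params, duration = 3000, n_snapshots = 500,
                            burn_in = 500, positions = seq(0, 100, by = 2)) {
  stopifnot(inherits(params, "mt_params"))
  if (burn_in >= duration) stop("burn_in must be < duration", call. = FALSE)
  snap_int <- (duration - burn_in) / n_snapshots
  if (snap_int < params$dt) stop("too many snapshots requested", call. = FALSE)
  tr <- simulate_cell(params, duration, record_interval = duration,
                      snapshot_interval = snap_int)
  keep <- tr$snapshot_times >= burn_in
  if (sum(keep) < 2) stop("insufficient post-burn-in snapshots", call. = FALSE)
  snaps <- tr$snapshots[, keep, drop = FALSE]
  LBs <- tr$snapshot_L_B[keep]
  occ <- vapply(positions, function(p) {
    # fraction-of-length threshold per snapshot; tips at >= threshold overlap
    mean(colSums(snaps >= rep(p / 100 * LBs, each = nrow(snaps)) - 1e-12))
  }, numeric(1))
  structure(list(positions = positions, occupancy = occ,
                 n_snapshots = sum(keep), params = params),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf(
    "Microtubule occupancy profile (%d snapshots): %.1f at centre, %.2f at edge\n",
    x$n_snapshots, x$occupancy[1], x$occupancy[length(x$occupancy)]))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  plot(x$positions, x$occupancy, type = "b", xlab = "% of cell half-length",
       ylab = "microtubule occupancy", ...)
  invisible(x)
}

#' Steady-state cell length as a function of growth velocity
#'
#' Simulates to steady state for each growth velocity in \code{vg_values}
#' (one independently derived seed per point, all other parameters held
#' fixed) and fits an ordinary least-squares line of mean post-burn-in cell
#' length against v_g. The model predicts a linear relationship; the fit of
#' half-length against v_g is returned alongside so either length convention
#' can be inspected.
#'
#' @param vg_values growth velocities to sweep, um/min; at least 3 distinct
#'   values, all > v_B.
#' @param params baseline \code{\link{mt_params}}.
#' @param duration simulated time per point, min.
#' @param burn_in discarded transient, min.
#' @return An object of class \code{length_vg_fit}: slope (min), intercept
#'   (um), per-point means and sds, the underlying \code{lm} fit, and the
#'   half-length slope/intercept.
#' @export
length_vs_vg_fit <- function(vg_values, params = mt_params(),
                             duration = 10000, burn_in = 500) {
  stopifnot(inherits(params, "mt_params"))
  vg_values <- as.numeric(vg_values)
  if (length(unique(vg_values)) < 3) {
    stop("need at least 3 distinct v_g values", call. = FALSE)
  }
  if (any(vg_values <= params$v_B)) {
    stop("every v_g must exceed v_B: no steady state exists otherwise",
         call. = FALSE)
  }
  means <- sds <- n_Bs <- numeric(length(vg_values))
  for (i in seq_along(vg_values)) {
    p <- mt_params(modifyList(unclass(params), list(
      v_g = vg_values[i], seed = derive_seed(params$seed, i))))
    ss <- summarize_steady_state(simulate_cell(p, duration), burn_in)
    means[i] <- ss$mean_length
    sds[i] <- ss$sd_length
    n_Bs[i] <- ss$mean_n_B
  }
  fit <- stats::lm(means ~ vg_values)
  fit_half <- stats::lm(I(means / 2) ~ vg_values)
  structure(list(
    vg_values = vg_values, mean_length = means, sd_length = sds,
    mean_n_B = n_Bs,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_half = unname(stats::coef(fit_half)[2]),
    intercept_half = unname(stats::coef(fit_half)[1]),
    fit = fit, duration = duration, burn_in = burn_in),
    class = "length_vg_fit")
}

#' @export
print.length_vg_fit <- function(x, ...) {
  cat(sprintf(
    "Cell length vs growth velocity (OLS over %d points):\n  length = %.2f * v_g + %.2f  (um, v_g in um/min)\n",
    length(x$vg_values), x$slope, x$intercept))
  cat(sprintf("  half-length fit: slope %.2f, intercept %.2f\n",
              x$slope_half, x$intercept_half))
  invisible(x)
}

#' @export
plot.length_vg_fit <- function(x, ...) {
  plot(x$vg_values, x$mean_length, pch = 19,
       xlab = "v_g (um/min)", ylab = "steady-state cell length (um)", ...)
  graphics::arrows(x$vg_values, x$mean_length - x$sd_length,
                   x$vg_values, x$mean_length + x$sd_length,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(x$fit)
  invisible(x)
}
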