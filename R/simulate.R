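#' Boundary advance velocity for a given cortical contact count
#'
#' The cell boundary advances at \code{v_g * exp(-alpha / n) - v_B} when
#' \code{n} microtubule tips are in contact with the cortex zone, with the
#' convention \code{exp(-alpha / 0) := 0}: with no contacts the margin
#' retracts at the bare rate \code{-v_B}.
#'
#' @param n_contact number of microtubules in the cortex zone (0..N_m).
#' @param params an \code{\link{mt_params}} object.
#' @return velocity in um/min.
#' @examples
#' boundary_velocity(0, mt_params())   # -0.4: pure retraction
#' boundary_velocity(11, mt_params())  # 15 * exp(-8/11) - 0.4 = 6.86
#' @export
boundary_velocity <- function(n_contact, params) {
  stopifnot(inherits(params, "mt_params"))
  if (any(n_contact < 0)) stop("n_contact must be >= 0", call. = FALSE)
  if (any(n_contact > params$N_m)) {
    stop("n_contact cannot exceed N_m", call. = FALSE)
  }
  coop <- ifelse(n_contact == 0, 0, exp(-params$alpha / n_contact))
  params$v_g * coop - params$v_B
}

#' Catastrophe hazard at a given tip position
#'
#' A tip within the cortex zone (within \code{w_c} of the boundary,
#' inclusive) is under the cortical hazard \code{c_B}; elsewhere it is under
#' the interior hazard \code{c_I}.
#'
#' @param tip_position microtubule tip position from the cell centre, um.
#' @param boundary current half-cell boundary position, um.
#' @param params an \code{\link{mt_params}} object.
#' @return hazard rate in 1/min.
#' @export
catastrophe_rate_for <- function(tip_position, boundary, params) {
  stopifnot(inherits(params, "mt_params"))
  if (any(tip_position < 0) || any(tip_position > boundary)) {
    stop("tip_position must lie in [0, boundary]", call. = FALSE)
  }
  ifelse(boundary - tip_position <= params$w_c, params$c_B, params$c_I)
}

#' Advance the model by a single Euler step
#'
#' One fixed step of length \code{dt}: each microtubule independently draws a
#' uniform number and undergoes catastrophe (reset to length 0, instant
#' renucleation at the centre) with probability \code{dt * c_m}, otherwise
#' grows by \code{dt * v_g} capped at the boundary; the boundary then moves
#' by \code{dt * boundary_velocity(n)} with \code{n} the post-update contact
#' count, floored at 0, and tips are reconciled with the new boundary.
#' Consumes \code{N_m} draws from the current R RNG stream.
#'
#' @param params an \code{\link{mt_params}} object.
#' @param lengths numeric vector of \code{N_m} tip positions, um.
#' @param boundary half-cell boundary position, um.
#' @return list with elements \code{lengths}, \code{boundary},
#'   \code{n_contact}.
#' @export
mt_step <- function(params, lengths, boundary) {
  stopifnot(inherits(params, "mt_params"))
  if (length(lengths) != params$N_m) {
    stop("lengths must have exactly N_m entries", call. = FALSE)
  }
  if (any(lengths < 0) || any(lengths > boundary) || boundary < 0) {
    stop("state violates confinement: 0 <= lengths <= boundary required",
         call. = FALSE)
  }
  res <- sim_core(1L, 1L, as.numeric(lengths), boundary, 0,
                  params$v_g, params$c_I, params$c_B, params$v_B,
                  params$alpha, params$dt, params$w_c,
                  FALSE, 0L)
  list(lengths = res$Lm_final, boundary = res$LB_final,
       n_contact = res$nB_series[1L])
}

#' Simulate a half-cell elongation trajectory
#'
#' Runs the stochastic half-cell model from its standard initial condition
#' (boundary at \code{L0}, all microtubule lengths 0) for \code{duration}
#' minutes of model time, recording the boundary position and cortical
#' contact count at a fixed cadence. Reported cell length is twice the
#' half-cell boundary position. The trajectory is a deterministic function
#' of \code{params$seed}.
#'
#' @param params an \code{\link{mt_params}} object.
#' @param duration total simulated time, min. Truncated down to a whole
#'   number of steps with a warning if not a multiple of \code{dt}.
#' @param record_interval recording cadence, min (>= \code{dt}).
#' @param record_events if TRUE, catastrophe events (time, microtubule
#'   index, cortex-zone flag) are collected in \code{$events}.
#' @param snapshot_interval if non-NULL, full ensembles of tip positions are
#'   stored at this cadence in \code{$snapshots} (matrix N_m x n_snapshots).
#' @param init internal: list(lengths, boundary, t0) to continue from a
#'   previous state instead of the standard initial condition.
#' @param reseed internal: set to FALSE to continue the current RNG stream
#'   rather than reseeding from \code{params$seed}.
#' @return An object of class \code{mt_trajectory}: a list with
#'   \code{$series} (data.frame time_min, L_B_um, n_B, cell_length_um),
#'   \code{$params}, \code{$final} state, and optionally \code{$events} and
#'   \code{$snapshots}.
#' @examples
#' tr <- simulate_cell(mt_params(seed = 42), duration = 30)
#' head(tr$series)
#' @export
simulate_cell <- function(params, duration, record_interval = 1,
                          record_events = FALSE, snapshot_interval = NULL,
                          init = NULL, reseed = TRUE) {
  stopifnot(inherits(params, "mt_params"))
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (record_interval < params$dt) {
    stop("record_interval must be >= dt", call. = FALSE)
  }
  n_steps <- floor(duration / params$dt + 1e-9)
  if (abs(n_steps * params$dt - duration) > 1e-9 * max(1, duration)) {
    warning(sprintf(
      "duration %g min is not a multiple of dt = %g; truncated to %g min",
      duration, params$dt, n_steps * params$dt))
  }
  record_every <- max(1L, as.integer(round(record_interval / params$dt)))
  snapshot_every <- if (is.null(snapshot_interval)) 0L else {
    max(1L, as.integer(round(snapshot_interval / params$dt)))
  }

  if (is.null(init)) {
    lengths0 <- rep(0, params$N_m)
    boundary0 <- params$L0
    t0 <- 0
  } else {
    lengths0 <- init$lengths
    boundary0 <- init$boundary
    t0 <- init$t0
  }
  if (reseed) set.seed(params$seed)

  res <- sim_core(as.integer(n_steps), record_every,
                  as.numeric(lengths0), boundary0, t0,
                  params$v_g, params$c_I, params$c_B, params$v_B,
                  params$alpha, params$dt, params$w_c,
                  record_events, snapshot_every)

  n_B0 <- sum(boundary0 - lengths0 <= params$w_c)
  series <- data.frame(
    time_min = c(t0, res$times),
    L_B_um = c(boundary0, res$LB_series),
    n_B = c(n_B0, res$nB_series))
  series$cell_length_um <- 2 * series$L_B_um

  out <- list(series = series, params = params,
              final = list(lengths = res$Lm_final, boundary = res$LB_final,
                           t = t0 + n_steps * params$dt))
  if (record_events) {
    out$events <- data.frame(time_min = res$event_time,
                             mt = res$event_mt,
                             in_cortex_zone = res$event_zone == 1L)
  }
  if (snapshot_every > 0L) {
    out$snapshots <- res$snapshots
    out$snapshot_times <- res$snapshot_times
    out$snapshot_L_B <- res$snapshot_LB
  }
  structure(out, class = "mt_trajectory")
}

#' @export
print.mt_trajectory <- function(x, ...) {
  s <- x$series
  cat(sprintf(
    "Half-cell trajectory: %d samples over %g min (N_m = %d, alpha = %g)\n",
    nrow(s), max(s$time_min), x$params$N_m, x$params$alpha))
  cat(sprintf("  final half-length %.2f um (cell length %.2f um), n_B = %d\n",
              s$L_B_um[nrow(s)], s$cell_length_um[nrow(s)], s$n_B[nrow(s)]))
  if (!is.null(attr(x, "switch_time"))) {
    cat(sprintf("  parameter switch at t = %g min\n", attr(x, "switch_time")))
  }
  invisible(x)
}

#' @export
plot.mt_trajectory <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(s$time_min, s$cell_length_um, type = "l", xlab = "time (min)",
       ylab = "cell length (um)", ...)
  plot(s$time_min, s$n_B, type = "s", xlab = "time (min)",
       ylab = "contacts n_B", ...)
  invisible(x)
}

#' @export
summary.mt_trajectory <- function(object, burn_in = 500, ...) {
  summarize_steady_state(object, burn_in = burn_in)
}

#' Export a trajectory as tidy CSV with a JSON parameter sidecar
#'
#' Writes \code{<path>} (columns time_min, L_B_um, n_B, cell_length_um) and
#' \code{<path>.json} holding the full parameter set, seed and package
#' version.
#'
#' @param traj an \code{mt_trajectory}.
#' @param path output CSV path.
#' @return invisibly, the paths written.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mt_trajectory"))
  utils::write.csv(traj$series[, c("time_min", "L_B_um", "n_B",
                                   "cell_length_um")],
                   path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- list(params = unclass(traj$params),
               package = "mtlength",
               version = as.character(utils::packageVersion("mtlength")))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}
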