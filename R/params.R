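#' Model parameters for the half-cell microtubule simulation
#'
#' Builds a validated parameter set for the stochastic half-cell model of
#' microtubule-driven cell elongation. Defaults are the published reference
#' values: microtubule growth velocity \code{v_g} = 15 um/min, interior
#' catastrophe rate \code{c_I} = 0.3 /min, cortex catastrophe rate
#' \code{c_B} = 4.8 /min, boundary retraction rate \code{v_B} = 0.4 um/min,
#' \code{N_m} = 11 nucleation sites and cooperation constant
#' \code{alpha} = 8.
#'
#' The catastrophe hazard is discretised per time step as a Bernoulli trial
#' with probability \code{dt * c}; validation enforces
#' \code{dt * max(c_I, c_B) <= 0.1} so that this approximation of the
#' exponential hazard stays accurate.
#'
#' @param ... named overrides of the default fields. Unknown names are an
#'   error. Fields: \code{v_g}, \code{c_I}, \code{c_B}, \code{v_B},
#'   \code{N_m}, \code{alpha}, \code{dt} (time step, min), \code{w_c}
#'   (cortex-zone width, um), \code{L0} (initial half-cell boundary
#'   position, um), \code{seed} (integer RNG seed).
#'
#' @return An object of class \code{mt_params}: a named list of validated
#'   parameter values.
#' @examples
#' p <- mt_params()
#' p$c_B / p$c_I          # 16: the cortex-to-interior catastrophe ratio
#' mt_params(alpha = 0)   # degenerate no-cooperation limit is allowed
#' @export
mt_params <- function(...) {
  defaults <- list(
    v_g = 15, c_I = 0.3, c_B = 4.8, v_B = 0.4,
    N_m = 11L, alpha = 8, dt = 0.001, w_c = 3, L0 = 10,
    seed = 1L)
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]])) {
    overrides <- overrides[[1L]]
  }
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[nm] <- overrides
  }
  p <- defaults
  p$N_m <- as.integer(p$N_m)
  p$seed <- as.integer(p$seed)
  validate_mt_params(p)
  structure(p, class = "mt_params")
}

validate_mt_params <- function(p) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop("invalid parameter '", field, "': ", msg, call. = FALSE)
    }
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$v_g) && p$v_g > 0, "v_g", "must be a positive number")
  chk(num1(p$v_B) && p$v_B >= 0, "v_B", "must be >= 0")
  chk(num1(p$c_I) && p$c_I >= 0, "c_I", "must be >= 0")
  chk(num1(p$c_B) && p$c_B >= 0, "c_B", "must be >= 0")
  chk(length(p$N_m) == 1L && !is.na(p$N_m) && p$N_m >= 0L, "N_m",
      "must be a non-negative integer")
  chk(num1(p$alpha) && p$alpha >= 0, "alpha", "must be >= 0")
  chk(num1(p$dt) && p$dt > 0, "dt", "must be > 0")
  chk(p$dt * max(p$c_I, p$c_B) <= 0.1, "dt",
      sprintf("dt * max(c_I, c_B) = %.3g exceeds 0.1; the per-step Bernoulli
approximation of the catastrophe hazard breaks down (reduce dt)",
              p$dt * max(p$c_I, p$c_B)))
  chk(num1(p$w_c) && p$w_c > 0, "w_c", "must be > 0")
  chk(num1(p$L0) && p$L0 >= p$w_c, "L0", "must be >= w_c")
  chk(length(p$seed) == 1L && !is.na(p$seed), "seed", "must be an integer")
  invisible(p)
}

#' @export
print.mt_params <- function(x, ...) {
  cat("Half-cell microtubule model parameters\n")
  cat(sprintf("  v_g   = %g um/min   (growth velocity)\n", x$v_g))
  cat(sprintf("  c_I   = %g /min     (interior catastrophe rate)\n", x$c_I))
  cat(sprintf("  c_B   = %g /min     (cortex catastrophe rate)\n", x$c_B))
  cat(sprintf("  v_B   = %g um/min   (boundary retraction rate)\n", x$v_B))
  cat(sprintf("  N_m   = %d          (nucleation sites)\n", x$N_m))
  cat(sprintf("  alpha = %g          (cooperation constant)\n", x$alpha))
  cat(sprintf("  dt = %g min, w_c = %g um, L0 = %g um, seed = %d\n",
              x$dt, x$w_c, x$L0, x$seed))
  invisible(x)
}

#' Read or write a simulation configuration file
#'
#' Config files are flat YAML mappings whose keys mirror the
#' \code{\link{mt_params}} field names exactly.
#'
#' @param path file path.
#' @return \code{read_mt_config} returns an \code{mt_params} object.
#' @export
read_mt_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must be a YAML mapping", call. = FALSE)
  do.call(mt_params, cfg)
}

#' @param params an \code{mt_params} object.
#' @rdname read_mt_config
#' @export
write_mt_config <- function(params, path) {
  stopifnot(inherits(params, "mt_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
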