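#' Classification protocol
#'
#' Pins every tunable of qualitative dynamics classification so that a
#' verdict is a deterministic function of (instance, protocol).  Defaults:
#' a 2400 min horizon sampled every 0.3 min, the first half discarded as
#' transient; a fixed point requires relative post-transient variation of
#' every state below \code{tol_fp}; a limit cycle requires at least
#' \code{n_peaks} successive peaks with period coefficient-of-variation below
#' \code{tol_period_cv} and peak heights stationary within
#' \code{sustain_tol} (this last guard keeps slowly decaying stable foci out
#' of the oscillation class); an excitable switch is a reached fixed point
#' from which an upward perturbation of \code{perturb_frac} of the perturbed
#' variable's steady-state value triggers an excursion at least
#' \code{excitability_ratio} times the perturbation before returning.
#'
#' @param horizon simulation horizon in minutes.
#' @param step output grid step in minutes.
#' @param transient_fraction fraction of the horizon discarded as transient.
#' @param tol_fp relative variation threshold for fixed-point detection.
#' @param n_peaks minimum number of successive peaks for an oscillation.
#' @param tol_period_cv maximum coefficient of variation of peak intervals.
#' @param sustain_tol maximum relative drift of peak heights.
#' @param excitability_ratio minimum excursion/perturbation ratio.
#' @param perturb_frac perturbation size as a fraction of steady-state value.
#' @param perturb_symbol state symbol to perturb (default: the last state
#'   symbol, the slow accumulating variable in the packaged models).
#' @param perturb_reference optional state symbol whose steady-state value
#'   sets the perturbation magnitude (default: the perturbed symbol
#'   itself).  Needed when the physically meaningful lever is a pool that
#'   is nearly empty at steady state, e.g. free cyclin in the six-variable
#'   MPF model, whose accumulated counterpart is the inactive-MPF pool.
#' @param rtol,atol integration tolerances.
#' @return An object of class \code{"sf_protocol"}.
#' @export
classification_protocol <- function(horizon = 2400, step = 0.3,
                                    transient_fraction = 0.5,
                                    tol_fp = 1e-6,
                                    n_peaks = 5L, tol_period_cv = 0.01,
                                    sustain_tol = 0.02,
                                    excitability_ratio = 10,
                                    perturb_frac = 0.05,
                                    perturb_symbol = NULL,
                                    perturb_reference = NULL,
                                    rtol = 1e-9, atol = 1e-9) {
  if (horizon <= 0 || step <= 0)
    stop("protocol error: horizon and step must be positive", call. = FALSE)
  if (transient_fraction < 0 || transient_fraction >= 1)
    stop("protocol error: transient_fraction must be in [0, 1)", call. = FALSE)
  if (horizon * (1 - transient_fraction) < 10 * step)
    stop("protocol error: horizon leaves too short a post-transient window",
         call. = FALSE)
  structure(list(horizon = horizon, step = step,
                 transient_fraction = transient_fraction, tol_fp = tol_fp,
                 n_peaks = as.integer(n_peaks), tol_period_cv = tol_period_cv,
                 sustain_tol = sustain_tol,
                 excitability_ratio = excitability_ratio,
                 perturb_frac = perturb_frac, perturb_symbol = perturb_symbol,
                 perturb_reference = perturb_reference,
                 rtol = rtol, atol = atol),
            class = "sf_protocol")
}

dynamics_class <- function(label, teddy = NULL) {
  label <- match.arg(label, c("stable_fixed_point", "limit_cycle_oscillation",
                              "excitable_switch", "unclassified"))
  if (is.null(teddy) && label == "stable_fixed_point")
    teddy <- annotation("teddy", "TEDDY_0000113")
  structure(list(label = label, teddy = teddy), class = "sf_dynamics_class")
}

#' @export
print.sf_dynamics_class <- function(x, ...) {
  t <- if (is.null(x$teddy)) "" else paste0(" (", format_urn(x$teddy), ")")
  cat("<dynamics>", x$label, t, "\n", sep = "")
  invisible(x)
}

characteristics <- function(steady_state_values = NULL, period = NULL,
                            amplitude_extrema = NULL,
                            excursion_magnitude = NULL, diagnostic = NULL) {
  structure(list(steady_state_values = steady_state_values, period = period,
                 amplitude_extrema = amplitude_extrema,
                 excursion_magnitude = excursion_magnitude,
                 diagnostic = diagnostic),
            class = "sf_characteristics")
}

# interior local maxima with parabolic refinement of time and height
find_peaks <- function(t, x) {
  n <- length(x)
  if (n < 3L) return(data.frame(time = numeric(), height = numeric()))
  i <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(i) == 0L) return(data.frame(time = numeric(), height = numeric()))
  dt <- t[2L] - t[1L]
  a <- x[i - 1L]; b <- x[i]; c <- x[i + 1L]
  denom <- a - 2 * b + c
  off <- ifelse(abs(denom) > 0, 0.5 * (a - c) / denom, 0)
  off[abs(off) > 1] <- 0
  data.frame(time = t[i] + off * dt,
             height = b - 0.25 * (a - c) * off)
}

#' Classify the qualitative dynamics of an instantiated model
#'
#' Runs the protocol's horizon, discards the transient, and decides between
#' a stable fixed point, a sustained limit-cycle oscillation, an excitable
#' switch (fixed point reached, but a suprathreshold perturbation triggers a
#' large excursion before return) and unclassified.  Deterministic given
#' (instance, protocol).
#'
#' @param instance an \code{\link{instantiate}}d model.
#' @param protocol a \code{\link{classification_protocol}}.
#' @return A list with elements \code{class} (a dynamics class with optional
#'   TEDDY annotation) and \code{characteristics} (steady-state values,
#'   period, per-state amplitude extrema, excursion magnitude, as the class
#'   admits).
#' @export
classify <- function(instance, protocol = classification_protocol()) {
  stopifnot(inherits(instance, "sf_sim_instance"),
            inherits(protocol, "sf_protocol"))
  setup <- simulation_setup(0, protocol$horizon, protocol$step)
  inst <- instance
  verdict <- NULL
  # a trajectory with a clean period but still-drifting peak heights is
  # still settling (onto a limit cycle, or toward a fixed point); one
  # extension leg restarted from the final state decides it
  for (leg in 1:2) {
    traj <- run_timecourse(inst, setup, rtol = protocol$rtol,
                           atol = protocol$atol)
    verdict <- assess_window(instance, protocol, traj)
    if (!identical(verdict, "settling")) break
    inst$x0 <- as.list(traj$raw[nrow(traj$raw), ])
  }
  if (identical(verdict, "settling"))
    verdict <- list(class = dynamics_class("unclassified"),
                    characteristics = characteristics(
                      diagnostic = "peak heights still drifting after the extension leg"))
  verdict
}

assess_window <- function(instance, protocol, traj) {
  post <- traj$index >= protocol$transient_fraction * protocol$horizon
  tt <- traj$index[post]
  xx <- traj$raw[post, , drop = FALSE]
  state <- colnames(xx)

  rng <- apply(xx, 2L, range)
  mid <- colMeans(xx)
  relvar <- (rng[2L, ] - rng[1L, ]) / pmax(abs(mid), 1e-8)

  if (all(relvar < protocol$tol_fp)) {
    x_ss <- xx[nrow(xx), ]
    names(x_ss) <- state
    return(excitability_verdict(instance, protocol, x_ss))
  }

  # oscillation: the period is read off the relatively most active state;
  # sustainment (no systematic drift of peak heights, first vs second half
  # of the window) may be certified by any appreciably oscillating state --
  # sharp undersampled spikes make one state's interpolated heights noisy,
  # while a slowly decaying focus drifts in every state alike
  period <- NA_real_
  sustained <- FALSE
  for (s in state[order(relvar, decreasing = TRUE)]) {
    if (relvar[[s]] < 1e-3) break
    peaks <- find_peaks(tt, xx[, s])
    if (nrow(peaks) < protocol$n_peaks) next
    intervals <- diff(peaks$time)
    cv <- stats::sd(intervals) / mean(intervals)
    if (!is.finite(cv) || cv >= protocol$tol_period_cv) next
    if (is.na(period)) period <- mean(intervals)
    amp <- mean(peaks$height) - min(xx[, s])
    half <- seq_len(nrow(peaks)) <= nrow(peaks) / 2
    drift <- abs(mean(peaks$height[half]) - mean(peaks$height[!half]))
    if (amp > 0 && drift / amp < protocol$sustain_tol) {
      sustained <- TRUE
      break
    }
  }
  if (!is.na(period)) {
    if (sustained) {
      extrema <- lapply(state, function(s) c(min = unname(rng[1L, s]),
                                             max = unname(rng[2L, s])))
      names(extrema) <- state
      return(list(class = dynamics_class("limit_cycle_oscillation"),
                  characteristics = characteristics(
                    period = period, amplitude_extrema = extrema)))
    }
    return("settling")
  }

  list(class = dynamics_class("unclassified"),
       characteristics = characteristics(
         diagnostic = "neither converged nor sustained oscillation within the protocol horizon"))
}

# decide excitable_switch vs stable_fixed_point for a converged trajectory
excitability_verdict <- function(instance, protocol, x_ss) {
  fp <- list(class = dynamics_class("stable_fixed_point"),
             characteristics = characteristics(steady_state_values = x_ss))
  if (protocol$excitability_ratio <= 0) return(fp)
  state <- names(x_ss)
  s <- protocol$perturb_symbol %||% state[length(state)]
  if (!s %in% state)
    stop("perturbation symbol ", sQuote(s), " is not a state symbol",
         call. = FALSE)
  ref <- protocol$perturb_reference %||% s
  if (!ref %in% state)
    stop("perturbation reference ", sQuote(ref), " is not a state symbol",
         call. = FALSE)
  delta <- protocol$perturb_frac * x_ss[[ref]]
  if (delta <= 0) delta <- protocol$perturb_frac * max(x_ss, 1e-3)
  x1 <- x_ss
  x1[[s]] <- x1[[s]] + delta
  inst2 <- instance
  inst2$x0 <- as.list(x1)
  horizon2 <- protocol$horizon / 2
  traj2 <- run_timecourse(inst2, simulation_setup(0, horizon2, protocol$step),
                          rtol = protocol$rtol, atol = protocol$atol)
  dev <- sweep(traj2$raw, 2L, unlist(x_ss))
  excursion <- max(abs(dev)) / delta
  scale <- pmax(abs(unlist(x_ss)), delta)
  returned <- all(abs(dev[nrow(dev), ]) / scale < 0.01)
  if (excursion >= protocol$excitability_ratio) {
    if (!returned)
      return(list(class = dynamics_class("unclassified"),
                  characteristics = characteristics(
                    steady_state_values = x_ss,
                    excursion_magnitude = excursion,
                    diagnostic = "large excursion without return to the fixed point")))
    return(list(class = dynamics_class("excitable_switch"),
                characteristics = characteristics(
                  steady_state_values = x_ss,
                  excursion_magnitude = excursion)))
  }
  fp$characteristics$excursion_magnitude <- excursion
  fp
}

#' Solve for an equilibrium by Newton iteration
#'
#' @param instance an \code{\link{instantiate}}d model.
#' @param x0 named numeric starting point.
#' @param tol convergence tolerance on the infinity norm of the right-hand
#'   side.
#' @param max_iter maximum Newton steps.
#' @return Named numeric equilibrium point.
#' @export
newton_equilibrium <- function(instance, x0, tol = 1e-12, max_iter = 100L) {
  x <- unlist(x0)[instance$programme$state_symbols]
  for (i in seq_len(max_iter)) {
    f <- instance$rhs_fun(0, x, NULL)[[1L]]
    if (max(abs(f)) < tol) return(x)
    J <- instance$jac_fun(x)
    step <- tryCatch(solve(J, f), error = function(e)
      stop("singular Jacobian during equilibrium search", call. = FALSE))
    # damped Newton: halve until the residual does not blow up
    lambda <- 1
    repeat {
      x_new <- x - lambda * step
      f_new <- instance$rhs_fun(0, x_new, NULL)[[1L]]
      if (all(is.finite(f_new)) &&
          (max(abs(f_new)) < max(abs(f)) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    x <- x_new
  }
  if (max(abs(instance$rhs_fun(0, x, NULL)[[1L]])) < tol * 1e3) return(x)
  stop("equilibrium search did not converge", call. = FALSE)
}

#' Local stability verdict at a fixed point (Jacobian eigenvalues)
#'
#' Linearizes the programme at an approximate equilibrium (the Jacobian is
#' built symbolically from the closed-form right-hand sides) and reports the
#' sign pattern of the eigenvalue real parts.  This is the independent
#' oracle against which the simulation-based \code{\link{classify}} verdict
#' is checked, and the workhorse of Hopf-boundary location.
#'
#' @param instance an \code{\link{instantiate}}d model.
#' @param point named numeric state; must satisfy
#'   \code{max(abs(rhs)) < equilibrium_tol}.
#' @param equilibrium_tol tolerance for accepting \code{point} as an
#'   equilibrium.
#' @return An object of class \code{"sf_stability"}: \code{verdict}
#'   (\code{"stable"}, \code{"unstable"} or \code{"marginal"}),
#'   \code{eigenvalues}, \code{real_parts} and \code{sign_pattern}.
#' @export
jacobian_class_at_fixed_point <- function(instance, point,
                                          equilibrium_tol = 1e-6) {
  stopifnot(inherits(instance, "sf_sim_instance"))
  x <- unlist(point)[instance$programme$state_symbols]
  f <- instance$rhs_fun(0, x, NULL)[[1L]]
  scale <- max(1, max(abs(x)))
  if (max(abs(f)) >= equilibrium_tol * scale)
    stop("point is not an equilibrium (||rhs|| = ", format(max(abs(f))), ")",
         call. = FALSE)
  ev <- eigen(instance$jac_fun(x), only.values = TRUE)$values
  re <- Re(ev)
  verdict <- if (all(re < 0)) "stable" else if (any(re > 0)) "unstable"
             else "marginal"
  structure(list(verdict = verdict, eigenvalues = ev, real_parts = re,
                 sign_pattern = sign(re)),
            class = "sf_stability")
}

#' @export
print.sf_stability <- function(x, ...) {
  cat("<stability>", x$verdict, "- Re(eigenvalues):",
      paste(format(x$real_parts, digits = 4), collapse = ", "), "\n")
  invisible(x)
}
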