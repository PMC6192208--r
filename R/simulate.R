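#' Integrate the model over two cell cycles
#'
#' Solves the model ODE from t = 0 (the synchronization release) to
#' t = 2T, two full cell-cycle periods, the horizon over which time
#' averages are taken. The trajectory is evaluated on a dense grid
#' (10-second spacing by default, 481 points for an 80-min cycle) plus
#' any requested evaluation times.
#'
#' Two solver backends are available. \code{"lsoda"} (the default) uses
#' the stiff-capable adaptive solver from \pkg{deSolve} at relative
#' tolerance 1e-7 and absolute tolerance 1e-10 uM. \code{"rk4"} is a
#' compiled fixed-step classical Runge-Kutta integrator whose step is
#' capped from the fastest first-order rate in the parameter vector; it
#' is used on the sampler's hot path where millions of solves are needed,
#' and agrees with lsoda well within the likelihood's resolution for
#' parameters in the default prior box (see the methods vignette).
#' Solver failure is reported via the \code{success} flag, never as
#' silent NaN; the likelihood maps failures to a log-density of
#' \code{-Inf}.
#'
#' @param model A \code{cyclin_model}.
#' @param params Parameter vector on the storage scale (see
#'   [param_info()]); initial conditions are taken from its
#'   \code{m0_*}/\code{p0_*} entries.
#' @param eval_times Extra evaluation times (seconds) within [0, 2T].
#' @param method "lsoda" or "rk4".
#' @param rtol,atol Tolerances for the lsoda backend.
#' @param grid_points Number of points of the dense output grid.
#' @param ymax Divergence guard for the rk4 backend: any concentration
#'   above this aborts the solve as a failure.
#' @return Object of class \code{cyclin_traj}: list with \code{times}
#'   (seconds), \code{conc} (matrix, time x species, uM), \code{species},
#'   \code{period}, \code{success}, \code{method}.
#' @export
integrate_model <- function(model, params,
                            eval_times = NULL,
                            method = c("lsoda", "rk4"),
                            rtol = 1e-7, atol = 1e-10,
                            grid_points = 481L, ymax = 1e12) {
  method <- match.arg(method)
  stopifnot(inherits(model, "cyclin_model"))
  T2 <- 2 * model$period
  if (!is.null(eval_times)) {
    if (any(eval_times < 0 | eval_times > T2))
      stop("eval_times must lie within [0, 2T] = [0, ", T2, "] seconds",
           call. = FALSE)
  }
  times <- sort(unique(c(seq(0, T2, length.out = grid_points), eval_times)))
  linear <- unpack_log10(params, model)
  parms <- model_parms(model, linear)
  gn <- model$genes$name
  y0 <- c(linear[paste0("m0_", gn)], linear[paste0("p0_", gn)])
  names(y0) <- model$species

  if (method == "rk4") {
    res <- .Call(C_integrate_rk4, as.numeric(y0), times, parms,
                 rk4_step(linear, gn), ymax)
    conc <- res$y
    success <- res$success
  } else {
    func <- function(t, y, p) list(.Call(C_cyclin_rhs, y, parms))
    sol <- try(deSolve::ode(y = as.numeric(y0), times = times, func = func,
                            parms = NULL, method = "lsoda",
                            rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
        anyNA(sol[, -1])) {
      conc <- matrix(NA_real_, length(times), length(y0))
      success <- FALSE
    } else {
      conc <- unname(sol[, -1, drop = FALSE])
      success <- TRUE
      attr(sol, "istate") <- NULL
    }
  }
  colnames(conc) <- model$species
  structure(list(times = times, conc = conc, species = model$species,
                 period = model$period, success = success, method = method,
                 rtol = rtol, atol = atol),
            class = "cyclin_traj")
}

# Internal step cap for the fixed-step integrator: bound the fastest
# first-order timescale from row sums of the (locally linearized) rate
# matrix and keep lambda * h <= 0.25, never exceeding the 10 s output
# spacing.
rk4_step <- function(linear, gene_names) {
  lam <- max(linear["deltam"] + max(linear[paste0("alpha_", gene_names)]),
             linear["kappa"] + max(linear[paste0("deltap_", gene_names)]))
  min(10, 0.25 / lam)
}

#' @export
print.cyclin_traj <- function(x, ...) {
  cat(sprintf("cyclin trajectory: %d species x %d times over [0, %.0f] s (%s, %s)\n",
              length(x$species), length(x$times), max(x$times), x$method,
              if (x$success) "success" else "FAILED"))
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x A \code{cyclin_traj}.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return Data frame with columns \code{time}, \code{species},
#'   \code{value}.
#' @export
as.data.frame.cyclin_traj <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = rep(x$times, times = length(x$species)),
             species = rep(x$species, each = length(x$times)),
             value = as.vector(x$conc),
             stringsAsFactors = FALSE)
}

#' Time average of a species over two cell cycles
#'
#' Trapezoidal integral of the concentration over [0, 2T] divided by 2T.
#' This time average is the modeled value of steady-state (unsynchronized
#' population) measurements, and the denominator of the modeled relative
#' expression ratios.
#'
#' @param traj A \code{cyclin_traj} spanning [0, 2T].
#' @param species Species name (or index) to average; may be a vector.
#' @return Named numeric vector of time averages, uM.
#' @export
time_average <- function(traj, species = traj$species) {
  stopifnot(inherits(traj, "cyclin_traj"))
  T2 <- 2 * traj$period
  if (max(traj$times) < T2 - 1e-9 || min(traj$times) > 1e-9)
    stop("trajectory must span the full two-cycle horizon [0, ", T2, "] s",
         call. = FALSE)
  y <- traj$conc[, species, drop = FALSE]
  out <- trapz_mean(traj$times, y)
  names(out) <- colnames(y)
  out
}

# Trapezoidal mean of each column of y over the span of x.
trapz_mean <- function(x, y) {
  dx <- diff(x)
  w <- c(dx / 2, 0) + c(0, dx / 2)
  drop(crossprod(w, as.matrix(y))) / (max(x) - min(x))
}

#' Rescale native experiment times to a common cell-cycle period
#'
#' Time-course experiments run under different growth conditions have
#' different doubling times (60 to 100 min in the emulated studies). To
#' make them comparable they are linearly rescaled to a common 80-min
#' cycle, a typical doubling time in rich medium:
#' t' = t * target_period / native_period.
#'
#' @param native_times Times in minutes on the experiment's native clock.
#' @param native_period Native doubling time, minutes (warns outside
#'   60-100).
#' @param target_period Target period, minutes (default 80).
#' @return Rescaled times, minutes.
#' @export
rescale_times <- function(native_times, native_period, target_period = 80) {
  if (native_period <= 0 || target_period <= 0)
    stop("periods must be strictly positive", call. = FALSE)
  if (native_period < 60 || native_period > 100)
    warning("native doubling time ", native_period,
            " min is outside the typical 60-100 min range")
  native_times * target_period / native_period
}
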