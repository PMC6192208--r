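#' Log density of the location-scale Student-t distribution
#'
#' The error model for both data channels is a t-distribution with three
#' degrees of freedom, a standard device for robust inference: occasional
#' measurements far from the model are penalized much less than under a
#' Gaussian. At the mode the standard (scale 1) t3 density equals
#' 2 / (pi * sqrt(3)).
#'
#' @param x Observed value(s).
#' @param center Location.
#' @param scale Scale, strictly positive.
#' @param df Degrees of freedom (default 3).
#' @return Log density, vectorized over \code{x}/\code{center}.
#' @export
log_t_density <- function(x, center, scale, df = 3) {
  if (any(scale <= 0)) stop("scale must be strictly positive", call. = FALSE)
  stats::dt((x - center) / scale, df = df, log = TRUE) - log(scale)
}

#' Log-likelihood of relative time-course data
#'
#' Synchronized-culture expression measured relative to an unsynchronized
#' control is modeled as the log ratio of the transcript concentration to
#' its own time average over two cell cycles:
#' center = log(m_g(t) / mbar_g). Each record contributes a t3 log
#' density with scale \code{sigma_tc}. The centering makes the channel
#' invariant to the absolute concentration scale, which is exactly what
#' relative data cannot measure. A failed simulation yields \code{-Inf}.
#'
#' @param traj A \code{cyclin_traj} spanning two cycles.
#' @param data Time-course data frame with columns \code{experiment},
#'   \code{gene}, \code{time_min} (minutes on the common 80-min scale)
#'   and \code{log_ratio}.
#' @param sigma_tc Error scale on the log-ratio scale (linear value).
#' @param log_base "natural" (default) or "log2" for data reported as
#'   log2 ratios (microarray convention).
#' @return Scalar log-likelihood.
#' @export
relative_loglik <- function(traj, data, sigma_tc, log_base = c("natural", "log2")) {
  log_base <- match.arg(log_base)
  stopifnot(inherits(traj, "cyclin_traj"))
  if (!traj$success) return(-Inf)
  sp <- paste0("mRNA_", data$gene)
  bad <- setdiff(unique(sp), traj$species)
  if (length(bad) > 0)
    stop("gene(s) absent from the model: ",
         paste(sub("^mRNA_", "", bad), collapse = ", "), call. = FALSE)
  t_sec <- data$time_min * 60
  if (any(t_sec < min(traj$times) - 1e-9 | t_sec > max(traj$times) + 1e-9))
    stop("data times outside the simulated horizon", call. = FALSE)
  avg <- time_average(traj, unique(sp))
  m <- vapply(seq_len(nrow(data)), function(i)
    stats::approx(traj$times, traj$conc[, sp[i]], xout = t_sec[i])$y,
    numeric(1))
  if (any(m <= 0) || any(avg[sp] <= 0)) return(-Inf)
  center <- log(m / avg[sp])
  if (log_base == "log2") center <- center / log(2)
  sum(log_t_density(data$log_ratio, center, sigma_tc))
}

#' Log-likelihood of absolute steady-state data
#'
#' Population-average concentrations in unsynchronized cells are modeled
#' as the time average of the corresponding trajectory over two cell
#' cycles, log10 transformed; each record contributes a t3 log density
#' with scale \code{sigma_ss} on the log10 scale (the model is only asked
#' to capture the right order of magnitude).
#'
#' @param traj A \code{cyclin_traj} spanning two cycles.
#' @param data Steady-state data frame with columns \code{kind} ("mRNA"
#'   or "protein"), \code{gene}, \code{log10_conc_uM}, \code{source}.
#' @param sigma_ss Error scale on the log10 scale (linear value).
#' @return Scalar log-likelihood; \code{-Inf} on failed simulation or
#'   non-positive time average.
#' @export
absolute_loglik <- function(traj, data, sigma_ss) {
  stopifnot(inherits(traj, "cyclin_traj"))
  if (!traj$success) return(-Inf)
  sp <- paste0(ifelse(data$kind == "mRNA", "mRNA_", "protein_"), data$gene)
  bad <- setdiff(unique(sp), traj$species)
  if (length(bad) > 0)
    stop("species absent from the model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  avg <- time_average(traj, unique(sp))
  if (any(avg[sp] <= 0)) return(-Inf)
  center <- log10(avg[sp])
  sum(log_t_density(data$log10_conc_uM, center, sigma_ss))
}

#' Log density of the box-uniform prior
#'
#' Independent uniform priors on the storage scale (log10 for all
#' parameters except the Hill exponents). Inside the closed box the log
#' density is the negative log box volume; outside it is \code{-Inf}.
#'
#' @param params Parameter vector on the storage scale.
#' @param prior Prior data frame (see [default_priors()]).
#' @return Scalar log density.
#' @export
log_prior <- function(params, prior) {
  stopifnot(all(prior$lower < prior$upper))
  x <- params[prior$name]
  if (anyNA(x))
    stop("parameter vector is missing entries named in the prior", call. = FALSE)
  if (any(x < prior$lower) || any(x > prior$upper)) return(-Inf)
  -sum(log(prior$upper - prior$lower))
}

#' Tempered log posterior
#'
#' log prior + beta * (time-course log-likelihood + steady-state
#' log-likelihood). Only the likelihood is tempered: at beta = 0 the
#' tempered posterior is exactly the prior, so the coldest replica of the
#' parallel-tempering ladder samples the prior and replica round trips
#' run from prior to posterior.
#'
#' @param params Parameter vector on the storage scale.
#' @param model A \code{cyclin_model}.
#' @param prior Prior data frame.
#' @param tc_data,ss_data Data frames for the two channels (either may be
#'   NULL).
#' @param beta Inverse temperature in [0, 1].
#' @param method Solver backend passed to [integrate_model()].
#' @param log_base Log convention for the relative channel.
#' @return Scalar tempered log posterior.
#' @export
log_posterior_tempered <- function(params, model, prior,
                                   tc_data = NULL, ss_data = NULL,
                                   beta = 1, method = "lsoda",
                                   log_base = "natural") {
  if (beta < 0 || beta > 1)
    stop("beta must lie in [0, 1]", call. = FALSE)
  lp <- log_prior(params, prior)
  if (!is.finite(lp) || beta == 0) return(lp)
  eval_t <- if (!is.null(tc_data)) tc_data$time_min * 60 else NULL
  traj <- integrate_model(model, params, eval_times = eval_t, method = method)
  sigma <- unpack_log10(params, model)
  ll <- 0
  if (!is.null(tc_data))
    ll <- ll + relative_loglik(traj, tc_data, sigma[["sigma_tc"]], log_base)
  if (!is.null(ss_data))
    ll <- ll + absolute_loglik(traj, ss_data, sigma[["sigma_ss"]])
  lp + beta * ll
}

# Physical ceiling on concentrations during inference: a trajectory
# exceeding 1e3 uM (millimolar mRNA or protein, far beyond anything a
# yeast cell holds) is treated as a failed simulation, giving the
# parameter point a -Inf log-likelihood. The same ceiling defines the
# set of simulable parameters used when drawing ground truths for
# calibration studies, so the two supports coincide exactly.
conc_ceiling <- 1e3

#' Can a parameter point be simulated within physical bounds?
#'
#' Checks that the fast solver integrates the model over two cycles
#' without failure and that no concentration exceeds the inference
#' ceiling of 1e3 uM. Parameter points violating this receive a
#' log-likelihood of \code{-Inf} during inference, so calibration
#' studies draw their ground truths conditional on this predicate.
#'
#' @param model A \code{cyclin_model}.
#' @param params Parameter vector on the storage scale.
#' @return Logical.
#' @export
params_simulable <- function(model, params) {
  traj <- integrate_model(model, params, method = "rk4",
                          ymax = conc_ceiling)
  traj$success
}

# Precompute an index map from the parameter-info order onto the flat
# parms vector used by the compiled right-hand side, so the sampler's
# likelihood closure avoids name lookups.
make_parms_mapper <- function(model) {
  info <- param_info(model)
  gn <- model$genes$name
  n <- length(gn)
  template <- model_parms(model, stats::setNames(rep(1, nrow(info)), info$name))
  slot <- function(names, offset)
    list(parms_pos = offset + seq_along(names),
         full_pos = match(names, info$name))
  maps <- list(
    slot(paste0("beta_", gn), 3 * n + 1),
    slot(paste0("alpha_", gn), 4 * n + 1),
    slot(paste0("deltap_", gn), 5 * n + 1),
    slot("deltam", 6 * n + 1),
    slot("kappa", 6 * n + 2))
  ti <- which(!is.na(model$genes$transcription_inhibitor))
  if (length(ti) > 0) {
    maps <- c(maps, list(
      list(parms_pos = 6 * n + 3 + ti,
           full_pos = match(paste0("K_tx_", gn[ti]), info$name)),
      list(parms_pos = 7 * n + 3 + ti,
           full_pos = match(paste0("h_tx_", gn[ti]), info$name))))
  }
  di <- which(!is.na(model$genes$degradation_inhibitor))
  if (length(di) > 0) {
    maps <- c(maps, list(
      list(parms_pos = 8 * n + 3 + di,
           full_pos = match(paste0("K_deg_", gn[di]), info$name)),
      list(parms_pos = 9 * n + 3 + di,
           full_pos = match(paste0("h_deg_", gn[di]), info$name))))
  }
  list(template = template,
       parms_pos = unlist(lapply(maps, `[[`, "parms_pos")),
       full_pos = unlist(lapply(maps, `[[`, "full_pos")),
       y0_pos = match(c(paste0("m0_", gn), paste0("p0_", gn)), info$name),
       alpha_pos = match(paste0("alpha_", gn), info$name),
       deltap_pos = match(paste0("deltap_", gn), info$name),
       deltam_pos = match("deltam", info$name),
       kappa_pos = match("kappa", info$name),
       log_mask = info$scale == "log10",
       info = info)
}

#' Build fast prior and likelihood evaluators for inference
#'
#' Returns closures over a subset of free parameters (the rest held fixed)
#' evaluating the box-uniform log prior and the joint log-likelihood of
#' the supplied channels. The likelihood solves the ODE once per call
#' with the compiled fixed-step integrator and reuses the solution for
#' both channels; out-of-box states short-circuit in the prior without
#' touching the solver. This is the evaluation path used by [run_pt()].
#'
#' @param model A \code{cyclin_model}.
#' @param prior Prior data frame covering every model parameter.
#' @param tc_data,ss_data Data frames for the two channels (either may be
#'   NULL for single-channel inference).
#' @param fixed Named numeric vector of parameters held fixed at the
#'   given storage-scale values; all others are free.
#' @param log_base Log convention for the relative channel.
#' @param grid_points Dense-grid resolution for time averaging.
#' @return List with elements \code{log_prior(theta)},
#'   \code{log_lik(theta)}, \code{free} (names of free parameters),
#'   \code{lower}, \code{upper} (their bounds), and
#'   \code{full(theta)} mapping free values to a full parameter vector.
#' @export
make_loglik <- function(model, prior, tc_data = NULL, ss_data = NULL,
                        fixed = NULL, log_base = c("natural", "log2"),
                        grid_points = 481L) {
  log_base <- match.arg(log_base)
  mp <- make_parms_mapper(model)
  info <- mp$info
  if (!setequal(prior$name, info$name))
    stop("prior must cover exactly the model's parameters", call. = FALSE)
  prior <- prior[match(info$name, prior$name), ]
  full0 <- stats::setNames(rep(NA_real_, nrow(info)), info$name)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), info$name)
    if (length(bad) > 0)
      stop("fixed parameter(s) not in the model: ",
           paste(bad, collapse = ", "), call. = FALSE)
    full0[names(fixed)] <- fixed
  }
  free_idx <- which(is.na(full0))
  free <- info$name[free_idx]
  lower <- prior$lower[free_idx]
  upper <- prior$upper[free_idx]
  lp_const <- -sum(log(upper - lower))
  T2 <- 2 * model$period
  ln2 <- log(2)

  tc_t <- if (!is.null(tc_data)) tc_data$time_min * 60 else numeric(0)
  grid <- sort(unique(c(seq(0, T2, length.out = grid_points), tc_t)))
  w <- { dx <- diff(grid); (c(dx / 2, 0) + c(0, dx / 2)) / T2 }
  nsp <- length(model$species)

  if (!is.null(tc_data)) {
    tc_col <- match(paste0("mRNA_", tc_data$gene), model$species)
    if (anyNA(tc_col))
      stop("time-course gene(s) absent from the model: ",
           paste(unique(tc_data$gene[is.na(tc_col)]), collapse = ", "),
           call. = FALSE)
    tc_row <- match(tc_t, grid)
    tc_y <- tc_data$log_ratio
  }
  if (!is.null(ss_data)) {
    ss_col <- match(paste0(ifelse(ss_data$kind == "mRNA", "mRNA_", "protein_"),
                           ss_data$gene), model$species)
    if (anyNA(ss_col))
      stop("steady-state species absent from the model", call. = FALSE)
    ss_y <- ss_data$log10_conc_uM
  }
  sig_tc_pos <- match("sigma_tc", info$name)
  sig_ss_pos <- match("sigma_ss", info$name)

  to_linear <- function(full) {
    lin <- full
    lin[mp$log_mask] <- 10^full[mp$log_mask]
    lin
  }
  full_fun <- function(theta) {
    full <- full0
    full[free_idx] <- theta
    full
  }
  log_prior_fun <- function(theta) {
    if (any(theta < lower) || any(theta > upper)) -Inf else lp_const
  }
  log_lik_fun <- function(theta) {
    full <- full0
    full[free_idx] <- theta
    lin <- to_linear(full)
    parms <- mp$template
    parms[mp$parms_pos] <- lin[mp$full_pos]
    lam <- max(lin[mp$deltam_pos] + max(lin[mp$alpha_pos]),
               lin[mp$kappa_pos] + max(lin[mp$deltap_pos]))
    res <- .Call(C_integrate_rk4, lin[mp$y0_pos], grid, parms,
                 min(10, 0.25 / lam), conc_ceiling)
    if (!res$success) return(-Inf)
    Y <- res$y
    ll <- 0
    if (!is.null(tc_data)) {
      avg <- as.vector(w %*% Y)
      m <- Y[cbind(tc_row, tc_col)]
      a <- avg[tc_col]
      if (any(m <= 0) || any(a <= 0)) return(-Inf)
      center <- log(m / a)
      if (log_base == "log2") center <- center / ln2
      s <- lin[sig_tc_pos]
      ll <- ll + sum(stats::dt((tc_y - center) / s, df = 3, log = TRUE)) -
        length(tc_y) * log(s)
    }
    if (!is.null(ss_data)) {
      if (is.null(tc_data)) avg <- as.vector(w %*% Y)
      a <- avg[ss_col]
      if (any(a <= 0)) return(-Inf)
      s <- lin[sig_ss_pos]
      ll <- ll + sum(stats::dt((ss_y - log10(a)) / s, df = 3, log = TRUE)) -
        length(ss_y) * log(s)
    }
    as.numeric(ll)
  }
  list(log_prior = log_prior_fun, log_lik = log_lik_fun,
       free = free, lower = lower, upper = upper, full = full_fun)
}
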