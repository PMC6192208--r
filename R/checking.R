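#' Posterior predictive bands for the relative time-course channel
#'
#' For each posterior draw, simulates the model and evaluates the
#' modeled log ratio (concentration over its own two-cycle time average)
#' at the design times; reports pointwise quantiles across draws. By
#' default this is the predictive distribution of the *mean* of the
#' data (no observation noise re-added); set \code{add_noise} to overlay
#' t3 observation noise for a full predictive check, in which case the
#' draw matrix must contain a \code{sigma_tc} column.
#'
#' @param draws Matrix of posterior draws, columns named with full model
#'   parameters (use the \code{full} mapper from [make_loglik()] if some
#'   parameters were held fixed).
#' @param model A \code{cyclin_model}.
#' @param genes Genes to predict.
#' @param times_min Evaluation times, minutes on the common 80-min
#'   scale.
#' @param probs Quantiles to report (default 5/50/95%).
#' @param add_noise Add t3 observation noise to each curve.
#' @param log_base Log convention for the ratios.
#' @param method Solver backend.
#' @return Data frame with columns \code{gene}, \code{time_min} and one
#'   \code{q<prob>} column per quantile, plus attribute
#'   \code{n_failed} (simulation failures dropped).
#' @export
posterior_predictive <- function(draws, model, genes = model$genes$name,
                                 times_min = seq(0, 160, by = 2.5),
                                 probs = c(0.05, 0.5, 0.95),
                                 add_noise = FALSE,
                                 log_base = c("natural", "log2"),
                                 method = "rk4") {
  log_base <- match.arg(log_base)
  draws <- as.matrix(draws)
  if (nrow(draws) < 1) stop("need at least one draw", call. = FALSE)
  sp <- paste0("mRNA_", genes)
  nt <- length(times_min)
  curves <- array(NA_real_, c(nrow(draws), nt, length(genes)))
  failed <- 0L
  for (k in seq_len(nrow(draws))) {
    traj <- integrate_model(model, draws[k, ], eval_times = times_min * 60,
                            method = method)
    if (!traj$success) { failed <- failed + 1L; next }
    avg <- time_average(traj, sp)
    if (any(avg <= 0)) { failed <- failed + 1L; next }
    idx <- match(times_min * 60, traj$times)
    for (j in seq_along(genes)) {
      v <- log(traj$conc[idx, sp[j]] / avg[sp[j]])
      if (log_base == "log2") v <- v / log(2)
      curves[k, , j] <- v
    }
    if (add_noise) {
      s <- 10^draws[k, "sigma_tc"]
      curves[k, , ] <- curves[k, , ] + s * stats::rt(nt * length(genes), df = 3)
    }
  }
  if (failed > 0)
    message("posterior_predictive: dropped ", failed, " failed simulation(s)")
  if (failed == nrow(draws))
    stop("all simulations failed", call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(genes), function(j) {
    q <- apply(curves[, , j, drop = FALSE], 2, stats::quantile, probs = probs,
               na.rm = TRUE)
    d <- data.frame(gene = genes[j], time_min = times_min)
    for (i in seq_along(probs))
      d[[paste0("q", format(100 * probs[i], trim = TRUE))]] <- q[i, ]
    d
  }))
  attr(out, "n_failed") <- failed
  out
}

#' Coefficient of determination against a per-experiment-mean null
#'
#' R^2 = 1 - SS_res / SS_null where the null model predicts each
#' experiment's own mean. This null absorbs between-experiment offsets,
#' so R^2 measures how much of the within-experiment (dynamic) variation
#' the predictions explain; predictions worse than the per-experiment
#' means give negative values.
#'
#' @param observed,predicted Numeric vectors.
#' @param experiment Experiment identifier per record.
#' @return Scalar R^2 (NA with a warning if the null has zero variance).
#' @export
r_squared <- function(observed, predicted, experiment) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(experiment))
  if (any(table(experiment) < 2))
    stop("need at least 2 records per experiment", call. = FALSE)
  mu <- tapply(observed, experiment, mean)
  ss_null <- sum((observed - mu[as.character(experiment)])^2)
  if (ss_null == 0) {
    warning("null model has zero residual variance; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_null
}

#' Reference R^2 from a cross-validated smoothing spline
#'
#' Fits a cubic smoothing spline per experiment with the smoothing
#' parameter selected by leave-one-out cross-validation over a fixed
#' grid of 25 log-spaced penalty values (deterministic: identical input
#' gives identical output). The resulting [r_squared()] against the
#' per-experiment-mean null is an estimate of the best fit any smooth
#' curve could achieve, the yardstick against which model R^2 values
#' are judged.
#'
#' @param data Data frame with columns \code{experiment},
#'   \code{time_min}, \code{log_ratio} for a single gene.
#' @param lambda_grid Penalty grid searched by leave-one-out CV.
#' @return List with \code{r2} and per-experiment selected
#'   \code{lambda}; \code{r2} is NA if any experiment has fewer than 8
#'   time points.
#' @export
spline_reference_r2 <- function(data,
                                lambda_grid = 10^seq(-10, 2, length.out = 25)) {
  stopifnot(all(c("experiment", "time_min", "log_ratio") %in% names(data)))
  exps <- unique(data$experiment)
  if (any(vapply(exps, function(e)
    length(unique(data$time_min[data$experiment == e])), numeric(1)) < 8)) {
    return(list(r2 = NA_real_, lambda = NULL))
  }
  pred <- numeric(nrow(data))
  lam_sel <- stats::setNames(numeric(length(exps)), exps)
  for (e in exps) {
    i <- which(data$experiment == e)
    x <- data$time_min[i]; y <- data$log_ratio[i]
    cvs <- vapply(lambda_grid, function(lam) {
      # genuine leave-one-out refits: exact for every penalty, including
      # near-interpolating ones where the leverage shortcut is unstable
      err <- vapply(seq_along(x), function(k) {
        f <- try(stats::smooth.spline(x[-k], y[-k], lambda = lam,
                                      keep.stuff = FALSE), silent = TRUE)
        if (inherits(f, "try-error")) return(Inf)
        (y[k] - stats::predict(f, x[k])$y)^2
      }, numeric(1))
      mean(err)
    }, numeric(1))
    lam <- lambda_grid[which.min(cvs)]
    lam_sel[as.character(e)] <- lam
    f <- stats::smooth.spline(x, y, lambda = lam)
    pred[i] <- stats::predict(f, x)$y
  }
  list(r2 = r_squared(data$log_ratio, pred, data$experiment),
       lambda = lam_sel)
}

#' Credible-interval width accounting
#'
#' For each parameter, the width of the central 90% credible interval
#' (q95 - q5 on the storage scale, log10 for all but Hill exponents),
#' its ratio to the prior range, and the count of parameters whose
#' interval is narrower than half the prior range — the summary used to
#' quantify how much each data combination constrains the model.
#'
#' @param draws Named-column matrix of posterior draws.
#' @param prior Prior data frame covering (at least) the draw columns.
#' @return List with \code{table} (parameter, width, prior_width, ratio)
#'   and \code{n_below_half} (ratio < 0.5 count).
#' @export
ci_width_summary <- function(draws, prior) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 100)
    stop("need at least 100 draws for stable interval widths", call. = FALSE)
  nm <- colnames(draws)
  if (is.null(nm)) stop("draws must have named columns", call. = FALSE)
  i <- match(nm, prior$name)
  if (anyNA(i))
    stop("parameter(s) missing from prior: ",
         paste(nm[is.na(i)], collapse = ", "), call. = FALSE)
  q <- apply(draws, 2, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
  width <- q[2, ] - q[1, ]
  pw <- prior$upper[i] - prior$lower[i]
  tab <- data.frame(parameter = nm, width = width, prior_width = pw,
                    ratio = width / pw, row.names = NULL)
  list(table = tab, n_below_half = sum(tab$ratio < 0.5))
}

#' Plot posterior predictive bands over the data
#'
#' Base-graphics overlay of the predictive median and band on the
#' observed time-course records, one panel per gene (the standard
#' graphical posterior-predictive check).
#'
#' @param pp Output of [posterior_predictive()].
#' @param data Time-course data frame.
#' @param file Optional PNG path; if NULL, plots to the active device.
#' @return Invisibly, NULL.
#' @export
plot_predictive_bands <- function(pp, data, file = NULL) {
  genes <- unique(pp$gene)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 300 * ceiling(length(genes) / 3))
    on.exit(grDevices::dev.off())
  }
  graphics::par(mfrow = c(ceiling(length(genes) / 3), min(3, length(genes))),
                mar = c(4, 4, 2, 1))
  qlo <- pp[[grep("^q", names(pp), value = TRUE)[1]]]
  qhi <- pp[[rev(grep("^q", names(pp), value = TRUE))[1]]]
  for (g in genes) {
    i <- pp$gene == g
    j <- data$gene == g
    ylim <- range(c(qlo[i], qhi[i], data$log_ratio[j]), finite = TRUE)
    plot(NA, xlim = range(pp$time_min), ylim = ylim, xlab = "time (min)",
         ylab = "log ratio", main = g)
    graphics::polygon(c(pp$time_min[i], rev(pp$time_min[i])),
                      c(qlo[i], rev(qhi[i])),
                      col = grDevices::adjustcolor("red", 0.25), border = NA)
    graphics::lines(pp$time_min[i], pp$q50[i], col = "red", lwd = 2)
    for (e in unique(data$experiment[j])) {
      k <- j & data$experiment == e
      graphics::lines(data$time_min[k], data$log_ratio[k], type = "b",
                      pch = 16, cex = 0.6)
    }
  }
  invisible(NULL)
}
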