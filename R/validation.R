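#' Time-averaged total transcription rate of a gene
#'
#' Published transcription-rate measurements are population averages over
#' unsynchronized cells, so each cell sits at a different cell-cycle
#' phase. The comparable model quantity is the total transcription rate
#' (basal + activator-induced, including any transcriptional
#' inhibition) averaged over two cell cycles:
#' mean over [0, 2T] of (beta_g + alpha_g P_act(t)) f_inh(t).
#'
#' @param traj A \code{cyclin_traj} spanning two cycles.
#' @param params Parameter vector on the storage scale.
#' @param model A \code{cyclin_model}.
#' @param gene Gene name(s); default all genes.
#' @return Named numeric vector of time-averaged transcription rates,
#'   uM/s.
#' @export
time_avg_transcription_rate <- function(traj, params, model,
                                        gene = model$genes$name) {
  stopifnot(inherits(traj, "cyclin_traj"))
  T2 <- 2 * model$period
  if (max(traj$times) < T2 - 1e-9)
    stop("trajectory must span two full cycles", call. = FALSE)
  linear <- unpack_log10(params, model)
  out <- vapply(gene, function(g) {
    i <- match(g, model$genes$name)
    if (is.na(i)) stop("gene not in model: ", g, call. = FALSE)
    act <- model$genes$activator[i]
    rate <- linear[[paste0("beta_", g)]] +
      linear[[paste0("alpha_", g)]] * traj$conc[, paste0("protein_", act)]
    ti <- model$genes$transcription_inhibitor[i]
    if (!is.na(ti)) {
      rate <- rate * inhibition_factor(pmax(traj$conc[, paste0("protein_", ti)], 0),
                                       linear[[paste0("K_tx_", g)]],
                                       linear[[paste0("h_tx_", g)]])
    }
    trapz_mean(traj$times, matrix(rate, ncol = 1))
  }, numeric(1))
  names(out) <- gene
  out
}

#' Maximum a posteriori draw
#'
#' Returns the posterior draw with the highest recorded (unnormalized)
#' log posterior density; ties resolve to the first such draw. Used for
#' order-of-magnitude comparisons of rate estimates against independent
#' measurements.
#'
#' @param fit A \code{pt_fit}, or a draw matrix together with
#'   \code{log_post}.
#' @param log_post Log posterior densities per draw (taken from the fit
#'   if omitted).
#' @return Named numeric vector: the MAP draw.
#' @export
map_estimate <- function(fit, log_post = NULL) {
  if (inherits(fit, "pt_fit")) {
    draws <- fit$draws
    if (is.null(log_post)) log_post <- fit$log_post
  } else draws <- as.matrix(fit)
  if (is.null(log_post) || nrow(draws) == 0 || length(log_post) != nrow(draws))
    stop("need a non-empty draw set with one log posterior value per draw",
         call. = FALSE)
  draws[which.max(log_post), ]
}

#' Compare rate estimates with independent validation measurements
#'
#' For each validation record, reports the log10 difference
#' Delta = log10(measured) - log10(estimate) and whether the two agree
#' within half an order of magnitude (|Delta| < 0.5). If posterior draws
#' of the rate are supplied, also reports whether the measured value
#' falls inside the central 90% credible interval.
#'
#' @param estimates Named numeric vector of point estimates on the
#'   linear scale (names matching \code{paste(kind, gene)} keys; see
#'   Details).
#' @param rates Validation data frame with columns \code{kind}
#'   (\code{mrna_degradation}, \code{transcription},
#'   \code{translation}), \code{gene}, \code{value}, \code{units},
#'   \code{source}.
#' @param draws Optional named list mapping the same keys to numeric
#'   vectors of posterior draws (linear scale) for the CI check.
#'
#' @details The estimate for a record with kind \code{k} and gene
#'   \code{g} is looked up as \code{estimates[[paste(k, g, sep = ".")]]}
#'   and, if absent, as \code{estimates[[k]]} (shared parameters such as
#'   the common mRNA degradation rate or the shared translation rate are
#'   compared against per-gene measurements).
#'
#' @return Data frame: the input records plus \code{estimate},
#'   \code{delta_log10}, \code{within_half_order} and (if draws given)
#'   \code{in_ci90}.
#' @export
compare_to_validation <- function(estimates, rates, draws = NULL) {
  stopifnot(all(c("kind", "gene", "value") %in% names(rates)))
  bad <- setdiff(rates$kind, c("mrna_degradation", "transcription", "translation"))
  if (length(bad) > 0)
    stop("unknown validation rate kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(rates$value <= 0))
    stop("validation rate values must be positive", call. = FALSE)
  lookup <- function(set, k, g) {
    key <- paste(k, g, sep = ".")
    if (!is.null(set[[key]])) set[[key]] else set[[k]]
  }
  est <- vapply(seq_len(nrow(rates)), function(i) {
    v <- lookup(as.list(estimates), rates$kind[i], rates$gene[i])
    if (is.null(v)) stop("no estimate for validation record ", i, " (",
                         rates$kind[i], " ", rates$gene[i], ")",
                         call. = FALSE)
    v
  }, numeric(1))
  out <- rates
  out$estimate <- est
  out$delta_log10 <- log10(rates$value) - log10(est)
  out$within_half_order <- abs(out$delta_log10) < 0.5
  if (!is.null(draws)) {
    out$in_ci90 <- vapply(seq_len(nrow(rates)), function(i) {
      dv <- lookup(draws, rates$kind[i], rates$gene[i])
      if (is.null(dv)) return(NA)
      ci <- stats::quantile(dv, c(0.05, 0.95), names = FALSE)
      rates$value[i] >= ci[1] && rates$value[i] <= ci[2]
    }, logical(1))
  }
  out
}
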