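# High-level pipeline steps driven by a run-configuration file. Each
# step reads and writes only the files declared in the config, so a full
# analysis is: synth -> infer -> check -> compare. A thin command-line
# wrapper over these functions ships in inst/scripts/cyclinpt.R.

as_config <- function(config) {
  if (is.character(config)) read_run_config(config) else config
}

#' Generate a synthetic study into the output directory
#'
#' Builds the model named by the config, takes the ground truth from the
#' configured preset (or a prior draw), generates all three data
#' channels with [gen_time_course()], [gen_steady_state()] and
#' [gen_validation_rates()], and writes \code{time_course.csv},
#' \code{steady_state.csv}, \code{validation_rates.csv} and
#' \code{truth.csv} to \code{output_dir}. The config's \code{synth}
#' block may set \code{preset} ("v4", "reduced" or "prior-draw"),
#' \code{seed} and the three noise scales.
#'
#' @param config Path to a YAML run config, or an already-validated
#'   config list.
#' @return Invisibly, the output directory.
#' @export
pipeline_synth <- function(config) {
  cfg <- as_config(config)
  mp <- config_model(cfg)
  sy <- cfg$synth %||% list()
  preset <- sy$preset %||% "v4"
  seed <- sy$seed %||% cfg$sampler$seed
  truth <- if (preset == "prior-draw")
    gen_ground_truth(seed, mp$prior, mode = "prior-draw")
  else gen_ground_truth(seed, mp$prior, mode = "preset", preset = preset)
  design <- synth_design(mp$model, truth,
                         sigma_tc = sy$sigma_tc %||% 0.2,
                         sigma_ss = sy$sigma_ss %||% 0.2,
                         sigma_val = sy$sigma_val %||% 0.2,
                         seed = seed)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_time_course(gen_time_course(design),
                    file.path(cfg$output_dir, "time_course.csv"))
  write_steady_state(gen_steady_state(design),
                     file.path(cfg$output_dir, "steady_state.csv"))
  write_validation_rates(gen_validation_rates(design),
                         file.path(cfg$output_dir, "validation_rates.csv"))
  write_truth(design$truth, file.path(cfg$output_dir, "truth.csv"))
  invisible(cfg$output_dir)
}

# Shared setup for infer/check/compare: model, prior, data, fixed mask.
pipeline_setup <- function(cfg) {
  mp <- config_model(cfg)
  tc <- if (!is.null(cfg$data$time_course))
    read_time_course(cfg$data$time_course)
  ss <- if (!is.null(cfg$data$steady_state))
    read_steady_state(cfg$data$steady_state)
  fixed <- if (!is.null(cfg$fixed)) unlist(cfg$fixed)
  c(mp, list(tc = tc, ss = ss, fixed = fixed))
}

#' Run parallel-tempered inference from a config
#'
#' Reads the configured datasets, assembles the tempered posterior with
#' [make_loglik()] (any \code{fixed} parameters held at their configured
#' storage-scale values), runs [run_pt()] with the configured sampler
#' settings, and writes the posterior archive to
#' \code{output_dir/posterior/}.
#'
#' @param config Path to a YAML run config, or a config list.
#' @return The \code{pt_fit}, invisibly.
#' @export
pipeline_infer <- function(config) {
  cfg <- as_config(config)
  st <- pipeline_setup(cfg)
  if (is.null(st$tc) && is.null(st$ss))
    stop("config: no datasets given; need data.time_course and/or data.steady_state",
         call. = FALSE)
  L <- make_loglik(st$model, st$prior, st$tc, st$ss, fixed = st$fixed,
                   log_base = cfg$log_base)
  s <- cfg$sampler
  fit <- run_pt(L$log_lik, L$lower, L$upper,
                ladder = make_ladder(s$n_chains, s$swap_prob, s$mh_steps),
                burn_in = s$burn_in, n_iter = s$n_iter,
                subsample = s$subsample, seed = s$seed,
                par_names = L$free)
  write_posterior_archive(fit, file.path(cfg$output_dir, "posterior"))
  invisible(fit)
}

# Map archive draws (free parameters only) to full parameter rows.
full_draws <- function(draws, model, fixed) {
  info <- param_info(model)
  out <- matrix(NA_real_, nrow(draws), nrow(info),
                dimnames = list(NULL, info$name))
  out[, colnames(draws)] <- draws
  if (!is.null(fixed)) out[, names(fixed)] <- rep(fixed, each = nrow(draws))
  if (anyNA(out))
    stop("draws + fixed values do not cover all model parameters",
         call. = FALSE)
  out
}

#' Posterior checking from a config
#'
#' Loads the posterior archive, computes posterior-predictive bands for
#' every gene, the per-gene R^2 distribution over posterior draws
#' (against the per-experiment-mean null), the smoothing-spline
#' reference R^2, and the credible-interval width summary. Writes
#' \code{predictive_bands.csv}, \code{r2.csv}, \code{ci_widths.csv} and
#' \code{bands.png} under \code{output_dir/check/}.
#'
#' @param config Path to a YAML run config, or a config list.
#' @param n_pp_draws Maximum posterior draws used for simulation-based
#'   summaries.
#' @return List with the three tables, invisibly.
#' @export
pipeline_check <- function(config, n_pp_draws = 100) {
  cfg <- as_config(config)
  st <- pipeline_setup(cfg)
  if (is.null(st$tc))
    stop("config: checking requires data.time_course", call. = FALSE)
  arch <- read_posterior_archive(file.path(cfg$output_dir, "posterior"))
  fd <- full_draws(arch$draws, st$model, st$fixed)
  keep <- seq_len(nrow(fd))
  if (length(keep) > n_pp_draws)
    keep <- round(seq(1, nrow(fd), length.out = n_pp_draws))
  genes <- intersect(st$model$genes$name, unique(st$tc$gene))
  pp <- posterior_predictive(fd[keep, , drop = FALSE], st$model, genes)

  r2_draws <- matrix(NA_real_, length(keep), length(genes),
                     dimnames = list(NULL, genes))
  for (k in seq_along(keep)) {
    traj <- integrate_model(st$model, fd[keep[k], ],
                            eval_times = st$tc$time_min * 60, method = "rk4")
    if (!traj$success) next
    avg <- time_average(traj, paste0("mRNA_", genes))
    for (g in genes) {
      i <- st$tc$gene == g
      sp <- paste0("mRNA_", g)
      m <- stats::approx(traj$times, traj$conc[, sp],
                         st$tc$time_min[i] * 60)$y
      pred <- log(m / avg[sp])
      if (cfg$log_base == "log2") pred <- pred / log(2)
      r2_draws[k, g] <- r_squared(st$tc$log_ratio[i], pred,
                                  st$tc$experiment[i])
    }
  }
  r2 <- do.call(rbind, lapply(genes, function(g) {
    v <- r2_draws[, g]
    spl <- spline_reference_r2(st$tc[st$tc$gene == g, ])
    data.frame(gene = g,
               r2_median = stats::median(v, na.rm = TRUE),
               r2_lo = stats::quantile(v, 0.05, na.rm = TRUE, names = FALSE),
               r2_hi = stats::quantile(v, 0.95, na.rm = TRUE, names = FALSE),
               r2_spline = spl$r2)
  }))
  ci <- ci_width_summary(arch$draws, st$prior)

  out <- file.path(cfg$output_dir, "check")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pp, file.path(out, "predictive_bands.csv"),
                   row.names = FALSE)
  utils::write.csv(r2, file.path(out, "r2.csv"), row.names = FALSE)
  utils::write.csv(ci$table, file.path(out, "ci_widths.csv"),
                   row.names = FALSE)
  plot_predictive_bands(pp, st$tc, file.path(out, "bands.png"))
  invisible(list(predictive = pp, r2 = r2, ci = ci))
}

#' Compare posterior rate estimates with validation measurements
#'
#' Loads the posterior archive and the validation rate table, forms
#' point estimates at the maximum a posteriori draw (shared mRNA
#' degradation rate deltam, shared translation rate kappa, and per-gene
#' time-averaged transcription rates), posterior draws of each rate for
#' the credible-interval check, and writes \code{comparison.csv} under
#' \code{output_dir/compare/}.
#'
#' @param config Path to a YAML run config, or a config list.
#' @param n_rate_draws Maximum posterior draws used for the
#'   transcription-rate posteriors.
#' @return The comparison data frame, invisibly.
#' @export
pipeline_compare <- function(config, n_rate_draws = 100) {
  cfg <- as_config(config)
  st <- pipeline_setup(cfg)
  if (is.null(cfg$data$validation_rates))
    stop("config: comparison requires data.validation_rates", call. = FALSE)
  rates <- read_validation_rates(cfg$data$validation_rates)
  arch <- read_posterior_archive(file.path(cfg$output_dir, "posterior"))
  fd <- full_draws(arch$draws, st$model, st$fixed)
  map <- fd[which.max(arch$log_post), ]

  genes <- unique(rates$gene[rates$kind == "transcription"])
  genes <- intersect(genes, st$model$genes$name)
  traj_map <- integrate_model(st$model, map, method = "lsoda")
  tx_map <- if (length(genes) > 0 && traj_map$success)
    time_avg_transcription_rate(traj_map, map, st$model, genes)
  estimates <- c(list(mrna_degradation = 10^map[["deltam"]],
                      translation = 10^map[["kappa"]]),
                 stats::setNames(as.list(unname(tx_map)),
                                 paste0("transcription.", genes)))

  keep <- seq_len(nrow(fd))
  if (length(keep) > n_rate_draws)
    keep <- round(seq(1, nrow(fd), length.out = n_rate_draws))
  tx_draws <- matrix(NA_real_, length(keep), length(genes),
                     dimnames = list(NULL, genes))
  for (k in seq_along(keep)) {
    traj <- integrate_model(st$model, fd[keep[k], ], method = "rk4")
    if (!traj$success) next
    tx_draws[k, ] <- time_avg_transcription_rate(traj, fd[keep[k], ],
                                                 st$model, genes)
  }
  draws <- c(list(mrna_degradation = 10^fd[, "deltam"],
                  translation = 10^fd[, "kappa"]),
             stats::setNames(lapply(genes, function(g)
               tx_draws[is.finite(tx_draws[, g]), g]),
               paste0("transcription.", genes)))
  cmp <- compare_to_validation(estimates, rates, draws)
  out <- file.path(cfg$output_dir, "compare")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cmp, file.path(out, "comparison.csv"), row.names = FALSE)
  invisible(cmp)
}

#' Dispatch a pipeline step by name
#'
#' Entry point used by the command-line wrapper: runs one of
#' \code{synth}, \code{infer}, \code{check} or \code{compare} against a
#' config file.
#'
#' @param step Step name.
#' @param config Path to a YAML run config.
#' @return The step's return value, invisibly.
#' @export
cyclinpt_run <- function(step = c("synth", "infer", "check", "compare"),
                         config) {
  step <- match.arg(step)
  switch(step,
         synth = pipeline_synth(config),
         infer = pipeline_infer(config),
         check = pipeline_check(config),
         compare = pipeline_compare(config))
}
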