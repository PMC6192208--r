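#' Quadratic inverse-temperature ladder
#'
#' Configuration for parallel tempering: n chains with inverse
#' temperatures distributed quadratically, beta_i = (i/(n-1))^2 for
#' i = 0..n-1, so beta_0 = 0 (the prior) and beta_{n-1} = 1 (the
#' posterior). Defaults mirror the reference sampler settings: 32
#' chains, swap probability 0.99, five Metropolis-Hastings steps per
#' update move.
#'
#' @param n_chains Number of chains (>= 2).
#' @param swap_prob Probability that an iteration is a swap move.
#' @param mh_steps Metropolis-Hastings sweeps per update move.
#' @return Object of class \code{pt_ladder} with elements \code{betas},
#'   \code{n_chains}, \code{swap_prob}, \code{mh_steps}.
#' @export
make_ladder <- function(n_chains = 32, swap_prob = 0.99, mh_steps = 5) {
  if (length(n_chains) != 1 || n_chains < 2 || n_chains != round(n_chains))
    stop("n_chains must be an integer >= 2", call. = FALSE)
  if (swap_prob <= 0 || swap_prob >= 1)
    stop("swap_prob must lie in (0, 1)", call. = FALSE)
  n <- as.integer(n_chains)
  structure(list(betas = ((seq_len(n) - 1) / (n - 1))^2,
                 n_chains = n, swap_prob = swap_prob,
                 mh_steps = as.integer(mh_steps)),
            class = "pt_ladder")
}

#' Automated parameter blocking from recent draws
#'
#' Partitions parameters into correlated blocks that are proposed
#' jointly. Parameters are clustered by single-linkage on the distance
#' 1 - |correlation|, cutting where |correlation| >= \code{threshold};
#' each block's proposal covariance is the empirical covariance of the
#' draws plus a small diagonal jitter. Zero-variance parameters get their
#' own singleton block with unit variance. With fewer than
#' \code{min_samples} draws, a single block containing all parameters is
#' returned.
#'
#' @param draws Matrix of recent samples (rows = draws, columns =
#'   parameters).
#' @param threshold Absolute-correlation threshold for joining blocks.
#' @param min_samples Minimum draw count before clustering is attempted.
#' @param jitter Diagonal regularization added to each block covariance.
#' @return Object of class \code{block_plan}: list with \code{blocks}
#'   (list of column-index vectors), \code{chol} (per-block upper
#'   Cholesky factors of the proposal covariance) and \code{scale}
#'   (per-block initial scalar scale, 2.38/sqrt(block size)).
#' @export
auto_block <- function(draws, threshold = 0.5, min_samples = 100,
                       jitter = 1e-8) {
  draws <- as.matrix(draws)
  d <- ncol(draws)
  fallback <- function() {
    cv <- if (nrow(draws) >= 2) {
      v <- apply(draws, 2, stats::var)
      diag(pmax(v, 1), d)
    } else diag(1, d)
    new_plan(list(seq_len(d)), list(cv + jitter * diag(d)))
  }
  if (nrow(draws) < min_samples) return(fallback())
  sds <- apply(draws, 2, stats::sd)
  degen <- which(sds < 1e-12)
  live <- setdiff(seq_len(d), degen)
  blocks <- lapply(degen, function(i) i)
  covs <- lapply(degen, function(i) matrix(1, 1, 1))
  if (length(live) == 1) {
    blocks <- c(blocks, list(live))
    covs <- c(covs, list(matrix(stats::var(draws[, live]) + jitter, 1, 1)))
  } else if (length(live) > 1) {
    cm <- abs(stats::cor(draws[, live, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    cl <- stats::cutree(stats::hclust(stats::as.dist(1 - cm),
                                      method = "single"),
                        h = 1 - threshold)
    for (k in unique(cl)) {
      idx <- live[cl == k]
      blocks <- c(blocks, list(idx))
      cv <- stats::cov(draws[, idx, drop = FALSE]) +
        jitter * diag(length(idx))
      covs <- c(covs, list(cv))
    }
  }
  ord <- order(vapply(blocks, min, numeric(1)))
  new_plan(blocks[ord], covs[ord])
}

new_plan <- function(blocks, covs) {
  structure(list(blocks = blocks,
                 chol = lapply(covs, chol),
                 scale = 2.38 / sqrt(lengths(blocks))),
            class = "block_plan")
}

#' Diminishing-adaptation update of a proposal scale
#'
#' Robbins-Monro update targeting a Metropolis acceptance rate of 0.23:
#' log s <- log s + t^(-0.6) (acc - target). Applied per block during
#' burn-in only (adaptation is frozen afterwards, preserving the
#' stationary distribution). The scale is clamped to [1e-6, 1e3].
#'
#' @param scale Current scalar proposal scale.
#' @param acc_rate Recent acceptance rate (or 0/1 indicator).
#' @param t Adaptation step counter (>= 1).
#' @param target Target acceptance rate.
#' @return Updated scale.
#' @export
adapt_scale <- function(scale, acc_rate, t, target = 0.23) {
  s <- exp(log(scale) + t^(-0.6) * (acc_rate - target))
  min(max(s, 1e-6), 1e3)
}

#' One round of blocked Metropolis-Hastings updates
#'
#' For each block of the plan, proposes a multivariate-normal step on the
#' block's coordinates (symmetric, so no Hastings correction) and accepts
#' with the tempered posterior ratio
#' exp(dlogprior + beta * dloglik). Proposals falling outside the prior's
#' support are rejected without evaluating the likelihood.
#'
#' @param theta Current parameter values.
#' @param lp,ll Cached log prior and untempered log likelihood at
#'   \code{theta}.
#' @param beta Inverse temperature in [0, 1].
#' @param plan A \code{block_plan}.
#' @param scales Per-block scalar scales (defaults to the plan's).
#' @param log_prior_fn,log_lik_fn Evaluators taking a parameter vector.
#' @param n_steps Number of full sweeps over the blocks.
#' @return List with updated \code{theta}, \code{lp}, \code{ll}, and
#'   per-block \code{accepts} and \code{proposals} counts.
#' @export
mh_block_update <- function(theta, lp, ll, beta, plan,
                            scales = plan$scale,
                            log_prior_fn, log_lik_fn, n_steps = 1) {
  nb <- length(plan$blocks)
  acc <- integer(nb)
  for (s in seq_len(n_steps)) {
    for (b in seq_len(nb)) {
      idx <- plan$blocks[[b]]
      z <- rnorm(length(idx))
      prop <- theta
      prop[idx] <- prop[idx] + scales[b] * drop(crossprod(plan$chol[[b]], z))
      lp2 <- log_prior_fn(prop)
      if (!is.finite(lp2)) next
      ll2 <- log_lik_fn(prop)
      logr <- (lp2 - lp) + dll_tempered(ll2, ll, beta)
      if (is.finite(logr) && logr >= 0 || log(runif(1)) < logr) {
        theta <- prop; lp <- lp2; ll <- ll2
        acc[b] <- acc[b] + 1L
      }
    }
  }
  list(theta = theta, lp = lp, ll = ll, accepts = acc,
       proposals = rep(n_steps, nb))
}

# beta * (ll2 - ll) with -Inf handled explicitly so that 0 * Inf and
# Inf - Inf never produce NaN.
dll_tempered <- function(ll2, ll, beta) {
  if (beta == 0) return(0)
  if (ll2 == -Inf && ll == -Inf) return(0)
  if (ll2 == -Inf) return(-Inf)
  if (ll == -Inf) return(Inf)
  beta * (ll2 - ll)
}

# Log acceptance ratio of a swap between adjacent chains i and i+1:
# (beta_i - beta_{i+1}) * (ll_{i+1} - ll_i), on the untempered
# log-likelihoods, with -Inf handled explicitly.
swap_log_ratio <- function(beta_i, beta_j, ll_i, ll_j) {
  if (ll_i == ll_j) return(0)
  if (ll_j == -Inf) return(Inf)   # -Inf likelihood moves down the ladder
  if (ll_i == -Inf) return(-Inf)
  (beta_i - beta_j) * (ll_j - ll_i)
}

#' Adaptive blocked Metropolis-Hastings on a generic target
#'
#' Single-chain driver used both stand-alone (for targets with a known
#' density, e.g. sampler calibration on a correlated Gaussian) and as a
#' reference for the per-chain updates inside [run_pt()]. During burn-in,
#' blocks are re-learned every \code{reblock_every} iterations from the
#' recent draws and per-block scales adapt toward an acceptance rate of
#' \code{target_acc}; both are frozen afterwards.
#'
#' @param log_target Function returning the log target density.
#' @param init Initial parameter vector.
#' @param n_iter Post-burn-in iterations (one sweep each).
#' @param burn_in Burn-in iterations.
#' @param seed Optional RNG seed.
#' @param reblock_every Burn-in interval between re-blockings.
#' @param block_threshold,min_block_samples Passed to [auto_block()].
#' @param target_acc Target acceptance rate for scale adaptation.
#' @param plan Optional initial \code{block_plan}.
#' @return List with \code{draws} (post-burn-in), \code{plan},
#'   \code{scales}, and post-burn-in per-block \code{accepts} and
#'   \code{proposals}.
#' @export
run_blocked_mh <- function(log_target, init, n_iter, burn_in = 1000,
                           seed = NULL, reblock_every = 2000,
                           block_threshold = 0.5, min_block_samples = 100,
                           target_acc = 0.23, plan = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  if (is.null(plan)) plan <- auto_block(matrix(numeric(0), 0, d))
  scales <- plan$scale
  theta <- init
  ll <- log_target(theta)
  if (!is.finite(ll)) stop("log_target is not finite at init", call. = FALSE)
  total <- burn_in + n_iter
  hist_draws <- matrix(NA_real_, total, d)
  acc_post <- prop_post <- NULL
  adapt_t <- rep(0L, length(plan$blocks))
  for (it in seq_len(total)) {
    up <- mh_block_update(theta, 0, ll, 1, plan, scales,
                          function(th) 0, log_target, n_steps = 1)
    theta <- up$theta; ll <- up$ll
    hist_draws[it, ] <- theta
    if (it <= burn_in) {
      adapt_t <- adapt_t + 1L
      for (b in seq_along(scales))
        scales[b] <- adapt_scale(scales[b], up$accepts[b] / up$proposals[b],
                                 adapt_t[b], target_acc)
      if (it %% reblock_every == 0 && it < burn_in) {
        win <- hist_draws[max(1, it - 4999):it, , drop = FALSE]
        plan <- auto_block(win, threshold = block_threshold,
                           min_samples = min_block_samples)
        scales <- plan$scale
        adapt_t <- rep(0L, length(plan$blocks))
      }
    } else {
      if (is.null(acc_post)) {
        acc_post <- integer(length(plan$blocks))
        prop_post <- integer(length(plan$blocks))
      }
      acc_post <- acc_post + up$accepts
      prop_post <- prop_post + up$proposals
    }
  }
  list(draws = hist_draws[(burn_in + 1):total, , drop = FALSE],
       plan = plan, scales = scales,
       accepts = acc_post, proposals = prop_post)
}

#' Parallel-tempered MCMC with adaptive blocking
#'
#' Samples a posterior with n tempered chains on a quadratic
#' inverse-temperature ladder. At each iteration, with probability
#' \code{swap_prob} a random adjacent pair of chains attempts a state
#' swap (accepted with probability
#' min(1, exp((beta_i - beta_j)(ll_j - ll_i))) on the untempered
#' log-likelihoods); otherwise every chain performs \code{mh_steps}
#' blocked Metropolis-Hastings sweeps. Replica labels travel with the
#' states, and the ledger of replica positions supports the
#' [count_round_trips()] mixing diagnostic: a round trip is one complete
#' journey of a replica from the prior chain (beta = 0) to the posterior
#' chain (beta = 1) and back.
#'
#' During burn-in, proposal scales adapt per chain and block toward a
#' 0.23 acceptance rate, and the blocking plan (shared across chains) is
#' re-learned every \code{reblock_every} iterations from the cold
#' chain's recent draws. Adaptation and blocking are frozen after
#' burn-in. Given a seed the run is exactly reproducible.
#'
#' @param log_lik Function: untempered log likelihood of a parameter
#'   vector (may return \code{-Inf}; \code{NaN} is an error).
#' @param lower,upper Prior box bounds on the storage scale; also used
#'   to initialize chains from the (uniform) prior.
#' @param log_prior Optional log-prior function (default: uniform on the
#'   box).
#' @param ladder A \code{pt_ladder}.
#' @param burn_in,n_iter Iteration counts for the two phases.
#' @param subsample Keep one cold-chain draw per this many sampling
#'   iterations.
#' @param seed RNG seed.
#' @param reblock_every Burn-in interval between re-blockings.
#' @param block_threshold,min_block_samples Passed to [auto_block()].
#' @param target_acc Target acceptance rate for adaptation.
#' @param keep_ledger Store the full replica-position ledger (needed for
#'   round-trip counting).
#' @param par_names Optional parameter names for the draw matrix.
#' @return Object of class \code{pt_fit}: list with \code{draws}
#'   (subsampled cold-chain draws), \code{log_post} (their log prior +
#'   log likelihood), \code{prior_draws} (subsampled beta = 0 chain
#'   draws), \code{betas}, \code{swap_accept} / \code{swap_attempt} per
#'   adjacent pair, per-chain block acceptance summaries, the replica
#'   \code{ledger} (iterations x replicas, entries = chain index),
#'   \code{round_trips}, frozen \code{plan} and \code{scales}, and the
#'   \code{settings} snapshot.
#' @export
run_pt <- function(log_lik, lower, upper, log_prior = NULL,
                   ladder = make_ladder(), burn_in = 5000, n_iter = 20000,
                   subsample = 10, seed = NULL, reblock_every = 10000,
                   block_threshold = 0.5, min_block_samples = 100,
                   target_acc = 0.23, keep_ledger = TRUE,
                   par_names = NULL) {
  stopifnot(inherits(ladder, "pt_ladder"), length(lower) == length(upper),
            all(lower < upper), burn_in >= 0, n_iter > 0, subsample >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  nc <- ladder$n_chains
  betas <- ladder$betas
  width <- upper - lower
  lp_const <- -sum(log(width))
  if (is.null(log_prior))
    log_prior <- function(th)
      if (any(th < lower) || any(th > upper)) -Inf else lp_const

  eval_lik <- function(th) {
    v <- log_lik(th)
    if (is.nan(v)) stop("log_lik returned NaN; -Inf is the only legal failure value",
                        call. = FALSE)
    v
  }

  theta <- matrix(NA_real_, nc, d)
  lp <- ll <- numeric(nc)
  for (i in seq_len(nc)) {
    # tempered chains start at finite-likelihood states; the beta = 0
    # chain starts from an unconditioned prior draw, since states with
    # failed simulations carry genuine prior mass there
    for (try in 1:200) {
      cand <- lower + width * runif(d)
      v <- eval_lik(cand)
      if (betas[i] == 0 || is.finite(v) || try == 200) {
        theta[i, ] <- cand; ll[i] <- v; lp[i] <- log_prior(cand)
        break
      }
    }
  }

  # initial plan: one block, proposal sd a tenth of the box width
  plan <- new_plan(list(seq_len(d)),
                   list(diag((width / 10)^2, nrow = d) + 1e-12 * diag(d)))
  scales <- matrix(rep(plan$scale, each = nc), nc, length(plan$blocks))
  adapt_t <- matrix(0L, nc, length(plan$blocks))

  total <- burn_in + n_iter
  n_keep <- floor(n_iter / subsample)
  draws <- matrix(NA_real_, n_keep, d)
  log_post <- numeric(n_keep)
  prior_draws <- matrix(NA_real_, n_keep, d)
  kept <- 0L
  cold_hist <- matrix(NA_real_, burn_in, d)
  ledger <- if (keep_ledger) matrix(NA_integer_, total, nc) else NULL
  chain_of_replica <- seq_len(nc)
  swap_att <- swap_acc <- integer(nc - 1)
  acc_tot <- prop_tot <- matrix(0, nc, length(plan$blocks))
  scales_end_burnin <- NULL

  for (it in seq_len(total)) {
    if (runif(1) < ladder$swap_prob) {
      j <- sample.int(nc - 1L, 1L)
      swap_att[j] <- swap_att[j] + 1L
      lr <- swap_log_ratio(betas[j], betas[j + 1], ll[j], ll[j + 1])
      if (lr >= 0 || log(runif(1)) < lr) {
        swap_acc[j] <- swap_acc[j] + 1L
        tmp <- theta[j, ]; theta[j, ] <- theta[j + 1, ]; theta[j + 1, ] <- tmp
        tmp <- ll[j]; ll[j] <- ll[j + 1]; ll[j + 1] <- tmp
        tmp <- lp[j]; lp[j] <- lp[j + 1]; lp[j + 1] <- tmp
        r1 <- which(chain_of_replica == j)
        r2 <- which(chain_of_replica == j + 1L)
        chain_of_replica[r1] <- j + 1L
        chain_of_replica[r2] <- j
      }
    } else {
      for (i in seq_len(nc)) {
        up <- mh_block_update(theta[i, ], lp[i], ll[i], betas[i], plan,
                              scales[i, ], log_prior, eval_lik,
                              n_steps = ladder$mh_steps)
        theta[i, ] <- up$theta; lp[i] <- up$lp; ll[i] <- up$ll
        acc_tot[i, ] <- acc_tot[i, ] + up$accepts
        prop_tot[i, ] <- prop_tot[i, ] + up$proposals
        if (it <= burn_in) {
          adapt_t[i, ] <- adapt_t[i, ] + 1L
          for (b in seq_along(plan$blocks))
            scales[i, b] <- adapt_scale(scales[i, b],
                                        up$accepts[b] / up$proposals[b],
                                        adapt_t[i, b], target_acc)
        }
      }
    }
    if (keep_ledger) ledger[it, ] <- chain_of_replica
    if (it <= burn_in) {
      cold_hist[it, ] <- theta[nc, ]
      if (it %% reblock_every == 0 && it < burn_in) {
        win <- cold_hist[max(1, it - 4999):it, , drop = FALSE]
        # carry each chain's adaptation level (scale relative to the
        # theoretical 2.38/sqrt(d) start) across the re-blocking, so hot
        # chains keep their wide proposals instead of re-adapting from
        # scratch after every plan change
        level <- exp(rowMeans(log(scales / matrix(rep(plan$scale, each = nc),
                                                  nc))))
        plan <- auto_block(win, threshold = block_threshold,
                           min_samples = min_block_samples)
        scales <- level %o% plan$scale
        adapt_t <- matrix(0L, nc, length(plan$blocks))
        acc_tot <- prop_tot <- matrix(0, nc, length(plan$blocks))
      }
      if (it == burn_in) scales_end_burnin <- scales
    } else if ((it - burn_in) %% subsample == 0 && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- theta[nc, ]
      log_post[kept] <- lp[nc] + ll[nc]
      prior_draws[kept, ] <- theta[1, ]
    }
  }
  if (!is.null(par_names)) {
    colnames(draws) <- par_names
    colnames(prior_draws) <- par_names
  }
  rt <- if (keep_ledger) count_round_trips(ledger) else NULL
  structure(list(
    draws = draws, log_post = log_post, prior_draws = prior_draws,
    betas = betas, swap_accept = swap_acc, swap_attempt = swap_att,
    block_accepts = acc_tot, block_proposals = prop_tot,
    ledger = ledger, round_trips = rt,
    plan = plan, scales = scales, scales_end_burnin = scales_end_burnin,
    settings = list(n_chains = nc, swap_prob = ladder$swap_prob,
                    mh_steps = ladder$mh_steps, burn_in = burn_in,
                    n_iter = n_iter, subsample = subsample, seed = seed,
                    reblock_every = reblock_every,
                    target_acc = target_acc)),
    class = "pt_fit")
}

#' @export
print.pt_fit <- function(x, ...) {
  cat(sprintf("parallel-tempering fit: %d chains, %d kept draws, %s round trips\n",
              x$settings$n_chains, nrow(x$draws),
              if (is.null(x$round_trips)) "untracked" else x$round_trips$total))
  invisible(x)
}

#' Count replica round trips from the ledger
#'
#' A round trip is one completed journey of a replica from the prior
#' chain (chain 1, beta = 0) to the posterior chain (chain n, beta = 1)
#' and back to the prior chain. The count is a direct measure of how
#' freely states flow along the temperature ladder.
#'
#' @param ledger Integer matrix (iterations x replicas) giving each
#'   replica's chain index at every iteration, as stored by [run_pt()].
#' @param n_chains Index of the posterior (top) chain; defaults to the
#'   largest chain index appearing in the ledger.
#' @return List with \code{per_replica} counts and their \code{total}.
#' @export
count_round_trips <- function(ledger, n_chains = max(ledger)) {
  ledger <- as.matrix(ledger)
  nc <- n_chains
  per <- apply(ledger, 2, function(path) {
    e <- path[path == 1L | path == nc]
    if (length(e) == 0) return(0L)
    r <- rle(e)$values
    if (r[1] == nc) r <- r[-1]
    if (length(r) == 0) return(0L)
    # r now alternates 1, nc, 1, nc, ...; each nc followed by 1 completes
    # a round trip
    as.integer((length(r) - 1) %/% 2)
  })
  list(per_replica = per, total = sum(per))
}

#' Convergence diagnostics for posterior draws
#'
#' Per-parameter summary of an MCMC draw matrix: mean, standard
#' deviation, lag-1 autocorrelation, and effective sample size from the
#' initial-positive-sequence truncated autocorrelation sum,
#' ESS = n / (1 + 2 sum rho_k). Constant chains are flagged degenerate.
#'
#' @param draws Draw matrix (rows = draws) or a \code{pt_fit}.
#' @param max_lag Largest lag considered.
#' @return Data frame with one row per parameter.
#' @export
mcmc_diagnostics <- function(draws, max_lag = NULL) {
  if (inherits(draws, "pt_fit")) draws <- draws$draws
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 10) stop("need at least 10 draws for diagnostics", call. = FALSE)
  if (is.null(max_lag)) max_lag <- min(n - 1, max(50, floor(10 * log10(n))))
  out <- lapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    s <- stats::sd(x)
    if (s < 1e-300) {
      return(data.frame(parameter = colnames(draws)[j] %||% paste0("p", j),
                        mean = mean(x), sd = s, lag1 = NA_real_,
                        ess = NA_real_, degenerate = TRUE))
    }
    rho <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
    cut <- which(rho < 0)
    if (length(cut) > 0) rho <- rho[seq_len(cut[1] - 1)]
    ess <- n / (1 + 2 * sum(rho))
    data.frame(parameter = colnames(draws)[j] %||% paste0("p", j),
               mean = mean(x), sd = s,
               lag1 = stats::acf(x, lag.max = 1, plot = FALSE)$acf[2],
               ess = min(ess, n), degenerate = FALSE)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
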