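test_that("the inverse-temperature ladder is quadratic with fixed endpoints", {
  l <- make_ladder(32)
  expect_equal(l$betas[1], 0)
  expect_equal(l$betas[32], 1)
  expect_equal(l$betas[17], (16 / 31)^2)
  expect_equal(make_ladder(2)$betas, c(0, 1))
  expect_true(all(diff(l$betas) > 0))
  expect_error(make_ladder(1), ">= 2")
  expect_error(make_ladder(8, swap_prob = 1), "0, 1")
})

test_that("automated blocking groups correlated parameters", {
  # independent standard normals: overwhelmingly singleton blocks
  singleton_frac <- vapply(1:5, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(1000 * 6), 1000, 6)
    plan <- auto_block(x)
    mean(lengths(plan$blocks) == 1)
  }, numeric(1))
  expect_gte(mean(singleton_frac), 0.9)

  # near-duplicated variable joins its copy's block
  set.seed(10)
  a <- rnorm(500)
  x <- cbind(a, a + 1e-6 * rnorm(500), rnorm(500))
  plan <- auto_block(x)
  blk <- vapply(plan$blocks, function(b) all(c(1, 2) %in% b), logical(1))
  expect_true(any(blk))

  # below the sample threshold: one block with everything
  plan50 <- auto_block(matrix(rnorm(50 * 4), 50, 4))
  expect_length(plan50$blocks, 1)
  expect_equal(sort(plan50$blocks[[1]]), 1:4)

  # zero-variance parameter gets a unit-variance singleton
  x <- cbind(rnorm(200), 1.5, rnorm(200))
  pz <- auto_block(x)
  zi <- which(vapply(pz$blocks, function(b) identical(b, 2L), logical(1)))
  expect_length(zi, 1)
  expect_equal(unname(pz$chol[[zi]][1, 1]), 1)

  # blocks partition the parameters
  expect_setequal(unlist(plan$blocks), 1:3)
})

test_that("scale adaptation has the right fixed point and direction", {
  expect_equal(adapt_scale(0.7, 0.23, 5), 0.7)
  expect_gt(adapt_scale(0.7, 1, 5), 0.7)
  expect_lt(adapt_scale(0.7, 0, 5), 0.7)
  # clamped
  expect_equal(adapt_scale(1e-6, 0, 1), 1e-6)
  # long-run acceptance converges to the 0.23 target on a Gaussian
  set.seed(21)
  fit <- run_blocked_mh(function(th) -0.5 * sum(th^2), rnorm(4),
                        n_iter = 8000, burn_in = 8000, seed = 33)
  acc <- sum(fit$accepts) / sum(fit$proposals)
  expect_lt(abs(acc - 0.23), 0.05)
})

test_that("block updates target the correct distribution", {
  # flat target inside a box: every in-box proposal is accepted
  flat_prior <- function(th) if (any(abs(th) > 1)) -Inf else 0
  plan <- auto_block(matrix(numeric(0), 0, 2))
  set.seed(2)
  th <- c(0, 0); acc <- 0; prop <- 200
  for (i in 1:prop) {
    up <- mh_block_update(th, 0, 0, 1, plan, c(0.2),
                          flat_prior, function(th) 0)
    moved <- !identical(up$theta, th)
    inbox <- all(abs(up$theta) <= 1)
    expect_true(inbox)
    th <- up$theta
    acc <- acc + up$accepts
  }
  # with small proposals nearly everything lands in the box
  expect_gt(acc / prop, 0.8)

  # 2-d correlated Gaussian: sampled moments match the truth
  S <- matrix(c(1, 0.8, 0.8, 2), 2)
  P <- solve(S)
  lt <- function(th) -0.5 * drop(th %*% P %*% th)
  fit <- run_blocked_mh(lt, c(0, 0), n_iter = 20000, burn_in = 5000,
                        seed = 5)
  ess <- min(mcmc_diagnostics(fit$draws)$ess)
  mc_se <- sqrt(diag(S)) / sqrt(ess)
  expect_lt(abs(mean(fit$draws[, 1])), 3 * mc_se[1])
  expect_lt(abs(mean(fit$draws[, 2])), 3 * mc_se[2])
  expect_equal(stats::cov(fit$draws), S, tolerance = 0.15)
})

test_that("block updates satisfy detailed balance on a discretized target", {
  # three-plateau density on [0, 3); bin transitions must balance
  w <- c(0.2, 0.5, 0.3)
  lt <- function(th) {
    if (th < 0 || th >= 3) return(-Inf)
    log(w[floor(th) + 1])
  }
  plan <- auto_block(matrix(numeric(0), 0, 1))
  set.seed(14)
  th <- 1.5
  n <- 60000
  states <- integer(n)
  for (i in seq_len(n)) {
    up <- mh_block_update(th, 0, lt(th), 1, plan, c(1.0),
                          function(x) 0, lt)
    th <- up$theta
    states[i] <- floor(th) + 1L
  }
  counts <- table(factor(states, levels = 1:3)) / n
  expect_equal(as.numeric(counts), w, tolerance = 0.05)
  trans <- table(factor(states[-n], 1:3), factor(states[-1], 1:3)) / (n - 1)
  # pi_i P(i->j) = flux(i,j) must equal flux(j,i) within MC error
  for (i in 1:2) for (j in (i + 1):3) {
    flux_ij <- trans[i, j]; flux_ji <- trans[j, i]
    se <- sqrt((flux_ij + flux_ji) / n)
    expect_lt(abs(flux_ij - flux_ji), 4 * se + 1e-4)
  }
})

test_that("swap acceptance follows the tempered exchange rule", {
  # equal log-likelihoods: always accepted
  expect_equal(cyclinpt:::swap_log_ratio(0.1, 0.3, -5, -5), 0)
  expect_equal(cyclinpt:::swap_log_ratio(0.1, 0.3, -Inf, -Inf), 0)
  # -Inf likelihood always moves down the ladder, never up
  expect_identical(cyclinpt:::swap_log_ratio(0.1, 0.3, -2, -Inf), Inf)
  expect_identical(cyclinpt:::swap_log_ratio(0.1, 0.3, -Inf, -2), -Inf)
  # finite case: (beta_i - beta_j) * (ll_j - ll_i)
  expect_equal(cyclinpt:::swap_log_ratio(0.2, 0.5, -1, -4), 0.9)
})

test_that("tempered ladder marginals match independent single-chain runs", {
  # conjugate toy: uniform box prior on [-3, 3], Gaussian likelihood;
  # at inverse temperature b the target is N(1, 1/(2b)) truncated to the box
  loglik <- function(th) -(th - 1)^2
  fit <- run_pt(loglik, lower = -3, upper = 3,
                ladder = make_ladder(8, swap_prob = 0.9, mh_steps = 5),
                burn_in = 2000, n_iter = 30000, subsample = 15, seed = 17)
  # cold chain (beta = 1): N(1, 0.5) truncated; compare to direct samples
  set.seed(99)
  ref <- rnorm(40000, 1, sqrt(0.5))
  ref <- ref[ref >= -3 & ref <= 3]
  ks <- suppressWarnings(stats::ks.test(fit$draws[, 1], ref))
  expect_gt(ks$p.value, 0.01)
  # prior chain (beta = 0): uniform on the box
  ksu <- suppressWarnings(
    stats::ks.test(fit$prior_draws[, 1], "punif", -3, 3))
  expect_gt(ksu$p.value, 0.01)
})

test_that("posterior means are recovered on a conjugate 1-d problem", {
  # Gaussian likelihood with known sd 0.5 around 20 obs, wide uniform prior
  set.seed(31)
  obs <- rnorm(20, -1.2, 0.5)
  loglik <- function(th) -sum((obs - th)^2) / (2 * 0.5^2)
  fit <- run_pt(loglik, lower = -5, upper = 5,
                ladder = make_ladder(6, swap_prob = 0.9),
                burn_in = 2000, n_iter = 20000, subsample = 10, seed = 8)
  post_mean <- mean(obs)          # flat prior: posterior N(xbar, sd^2/n)
  post_sd <- 0.5 / sqrt(20)
  ess <- mcmc_diagnostics(fit$draws)$ess[1]
  expect_lt(abs(mean(fit$draws[, 1]) - post_mean),
            3 * post_sd / sqrt(ess) + 0.01)
  expect_equal(sd(fit$draws[, 1]), post_sd, tolerance = 0.15)
})

test_that("runs are exactly reproducible and adaptation freezes", {
  loglik <- function(th) -0.5 * sum(th^2)
  args <- list(loglik, lower = c(-4, -4), upper = c(4, 4),
               ladder = make_ladder(4, swap_prob = 0.8),
               burn_in = 500, n_iter = 1500, subsample = 5, seed = 123)
  f1 <- do.call(run_pt, args)
  f2 <- do.call(run_pt, args)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$ledger, f2$ledger)
  expect_identical(f1$prior_draws, f2$prior_draws)
  # scales identical at end of burn-in and end of run: frozen adaptation
  expect_identical(f1$scales, f1$scales_end_burnin)
})

test_that("NaN posteriors are a hard error", {
  expect_error(
    run_pt(function(th) NaN, lower = -1, upper = 1,
           ladder = make_ladder(2, swap_prob = 0.5),
           burn_in = 10, n_iter = 10, subsample = 1, seed = 1),
    "NaN")
})

test_that("round-trip counting matches brute-force enumeration", {
  # single replica going 1 -> top -> 1 once
  path <- matrix(c(1, 2, 3, 2, 3, 2, 1), ncol = 1)
  expect_equal(count_round_trips(path)$total, 1)
  # never reaching the top chain
  expect_equal(count_round_trips(matrix(c(1, 2, 2, 1), ncol = 1),
                                 n_chains = 3)$total, 0)
  # brute-force state machine oracle on random label paths
  brute <- function(path, nc) {
    state <- "none"; trips <- 0
    for (p in path) {
      if (p == 1 && state == "none") state <- "bottom"
      else if (p == nc && state == "bottom") state <- "top"
      else if (p == 1 && state == "top") { trips <- trips + 1; state <- "bottom" }
    }
    trips
  }
  set.seed(77)
  for (k in 1:20) {
    nc <- sample(3:6, 1)
    # random walk on 1..nc
    path <- numeric(300)
    p <- sample(nc, 1)
    for (i in 1:300) {
      p <- min(max(p + sample(c(-1, 0, 1), 1), 1), nc)
      path[i] <- p
    }
    ledger <- matrix(path, ncol = 1)
    # embed in a ledger where other replicas idle at interior chains
    expect_equal(count_round_trips(cbind(ledger, 2, nc - 1))$per_replica[1],
                 brute(path, nc))
  }
})

test_that("diagnostics report sane autocorrelation and ESS", {
  set.seed(55)
  n <- 4000
  iid <- matrix(rnorm(n), ncol = 1)
  d <- mcmc_diagnostics(iid)
  expect_lt(abs(d$lag1), 3 / sqrt(n))
  expect_gt(d$ess, n / 2)
  # AR(1) with rho = 0.9: ESS/n ~ (1-rho)/(1+rho)
  x <- numeric(n); x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- 0.9 * x[i - 1] + sqrt(1 - 0.81) * rnorm(1)
  d2 <- mcmc_diagnostics(matrix(x, ncol = 1))
  expect_equal(d2$ess / n, (1 - 0.9) / (1 + 0.9), tolerance = 0.3)
  # constant chain is flagged degenerate
  d3 <- mcmc_diagnostics(matrix(1, 100, 1))
  expect_true(d3$degenerate)
  expect_error(mcmc_diagnostics(matrix(1, 5, 1)), "at least 10")
})
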