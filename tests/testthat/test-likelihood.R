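test_that("t3 log density matches the closed form", {
  # standard t3 at its mode: density = 2 / (pi sqrt(3))
  expect_equal(log_t_density(0, 0, 1), log(2 / (pi * sqrt(3))),
               tolerance = 1e-12)
  # symmetry
  expect_equal(log_t_density(1.7, 0.5, 0.8), log_t_density(-0.7, 0.5, 0.8))
  # location-scale change of variables vs the direct formula
  direct <- function(x, c, s, df = 3) {
    z <- (x - c) / s
    lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi) - log(s) -
      (df + 1) / 2 * log1p(z^2 / df)
  }
  set.seed(3)
  x <- rnorm(20); c <- rnorm(20); s <- runif(20, 0.1, 3)
  expect_equal(log_t_density(x, c, s), direct(x, c, s), tolerance = 1e-12)
  expect_error(log_t_density(0, 0, 0), "strictly positive")
})

test_that("relative likelihood centers on the log ratio to the time average", {
  st <- reduced_setup(seed = 2, sigma_tc = 0)
  tr <- integrate_model(st$model, st$truth)
  # zero-noise data sit exactly at the modeled centers: every term is
  # the t3 mode density
  ll <- relative_loglik(tr, st$tc, 0.2)
  expect_equal(ll, nrow(st$tc) * (log(2 / (pi * sqrt(3))) - log(0.2)),
               tolerance = 1e-6)
  # constant trajectory: modeled log-ratios are all zero
  trc <- tr
  trc$conc[, "mRNA_G1"] <- 0.25
  d0 <- st$tc
  d0$log_ratio <- 0
  expect_equal(relative_loglik(trc, d0, 0.3),
               nrow(d0) * (log(2 / (pi * sqrt(3))) - log(0.3)),
               tolerance = 1e-9)
  # unknown gene is reported by name
  bad <- st$tc
  bad$gene[1] <- "NOPE"
  expect_error(relative_loglik(tr, bad, 0.2), "NOPE")
})

test_that("likelihoods equal naive per-record loop oracles", {
  st <- reduced_setup(seed = 5)
  tr <- integrate_model(st$model, st$truth)
  avg_m <- time_average(tr, "mRNA_G1")
  avg_p <- time_average(tr, "protein_G1")
  loop_rel <- 0
  for (i in seq_len(nrow(st$tc))) {
    mi <- approx(tr$times, tr$conc[, "mRNA_G1"], st$tc$time_min[i] * 60)$y
    loop_rel <- loop_rel +
      log_t_density(st$tc$log_ratio[i], log(mi / avg_m), 0.2)
  }
  expect_equal(relative_loglik(tr, st$tc, 0.2), unname(loop_rel),
               tolerance = 1e-10)
  loop_abs <- 0
  for (i in seq_len(nrow(st$ss))) {
    a <- if (st$ss$kind[i] == "mRNA") avg_m else avg_p
    loop_abs <- loop_abs +
      log_t_density(st$ss$log10_conc_uM[i], log10(a), 0.2)
  }
  expect_equal(absolute_loglik(tr, st$ss, 0.2), unname(loop_abs),
               tolerance = 1e-10)
})

test_that("likelihoods are invariant to record order and trajectory scale", {
  st <- reduced_setup(seed = 7)
  tr <- integrate_model(st$model, st$truth)
  perm <- sample(nrow(st$tc))
  expect_equal(relative_loglik(tr, st$tc[perm, ], 0.2),
               relative_loglik(tr, st$tc, 0.2))
  expect_equal(absolute_loglik(tr, st$ss[sample(nrow(st$ss)), ], 0.2),
               absolute_loglik(tr, st$ss, 0.2))
  # relative channel ignores an overall concentration rescaling
  tr2 <- tr
  tr2$conc <- tr$conc * 37.5
  expect_equal(relative_loglik(tr2, st$tc, 0.2),
               relative_loglik(tr, st$tc, 0.2), tolerance = 1e-9)
})

test_that("absolute likelihood handles modes and degenerate averages", {
  st <- reduced_setup(seed = 9, sigma_ss = 0)
  tr <- integrate_model(st$model, st$truth)
  # observation equal to log10 time average sits at the mode
  one <- st$ss[1, ]
  mode_ll <- log_t_density(0, 0, 0.2)
  expect_equal(absolute_loglik(tr, one, 0.2), unname(mode_ll),
               tolerance = 1e-9)
  # time average of exactly 1 uM gives center 0
  trc <- tr
  trc$conc[, "mRNA_G1"] <- 1
  obs0 <- data.frame(kind = "mRNA", gene = "G1", log10_conc_uM = 0,
                     source = "s")
  expect_equal(absolute_loglik(trc, obs0, 0.5),
               unname(log_t_density(0, 0, 0.5)))
  # zero trajectory: non-positive average contributes -Inf
  trz <- tr
  trz$conc[, "mRNA_G1"] <- 0
  expect_identical(absolute_loglik(trz, obs0, 0.5), -Inf)
  # failed simulation propagates -Inf
  trf <- tr
  trf$success <- FALSE
  expect_identical(absolute_loglik(trf, st$ss, 0.2), -Inf)
  expect_identical(relative_loglik(trf, st$tc, 0.2), -Inf)
})

test_that("box prior density is the inverse box volume", {
  m <- single_gene_model()
  prior <- default_priors(m)
  th <- random_params(m, prior, seed = 1)
  expect_equal(log_prior(th, prior), -sum(log(prior$upper - prior$lower)))
  # position independence
  expect_equal(log_prior(random_params(m, prior, seed = 2), prior),
               log_prior(th, prior))
  th2 <- th
  th2["deltam"] <- prior$upper[prior$name == "deltam"] + 0.01
  expect_identical(log_prior(th2, prior), -Inf)
  # two-parameter box with log10 widths 4 and 2
  p2 <- data.frame(name = c("a", "b"), lower = c(-5, 0), upper = c(-1, 2),
                   scale = "log10")
  expect_equal(log_prior(c(a = -3, b = 1), p2), -(log(4) + log(2)))
})

test_that("tempering interpolates linearly between prior and posterior", {
  st <- reduced_setup(seed = 3)
  lp0 <- log_posterior_tempered(st$truth, st$model, st$prior,
                                st$tc, st$ss, beta = 0)
  expect_equal(lp0, log_prior(st$truth, st$prior))
  tr <- integrate_model(st$model, st$truth,
                        eval_times = st$tc$time_min * 60)
  ll <- relative_loglik(tr, st$tc, 0.2) + absolute_loglik(tr, st$ss, 0.2)
  lp1 <- log_posterior_tempered(st$truth, st$model, st$prior,
                                st$tc, st$ss, beta = 1)
  expect_equal(lp1, lp0 + ll, tolerance = 1e-8)
  lph <- log_posterior_tempered(st$truth, st$model, st$prior,
                                st$tc, st$ss, beta = 0.5)
  expect_equal(lph, lp0 + 0.5 * ll, tolerance = 1e-8)
  expect_error(log_posterior_tempered(st$truth, st$model, st$prior,
                                      st$tc, st$ss, beta = 1.2), "0, 1")
})

test_that("joint likelihood separates across channels", {
  st <- reduced_setup(seed = 6)
  L_both <- reduced_loglik(st)
  L_tc <- reduced_loglik(st, ss = FALSE)
  L_ss <- reduced_loglik(st, tc = FALSE)
  th <- st$truth[L_both$free]
  # channels separate exactly up to the quadrature-grid difference (the
  # joint evaluator folds the data times into its averaging grid)
  expect_equal(L_both$log_lik(th), L_tc$log_lik(th) + L_ss$log_lik(th),
               tolerance = 1e-6)
})

test_that("the fast inference path agrees with the reference operations", {
  st <- reduced_setup(seed = 4)
  L <- reduced_loglik(st)
  th <- st$truth[L$free]
  # reference: high-accuracy solver on the same evaluation grid
  tr <- integrate_model(st$model, st$truth,
                        eval_times = st$tc$time_min * 60)
  ref <- relative_loglik(tr, st$tc, 0.2) + absolute_loglik(tr, st$ss, 0.2)
  expect_equal(L$log_lik(th), ref, tolerance = 1e-4)
  # out-of-box parameters are a prior concern, not a likelihood crash
  expect_identical(L$log_prior(L$lower - 1), -Inf)
  expect_equal(L$log_prior(th), -sum(log(L$upper - L$lower)))
  # full() reconstructs the complete parameter vector
  expect_equal(L$full(th)[names(st$truth)], st$truth)
})
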