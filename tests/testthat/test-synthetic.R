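test_that("ground truth generation respects bounds and seeds", {
  m <- single_gene_model()
  prior <- default_priors(m)
  d1 <- gen_ground_truth(4, prior, mode = "prior-draw")
  d2 <- gen_ground_truth(4, prior, mode = "prior-draw")
  d3 <- gen_ground_truth(5, prior, mode = "prior-draw")
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  expect_true(all(d1 >= prior$lower & d1 <= prior$upper))
  expect_named(d1, prior$name)
})

test_that("the committed preset truth oscillates over two cycles", {
  m <- build_model(4)
  th <- preset_truth("v4")
  prior <- default_priors(m)
  expect_true(all(th[prior$name] >= prior$lower &
                    th[prior$name] <= prior$upper))
  tr <- integrate_model(m, th)
  expect_true(tr$success)
  y <- tr$conc[, "mRNA_CLN2"]
  d <- diff(y)
  n_maxima <- sum(d[-length(d)] > 1e-14 & d[-1] < -1e-14)
  expect_gte(n_maxima, 2)
})

test_that("time-course generation matches the model at zero noise", {
  st0 <- reduced_setup(seed = 3, sigma_tc = 0)
  tr <- integrate_model(st0$model, st0$truth,
                        eval_times = st0$tc$time_min * 60)
  avg <- time_average(tr, "mRNA_G1")
  expected <- log(approx(tr$times, tr$conc[, "mRNA_G1"],
                         st0$tc$time_min * 60)$y / avg)
  expect_equal(st0$tc$log_ratio, unname(expected), tolerance = 1e-8)
  # native 80-min experiment keeps its times; others rescale into [0, 160]
  e80 <- st0$tc[st0$tc$native_period_min == 80, ]
  expect_equal(sort(unique(e80$time_min)), seq(0, 160, length.out = 17))
  expect_true(all(st0$tc$time_min >= 0 & st0$tc$time_min <= 160))
  expect_equal(length(unique(st0$tc$experiment)), 3)
  # reproducible
  expect_identical(gen_time_course(st0$design), st0$tc)
})

test_that("time-course noise has the t3 variance 3 sigma^2", {
  m <- single_gene_model()
  truth <- preset_truth("reduced")
  sigma <- 0.15
  design <- synth_design(
    m, truth,
    experiments = data.frame(id = "big", native_period_min = 80,
                             n_points = 1000L),
    sigma_tc = sigma, seed = 99)
  tc <- gen_time_course(design)
  tr <- integrate_model(m, truth, eval_times = tc$time_min * 60)
  avg <- time_average(tr, "mRNA_G1")
  resid <- tc$log_ratio -
    log(approx(tr$times, tr$conc[, "mRNA_G1"], tc$time_min * 60)$y / avg)
  expect_equal(var(resid), 3 * sigma^2, tolerance = 0.2)
})

test_that("steady-state generation is exact at zero noise with all sources", {
  st0 <- reduced_setup(seed = 5, sigma_ss = 0)
  tr <- integrate_model(st0$model, st0$truth)
  expect_equal(sum(st0$ss$kind == "mRNA"), 2)      # two transcript sources
  expect_equal(sum(st0$ss$kind == "protein"), 3)   # three protein sources
  expect_equal(st0$ss$log10_conc_uM[st0$ss$kind == "mRNA"],
               rep(unname(log10(time_average(tr, "mRNA_G1"))), 2),
               tolerance = 1e-8)
  # median of replicated noisy values recovers the truth (symmetric noise)
  meds <- vapply(1:40, function(s) {
    d <- synth_design(st0$model, st0$truth, sigma_ss = 0.2, seed = s)
    ss <- gen_steady_state(d)
    median(ss$log10_conc_uM[ss$kind == "protein"])
  }, numeric(1))
  expect_equal(median(meds),
               unname(log10(time_average(tr, "protein_G1"))),
               tolerance = 0.1)
})

test_that("validation rates derive from the true kinetics", {
  m <- single_gene_model()
  truth <- preset_truth("reduced")
  d0 <- synth_design(m, truth, sigma_val = 0, seed = 7)
  vr <- gen_validation_rates(d0)
  lin <- unpack_log10(truth, m)
  expect_equal(vr$value[vr$kind == "mrna_degradation"], lin[["deltam"]],
               tolerance = 1e-12)
  expect_equal(vr$value[vr$kind == "translation"], lin[["kappa"]],
               tolerance = 1e-12)
  tr <- integrate_model(m, truth)
  expect_equal(vr$value[vr$kind == "transcription"],
               unname(time_avg_transcription_rate(tr, truth, m, "G1")),
               tolerance = 1e-9)
  # seeded reproducibility with noise
  dn <- synth_design(m, truth, sigma_val = 0.2, seed = 7)
  expect_identical(gen_validation_rates(dn), gen_validation_rates(dn))
  expect_false(identical(gen_validation_rates(dn), vr))
})

test_that("zero-noise data peak the likelihood at the generating truth", {
  st0 <- reduced_setup(seed = 11, sigma_tc = 0, sigma_ss = 0)
  # evaluate with a small working error scale (the generator used none)
  fixed <- st0$truth[c("m0_G1", "p0_G1")]
  fixed["sigma_tc"] <- log10(0.05)
  fixed["sigma_ss"] <- log10(0.05)
  L <- make_loglik(st0$model, st0$prior, st0$tc, st0$ss, fixed = fixed)
  th <- st0$truth[L$free]
  ll0 <- L$log_lik(th)
  for (j in seq_along(th)) for (s in c(-0.2, 0.2)) {
    thp <- th
    thp[j] <- thp[j] + s
    expect_lt(L$log_lik(thp), ll0)
  }
})

test_that("generated files pass the strict readers unchanged", {
  st <- reduced_setup(seed = 13)
  d <- st$design
  td <- withr::local_tempdir()
  p1 <- write_time_course(st$tc, file.path(td, "tc.csv"))
  p2 <- write_steady_state(st$ss, file.path(td, "ss.csv"))
  p3 <- write_validation_rates(gen_validation_rates(d),
                               file.path(td, "vr.csv"))
  expect_equal(read_time_course(p1)$log_ratio, st$tc$log_ratio,
               tolerance = 1e-12)
  expect_silent(read_steady_state(p2))
  expect_silent(read_validation_rates(p3))
})
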