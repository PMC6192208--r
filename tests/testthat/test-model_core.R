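test_that("the four network variants are wired and nested as specified", {
  m1 <- build_model(1)
  expect_equal(nrow(m1$genes), 7)
  expect_length(m1$species, 14)
  expect_true(all(is.na(m1$genes$transcription_inhibitor)))
  expect_true(all(is.na(m1$genes$degradation_inhibitor)))
  expect_equal(m1$genes$activator[m1$genes$name == "NDD1"], "SWI4")

  m2 <- build_model(2)
  expect_true("HCM1" %in% m2$genes$name)
  expect_equal(m2$genes$activator[m2$genes$name == "NDD1"], "HCM1")
  expect_equal(m2$genes$activator[m2$genes$name == "HCM1"], "SWI4")

  m3 <- build_model(3)
  expect_equal(m3$genes$transcription_inhibitor[m3$genes$name %in%
                                                  c("SWI4", "CLN3")],
               c("YOX1", "YOX1"))
  expect_equal(m3$genes$activator[m3$genes$name == "YOX1"], "SWI4")

  m4 <- build_model(4)
  expect_equal(nrow(m4$genes), 9)
  expect_length(m4$species, 18)
  expect_equal(sum(!is.na(m4$genes$transcription_inhibitor)), 2)
  expect_equal(m4$genes$degradation_inhibitor[m4$genes$name == "NDD1"],
               "CLN2")
  # nesting: each variant's gene set contains the previous one's
  for (v in 2:4)
    expect_true(all(build_model(v - 1)$genes$name %in%
                      build_model(v)$genes$name))
  # v4 adds only an edge over v3
  expect_setequal(build_model(3)$genes$name, build_model(4)$genes$name)

  expect_error(build_model(5), "1, 2, 3, 4")
  expect_error(build_model(0), "1, 2, 3, 4")
})

test_that("model_spec rejects inconsistent gene tables", {
  g <- data.frame(name = "A", activator = "B",
                  transcription_inhibitor = NA, degradation_inhibitor = NA)
  expect_error(model_spec(g), "not present")
  g$activator <- NA
  expect_error(model_spec(g), "activating transcription factor")
  g2 <- rbind(data.frame(name = "A", activator = "A",
                         transcription_inhibitor = NA,
                         degradation_inhibitor = NA),
              data.frame(name = "A", activator = "A",
                         transcription_inhibitor = NA,
                         degradation_inhibitor = NA))
  expect_error(model_spec(g2), "duplicated")
})

test_that("every parameter symbol appears exactly once in the inventory", {
  for (m in list(build_model(1), build_model(4), single_gene_model())) {
    info <- param_info(m)
    expect_false(anyDuplicated(info$name) > 0)
    n <- nrow(m$genes)
    n_ti <- sum(!is.na(m$genes$transcription_inhibitor))
    n_di <- sum(!is.na(m$genes$degradation_inhibitor))
    # per gene: beta, alpha, deltap, m0, p0; shared deltam, kappa;
    # K + h per inhibition edge; two error scales
    expect_equal(nrow(info), 5 * n + 2 + 2 * (n_ti + n_di) + 2)
    expect_setequal(unique(info$kind[info$scale == "linear"]),
                    if (n_ti + n_di > 0) c("h_tx", "h_deg")[c(n_ti, n_di) > 0]
                    else character(0))
  }
  expect_equal(nrow(param_info(build_model(4))), 55)
})

test_that("pack/unpack are exact inverses and reject bad input", {
  m <- build_model(2)
  expect_equal(pack_log10(setNames(rep(1, nrow(param_info(m))),
                                   param_info(m)$name), m)[["deltam"]], 0)
  set.seed(4)
  lin <- setNames(10^runif(nrow(param_info(m)), -5, 1), param_info(m)$name)
  rt <- unpack_log10(pack_log10(lin, m), m)
  expect_equal(unname(rt[names(lin)]), unname(lin), tolerance = 1e-12)
  lin[1] <- -1
  expect_error(pack_log10(lin, m), "strictly positive")
  expect_error(pack_log10(lin[-1], m), "missing parameter")
})

test_that("inhibition factor has the Hill repression shape", {
  expect_equal(inhibition_factor(0, 0.5, 2), 1)
  expect_equal(inhibition_factor(0.5, 0.5, 7), 0.5)
  expect_equal(inhibition_factor(1e9, 0.01, 2), 0, tolerance = 1e-12)
  x <- seq(0, 2, by = 0.01)
  expect_true(all(diff(inhibition_factor(x, 0.3, 2.5)) <= 0))
  expect_error(inhibition_factor(-1, 0.5, 2), "non-negative")
  expect_error(inhibition_factor(1, 0, 2), "strictly positive")
})

test_that("rate equations match their three-term structure", {
  m <- build_model(4)
  th <- random_params(m, seed = 11)
  lin <- unpack_log10(th, m)
  gn <- m$genes$name
  n <- length(gn)

  # all-zero state: dm = beta, dP = 0
  d0 <- cyclin_rhs(rep(0, 2 * n), th, m)
  expect_equal(unname(d0[1:n]), unname(lin[paste0("beta_", gn)]),
               tolerance = 1e-12)
  expect_equal(unname(d0[(n + 1):(2 * n)]), rep(0, n))

  # R reference implementation agrees with the compiled one
  r_rhs <- function(state, lin, m) {
    gn <- m$genes$name; n <- length(gn)
    mR <- state[1:n]; P <- state[(n + 1):(2 * n)]
    names(mR) <- names(P) <- gn
    dm <- dP <- numeric(n)
    for (i in seq_len(n)) {
      g <- gn[i]
      tx <- lin[[paste0("beta_", g)]] +
        lin[[paste0("alpha_", g)]] * P[m$genes$activator[i]]
      ti <- m$genes$transcription_inhibitor[i]
      if (!is.na(ti))
        tx <- tx * inhibition_factor(P[ti], lin[[paste0("K_tx_", g)]],
                                     lin[[paste0("h_tx_", g)]])
      dm[i] <- tx - lin[["deltam"]] * mR[i]
      deg <- lin[[paste0("deltap_", g)]] * P[i]
      di <- m$genes$degradation_inhibitor[i]
      if (!is.na(di))
        deg <- deg * inhibition_factor(P[di], lin[[paste0("K_deg_", g)]],
                                       lin[[paste0("h_deg_", g)]])
      dP[i] <- lin[["kappa"]] * mR[i] - deg
    }
    c(dm, dP)
  }
  set.seed(2)
  for (k in 1:20) {
    state <- 10^runif(2 * n, -4, 0)
    expect_equal(cyclin_rhs(state, th, m), r_rhs(state, lin, m),
                 tolerance = 1e-12)
  }

  # transcription inhibitor at K halves transcription exactly
  mr <- single_gene_model()
  g2 <- rbind(mr$genes,
              data.frame(name = "R1", activator = "G1",
                         transcription_inhibitor = NA,
                         degradation_inhibitor = NA))
  g2$transcription_inhibitor[1] <- "R1"
  m2 <- model_spec(g2)
  th2 <- random_params(m2, seed = 5)
  lin2 <- unpack_log10(th2, m2)
  state <- c(0, 0, 0.3, lin2[["K_tx_G1"]])  # repressor protein at K
  d_inh <- cyclin_rhs(state, th2, m2)
  state0 <- state; state0[4] <- 0
  d_no <- cyclin_rhs(state0, th2, m2)
  expect_equal(d_inh[1], d_no[1] / 2, tolerance = 1e-12)

  expect_error(cyclin_rhs(rep(0, 3), th, m), "does not match")
})

test_that("species at zero never have negative derivatives", {
  for (seed in 1:5) {
    m <- build_model(4)
    th <- random_params(m, seed = seed)
    set.seed(seed + 100)
    n <- length(m$species)
    state <- 10^runif(n, -4, 0)
    zero <- runif(n) < 0.5
    state[zero] <- 0
    d <- cyclin_rhs(state, th, m)
    expect_true(all(d[zero] >= 0))
  }
})
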