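# Shared fixtures: reduced single-gene setup and small synthetic
# datasets, built in code at test time.

reduced_prior <- function(model = single_gene_model()) {
  default_priors(model, overrides = list(
    beta_G1 = c(-5, -1), alpha_G1 = c(-5, -1), deltap_G1 = c(-5, -1),
    deltam = c(-5, -1), kappa = c(-5, -1)))
}

reduced_setup <- function(seed = 1, sigma_tc = 0.2, sigma_ss = 0.2) {
  model <- single_gene_model()
  prior <- reduced_prior(model)
  truth <- preset_truth("reduced")
  design <- synth_design(model, truth, sigma_tc = sigma_tc,
                         sigma_ss = sigma_ss, seed = seed)
  list(model = model, prior = prior, truth = truth, design = design,
       tc = gen_time_course(design), ss = gen_steady_state(design))
}

# Free kinetic rates; initial conditions and error scales fixed at truth.
reduced_loglik <- function(setup, tc = TRUE, ss = TRUE) {
  fixed <- setup$truth[c("m0_G1", "p0_G1", "sigma_tc", "sigma_ss")]
  make_loglik(setup$model, setup$prior,
              tc_data = if (tc) setup$tc,
              ss_data = if (ss) setup$ss,
              fixed = fixed)
}

# Deterministic pseudo-random parameter vector inside the prior box.
random_params <- function(model, prior = default_priors(model), seed = 1) {
  set.seed(seed)
  setNames(prior$lower + (prior$upper - prior$lower) * runif(nrow(prior)),
           prior$name)
}
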