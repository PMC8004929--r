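# Shared fixtures, memoized per test session. The recovery experiment is the
# expensive one (10 maximum-likelihood refits of synthetic studies); it is
# computed once and shared between the estimation property tests and the
# acceptance tests.
.fx <- new.env(parent = emptyenv())

fx_phys <- function() {
  if (is.null(.fx$phys)) .fx$phys <- load_physiology()
  .fx$phys
}

fx_drug <- function() {
  if (is.null(.fx$drug)) .fx$drug <- drug_params()
  .fx$drug
}

fx_tum <- function() {
  if (is.null(.fx$tum)) .fx$tum <- tumor_params()
  .fx$tum
}

fx_system <- function() {
  if (is.null(.fx$system))
    .fx$system <- build_pbpk_system(fx_phys(), fx_drug(), fx_tum())
  .fx$system
}

fx_sim <- function() {
  if (is.null(.fx$sim))
    .fx$sim <- simulate_pbpk(dose_event(0.1, 28), system = fx_system())
  .fx$sim
}

# noise-free synthetic study (sigma1 = sigma2 = 0)
fx_dataset_exact <- function() {
  if (is.null(.fx$ds_exact)) {
    des <- study_design(sigma1 = 0, sigma2 = 0, seed = 7)
    .fx$ds_exact <- generate_study(des, fx_phys(), fx_drug(), fx_tum())
  }
  .fx$ds_exact
}

# 10-seed parameter-recovery experiment at the generating values
fx_recovery <- function() {
  if (is.null(.fx$recovery)) {
    .fx$recovery <- recovery_experiment(seeds = 1:10, fx_phys(), fx_drug(),
                                        fx_tum())
  }
  .fx$recovery
}

# generating ("truth") values of the estimated parameter set
fx_truth <- function() {
  drug <- fx_drug(); tum <- fx_tum()
  nms <- fit_spec()$estimate
  vapply(nms, mmaepbpk:::.get_param, numeric(1), drug = drug, tum = tum)
}
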