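# Shared fixtures, built in code at test time.

zero_bias <- function() {
  device_bias(0, 0, 0, 0, c(power = 0, gct = 0, lss = 0))
}

# small noiseless session, memoised across tests
.fixture_env <- new.env(parent = emptyenv())

noiseless_session <- function() {
  if (is.null(.fixture_env$session)) {
    .fixture_env$session <- suppressWarnings(simulate_session(
      subject_profile(70, 1.75, initial_speed = 10),
      protocol_config(max_stages = 4),
      zero_bias(), kleg_true = 10, seed = 42, vo2_noise_sd = 0
    ))
  }
  .fixture_env$session
}

noiseless_processed <- function() {
  if (is.null(.fixture_env$processed)) {
    .fixture_env$processed <- process_session(noiseless_session())
  }
  .fixture_env$processed
}

# data simulated from the agreement mixed model with subject random
# intercepts/slopes; used by recovery and Bayes-factor tests
sim_agreement_data <- function(seed, device_effect = -300, n_subjects = 6,
                               n_laps = 20, sigma = 50, sd_intercept = 86,
                               sd_slope = 17, interaction = -24,
                               speed_effect = 65, intercept = 568) {
  set.seed(seed)
  subj <- rep(sprintf("s%d", seq_len(n_subjects)), each = 2 * n_laps)
  speed <- rep(rep(seq(2.8, 4.2, length.out = n_laps), times = 2), n_subjects)
  dev <- rep(rep(c(0, 1), each = n_laps), n_subjects)
  S0 <- rep(rnorm(n_subjects, 0, sd_intercept), each = 2 * n_laps)
  S1 <- rep(rnorm(n_subjects, 0, sd_slope), each = 2 * n_laps)
  sp_s <- as.numeric(scale(speed))
  y <- intercept + S0 + device_effect * dev + (speed_effect + S1) * sp_s +
    interaction * dev * sp_s + rnorm(length(dev), 0, sigma)
  tibble::tibble(subject = subj, value = y, device_num = dev,
                 speed_s = sp_s, speed = speed)
}

fast_settings <- function() sampler_settings(chains = 2, iter = 1400, warmup = 600)
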