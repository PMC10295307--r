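#' Generate a synthetic labelled EEG trial set
#'
#' Simulates trial-wise multi-channel EEG for a balanced two-class task.
#' Noise is drawn independently per trial and per time sample from a
#' zero-mean multichannel Gaussian with unit variances and a single
#' equicorrelation parameter `noise_correlation` between channels. Each
#' informative channel additionally carries a class-dependent evoked
#' component: a fixed half-period sinusoid template across samples, scaled by
#' `+effect_size / 2` for class 1 trials and `-effect_size / 2` for class 0
#' trials, so the between-class mean difference at the template peak equals
#' `effect_size` noise standard deviations and the discriminative weight mass
#' is spread over samples as in real evoked activity.
#'
#' @param n_trials Number of trials; must be even and at least 4. The first
#'   half is labelled 0, the second half 1.
#' @param n_channels Number of channels (>= 2).
#' @param n_samples Number of time samples per trial (>= 1).
#' @param informative_channels Integer indices of channels that carry the
#'   class signal (possibly empty).
#' @param effect_size Non-negative class separation at the template peak, in
#'   units of the noise standard deviation.
#' @param noise_correlation Equicorrelation of the channel noise, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param sampling_rate,participant_id,task_id,period_id Passed to
#'   [trialset()].
#'
#' @return A list with elements `trialset` (an `eeg_trialset`) and `truth`
#'   (a `ground_truth` list: `informative_channels`, `effect_size`,
#'   `noise_correlation`, `seed`, `template`).
#' @examples
#' sim <- generate_trialset(40, 8, 16, informative_channels = c(2, 5),
#'                          effect_size = 2, noise_correlation = 0.3, seed = 1)
#' sim$trialset
#' @export
generate_trialset <- function(n_trials, n_channels, n_samples,
                              informative_channels = integer(),
                              effect_size = 2, noise_correlation = 0.3,
                              seed = 1L, sampling_rate = 512,
                              participant_id = "P01", task_id = "task1",
                              period_id = 1L) {
  if (n_trials < 4 || n_trials %% 2 != 0) {
    abort("`n_trials` must be even and at least 4.")
  }
  if (n_channels < 2) abort("`n_channels` must be at least 2.")
  if (n_samples < 1) abort("`n_samples` must be at least 1.")
  if (noise_correlation < 0 || noise_correlation >= 1) {
    abort("`noise_correlation` must lie in [0, 1).")
  }
  if (effect_size < 0) abort("`effect_size` must be non-negative.")
  informative_channels <- as.integer(informative_channels)
  if (length(informative_channels) &&
    any(informative_channels < 1L | informative_channels > n_channels)) {
    abort("`informative_channels` contains out-of-range channel indices.")
  }

  labels <- rep(c(0L, 1L), each = n_trials / 2)
  # template peaks at 1 in the middle sample; no exact zeros at the edges
  template <- sin(pi * (seq_len(n_samples) - 0.5) / n_samples)

  data <- withr::with_seed(seed, {
    rho <- noise_correlation
    # equicorrelated noise via a shared factor: unit diagonal, rho off-diagonal
    common <- array(rnorm(n_trials * n_samples), c(n_trials, 1, n_samples))
    own <- array(rnorm(n_trials * n_channels * n_samples),
      c(n_trials, n_channels, n_samples)
    )
    arr <- sqrt(1 - rho) * own +
      sqrt(rho) * common[, rep(1, n_channels), , drop = FALSE]
    if (length(informative_channels)) {
      sgn <- ifelse(labels == 1L, 1, -1) * effect_size / 2
      evoked <- outer(sgn, template) # trials x samples
      for (ch in informative_channels) {
        arr[, ch, ] <- arr[, ch, ] + evoked
      }
    }
    arr
  })

  list(
    trialset = trialset(
      data = data, labels = labels,
      sampling_rate = sampling_rate,
      participant_id = participant_id, task_id = task_id,
      period_id = period_id
    ),
    truth = structure(
      list(
        informative_channels = informative_channels,
        effect_size = effect_size,
        noise_correlation = noise_correlation,
        seed = as.integer(seed),
        template = template
      ),
      class = "ground_truth"
    )
  )
}

#' Generate a synthetic participant group
#'
#' Simulates `n_participants` independent participants that share the same
#' informative channel set, optionally with per-participant effect-size
#' jitter, and optionally several analysis periods per participant (each
#' period is an independently drawn trial set with the same ground truth).
#' All per-participant/period seeds are derived deterministically from the
#' master `seed`.
#'
#' @param n_participants Number of participants (>= 2).
#' @param n_trials,n_channels,n_samples,noise_correlation,sampling_rate,task_id
#'   Passed to [generate_trialset()].
#' @param shared_informative_channels Channel indices carrying signal for
#'   every participant.
#' @param effect_size Group-level effect size.
#' @param per_participant_jitter Half-width of the uniform jitter added to
#'   `effect_size` per participant (0 = identical effects; jittered effects
#'   are floored at 0).
#' @param n_periods Number of independent analysis periods per participant.
#' @param seed Master seed.
#'
#' @return A list of length `n_participants`; each element has `trialsets`
#'   (list of `eeg_trialset`, one per period) and `truth` (the participant's
#'   `ground_truth`).
#' @export
generate_participant_group <- function(n_participants, n_trials, n_channels,
                                       n_samples,
                                       shared_informative_channels,
                                       effect_size = 2,
                                       per_participant_jitter = 0,
                                       noise_correlation = 0.3,
                                       n_periods = 1L, seed = 1L,
                                       sampling_rate = 512,
                                       task_id = "task1") {
  if (n_participants < 2) abort("`n_participants` must be at least 2.")
  jit <- withr::with_seed(
    derive_seed(seed, 1L),
    runif(n_participants, -per_participant_jitter, per_participant_jitter)
  )
  effects <- pmax(0, effect_size + jit)
  purrr::map(seq_len(n_participants), function(i) {
    pid <- sprintf("P%02d", i)
    tsets <- purrr::map(seq_len(n_periods), function(p) {
      generate_trialset(
        n_trials = n_trials, n_channels = n_channels, n_samples = n_samples,
        informative_channels = shared_informative_channels,
        effect_size = effects[i], noise_correlation = noise_correlation,
        seed = derive_seed(seed, i + 1L, p),
        sampling_rate = sampling_rate, participant_id = pid,
        task_id = task_id, period_id = p
      )
    })
    list(
      trialsets = purrr::map(tsets, "trialset"),
      truth = tsets[[1]]$truth
    )
  })
}
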