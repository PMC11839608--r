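# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Value iteration on a deterministic MDP given as transition/reward arrays:
# trans[s, a] = successor state, rew[s, a] = immediate reward.
value_iteration <- function(trans, rew, gamma, tol = 1e-12, max_iter = 10000) {
  q <- matrix(0, nrow(trans), ncol(trans))
  for (it in seq_len(max_iter)) {
    v <- apply(q, 1, max)
    q_new <- rew + gamma * matrix(v[trans], nrow(trans))
    if (max(abs(q_new - q)) < tol) return(q_new)
    q <- q_new
  }
  q
}

# Run q_update sweeps over all (s, a) pairs of a deterministic MDP with
# learning rate 1; returns the package's Q matrix.
q_sweeps <- function(trans, rew, gamma, sweeps = 200) {
  q <- q_table(nrow(trans), ncol(trans), eta_lr = 1, gamma_discount = gamma)
  for (k in seq_len(sweeps)) {
    for (s in seq_len(nrow(trans))) {
      for (a in seq_len(ncol(trans))) {
        q <- q_update(q, s, a, rew[s, a], trans[s, a])
      }
    }
  }
  q$values
}

# Random deterministic MDP.
random_mdp <- function(n_s, n_a, seed) {
  set.seed(seed)
  list(trans = matrix(sample.int(n_s, n_s * n_a, replace = TRUE), n_s, n_a),
       rew = matrix(round(runif(n_s * n_a, -1, 1), 3), n_s, n_a))
}

# Direct periodogram power of a single tone signal (no Welch, no package
# code): mean squared amplitude within a band via the FFT.
tone_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n^2
  freq <- (seq_len(n) - 1) * fs / n
  sel <- freq >= lo & freq < hi & freq <= fs / 2
  2 * sum(sp[sel])
}

# Build a pure-tone eeg_trace without synthesize_eeg.
tone_trace <- function(freq, fs = 256, duration = 8, amplitude = 1,
                       n_channels = 1) {
  tt <- (seq_len(duration * fs) - 1) / fs
  samples <- matrix(rep(amplitude * sin(2 * pi * freq * tt), n_channels),
                    ncol = n_channels)
  apeo:::new_eeg_trace(samples, fs)
}

signal_power <- function(trace) mean(trace$samples^2)

# Closed-form steady-state offset of pure-P control on the leaky plant
# S(t+1) = (1 - a) S + b u + d with constant target.
p_control_offset <- function(a, b, kp, target, d) {
  (a * target - d) / (a + b * kp)
}
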