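# Independent oracles, coded separately from the implementation paths they
# check.

# Euler-Mascheroni constant; E[ln|Z|] = -(gamma + ln 2)/2 for Z ~ N(0,1)
EULER_GAMMA <- 0.57721566490153286
E_LOG_ABS_Z <- -(EULER_GAMMA + log(2)) / 2

# Expected mean kappa for iid N(0, sigma^2) noise at interval dt:
# dV ~ N(0, 2 sigma^2), E ln|dV| = ln(sigma * sqrt(2)) + E ln|Z|
expected_kappa_white_noise <- function(sigma, dt) {
  (log(sigma * sqrt(2)) + E_LOG_ABS_Z) / log(dt)
}

# Expected mean kappa for fBm with Hurst H and scale sigma at interval dt
expected_kappa_fbm <- function(hurst, sigma, dt) {
  hurst + (log(sigma) + E_LOG_ABS_Z) / log(dt)
}

# Brute-force sequential sums-of-squares decomposition for the two-state
# repeated-measures ANOVA, written from the definition: group means taken
# directly, no lm()/aov() machinery shared with the implementation.
brute_force_rm_anova <- function(y, state, subject) {
  state <- as.character(state); subject <- as.character(subject)
  n <- length(y)
  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  # state first
  ss_state <- 0
  for (s in unique(state)) {
    ys <- y[state == s]
    ss_state <- ss_state + length(ys) * (mean(ys) - gm)^2
  }
  # subject after state: residuals from the state-mean model, then the
  # projection onto subject indicators orthogonalized against {1, state}.
  # For the sequential decomposition we fit state, take residuals, and fit
  # subject to the residuals by least squares on the joint design.
  X1 <- stats::model.matrix(~ factor(state))
  X2 <- stats::model.matrix(~ factor(state) + factor(subject))
  rss1 <- sum(stats::lsfit(X1, y, intercept = FALSE)$residuals^2)
  rss2 <- sum(stats::lsfit(X2, y, intercept = FALSE)$residuals^2)
  ss_subject <- rss1 - rss2
  ss_error <- ss_total - ss_state - ss_subject
  n_subj <- length(unique(subject))
  df_den <- n - 1 - 1 - (n_subj - 1)
  f <- (ss_state / 1) / (ss_error / df_den)
  list(f = f, df_den = df_den,
       p = stats::pf(f, 1, df_den, lower.tail = FALSE))
}

# Direct DFT power peak on evenly spaced data (oracle for the Lomb-Scargle
# peak location on an even grid)
dft_peak_frequency <- function(x, y) {
  y <- y - mean(y)
  n <- length(y)
  dt <- x[2] - x[1]
  spec <- Mod(stats::fft(y))^2
  freqs <- (0:(n - 1)) / (n * dt)
  half <- 2:floor(n / 2)
  freqs[half][which.max(spec[half])]
}

# A comb-distributed kappa sample: equally spaced narrow Gaussian bumps
comb_sample <- function(n = 15000, spacing = 0.1, n_bumps = 8,
                        bump_sd = 0.012) {
  centers <- (seq_len(n_bumps) - 1) * spacing
  stats::rnorm(n, sample(centers, n, replace = TRUE), bump_sd)
}

# Small random cohort table for ANOVA oracle checks
random_small_table <- function(seed) {
  set.seed(seed)
  n_subj <- sample(3:5, 1)
  n_seg <- sample(2:4, 1)
  df <- expand.grid(subject_id = sprintf("s%02d", seq_len(n_subj)),
                    state = c("a", "b"),
                    segment_id = sprintf("g%02d", seq_len(n_seg)),
                    stringsAsFactors = FALSE)
  df$delta_t_s <- 0.004
  df$kappa_avg <- stats::rnorm(nrow(df)) +
    stats::rnorm(n_subj)[match(df$subject_id, unique(df$subject_id))] +
    ifelse(df$state == "b", stats::runif(1, 0, 1), 0)
  df$low_it_fraction <- stats::runif(nrow(df))
  df
}

quick_fbm <- function(hurst, sigma = 1, seed = 1, duration_s = 60, fs = 250) {
  generate_segment(synth_spec("fbm", hurst = hurst, sigma = sigma,
                              seed = seed, duration_s = duration_s, fs = fs))
}
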