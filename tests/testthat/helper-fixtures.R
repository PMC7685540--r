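## Shared fixtures and independent oracles.  Everything is generated in
## code; no binary fixtures on disk.

## Short, coarse protocol for fast closed-loop tests: 20 deg excursion at
## 4 Hz -> 18 outward frames, 35 with return.
tiny_profile <- function(include_return = TRUE) {
  table_profile(accel = 6, plateau_velocity = 6, max_angle = 20,
                frame_rate = 4, include_return = include_return)
}

## Brute-force two-way crossed ANOVA by definition-level sums of squares
## (explicit loops; independent of the matrix-algebra implementation).
anova_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_err <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_err <- ss_err + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  ms_s <- ss_rows / (n - 1)
  ms_r <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  icc_a1 <- (ms_s - ms_e) / (ms_s + (k - 1) * ms_e + (k / n) * (ms_r - ms_e))
  list(ms_subjects = ms_s, ms_raters = ms_r, ms_error = ms_e, icc_a1 = icc_a1)
}

## Definition-level MSI/MSV from a per-frame range vector.
msi_oracle <- function(frc) {
  acc <- 0
  for (x in frc) acc <- acc + x
  acc / length(frc)
}
msv_oracle <- function(frc) {
  m <- msi_oracle(frc)
  acc <- 0
  for (x in frc) acc <- acc + (x - m)^2
  sqrt(acc / length(frc))
}

## Integer circular shift of a matrix (for translation-equivariance tests).
roll_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}
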