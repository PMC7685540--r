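ramp_sequence <- function(n = 101, peak = 40, shares = c(0.4, 0.3, 0.2, 0.1)) {
  g <- seq(0, peak, length.out = n)
  motion_sequence((0:(n - 1)) / 15, g, outer(g, shares))
}

test_that("proportional scaling preserves shares and signs", {
  ## equal-share noiseless subject: p = 0.25 everywhere retained
  subj <- generate_subject(tiny_profile(),
                           sharing_profile(base_shares = rep(0.25, 4),
                                           share_drift = 0, noise_sd = 0),
                           seed = 1)
  prop <- to_proportional(subj, trim_middle80(subj))
  expect_equal(range(prop$p, na.rm = TRUE), c(0.25, 0.25), tolerance = 1e-12)

  ## direct arithmetic, including a negative share
  seq <- motion_sequence(0:2, c(0, 2, 4),
                         rbind(c(0, 0, 0, 0), c(1, 0.5, 0.25, 0.25),
                               c(2, 1, 0.5, 0.5)))
  p <- to_proportional(seq, c(FALSE, TRUE, TRUE))
  expect_equal(unname(p$p[3, ]), c(0.5, 0.25, 0.125, 0.125))

  ## noiseless generated subject: proportions sum to 1 to 1e-9
  subj2 <- generate_subject(tiny_profile(),
                            sharing_profile(share_drift = 0.05, noise_sd = 0),
                            seed = 2)
  p2 <- to_proportional(subj2, trim_middle80(subj2))
  expect_lt(max(abs(rowSums(p2$p[p2$trim_mask, ]) - 1)), 1e-9)

  ## zero gross on a retained frame is an error
  expect_error(to_proportional(seq, c(TRUE, TRUE, TRUE)), "zero gross")
})

test_that("middle-80% amplitude trim retains gross angles in [4, 36] deg", {
  ## monotone outward ramp 0 -> 40
  seq <- ramp_sequence()
  mask <- trim_middle80(seq)
  expect_identical(mask, seq$gross_deg >= 4 - 1e-12 & seq$gross_deg <= 36 + 1e-12)

  ## default protocol: trim is symmetric about the peak and trims both
  ## shoulders of both phases
  full <- generate_table_motion(table_profile())
  full$level_deg <- outer(full$gross_deg, c(0.4, 0.3, 0.2, 0.1)) # not used by trim
  m <- trim_middle80(full)
  expect_identical(m, rev(m))
  expect_false(m[1]); expect_false(m[length(m)])
  expect_false(m[which.max(full$gross_deg)])
  expect_identical(m, full$gross_deg >= 4 - 1e-12 & full$gross_deg <= 36 + 1e-12)

  ## time-based alternative trims 10% of frames at each end of each phase
  mt <- trim_middle80(full, basis = "time")
  out <- which(full$phase == "outward")
  expect_false(mt[out[1]]); expect_true(mt[out[round(length(out) / 2)]])

  ## all-zero gross series errors
  zero <- motion_sequence(0:9 / 15, rep(0, 10), matrix(0, 10, 4))
  expect_error(trim_middle80(zero), "zero")
})

test_that("frame range of proportions behaves as a range", {
  expect_equal(frame_range(rbind(c(0.4, 0.3, 0.2, 0.1))), 0.3)
  expect_equal(frame_range(rbind(rep(0.25, 4))), 0)
  ## a negative share: range exceeds the maximum share
  expect_equal(frame_range(rbind(c(0.6, 0.5, 0.1, -0.2))), 0.8)
  frc <- frame_range(rbind(c(0.4, 0.3, 0.2, 0.1), rep(0.25, 4)))
  expect_true(all(frc >= 0))
})

test_that("MSI and MSV match their definitions and the brute-force oracle", {
  expect_equal(compute_msi(c(0.3, 0)), 0.15)
  expect_equal(compute_msv(c(0.3, 0)), 0.15)   # two-point population SD
  expect_equal(compute_msv(rep(0.2, 10)), 0)
  expect_error(compute_msi(numeric(0)), "at least 2")

  set.seed(31)
  for (rep in 1:5) {
    frc <- runif(50, 0, 0.6)
    expect_equal(compute_msi(frc), msi_oracle(frc), tolerance = 1e-12)
    expect_equal(compute_msv(frc), msv_oracle(frc), tolerance = 1e-12)
    ## sample-SD variant for completeness
    expect_equal(compute_msv(frc, denominator = "sample"), sd(frc),
                 tolerance = 1e-12)
  }
})

test_that("biomarkers are invariant to a common angular rescaling", {
  subj <- generate_subject(tiny_profile(), sharing_profile(), seed = 6)
  scaled <- motion_sequence(subj$frame_times, subj$gross_deg * 2.5,
                            subj$level_deg * 2.5, subj$phase)
  a <- motion_share(subj); b <- motion_share(scaled)
  expect_equal(b$msi, a$msi, tolerance = 1e-12)
  expect_equal(b$msv, a$msv, tolerance = 1e-12)
  expect_identical(a$trim_mask, b$trim_mask)
})

test_that("MSI = 0 iff shares are equal; equal shares give zero MSV", {
  subj <- generate_subject(tiny_profile(),
                           sharing_profile(base_shares = rep(0.25, 4),
                                           share_drift = 0, noise_sd = 0),
                           seed = 1)
  r <- motion_share(subj)
  expect_equal(r$msi, 0, tolerance = 1e-12)
  expect_equal(r$msv, 0, tolerance = 1e-12)
  r2 <- motion_share(generate_subject(tiny_profile(), sharing_profile(noise_sd = 0),
                                      seed = 2))
  expect_gt(r2$msi, 0)
})

test_that("outward-only analysis restricts to the outward phase", {
  subj <- generate_subject(tiny_profile(), sharing_profile(), seed = 8)
  both <- motion_share(subj)
  outw <- motion_share(subj, phases = "outward")
  expect_lt(outw$n_retained, both$n_retained)
  expect_true(all(subj$phase[outw$trim_mask] == "outward"))
})

test_that("expected MSV does not decrease with measurement noise", {
  p <- tiny_profile()
  msv_at <- function(noise) {
    mean(vapply(1:70, function(i) {
      subj <- generate_subject(p, sharing_profile(noise_sd = noise),
                               seed = 3000 + i)
      motion_share(subj)$msv
    }, 1))
  }
  m <- vapply(c(0, 0.52, 1.5), msv_at, 1)
  expect_true(all(diff(m) > -1e-3))
})

test_that("cohort-mean MSI tracks the calibrated true mean range of 0.24", {
  ## full protocol (40 deg, 15 Hz): noise-induced inflation of the range is
  ## small (~ +0.01); sampling SE of the cohort mean is ~ 0.012 at n = 60
  co <- generate_cohort(60, table_profile(), seed = 21)
  msi <- vapply(co$sequences, function(s) motion_share(s)$msi, 1)
  true_mean <- mean(co$truth$target_range)
  expect_lt(abs(mean(msi) - true_mean), 0.03)
  expect_lt(abs(mean(msi) - 0.24), 0.04)
})
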