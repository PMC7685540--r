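## Shared rendered fixture: short noise-free sequence, default geometry.
tracked_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      subj <- generate_subject(tiny_profile(),
                               sharing_profile(noise_sd = 0), seed = 3)
      geo <- vertebral_geometry()
      iseq <- render_frames(subj, geo)
      cache <<- list(subj = subj, geo = geo, iseq = iseq)
    }
    cache
  }
})

test_that("first-image registration honours the perturbation model", {
  fx <- tracked_fixture()
  frame0 <- fx$iseq$frames[[1]]

  ## sd = 0: templates reproduce the fixture exactly
  tmpl <- register_first_image(frame0, fx$geo, n_repeats = 5,
                               perturbation_sd = 0, seed = 1)
  expect_equal(tmpl$L3$corners, unname(fx$geo$vertebrae$L3),
               ignore_attr = TRUE)

  ## n_repeats = 1 is a single manual placement (perturbed once)
  t1 <- register_first_image(frame0, fx$geo, n_repeats = 1,
                             perturbation_sd = 2, seed = 7)
  expect_false(isTRUE(all.equal(t1$L3$corners,
                                unname(fx$geo$vertebrae$L3),
                                check.attributes = FALSE)))

  ## malformed fixture
  bad <- list(vertebrae = list(L2 = fx$geo$vertebrae$L2[1:3, ]))
  expect_error(register_first_image(frame0, bad, seed = 1),
               "fewer than 4 corner")
})

test_that("averaging 5 repeats shrinks corner error by about sqrt(5)", {
  fx <- tracked_fixture()
  frame0 <- fx$iseq$frames[[1]]
  fixture1 <- list(vertebrae = fx$geo$vertebrae["L4"])
  nominal <- fx$geo$vertebrae$L4
  reps <- 300
  errs <- vapply(seq_len(reps), function(i) {
    tm <- register_first_image(frame0, fixture1, n_repeats = 5,
                               perturbation_sd = 1, seed = i)
    as.numeric(tm$L4$corners - nominal)
  }, numeric(8))
  ## empirical SD of each averaged corner coordinate ~ 1/sqrt(5)
  emp_sd <- mean(apply(errs, 1, sd))
  expect_equal(emp_sd, 1 / sqrt(5), tolerance = 0.15)
})

test_that("identical frames track to the frame-0 pose with zero rotation", {
  fx <- tracked_fixture()
  frames <- rep(fx$iseq$frames[1], 4)
  tmpl <- register_first_image(frames[[1]], fx$geo, perturbation_sd = 0, seed = 1)
  series <- track_sequence(frames, tmpl)
  expect_false(any(series$flag))
  expect_lt(max(abs(series$tx)), 0.1)
  expect_lt(max(abs(series$ty)), 0.1)
  expect_lt(max(abs(series$rot_deg)), 0.05)
})

test_that("tracking is equivariant to an integer global shift", {
  fx <- tracked_fixture()
  frames <- fx$iseq$frames[1:6]
  tmpl <- register_first_image(frames[[1]], fx$geo, perturbation_sd = 0, seed = 1)
  base <- track_sequence(frames, tmpl)
  shifted <- lapply(frames, roll_matrix, dy = 2, dx = 3)
  shifted[[1]] <- frames[[1]]   # registration still on the unshifted frame 0
  moved <- track_sequence(shifted, tmpl)
  keep <- moved$frame > 1
  expect_equal(moved$tx[keep], base$tx[keep] + 3, tolerance = 1e-6)
  expect_equal(moved$ty[keep], base$ty[keep] + 2, tolerance = 1e-6)
  expect_equal(moved$rot_deg[keep], base$rot_deg[keep], tolerance = 1e-6)
})

test_that("a global rigid motion leaves intervertebral angles at zero", {
  fx <- tracked_fixture()
  f0 <- fx$iseq$frames[[1]]
  frames <- list(f0, roll_matrix(f0, 1, 2), roll_matrix(f0, 2, 4),
                 roll_matrix(f0, 3, 6))
  tmpl <- register_first_image(f0, fx$geo, perturbation_sd = 0, seed = 1)
  series <- track_sequence(frames, tmpl)
  seq_hat <- extract_intervertebral_angles(series)
  expect_lt(max(abs(seq_hat$level_deg)), 0.05)
  expect_lt(max(abs(seq_hat$gross_deg)), 0.05)
  ## frame 0 angles are exactly zero by construction
  expect_identical(unname(seq_hat$level_deg[1, ]), rep(0, 4))
})

test_that("blanking a vertebra raises a failure flag and extraction refuses", {
  fx <- tracked_fixture()
  frames <- fx$iseq$frames[1:3]
  geo <- fx$geo
  ## occlude L3 in frame 2 with flat background
  corners <- geo$vertebrae$L3
  ys <- (floor(min(corners[, 2])) - 6):(ceiling(max(corners[, 2])) + 6)
  xs <- (floor(min(corners[, 1])) - 6):(ceiling(max(corners[, 1])) + 6)
  frames[[2]][ys, xs] <- geo$background
  tmpl <- register_first_image(frames[[1]], geo, perturbation_sd = 0, seed = 1)
  series <- track_sequence(frames, tmpl)
  expect_true(any(series$flag[series$vertebra == "L3" & series$frame == 2]))
  expect_false(any(series$flag[series$vertebra != "L3"]))
  ## permanently occluded: retracking cannot clear it, extraction refuses
  re <- retrack_failures(series, frames, tmpl)
  expect_true(any(re$flag))
  expect_error(extract_intervertebral_angles(re), "L3@frame2")
})

test_that("retracking clears spurious flags and is a no-op without failures", {
  fx <- tracked_fixture()
  frames <- fx$iseq$frames[1:4]
  tmpl <- register_first_image(frames[[1]], fx$geo, perturbation_sd = 0, seed = 1)
  series <- track_sequence(frames, tmpl)
  expect_identical(retrack_failures(series, frames, tmpl), series)

  ## an over-conservative flag on a trackable frame is cleared on retry
  flagged <- series
  i <- which(flagged$vertebra == "L4" & flagged$frame == 3)
  flagged$flag[i] <- TRUE
  fixed <- retrack_failures(flagged, frames, tmpl)
  expect_false(fixed$flag[i])
  expect_equal(fixed$rot_deg[i], series$rot_deg[i], tolerance = 0.05)
})

test_that("closed loop: render -> track -> extract recovers the kinematics", {
  fx <- tracked_fixture()
  tmpl <- register_first_image(fx$iseq$frames[[1]], fx$geo,
                               perturbation_sd = 0, seed = 1)
  series <- track_sequence(fx$iseq, tmpl)
  expect_false(any(series$flag))
  seq_hat <- extract_intervertebral_angles(series)
  err <- seq_hat$level_deg - fx$subj$level_deg
  expect_lt(sqrt(mean(err^2)), 0.52)   # instrument precision limit
  expect_equal(seq_hat$frame_times, fx$subj$frame_times)
})

test_that("degenerate tracking inputs error", {
  fx <- tracked_fixture()
  tmpl <- register_first_image(fx$iseq$frames[[1]], fx$geo,
                               perturbation_sd = 0, seed = 1)
  expect_error(track_sequence(list(), tmpl), "empty frame stack")
  expect_error(track_sequence(list(matrix(0, 20, 20)), tmpl),
               "larger than the frames")
})
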