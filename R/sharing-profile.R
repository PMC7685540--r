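#' Motion sharing profile of a simulated subject
#'
#' Ground truth for how the four lumbar levels share the gross L2-S1
#' flexion angle.  Each level's instantaneous share is its `base_shares`
#' entry plus a smooth low-frequency sinusoidal drift of amplitude
#' `share_drift`, re-centred every frame so the noiseless shares always
#' sum to exactly 1.  Measured level angles additionally receive i.i.d.
#' Gaussian noise of SD `noise_sd` degrees, the instrument precision limit
#' of the QF system (default 0.52 deg).
#'
#' The default `base_shares` place the per-frame range of shares at 0.24,
#' the healthy-control group mean of the MSI biomarker, with the largest
#' contribution at the most cranial level.
#'
#' @param base_shares numeric length-4, per-level proportion of the gross
#'   angle; must sum to 1 (within 1e-9).
#' @param share_drift per-level amplitude of the sinusoidal share drift
#'   (unitless; scalar recycled to 4).
#' @param noise_sd SD of additive Gaussian angle noise per level, degrees.
#' @param drift_period period of the share drift in seconds; `NULL`
#'   (default) uses the outward-phase duration, i.e. one slow cycle per
#'   bend.
#' @param n_levels number of intervertebral levels; fixed at 4 for the
#'   lumbar L2-S1 configuration.
#'
#' @return An object of class `sharing_profile`.
#' @export
sharing_profile <- function(base_shares = c(0.36, 0.28, 0.24, 0.12),
                            share_drift = 0.04, noise_sd = 0.52,
                            drift_period = NULL, n_levels = 4L) {
  if (n_levels != 4L)
    stop("only the 4-level lumbar configuration (L2-L3 .. L5-S1) is supported")
  if (length(base_shares) != n_levels)
    stop("`base_shares` must have length ", n_levels)
  if (abs(sum(base_shares) - 1) > 1e-9)
    stop("`base_shares` must sum to 1 (got ", format(sum(base_shares)), ")")
  share_drift <- rep_len(share_drift, n_levels)
  if (any(share_drift < 0)) stop("`share_drift` must be >= 0")
  assert_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(drift_period))
    assert_number(drift_period, "drift_period", lower = 0, strict_lower = TRUE)
  structure(
    list(n_levels = n_levels, base_shares = as.numeric(base_shares),
         share_drift = share_drift, noise_sd = noise_sd,
         drift_period = drift_period),
    class = "sharing_profile")
}

#' Simulate one subject's intervertebral motion sequence
#'
#' Builds the gross angle from the table profile and distributes it over
#' the four levels according to the sharing profile:
#' `level = share(t) * gross(t) + N(0, noise_sd^2)`, where `share(t)` is
#' the drifted, re-centred share trajectory.  The noiseless construction
#' conserves the gross angle exactly (per-frame level sum equals the gross
#' angle); the generator is deterministic given `seed`.
#'
#' @param profile a [table_profile()].
#' @param sharing a [sharing_profile()].
#' @param seed integer seed for drift phases and measurement noise.
#' @return A [motion_sequence()] with `level_deg` filled in.  Simulation
#'   ground truth (true share trajectories, true per-frame share range) is
#'   stored in `meta$truth`.
#' @export
generate_subject <- function(profile, sharing, seed = 1L) {
  stopifnot(inherits(profile, "table_profile"), inherits(sharing, "sharing_profile"))
  skel <- generate_table_motion(profile)
  n <- length(skel$frame_times)
  k <- sharing$n_levels
  period <- sharing$drift_period %||% skel$meta$t_outward
  with_seed(seed, {
    phases <- runif(k, 0, 2 * pi)
    drift <- vapply(seq_len(k), function(l) {
      sharing$share_drift[l] * sin(2 * pi * skel$frame_times / period + phases[l])
    }, numeric(n))
    shares <- matrix(sharing$base_shares, n, k, byrow = TRUE) + drift
    ## re-centre so shares sum to exactly 1 each frame (linear correction)
    shares <- shares - (rowSums(shares) - 1) / k
    noise <- matrix(rnorm(n * k, 0, sharing$noise_sd), n, k)
    levels <- shares * skel$gross_deg + noise
  })
  colnames(shares) <- .lvl_names
  true_frc <- apply(shares, 1L, max) - apply(shares, 1L, min)
  motion_sequence(
    skel$frame_times, skel$gross_deg, levels, skel$phase,
    meta = c(skel$meta,
             list(seed = seed, sharing = unclass(sharing),
                  truth = list(shares = shares, frc = true_frc))))
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject sharing profiles around the population defaults and
#' generates one motion sequence per subject.  Between-subject variation
#' enters through (a) a subject-specific spread factor that rescales the
#' base shares about the equal-share point 0.25 — so the subject's true
#' share range (the MSI ground truth for constant shares) is Gaussian with
#' mean `msi_mean` and SD `msi_sd` — and (b) a subject-specific drift
#' amplitude.  Defaults match the healthy-control group scale: MSI mean
#' 0.24, SD 0.09.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param profile a [table_profile()].
#' @param seed integer base seed; per-subject seeds are derived from it.
#' @param msi_mean,msi_sd population mean and SD of the true per-frame
#'   share range.
#' @param drift_mean,drift_sd population mean and SD of the per-subject
#'   sinusoidal drift amplitude.
#' @param noise_sd measurement noise SD in degrees per level.
#' @return A list with `sequences` (list of [motion_sequence()]) and
#'   `truth` (data.frame of per-subject generating parameters).
#' @export
generate_cohort <- function(n_subjects = 30L, profile = table_profile(),
                            seed = 1L, msi_mean = 0.24, msi_sd = 0.09,
                            drift_mean = 0.04, drift_sd = 0.015,
                            noise_sd = 0.52) {
  stopifnot(n_subjects >= 1L)
  base0 <- c(0.36, 0.28, 0.24, 0.12)   # range 0.24 about the 0.25 centre
  range0 <- max(base0) - min(base0)
  pars <- with_seed(seed, {
    data.frame(
      subject = sprintf("S%02d", seq_len(n_subjects)),
      target_range = pmin(pmax(rnorm(n_subjects, msi_mean, msi_sd), 0.02), 0.9),
      drift = pmax(rnorm(n_subjects, drift_mean, drift_sd), 0.005))
  })
  sequences <- lapply(seq_len(n_subjects), function(i) {
    s <- pars$target_range[i] / range0
    shares <- 0.25 + s * (base0 - 0.25)
    sp <- sharing_profile(base_shares = shares,
                          share_drift = pars$drift[i] * s,
                          noise_sd = noise_sd)
    subj_seed <- derive_seed(seed, i)
    ## two-pass exact calibration: share trajectories are affine about the
    ## equal-share point 0.25, so rescaling the base spread and the drift
    ## amplitude by a common factor rescales the true per-frame range
    ## exactly; the second pass pins the subject's true mean range (the
    ## ground-truth MSI) at its target value.
    first <- generate_subject(profile, sp, seed = subj_seed)
    c_adj <- pars$target_range[i] / mean(first$meta$truth$frc)
    sp2 <- sharing_profile(base_shares = 0.25 + c_adj * (sp$base_shares - 0.25),
                           share_drift = sp$share_drift * c_adj,
                           noise_sd = noise_sd)
    generate_subject(profile, sp2, seed = subj_seed)
  })
  names(sequences) <- pars$subject
  list(sequences = sequences, truth = pars)
}
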