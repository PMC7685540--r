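#' Middle-80% trim of a motion sequence
#'
#' Near the start and end of a bend the intervertebral angle changes are
#' close to the instrument precision limit, so the proportional scaling
#' divides two small noisy numbers and the error is amplified.  Only the
#' middle 80% of movement is therefore analysed.  With `basis =
#' "amplitude"` (default) a frame is retained when its gross angle lies in
#' `[0.10, 0.90] * G_max` (G_max = peak gross angle), applied to the
#' outward and return phases separately so both shoulders of each phase
#' are trimmed; `basis = "time"` instead retains the middle 80% of each
#' phase's frames by time.
#'
#' @param seq a [motion_sequence()].
#' @param basis `"amplitude"` (default) or `"time"`.
#' @return Logical vector: `TRUE` for retained frames.
#' @export
trim_middle80 <- function(seq, basis = c("amplitude", "time")) {
  stopifnot(inherits(seq, "motion_sequence"))
  basis <- match.arg(basis)
  g <- seq$gross_deg
  gmax <- max(abs(g))
  if (gmax <= 0) stop("gross angle range is zero; nothing to trim")
  mask <- logical(length(g))
  if (basis == "amplitude") {
    mask <- abs(g) >= 0.10 * gmax - 1e-12 & abs(g) <= 0.90 * gmax + 1e-12
  } else {
    for (ph in unique(seq$phase)) {
      idx <- which(seq$phase == ph)
      t <- seq$frame_times[idx]
      t0 <- min(t); dur <- max(t) - t0
      mask[idx] <- t >= t0 + 0.10 * dur - 1e-12 & t <= t0 + 0.90 * dur + 1e-12
    }
  }
  if (sum(mask) < 2L)
    stop("fewer than 2 frames retained after the middle-80% trim")
  mask
}

#' Proportional intervertebral motion
#'
#' Scales each level's angle by the simultaneous gross L2-S1 angle:
#' `p(level, frame) = level_angle / gross_angle`.  Signs are preserved — a
#' level momentarily moving against the gross direction yields a negative
#' proportion.  Proportions are only computed on frames retained by the
#' trim mask; a zero gross angle on a retained frame is an error (the trim
#' exists precisely to exclude such frames).
#'
#' @param seq a [motion_sequence()] with level angles.
#' @param mask logical retained-frame mask, e.g. from [trim_middle80()];
#'   `NULL` computes proportions on all frames.
#' @return A `proportional_motion` object: list with `p` (frames x 4
#'   matrix, `NA` outside the mask), `trim_mask`, `frc` (per-frame range
#'   of proportions, `NA` outside the mask), `n_retained`, `frame_times`.
#' @export
to_proportional <- function(seq, mask = NULL) {
  stopifnot(inherits(seq, "motion_sequence"))
  if (is.null(seq$level_deg)) stop("sequence has no level angles")
  n <- length(seq$gross_deg)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  zero <- mask & abs(seq$gross_deg) < 1e-12
  if (any(zero))
    stop("zero gross angle on retained frame(s) ",
         paste(which(zero), collapse = ", "),
         "; apply a trim that excludes them")
  p <- matrix(NA_real_, n, 4L, dimnames = list(NULL, .lvl_names))
  p[mask, ] <- seq$level_deg[mask, , drop = FALSE] / seq$gross_deg[mask]
  structure(
    list(p = p, trim_mask = mask, frc = frame_range(p),
         n_retained = sum(mask), frame_times = seq$frame_times),
    class = "proportional_motion")
}

#' Per-frame range of proportional contributions (fRC)
#'
#' For each frame, the spread between the most- and least-contributing
#' levels: `fRC_i = max_l p(l, i) - min_l p(l, i)`.  Zero iff all four
#' proportions are equal; can exceed the maximum share when a level moves
#' against the gross direction (negative proportion).
#'
#' @param p a `proportional_motion` object, or a frames x levels matrix of
#'   proportions (rows with any `NA` yield `NA`).
#' @return Numeric vector of per-frame ranges.
#' @export
frame_range <- function(p) {
  if (inherits(p, "proportional_motion")) p <- p$p
  p <- as.matrix(p)
  apply(p, 1L, function(r) if (anyNA(r)) NA_real_ else max(r) - min(r))
}

#' Motion Sharing Inequality (MSI)
#'
#' The mean of the per-frame range of proportional intervertebral motion
#' over the `N` retained frames: `MSI = sum(fRC_i) / N`.  A measure of the
#' inequality of passive restraint across the four lumbar levels.
#'
#' @param frc numeric vector of per-frame ranges (`NA` entries, i.e.
#'   trimmed frames, are dropped).
#' @return MSI (unitless).
#' @export
compute_msi <- function(frc) {
  if (inherits(frc, "proportional_motion")) frc <- frc$frc
  frc <- frc[!is.na(frc)]
  if (length(frc) < 2L) stop("need at least 2 retained frames to compute MSI")
  sum(frc) / length(frc)
}

#' Motion Sharing Variability (MSV)
#'
#' The standard deviation of the per-frame range of proportional
#' intervertebral motion: `MSV = sqrt(sum((fRC_i - MSI)^2) / N)`.  The
#' population form (denominator `N`) is the default, matching the printed
#' definition; `denominator = "sample"` uses `N - 1`.  A measure of the
#' unevenness of motion control over the bend.
#'
#' @param frc numeric vector of per-frame ranges (`NA` dropped).
#' @param msi optional precomputed MSI; computed from `frc` when `NULL`.
#' @param denominator `"population"` (N, default) or `"sample"` (N - 1).
#' @return MSV (unitless).
#' @export
compute_msv <- function(frc, msi = NULL, denominator = c("population", "sample")) {
  if (inherits(frc, "proportional_motion")) frc <- frc$frc
  denominator <- match.arg(denominator)
  frc <- frc[!is.na(frc)]
  if (length(frc) < 2L) stop("need at least 2 retained frames to compute MSV")
  if (is.null(msi)) msi <- sum(frc) / length(frc)
  n <- length(frc)
  den <- if (denominator == "population") n else n - 1L
  sqrt(sum((frc - msi)^2) / den)
}

#' Motion sharing biomarkers for one sequence
#'
#' End-to-end derivation of MSI and MSV from an intervertebral angle time
#' series: proportional scaling against the gross L2-S1 angle, middle-80%
#' trim, per-frame range series fRC, then `MSI = mean(fRC)` and
#' `MSV = population SD(fRC)`.
#'
#' @param seq a [motion_sequence()] with level angles.
#' @param trim `"amplitude"` (default), `"time"`, or `"none"`.
#' @param phases `"both"` (default) analyses outward and return;
#'   `"outward"` restricts to the outward phase.
#' @param msv_denominator passed to [compute_msv()].
#' @return A `motion_share_result`: list with `msi`, `msv`, `frc`,
#'   `trim_mask`, `n_retained`, `params`.
#' @export
motion_share <- function(seq, trim = c("amplitude", "time", "none"),
                         phases = c("both", "outward"),
                         msv_denominator = "population") {
  stopifnot(inherits(seq, "motion_sequence"))
  trim <- match.arg(trim)
  phases <- match.arg(phases)
  mask <- if (trim == "none") rep(TRUE, length(seq$gross_deg))
          else trim_middle80(seq, basis = trim)
  if (phases == "outward") mask <- mask & seq$phase == "outward"
  if (sum(mask) < 2L) stop("fewer than 2 frames retained for analysis")
  prop <- to_proportional(seq, mask)
  msi <- compute_msi(prop$frc)
  msv <- compute_msv(prop$frc, msi, denominator = msv_denominator)
  structure(
    list(msi = msi, msv = msv, frc = prop$frc, trim_mask = mask,
         n_retained = prop$n_retained,
         params = list(trim = trim, phases = phases,
                       msv_denominator = msv_denominator)),
    class = "motion_share_result")
}

#' @export
print.motion_share_result <- function(x, ...) {
  cat("<motion_share_result>\n")
  cat(sprintf("  MSI = %.3f   MSV = %.3f   (N = %d retained frames)\n",
              x$msi, x$msv, x$n_retained))
  cat(sprintf("  trim = %s, phases = %s\n", x$params$trim, x$params$phases))
  invisible(x)
}
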