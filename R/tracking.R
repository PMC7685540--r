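#' First-image registration of vertebral templates
#'
#' Emulates the manual first-image registration step of a QF analysis: the
#' investigator marks the four corners of each vertebral body and outlines
#' it with a tracking template, and repeats the registration `n_repeats`
#' times.  Here the nominal corner landmarks come from a geometry fixture;
#' investigator placement variability is simulated by perturbing every
#' corner with isotropic Gaussian noise of SD `perturbation_sd` pixels
#' independently per repeat, and the repeats are combined by averaging each
#' corner.  Reference pose (centroid + orientation) and the template image
#' patch are then built from the averaged corners on the first frame.
#'
#' @param frame0 first image of the sequence (matrix in `[0, 1]`).
#' @param fixture a [vertebral_geometry()] (or a list with a `vertebrae`
#'   element of 4x2 corner matrices) supplying nominal corner landmarks.
#' @param n_repeats number of registration repeats to average (>= 1;
#'   the study protocol used 5).
#' @param perturbation_sd SD of the simulated corner placement error (px).
#' @param seed RNG seed for the perturbations.
#' @param outline_pad outward dilation of the body quadrilateral used as
#'   the tracking outline (px).
#' @param sample_pad extra margin around the outline from which template
#'   pixels are sampled (px); includes the informative edge region.
#' @return A `vertebral_templates` object: named list (one element per
#'   vertebra) of lists with `corners`, `centroid`, `orientation_deg`,
#'   `outline`, `patch_off` (n x 2 offsets from the centroid) and
#'   `patch_vals`.
#' @export
register_first_image <- function(frame0, fixture, n_repeats = 5L,
                                 perturbation_sd = 1, seed = 1L,
                                 outline_pad = 2, sample_pad = 3) {
  stopifnot(is.matrix(frame0), n_repeats >= 1L, perturbation_sd >= 0)
  vertebrae <- fixture$vertebrae
  if (is.null(vertebrae)) stop("fixture must supply a `vertebrae` corner list")
  bad <- vapply(vertebrae, function(m) is.null(dim(m)) || nrow(m) < 4L, logical(1))
  if (any(bad))
    stop("fewer than 4 corner landmarks for vertebra(e): ",
         paste(names(vertebrae)[bad], collapse = ", "))
  templates <- with_seed(seed, lapply(names(vertebrae), function(v) {
    nominal <- as.matrix(vertebrae[[v]])
    if (!is.null(colnames(nominal)) && all(c("x", "y") %in% colnames(nominal)))
      nominal <- nominal[, c("x", "y"), drop = FALSE]
    reps <- lapply(seq_len(n_repeats), function(r)
      nominal + matrix(rnorm(length(nominal), 0, perturbation_sd),
                       nrow(nominal), 2L))
    corners <- Reduce(`+`, reps) / n_repeats
    build_template(frame0, v, corners, outline_pad, sample_pad)
  }))
  names(templates) <- names(vertebrae)
  structure(templates, class = "vertebral_templates",
            n_repeats = n_repeats, perturbation_sd = perturbation_sd)
}

## Build one vertebra's template from (averaged) corners on frame 0.
build_template <- function(frame0, name, corners, outline_pad, sample_pad) {
  centroid <- colMeans(corners)
  ## orientation from the mean direction of the two horizontal edges
  e_top <- corners[2, ] - corners[1, ]
  e_bot <- corners[3, ] - corners[4, ]
  e <- (e_top + e_bot) / 2
  orientation <- atan2(e[2], e[1]) * 180 / pi
  outline <- sweep(sweep(corners, 2L, centroid), 1L,
                   1 + outline_pad / sqrt(rowSums(sweep(corners, 2L, centroid)^2)),
                   "*")
  outline <- sweep(outline, 2L, centroid, "+")
  ## sample every integer pixel within sample_pad of the outline quad
  x0 <- max(1L, floor(min(outline[, 1])) - ceiling(sample_pad))
  x1 <- min(ncol(frame0), ceiling(max(outline[, 1])) + ceiling(sample_pad))
  y0 <- max(1L, floor(min(outline[, 2])) - ceiling(sample_pad))
  y1 <- min(nrow(frame0), ceiling(max(outline[, 2])) + ceiling(sample_pad))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  keep <- signed_distance_convex(gx, gy, outline) <= sample_pad
  gx <- gx[keep]; gy <- gy[keep]
  list(name = name, corners = corners, centroid = centroid,
       orientation_deg = orientation, outline = outline,
       patch_off = cbind(x = gx - centroid[1], y = gy - centroid[2]),
       patch_vals = frame0[cbind(gy, gx)])
}

#' Tracking search configuration
#'
#' @param window_px half-width of the coarse translation search window
#'   around the previous frame's pose (px).
#' @param step_px coarse translation grid step (px).
#' @param rot_window_deg half-width of the rotation search (deg).
#' @param rot_step_deg coarse rotation grid step (deg).
#' @param fine_step_px,fine_step_deg fine grid steps around the coarse
#'   optimum; parabolic sub-grid refinement is applied on the fine grid.
#' @param threshold minimum peak normalized cross-correlation below which
#'   a frame is flagged as a tracking failure.
#' @return A list of class `track_search`.
#' @export
track_search_config <- function(window_px = 10, step_px = 2,
                                rot_window_deg = 3, rot_step_deg = 1,
                                fine_step_px = 0.5, fine_step_deg = 0.25,
                                threshold = 0.5) {
  structure(list(window_px = window_px, step_px = step_px,
                 rot_window_deg = rot_window_deg, rot_step_deg = rot_step_deg,
                 fine_step_px = fine_step_px, fine_step_deg = fine_step_deg,
                 threshold = threshold),
            class = "track_search")
}

## One NCC grid search: returns best pose (tx, ty, rot), its score, and the
## parabolic sub-grid refinement.  Grids are centred on `center` (length 3).
ncc_search <- function(image, tmpl, center, txs, tys, rots, refine = FALSE) {
  grid <- expand.grid(tx = txs, ty = tys, rot = rots, KEEP.OUT.ATTRS = FALSE)
  scores <- ncc_pose_scores(image, tmpl$patch_off[, 1], tmpl$patch_off[, 2],
                            tmpl$patch_vals, tmpl$centroid[1], tmpl$centroid[2],
                            center[1] + grid$tx, center[2] + grid$ty,
                            center[3] + grid$rot)
  valid <- !is.na(scores)
  if (!any(valid)) return(list(pose = center, score = NA_real_))
  best_score <- max(scores[valid])
  ## tie-break toward the smallest pose change from the previous frame
  cand <- which(valid & scores >= best_score - 1e-9)
  dist <- grid$tx[cand]^2 + grid$ty[cand]^2 + (0.5 * grid$rot[cand])^2
  b <- cand[which.min(dist)]
  pose <- center + as.numeric(grid[b, ])
  if (refine) {
    dims <- list(txs, tys, rots)
    idx <- c(match(grid$tx[b], txs), match(grid$ty[b], tys), match(grid$rot[b], rots))
    arr <- array(scores, dim = c(length(txs), length(tys), length(rots)))
    for (d in 1:3) {
      if (idx[d] <= 1L || idx[d] >= length(dims[[d]])) next
      i0 <- idx; im <- idx; ip <- idx
      im[d] <- idx[d] - 1L; ip[d] <- idx[d] + 1L
      s0 <- arr[i0[1], i0[2], i0[3]]
      sm <- arr[im[1], im[2], im[3]]
      sp <- arr[ip[1], ip[2], ip[3]]
      den <- sm - 2 * s0 + sp
      if (is.finite(den) && den < -1e-12) {
        delta <- 0.5 * (sm - sp) / den
        step <- dims[[d]][2] - dims[[d]][1]
        pose[d] <- pose[d] + max(-1, min(1, delta)) * step
      }
    }
  }
  list(pose = pose, score = best_score)
}

## Track one vertebra over a span of frames starting from `start_pose`.
track_vertebra_span <- function(frames, tmpl, frame_idx, start_pose, search) {
  out <- data.frame(frame = frame_idx, vertebra = tmpl$name,
                    tx = NA_real_, ty = NA_real_, rot_deg = NA_real_,
                    score = NA_real_, flag = FALSE)
  pose <- start_pose
  coarse_t <- seq(-search$window_px, search$window_px, by = search$step_px)
  coarse_r <- seq(-search$rot_window_deg, search$rot_window_deg,
                  by = search$rot_step_deg)
  fine_t <- seq(-search$step_px, search$step_px, by = search$fine_step_px)
  fine_r <- seq(-search$rot_step_deg, search$rot_step_deg,
                by = search$fine_step_deg)
  for (i in seq_along(frame_idx)) {
    img <- frames[[frame_idx[i]]]
    coarse <- ncc_search(img, tmpl, pose, coarse_t, coarse_t, coarse_r)
    fine <- ncc_search(img, tmpl, coarse$pose, fine_t, fine_t, fine_r,
                       refine = TRUE)
    ok <- is.finite(fine$score) && fine$score >= search$threshold
    if (ok) pose <- fine$pose   # failure: hold last good pose as the seed
    out$tx[i] <- fine$pose[1]; out$ty[i] <- fine$pose[2]
    out$rot_deg[i] <- fine$pose[3]
    out$score[i] <- fine$score
    out$flag[i] <- !ok
  }
  out
}

#' Track vertebral templates through an image sequence
#'
#' For every vertebra and frame, maximises the normalized cross-correlation
#' between the registered template patch and the image over a rigid pose
#' grid (translation and in-plane rotation) seeded at the previous frame's
#' pose, followed by a finer grid and parabolic sub-pixel/sub-degree
#' refinement.  Frames whose peak similarity falls below
#' `search$threshold` are flagged as tracking failures; their pose is held
#' at the last successful estimate so tracking can resume.
#'
#' @param iseq an `image_sequence` (or plain list of image matrices).
#' @param templates a `vertebral_templates` set from
#'   [register_first_image()].
#' @param search a [track_search_config()].
#' @return A `tracked_pose_series`: data.frame with columns `frame`,
#'   `vertebra`, `tx`, `ty`, `rot_deg` (pose change relative to the
#'   registered frame-0 pose), `score`, `flag`.  Frame times/phases are
#'   carried in attributes.
#' @export
track_sequence <- function(iseq, templates, search = track_search_config()) {
  frames <- if (inherits(iseq, "image_sequence")) iseq$frames else iseq
  if (length(frames) == 0L) stop("empty frame stack")
  stopifnot(inherits(templates, "vertebral_templates"))
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  for (tmpl in templates) {
    ext <- apply(abs(tmpl$patch_off), 2L, max)
    if (2 * ext[1] > w || 2 * ext[2] > h)
      stop("template for ", tmpl$name, " is larger than the frames")
  }
  res <- lapply(templates, function(tmpl) {
    first <- data.frame(frame = 1L, vertebra = tmpl$name, tx = 0, ty = 0,
                        rot_deg = 0, score = 1, flag = FALSE)
    if (length(frames) == 1L) return(first)
    rest <- track_vertebra_span(frames, tmpl, seq_along(frames)[-1L],
                                c(0, 0, 0), search)
    rbind(first, rest)
  })
  series <- do.call(rbind, res)
  rownames(series) <- NULL
  series <- series[order(series$frame, match(series$vertebra, .vert_names)), ]
  structure(series, class = c("tracked_pose_series", "data.frame"),
            frame_times = if (inherits(iseq, "image_sequence")) iseq$frame_times,
            phase = if (inherits(iseq, "image_sequence")) iseq$phase,
            search = search)
}

#' Re-track flagged tracking failures with a widened search
#'
#' Spans of frames flagged as failures are re-tracked with the search
#' window and rotation range widened by `widen`, re-seeded from the last
#' successful pose before each span.  Frames whose similarity still does
#' not reach the threshold remain flagged.
#'
#' @param series a `tracked_pose_series` from [track_sequence()].
#' @param iseq the image sequence the series was tracked on.
#' @param templates the template set used for tracking.
#' @param widen multiplicative widening of the search windows.
#' @return An updated `tracked_pose_series`.
#' @export
retrack_failures <- function(series, iseq, templates, widen = 2) {
  stopifnot(inherits(series, "tracked_pose_series"))
  if (!any(series$flag)) return(series)
  frames <- if (inherits(iseq, "image_sequence")) iseq$frames else iseq
  search <- attr(series, "search") %||% track_search_config()
  wide <- search
  wide$window_px <- search$window_px * widen
  wide$rot_window_deg <- search$rot_window_deg * widen
  for (v in unique(series$vertebra[series$flag])) {
    tmpl <- templates[[v]]
    rows <- which(series$vertebra == v)
    rows <- rows[order(series$frame[rows])]
    flagged <- rows[series$flag[rows]]
    ## contiguous flagged spans
    spans <- split(flagged, cumsum(c(1, diff(series$frame[flagged]) != 1)))
    for (sp in spans) {
      fr <- series$frame[sp]
      prev_rows <- rows[series$frame[rows] < fr[1] & !series$flag[rows]]
      seed_pose <- if (length(prev_rows)) {
        pr <- prev_rows[which.max(series$frame[prev_rows])]
        c(series$tx[pr], series$ty[pr], series$rot_deg[pr])
      } else c(0, 0, 0)
      redo <- track_vertebra_span(frames, tmpl, fr, seed_pose, wide)
      series$tx[sp] <- redo$tx; series$ty[sp] <- redo$ty
      series$rot_deg[sp] <- redo$rot_deg
      series$score[sp] <- redo$score; series$flag[sp] <- redo$flag
    }
  }
  series
}

#' Extract intervertebral angles from tracked poses
#'
#' Converts per-vertebra rotations (change from frame 0) into the four
#' intervertebral level angles — upper vertebra rotation minus lower
#' vertebra rotation — and the gross L2-S1 angle (L2 minus S1), in the
#' flexion-positive convention.  Refuses sequences with outstanding
#' tracking failure flags.
#'
#' @param series a `tracked_pose_series` without failure flags.
#' @return A [motion_sequence()].
#' @export
extract_intervertebral_angles <- function(series) {
  stopifnot(inherits(series, "tracked_pose_series"))
  if (any(series$flag)) {
    bad <- series[series$flag, c("frame", "vertebra")]
    stop("outstanding tracking failures at ",
         paste(sprintf("%s@frame%d", bad$vertebra, bad$frame), collapse = ", "),
         "; run retrack_failures() first")
  }
  rot <- matrix(NA_real_, length(unique(series$frame)), length(.vert_names),
                dimnames = list(NULL, .vert_names))
  for (v in .vert_names) {
    sv <- series[series$vertebra == v, ]
    rot[sv$frame, v] <- sv$rot_deg
  }
  levels <- rot[, 1:4, drop = FALSE] - rot[, 2:5, drop = FALSE]
  colnames(levels) <- .lvl_names
  gross <- rot[, "L2"] - rot[, "S1"]
  times <- attr(series, "frame_times") %||% (seq_len(nrow(rot)) - 1)
  motion_sequence(times, gross, levels, attr(series, "phase"),
                  meta = list(source = "tracking",
                              sign_convention = "flexion_positive"))
}
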