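## Signed distance (px) from points to a convex polygon: negative inside.
## pts: n x 2, poly: m x 2 ordered vertices.
signed_distance_convex <- function(px, py, poly) {
  m <- nrow(poly)
  ## polygon orientation via the shoelace sum so edge normals point outwards
  nx_ <- c(seq_len(m)[-1L], 1L)
  area2 <- sum(poly[, 1] * poly[nx_, 2] - poly[nx_, 1] * poly[, 2])
  orient <- if (area2 >= 0) 1 else -1
  d <- rep(-Inf, length(px))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]
    ey <- poly[j, 2] - poly[i, 2]
    len <- sqrt(ex^2 + ey^2)
    ## outward normal of edge i->j (y-down coordinates)
    nx <- orient * ey / len
    ny <- -orient * ex / len
    di <- (px - poly[i, 1]) * nx + (py - poly[i, 2]) * ny
    d <- pmax(d, di)
  }
  d
}

#' Render a motion sequence into a synthetic fluoroscopic image stack
#'
#' Draws the five vertebral bodies as soft-edged convex quadrilaterals,
#' rigidly moved frame by frame through the kinematic chain so that the
#' inter-body angles equal the sequence's intervertebral level angles
#' exactly.  A ground-truth pose table (centroid and rotation per vertebra
#' per frame) is emitted alongside the frames, which closes the loop for
#' tracking validation.
#'
#' @param seq a [motion_sequence()] with level angles.
#' @param geometry a [vertebral_geometry()].
#' @param noise_sd SD of additive Gaussian pixel noise (image units; 0 =
#'   noise free).
#' @param gradient if `TRUE`, adds a mild horizontal background intensity
#'   ramp emulating uneven exposure.
#' @param seed RNG seed for the pixel noise.
#' @return An object of class `image_sequence`: list with `frames` (list
#'   of height x width matrices in `[0, 1]`), `poses` (data.frame: frame,
#'   vertebra, cx, cy, rot_deg), `geometry`, `frame_times`, `phase`.
#' @export
render_frames <- function(seq, geometry = vertebral_geometry(),
                          noise_sd = 0, gradient = FALSE, seed = 1L) {
  stopifnot(inherits(seq, "motion_sequence"), inherits(geometry, "vertebral_geometry"))
  if (is.null(seq$level_deg))
    stop("sequence has no level angles; generate a subject first")
  h <- geometry$image_size[1]; w <- geometry$image_size[2]
  bg <- matrix(geometry$background, h, w)
  if (gradient)
    bg <- bg + 0.06 * matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
  n <- length(seq$frame_times)
  frames <- vector("list", n)
  poses <- vector("list", n)
  pad <- ceiling(3 * geometry$edge_width) + 1L
  for (f in seq_len(n)) {
    trs <- chain_transforms(geometry, seq$level_deg[f, ])
    canvas <- bg
    pose_f <- data.frame(frame = f, vertebra = .vert_names,
                         cx = NA_real_, cy = NA_real_, rot_deg = NA_real_)
    for (v in seq_along(geometry$vertebrae)) {
      corners <- apply_transform(trs[[v]], geometry$vertebrae[[v]])
      if (any(corners[, 1] < 1 + pad) || any(corners[, 1] > w - pad) ||
          any(corners[, 2] < 1 + pad) || any(corners[, 2] > h - pad))
        stop(sprintf("vertebra %s drawn outside image bounds at frame %d",
                     .vert_names[v], f))
      x0 <- floor(min(corners[, 1])) - pad; x1 <- ceiling(max(corners[, 1])) + pad
      y0 <- floor(min(corners[, 2])) - pad; y1 <- ceiling(max(corners[, 2])) + pad
      xs <- x0:x1; ys <- y0:y1
      grid_x <- rep(xs, each = length(ys))
      grid_y <- rep(ys, times = length(xs))
      d <- signed_distance_convex(grid_x, grid_y, corners)
      cov <- pmin(1, pmax(0, 0.5 - d / (2 * geometry$edge_width)))
      patch <- canvas[ys, xs]
      patch <- patch * (1 - cov) + geometry$intensity * cov
      canvas[ys, xs] <- patch
      ctr <- colMeans(corners)
      pose_f$cx[v] <- ctr[1]; pose_f$cy[v] <- ctr[2]
      pose_f$rot_deg[v] <- transform_angle(trs[[v]])
    }
    frames[[f]] <- canvas
    poses[[f]] <- pose_f
  }
  if (noise_sd > 0) {
    frames <- with_seed(seed, lapply(frames, function(fr) {
      pmin(pmax(fr + matrix(rnorm(h * w, 0, noise_sd), h, w), 0), 1)
    }))
  }
  structure(
    list(frames = frames, poses = do.call(rbind, poses), geometry = geometry,
         frame_times = seq$frame_times, phase = seq$phase,
         meta = list(noise_sd = noise_sd, gradient = gradient, seed = seed)),
    class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  cat(sprintf("<image_sequence> %d frames of %d x %d px\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' Write / read an image sequence as plain-text PGM frames
#'
#' Frames are stored as ASCII PGM (P2, 16-bit) files `frame_0001.pgm` ...
#' plus JSON sidecars: `poses.json` (ground-truth poses, if present),
#' `geometry.json` and `frames.json` (times and phases).  Plain-text PGM is
#' deliberately chosen over binary formats so fixtures remain inspectable
#' and diffable.
#'
#' @param iseq an `image_sequence`.
#' @param dir output directory (created if needed).
#' @return `write_image_sequence()` returns `dir` invisibly;
#'   `read_image_sequence()` returns an `image_sequence` (poses become a
#'   data.frame again; pixel values are quantised to 16 bits).
#' @export
write_image_sequence <- function(iseq, dir) {
  stopifnot(inherits(iseq, "image_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(iseq$frames))
    write_pgm(iseq$frames[[f]], file.path(dir, sprintf("frame_%04d.pgm", f)))
  if (!is.null(iseq$poses))
    jsonlite::write_json(iseq$poses, file.path(dir, "poses.json"), digits = NA)
  geo <- iseq$geometry
  jsonlite::write_json(
    list(image_size = geo$image_size,
         vertebrae = lapply(geo$vertebrae, function(m) unname(as.matrix(m))),
         disc_centers = unname(as.matrix(geo$disc_centers)),
         intensity = geo$intensity, background = geo$background,
         edge_width = geo$edge_width),
    file.path(dir, "geometry.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(frame_times = iseq$frame_times, phase = iseq$phase, meta = iseq$meta),
    file.path(dir, "frames.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_image_sequence
#' @export
read_image_sequence <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.pgm$", full.names = TRUE))
  if (length(files) == 0L) stop("no PGM frames found in ", dir)
  frames <- lapply(files, read_pgm)
  meta <- jsonlite::read_json(file.path(dir, "frames.json"), simplifyVector = TRUE)
  gj <- jsonlite::read_json(file.path(dir, "geometry.json"), simplifyVector = TRUE)
  geometry <- structure(
    list(image_size = as.integer(gj$image_size),
         vertebrae = lapply(gj$vertebrae, function(m) {
           m <- as.matrix(m); colnames(m) <- c("x", "y"); m
         }),
         disc_centers = {
           dc <- as.matrix(gj$disc_centers)
           dimnames(dc) <- list(.lvl_names, c("x", "y")); dc
         },
         intensity = gj$intensity, background = gj$background,
         edge_width = gj$edge_width),
    class = "vertebral_geometry")
  poses_path <- file.path(dir, "poses.json")
  poses <- if (file.exists(poses_path))
    jsonlite::read_json(poses_path, simplifyVector = TRUE) else NULL
  structure(
    list(frames = frames, poses = poses, geometry = geometry,
         frame_times = meta$frame_times, phase = meta$phase, meta = meta$meta),
    class = "image_sequence")
}

## ASCII PGM (P2) writer/reader, 16-bit depth.
write_pgm <- function(img, path, maxval = 65535L) {
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  ## one image row per line
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  hdr <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  w <- hdr[1]; h <- hdr[2]
  maxval <- as.integer(txt[3])
  vals <- as.numeric(unlist(strsplit(trimws(txt[-(1:3)]), "\\s+")))
  if (length(vals) != w * h) stop("corrupt PGM payload in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}
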