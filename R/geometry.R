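#' Vertebral geometry for synthetic frame rendering
#'
#' Defines five vertebral bodies (L2, L3, L4, L5, S1) as convex
#' quadrilaterals in image coordinates (origin top-left, x right, y down,
#' units pixels), stacked along the spine with the sacral base at the
#' bottom, plus the four disc centres about which the intervertebral
#' rotations act.  This is the neutral (frame 0) configuration; flexion is
#' modelled as a kinematic chain of planar rotations of each vertebra and
#' everything above it about the disc centre below it.
#'
#' @param image_size `c(height, width)` of the rendered frames in pixels.
#' @param body_w,body_h vertebral body width/height in pixels.
#' @param spacing centre-to-centre distance between adjacent bodies (px).
#' @param spine_x x coordinate of the neutral spine axis (px).
#' @param s1_y y coordinate of the S1 body centre (px).
#' @param intensity body fill intensity in `[0, 1]`.
#' @param background background intensity in `[0, 1]`.
#' @param edge_width softness of the body edge in pixels (the rendered
#'   edge profile is linear over roughly `2 * edge_width`); a non-zero
#'   value makes the image differentiable in pose, which sub-pixel
#'   tracking relies on.
#'
#' @return An object of class `vertebral_geometry`: a list with
#'   `vertebrae` (named list of 4x2 corner matrices, corner order
#'   top-left, top-right, bottom-right, bottom-left), `disc_centers`
#'   (4x2 matrix, one row per intervertebral level, cranial first) and the
#'   rendering parameters.
#' @export
vertebral_geometry <- function(image_size = c(360L, 360L),
                               body_w = 44, body_h = 28, spacing = 36,
                               spine_x = 150, s1_y = 300,
                               intensity = 0.85, background = 0.08,
                               edge_width = 1.5) {
  stopifnot(length(image_size) == 2L, all(image_size > 0),
            body_w > 0, body_h > 0, spacing > body_h / 2)
  centers_y <- s1_y - spacing * (4:0)      # L2 at top, S1 at bottom
  vertebrae <- lapply(seq_along(.vert_names), function(i) {
    cx <- spine_x; cy <- centers_y[i]
    m <- rbind(c(cx - body_w / 2, cy - body_h / 2),
               c(cx + body_w / 2, cy - body_h / 2),
               c(cx + body_w / 2, cy + body_h / 2),
               c(cx - body_w / 2, cy + body_h / 2))
    colnames(m) <- c("x", "y")
    m
  })
  names(vertebrae) <- .vert_names
  disc_centers <- cbind(x = rep(spine_x, 4L),
                        y = (centers_y[1:4] + centers_y[2:5]) / 2)
  rownames(disc_centers) <- .lvl_names
  structure(
    list(image_size = as.integer(image_size), vertebrae = vertebrae,
         disc_centers = disc_centers, intensity = intensity,
         background = background, edge_width = edge_width),
    class = "vertebral_geometry")
}

#' @export
print.vertebral_geometry <- function(x, ...) {
  cat("<vertebral_geometry>\n")
  cat(sprintf("  image %d x %d px, %d vertebral bodies (%s)\n",
              x$image_size[1], x$image_size[2], length(x$vertebrae),
              paste(names(x$vertebrae), collapse = ", ")))
  invisible(x)
}

## Per-frame rigid transforms of the kinematic chain.
## level_deg: numeric length-4 intervertebral angles (deg, flexion positive)
## Returns list of 5 transforms, each list(R = 2x2, t = length-2), mapping
## neutral coordinates to frame coordinates: x' = R %*% x + t.
chain_transforms <- function(geometry, level_deg) {
  stopifnot(length(level_deg) == 4L)
  transforms <- vector("list", 5L)
  transforms[[5L]] <- list(R = diag(2), t = c(0, 0))   # S1 static
  for (i in 4:1) {
    c_i <- as.numeric(geometry$disc_centers[i, ])
    R_i <- rot2(level_deg[i])
    t_i <- c_i - R_i %*% c_i
    below <- transforms[[i + 1L]]
    transforms[[i]] <- list(R = below$R %*% R_i,
                            t = as.numeric(below$R %*% t_i + below$t))
  }
  names(transforms) <- .vert_names
  transforms
}

apply_transform <- function(tr, pts) {
  ## pts: n x 2 matrix
  sweep(pts %*% t(tr$R), 2L, tr$t, "+")
}

## Rotation angle (deg) encoded by a 2x2 rotation matrix under the
## image-coordinate convention of rot2().
transform_angle <- function(tr) atan2(tr$R[2, 1], tr$R[1, 1]) * 180 / pi
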