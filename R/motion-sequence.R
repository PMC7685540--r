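#' Intervertebral motion sequence
#'
#' Container for one passive recumbent flexion examination: per-frame times,
#' the gross L2-S1 angle and (optionally) the four intervertebral level
#' angles L2-L3, L3-L4, L4-L5 and L5-S1.  All angles are stored in degrees
#' as *change from the starting position*, with lumbar flexion positive
#' (on the fluoroscopic image the absolute intervertebral angle decreases
#' in flexion; the sign convention is recorded in `meta$sign_convention`).
#'
#' @param frame_times numeric vector of frame times in seconds, starting at 0.
#' @param gross_deg gross L2-S1 angle per frame (degrees, change from start).
#' @param level_deg optional numeric matrix (frames x 4) of intervertebral
#'   angles with columns `l2l3`, `l3l4`, `l4l5`, `l5s1`.
#' @param phase character vector per frame, `"outward"` or `"return"`.
#' @param meta list of free-form metadata (simulation truth, provenance).
#'
#' @return An object of class `motion_sequence`.
#' @export
motion_sequence <- function(frame_times, gross_deg, level_deg = NULL,
                            phase = NULL, meta = list()) {
  n <- length(frame_times)
  if (length(gross_deg) != n)
    stop("`frame_times` and `gross_deg` must have the same length")
  if (!is.null(level_deg)) {
    level_deg <- as.matrix(level_deg)
    if (nrow(level_deg) != n)
      stop("`level_deg` must have one row per frame")
    if (ncol(level_deg) != 4L)
      stop("`level_deg` must have 4 columns (", paste(.lvl_names, collapse = ", "), ")")
    colnames(level_deg) <- .lvl_names
  }
  if (is.null(phase)) phase <- rep("outward", n)
  if (length(phase) != n) stop("`phase` must have one entry per frame")
  if (!all(phase %in% c("outward", "return")))
    stop("`phase` entries must be 'outward' or 'return'")
  if (abs(gross_deg[1L]) > 1e-9)
    stop("gross angle must be 0 at the first frame (change-from-start convention)")
  meta$sign_convention <- meta$sign_convention %||% "flexion_positive"
  structure(
    list(frame_times = as.numeric(frame_times),
         gross_deg = as.numeric(gross_deg),
         level_deg = level_deg,
         phase = as.character(phase),
         meta = meta),
    class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat("<motion_sequence>\n")
  cat(sprintf("  frames      : %d (%.3f s at ~%.1f Hz)\n",
              length(x$frame_times), max(x$frame_times),
              1 / stats::median(diff(x$frame_times))))
  cat(sprintf("  gross range : %.2f deg\n", max(x$gross_deg) - min(x$gross_deg)))
  cat(sprintf("  levels      : %s\n",
              if (is.null(x$level_deg)) "<none (gross-only skeleton)>"
              else paste(.lvl_names, collapse = ", ")))
  cat(sprintf("  phases      : %s\n", paste(unique(x$phase), collapse = " + ")))
  invisible(x)
}

#' @export
as.data.frame.motion_sequence <- function(x, ...) {
  df <- data.frame(time_s = x$frame_times, phase = x$phase,
                   gross_deg = x$gross_deg)
  if (!is.null(x$level_deg)) {
    lv <- as.data.frame(x$level_deg)
    names(lv) <- paste0(.lvl_names, "_deg")
    df <- cbind(df, lv)
  }
  df
}

#' Read and write motion sequence CSV files
#'
#' The on-disk format is a plain CSV with columns `time_s`, `phase`,
#' `gross_deg`, `l2l3_deg`, `l3l4_deg`, `l4l5_deg`, `l5s1_deg` and a leading
#' `#` comment line documenting units (degrees) and sign convention.
#' The round trip preserves values to better than 1e-12.
#'
#' @param seq a [motion_sequence()].
#' @param path file path.
#' @return `write_motion_sequence()` returns `path` invisibly;
#'   `read_motion_sequence()` returns a [motion_sequence()].
#' @export
write_motion_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "motion_sequence"))
  df <- as.data.frame(seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# angles in degrees, change from start, flexion positive (",
                    seq$meta$sign_convention, ")"), con)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_sequence
#' @export
read_motion_sequence <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "phase", "gross_deg")
  if (!all(need %in% names(df)))
    stop("not a motion sequence CSV: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lvl_cols <- paste0(.lvl_names, "_deg")
  lv <- if (all(lvl_cols %in% names(df))) as.matrix(df[lvl_cols]) else NULL
  if (!is.null(lv)) colnames(lv) <- .lvl_names
  motion_sequence(df$time_s, df$gross_deg, lv, df$phase,
                  meta = list(source = path))
}
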