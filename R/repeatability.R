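#' Single-measures two-way random-effects ICC
#'
#' Estimates the intraclass correlation of a complete subjects x raters
#' matrix under the two-way random-effects model (both subjects and raters
#' random), single measures.  The default `type = "agreement"` is ICC(2,1)
#' = ICC(A,1), which charges systematic rater differences to the error —
#' the appropriate form when SEM and MD are the quantities of interest;
#' `type = "consistency"` (ICC(C,1)) ignores rater offsets.
#'
#' With mean squares from the two-way ANOVA (`MS_S` subjects, `MS_R`
#' raters, `MS_E` residual; n subjects, k raters):
#' \deqn{ICC(A,1) = \frac{MS_S - MS_E}{MS_S + (k-1) MS_E + \frac{k}{n}(MS_R - MS_E)}}
#' The 95% confidence interval uses the F-based interval of McGraw & Wong
#' (1996) with a Satterthwaite approximation to the denominator degrees of
#' freedom (agreement form), or the exact F interval (consistency form).
#'
#' @param m numeric matrix, subjects in rows, raters/occasions in columns;
#'   complete (no `NA`), at least 2 x 2.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf confidence level (default 0.95).
#' @return A list of class `icc_result`: `icc`, `ci95` (`lower`, `upper`),
#'   `type`, `anova` (`ms_subjects`, `ms_raters`, `ms_error`, `n`, `k`,
#'   `pooled_sd`), `undefined` (`TRUE` when the matrix is constant and the
#'   ICC is undefined).
#' @export
icc_two_way_random_single <- function(m, type = c("agreement", "consistency"),
                                      conf = 0.95) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (anyNA(m)) stop("observation matrix must be complete (no NA)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_s <- ss_rows / (n - 1)
  ms_r <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  pooled_sd <- stats::sd(as.vector(m))
  anova <- list(ms_subjects = ms_s, ms_raters = ms_r, ms_error = ms_e,
                n = n, k = k, pooled_sd = pooled_sd)
  if (ss_total < 1e-24) {
    return(structure(list(icc = NA_real_,
                          ci95 = c(lower = NA_real_, upper = NA_real_),
                          type = type, anova = anova, undefined = TRUE),
                     class = "icc_result"))
  }
  alpha <- 1 - conf
  if (type == "agreement") {
    icc <- (ms_s - ms_e) / (ms_s + (k - 1) * ms_e + (k / n) * (ms_r - ms_e))
    ## McGraw & Wong F interval with Satterthwaite df
    r <- max(icc, 1e-12)   # df formula degenerates at icc <= 0
    a <- (k * r) / (n * (1 - r))
    b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    v <- (a * ms_r + b * ms_e)^2 /
      ((a * ms_r)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (ms_s - f_l * ms_e) /
      (f_l * (k * ms_r + (k * n - k - n) * ms_e) + n * ms_s)
    upper <- n * (f_u * ms_s - ms_e) /
      (k * ms_r + (k * n - k - n) * ms_e + n * f_u * ms_s)
  } else {
    icc <- (ms_s - ms_e) / (ms_s + (k - 1) * ms_e)
    fobs <- ms_s / ms_e
    f_l <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_u <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (f_l - 1) / (f_l + k - 1)
    upper <- (f_u - 1) / (f_u + k - 1)
  }
  structure(list(icc = icc, ci95 = c(lower = lower, upper = upper),
                 type = type, anova = anova, undefined = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$undefined) {
    cat("ICC undefined (constant observation matrix)\n")
  } else {
    cat(sprintf("ICC(%s,1) = %.2f, 95%% CI (%.2f, %.2f)  [%s]\n",
                if (x$type == "agreement") "2" else "C", x$icc,
                x$ci95["lower"], x$ci95["upper"], categorize_icc(x$icc)))
  }
  invisible(x)
}

#' Standard error of measurement from the two-way ANOVA
#'
#' The default `method = "anova"` takes the square root of the error
#' variance of the two-way random-effects ANOVA (`sqrt(MS_E)`); `method =
#' "sd_icc"` uses the classical `pooled_sd * sqrt(1 - ICC)` with the
#' pooled SD of all n x k readings about the grand mean.
#'
#' @param anova ANOVA component of an [icc_two_way_random_single()] result
#'   (or the full `icc_result`).
#' @param method `"anova"` (default) or `"sd_icc"`.
#' @param icc ICC estimate, required for `method = "sd_icc"` (taken from
#'   the `icc_result` when one is supplied).
#' @return SEM in biomarker units.
#' @export
sem_from_anova <- function(anova, method = c("anova", "sd_icc"), icc = NULL) {
  method <- match.arg(method)
  if (inherits(anova, "icc_result")) {
    icc <- icc %||% anova$icc
    anova <- anova$anova
  }
  if (method == "anova") {
    if (anova$ms_error < 0) stop("negative error mean square")
    sqrt(anova$ms_error)
  } else {
    if (is.null(icc)) stop("`icc` is required for method = 'sd_icc'")
    if (icc > 1) stop("icc > 1")
    anova$pooled_sd * sqrt(1 - icc)
  }
}

#' Minimal difference
#'
#' The smallest change between two readings that exceeds measurement error
#' with 95% confidence: `MD = SEM * 1.96 * sqrt(2)`.
#'
#' @param sem standard error of measurement (>= 0).
#' @return MD in biomarker units.
#' @export
minimal_difference <- function(sem) {
  stopifnot(all(sem >= 0))
  sem * 1.96 * sqrt(2)
}

#' Qualitative reliability category of an ICC
#'
#' Band lookup with inclusive upper edges: slight (0.11-0.40), fair
#' (0.41-0.60), moderate (0.61-0.80), substantial (0.81-1.00); estimates
#' below 0.11 (including negative ICCs) are `"below-slight"`.
#'
#' @param icc ICC estimate(s), each <= 1.
#' @return Character vector of categories.
#' @export
categorize_icc <- function(icc) {
  stopifnot(all(icc <= 1 + 1e-12, na.rm = TRUE))
  vapply(icc, function(x) {
    if (is.na(x)) NA_character_
    else if (x <= 0.40) { if (x < 0.11) "below-slight" else "slight" }
    else if (x <= 0.60) "fair"
    else if (x <= 0.80) "moderate"
    else "substantial"
  }, character(1L))
}

## One pairing's full repeatability analysis.
repeatability_result <- function(m, type = "agreement", sem_method = "anova") {
  fit <- icc_two_way_random_single(m, type = type)
  sem <- sem_from_anova(fit, method = sem_method)
  md <- minimal_difference(sem)
  grand <- mean(m)
  structure(
    list(icc = fit$icc, ci95 = fit$ci95,
         category = if (fit$undefined) NA_character_ else categorize_icc(fit$icc),
         sem = sem, sem_pct = 100 * sem / grand, md = md,
         anova = fit$anova, type = fit$type, undefined = fit$undefined,
         grand_mean = grand),
    class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("ICC %.2f (%.2f, %.2f) %s | SEM %.3f (%.0f%%) | MD %.3f\n",
              x$icc, x$ci95["lower"], x$ci95["upper"], x$category,
              x$sem, x$sem_pct, x$md))
  invisible(x)
}

#' Intra-/inter-investigator repeatability report
#'
#' Runs the full repeatability analysis for each biomarker and each
#' reading pairing: group descriptive statistics per reading set, ICC(2,1)
#' with 95% CI and qualitative category, SEM (also as percent of the
#' pairing's grand mean) and MD per pairing, and identity-line
#' scatterplots (one page per biomarker) when `outdir` is given.
#'
#' @param readings either a long data.frame with columns `subject`,
#'   `rater`, `biomarker`, `value`, or a named list of complete
#'   subjects x raters matrices (one per biomarker, rater ids as column
#'   names, subject ids as row names).
#' @param pairings named list of length-2 character vectors of rater ids,
#'   e.g. `list(intra = c("DT1", "DT2"), inter = c("AxB", "DT1"))`.
#' @param outdir optional directory for `scatterplots_<biomarker>.pdf`.
#' @param type,sem_method passed to the per-pairing analysis.
#' @return A `repeatability_report`: list with `group_stats` (data.frame),
#'   `results` (nested list biomarker -> pairing ->
#'   `repeatability_result`), `table` (flat data.frame, values rounded for
#'   reporting: ICC 2 dp, SEM/MD 3 dp), `plots` (paths).
#' @export
repeatability_report <- function(readings,
                                 pairings = list(intra = c("DT1", "DT2"),
                                                 inter = c("AxB", "DT1")),
                                 outdir = NULL, type = "agreement",
                                 sem_method = "anova") {
  mats <- readings_to_matrices(readings)
  for (p in pairings) {
    stopifnot(length(p) == 2L)
    for (bm in names(mats)) {
      missing_r <- setdiff(p, colnames(mats[[bm]]))
      if (length(missing_r))
        stop("rater(s) ", paste(missing_r, collapse = ", "),
             " not present in the ", bm, " readings")
    }
  }
  group_stats <- do.call(rbind, lapply(names(mats), function(bm) {
    m <- mats[[bm]]
    data.frame(biomarker = bm, rater = colnames(m),
               mean = colMeans(m), sd = apply(m, 2L, stats::sd),
               n = nrow(m), row.names = NULL)
  }))
  results <- lapply(mats, function(m) {
    lapply(pairings, function(p)
      repeatability_result(m[, p, drop = FALSE], type = type,
                           sem_method = sem_method))
  })
  table <- do.call(rbind, lapply(names(results), function(bm) {
    do.call(rbind, lapply(names(results[[bm]]), function(pr) {
      r <- results[[bm]][[pr]]
      data.frame(biomarker = bm, pairing = pr,
                 raters = paste(pairings[[pr]], collapse = " vs "),
                 icc = round(r$icc, 2L),
                 ci_lower = round(r$ci95[["lower"]], 2L),
                 ci_upper = round(r$ci95[["upper"]], 2L),
                 category = r$category,
                 sem = round(r$sem, 3L), sem_pct = round(r$sem_pct),
                 md = round(r$md, 3L), row.names = NULL)
    }))
  }))
  plots <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (bm in names(mats))
      plots <- c(plots, plot_pairings(mats[[bm]], results[[bm]], pairings,
                                      bm, outdir))
  }
  structure(list(group_stats = group_stats, results = results,
                 table = table, plots = plots),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat("Group descriptive statistics:\n")
  print(x$group_stats, digits = 2)
  cat("\nRepeatability:\n")
  print(x$table)
  invisible(x)
}

readings_to_matrices <- function(readings) {
  if (is.data.frame(readings)) {
    need <- c("subject", "rater", "biomarker", "value")
    if (!all(need %in% names(readings)))
      stop("long-format readings need columns ", paste(need, collapse = ", "))
    mats <- lapply(split(readings, readings$biomarker), function(d) {
      m <- tapply(d$value, list(d$subject, d$rater), identity)
      storage.mode(m) <- "double"
      m
    })
  } else if (is.list(readings)) {
    mats <- lapply(readings, as.matrix)
    if (is.null(names(mats))) stop("list of reading matrices must be named")
  } else stop("`readings` must be a data.frame or a named list of matrices")
  for (bm in names(mats)) {
    m <- mats[[bm]]
    if (anyNA(m))
      stop("incomplete readings for ", bm,
           ": subject sets differ between raters")
  }
  mats
}

plot_pairings <- function(m, results, pairings, biomarker, outdir) {
  path <- file.path(outdir, sprintf("scatterplots_%s.pdf", biomarker))
  grDevices::pdf(path, width = 4 * length(pairings), height = 4)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(pairings)), pty = "s")
  for (pr in names(pairings)) {
    p <- pairings[[pr]]
    r <- results[[pr]]
    lim <- range(m[, p])
    graphics::plot(m[, p[1]], m[, p[2]], xlim = lim, ylim = lim,
                   xlab = p[1], ylab = p[2],
                   main = sprintf("%s, %s\nICC %.2f (%.2f, %.2f)", biomarker,
                                  pr, r$icc, r$ci95[1], r$ci95[2]),
                   pch = 19, col = "grey30", cex = 0.8)
    graphics::abline(0, 1, lty = 2)
  }
  path
}
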