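# Method-comparison and reliability statistics for paired joint-angle
# measurements: Bland-Altman limits of agreement with proportional-bias
# testing, ICC(2,1) (two-way random effects, absolute agreement, single
# measurement) with McGraw-Wong confidence limits, SEM and MDC.
#
# Conventions used throughout (matching the clinical-reporting practice
# this battery mirrors):
#   LoA  = bias +/- 1.96 * SD(differences)        (z, not a t quantile)
#   SEM  = SD * sqrt(1 - ICC)
#   MDC  = SEM * sqrt(2) * 1.96
# The bias CI uses the t quantile on n-1 df (more conservative than z).

#' Limits of agreement from the difference moments
#'
#' @param mean_diff Mean of the paired differences (degrees).
#' @param sd_diff Standard deviation of the differences (degrees, >= 0).
#' @return Named numeric vector `c(lower, upper)` =
#'   `mean_diff -/+ 1.96 * sd_diff`.
#' @examples
#' loa_from_moments(0.76, 1.25)   # c(-1.69, 3.21)
#' @export
loa_from_moments <- function(mean_diff, sd_diff) {
  if (any(sd_diff < 0)) stop("sd_diff must be >= 0", call. = FALSE)
  c(lower = mean_diff - 1.96 * sd_diff, upper = mean_diff + 1.96 * sd_diff)
}

#' Bland-Altman agreement analysis
#'
#' Summarizes paired measurements from two tools by the mean difference
#' (bias), the SD of differences (n-1 denominator), the 95 per cent limits
#' of agreement `bias +/- 1.96 SD`, a t-based CI for the bias, and a
#' proportional-bias test: the least-squares slope of the differences on
#' the pair means, with a two-sided t-test on the slope.
#'
#' @param m1,m2 Numeric vectors of paired measurements (tool 1, tool 2),
#'   or `m1` a two-column matrix/data frame with `m2` missing.
#' @param conf Confidence level for the bias CI (default 0.95).
#' @return Object of class `bland_altman` with elements `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `bias_ci_low`, `bias_ci_high`,
#'   `prop_bias_slope`, `prop_bias_p`, plus the differences and means for
#'   plotting.
#' @export
bland_altman <- function(m1, m2 = NULL, conf = 0.95) {
  if (is.null(m2)) {
    m1 <- as.matrix(m1)
    if (ncol(m1) != 2) stop("need two measurement columns", call. = FALSE)
    m2 <- m1[, 2]; m1 <- m1[, 1]
  }
  if (length(m1) != length(m2)) stop("m1 and m2 must have equal length", call. = FALSE)
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  n <- length(m1)
  if (n < 3) stop("insufficient data: need at least 3 complete pairs", call. = FALSE)

  d <- m1 - m2
  means <- (m1 + m2) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa <- loa_from_moments(bias, sd_diff)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se <- sd_diff / sqrt(n)

  if (stats::var(means) > 0 && sd_diff > 0) {
    fit <- stats::lm(d ~ means)
    cf <- summary(fit)$coefficients
    slope <- cf["means", "Estimate"]
    slope_p <- cf["means", "Pr(>|t|)"]
  } else {
    slope <- 0
    slope_p <- NA_real_
  }

  structure(
    list(n = n, bias = bias, sd_diff = sd_diff,
         loa_low = unname(loa["lower"]), loa_high = unname(loa["upper"]),
         bias_ci_low = bias - tq * se, bias_ci_high = bias + tq * se,
         prop_bias_slope = slope, prop_bias_p = slope_p,
         conf = conf, differences = d, means = means),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 2, ...) {
  cat("Bland-Altman agreement (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  bias: %.*f (SD %.*f; %d%% CI %.*f to %.*f)\n",
              digits, x$bias, digits, x$sd_diff, round(100 * x$conf),
              digits, x$bias_ci_low, digits, x$bias_ci_high))
  cat(sprintf("  95%% limits of agreement: %.*f to %.*f\n",
              digits, x$loa_low, digits, x$loa_high))
  if (!is.na(x$prop_bias_p)) {
    cat(sprintf("  proportional bias: slope %.*f (p = %.3g)%s\n",
                max(digits, 3), x$prop_bias_slope, x$prop_bias_p,
                if (x$prop_bias_p < 0.05) " [flagged]" else ""))
  }
  invisible(x)
}

#' @export
summary.bland_altman <- function(object, ...) {
  print(object, ...)
  frac_in <- mean(object$differences >= object$loa_low &
                    object$differences <= object$loa_high)
  cat(sprintf("  differences within LoA: %.1f%%\n", 100 * frac_in))
  invisible(object)
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias (solid), limits of
#' agreement (dashed) and, when estimable, the proportional-bias
#' regression line (dotted).
#'
#' @param x A [bland_altman()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of the two tools (deg)",
                 ylab = "Difference, tool 1 - tool 2 (deg)", ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  if (!is.na(x$prop_bias_p) && stats::var(x$means) > 0) {
    graphics::abline(stats::lm(x$differences ~ x$means), lty = 3)
  }
  invisible(x)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Decomposes an `n x k` matrix (subjects x raters/tools) by two-way ANOVA
#' into between-subject (`MSR`), between-rater (`MSC`) and residual (`MSE`)
#' mean squares and reports
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with the McGraw-Wong 95 per cent confidence interval for the
#' absolute-agreement single-measure case, and the test
#' `F = MSR / MSE` on `(n-1, (n-1)(k-1))` degrees of freedom with a
#' one-sided p-value.
#'
#' @param x Numeric matrix or data frame, `n >= 3` subjects in rows,
#'   `k >= 2` raters in columns, no missing cells (exclude incomplete
#'   observations upstream).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `icc21` with elements `icc`, `ci_low`, `ci_high`,
#'   `f`, `df1`, `df2`, `p`, `msr`, `msc`, `mse`, `n_subjects`, `k_raters`.
#' @export
icc21 <- function(x, conf = 0.95) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  if (anyNA(x)) stop("incomplete matrix: remove observations with missing cells",
                     call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (k < 2) stop("need at least 2 raters", call. = FALSE)

  grand <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  resid <- x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  df2 <- (n - 1) * (k - 1)
  mse <- sum(resid^2) / df2

  if (msr == 0 && msc == 0 && mse == 0) {
    stop("undefined ICC: matrix has zero total variance", call. = FALSE)
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  df1 <- n - 1
  fstat <- if (mse > 0) msr / mse else Inf
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)

  alpha <- 1 - conf
  if (mse > 0 && icc < 1) {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / df2)
    fl <- stats::qf(1 - alpha / 2, df1, v)
    fu <- stats::qf(1 - alpha / 2, v, df1)
    ci_low <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    ci_low <- icc; ci_high <- icc
  }

  structure(
    list(icc = icc, ci_low = ci_low, ci_high = ci_high, conf = conf,
         f = fstat, df1 = df1, df2 = df2, p = p,
         msr = msr, msc = msc, mse = mse,
         n_subjects = n, k_raters = k),
    class = "icc21")
}

#' @export
print.icc21 <- function(x, digits = 3, ...) {
  cat("ICC(2,1), two-way random effects, absolute agreement, single measure\n")
  cat(sprintf("  ICC = %.*f (%d%% CI %.*f to %.*f) [%s]\n",
              digits, x$icc, round(100 * x$conf),
              digits, x$ci_low, digits, x$ci_high, interpret_icc(x$icc)))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g\n", x$df1, x$df2, x$f, x$p))
  cat(sprintf("  subjects: %d  raters: %d\n", x$n_subjects, x$k_raters))
  invisible(x)
}

#' Standard error of measurement
#'
#' `SEM = sd * sqrt(1 - icc)`: the measurement noise attached to a single
#' observation given the score spread `sd` and reliability `icc`.
#'
#' @param sd Standard deviation of the scores (degrees, >= 0). The choice
#'   of SD (pooled across repetitions and tools, or per-tool) is the
#'   caller's; report functions echo the SD used.
#' @param icc Reliability coefficient (<= 1).
#' @return SEM in degrees.
#' @export
sem_from <- function(sd, icc) {
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(icc > 1)) stop("icc must be <= 1", call. = FALSE)
  sd * sqrt(1 - icc)
}

#' Minimum detectable change
#'
#' `MDC = SEM * sqrt(2) * 1.96`: the smallest change exceeding measurement
#' error with 95 per cent confidence.
#'
#' @param sem Standard error of measurement (degrees, >= 0).
#' @return MDC in degrees.
#' @examples
#' mdc_from(11.78)  # 32.65
#' @export
mdc_from <- function(sem) {
  if (any(sem < 0)) stop("sem must be >= 0", call. = FALSE)
  sem * sqrt(2) * 1.96
}

#' Qualitative ICC interpretation band
#'
#' Bands: `[0.81, 1.0]` excellent; `[0.61, 0.80]` good; `[0.41, 0.60]`
#' moderate; `[0.21, 0.40]` fair; below 0.20 poor. The printed band edges
#' leave small gaps (e.g. 0.805); gaps are assigned to the lower band, so
#' the implemented rule is: excellent iff `icc >= 0.81`, good iff
#' `icc >= 0.61`, and so on.
#'
#' @param icc Numeric vector of ICC estimates (<= 1).
#' @return Character vector of band labels.
#' @export
interpret_icc <- function(icc) {
  if (any(icc > 1)) stop("icc must be <= 1", call. = FALSE)
  ifelse(icc >= 0.81, "excellent",
         ifelse(icc >= 0.61, "good",
                ifelse(icc >= 0.41, "moderate",
                       ifelse(icc >= 0.21, "fair", "poor"))))
}

#' Test-retest reliability from a repetition matrix
#'
#' Treats the `k` repeated measures of each subject as the "raters" of a
#' two-way design, computes [icc21()], then SEM and MDC. By default the SD
#' entering the SEM is the pooled SD of all measurements in the matrix.
#'
#' @param x `n x k` matrix: subjects in rows, repetitions in columns.
#' @param sd_used SD entering `SEM = sd * sqrt(1 - ICC)`; defaults to the
#'   SD of all cells pooled.
#' @param conf Confidence level for the ICC CI.
#' @return Object of class `reliability` with `icc` (the full [icc21()]
#'   fit), `sem`, `mdc`, `sd_used`.
#' @export
reliability <- function(x, sd_used = NULL, conf = 0.95) {
  fit <- icc21(x, conf = conf)
  if (is.null(sd_used)) sd_used <- stats::sd(as.numeric(as.matrix(x)))
  sem <- sem_from(sd_used, fit$icc)
  structure(list(icc = fit, sem = sem, mdc = mdc_from(sem),
                 sd_used = sd_used),
            class = "reliability")
}

#' @export
print.reliability <- function(x, digits = 2, ...) {
  cat(sprintf("Test-retest reliability: ICC = %.*f [%s], SEM = %.*f, MDC = %.*f (SD used: %.*f)\n",
              digits, x$icc$icc, interpret_icc(x$icc$icc),
              digits, x$sem, digits, x$mdc, digits, x$sd_used))
  invisible(x)
}

# ---- grouped reports ------------------------------------------------------

#' Between-tool agreement report over grouped paired measurements
#'
#' Takes long-format paired measurements (two tools rating the same
#' observations), groups them by setting x side x task x joint, and emits
#' one row per group with the full battery: n, bias (SD; CI), limits of
#' agreement, ICC(2,1) with CI, F test with df, p, interpretation band,
#' proportional-bias slope and p, and SEM/MDC. Groups failing the
#' preconditions (fewer than 3 complete pairs) are reported as skipped with
#' the reason in `note`, never silently dropped. Full precision is
#' retained; the print method rounds to 2 decimals for display.
#'
#' @param df Data frame with columns `participant`, `setting`, `task`,
#'   `joint`, `side`, `rep`, `tool`, `angle_deg` (long; exactly two tools).
#' @param sd_method SD entering SEM/MDC: `"pooled"` (all measurements in
#'   the group, both tools; default), `"tool1"`, or `"tool2"`.
#' @param conf Confidence level.
#' @return Data frame of class `agreement_report`.
#' @export
agreement_report <- function(df, sd_method = c("pooled", "tool1", "tool2"),
                             conf = 0.95) {
  sd_method <- match.arg(sd_method)
  need <- c("participant", "setting", "task", "joint", "side", "rep",
            "tool", "angle_deg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tools <- sort(unique(df$tool))
  if (length(tools) != 2) {
    stop("exactly two tools are required; found: ",
         paste(tools, collapse = ", "), call. = FALSE)
  }
  groups <- unique(df[, c("setting", "side", "task", "joint")])
  groups <- groups[order(groups$setting, groups$side, groups$task,
                         groups$joint), ]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- df[df$setting == g$setting & df$side == g$side &
                df$task == g$task & df$joint == g$joint, ]
    wide <- stats::reshape(
      sub[, c("participant", "rep", "tool", "angle_deg")],
      idvar = c("participant", "rep"), timevar = "tool",
      direction = "wide")
    v1 <- wide[[paste0("angle_deg.", tools[1])]]
    v2 <- wide[[paste0("angle_deg.", tools[2])]]
    complete <- is.finite(v1) & is.finite(v2)
    n_excluded <- sum(!complete)
    v1 <- v1[complete]; v2 <- v2[complete]
    base <- data.frame(setting = g$setting, side = g$side, task = g$task,
                       joint = g$joint, n = length(v1),
                       n_excluded = n_excluded, stringsAsFactors = FALSE)
    if (length(v1) < 3) {
      return(cbind(base, data.frame(
        bias = NA_real_, sd_diff = NA_real_, bias_ci_low = NA_real_,
        bias_ci_high = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
        icc = NA_real_, icc_ci_low = NA_real_, icc_ci_high = NA_real_,
        f = NA_real_, df1 = NA_integer_, df2 = NA_integer_, p = NA_real_,
        band = NA_character_, prop_bias_slope = NA_real_,
        prop_bias_p = NA_real_, sd_used = NA_real_, sem = NA_real_,
        mdc = NA_real_, note = "skipped: insufficient data (n < 3)")))
    }
    ba <- bland_altman(v1, v2, conf = conf)
    ic <- icc21(cbind(v1, v2), conf = conf)
    sd_used <- switch(sd_method,
                      pooled = stats::sd(c(v1, v2)),
                      tool1 = stats::sd(v1),
                      tool2 = stats::sd(v2))
    sem <- sem_from(sd_used, ic$icc)
    cbind(base, data.frame(
      bias = ba$bias, sd_diff = ba$sd_diff,
      bias_ci_low = ba$bias_ci_low, bias_ci_high = ba$bias_ci_high,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
      f = ic$f, df1 = ic$df1, df2 = ic$df2, p = ic$p,
      band = interpret_icc(ic$icc),
      prop_bias_slope = ba$prop_bias_slope, prop_bias_p = ba$prop_bias_p,
      sd_used = sd_used, sem = sem, mdc = mdc_from(sem),
      note = ""))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tools") <- tools
  attr(out, "sd_method") <- sd_method
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' Test-retest reliability report over grouped repeated measurements
#'
#' Groups long-format measurements of a single tool by setting x side x
#' task x joint, pivots each group to a participants x repetitions matrix,
#' and reports ICC(2,1) across repetitions together with SEM and MDC
#' (SD pooled over all of the group's measurements).
#'
#' @param df Data frame with columns `participant`, `setting`, `task`,
#'   `joint`, `side`, `rep`, `tool`, `angle_deg`.
#' @param tool Which tool's measurements to use (default: the first).
#' @param conf Confidence level.
#' @return Data frame of class `reliability_report` with one row per group:
#'   n participants, k repetitions, icc, icc CI, sem, mdc, sd_used, note.
#' @export
reliability_report <- function(df, tool = NULL, conf = 0.95) {
  if (is.null(tool)) tool <- sort(unique(df$tool))[1]
  df <- df[df$tool == tool, ]
  groups <- unique(df[, c("setting", "side", "task", "joint")])
  groups <- groups[order(groups$setting, groups$side, groups$task,
                         groups$joint), ]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- df[df$setting == g$setting & df$side == g$side &
                df$task == g$task & df$joint == g$joint, ]
    wide <- stats::reshape(sub[, c("participant", "rep", "angle_deg")],
                           idvar = "participant", timevar = "rep",
                           direction = "wide")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    complete <- stats::complete.cases(mat)
    mat <- mat[complete, , drop = FALSE]
    base <- data.frame(setting = g$setting, side = g$side, task = g$task,
                       joint = g$joint, n = nrow(mat), k = ncol(mat),
                       stringsAsFactors = FALSE)
    if (nrow(mat) < 3 || ncol(mat) < 2) {
      return(cbind(base, data.frame(
        icc = NA_real_, icc_ci_low = NA_real_, icc_ci_high = NA_real_,
        band = NA_character_, sd_used = NA_real_, sem = NA_real_,
        mdc = NA_real_, note = "skipped: insufficient data")))
    }
    rel <- reliability(mat, conf = conf)
    cbind(base, data.frame(
      icc = rel$icc$icc, icc_ci_low = rel$icc$ci_low,
      icc_ci_high = rel$icc$ci_high, band = interpret_icc(rel$icc$icc),
      sd_used = rel$sd_used, sem = rel$sem, mdc = rel$mdc, note = ""))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tool") <- tool
  class(out) <- c("reliability_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, digits = 2, ...) {
  cat("Between-tool agreement report (tools: ",
      paste(attr(x, "tools"), collapse = " vs "), ")\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.reliability_report <- function(x, digits = 2, ...) {
  cat("Test-retest reliability report (tool: ", attr(x, "tool"), ")\n",
      sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write an agreement or reliability report to CSV and JSON
#'
#' CSV and JSON carry full precision; rounding is a display concern only.
#'
#' @param report An [agreement_report()] or [reliability_report()].
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the paths written.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  written <- list()
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
    written$csv <- csv_path
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(report), json_path,
                         auto_unbox = TRUE, digits = NA, na = "null")
    written$json <- json_path
  }
  invisible(written)
}
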