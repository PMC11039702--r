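# The IMBT <-> DOU transfer function.
#
# The calibration is an ordinary least-squares fit of log10(DOU) on IMBT:
#
#     log10(DOU) = intercept + slope * IMBT
#
# fitted in that direction (not inverse regression). DOU is diffusive
# oxygen uptake across the sediment-water interface in umol m-2 d-1. The
# shipped constant model carries the published coefficients (slope 1.5,
# intercept 2.1, r 0.88, RMSE 400 umol m-2 d-1 on back-transformed
# predictions) and a default applicable range of 100-2000 umol m-2 d-1,
# the range over which the calibration data were observed.

.new_dou_calibration <- function(slope, intercept, r = NA_real_,
                                 p.value = NA_real_, rmse_log = NA_real_,
                                 rmse_linear = NA_real_, n = NA_integer_,
                                 range = c(100, 2000), lm = NULL,
                                 data = NULL, published = FALSE) {
  structure(list(slope = slope, intercept = intercept, r = r,
                 p.value = p.value, rmse_log = rmse_log,
                 rmse_linear = rmse_linear, n = n, range = range,
                 lm = lm, data = data, published = published),
            class = "dou_calibration")
}

#' Fit the IMBT-DOU transfer function
#'
#' Ordinary least squares of `log10(dou)` on `imbt`. Reports the Pearson
#' correlation between IMBT and log10(DOU) with its two-sided t-test
#' p-value, the root-mean-square residual in log10 space (`rmse_log`) and
#' the RMSE of the back-transformed predictions in linear units
#' (`rmse_linear`, umol m-2 d-1).
#'
#' @param imbt numeric vector of IMBT values (see [compute_imbt()]).
#' @param dou numeric vector of diffusive oxygen uptake, umol m-2 d-1;
#'   must be positive.
#' @param range applicable DOU interval; predictions outside it are
#'   flagged as extrapolation. Default `c(100, 2000)`, the observed
#'   deep-sea trench range; deep-sea settings more broadly span about
#'   50-4000.
#' @return An object of class `dou_calibration` with components `slope`,
#'   `intercept`, `r`, `p.value`, `rmse_log`, `rmse_linear`, `n`, `range`,
#'   the underlying `lm` fit and the fitting `data`. Methods: [print],
#'   [summary], [coef], [predict][predict.dou_calibration], [plot],
#'   [residuals], [simulate], [confint].
#' @seealso [imbt_dou_calibration()] for the shipped published model;
#'   [predict_dou()], [invert_dou_to_fraction()], [sensitivity_curve()].
#' @export
fit_dou_calibration <- function(imbt, dou, range = c(100, 2000)) {
  ok <- stats::complete.cases(imbt, dou)
  imbt <- as.numeric(imbt)[ok]
  dou <- as.numeric(dou)[ok]
  n <- length(imbt)
  if (n < 3) stop("need at least 3 complete (imbt, dou) pairs", call. = FALSE)
  if (any(dou <= 0)) stop("dou must be positive", call. = FALSE)
  if (stats::sd(imbt) == 0) {
    stop("zero variance in imbt: calibration line not identifiable",
         call. = FALSE)
  }
  y <- log10(dou)
  d <- data.frame(imbt = imbt, y = y)
  fit <- stats::lm(y ~ imbt, data = d)
  ct <- stats::cor.test(imbt, y, alternative = "two.sided")
  res <- stats::residuals(fit)
  rmse_log <- sqrt(mean(res^2))
  rmse_linear <- sqrt(mean((10^stats::fitted(fit) - dou)^2))
  .new_dou_calibration(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = unname(ct$estimate), p.value = ct$p.value,
    rmse_log = rmse_log, rmse_linear = rmse_linear, n = n,
    range = range, lm = fit, data = data.frame(imbt = imbt, dou = dou)
  )
}

#' The published IMBT-DOU calibration
#'
#' The shipped constant transfer function
#' `log10(DOU) = 1.5 * IMBT + 2.1` (r = 0.88, RMSE = 400 umol m-2 d-1 on
#' back-transformed predictions), applicable over DOU 100-2000
#' umol m-2 d-1 by default. The log-space residual RMSE was not reported
#' for this model, so `rmse_log` is `NA` and symmetric-in-log prediction
#' bands are unavailable from it; point predictions, inversion and
#' sensitivity analysis are unaffected.
#'
#' @param range applicable DOU interval (default `c(100, 2000)`; the
#'   deep-sea envelope `c(50, 4000)` is a documented extension).
#' @return A `dou_calibration` object.
#' @examples
#' predict(imbt_dou_calibration(), imbt = 0)  # 10^2.1 ~ 126 umol m-2 d-1
#' @export
imbt_dou_calibration <- function(range = c(100, 2000)) {
  .new_dou_calibration(slope = 1.5, intercept = 2.1, r = 0.88,
                       rmse_linear = 400, range = range, published = TRUE)
}

#' @export
coef.dou_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.dou_calibration <- function(x, digits = 4, ...) {
  cat("IMBT-DOU transfer function",
      if (isTRUE(x$published)) "(published coefficients)" else "", "\n")
  cat(sprintf("  log10(DOU) = %s + %s * IMBT\n",
              format(x$intercept, digits = digits),
              format(x$slope, digits = digits)))
  cat(sprintf("  r = %s, n = %s, RMSE = %s umol m-2 d-1%s\n",
              format(x$r, digits = digits),
              ifelse(is.na(x$n), "NA", x$n),
              format(x$rmse_linear, digits = digits),
              if (is.na(x$rmse_log)) "" else
                sprintf(" (%.4f log10 units)", x$rmse_log)))
  cat(sprintf("  applicable DOU range: %g-%g umol m-2 d-1\n",
              x$range[1], x$range[2]))
  invisible(x)
}

#' @export
summary.dou_calibration <- function(object, ...) {
  structure(list(model = object,
                 lm_summary = if (!is.null(object$lm))
                   summary(object$lm) else NULL),
            class = "summary.dou_calibration")
}

#' @export
print.summary.dou_calibration <- function(x, ...) {
  print(x$model)
  if (!is.null(x$lm_summary)) {
    cat("\nOLS detail (log10(DOU) ~ IMBT):\n")
    stats::printCoefmat(x$lm_summary$coefficients)
    cat(sprintf("two-sided t-test p-value for r: %.3g\n", x$model$p.value))
  }
  invisible(x)
}

#' @export
residuals.dou_calibration <- function(object, ...) {
  if (is.null(object$lm)) {
    stop("published constant model has no fitting data", call. = FALSE)
  }
  stats::residuals(object$lm)
}

#' @export
confint.dou_calibration <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$lm)) {
    stop("published constant model has no fitting data", call. = FALSE)
  }
  ci <- stats::confint(object$lm, level = level)
  rownames(ci) <- c("intercept", "slope")
  ci
}

#' Predict DOU from IMBT
#'
#' Forward application of the transfer function:
#' `DOU = 10^(intercept + slope * IMBT)`. Uncertainty bands are symmetric
#' in log space by default (back-transformed +/- 1 `rmse_log`); a full
#' regression prediction interval is available for fitted models.
#'
#' @param object a `dou_calibration`.
#' @param imbt numeric vector of IMBT values; `NA` (undefined IMBT)
#'   propagates to an `NA` prediction.
#' @param interval `"none"` (default), `"rmse"` (+/- 1 residual RMSE in
#'   log space) or `"prediction"` (regression prediction interval at
#'   `level`; requires a fitted model).
#' @param level confidence level for `interval = "prediction"`.
#' @param ... unused.
#' @return A data frame with columns `imbt`, `dou` (umol m-2 d-1),
#'   optionally `lwr`/`upr`, and `extrapolated` (TRUE where the estimate
#'   leaves the model's applicable range).
#' @export
predict.dou_calibration <- function(object, imbt,
                                    interval = c("none", "rmse", "prediction"),
                                    level = 0.95, ...) {
  interval <- match.arg(interval)
  imbt <- as.numeric(imbt)
  logd <- object$intercept + object$slope * imbt
  out <- data.frame(imbt = imbt, dou = 10^logd)
  if (interval == "rmse") {
    if (is.na(object$rmse_log)) {
      warning("rmse_log unavailable for this model; band is NA", call. = FALSE)
    }
    out$lwr <- 10^(logd - object$rmse_log)
    out$upr <- 10^(logd + object$rmse_log)
  } else if (interval == "prediction") {
    if (is.null(object$lm)) {
      stop("prediction intervals require a fitted model", call. = FALSE)
    }
    pi <- stats::predict(object$lm, newdata = data.frame(imbt = imbt),
                         interval = "prediction", level = level)
    out$lwr <- 10^pi[, "lwr"]
    out$upr <- 10^pi[, "upr"]
  }
  out$extrapolated <- !is.na(out$dou) &
    (out$dou < object$range[1] | out$dou > object$range[2])
  out
}

#' @rdname predict.dou_calibration
#' @param model a `dou_calibration` (default: the published model).
#' @export
predict_dou <- function(imbt, model = imbt_dou_calibration(), ...) {
  predict(model, imbt = imbt, ...)
}

#' @export
simulate.dou_calibration <- function(object, nsim = 1, seed = NULL,
                                     imbt = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(imbt)) {
    if (is.null(object$data)) {
      stop("supply 'imbt' to simulate from the published model", call. = FALSE)
    }
    imbt <- object$data$imbt
  }
  if (is.na(object$rmse_log)) {
    stop("simulation requires rmse_log (fit the model to data)", call. = FALSE)
  }
  mu <- object$intercept + object$slope * imbt
  out <- as.data.frame(replicate(
    nsim, 10^(mu + stats::rnorm(length(mu), sd = object$rmse_log))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.dou_calibration <- function(x, ...) {
  if (!is.null(x$data)) {
    graphics::plot(x$data$imbt, log10(x$data$dou),
                   xlab = "IMBT", ylab = "log10(DOU) [umol m-2 d-1]",
                   main = "IMBT-DOU calibration", ...)
  } else {
    i <- seq((log10(x$range[1]) - x$intercept) / x$slope,
             (log10(x$range[2]) - x$intercept) / x$slope, length.out = 50)
    graphics::plot(i, x$intercept + x$slope * i, type = "n",
                   xlab = "IMBT", ylab = "log10(DOU) [umol m-2 d-1]",
                   main = "IMBT-DOU calibration (published)", ...)
  }
  graphics::abline(a = x$intercept, b = x$slope, lwd = 2)
  invisible(x)
}

#' Invert the transfer function to a 6-methyl fraction
#'
#' Maps a DOU value back to the proportion of the 6-methyl compounds
#' (IIIa′ + IIa′) among the five acyclic brGDGTs implied by the
#' calibration: `f = 10^(-(log10(dou) - intercept) / slope)`. Since f is a
#' fraction, the raw value is truncated at 1 (100%); both are returned.
#' At the published model's low end (DOU = 100 umol m-2 d-1) the raw value
#' exceeds 1 and the truncated fraction is exactly 100%.
#'
#' @param dou positive numeric vector, umol m-2 d-1.
#' @param model a `dou_calibration` (default: published).
#' @return Data frame with columns `dou`, `imbt` (implied IMBT), `f_raw`,
#'   `f` (truncated at 1) and `truncated`.
#' @examples
#' invert_dou_to_fraction(c(100, 10^2.1, 2000))
#' @export
invert_dou_to_fraction <- function(dou, model = imbt_dou_calibration()) {
  if (model$slope == 0) stop("slope is zero: inversion undefined", call. = FALSE)
  dou <- as.numeric(dou)
  if (any(dou <= 0, na.rm = TRUE)) stop("dou must be positive", call. = FALSE)
  imbt <- (log10(dou) - model$intercept) / model$slope
  f_raw <- 10^(-imbt)
  data.frame(dou = dou, imbt = imbt, f_raw = f_raw,
             f = pmin(f_raw, 1), truncated = f_raw > 1)
}

#' Sensitivity of the acyclic composition to DOU
#'
#' Evaluates the inverse mapping of [invert_dou_to_fraction()] over a
#' log-spaced DOU grid (default: the model's applicable range), showing
#' how strongly the 6-methyl share of the acyclic brGDGTs responds to DOU.
#' For a positive slope the raw fraction is strictly decreasing in DOU, so
#' compositions are most sensitive at the low-DOU end.
#'
#' @param model a `dou_calibration`.
#' @param dou optional explicit DOU grid; otherwise `n` log-spaced points
#'   over `model$range`.
#' @param n grid size when `dou` is not given.
#' @return Data frame with columns `dou`, `imbt`, `f_raw`, `f_truncated`.
#' @export
sensitivity_curve <- function(model = imbt_dou_calibration(), dou = NULL,
                              n = 101) {
  if (is.null(dou)) {
    dou <- 10^seq(log10(model$range[1]), log10(model$range[2]),
                  length.out = n)
  }
  inv <- invert_dou_to_fraction(dou, model)
  data.frame(dou = inv$dou, imbt = inv$imbt, f_raw = inv$f_raw,
             f_truncated = inv$f)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a `dou_calibration`.
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns a `dou_calibration` (without the `lm`
#'   object or fitting data).
#' @export
write_calibration <- function(model, path) {
  keep <- model[c("slope", "intercept", "r", "p.value", "rmse_log",
                  "rmse_linear", "n", "range", "published")]
  keep$generator <- "brgdgt dou_calibration"
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  .new_dou_calibration(slope = num(j$slope), intercept = num(j$intercept),
                       r = num(j$r), p.value = num(j$p.value),
                       rmse_log = num(j$rmse_log),
                       rmse_linear = num(j$rmse_linear),
                       n = if (is.null(j$n)) NA_integer_ else as.integer(j$n),
                       range = as.numeric(j$range),
                       published = isTRUE(j$published))
}
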