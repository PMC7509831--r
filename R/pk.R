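#' Elimination half-life from a log10-linear decay slope
#'
#' For first-order elimination fitted as `log10(C) = a - b t`, the half-life
#' is `log10(2) / b` hours.
#'
#' @param b Decay slope in log10 units per hour, > 0.
#' @return Half-life in hours.
#' @export
#' @examples
#' half_life(0.0211)  # ~14.3 h
half_life <- function(b) {
  if (any(!is.finite(b)) || any(b <= 0)) {
    stop("b must be positive (no elimination detected for b <= 0)",
         call. = FALSE)
  }
  log10(2) / b
}

new_elimination_fit <- function(intercept, slope, r_squared, n, flag,
                                model = NULL, data = NULL) {
  hl <- if (flag == "ok") log10(2) / slope else NA_real_
  structure(
    list(intercept = intercept, slope = slope, r_squared = r_squared,
         half_life = hl, n = n, flag = flag, model = model, data = data),
    class = "elimination_fit"
  )
}

#' Fit first-order elimination to a plasma concentration time course
#'
#' Ordinary least squares of `log10(concentration)` on time. The slope is
#' reported in the decay-positive convention `y = a - b t`, so `b > 0`
#' means elimination and the half-life is `log10(2) / b`. With
#' `per_time_means = TRUE` (the default, matching destructive sampling
#' designs where each time point uses different animals) concentrations are
#' averaged per time point before fitting; set it to `FALSE` to fit all
#' points, e.g. longitudinal data per subject.
#'
#' @param data Data frame with the series.
#' @param time,conc Column names (tidy-eval): time (h) and concentration
#'   (strictly positive; any concentration unit — the intercept is carried
#'   opaquely in log10 of that unit).
#' @param per_time_means Average concentrations per time point first.
#' @return An `elimination_fit` with `intercept` (a), `slope` (b, decay
#'   positive), `r_squared`, `half_life` (h), `n` and `flag`
#'   (`"ok"` or `"no elimination"`).
#' @export
#' @examples
#' d <- tibble::tibble(t = c(6, 12, 24, 48), c = 10^(1.4 - 0.02 * c(6, 12, 24, 48)))
#' fit_first_order(d, t, c)$half_life
fit_first_order <- function(data, time = time, conc = conc,
                            per_time_means = TRUE) {
  tt <- rlang::eval_tidy(rlang::enquo(time), data)
  cc <- rlang::eval_tidy(rlang::enquo(conc), data)
  if (any(!is.finite(cc)) || any(cc <= 0)) {
    stop("concentrations must be positive and finite (log-transform)",
         call. = FALSE)
  }
  d <- tibble::tibble(.time = tt, .conc = cc)
  if (per_time_means) {
    d <- d |>
      dplyr::group_by(.data$.time) |>
      dplyr::summarise(.conc = mean(.data$.conc), .groups = "drop")
  }
  if (nrow(d) < 3) stop("need at least 3 (distinct) time points",
                        call. = FALSE)
  d$.y <- log10(d$.conc)
  m <- stats::lm(.y ~ .time, data = d)
  a <- unname(stats::coef(m)[1])
  b <- -unname(stats::coef(m)[2])
  r2 <- suppressWarnings(summary(m)$r.squared)
  # a slope indistinguishable from zero (numerically flat series) is not decay
  flag <- if (is.finite(b) && b > 1e-12) "ok" else "no elimination"
  new_elimination_fit(a, b, r2, nrow(d), flag, model = m, data = d)
}

#' @export
print.elimination_fit <- function(x, ...) {
  cat("<elimination_fit>\n")
  cat(sprintf("  y = %.4g - %.4g x  (r^2 = %.4g, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  if (x$flag == "ok") {
    cat(sprintf("  half-life = %.3g h\n", x$half_life))
  } else {
    cat("  flag:", x$flag, "\n")
  }
  invisible(x)
}

#' @rdname tidy.npamyloid
#' @export
tidy.elimination_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope", "half_life"),
    estimate = c(x$intercept, x$slope, x$half_life),
    unit = c("log10 conc", "log10 conc / h", "h")
  )
}

#' @rdname glance.npamyloid
#' @export
glance.elimination_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope,
                 r_squared = x$r_squared, half_life = x$half_life,
                 n = x$n, flag = x$flag)
}

#' @export
autoplot.elimination_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$.time, y = .data$.y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = -object$slope, colour = "firebrick") +
    ggplot2::labs(x = "Time (h)", y = "log10 concentration") +
    ggplot2::theme_minimal()
}

#' Peak time and fold-change of a biodistribution time series
#'
#' For each treated group, computes per-time mean values, finds the time of
#' the maximum mean (ties broken by the earliest time) and the fold-change
#' relative to the control-group mean at that time.
#'
#' @param data Data frame in long format.
#' @param time,value,group Column names (tidy-eval).
#' @param control Label of the control group in `group`.
#' @return Tibble with one row per non-control group: `group`,
#'   `peak_time`, `peak_mean`, `control_mean`, `fold_change`.
#' @export
peak_summary <- function(data, time = time, value = value, group = group,
                         control = "control") {
  d <- tibble::tibble(
    .time = rlang::eval_tidy(rlang::enquo(time), data),
    .value = rlang::eval_tidy(rlang::enquo(value), data),
    .group = rlang::eval_tidy(rlang::enquo(group), data)
  )
  if (!control %in% d$.group) {
    stop("control group '", control, "' not present", call. = FALSE)
  }
  means <- d |>
    dplyr::group_by(.data$.group, .data$.time) |>
    dplyr::summarise(.mean = mean(.data$.value), .groups = "drop")
  grids <- split(means$.time, means$.group)
  ctrl_grid <- sort(grids[[control]])
  for (g in names(grids)) {
    if (!identical(sort(grids[[g]]), ctrl_grid)) {
      stop("mismatched measurement grids: group '", g,
           "' does not share the control's time points", call. = FALSE)
    }
  }
  ctrl <- means[means$.group == control, ]
  means |>
    dplyr::filter(.data$.group != control) |>
    dplyr::group_by(.data$.group) |>
    dplyr::group_map(function(gd, key) {
      gd <- dplyr::arrange(gd, .data$.time)  # earliest-time tie-break
      i <- which.max(gd$.mean)
      t_peak <- gd$.time[i]
      c_mean <- ctrl$.mean[match(t_peak, ctrl$.time)]
      if (!is.finite(c_mean) || c_mean == 0) {
        stop("control mean is zero at the peak time", call. = FALSE)
      }
      tibble::tibble(group = key$.group, peak_time = t_peak,
                     peak_mean = gd$.mean[i], control_mean = c_mean,
                     fold_change = gd$.mean[i] / c_mean)
    }) |>
    purrr::list_rbind()
}
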