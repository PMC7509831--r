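#' Sigmoidal fibrillation model
#'
#' Boltzmann sigmoid used to describe nucleation-growth fibrillation
#' kinetics as reported by thioflavin-T fluorescence:
#' `F(t) = F0 + A / (1 + exp(-k * (t - t_half)))`, with baseline `F0`,
#' amplitude `A`, apparent aggregation constant `k` (per hour) and
#' half-time `t_half` (hours).
#'
#' @param t Time (h).
#' @param F0 Baseline fluorescence (a.u.).
#' @param A Amplitude, maximum minus baseline (a.u.).
#' @param k Apparent aggregation constant (1/h), > 0.
#' @param t_half Time to half-maximal signal (h).
#' @return Fluorescence (a.u.).
#' @export
#' @examples
#' sigmoid_model(18, F0 = 5, A = 95, k = 0.4, t_half = 18)  # midpoint: F0 + A/2
sigmoid_model <- function(t, F0, A, k, t_half) {
  stopifnot(k > 0)
  F0 + A / (1 + exp(-k * (t - t_half)))
}

new_sigmoid_fit <- function(F0, A, k, t_half, rss, converged, n, label = NA,
                            replicate = NA, message = NA_character_,
                            data = NULL) {
  lag_time <- if (is.finite(k) && k > 0) t_half - 2 / k else NA_real_
  structure(
    list(F0 = F0, A = A, k = k, t_half = t_half, lag_time = lag_time,
         rss = rss, converged = converged, n = n, label = label,
         replicate = replicate, message = message, data = data),
    class = "sigmoid_fit"
  )
}

sigmoid_start_values <- function(time, value) {
  F0 <- min(value)
  A <- max(value) - F0
  half <- F0 + A / 2
  above <- which(value >= half)
  t_half <- if (length(above) > 0) {
    i <- above[1]
    if (i == 1) time[1] else {
      # linear interpolation of the half-range crossing
      t0 <- time[i - 1]; t1 <- time[i]
      v0 <- value[i - 1]; v1 <- value[i]
      if (v1 == v0) t1 else t0 + (half - v0) / (v1 - v0) * (t1 - t0)
    }
  } else stats::median(time)
  slopes <- diff(value) / diff(time)
  k <- 4 * max(slopes) / A
  if (!is.finite(k) || k <= 0) k <- 1 / max(diff(range(time)), 1)
  list(F0 = F0, A = A, k = k, t_half = t_half)
}

#' Fit a sigmoid to a thioflavin-T curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [sigmoid_model()] with
#' data-driven starting values: baseline from the minimum, amplitude from
#' the range, half-time from the interpolated half-range crossing and rate
#' from the steepest slope. The lag time uses the tangent-at-midpoint
#' convention standard in amyloid kinetics,
#' `lag_time = t_half - 2 / k`.
#'
#' @param data Data frame with the curve.
#' @param time,value Column names (tidy-eval) holding times (h, strictly
#'   increasing, >= 6 points) and fluorescence values.
#' @param label,replicate Optional identifiers carried into the result.
#' @return A `sigmoid_fit` with elements `F0`, `A`, `k`, `t_half`,
#'   `lag_time`, `rss`, `converged`. Non-convergence is returned as a
#'   flagged fit, never silent success; a flat curve is an error
#'   ("no transition").
#' @seealso [fit_tht()] for fitting many replicates at once.
#' @export
#' @examples
#' d <- tibble::tibble(t = 0:48,
#'                     f = sigmoid_model(0:48, 5, 95, 0.4, 18))
#' fit <- fit_sigmoid(d, t, f)
#' fit$t_half
fit_sigmoid <- function(data, time = time, value = value, label = NA,
                        replicate = NA) {
  tt <- rlang::eval_tidy(rlang::enquo(time), data)
  vv <- rlang::eval_tidy(rlang::enquo(value), data)
  if (length(tt) < 6) stop("need at least 6 time points", call. = FALSE)
  if (any(tt < 0) || any(diff(tt) <= 0)) {
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(vv))) stop("fluorescence values must be finite",
                                call. = FALSE)
  rng <- diff(range(vv))
  scale_ref <- max(abs(vv), 1)
  if (rng <= 1e-8 * scale_ref) {
    stop("no transition: curve is flat (range ~ 0)", call. = FALSE)
  }
  st <- sigmoid_start_values(tt, vv)
  df <- data.frame(.t = tt, .v = vv)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      .v ~ F0 + A / (1 + exp(-k * (.t - t_half))),
      data = df, start = st,
      lower = c(F0 = -Inf, A = 0, k = 1e-8, t_half = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_sigmoid_fit(st$F0, st$A, st$k, st$t_half, NA_real_,
                           converged = FALSE, n = length(tt), label = label,
                           replicate = replicate,
                           message = conditionMessage(fit), data = df))
  }
  co <- stats::coef(fit)
  conv <- fit$convInfo$isConv && co[["k"]] > 0
  new_sigmoid_fit(co[["F0"]], co[["A"]], co[["k"]], co[["t_half"]],
                  sum(stats::residuals(fit)^2), converged = conv,
                  n = length(tt), label = label, replicate = replicate,
                  data = df)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>",
      if (!isTRUE(x$converged)) " (NOT converged)", "\n", sep = "")
  cat(sprintf("  F0 = %.4g, A = %.4g, k = %.4g /h, t_half = %.4g h, lag = %.4g h\n",
              x$F0, x$A, x$k, x$t_half, x$lag_time))
  invisible(x)
}

#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per fitted quantity or observation group;
#' `glance()` returns a one-row model summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.npamyloid
NULL

#' @rdname tidy.npamyloid
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("F0", "A", "k", "t_half", "lag_time"),
    estimate = c(x$F0, x$A, x$k, x$t_half, x$lag_time)
  )
}

#' One-row summaries for fitted objects
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance.npamyloid
NULL

#' @rdname glance.npamyloid
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(F0 = x$F0, A = x$A, k = x$k, t_half = x$t_half,
                 lag_time = x$lag_time, rss = x$rss, n = x$n,
                 converged = x$converged, label = x$label,
                 replicate = x$replicate)
}

#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  grid <- tibble::tibble(
    .t = seq(min(object$data$.t), max(object$data$.t), length.out = 200))
  grid$.v <- sigmoid_model(grid$.t, object$F0, object$A,
                           max(object$k, 1e-8), object$t_half)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$.t, y = .data$.v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Time (h)", y = "ThT fluorescence (a.u.)") +
    ggplot2::theme_minimal()
}

#' Fit sigmoid curves for every (label, replicate) group
#'
#' Each replicate is fitted independently; group summaries should be taken
#' as mean and standard deviation of the per-replicate parameters rather
#' than fits of averaged curves, preserving replicate variance.
#'
#' @param data Long-format data frame.
#' @param time,value,label,replicate Column names (tidy-eval).
#' @return Tibble with one row per group: the fitted parameters plus `rss`,
#'   `converged`, and a `fit` list-column of `sigmoid_fit` objects.
#' @export
fit_tht <- function(data, time = time, value = value, label = label,
                    replicate = replicate) {
  tq <- rlang::enquo(time); vq <- rlang::enquo(value)
  d <- tibble::tibble(
    .time = rlang::eval_tidy(tq, data),
    .value = rlang::eval_tidy(vq, data),
    .label = rlang::eval_tidy(rlang::enquo(label), data),
    .replicate = rlang::eval_tidy(rlang::enquo(replicate), data)
  )
  d |>
    dplyr::group_by(.data$.label, .data$.replicate) |>
    dplyr::group_map(function(g, key) {
      f <- fit_sigmoid(g, .time, .value, label = key$.label,
                       replicate = key$.replicate)
      glance.sigmoid_fit(f) |> dplyr::mutate(fit = list(f))
    }) |>
    purrr::list_rbind() |>
    dplyr::relocate("label", "replicate")
}

amplitude_of <- function(fit, method = "amplitude") {
  if (inherits(fit, "sigmoid_fit")) {
    if (!isTRUE(fit$converged)) {
      stop("fit has not converged; refusing to compare", call. = FALSE)
    }
    switch(method, amplitude = fit$A, plateau = fit$F0 + fit$A)
  } else {
    as.numeric(fit)
  }
}

#' Percent decrease in maximum ThT intensity
#'
#' `100 * (1 - A_treated / A_control)` using fitted amplitudes (default) or
#' raw plateau maxima (`F0 + A`).
#'
#' @param control,treated `sigmoid_fit` objects (or bare amplitudes).
#' @param method `"amplitude"` (default) or `"plateau"`.
#' @return Percent decrease (100 = complete suppression; negative values
#'   mean enhancement).
#' @export
#' @examples
#' max_intensity_decrease(100, 40)  # 60
max_intensity_decrease <- function(control, treated,
                                   method = c("amplitude", "plateau")) {
  method <- match.arg(method)
  a_c <- amplitude_of(control, method)
  a_t <- amplitude_of(treated, method)
  if (!is.finite(a_c) || a_c <= 0) {
    stop("invalid baseline: control amplitude must be positive",
         call. = FALSE)
  }
  100 * (1 - a_t / a_c)
}

#' Compare fitted fibrillation kinetics against a control
#'
#' Summarises lag time, half-time, rate and amplitude per label (mean over
#' replicates) and flags which quantities moved in the inhibition direction
#' relative to the control: lag up, rate down, amplitude down.
#'
#' @param fits Tibble from [fit_tht()], or a list of `sigmoid_fit` objects.
#' @param control Label of the control group.
#' @return Tibble with one row per label: mean `lag_time`, `t_half`, `k`,
#'   `A`, `pct_decrease` and `pct_decrease_plateau` vs the control, and
#'   logical flags `lag_up`, `k_down`, `amp_down`.
#' @export
compare_fits <- function(fits, control = "control") {
  if (is.list(fits) && !is.data.frame(fits) &&
      all(vapply(fits, inherits, logical(1), "sigmoid_fit"))) {
    fits <- purrr::map(fits, glance.sigmoid_fit) |> purrr::list_rbind()
  }
  fits <- tibble::as_tibble(fits)
  if (!control %in% fits$label) {
    stop("missing control label: ", control, call. = FALSE)
  }
  if (any(!fits$converged)) {
    stop("all fits must have converged", call. = FALSE)
  }
  if (nrow(fits) < 2) stop("need at least 2 fits to compare", call. = FALSE)
  s <- fits |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(lag_time = mean(.data$lag_time),
                     t_half = mean(.data$t_half),
                     k = mean(.data$k),
                     A = mean(.data$A),
                     plateau = mean(.data$F0 + .data$A),
                     n = dplyr::n(), .groups = "drop")
  ctrl <- s[s$label == control, ]
  s |>
    dplyr::mutate(
      pct_decrease = 100 * (1 - .data$A / ctrl$A),
      pct_decrease_plateau = 100 * (1 - .data$plateau / ctrl$plateau),
      lag_up = .data$lag_time > ctrl$lag_time,
      k_down = .data$k < ctrl$k,
      amp_down = .data$A < ctrl$A,
      is_control = .data$label == control
    ) |>
    dplyr::arrange(!.data$is_control) |>
    dplyr::select(-"is_control", -"plateau")
}
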