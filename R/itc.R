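R_KCAL <- 1.987e-3  # gas constant, kcal / (mol K)

#' Describe an ITC titration geometry
#'
#' Defaults mirror a titration of 138 uM peptide injected in 2 uL steps
#' (20 injections, 40 uL total) into a 200 uL cell holding 1.5 uM
#' nanoparticle solution at 25 degrees C.
#'
#' @param cell_volume_uL Active cell volume (uL).
#' @param syringe_conc_uM Titrant (peptide) concentration in the syringe (uM).
#' @param cell_conc_uM Macromolecule (nanoparticle) concentration in the
#'   cell (uM).
#' @param injection_volumes_uL Vector of injection volumes (uL).
#' @param temperature_K Temperature (K).
#' @return An `itc_geometry` list.
#' @export
itc_geometry <- function(cell_volume_uL = 200,
                         syringe_conc_uM = 138,
                         cell_conc_uM = 1.5,
                         injection_volumes_uL = rep(2, 20),
                         temperature_K = 298.15) {
  stopifnot(cell_volume_uL > 0, syringe_conc_uM > 0, cell_conc_uM > 0,
            all(injection_volumes_uL > 0), temperature_K > 0)
  structure(list(cell_volume_uL = cell_volume_uL,
                 syringe_conc_uM = syringe_conc_uM,
                 cell_conc_uM = cell_conc_uM,
                 injection_volumes_uL = as.numeric(injection_volumes_uL),
                 temperature_K = temperature_K),
            class = "itc_geometry")
}

# Running total concentrations under the perfusion (overfill) convention:
# each injection of dv dilutes cell contents by (1 - dv/2V0)/(1 + dv/2V0)
# and delivers fresh titrant attenuated by 1/(1 + dv/2V0).
itc_concentrations <- function(geometry) {
  V0 <- geometry$cell_volume_uL * 1e-6      # L
  dv <- geometry$injection_volumes_uL * 1e-6
  M0 <- geometry$cell_conc_uM * 1e-6        # M
  Xs <- geometry$syringe_conc_uM * 1e-6
  n <- length(dv)
  M <- X <- f <- numeric(n)
  m_prev <- M0; x_prev <- 0
  for (i in seq_len(n)) {
    delta <- dv[i] / (2 * V0)
    f[i] <- (1 - delta) / (1 + delta)
    M[i] <- m_prev * f[i]
    X[i] <- x_prev * f[i] + Xs * (dv[i] / V0) / (1 + delta)
    m_prev <- M[i]; x_prev <- X[i]
  }
  list(M_total = M, X_total = X, dilution = f, V0 = V0)
}

# Closed-form bound-titrant concentration for n0 identical independent sites
one_site_bound <- function(X_total, M_total, n0, K) {
  nM <- n0 * M_total
  B <- 1 + X_total / nM + 1 / (K * nM)
  disc <- B^2 - 4 * X_total / nM
  stopifnot(all(disc >= -1e-12))
  disc <- pmax(disc, 0)
  (B - sqrt(disc)) * nM / 2
}

#' Predicted one-site ITC heats
#'
#' Forward model for the integrated heat of each injection when the cell
#' species carries `n0` identical independent binding sites with binding
#' constant `K` and molar enthalpy `dH`. Cell concentrations are tracked
#' under a perfusion displaced-volume convention; the bound-titrant
#' concentration follows the one-site closed form and the heat of injection
#' `i` is `dH * V0 * (Xb_i - Xb_{i-1} * dilution_i)`, in microcalories.
#'
#' @param n0 Binding stoichiometry (sites per cell-species particle), > 0.
#'   For peptide titrated onto a nanoparticle this counts peptides per
#'   particle and can be large (multilayer adsorption); it is not
#'   constrained near 1.
#' @param K Binding constant (1/M), > 0.
#' @param dH Enthalpy change (kcal/mol of titrant bound).
#' @param geometry An [itc_geometry()].
#' @param q_dil Constant per-injection heat-of-dilution offset (ucal).
#' @return Numeric vector of per-injection heats (ucal).
#' @export
#' @examples
#' q <- one_site_heats(10, 3e6, -8, itc_geometry())
#' length(q)
one_site_heats <- function(n0, K, dH, geometry = itc_geometry(), q_dil = 0) {
  stopifnot(inherits(geometry, "itc_geometry"), n0 > 0, K > 0)
  cc <- itc_concentrations(geometry)
  Xb <- one_site_bound(cc$X_total, cc$M_total, n0, K)
  Xb_prev <- c(0, Xb[-length(Xb)])
  dH * cc$V0 * (Xb - Xb_prev * cc$dilution) * 1e9 + q_dil
}

#' Derive Gibbs energy and entropy from a binding constant and enthalpy
#'
#' `dG = -R T ln K` and `dS = (dH - dG) / T`, with
#' R = 1.987e-3 kcal / (mol K).
#'
#' @param K Binding constant (1/M).
#' @param dH Enthalpy change (kcal/mol).
#' @param temperature_K Temperature (K).
#' @return Tibble with `dG` (kcal/mol) and `dS` (cal/(mol K)).
#' @export
#' @examples
#' derive_thermo(1, -8, 298.15)$dG  # ln 1 = 0
derive_thermo <- function(K, dH, temperature_K = 298.15) {
  stopifnot(all(K > 0), all(temperature_K > 0))
  dG <- -R_KCAL * temperature_K * log(K)
  dS <- (dH - dG) / temperature_K * 1000
  tibble::tibble(dG = dG, dS = dS)
}

new_one_site_fit <- function(n0, K, dH, geometry, q_dil, rss, converged,
                             message = NA_character_, data = NULL,
                             fitted = NULL) {
  T_K <- geometry$temperature_K
  th <- if (is.finite(K) && K > 0) derive_thermo(K, dH, T_K) else
    tibble::tibble(dG = NA_real_, dS = NA_real_)
  c_value <- n0 * K * geometry$cell_conc_uM * 1e-6
  structure(
    list(n0 = n0, K = K, dH = dH, dG = th$dG, dS = th$dS,
         temperature_K = T_K, q_dil = q_dil, c_value = c_value,
         rss = rss, converged = converged, message = message,
         geometry = geometry, data = data, fitted = fitted),
    class = "one_site_fit"
  )
}

#' Fit the one-site binding model to an ITC thermogram
#'
#' Nonlinear least squares (Levenberg-Marquardt, with `log10 K` as the
#' internal scale parameter) of [one_site_heats()] against per-injection
#' heats. Starting values come from the stoichiometric limit (first-heat
#' enthalpy estimate) and the total-heat capacity. Gibbs energy and entropy
#' are derived at the thermogram temperature; a Wiseman c-value
#' (`n0 * K * [cell]`) outside `[1, 1e4]` triggers a reliability warning,
#' not a failure.
#'
#' @param data Data frame with columns `injection`, `volume_uL`,
#'   `heat_ucal` (>= 10 injections).
#' @param geometry An [itc_geometry()]; its injection volumes are replaced
#'   by the `volume_uL` column.
#' @param dilution_offset Fit a constant per-injection heat-of-dilution
#'   offset (default on).
#' @return A `one_site_fit` with `n0`, `K` (1/M), `dH` (kcal/mol), derived
#'   `dG` (kcal/mol) and `dS` (cal/(mol K)), `c_value`, `rss`, `converged`.
#'   Non-convergence (including degenerate all-zero heats) is returned as a
#'   flagged fit.
#' @export
fit_one_site <- function(data, geometry = itc_geometry(),
                         dilution_offset = TRUE) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("injection", "volume_uL", "heat_ucal") %in% names(data)))
  if (nrow(data) < 10) stop("need at least 10 injections", call. = FALSE)
  geometry$injection_volumes_uL <- data$volume_uL
  q <- data$heat_ucal

  if (all(abs(q) < 1e-12)) {
    return(new_one_site_fit(NA_real_, NA_real_, NA_real_, geometry, 0,
                            rss = 0, converged = FALSE,
                            message = "degenerate thermogram: all heats zero",
                            data = data))
  }

  cc <- itc_concentrations(geometry)
  moles1 <- geometry$injection_volumes_uL[1] * 1e-6 *
    geometry$syringe_conc_uM * 1e-6
  dH0 <- q[1] / (moles1 * 1e9)
  if (!is.finite(dH0) || abs(dH0) < 1e-6) dH0 <- -1
  M_final <- cc$M_total[length(cc$M_total)]
  ratio_final <- cc$X_total[length(cc$X_total)] / M_final
  n00 <- sum(q) / (dH0 * cc$V0 * M_final * 1e9)
  if (!is.finite(n00) || n00 <= 0) n00 <- ratio_final / 2
  n00 <- min(max(n00, 0.1), 2 * ratio_final)
  lK0 <- log10(10 / (n00 * geometry$cell_conc_uM * 1e-6))

  start <- c(n0 = n00, lK = lK0, dH = dH0)
  lower <- c(n0 = 1e-6, lK = -2, dH = -Inf)
  upper <- c(n0 = Inf, lK = 14, dH = Inf)
  if (dilution_offset) {
    start <- c(start, q0 = 0)
    lower <- c(lower, q0 = -Inf)
    upper <- c(upper, q0 = Inf)
  }
  resid_fun <- function(par) {
    q - one_site_heats(par[["n0"]], 10^par[["lK"]], par[["dH"]], geometry,
                       q_dil = if (dilution_offset) par[["q0"]] else 0)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_one_site_fit(n00, 10^lK0, dH0, geometry, 0, NA_real_,
                            converged = FALSE,
                            message = conditionMessage(fit), data = data))
  }
  co <- fit$par
  q0 <- if (dilution_offset) co[["q0"]] else 0
  out <- new_one_site_fit(co[["n0"]], 10^co[["lK"]], co[["dH"]], geometry,
                          q0, fit$deviance,
                          converged = fit$info %in% 1:3,
                          message = fit$message, data = data,
                          fitted = q - as.numeric(fit$fvec))
  if (is.finite(out$c_value) &&
      (out$c_value < 1 || out$c_value > 1e4)) {
    warning(sprintf(paste0("Wiseman c-value %.3g outside [1, 1e4]; ",
                           "fitted constants may be poorly determined"),
                    out$c_value), call. = FALSE)
  }
  out
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat("<one_site_fit>",
      if (!isTRUE(x$converged)) " (NOT converged)", "\n", sep = "")
  cat(sprintf("  n0 = %.4g, K = %.4g 1/M, dH = %.4g kcal/mol\n",
              x$n0, x$K, x$dH))
  cat(sprintf("  dG = %.4g kcal/mol, dS = %.4g cal/(mol K) at %.2f K (c = %.3g)\n",
              x$dG, x$dS, x$temperature_K, x$c_value))
  invisible(x)
}

#' @rdname tidy.npamyloid
#' @export
tidy.one_site_fit <- function(x, ...) {
  tibble::tibble(
    term = c("n0", "K", "dH", "dG", "dS", "q_dil"),
    estimate = c(x$n0, x$K, x$dH, x$dG, x$dS, x$q_dil),
    unit = c("sites", "1/M", "kcal/mol", "kcal/mol", "cal/(mol K)", "ucal")
  )
}

#' @rdname glance.npamyloid
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble::tibble(n0 = x$n0, K = x$K, dH = x$dH, dG = x$dG, dS = x$dS,
                 temperature_K = x$temperature_K, c_value = x$c_value,
                 rss = x$rss, converged = x$converged)
}

#' @export
autoplot.one_site_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  geometry <- object$geometry
  cc <- itc_concentrations(geometry)
  d <- tibble::tibble(ratio = cc$X_total / cc$M_total,
                      heat = object$data$heat_ucal,
                      fitted = if (is.null(object$fitted)) NA_real_
                               else object$fitted)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio, y = .data$heat)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Molar ratio (titrant/cell species)",
                  y = "Heat per injection (ucal)") +
    ggplot2::theme_minimal()
  if (!is.null(object$fitted)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                                colour = "firebrick")
  }
  p
}
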