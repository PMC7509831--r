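# Seeded generators for every input the pipeline consumes. All generators
# are pure functions of their arguments and the seed. Default effect sizes
# for the treated fibrillation groups mirror the reported percent decreases
# (60/63/11%) so end-to-end demos are recognisable; they are emulation
# parameters, not data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default true parameters for synthetic fibrillation groups
#'
#' A control group plus three treated groups whose amplitudes are reduced
#' by 60%, 63% and 11% relative to the control, with extended lag and
#' reduced rate for the strongly inhibited groups.
#'
#' @return Tibble with columns `label`, `F0`, `A`, `k`, `t_half`.
#' @export
tht_truth_default <- function() {
  tibble::tibble(
    label = c("control", "NP_L", "NP_D", "NP_achiral"),
    F0 = 5,
    A = 95 * (1 - c(0, 0.60, 0.63, 0.11)),
    k = c(0.40, 0.25, 0.22, 0.36),
    t_half = c(18, 28, 30, 20)
  )
}

#' Generate synthetic thioflavin-T curves
#'
#' Draws replicate curves from [sigmoid_model()] with additive Gaussian
#' plate-reader noise.
#'
#' @param truth Tibble of group parameters (see [tht_truth_default()]).
#' @param times Sampling grid (h, strictly increasing).
#' @param n_replicates Replicates per group.
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param seed Integer seed; identical inputs give identical output.
#' @return Long tibble with `time`, `value`, `replicate`, `label`, carrying
#'   the seed in attribute `"seed"`.
#' @export
#' @examples
#' gen_tht(n_replicates = 1, noise_sd = 0, seed = 1)
gen_tht <- function(truth = tht_truth_default(),
                    times = seq(0, 48, by = 2),
                    n_replicates = 3,
                    noise_sd = 2,
                    seed = 1L) {
  stopifnot(noise_sd >= 0, all(diff(times) > 0), n_replicates >= 1)
  out <- with_seed(seed, {
    purrr::pmap(truth, function(label, F0, A, k, t_half) {
      purrr::map(seq_len(n_replicates), function(r) {
        tibble::tibble(
          time = times,
          value = sigmoid_model(times, F0, A, k, t_half) +
            stats::rnorm(length(times), 0, noise_sd),
          replicate = r,
          label = label
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Default true parameters for synthetic ITC presets
#'
#' Illustrative one-site parameters for the two chiral nanoparticle
#' surfaces: binding constants chosen so the derived Gibbs energies are
#' -6.7 ("L-like") and -7.3 ("D-like") kcal/mol at 298.15 K, with a
#' negative enthalpy and a multilayer-scale stoichiometry. The published
#' numeric n0/K/dH values are not available in accessible text, so these
#' presets are emulations anchored to the printed Gibbs energies only.
#'
#' @param which `"L"` or `"D"`.
#' @return List with `n0`, `K` (1/M), `dH` (kcal/mol).
#' @export
itc_truth_default <- function(which = c("L", "D")) {
  which <- match.arg(which)
  dG <- if (which == "L") -6.7 else -7.3
  list(n0 = 10, K = exp(-dG / (R_KCAL * 298.15)), dH = -8)
}

#' Generate a synthetic ITC thermogram
#'
#' Heats from [one_site_heats()] plus proportional Gaussian noise
#' (`sd = noise_prop * |heat|` per injection).
#'
#' @param n0,K,dH One-site parameters (see [one_site_heats()]).
#' @param geometry An [itc_geometry()]; the default matches the titration
#'   of 138 uM peptide in twenty 2 uL injections into 200 uL of 1.5 uM
#'   nanoparticle solution.
#' @param noise_prop Proportional noise level (e.g. 0.02 for 2%).
#' @param q_dil Constant heat-of-dilution offset (ucal).
#' @param seed Integer seed.
#' @return Tibble with `injection`, `volume_uL`, `heat_ucal`; the geometry,
#'   truth and seed ride along as attributes.
#' @export
gen_itc <- function(n0 = 10, K = itc_truth_default("L")$K, dH = -8,
                    geometry = itc_geometry(), noise_prop = 0.02,
                    q_dil = 0, seed = 1L) {
  stopifnot(noise_prop >= 0)
  q <- one_site_heats(n0, K, dH, geometry, q_dil = q_dil)
  q_noisy <- with_seed(seed, q + stats::rnorm(length(q), 0, noise_prop * abs(q)))
  out <- tibble::tibble(
    injection = seq_along(q),
    volume_uL = geometry$injection_volumes_uL,
    heat_ucal = q_noisy
  )
  attr(out, "geometry") <- geometry
  attr(out, "truth") <- list(n0 = n0, K = K, dH = dH, q_dil = q_dil)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Generate synthetic plasma elimination series
#'
#' Concentrations follow `C0 * 10^(-slope * t) * exp(eps)` with
#' `eps ~ Normal(0, noise_sdlog^2)`, i.e. multiplicative lognormal noise so
#' concentrations stay positive. The default grid matches sampling at 6,
#' 12, 24 and 48 h with 4 subjects per time point.
#'
#' @param intercept `a` in `log10 C = a - b t` (so `C0 = 10^a`).
#' @param slope `b`, log10 units per hour.
#' @param times Sampling grid (h).
#' @param n_subjects Subjects per time point (destructive sampling).
#' @param noise_sdlog Standard deviation of the log-scale noise.
#' @param group Group label.
#' @param seed Integer seed.
#' @return Tibble with `time_h`, `concentration`, `subject`, `group` and a
#'   `"seed"` attribute.
#' @export
#' @examples
#' gen_pk(noise_sdlog = 0, n_subjects = 1, seed = 1)
gen_pk <- function(intercept = 1.396, slope = 0.0211,
                   times = c(6, 12, 24, 48), n_subjects = 4,
                   noise_sdlog = 0.1, group = "NP", seed = 1L) {
  stopifnot(noise_sdlog >= 0, n_subjects >= 1, all(diff(sort(times)) > 0))
  out <- with_seed(seed, {
    purrr::map(seq_len(n_subjects), function(s) {
      tibble::tibble(
        time_h = times,
        concentration = 10^(intercept - slope * times) *
          exp(stats::rnorm(length(times), 0, noise_sdlog)),
        subject = s,
        group = group
      )
    }) |> purrr::list_rbind()
  })
  attr(out, "seed") <- as.integer(seed)
  out
}
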