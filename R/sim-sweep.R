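#' Number of nanoparticles matching a total surface-area budget
#'
#' Doses are matched on total nanoparticle surface area across diameters:
#' `n = round(total_surface_area / (pi * d^2))`.
#'
#' @param diameter Particle diameter.
#' @param total_surface_area Total surface area budget (same squared length
#'   unit as `diameter`).
#' @return Integer particle count.
#' @export
#' @examples
#' np_count_for_area(3, pi * 15^2)
np_count_for_area <- function(diameter, total_surface_area) {
  as.integer(round(total_surface_area / (pi * diameter^2)))
}

#' Surface-area-matched nanoparticle size sweep
#'
#' Runs replicate simulations for each nanoparticle diameter at equal total
#' nanoparticle surface area (the dosing rule used experimentally), plus a
#' zero-nanoparticle control, and reports the mean number of chains per
#' aggregate. Diameters are given in nanometres and converted to reduced
#' units via `base_config$sigma_nm`.
#'
#' @param diameters_nm Nanoparticle diameters to sweep, in nm.
#' @param total_surface_area_nm2 Total surface-area budget in nm^2; defaults
#'   to the area of a single particle of the largest swept diameter (the
#'   smallest budget for which every swept diameter receives at least one
#'   particle).
#' @param base_config Base [sim_config()]; defaults to `sim_preset("sweep")`.
#'   Its box must exceed twice the largest swept diameter.
#' @param n_replicates Replicates per condition (defaults to
#'   `base_config$n_replicates`); replicate `r` of every condition uses seed
#'   `base_config$seed + r`.
#' @param adsorption_energy,shell_thickness Per-bead adsorption well depth
#'   (kT) and shell thickness (sigma) applied to every swept particle.
#' @param include_control Include the zero-nanoparticle control condition.
#' @param progress Emit one message per condition to standard error.
#' @return A `size_sweep` tibble with one row per (condition, replicate):
#'   `diameter_nm` (`NA` for the control), `n_np`, `replicate`, `seed`,
#'   `mean_chains_per_aggregate`, `acceptance_rate`. Summarise with
#'   [tidy()] and plot with [ggplot2::autoplot()].
#' @export
size_sweep <- function(diameters_nm,
                       total_surface_area_nm2 = pi * max(diameters_nm)^2,
                       base_config = sim_preset("sweep"),
                       n_replicates = base_config$n_replicates,
                       adsorption_energy = 2,
                       shell_thickness = 0.5,
                       include_control = TRUE,
                       progress = FALSE) {
  stopifnot(length(diameters_nm) >= 1, all(diameters_nm > 0),
            total_surface_area_nm2 > 0)
  validate_sim_config(base_config)

  n_np <- np_count_for_area(diameters_nm, total_surface_area_nm2)
  if (any(n_np == 0)) {
    stop("surface-area budget too small: diameter(s) ",
         paste(diameters_nm[n_np == 0], collapse = ", "),
         " nm round to zero particles", call. = FALSE)
  }

  conditions <- tibble::tibble(diameter_nm = diameters_nm, n_np = n_np)
  if (include_control) {
    conditions <- dplyr::bind_rows(
      tibble::tibble(diameter_nm = NA_real_, n_np = 0L), conditions)
  }

  rows <- purrr::pmap(conditions, function(diameter_nm, n_np) {
    cfg <- base_config
    if (n_np > 0) {
      cfg$nanoparticles <- tibble::tibble(
        diameter = rep(diameter_nm / base_config$sigma_nm, n_np),
        adsorption_energy = adsorption_energy,
        shell_thickness = shell_thickness
      )
    } else {
      cfg$nanoparticles <- tibble::tibble(diameter = double(),
                                          adsorption_energy = double(),
                                          shell_thickness = double())
    }
    validate_sim_config(cfg)
    if (progress) {
      message(sprintf("size_sweep: d = %s nm (%d particles), %d replicates",
                      ifelse(is.na(diameter_nm), "control", diameter_nm),
                      n_np, n_replicates))
    }
    purrr::map(seq_len(n_replicates), function(r) {
      rep_out <- run_simulation(cfg, replicate = r)
      tibble::tibble(
        diameter_nm = diameter_nm,
        n_np = n_np,
        replicate = r,
        seed = rep_out$seed,
        mean_chains_per_aggregate = rep_out$mean_chains_per_aggregate,
        acceptance_rate = rep_out$acceptance_rate
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  structure(rows,
            class = c("size_sweep", class(tibble::tibble())),
            total_surface_area_nm2 = total_surface_area_nm2)
}

#' @rdname tidy.npamyloid
#' @export
tidy.size_sweep <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$diameter_nm, .data$n_np) |>
    dplyr::summarise(
      mean = mean(.data$mean_chains_per_aggregate),
      sd = stats::sd(.data$mean_chains_per_aggregate),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(!is.na(.data$diameter_nm), .data$diameter_nm)
}

#' @export
autoplot.size_sweep <- function(object, ...) {
  s <- tidy.size_sweep(object)
  ctrl <- s[is.na(s$diameter_nm), ]
  nps <- s[!is.na(s$diameter_nm), ]
  p <- ggplot2::ggplot(nps, ggplot2::aes(x = .data$diameter_nm, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "Nanoparticle diameter (nm)",
                  y = "Mean chains per aggregate") +
    ggplot2::theme_minimal()
  if (nrow(ctrl) == 1) {
    p <- p + ggplot2::geom_hline(yintercept = ctrl$mean, linetype = "dashed")
  }
  p
}
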