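#' Build a coarse-grained simulation configuration
#'
#' Defines the geometry, energetics and move schedule of the bead-chain
#' Monte Carlo model. Lengths are in reduced units of the bead diameter
#' (sigma); the mapping to physical size is `sigma_nm` nanometres per sigma,
#' so with the default `sigma_nm = 0.5` a 3.3 nm nanoparticle has diameter
#' 6.6 sigma. Energies are in units of kT.
#'
#' Peptide chains are freely jointed bead chains. Inter-chain "hydrogen
#' bonds" form between bead pairs closer than `hb_cutoff`, each bead holding
#' at most `max_bonds_per_bead` bonds (a beta-strand-like valence of 2 by
#' default) with well depth `eps_hb`. Nanoparticles are fixed hard spheres
#' with a square-well adsorption shell of thickness `shell_thickness` and
#' depth `adsorption_energy` per bead; beads sitting inside a shell are
#' barred from forming new inter-chain bonds when `adsorbed_bond_block` is
#' `TRUE`, expressing inhibition by monomer sequestration.
#'
#' A Monte Carlo step is one attempted move of one randomly chosen chain;
#' move types are drawn according to `move_weights`.
#'
#' @param box_length Cubic box edge (sigma). Must exceed twice the largest
#'   nanoparticle diameter.
#' @param n_chains Number of peptide chains.
#' @param chain_length Beads per chain (>= 3; crankshaft and kink-jump moves
#'   need interior beads).
#' @param bead_diameter Hard-core bead diameter (sigma; 1 by convention).
#' @param bond_length Backbone bond length (sigma).
#' @param eps_hb Hydrogen-bond well depth (kT, > 0 attractive). With
#'   `eps_hb = 0` bond formation is disabled entirely.
#' @param hb_cutoff Bond formation/breaking distance (sigma).
#' @param max_bonds_per_bead Bond valence per bead.
#' @param nanoparticles Data frame with columns `diameter`,
#'   `adsorption_energy`, `shell_thickness` (sigma/kT), one row per particle,
#'   or `NULL` for none.
#' @param move_weights Probabilities for pivot, crankshaft, kink-jump and
#'   translation moves; must sum to 1.
#' @param n_relax_steps,n_production_steps,n_analysis_steps Step counts for
#'   the relaxation run, the production run, and the trailing analysis window
#'   (`n_analysis_steps <= n_production_steps`).
#' @param snapshot_stride Steps between cluster snapshots in the analysis
#'   window.
#' @param n_replicates Default replicate count for [size_sweep()].
#' @param seed Base seed; replicate `r` runs with `seed + r`.
#' @param sigma_nm Physical length of one sigma, in nm.
#' @param adsorbed_bond_block Bar adsorbed beads from forming new bonds.
#' @param cluster_np_contact Also merge chains touching the same nanoparticle
#'   shell when clustering (off by default: aggregates are defined by
#'   hydrogen-bond connectivity).
#' @param crankshaft_max_angle Maximum crankshaft rotation angle (radians).
#'
#' @return A validated `sim_config` object (a named list).
#' @seealso [sim_preset()], [run_simulation()], [size_sweep()]
#' @export
#' @examples
#' cfg <- sim_config(box_length = 12, n_chains = 4, n_relax_steps = 10,
#'                   n_production_steps = 100, n_analysis_steps = 50,
#'                   snapshot_stride = 25)
#' cfg$n_chains
sim_config <- function(box_length = 20,
                       n_chains = 100,
                       chain_length = 8,
                       bead_diameter = 1,
                       bond_length = 1,
                       eps_hb = 4,
                       hb_cutoff = 1.2,
                       max_bonds_per_bead = 2,
                       nanoparticles = NULL,
                       move_weights = c(pivot = 0.25, crankshaft = 0.25,
                                        kink_jump = 0.25, translation = 0.25),
                       n_relax_steps = 1e4,
                       n_production_steps = 1e5,
                       n_analysis_steps = 1e4,
                       snapshot_stride = 1e3,
                       n_replicates = 5,
                       seed = 1L,
                       sigma_nm = 0.5,
                       adsorbed_bond_block = TRUE,
                       cluster_np_contact = FALSE,
                       crankshaft_max_angle = pi / 2) {
  if (is.null(nanoparticles)) {
    nanoparticles <- tibble::tibble(diameter = double(),
                                    adsorption_energy = double(),
                                    shell_thickness = double())
  }
  nanoparticles <- tibble::as_tibble(nanoparticles)
  cfg <- list(
    box_length = as.numeric(box_length),
    n_chains = as.integer(n_chains),
    chain_length = as.integer(chain_length),
    bead_diameter = as.numeric(bead_diameter),
    bond_length = as.numeric(bond_length),
    eps_hb = as.numeric(eps_hb),
    hb_cutoff = as.numeric(hb_cutoff),
    max_bonds_per_bead = as.integer(max_bonds_per_bead),
    nanoparticles = nanoparticles,
    move_weights = as.numeric(move_weights),
    n_relax_steps = as.integer(n_relax_steps),
    n_production_steps = as.integer(n_production_steps),
    n_analysis_steps = as.integer(n_analysis_steps),
    snapshot_stride = as.integer(snapshot_stride),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    sigma_nm = as.numeric(sigma_nm),
    adsorbed_bond_block = isTRUE(adsorbed_bond_block),
    cluster_np_contact = isTRUE(cluster_np_contact),
    crankshaft_max_angle = as.numeric(crankshaft_max_angle)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$box_length) || cfg$box_length <= 0) {
    stop("box_length must be positive", call. = FALSE)
  }
  if (cfg$chain_length < 3) {
    stop("chain_length must be >= 3 (interior beads are needed for ",
         "crankshaft and kink-jump moves)", call. = FALSE)
  }
  if (cfg$n_chains < 1) stop("n_chains must be >= 1", call. = FALSE)
  if (length(cfg$move_weights) != 4 || any(cfg$move_weights < 0)) {
    stop("move_weights must be 4 non-negative probabilities", call. = FALSE)
  }
  if (abs(sum(cfg$move_weights) - 1) > 1e-8) {
    stop("move_weights must sum to 1", call. = FALSE)
  }
  if (cfg$n_analysis_steps > cfg$n_production_steps) {
    stop("n_analysis_steps must not exceed n_production_steps", call. = FALSE)
  }
  np <- cfg$nanoparticles
  need <- c("diameter", "adsorption_energy", "shell_thickness")
  if (!all(need %in% names(np))) {
    stop("nanoparticles needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(np) > 0) {
    if (any(np$diameter <= 0) || any(np$shell_thickness < 0)) {
      stop("nanoparticle diameters must be positive and shells non-negative",
           call. = FALSE)
    }
    if (cfg$box_length <= 2 * max(np$diameter)) {
      stop("box_length must exceed twice the largest nanoparticle diameter",
           call. = FALSE)
    }
  }
  if (cfg$hb_cutoff < cfg$bead_diameter) {
    stop("hb_cutoff must be at least bead_diameter", call. = FALSE)
  }
  invisible(cfg)
}

#' Preset simulation configurations
#'
#' * `"desk"`: a small system for routine work — box 20 sigma, 100 chains,
#'   1e4 relaxation + 1e5 production steps with the last 1e4 analysed,
#'   5 replicates.
#' * `"paper2020"`: the full published geometry — box 77.4 sigma (38.7 nm at
#'   0.5 nm/sigma), 1330 chains, 1e4 relaxation + 1e6 production steps with
#'   the last 1e5 analysed, 10 replicates.
#' * `"sweep"`: the default base configuration for [size_sweep()] — box
#'   62 sigma, large enough to satisfy the two-diameter headroom rule for a
#'   15 nm (30 sigma) particle, with 680 chains preserving the full-scale
#'   chain number density, 1e4 relaxation + 1e6 production steps with the
#'   last 1e5 analysed, 5 replicates.
#'
#' @param name One of `"desk"`, `"paper2020"`, `"sweep"`.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
#' @examples
#' sim_preset("desk")$n_chains
sim_preset <- function(name = c("desk", "paper2020", "sweep"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    desk = list(),
    paper2020 = list(box_length = 77.4, n_chains = 1330L,
                     n_relax_steps = 1e4, n_production_steps = 1e6,
                     n_analysis_steps = 1e5, n_replicates = 10L),
    sweep = list(box_length = 62, n_chains = 680L,
                 n_relax_steps = 1e4, n_production_steps = 1e6,
                 n_analysis_steps = 1e5, n_replicates = 5L)
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  box %g sigma (%g nm), %d chains x %d beads\n",
              x$box_length, x$box_length * x$sigma_nm, x$n_chains,
              x$chain_length))
  cat(sprintf("  eps_hb %g kT, cutoff %g sigma, valence %d\n",
              x$eps_hb, x$hb_cutoff, x$max_bonds_per_bead))
  cat(sprintf("  %d nanoparticles\n", nrow(x$nanoparticles)))
  cat(sprintf("  steps: relax %d, production %d, analysis %d (stride %d)\n",
              x$n_relax_steps, x$n_production_steps, x$n_analysis_steps,
              x$snapshot_stride))
  invisible(x)
}
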