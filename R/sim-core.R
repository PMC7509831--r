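#' Minimum-image distance under cubic periodic boundaries
#'
#' Euclidean distance between points (or matrices of points, row-wise) taking
#' the nearest periodic image in a cubic box. The result never exceeds
#' `sqrt(3)/2 * box_length`.
#'
#' @param p1,p2 Numeric length-3 vectors or n x 3 matrices of coordinates in
#'   `[0, box_length)`.
#' @param box_length Box edge.
#' @return Numeric vector of distances.
#' @export
#' @examples
#' minimum_image_distance(c(0.1, 0, 0), c(9.9, 0, 0), 10)  # 0.2 across the wall
minimum_image_distance <- function(p1, p2, box_length) {
  p1 <- matrix(as.numeric(p1), ncol = 3)
  p2 <- matrix(as.numeric(p2), ncol = 3)
  d <- p1 - p2
  d <- d - box_length * round(d / box_length)
  sqrt(rowSums(d * d))
}

#' Rotate points about an axis through an origin
#'
#' Rodrigues rotation, used by the pivot and crankshaft moves. Exposed for
#' geometric testing; operates on unwrapped coordinates.
#'
#' @param points n x 3 matrix.
#' @param origin Length-3 vector the axis passes through.
#' @param axis Length-3 direction (normalised internally).
#' @param angle Rotation angle in radians.
#' @return n x 3 matrix of rotated points.
#' @export
rotate_about_axis <- function(points, origin, axis, angle) {
  points <- matrix(as.numeric(points), ncol = 3)
  u <- as.numeric(axis)
  u <- u / sqrt(sum(u^2))
  d <- sweep(points, 2, origin)
  c_ <- cos(angle); s_ <- sin(angle)
  dot <- drop(d %*% u)
  cross <- cbind(u[2] * d[, 3] - u[3] * d[, 2],
                 u[3] * d[, 1] - u[1] * d[, 3],
                 u[1] * d[, 2] - u[2] * d[, 1])
  r <- d * c_ + cross * s_ + outer(dot * (1 - c_), u)
  sweep(r, 2, origin, `+`)
}

new_sim_state <- function(cfg, coords, np, bonds, energy, step = 0L) {
  structure(
    list(coords = coords, np = np, bonds = bonds, energy = energy,
         step = as.integer(step), config = cfg),
    class = "sim_state"
  )
}

np_spec_matrix <- function(cfg) {
  np <- cfg$nanoparticles
  m <- as.matrix(np[, c("diameter", "adsorption_energy", "shell_thickness")])
  storage.mode(m) <- "double"
  m
}

np_state_matrix <- function(state) {
  m <- state$np
  if (is.null(dim(m))) m <- matrix(numeric(0), ncol = 6)
  storage.mode(m) <- "double"
  m
}

#' Initialise a simulation system
#'
#' Places nanoparticles uniformly at random without mutual overlap, grows
#' each chain as a self-avoiding random walk avoiding beads and
#' nanoparticles, scans for initial inter-chain hydrogen bonds
#' (nearest-first under the valence limit) and computes the total energy
#' from scratch. Identical `(config, seed)` pairs give bit-identical states.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `sim_state`: bead coordinates (`coords`, one row per bead in
#'   chain-major order), nanoparticle table (`np`), the bond registry
#'   (`bonds`, two columns of 1-based bead indices), and `energy` in kT.
#' @export
init_system <- function(config, seed = config$seed) {
  validate_sim_config(config)
  res <- cpp_init_system(unclass(config), np_spec_matrix(config),
                         as.integer(seed))
  new_sim_state(config, res$coords, res$np, res$bonds, res$energy)
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state>\n")
  cat(sprintf("  %d beads (%d chains), %d nanoparticles, %d bonds\n",
              nrow(x$coords), x$config$n_chains, nrow(x$np), nrow(x$bonds)))
  cat(sprintf("  energy %.4f kT at step %d\n", x$energy, x$step))
  invisible(x)
}

#' Propose a Monte Carlo move
#'
#' Selects a chain uniformly and a move type according to the configured
#' weights: pivot (rigid rotation of a random chain tail about a random
#' bead), crankshaft (rotation of an interior bead about the axis through
#' its neighbours), kink-jump (resampling an interior bead on the circle
#' preserving both adjacent bond lengths) or whole-chain translation with
#' components uniform in plus/minus one bead diameter. Only the affected
#' beads are recorded.
#'
#' @param state A `sim_state`.
#' @param config Configuration (defaults to the state's own).
#' @param seed Integer seed for the proposal.
#' @return List with `type`, `chain`, `beads` (global 1-based indices) and
#'   `new_coords` (wrapped positions, one row per moved bead).
#' @export
propose_move <- function(state, config = state$config, seed = 1L) {
  cpp_propose(unclass(config), state$coords, np_state_matrix(state),
              state$bonds, as.integer(seed))
}

#' Evaluate a proposed move
#'
#' Applies the hydrogen-bond judgment and energy difference for a proposal:
#' excluded-volume or nanoparticle overlap makes the move infeasible
#' (infinite energy change); otherwise bonds stretched past the cutoff break,
#' eligible new pairs within the cutoff form (nearest-distance first under
#' the valence limit, with adsorbed beads barred when configured), and the
#' energy change sums the bond term and the adsorption-shell term.
#'
#' @param state A `sim_state`.
#' @param proposal As returned by [propose_move()] (all moved beads must
#'   belong to one chain).
#' @param config Configuration (defaults to the state's own).
#' @return List with `feasible`, `delta_energy` (kT; `Inf` when infeasible),
#'   `bonds_broken` and `bonds_formed` (two-column matrices).
#' @export
evaluate_move <- function(state, proposal, config = state$config) {
  cpp_evaluate(unclass(config), state$coords, np_state_matrix(state),
               state$bonds, as.integer(proposal$beads),
               proposal$new_coords)
}

#' Metropolis acceptance
#'
#' Accepts with probability `min(1, exp(-delta_energy))` (energies in kT);
#' an infinite energy change is always rejected. Vectorised over
#' `delta_energy`.
#'
#' @param delta_energy Numeric vector of energy changes (kT).
#' @param u Uniform(0,1) draws; generated with [stats::runif()] when `NULL`.
#' @return Logical vector of acceptances.
#' @export
#' @examples
#' metropolis_accept(c(-1, 0), u = c(0.99, 0.99))  # downhill/neutral: TRUE
metropolis_accept <- function(delta_energy, u = NULL) {
  if (is.null(u)) u <- stats::runif(length(delta_energy))
  stopifnot(length(u) == length(delta_energy))
  ifelse(is.infinite(delta_energy) & delta_energy > 0,
         FALSE,
         delta_energy <= 0 | u < exp(-pmin(delta_energy, 700)))
}

#' Recompute the total system energy from scratch
#'
#' @param state A `sim_state`.
#' @param config Configuration (defaults to the state's own).
#' @return Energy in kT.
#' @export
full_system_energy <- function(state, config = state$config) {
  cpp_full_energy(unclass(config), state$coords, np_state_matrix(state),
                  state$bonds)
}

#' Scan a state for invariant violations
#'
#' Checks excluded volume, nanoparticle exclusion, backbone bond lengths,
#' bond-registry symmetry, the valence limit, inter-chain-only bonds and
#' that registered bonds lie within the cutoff.
#'
#' @param state A `sim_state`.
#' @param config Configuration (defaults to the state's own).
#' @return Invisibly `TRUE`; otherwise an error listing the violations.
#' @export
check_state <- function(state, config = state$config) {
  res <- cpp_check_state(unclass(config), state$coords,
                         np_state_matrix(state), state$bonds)
  if (!isTRUE(res$ok)) {
    stop("state invariants violated: ",
         paste(unique(unlist(res$problems)), collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cluster chains into aggregates
#'
#' Two chains belong to the same aggregate when connected through the
#' relation "share at least one inter-chain hydrogen bond" (transitively).
#' With `merge_np_contact = TRUE`, chains touching the same nanoparticle
#' adsorption shell are additionally merged.
#'
#' @param state A `sim_state`.
#' @param merge_np_contact Merge via shared nanoparticle contact as well.
#' @param config Configuration (defaults to the state's own).
#' @return Integer vector of aggregate sizes (descending); sizes sum to the
#'   number of chains.
#' @export
cluster_chains <- function(state,
                           merge_np_contact = state$config$cluster_np_contact,
                           config = state$config) {
  cpp_cluster_sizes(unclass(config), state$coords, np_state_matrix(state),
                    state$bonds, isTRUE(merge_np_contact))
}

#' Run a full simulation replicate
#'
#' Executes the relaxation then production schedule from a fresh
#' [init_system()] state and collects cluster-size snapshots at the
#' configured stride over the trailing analysis window. Replicate `r` uses
#' seed `config$seed + r`, so replicates (and repeated calls) are exactly
#' reproducible.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index (0 = the base seed itself).
#' @param debug_energy Compare the incrementally updated energy against a
#'   full recomputation every 1000 steps and stop on drift beyond 1e-8 kT.
#' @return An `aggregate_report`: a list with `snapshots` (tibble of `step`,
#'   `sizes` list-column, `n_aggregates`, `mean_size`),
#'   `mean_chains_per_aggregate` (mean over snapshots of the per-snapshot
#'   mean aggregate size), `acceptance_rate`, `replicate`, `seed`, the final
#'   `state`, and the `config`.
#' @export
run_simulation <- function(config, replicate = 0L, debug_energy = FALSE) {
  validate_sim_config(config)
  seed <- config$seed + as.integer(replicate)
  state <- init_system(config, seed = seed)
  n_steps <- config$n_relax_steps + config$n_production_steps
  analysis_start <- n_steps - config$n_analysis_steps
  res <- cpp_run(unclass(config), state$coords, np_state_matrix(state),
                 state$bonds, as.integer(n_steps),
                 as.integer(analysis_start),
                 as.integer(config$snapshot_stride),
                 as.integer(seed + 1000003L),  # run stream distinct from init
                 isTRUE(debug_energy), isTRUE(config$cluster_np_contact))
  sizes <- res$snapshots
  snapshots <- tibble::tibble(
    step = as.integer(res$snapshot_steps),
    sizes = sizes,
    n_aggregates = vapply(sizes, length, integer(1)),
    mean_size = vapply(sizes, function(s) config$n_chains / length(s),
                       numeric(1))
  )
  final_state <- new_sim_state(config, res$coords, state$np, res$bonds,
                               res$energy, step = n_steps)
  structure(
    list(snapshots = snapshots,
         mean_chains_per_aggregate = mean(snapshots$mean_size),
         acceptance_rate = res$accepted / res$proposed,
         replicate = as.integer(replicate),
         seed = as.integer(seed),
         state = final_state,
         config = config),
    class = "aggregate_report"
  )
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat("<aggregate_report>\n")
  cat(sprintf("  replicate %d (seed %d): mean chains per aggregate %.3f\n",
              x$replicate, x$seed, x$mean_chains_per_aggregate))
  cat(sprintf("  %d snapshots, acceptance rate %.3f\n",
              nrow(x$snapshots), x$acceptance_rate))
  invisible(x)
}

#' @rdname tidy.npamyloid
#' @export
tidy.aggregate_report <- function(x, ...) {
  dplyr::mutate(x$snapshots,
                replicate = x$replicate,
                seed = x$seed,
                .before = 1)
}

#' @rdname glance.npamyloid
#' @export
glance.aggregate_report <- function(x, ...) {
  tibble::tibble(
    mean_chains_per_aggregate = x$mean_chains_per_aggregate,
    n_snapshots = nrow(x$snapshots),
    acceptance_rate = x$acceptance_rate,
    replicate = x$replicate,
    seed = x$seed
  )
}

#' @export
autoplot.aggregate_report <- function(object, ...) {
  ggplot2::ggplot(object$snapshots,
                  ggplot2::aes(x = .data$step, y = .data$mean_size)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Monte Carlo step",
                  y = "Mean chains per aggregate") +
    ggplot2::theme_minimal()
}
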