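# Boltzmann constant in kcal/(mol K)
.kB <- 0.0019872041

#' Monte Carlo sampler state
#'
#' @param config current dihedral configuration (degrees).
#' @param energy its energy under the active energy model (kcal/mol).
#' @param temperature simulation temperature in Kelvin (> 0).
#' @return an object of class `mc_state` with step / acceptance / rejection /
#'   gate-skip / energy-call counters initialized to zero.
#' @export
mc_state <- function(config, energy, temperature = 300) {
  stopifnot(temperature > 0, is.finite(energy))
  structure(list(config = canonical_angle(as.numeric(config)),
                 energy = energy, temperature = temperature,
                 step = 0L, n_accepted = 0L, n_rejected = 0L,
                 n_gate_skips = 0L, n_energy_calls = 0L),
            class = "mc_state")
}

#' @export
print.mc_state <- function(x, ...) {
  cat(sprintf("<mc_state> step %d | E = %.4f kcal/mol | T = %g K | acc %d, rej %d (gate-skipped %d), energy calls %d\n",
              x$step, x$energy, x$temperature, x$n_accepted, x$n_rejected,
              x$n_gate_skips, x$n_energy_calls))
  invisible(x)
}

#' One Metropolis Monte Carlo step, optionally classifier-gated
#'
#' With a gate present the proposal is first classified: a high-energy
#' verdict rejects it outright without ever calling the energy model (the
#' gate-skip counter is incremented) — the cheap pre-filter that avoids
#' expensive evaluations of irrelevant conformations. Otherwise the move is
#' accepted with probability `min(1, exp(-dE / (kB T)))`,
#' `kB = 0.0019872041 kcal/(mol K)`, so downhill moves are always accepted.
#' A non-finite proposal energy rejects the move with a warning.
#'
#' Uses one uniform random number for the acceptance decision (none for
#' downhill or gate-rejected moves).
#'
#' @param state an [mc_state()].
#' @param proposal proposed configuration (degrees, same length).
#' @param energy_model `function(config) -> energy (kcal/mol)`.
#' @param gate optional [train_classifier_ensemble()] ensemble.
#' @return the updated `mc_state`, with an `accepted` attribute.
#' @export
metropolis_step <- function(state, proposal, energy_model, gate = NULL) {
  stopifnot(inherits(state, "mc_state"),
            length(proposal) == length(state$config))
  proposal <- canonical_angle(as.numeric(proposal))
  state$step <- state$step + 1L
  if (!is.null(gate)) {
    verdict <- classify(gate, proposal)
    if (!verdict$is_low) {
      state$n_gate_skips <- state$n_gate_skips + 1L
      state$n_rejected <- state$n_rejected + 1L
      attr(state, "accepted") <- FALSE
      return(state)
    }
  }
  e_new <- energy_model(proposal)
  state$n_energy_calls <- state$n_energy_calls + 1L
  if (!is.finite(e_new)) {
    warning("non-finite proposal energy; move rejected")
    state$n_rejected <- state$n_rejected + 1L
    attr(state, "accepted") <- FALSE
    return(state)
  }
  dE <- e_new - state$energy
  accept <- dE <= 0 ||
    stats::runif(1) < exp(-dE / (.kB * state$temperature))
  if (accept) {
    state$config <- proposal
    state$energy <- e_new
    state$n_accepted <- state$n_accepted + 1L
  } else {
    state$n_rejected <- state$n_rejected + 1L
  }
  attr(state, "accepted") <- accept
  state
}

#' Run a Metropolis Monte Carlo trajectory over dihedral space
#'
#' Proposals perturb one uniformly chosen dihedral by a uniform offset in
#' `[-proposal_width, +proposal_width]` degrees. The trajectory is
#' reproducible given the seed. With a gate, proposals classified
#' high-energy are rejected without an energy evaluation, so the chain
#' samples the energy model restricted to the classifier's low-energy
#' region.
#'
#' @param initial starting configuration (degrees) or an [mc_state()].
#' @param energy_model `function(config) -> energy (kcal/mol)`.
#' @param n_steps number of Monte Carlo steps (>= 1).
#' @param gate optional classifier ensemble.
#' @param proposal_width half-width of the single-angle move, degrees.
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @param record keep the full per-step trajectory (step, angles, energy,
#'   accepted); disable for long exploratory runs.
#' @return an object of class `mc_run`: `state` (final), `summary`
#'   (acceptance rate, gate-skip rate, energy-call count, energy trace
#'   quantiles) and, when recorded, `trajectory` (a data frame).
#' @export
run_mc <- function(initial, energy_model, n_steps, gate = NULL,
                   proposal_width = 30, temperature = 300, seed = 1L,
                   record = TRUE) {
  stopifnot(n_steps >= 1, proposal_width > 0)
  if (!inherits(initial, "mc_state")) {
    e0 <- energy_model(canonical_angle(as.numeric(initial)))
    initial <- mc_state(initial, e0, temperature)
    initial$n_energy_calls <- 1L
  }
  state <- initial
  n_d <- length(state$config)
  if (record) {
    traj_angles <- matrix(NA_real_, n_steps, n_d)
    traj_energy <- numeric(n_steps)
    traj_accepted <- logical(n_steps)
  }
  energies <- numeric(n_steps)
  with_seed(seed, {
    for (s in seq_len(n_steps)) {
      d <- sample.int(n_d, 1L)
      proposal <- state$config
      proposal[d] <- proposal[d] + stats::runif(1, -proposal_width,
                                                proposal_width)
      state <- metropolis_step(state, proposal, energy_model, gate)
      energies[s] <- state$energy
      if (record) {
        traj_angles[s, ] <- state$config
        traj_energy[s] <- state$energy
        traj_accepted[s] <- attr(state, "accepted")
      }
    }
  })
  out <- list(
    state = state,
    summary = list(
      n_steps = n_steps,
      acceptance_rate = state$n_accepted / n_steps,
      gate_skip_rate = state$n_gate_skips / n_steps,
      n_energy_calls = state$n_energy_calls,
      temperature = temperature,
      proposal_width = proposal_width,
      seed = as.integer(seed),
      energy_trace = stats::quantile(energies, c(0, .25, .5, .75, 1))))
  if (record) {
    traj <- as.data.frame(traj_angles)
    names(traj) <- sprintf("dihedral_%d_deg", seq_len(n_d))
    out$trajectory <- cbind(data.frame(step = seq_len(n_steps)), traj,
                            data.frame(energy_kcal_mol = traj_energy,
                                       accepted = traj_accepted))
  }
  structure(out, class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("<mc_run> %d steps | acceptance %.3f | gate-skip %.3f | %d energy calls | final E %.4f kcal/mol\n",
              x$summary$n_steps, x$summary$acceptance_rate,
              x$summary$gate_skip_rate, x$summary$n_energy_calls,
              x$state$energy))
  invisible(x)
}

#' Write a Monte Carlo trajectory to a delimited file
#'
#' @param run an [run_mc()] result (with `record = TRUE`).
#' @param path file path (CSV: step, angles, energy, accepted flag).
#' @export
write_trajectory <- function(run, path) {
  stopifnot(inherits(run, "mc_run"))
  if (is.null(run$trajectory))
    stop("run was not recorded; rerun with record = TRUE", call. = FALSE)
  utils::write.csv(run$trajectory, path, row.names = FALSE)
  invisible(path)
}
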