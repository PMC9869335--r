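# Staged alchemical coupling of an entire protein: lambda schedules, dummy
# states, and per-state sampling for one coupling leg.

#' Default lambda schedule for the soft-core sterics stage
#'
#' Dense near the decoupled end, where most of the free-energy change
#' occurs: intermediates at 0.005, 0.01, 0.015, 0.02, 0.04, 0.06, 0.08, 0.1,
#' 0.2, 0.3, 0.5, 0.7, 0.9 plus both endpoints (15 states).
#' @return Strictly increasing numeric vector including 0 and 1.
#' @export
default_lj_schedule <- function() {
  c(0, 0.005, 0.01, 0.015, 0.02, 0.04, 0.06, 0.08, 0.1, 0.2, 0.3, 0.5,
    0.7, 0.9, 1)
}

#' Default lambda schedule for the electrostatic stage
#'
#' Linear pathway from 0 to 1 in steps of 0.125 (9 states).
#' @return Strictly increasing numeric vector including 0 and 1.
#' @export
default_elec_schedule <- function() seq(0, 1, by = 0.125)

.check_schedule <- function(lambdas) {
  stopifnot(length(lambdas) >= 2, all(diff(lambdas) > 0),
            lambdas[1] == 0, lambdas[length(lambdas)] == 1)
  lambdas
}

#' Construct the dummy (fully decoupled) endpoint state
#'
#' Verifies that the protein to decouple is present and anchored to its
#' warhead through the pocket springs, then returns the system together with
#' the lambda = 0 alchemical state: all nonbonded terms between that protein
#' and the rest are off, while its internal ENM and the pocket anchors are
#' retained (the anchor springs are never perturbed and their contribution
#' cancels between binary and ternary legs).
#'
#' @param system a `cg_system`.
#' @param decouple `"target"` or `"e3"`.
#' @return List with `system` and `state` (an [alch_state] at lambda = 0).
#' @export
make_dummy_state <- function(system, decouple = c("target", "e3")) {
  decouple <- match.arg(decouple)
  if (!any(system$molecule == decouple))
    stop("molecule '", decouple, "' is not present")
  mol_idx <- which(system$molecule == decouple)
  anchors <- system$bonds[system$bonds[, "kind"] == 3, , drop = FALSE]
  has_anchor <- any(anchors[, 1] %in% mol_idx | anchors[, 2] %in% mol_idx)
  if (!has_anchor)
    stop("no pocket anchor springs attach '", decouple,
         "' to its warhead; cannot form a dummy state")
  list(system = system,
       state = alch_state("sterics", lambda_lj = 0, lambda_elec = 0,
                          decoupled_group = decouple))
}

#' Define one alchemical coupling leg
#'
#' A leg couples one protein (from dummy to fully interacting) to the rest
#' of a binary or ternary system, in fixed stage order: first soft-core
#' sterics (WCA plus any nonspecific attraction, one combined stage), then
#' -- if any bead carries charge -- electrostatics on top of full sterics.
#'
#' @param system a `cg_system`.
#' @param decouple `"target"` or `"e3"`.
#' @param stages character vector, subset of `c("sterics",
#'   "electrostatics")` in that order; default includes electrostatics only
#'   when the system carries charges on both sides.
#' @param lj_schedule,elec_schedule lambda schedules.
#' @return An object of class `coupling_leg`.
#' @export
coupling_leg <- function(system, decouple = c("target", "e3"), stages = NULL,
                         lj_schedule = default_lj_schedule(),
                         elec_schedule = default_elec_schedule()) {
  decouple <- match.arg(decouple)
  make_dummy_state(system, decouple)  # validates presence + anchors
  if (is.null(stages)) {
    dec_idx <- system$molecule == decouple
    charged <- any(system$charge[dec_idx] != 0) &&
      any(system$charge[!dec_idx] != 0)
    stages <- if (charged) c("sterics", "electrostatics") else "sterics"
  }
  if (!identical(stages, intersect(c("sterics", "electrostatics"), stages)) ||
      !all(stages %in% c("sterics", "electrostatics")) || !length(stages))
    stop("stages must be a subset of c('sterics', 'electrostatics') in order")
  if (identical(stages, "electrostatics"))
    stop("the electrostatic stage requires the sterics stage before it")
  sched <- list()
  if ("sterics" %in% stages)
    sched$sterics <- .check_schedule(lj_schedule)
  if ("electrostatics" %in% stages)
    sched$electrostatics <- .check_schedule(elec_schedule)
  states <- list()
  for (stg in stages) {
    for (l in sched[[stg]]) {
      states[[length(states) + 1]] <-
        if (stg == "sterics")
          alch_state("sterics", lambda_lj = l, decoupled_group = decouple)
        else
          alch_state("electrostatics", lambda_lj = 1, lambda_elec = l,
                     decoupled_group = decouple)
    }
  }
  structure(list(system = system, decouple = decouple, stages = stages,
                 schedules = sched, states = states),
            class = "coupling_leg")
}

#' @export
print.coupling_leg <- function(x, ...) {
  cat("<coupling_leg> decouple ", x$decouple, " (",
      if (x$system$is_ternary) "ternary" else "binary", "); stages: ",
      paste(sprintf("%s [%d states]", names(x$schedules),
                    lengths(x$schedules)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# deterministic per-(leg, state, trajectory) seed below 2^31
.state_seed <- function(base_seed, state_index, traj_index) {
  as.integer((as.numeric(base_seed) * 97 + state_index * 100003 +
                traj_index * 1009) %% 2147483629)
}

#' Sample every state of a coupling leg
#'
#' Runs `n_traj` independent Brownian-dynamics trajectories per alchemical
#' state (each from the assembled initial geometry, each with its own
#' deterministic seed), removes the equilibration prefix, and evaluates
#' per-frame dU/dlambda plus the lambda-scaled cross-group energy of every
#' frame at every state of the same stage (the inputs for TI, BAR and MBAR).
#'
#' @param leg a [coupling_leg].
#' @param n_traj trajectories per state.
#' @param n_steps integration steps per trajectory.
#' @param stride frame recording stride.
#' @param base_seed base seed; per-trajectory seeds derive deterministically
#'   from `(base_seed, state index, trajectory index)`.
#' @param burn_in leading fraction of frames discarded.
#' @param iparams an [integrator_params] (its `seed` field is ignored).
#' @param ff an [ff_params].
#' @return A list of class `leg_samples`: one [sample_set] per stage, plus
#'   provenance (`ff`, `decouple`, sampling protocol).
#' @export
sample_leg <- function(leg, n_traj = 4, n_steps = 1e5, stride = 500,
                       base_seed = 1, burn_in = 0.2,
                       iparams = integrator_params(), ff = ff_params()) {
  stopifnot(inherits(leg, "coupling_leg"), n_traj >= 1)
  sys <- leg$system
  out <- list()
  state_offset <- 0L
  for (stg in leg$stages) {
    lambdas <- leg$schedules[[stg]]
    K <- length(lambdas)
    lam_lj <- if (stg == "sterics") lambdas else rep(1, K)
    lam_el <- if (stg == "sterics") rep(0, K) else lambdas
    dudl <- vector("list", K)
    u_scaled <- vector("list", K)
    traj_id <- vector("list", K)
    pr <- .pair_table(sys, leg$decouple)
    for (k in seq_len(K)) {
      st <- if (stg == "sterics")
        alch_state("sterics", lambda_lj = lambdas[k],
                   decoupled_group = leg$decouple)
      else alch_state("electrostatics", lambda_lj = 1,
                      lambda_elec = lambdas[k],
                      decoupled_group = leg$decouple)
      dl <- list(); us <- list(); tid <- list()
      for (t in seq_len(n_traj)) {
        ip <- integrator_params(seed = .state_seed(base_seed,
                                                   state_offset + k, t))
        ip$D <- iparams$D; ip$dt <- iparams$dt; ip$kT <- iparams$kT
        tr <- run_trajectory(sys, st, n_steps = n_steps, stride = stride,
                             params = ip, ff = ff)
        tr <- discard_equilibration(tr, burn_in_fraction = burn_in)
        ev <- eval_frames_cpp(tr$frames, sys$bonds, pr, .ff_vector(ff),
                              lam_lj, lam_el, st$lambda_lj, st$lambda_elec,
                              if (stg == "sterics") 1L else 2L)
        dl[[t]] <- ev$dudl
        us[[t]] <- ev$scaled
        tid[[t]] <- rep(t, length(ev$dudl))
      }
      dudl[[k]] <- unlist(dl)
      u_scaled[[k]] <- do.call(rbind, us)
      traj_id[[k]] <- unlist(tid)
    }
    out[[stg]] <- sample_set(lambdas, stage = stg, dudl = dudl,
                             u_scaled = u_scaled, traj_id = traj_id,
                             provenance = list(base_seed = base_seed,
                                               n_traj = n_traj,
                                               n_steps = n_steps,
                                               stride = stride,
                                               burn_in = burn_in))
    state_offset <- state_offset + K
  }
  structure(list(stages = out, decouple = leg$decouple, ff = ff,
                 is_ternary = sys$is_ternary),
            class = "leg_samples")
}

#' @export
print.leg_samples <- function(x, ...) {
  cat("<leg_samples> decouple ", x$decouple, " (",
      if (x$is_ternary) "ternary" else "binary", ")\n", sep = "")
  for (s in names(x$stages)) print(x$stages[[s]])
  invisible(x)
}

#' Per-stage sample container for free-energy estimation
#'
#' @param lambdas the stage's lambda schedule (length K).
#' @param stage `"sterics"` or `"electrostatics"`.
#' @param dudl list of K numeric vectors: per-frame dU/dlambda at the
#'   sampling state.
#' @param u_scaled list of K matrices (frames x K): the lambda-scaled
#'   cross-group energy of each frame re-evaluated at every state of the
#'   stage.  Unscaled terms are omitted; they cancel in every energy
#'   difference.
#' @param traj_id list of K integer vectors: originating trajectory of each
#'   frame.
#' @param provenance free-form list (seeds, burn-in, protocol).
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(lambdas, stage, dudl, u_scaled, traj_id = NULL,
                       provenance = list()) {
  K <- length(lambdas)
  stopifnot(length(dudl) == K, length(u_scaled) == K)
  n <- vapply(dudl, length, integer(1))
  for (k in seq_len(K)) {
    stopifnot(nrow(u_scaled[[k]]) == n[k], ncol(u_scaled[[k]]) == K)
  }
  if (is.null(traj_id)) traj_id <- lapply(n, function(m) rep(1L, m))
  structure(list(lambdas = lambdas, stage = stage, dudl = dudl,
                 u_scaled = u_scaled, traj_id = traj_id, n = n,
                 provenance = provenance),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> stage ", x$stage, ": ", length(x$lambdas), " states, ",
      paste(range(x$n), collapse = "-"), " samples/state\n", sep = "")
  invisible(x)
}

#' Cross-state energy difference matrix
#'
#' For every configuration sampled from state `i`, the potential-energy
#' difference to every state `j`: `DeltaU_ij(x) = U_j(x) - U_i(x)`.  Only
#' lambda-scaled terms contribute; by construction
#' `DeltaU_ij(x) = -DeltaU_ji(x)` per configuration and `DeltaU_ii = 0`.
#'
#' @param samples a [sample_set].
#' @return List of K matrices; element `i` is `n_i x K` with columns `j`.
#' @export
cross_energy_matrix <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  lapply(seq_along(samples$lambdas), function(i) {
    samples$u_scaled[[i]] - samples$u_scaled[[i]][, i]
  })
}
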