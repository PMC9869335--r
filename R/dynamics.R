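# Overdamped Langevin (Brownian) sampling at a fixed alchemical state.

#' Integrator parameters
#'
#' Defaults follow the production CG protocol: a single diffusion
#' coefficient of 253 nm^2/s for every bead and a 30 ns time step (no
#' hydrodynamic interactions, no inertia).
#'
#' @param diffusion_coefficient nm^2/s.
#' @param dt time step, s.
#' @param kT energy unit (1 throughout the package).
#' @param seed RNG seed for the trajectory.
#' @return An object of class `integrator_params`.
#' @export
integrator_params <- function(diffusion_coefficient = 253, dt = 30e-9,
                              kT = 1, seed = 1L) {
  stopifnot(diffusion_coefficient > 0, dt > 0, kT > 0)
  structure(list(D = diffusion_coefficient, dt = dt, kT = kT,
                 seed = as.integer(seed)),
            class = "integrator_params")
}

#' One overdamped Langevin step
#'
#' `dx = (D/kT) F dt + sqrt(2 D dt) xi` with `xi ~ N(0, 1)` per coordinate.
#' This is the reference R form; [run_trajectory] uses the compiled loop.
#'
#' @param positions n x 3 matrix, nm.
#' @param forces n x 3 matrix, kT/nm.
#' @param params an [integrator_params].
#' @return Updated positions.
#' @export
brownian_step <- function(positions, forces, params = integrator_params()) {
  if (any(!is.finite(forces))) stop("non-finite force in brownian_step")
  positions + (params$D * params$dt / params$kT) * forces +
    sqrt(2 * params$D * params$dt) *
      matrix(rnorm(length(positions)), nrow(positions), 3)
}

#' Run a Brownian-dynamics trajectory at a fixed alchemical state
#'
#' Frames (including the initial configuration) are recorded every `stride`
#' steps, so `floor(n_steps / stride) + 1` frames are stored.  The RNG is
#' seeded from `params$seed`, making trajectories bit-reproducible.
#'
#' @param system a `cg_system` (or any list with `pos`, `bonds` and the bead
#'   fields used by [total_energy]).
#' @param state an [alch_state].
#' @param n_steps number of integration steps.
#' @param stride frame recording stride, steps.
#' @param params an [integrator_params].
#' @param ff an [ff_params].
#' @param mobile logical vector marking beads free to move (default: all).
#' @return An object of class `cg_trajectory`: `frames` (n x 3 x F array),
#'   `state`, `seed`, `n_steps`, `stride`, `final` positions.
#' @export
run_trajectory <- function(system, state = alch_state(), n_steps, stride = 500,
                           params = integrator_params(), ff = ff_params(),
                           mobile = NULL) {
  stopifnot(n_steps >= 0, stride >= 1)
  if (is.null(mobile)) mobile <- rep(TRUE, nrow(system$pos))
  pr <- .pair_table(system, state$decoupled_group)
  set.seed(params$seed)
  res <- run_bd_cpp(system$pos, system$bonds, pr, .ff_vector(ff),
                    state$lambda_lj, state$lambda_elec,
                    as.integer(n_steps), as.integer(stride),
                    params$D, params$dt, params$kT, mobile)
  structure(list(frames = res$frames, final = res$final, state = state,
                 seed = params$seed, n_steps = n_steps, stride = stride,
                 ff = ff, iparams = params, mobile = mobile,
                 rng_state = get(".Random.seed", envir = globalenv())),
            class = "cg_trajectory")
}

#' Continue a trajectory from its stored frame and RNG state
#'
#' Restores the random-number-generator state captured at the end of
#' `trajectory` and integrates onward from its final positions, so that a
#' run of `n1 + n2` steps and a run of `n1` steps followed by
#' `continue_trajectory(..., n_steps = n2)` produce identical samples.
#'
#' @param trajectory a `cg_trajectory`.
#' @param system the system it was generated from.
#' @param n_steps additional steps.
#' @return A `cg_trajectory` for the continuation segment (its first frame is
#'   the stored final frame).
#' @export
continue_trajectory <- function(trajectory, system, n_steps) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  pr <- .pair_table(system, trajectory$state$decoupled_group)
  assign(".Random.seed", trajectory$rng_state, envir = globalenv())
  res <- run_bd_cpp(trajectory$final, system$bonds, pr,
                    .ff_vector(trajectory$ff),
                    trajectory$state$lambda_lj, trajectory$state$lambda_elec,
                    as.integer(n_steps), as.integer(trajectory$stride),
                    trajectory$iparams$D, trajectory$iparams$dt,
                    trajectory$iparams$kT, trajectory$mobile)
  structure(list(frames = res$frames, final = res$final,
                 state = trajectory$state, seed = trajectory$seed,
                 n_steps = n_steps, stride = trajectory$stride,
                 ff = trajectory$ff, iparams = trajectory$iparams,
                 mobile = trajectory$mobile,
                 rng_state = get(".Random.seed", envir = globalenv())),
            class = "cg_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", dim(x$frames)[3], " frames (", x$n_steps,
      " steps, stride ", x$stride, "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$frames)[3]

#' Discard unequilibrated leading frames
#'
#' Either removes a fixed leading fraction, or (method `"auto"`) compares
#' block means of an observable series against the mean and spread of the
#' final half and drops leading blocks that deviate.  For a trajectory the
#' detector runs on the total bonded energy of each frame.
#'
#' @param x a `cg_trajectory`, or a numeric observable series.
#' @param burn_in_fraction leading fraction to remove (method `"fraction"`).
#' @param method `"fraction"` or `"auto"`.
#' @param n_blocks number of blocks for the detector.
#' @param system required to compute the detector observable when `x` is a
#'   trajectory and `method = "auto"`.
#' @return Same type as `x` with the equilibration prefix removed; the number
#'   of dropped frames is recorded in attribute `"discarded"`.
#' @export
discard_equilibration <- function(x, burn_in_fraction = 0.2,
                                  method = c("fraction", "auto"),
                                  n_blocks = 20, system = NULL) {
  method <- match.arg(method)
  if (inherits(x, "cg_trajectory")) {
    nf <- n_frames(x)
    drop <- if (method == "fraction") floor(burn_in_fraction * nf)
    else {
      if (is.null(system)) stop("method 'auto' on a trajectory needs `system`")
      obs <- vapply(seq_len(nf),
                    function(f) bonded_energy(system, x$frames[, , f]),
                    numeric(1))
      .burnin_auto(obs, n_blocks)
    }
    if (drop >= nf) stop("all frames would be discarded")
    x$frames <- x$frames[, , (drop + 1):nf, drop = FALSE]
    attr(x, "discarded") <- drop
    return(x)
  }
  n <- length(x)
  drop <- if (method == "fraction") floor(burn_in_fraction * n)
          else .burnin_auto(x, n_blocks)
  if (drop >= n) stop("all frames would be discarded")
  out <- x[(drop + 1):n]
  attr(out, "discarded") <- drop
  out
}

# block-mean changepoint heuristic: reference = block means of the last half;
# drop leading blocks whose mean deviates by > 3 sd of the reference block
# means (or a small floor, for noiseless series)
.burnin_auto <- function(obs, n_blocks = 20) {
  n <- length(obs)
  if (n < 2 * n_blocks) return(0L)
  block <- ceiling(seq_along(obs) / (n / n_blocks))
  m <- tapply(obs, block, mean)
  ref <- m[(n_blocks %/% 2 + 1):n_blocks]
  tol <- max(3 * sd(ref), 1e-9 * (abs(mean(ref)) + 1))
  bad <- abs(m - mean(ref)) > tol
  first_good <- 1L
  for (b in seq_len(n_blocks)) {
    if (bad[b]) first_good <- b + 1L else break
  }
  if (first_good == 1L) return(0L)
  sum(block < first_good)
}
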