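# Fully synthetic test systems and analytic oracles.  Oracle free energies
# are always computed by code independent of the sampling stack (closed form
# or direct quadrature).

# near-uniform points on a sphere (Fibonacci lattice)
.fib_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a synthetic coarse-grained protein
#'
#' Deterministic per seed.  Beads are packed on the chosen shape with
#' spacing suited to the default ENM cutoff (1.1 nm), small positional
#' jitter is added, the ENM is built, and the pocket defaults to the bead
#' with the largest x coordinate (the "front" of the protein).
#'
#' @param n_beads number of beads (>= 2).
#' @param shape `"sphere_cluster"`, `"rod"`, or `"disc"`.
#' @param net_charge either a single integer (distributed as unit charges
#'   over the first `|net_charge|` beads) or a vector of per-bead charges.
#' @param pocket pocket bead indices, or `NULL` for the +x extreme bead.
#' @param seed RNG seed for the jitter.
#' @param jitter jitter amplitude, nm.
#' @param enm_cutoff,enm_k ENM parameters passed to [build_enm].
#' @return A [cg_protein] with ENM and pocket set, source `"synthetic"`.
#' @export
make_toy_protein <- function(n_beads = 10, shape = c("sphere_cluster", "rod",
                                                     "disc"),
                             net_charge = 0, pocket = NULL, seed = 1,
                             jitter = 0.03, enm_cutoff = 1.1, enm_k = 500) {
  shape <- match.arg(shape)
  n_beads <- as.integer(n_beads)
  stopifnot(n_beads >= 2)
  pos <- switch(shape,
    rod = cbind(0.8 * (seq_len(n_beads) - 1), 0, 0),
    disc = {
      # hexagonal spiral in the xy plane, spacing 0.9 nm
      g <- 0.9
      pts <- matrix(0, 0, 3)
      ring <- 0
      while (nrow(pts) < n_beads) {
        if (ring == 0) pts <- rbind(pts, c(0, 0, 0))
        else {
          ang <- seq(0, 2 * pi, length.out = 6 * ring + 1)[-(6 * ring + 1)]
          pts <- rbind(pts, cbind(g * ring * cos(ang), g * ring * sin(ang), 0))
        }
        ring <- ring + 1
      }
      pts[seq_len(n_beads), , drop = FALSE]
    },
    sphere_cluster = {
      # shell radius giving ~0.9 nm nearest-neighbour spacing
      r <- max(0.45, 0.9 * sqrt(sqrt(3) * n_beads / (8 * pi)))
      .fib_sphere(n_beads, r)
    }
  )
  set.seed(seed)
  pos <- pos + jitter * matrix(rnorm(3 * n_beads), n_beads, 3)
  dmin <- min(stats::dist(pos))
  if (dmin < 0.4)
    stop("infeasible packing: minimum bead distance ", format(dmin), " nm")
  charge <- if (length(net_charge) == n_beads) as.numeric(net_charge)
  else {
    q <- rep(0, n_beads)
    nc <- as.integer(net_charge)
    if (abs(nc) > n_beads) stop("net_charge exceeds one unit charge per bead")
    if (nc != 0) q[seq_len(abs(nc))] <- sign(nc)
    q
  }
  p <- cg_protein(pos, radius = SIGMA_PROTEIN / 2, charge = charge,
                  source = "synthetic")
  p <- build_enm(p, cutoff = enm_cutoff, k = enm_k)
  p$pocket <- if (is.null(pocket)) which.max(pos[, 1]) else as.integer(pocket)
  p
}

#' Analytic oracle: isotropic harmonic well with lambda-switched stiffness
#'
#' A single 3-D bead in a well `U(r; lambda) = 0.5 k(lambda) |r|^2` with
#' linear interpolation `k(lambda) = (1 - lambda) k1 + lambda k2`.  The
#' partition function is Gaussian, so
#' `DeltaG = (3/2) ln(k2 / k1)` kT exactly.
#'
#' @param k1,k2 endpoint stiffnesses, kT/nm^2.
#' @return List of class `oracle_system` with `dg_exact`, the derivation tag,
#'   and closed-form helpers (`k_of_lambda`, `u_fn`, `dudl_fn`).
#' @export
make_harmonic_oracle <- function(k1, k2) {
  stopifnot(k1 > 0, k2 > 0)
  structure(list(
    description = "3-D isotropic harmonic well, lambda-linear stiffness",
    derivation = "closed_form",
    k1 = k1, k2 = k2,
    dg_exact = 1.5 * log(k2 / k1),
    k_of_lambda = function(l) (1 - l) * k1 + l * k2,
    u_fn = function(r2, l) 0.5 * ((1 - l) * k1 + l * k2) * r2,
    dudl_fn = function(r2) 0.5 * (k2 - k1) * r2
  ), class = "oracle_system")
}

#' Draw exact Boltzmann samples for the harmonic-switch oracle
#'
#' Each state's configuration distribution is an isotropic Gaussian with
#' variance `kT / k(lambda)` per coordinate, so samples are drawn exactly
#' (no dynamics involved) and assembled into a [sample_set] for the
#' estimators.
#'
#' @param oracle a [make_harmonic_oracle] result.
#' @param lambdas state schedule in `[0, 1]`.
#' @param n_per_state samples per state.
#' @param seed RNG seed.
#' @param n_traj nominal replicate count (samples are split evenly so that
#'   replicate uncertainties can be formed).
#' @return A [sample_set].
#' @export
draw_harmonic_samples <- function(oracle, lambdas = seq(0, 1, by = 0.125),
                                  n_per_state = 1e4, seed = 1, n_traj = 4) {
  stopifnot(inherits(oracle, "oracle_system"))
  set.seed(seed)
  K <- length(lambdas)
  dudl <- vector("list", K)
  u_scaled <- vector("list", K)
  traj_id <- vector("list", K)
  for (k in seq_len(K)) {
    s <- sqrt(1 / oracle$k_of_lambda(lambdas[k]))
    r2 <- rowSums(matrix(rnorm(3 * n_per_state, sd = s), ncol = 3)^2)
    dudl[[k]] <- oracle$dudl_fn(r2)
    u_scaled[[k]] <- outer(r2, lambdas, function(r2_, l) oracle$u_fn(r2_, l))
    traj_id[[k]] <- rep(seq_len(n_traj), length.out = n_per_state)
  }
  sample_set(lambdas, stage = "sterics", dudl = dudl, u_scaled = u_scaled,
             traj_id = traj_id,
             provenance = list(oracle = oracle$description, seed = seed))
}

#' Quadrature oracle: a WCA bead tethered near a fixed bead
#'
#' One mobile bead tethered by a radial harmonic spring
#' `0.5 k_tether (r - r0)^2` to a fixed bead, with a WCA pair potential
#' coupled alchemically.  The exact coupling free energy is computed by
#' direct 3-D midpoint quadrature of the configuration integral,
#' `DeltaG = -ln [ int exp(-(U_t + U_wca)) dV / int exp(-U_t) dV ]`,
#' with the grid refined until the value changes by less than `tol`.
#'
#' @param tether_k spring constant, kT/nm^2.
#' @param tether_r0 spring rest length, nm (the tether holds the mobile bead
#'   near this distance; inside the WCA core it creates a real insertion
#'   cost).
#' @param sigma summed pair radii, nm.
#' @param eps WCA strength, kT.
#' @param tol quadrature refinement tolerance, kT.
#' @return List of class `oracle_system` with `dg_exact`
#'   (tag `"quadrature"`) and `system`, a two-bead `cg_system` (fixed bead =
#'   a one-bead "e3", mobile bead = a one-bead "target" to be coupled) ready
#'   for [run_leg] with `mobile = c(FALSE, TRUE)` semantics handled by
#'   [sample_pair_oracle].
#' @export
make_pair_oracle <- function(tether_k = 50, tether_r0 = 0.5, sigma = 0.8,
                             eps = 1, tol = 1e-3) {
  stopifnot(tether_k > 0, tether_r0 >= 0, sigma > 0, eps > 0)
  u_wca <- function(r) {
    s6 <- ifelse(r > 0, (sigma / r)^6, Inf)
    ifelse(r < 2^(1 / 6) * sigma, 4 * eps * (s6^2 - s6) + eps, 0)
  }
  u_t <- function(r) 0.5 * tether_k * (r - tether_r0)^2
  L <- tether_r0 + 6 / sqrt(tether_k) + sigma  # integrand support
  quad <- function(m) {
    g <- seq(-L, L, length.out = m + 1)
    mid <- (g[-1] + g[-length(g)]) / 2
    h <- diff(g)[1]
    r2xy <- outer(mid^2, mid^2, "+")
    num <- 0; den <- 0
    for (z in mid) {
      r <- sqrt(r2xy + z^2)
      bt <- exp(-u_t(r))
      num <- num + sum(bt * exp(-u_wca(r)))
      den <- den + sum(bt)
    }
    -log(num / den)  # h^3 volume elements cancel
  }
  m <- 60
  dg <- quad(m)
  repeat {
    m <- round(m * 1.5)
    if (m > 2000) stop("quadrature did not converge")
    dg_new <- quad(m)
    if (abs(dg_new - dg) < tol) { dg <- dg_new; break }
    dg <- dg_new
  }
  # bead 1: tether anchor (bonded to the mobile bead, hence excluded from
  # nonbonded terms); bead 2: the WCA source, co-located with the anchor;
  # bead 3: the mobile bead to be coupled
  pos <- rbind(c(0, 0, 0), c(0, 0, 0), c(max(tether_r0, 0.1), 0, 0))
  sys <- structure(list(
    pos = pos, radius = c(sigma / 2, sigma / 2, sigma / 2),
    charge = c(0, 0, 0),
    group = c("e3", "e3", "target"), molecule = c("e3", "e3", "target"),
    bonds = cbind(i = 1, j = 3, r0 = max(tether_r0, 1e-6), k = tether_k,
                  kind = 3),
    pocket = list(e3 = 2L, target = 3L), is_ternary = FALSE),
    class = "cg_system")
  structure(list(
    description = "WCA bead radially tethered to a fixed bead",
    derivation = "quadrature", dg_exact = dg, grid_points = m,
    tether_k = tether_k, tether_r0 = tether_r0, sigma = sigma, eps = eps,
    system = sys
  ), class = "oracle_system")
}

#' @export
print.oracle_system <- function(x, ...) {
  cat("<oracle_system> ", x$description, "\n  exact Delta G = ",
      format(x$dg_exact), " kT (", x$derivation, ")\n", sep = "")
  invisible(x)
}

#' Sample the tethered-pair oracle through the full alchemical stack
#'
#' Runs the Brownian-dynamics sterics leg (soft-core schedule) on the
#' two-bead oracle system, with the fixed bead immobile, and estimates the
#' coupling free energy.
#'
#' @param oracle a [make_pair_oracle] result.
#' @param n_traj,n_steps,stride,base_seed,burn_in sampling protocol.
#' @param lj_schedule lambda schedule for the coupling.
#' @param methods estimators to run.
#' @return A [estimate_stage] `free_energy` object.
#' @export
sample_pair_oracle <- function(oracle, n_traj = 4, n_steps = 2e5,
                               stride = 200, base_seed = 1, burn_in = 0.1,
                               lj_schedule = default_lj_schedule(),
                               methods = c("ti", "bar", "mbar")) {
  stopifnot(inherits(oracle, "oracle_system"),
            identical(oracle$derivation, "quadrature"))
  sys <- oracle$system
  ff <- ff_params(eps_wca = oracle$eps)
  leg <- coupling_leg(sys, decouple = "target", stages = "sterics",
                      lj_schedule = lj_schedule)
  lambdas <- leg$schedules$sterics
  K <- length(lambdas)
  pr <- .pair_table(sys, "target")
  dudl <- vector("list", K); u_scaled <- vector("list", K)
  traj_id <- vector("list", K)
  mobile <- c(FALSE, FALSE, TRUE)
  for (k in seq_len(K)) {
    st <- alch_state("sterics", lambda_lj = lambdas[k],
                     decoupled_group = "target")
    dl <- list(); us <- list(); tid <- list()
    for (t in seq_len(n_traj)) {
      ip <- integrator_params(seed = .state_seed(base_seed, k, t))
      tr <- run_trajectory(sys, st, n_steps = n_steps, stride = stride,
                           params = ip, ff = ff, mobile = mobile)
      tr <- discard_equilibration(tr, burn_in_fraction = burn_in)
      ev <- eval_frames_cpp(tr$frames, sys$bonds, pr, .ff_vector(ff),
                            lambdas, rep(0, K), lambdas[k], 0, 1L)
      dl[[t]] <- ev$dudl; us[[t]] <- ev$scaled
      tid[[t]] <- rep(t, length(ev$dudl))
    }
    dudl[[k]] <- unlist(dl)
    u_scaled[[k]] <- do.call(rbind, us)
    traj_id[[k]] <- unlist(tid)
  }
  smp <- sample_set(lambdas, "sterics", dudl, u_scaled, traj_id)
  estimate_stage(smp, methods = methods)
}

#' Build a desk-scale synthetic ternary complex
#'
#' Two toy proteins (sphere clusters) joined by a PROTAC of the requested
#' linker length, assembled with the standard rules.  Deterministic per
#' seed; small enough that the full pipeline runs on one CPU in minutes.
#'
#' @param n_linker linker bead count (1..6 covers the compound series).
#' @param n_beads_target,n_beads_e3 protein sizes, beads.
#' @param charge_target,charge_e3 net charges (or per-bead vectors).
#' @param seed RNG seed.
#' @param ff [ff_params] used for the assembly shake.
#' @return A ternary `cg_system`.
#' @export
make_toy_ternary <- function(n_linker = 3, n_beads_target = 10,
                             n_beads_e3 = 12, charge_target = 0,
                             charge_e3 = 0, seed = 1, ff = ff_params()) {
  target <- make_toy_protein(n_beads_target, "sphere_cluster",
                             net_charge = charge_target, seed = seed)
  e3 <- make_toy_protein(n_beads_e3, "sphere_cluster",
                         net_charge = charge_e3, seed = seed + 1)
  protac <- build_protac(n_linker)
  assemble_ternary(target, e3, protac, params = ff)
}
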