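# Minimal CG force field: WCA volume exclusion, optional nonspecific LJ
# attraction between the two proteins, Debye-Hueckel electrostatics, and
# harmonic bonded terms (ENM, PROTAC chain, pocket anchors).  Alchemical
# scaling applies only to nonbonded terms that cross between the decoupled
# protein and the rest of the system.

#' Force-field parameters
#'
#' @param eps_wca WCA repulsion strength, kT.
#' @param eps_lj well depth of the nonspecific attraction between protein
#'   beads of the two different proteins, kT (0 disables it; the source
#'   trends use 0.125--0.25 kT).
#' @param alpha_softcore soft-core parameter in (0, 1].
#' @param bjerrum_length Bjerrum length, nm (0.7 nm for water at room
#'   temperature).
#' @param debye_length Debye screening length, nm (1.0 nm, roughly 100--150
#'   mM monovalent salt).
#' @param screening_scale multiplier on the Debye length; 10 reproduces the
#'   "10-fold weakened screening" setup.
#' @param lj_cutoff_factor attraction cutoff in units of sigma_ij.
#' @return An object of class `ff_params`.
#' @export
ff_params <- function(eps_wca = 1, eps_lj = 0, alpha_softcore = 0.5,
                      bjerrum_length = 0.7, debye_length = 1.0,
                      screening_scale = 1, lj_cutoff_factor = 3) {
  stopifnot(eps_wca > 0, eps_lj >= 0, alpha_softcore > 0, alpha_softcore <= 1,
            bjerrum_length > 0, debye_length > 0, screening_scale > 0,
            lj_cutoff_factor > 1)
  structure(list(eps_wca = eps_wca, eps_lj = eps_lj,
                 alpha_softcore = alpha_softcore,
                 bjerrum_length = bjerrum_length, debye_length = debye_length,
                 screening_scale = screening_scale,
                 lj_cutoff_factor = lj_cutoff_factor),
            class = "ff_params")
}

.ff_vector <- function(p) {
  c(p$eps_wca, p$eps_lj, p$alpha_softcore, p$bjerrum_length,
    p$debye_length * p$screening_scale, p$lj_cutoff_factor)
}

#' Alchemical state
#'
#' Identifies the coupling stage and the lambda values.  Electrostatics may
#' only be perturbed once volume exclusion is fully on (`lambda_lj = 1`),
#' for numerical stability.
#'
#' @param stage one of `"sterics"`, `"electrostatics"`, `"fully_coupled"`.
#' @param lambda_lj,lambda_elec coupling parameters in `[0, 1]`.
#' @param decoupled_group `"target"`, `"e3"`, or `"none"`.
#' @return An object of class `alch_state`.
#' @export
alch_state <- function(stage = c("fully_coupled", "sterics", "electrostatics"),
                       lambda_lj = 1, lambda_elec = NULL,
                       decoupled_group = "none") {
  stage <- match.arg(stage)
  if (is.null(lambda_elec))
    lambda_elec <- switch(stage, fully_coupled = 1, sterics = 0,
                          electrostatics = 0)
  if (stage == "fully_coupled") lambda_lj <- 1
  stopifnot(lambda_lj >= 0, lambda_lj <= 1, lambda_elec >= 0, lambda_elec <= 1)
  if (lambda_elec > 0 && lambda_lj < 1)
    stop("electrostatics may only be perturbed in the presence of full ",
         "volume exclusion (lambda_lj must be 1 when lambda_elec > 0)")
  if (stage == "electrostatics" && lambda_lj < 1)
    stop("the electrostatic stage starts from fully-on sterics")
  decoupled_group <- match.arg(decoupled_group, c("none", "target", "e3"))
  structure(list(stage = stage, lambda_lj = lambda_lj,
                 lambda_elec = lambda_elec,
                 decoupled_group = decoupled_group),
            class = "alch_state")
}

#' @export
print.alch_state <- function(x, ...) {
  cat(sprintf("<alch_state> %s: lambda_lj = %g, lambda_elec = %g, decoupled: %s\n",
              x$stage, x$lambda_lj, x$lambda_elec, x$decoupled_group))
  invisible(x)
}

# ---- pair potentials (reference R forms; the C++ core mirrors them) -------

#' Weeks-Chandler-Andersen repulsion
#'
#' `4 eps [(sigma/r)^12 - (sigma/r)^6] + eps` for `r < 2^(1/6) sigma`, zero
#' beyond.  `sigma_ij` is the sum of the two bead radii.
#' @param r pair distance, nm (> 0).
#' @param sigma_ij summed radii, nm.
#' @param eps repulsion strength, kT.
#' @return Energy in kT (vectorized).
#' @export
pair_wca <- function(r, sigma_ij, eps = 1) {
  if (any(r <= 0)) stop("WCA diverges at r = 0; use pair_softcore while coupling")
  s6 <- (sigma_ij / r)^6
  ifelse(r < 2^(1 / 6) * sigma_ij, 4 * eps * (s6^2 - s6) + eps, 0)
}

#' Lennard-Jones attraction (nonspecific protein-protein term)
#' @inheritParams pair_wca
#' @param eps_lj well depth, kT.
#' @param cutoff truncation distance, nm (default `3 sigma_ij`, no shift).
#' @return Energy in kT (vectorized).
#' @export
pair_lj <- function(r, sigma_ij, eps_lj, cutoff = 3 * sigma_ij) {
  if (any(r <= 0)) stop("LJ diverges at r = 0; use pair_softcore while coupling")
  s6 <- (sigma_ij / r)^6
  ifelse(r < cutoff, 4 * eps_lj * (s6^2 - s6), 0)
}

#' Soft-core lambda-scaled Lennard-Jones / WCA
#'
#' Beutler-form soft core: with `t = (r/sigma)^6` and `A = alpha (1-lambda)`,
#' `U = 4 lambda eps [(A + t)^-2 - (A + t)^-1]`.  The WCA variant is
#' truncated at its minimum `t = 2 - A` and shifted by `lambda eps`, so that
#' `lambda = 1` reproduces [pair_wca] exactly and `lambda = 0` vanishes; the
#' potential is finite at `r = 0` for `lambda < 1`.
#'
#' @inheritParams pair_wca
#' @param lambda_lj coupling parameter in `[0, 1]`.
#' @param alpha soft-core parameter (0.5).
#' @param wca if `TRUE` the repulsive (shifted, truncated) variant; otherwise
#'   the full LJ form truncated at `cutoff_factor * sigma_ij`.
#' @param cutoff_factor attraction cutoff in units of sigma_ij.
#' @return Energy in kT (vectorized).
#' @export
pair_softcore <- function(r, sigma_ij, eps, lambda_lj, alpha = 0.5,
                          wca = FALSE, cutoff_factor = 3) {
  stopifnot(all(lambda_lj >= 0), all(lambda_lj <= 1))
  a <- alpha * (1 - lambda_lj)
  s6 <- (sigma_ij / r)^6
  # q = 1/(a + (r/sigma)^6) written so that lambda = 1 (a = 0) reproduces the
  # plain potentials exactly; finite at r = 0 for lambda < 1
  q <- ifelse(is.finite(s6), s6 / (1 + a * s6), 1 / a)
  u <- 4 * lambda_lj * eps * (q^2 - q)
  # truncation conditions written identically to pair_wca / pair_lj so the
  # lambda = 1 endpoint matches them exactly, including at the cutoff
  if (wca) ifelse(r < (2 - a)^(1 / 6) * sigma_ij, u + lambda_lj * eps, 0)
  else ifelse(r < cutoff_factor * sigma_ij, u, 0)
}

#' Debye-Hueckel screened electrostatics
#'
#' `U = lambda_elec l_B q_i q_j exp(-r / l_D) / r` in kT, with the effective
#' screening length `l_D = debye_length * screening_scale`.  The lambda
#' interpolation is linear.
#'
#' @param r pair distance, nm (> 0).
#' @param q_i,q_j charges, elementary charges.
#' @param lambda_elec coupling parameter in `[0, 1]`.
#' @param params an [ff_params].
#' @return Energy in kT (vectorized).
#' @export
pair_debye_huckel <- function(r, q_i, q_j, lambda_elec = 1,
                              params = ff_params()) {
  if (any(r <= 0)) stop("Debye-Hueckel potential requires r > 0")
  lD <- params$debye_length * params$screening_scale
  lambda_elec * params$bjerrum_length * q_i * q_j * exp(-r / lD) / r
}

# ---- system-level pair table ----------------------------------------------

# Nonbonded pair table (i, j, sigma_ij, qq, attr, cross).
# Interacting pairs: beads of different molecules, plus PROTAC-internal pairs
# separated by >= 2 chain bonds.  Excluded: intra-protein pairs (the ENM
# maintains shape), directly bonded pairs (incl. anchors), and pairs between
# a warhead bead and the protein it is anchored into (the warhead is part of
# the bound pocket moiety).  `attr` marks protein-protein (target x e3)
# pairs eligible for the nonspecific attraction; `cross` marks pairs scaled
# by lambda for the given decoupled molecule.
.pair_table <- function(sys, decouple = "none") {
  n <- nrow(sys$pos)
  mol <- sys$molecule
  grp <- sys$group
  bonded <- rep(FALSE, n * n)
  bkey <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  if (nrow(sys$bonds))
    bonded[bkey(sys$bonds[, 1], sys$bonds[, 2])] <- TRUE

  # chain index within the PROTAC for the >= 2-bond separation rule
  ip <- which(mol == "protac")
  chain_pos <- rep(NA_integer_, n)
  chain_pos[ip] <- seq_along(ip)

  pairs <- matrix(numeric(0), 0, 6)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  inter <- mol[i] != mol[j]
  intra_pro <- mol[i] == "protac" & mol[j] == "protac" &
    abs(chain_pos[i] - chain_pos[j]) >= 2
  keep <- (inter | intra_pro) & !bonded[bkey(i, j)]
  # warhead has no nonbonded terms with its own anchored protein
  wh_excl <- (grp[i] == "warhead_t" & mol[j] == "target") |
    (grp[j] == "warhead_t" & mol[i] == "target") |
    (grp[i] == "warhead_e" & mol[j] == "e3") |
    (grp[j] == "warhead_e" & mol[i] == "e3")
  keep <- keep & !wh_excl
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(matrix(numeric(0), 0, 6))
  attr_flag <- as.numeric((grp[i] == "target" & grp[j] == "e3") |
                            (grp[i] == "e3" & grp[j] == "target"))
  cross <- if (decouple == "none") rep(0, length(i))
           else as.numeric((mol[i] == decouple) != (mol[j] == decouple))
  cbind(i, j, sys$radius[i] + sys$radius[j],
        sys$charge[i] * sys$charge[j], attr_flag, cross)
}

.state_lambdas <- function(state) {
  c(lj = state$lambda_lj, elec = state$lambda_elec)
}

#' Total potential energy with decomposition
#'
#' Bonded terms (ENM, PROTAC chain, pocket anchors) are never lambda-scaled;
#' nonbonded terms between the decoupled protein and the rest of the system
#' are scaled according to the alchemical state, all other nonbonded terms
#' act at full strength.
#'
#' @param system a `cg_system`.
#' @param positions coordinate matrix (defaults to the stored positions).
#' @param state an [alch_state].
#' @param params an [ff_params].
#' @return A list of class `energy_report` with `total` (kT) and `by_term`
#'   (`enm`, `linker_bonds`, `anchors`, `wca`, `lj`, `elec`).
#' @export
total_energy <- function(system, positions = system$pos,
                         state = alch_state(), params = ff_params()) {
  positions <- .check_positions(system, positions)
  pr <- .pair_table(system, state$decoupled_group)
  res <- energy_forces_cpp(positions, system$bonds, pr, .ff_vector(params),
                           state$lambda_lj, state$lambda_elec, FALSE)
  structure(list(total = res$total, by_term = res$by_term),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("total:", format(x$total), "kT\n")
  print(x$by_term)
  invisible(x)
}

.check_positions <- function(system, positions) {
  positions <- as.matrix(positions)
  if (!all(dim(positions) == dim(system$pos)))
    stop("positions must be a ", nrow(system$pos), " x 3 matrix")
  storage.mode(positions) <- "double"
  positions
}

#' Bonded energy of a system
#'
#' Sum of `0.5 k (|r_ij| - r0)^2` over ENM, PROTAC chain, and anchor
#' springs; never lambda-scaled.
#' @inheritParams total_energy
#' @return Energy in kT.
#' @export
bonded_energy <- function(system, positions = system$pos) {
  positions <- .check_positions(system, positions)
  b <- system$bonds
  if (!nrow(b)) return(0)
  d <- sqrt(rowSums((positions[b[, 1], , drop = FALSE] -
                       positions[b[, 2], , drop = FALSE])^2))
  sum(0.5 * b[, 4] * (d - b[, 3])^2)
}

#' Analytic forces
#'
#' Negative gradient of [total_energy]; matches central finite differences to
#' about 1e-5 relative tolerance.
#' @inheritParams total_energy
#' @return An n x 3 matrix, kT/nm.
#' @export
forces <- function(system, positions = system$pos, state = alch_state(),
                   params = ff_params()) {
  positions <- .check_positions(system, positions)
  pr <- .pair_table(system, state$decoupled_group)
  energy_forces_cpp(positions, system$bonds, pr, .ff_vector(params),
                    state$lambda_lj, state$lambda_elec, TRUE)$forces
}

#' Analytic dU/dlambda of the currently scaled terms
#'
#' For the sterics stage this is the soft-core lambda derivative of all
#' cross-group WCA (+ attraction) pairs; for the (linear) electrostatic
#' stage it is the unscaled Debye-Hueckel energy of the cross-group pairs.
#' @inheritParams total_energy
#' @return Scalar, kT.
#' @export
du_dlambda <- function(system, positions = system$pos, state,
                       params = ff_params()) {
  if (!state$stage %in% c("sterics", "electrostatics"))
    stop("state must identify exactly one active lambda ",
         "(stage 'sterics' or 'electrostatics')")
  positions <- .check_positions(system, positions)
  pr <- .pair_table(system, state$decoupled_group)
  res <- energy_forces_cpp(positions, system$bonds, pr, .ff_vector(params),
                           state$lambda_lj, state$lambda_elec, FALSE)
  if (state$stage == "sterics") res$dudl_lj else res$dudl_elec
}
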