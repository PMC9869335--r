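# Pair potentials, soft-core scaling, energies, forces, lambda derivatives.

test_that("WCA potential has the textbook values and support", {
  s <- 0.8
  expect_equal(pair_wca(2^(1 / 6) * s, s, 1), 0)
  expect_equal(pair_wca(s, s, 1), 1)            # 4(1-1) + 1
  expect_equal(pair_wca(1.5 * s, s, 1), 0)      # purely repulsive
  expect_error(pair_wca(0, s, 1), "r = 0")
})

test_that("LJ attraction crosses zero at sigma with well depth eps", {
  s <- 0.8
  expect_equal(pair_lj(s, s, 0.2), 0)
  expect_equal(pair_lj(2^(1 / 6) * s, s, 0.2), -0.2)
  expect_equal(pair_lj(seq(0.5, 2, by = 0.1), s, 0), rep(0, 16))
})

test_that("soft-core endpoints are exact and the core is finite", {
  r <- seq(0, 2.5, by = 0.005)
  s <- 0.8
  # lambda = 1: identical to the plain potentials (machine precision)
  expect_identical(pair_softcore(r[-1], s, 1, 1, wca = TRUE),
                   pair_wca(r[-1], s, 1))
  expect_identical(pair_softcore(r[-1], s, 0.25, 1),
                   pair_lj(r[-1], s, 0.25, cutoff = 3 * s))
  # lambda = 0: zero everywhere
  expect_equal(pair_softcore(r, s, 1, 0, wca = TRUE), rep(0, length(r)))
  expect_equal(pair_softcore(r, s, 1, 0), rep(0, length(r)))
  # finite at r = 0 for lambda < 1; hand-evaluated value at lambda = 0.5
  expect_equal(pair_softcore(0, s, 1, 0.5), 24)  # 4*0.5*(16 - 4)
  expect_true(all(is.finite(pair_softcore(r, s, 1, 0.5, wca = TRUE))))
})

test_that("Debye-Hueckel potential screens exponentially", {
  expect_equal(pair_debye_huckel(1, 0, 1), 0)
  expect_equal(pair_debye_huckel(1, 1, 1, lambda_elec = 0), 0)
  p <- ff_params(bjerrum_length = 0.7, debye_length = 0.7)
  expect_equal(pair_debye_huckel(0.7, 1, 1, 1, p), exp(-1))
  # screening_scale rescales the decay length
  p10 <- ff_params(bjerrum_length = 0.7, debye_length = 0.7,
                   screening_scale = 10)
  expect_equal(pair_debye_huckel(0.7, 1, 1, 1, p10), exp(-0.1))
  expect_error(pair_debye_huckel(0, 1, 1), "r > 0")
})

test_that("electrostatics may only be perturbed on top of full sterics", {
  expect_error(alch_state("electrostatics", lambda_lj = 0.5,
                          lambda_elec = 0.5), "volume exclusion")
  st <- alch_state("electrostatics", lambda_lj = 1, lambda_elec = 0.5,
                   decoupled_group = "e3")
  expect_equal(st$lambda_elec, 0.5)
})

test_that("bonded energy has closed-form values and rigid-motion invariance", {
  sys <- dimer_system(r0 = 1, k = 100)
  expect_equal(bonded_energy(sys), 0)                  # at rest length
  pos <- sys$pos; pos[2, 1] <- 1.3
  expect_equal(bonded_energy(sys, pos), 0.5 * 100 * 0.3^2)
  # rigid rotation + translation leaves every energy term unchanged
  sys2 <- make_toy_ternary(2, seed = 5)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pos2 <- sys2$pos %*% R + matrix(c(1, -2, 3), nrow(sys2$pos), 3, byrow = TRUE)
  e1 <- total_energy(sys2)
  e2 <- total_energy(sys2, pos2)
  expect_equal(e2$total, e1$total, tolerance = 1e-10)
  expect_equal(e2$by_term, e1$by_term, tolerance = 1e-10)
})

test_that("energy decomposition sums to the total on random configurations", {
  sys <- make_toy_ternary(2, seed = 6, charge_target = 2, charge_e3 = -2)
  st <- alch_state("sterics", lambda_lj = 0.4, decoupled_group = "e3")
  set.seed(42)
  for (i in 1:20) {
    pos <- sys$pos + 0.15 * matrix(rnorm(length(sys$pos)), nrow(sys$pos))
    e <- total_energy(sys, pos, st, ff_params(eps_lj = 0.2))
    expect_equal(e$total, sum(e$by_term), tolerance = 1e-12)
  }
})

test_that("the fully decoupled state separates into rest + dummy internal", {
  sys <- make_toy_ternary(1, seed = 2, charge_target = 1, charge_e3 = -1)
  st0 <- alch_state("sterics", lambda_lj = 0, decoupled_group = "target")
  bin <- make_binary(sys, remove = "target")
  it <- which(sys$molecule == "target")
  b <- sys$bonds
  dummy_internal <- (b[, 5] == 1 & b[, 1] %in% it) |
    (b[, 5] == 3 & (b[, 1] %in% it | b[, 2] %in% it))
  set.seed(7)
  for (i in 1:5) {
    pos <- sys$pos + 0.1 * matrix(rnorm(length(sys$pos)), nrow(sys$pos))
    e0 <- total_energy(sys, pos, st0)$total
    ebin <- total_energy(bin, pos[sys$molecule != "target", ])$total
    d <- sqrt(rowSums((pos[b[dummy_internal, 1], , drop = FALSE] -
                         pos[b[dummy_internal, 2], , drop = FALSE])^2))
    eint <- sum(0.5 * b[dummy_internal, 4] * (d - b[dummy_internal, 3])^2)
    expect_equal(e0, ebin + eint, tolerance = 1e-10)
  }
})

test_that("fully coupled cross energy matches an independent R re-summation", {
  sys <- make_toy_ternary(2, seed = 8, charge_target = 2, charge_e3 = -3)
  ff <- ff_params(eps_lj = 0.15)
  e <- total_energy(sys, state = alch_state("fully_coupled"), params = ff)
  # independent oracle: loop molecules/pairs with the documented rules
  mol <- sys$molecule; grp <- sys$group
  n <- nrow(sys$pos)
  bonded <- matrix(FALSE, n, n)
  bonded[sys$bonds[, 1:2]] <- TRUE
  bonded <- bonded | t(bonded)
  ip <- which(mol == "protac")
  wca <- lj <- elec <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same_mol <- mol[i] == mol[j]
    chain_ok <- same_mol && mol[i] == "protac" &&
      abs(match(i, ip) - match(j, ip)) >= 2
    if (same_mol && !chain_ok) next
    if (bonded[i, j]) next
    if ((grp[i] == "warhead_t" && mol[j] == "target") ||
        (grp[j] == "warhead_t" && mol[i] == "target") ||
        (grp[i] == "warhead_e" && mol[j] == "e3") ||
        (grp[j] == "warhead_e" && mol[i] == "e3")) next
    r <- sqrt(sum((sys$pos[i, ] - sys$pos[j, ])^2))
    sig <- sys$radius[i] + sys$radius[j]
    wca <- wca + pair_wca(r, sig, 1)
    if (grp[i] %in% c("target", "e3") && grp[j] %in% c("target", "e3") &&
        grp[i] != grp[j])
      lj <- lj + pair_lj(r, sig, ff$eps_lj, cutoff = 3 * sig)
    elec <- elec + pair_debye_huckel(r, sys$charge[i], sys$charge[j], 1, ff)
  }
  expect_equal(unname(e$by_term["wca"]), wca, tolerance = 1e-9)
  expect_equal(unname(e$by_term["lj"]), lj, tolerance = 1e-9)
  expect_equal(unname(e$by_term["elec"]), elec, tolerance = 1e-9)
})

test_that("analytic forces match central finite differences", {
  sys <- make_toy_ternary(1, seed = 2, charge_target = 2, charge_e3 = -2)
  ff <- ff_params(eps_lj = 0.2)
  set.seed(11)
  for (rep in 1:3) {
    st <- alch_state("sterics", lambda_lj = runif(1), decoupled_group = "target")
    pos <- sys$pos + 0.08 * matrix(rnorm(length(sys$pos)), nrow(sys$pos))
    f <- forces(sys, pos, st, ff)
    h <- 1e-6
    for (i in sample(nrow(pos), 4)) for (c in 1:3) {
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      fd <- -(total_energy(sys, pp, st, ff)$total -
                total_energy(sys, pm, st, ff)$total) / (2 * h)
      expect_equal(f[i, c], fd, tolerance = 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("net force on an isolated system vanishes; WCA cutoff force is zero", {
  sys <- make_toy_ternary(3, seed = 9)
  # cancellation among O(10^3 kT/nm) pair forces leaves ~1e-10 roundoff
  expect_lt(max(abs(colSums(forces(sys)))), 1e-9)
  d <- dimer_system(r0 = 2^(1 / 6) * 0.8, k = 0.001)
  d$bonds <- d$bonds[0, , drop = FALSE]  # nonbonded pair exactly at cutoff
  f <- forces(d)
  expect_equal(max(abs(f)), 0)
})

test_that("dU/dlambda matches the numeric lambda derivative", {
  sys <- make_toy_ternary(1, seed = 2, charge_target = 3, charge_e3 = -2)
  ff <- ff_params(eps_lj = 0.2)
  set.seed(13)
  pos <- sys$pos + 0.1 * matrix(rnorm(length(sys$pos)), nrow(sys$pos))
  h <- 1e-4  # central difference: truncation O(h^2), roundoff |U| eps / h
  for (l in c(0.15, 0.55, 0.95)) {
    st <- alch_state("sterics", lambda_lj = l, decoupled_group = "target")
    dl <- du_dlambda(sys, pos, st, ff)
    up <- total_energy(sys, pos, alch_state("sterics", lambda_lj = l + h,
                                            decoupled_group = "target"), ff)
    dn <- total_energy(sys, pos, alch_state("sterics", lambda_lj = l - h,
                                            decoupled_group = "target"), ff)
    expect_equal(dl, (up$total - dn$total) / (2 * h),
                 tolerance = 1e-6 * max(1, abs(dl)))
  }
  # linear electrostatic stage: derivative equals the unscaled cross DH energy
  ste <- alch_state("electrostatics", lambda_lj = 1, lambda_elec = 0.25,
                    decoupled_group = "target")
  dl <- du_dlambda(sys, pos, ste, ff)
  e1 <- total_energy(sys, pos, alch_state("electrostatics", lambda_lj = 1,
                                          lambda_elec = 1,
                                          decoupled_group = "target"), ff)
  e0 <- total_energy(sys, pos, alch_state("sterics", lambda_lj = 1,
                                          decoupled_group = "target"), ff)
  expect_equal(dl, unname(e1$by_term["elec"] - e0$by_term["elec"]),
               tolerance = 1e-9)
  expect_error(du_dlambda(sys, pos, alch_state("fully_coupled")), "exactly one")
})

test_that("cross-state energies are antisymmetric and match direct energies", {
  sys <- make_toy_ternary(1, seed = 2, charge_target = 2, charge_e3 = -2)
  leg <- coupling_leg(sys, "target",
                      lj_schedule = c(0, 0.1, 0.5, 1),
                      elec_schedule = c(0, 0.25, 0.5, 1))
  smp <- sample_leg(leg, n_traj = 2, n_steps = 2000, stride = 200,
                    base_seed = 3, iparams = test_iparams())
  for (stage in names(smp$stages)) {
    ss <- smp$stages[[stage]]
    dU <- cross_energy_matrix(ss)
    K <- length(ss$lambdas)
    for (i in seq_len(K)) expect_equal(max(abs(dU[[i]][, i])), 0)
    # antisymmetry per configuration (via the shared scaled-energy table)
    expect_equal(dU[[1]][, 2], -(ss$u_scaled[[1]][, 1] - ss$u_scaled[[1]][, 2]))
  }
  # linear electrostatic stage: DeltaU between 0.25 and 0.5 is 0.25 x unscaled
  es <- smp$stages$electrostatics
  unscaled <- es$u_scaled[[2]][, 4] - es$u_scaled[[2]][, 1]  # lambda 0 -> 1
  expect_equal(es$u_scaled[[2]][, 3] - es$u_scaled[[2]][, 2], 0.25 * unscaled,
               tolerance = 1e-9)
  # re-evaluation matches direct total_energy calls on a frame
  st_a <- alch_state("sterics", lambda_lj = 0.1, decoupled_group = "target")
  st_b <- alch_state("sterics", lambda_lj = 0.5, decoupled_group = "target")
  leg2 <- coupling_leg(sys, "target", lj_schedule = c(0, 0.1, 0.5, 1),
                       elec_schedule = c(0, 0.5, 1))
  smp2 <- sample_leg(leg2, n_traj = 1, n_steps = 400, stride = 100,
                     base_seed = 5, burn_in = 0, iparams = test_iparams())
  ss2 <- smp2$stages$sterics
  tr <- run_trajectory(sys, alch_state("sterics", lambda_lj = 0.1,
                                       decoupled_group = "target"),
                       n_steps = 400, stride = 100,
                       params = {ip <- test_iparams()
                                 ip$seed <- cgalchemy:::.state_seed(5, 2, 1)
                                 ip})
  f <- tr$frames[, , 3]
  direct <- total_energy(sys, f, st_b)$total - total_energy(sys, f, st_a)$total
  expect_equal(ss2$u_scaled[[2]][3, 3] - ss2$u_scaled[[2]][3, 2], direct,
               tolerance = 1e-9)
})
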