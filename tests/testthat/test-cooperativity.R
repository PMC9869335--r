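# DeltaDeltaG bookkeeping, sign conventions, stage decomposition, and the
# dummy-anchor cancellation argument.

# construct a minimal leg_result by hand (no sampling) so the combination
# arithmetic can be checked exactly
fake_leg <- function(dG_by_stage, std = 0.1, is_ternary = FALSE,
                     ff = ff_params(), method = "mbar") {
  stages <- lapply(dG_by_stage, function(g) {
    ms <- list(list(total = g, intervals = g, per_trajectory = c(g, g),
                    std = std))
    names(ms) <- method
    structure(list(methods = ms, lambdas = c(0, 1),
                   stage = "x", overlap = NULL, n = c(10, 10)),
              class = "free_energy")
  })
  structure(list(stages = stages, decouple = "target",
                 is_ternary = is_ternary, ff = ff),
            class = "leg_result")
}

test_that("identical legs give zero DeltaDeltaG and unit cooperativity", {
  bin <- fake_leg(list(sterics = 1.7))
  ter <- fake_leg(list(sterics = 1.7), is_ternary = TRUE)
  res <- compute_ddG(bin, ter)
  expect_equal(res$methods$mbar$ddG, 0)
  expect_equal(res$methods$mbar$cooperativity, 1)
  # quadrature propagation of the two stage stds
  expect_equal(res$methods$mbar$std, sqrt(0.1^2 + 0.1^2))
})

test_that("the sign convention follows exp(DeltaDeltaG/RT)", {
  bin <- fake_leg(list(sterics = 2))
  ter <- fake_leg(list(sterics = 1), is_ternary = TRUE)
  res <- compute_ddG(bin, ter)
  expect_equal(res$methods$mbar$ddG, 1)
  expect_equal(res$methods$mbar$cooperativity, exp(1))
  # a more favorable (lower) ternary coupling increases DeltaDeltaG
  ter2 <- fake_leg(list(sterics = 0.2), is_ternary = TRUE)
  res2 <- compute_ddG(bin, ter2)
  expect_gt(res2$methods$mbar$ddG, res$methods$mbar$ddG)
})

test_that("mismatched stages or force fields are rejected", {
  bin <- fake_leg(list(sterics = 1))
  ter <- fake_leg(list(sterics = 1, electrostatics = 0.2), is_ternary = TRUE)
  expect_error(compute_ddG(bin, ter), "stage mismatch")
  ter2 <- fake_leg(list(sterics = 1), is_ternary = TRUE,
                   ff = ff_params(eps_lj = 0.2))
  expect_error(compute_ddG(bin, ter2), "force field")
  expect_error(compute_ddG(ter, ter), "binary leg, ternary leg")
  # deliberately mismatched force fields between cycles are caught too
  a <- compute_ddG(bin, fake_leg(list(sterics = 1), is_ternary = TRUE))
  b_bin <- fake_leg(list(sterics = 1), ff = ff_params(eps_lj = 0.2))
  b <- compute_ddG(b_bin, ter2)
  expect_error(cycle_closure_check(a, b), "identical force fields")
})

test_that("cycle closure compares the two cycles statistically", {
  a <- compute_ddG(fake_leg(list(sterics = 2.0), std = 0.1),
                   fake_leg(list(sterics = 1.5), std = 0.1,
                            is_ternary = TRUE))
  b <- compute_ddG(fake_leg(list(sterics = 2.1), std = 0.1),
                   fake_leg(list(sterics = 1.7), std = 0.1,
                            is_ternary = TRUE))
  cc <- cycle_closure_check(a, b)
  expect_equal(cc$discrepancy, abs(0.5 - 0.4), tolerance = 1e-12)
  expect_equal(cc$combined_std, sqrt(2 * 0.1^2 + 2 * 0.1^2))
  expect_true(cc$pass)  # 0.1 < 2 * 0.28
})

test_that("the waterfall decomposition cumulates exactly to DeltaDeltaG", {
  bin <- fake_leg(list(sterics = 2.2, electrostatics = 0.3))
  ter <- fake_leg(list(sterics = 1.4, electrostatics = -0.2),
                  is_ternary = TRUE)
  res <- compute_ddG(bin, ter)
  wf <- stage_decomposition_report(res)
  expect_equal(wf$component, c("dG_binary", "minus_dG_ternary_other",
                               "minus_dG_ternary_charges"))
  expect_equal(wf$value, c(2.5, -1.4, 0.2))
  expect_equal(wf$cumulative[3], res$methods$mbar$ddG, tolerance = 1e-12)
  # charges-off run has a zero charge row
  res0 <- compute_ddG(fake_leg(list(sterics = 2.2)),
                      fake_leg(list(sterics = 1.4), is_ternary = TRUE))
  wf0 <- stage_decomposition_report(res0)
  expect_equal(wf0$value[3], 0)
  expect_equal(wf0$cumulative[3], res0$methods$mbar$ddG)
})

test_that("the dummy-attachment term is one shared function in both legs", {
  # at lambda = 0 the total energy minus the physically present part is the
  # same function of the dummy coordinates in the binary and ternary legs,
  # which is the premise for its cancellation in DeltaDeltaG
  sys <- make_toy_ternary(2, seed = 12)
  bin <- make_binary(sys, remove = "e3")
  st0 <- alch_state("sterics", lambda_lj = 0, decoupled_group = "target")
  # raw subset keeping only the physically present part (no guard rails)
  drop_molecule <- function(s, mol) {
    keep <- which(s$molecule != mol)
    remap <- match(seq_along(s$molecule), keep)
    b <- s$bonds
    b <- b[!is.na(remap[b[, 1]]) & !is.na(remap[b[, 2]]), , drop = FALSE]
    b[, 1] <- remap[b[, 1]]; b[, 2] <- remap[b[, 2]]
    s$pos <- s$pos[keep, , drop = FALSE]
    for (f in c("radius", "charge", "group", "molecule"))
      s[[f]] <- s[[f]][keep]
    s$bonds <- b
    s$pocket <- list()
    s
  }
  rest_ter <- drop_molecule(sys, "target")
  rest_bin <- drop_molecule(bin, "target")
  it <- which(sys$molecule == "target")
  ib <- which(bin$molecule == "target")
  set.seed(21)
  for (rep in 1:4) {
    shift <- 0.1 * matrix(rnorm(3 * length(it)), length(it), 3)
    pos_t <- sys$pos; pos_t[it, ] <- pos_t[it, ] + shift
    pos_b <- bin$pos; pos_b[ib, ] <- pos_b[ib, ] + shift
    d_ter <- total_energy(sys, pos_t, st0)$total -
      total_energy(rest_ter, pos_t[sys$molecule != "target", ])$total
    d_bin <- total_energy(bin, pos_b, st0)$total -
      total_energy(rest_bin, pos_b[bin$molecule != "target", ])$total
    expect_equal(d_ter, d_bin, tolerance = 1e-10)
  }
})

test_that("scaling anchors identically in both legs cancels in DeltaDeltaG
           at the decoupled endpoint", {
  sys <- make_toy_ternary(2, seed = 12)
  # stiffen only the dummy (target) attachment, the term shared by both legs
  stiffen <- function(s, f) {
    it <- which(s$molecule == "target")
    sel <- s$bonds[, "kind"] == 3 &
      (s$bonds[, 1] %in% it | s$bonds[, 2] %in% it)
    s$bonds[sel, "k"] <- s$bonds[sel, "k"] * f
    s
  }
  sys2 <- stiffen(sys, 3)
  bin <- make_binary(sys, "e3"); bin2 <- stiffen(bin, 3)
  st0 <- alch_state("sterics", lambda_lj = 0, decoupled_group = "target")
  # the anchor-energy change is identical in both legs, configuration by
  # configuration, so it cancels in any free-energy difference
  d_ter <- total_energy(sys2, state = st0)$total -
    total_energy(sys, state = st0)$total
  d_bin <- total_energy(bin2, state = st0)$total -
    total_energy(bin, state = st0)$total
  expect_equal(d_ter, d_bin, tolerance = 1e-10)
})

test_that("make_binary + cooperativity wiring produces consistent tables", {
  # minimal smoke run through linker_scan at a tiny protocol; checks the
  # table contract (columns, per-method rows, flags), not the statistics
  target <- make_toy_protein(6, seed = 1)
  e3 <- make_toy_protein(6, seed = 2)
  tab <- linker_scan(target, e3, linker_lengths = c(1, 3), eps_lj = 0,
                     n_traj = 2, n_steps = 3000, stride = 300, base_seed = 3,
                     iparams = test_iparams(), methods = c("ti", "mbar"))
  expect_s3_class(tab, "scan_result")
  expect_setequal(names(tab), c("linker", "eps_lj", "method", "ddG", "std",
                                "cooperativity", "converged"))
  expect_equal(nrow(tab), 4)                      # 2 lengths x 2 methods
  expect_equal(tab$cooperativity, exp(tab$ddG), tolerance = 1e-12)
})
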