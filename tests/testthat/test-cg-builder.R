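# Coarse-graining, charges, ENM, PROTAC chain, assembly.

test_that("residue-to-bead mapping follows the ceil rule", {
  p9 <- coarse_grain_protein(write_test_pdb(rep("GLY", 9)))
  expect_equal(nrow(p9$pos), 3)
  p10 <- coarse_grain_protein(write_test_pdb(rep("GLY", 10)))
  expect_equal(nrow(p10$pos), 4)           # trailing residue forms own bead
  expect_length(p10$residues[[4]], 1)
  expect_equal(p10$radius, rep(0.4, 4))    # sigma = 0.8 nm beads
  # a kinase-domain-sized construct: 261 modeled residues -> 87 beads
  p261 <- coarse_grain_protein(write_test_pdb(rep("ALA", 261)))
  expect_equal(nrow(p261$pos), 87)
})

test_that("bead positions are the heavy-atom center of mass of the triplet", {
  path <- write_test_pdb(rep("GLY", 3))
  p <- coarse_grain_protein(path)
  pdb <- bio3d::read.pdb(path)
  m <- c(N = 14.007, C = 12.011, O = 15.999)[pdb$atom$elesy]
  com <- colSums(cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) * m) / sum(m) / 10
  expect_equal(as.numeric(p$pos[1, ]), as.numeric(com), tolerance = 1e-12)
})

test_that("coarse-graining is deterministic (idempotent)", {
  path <- write_test_pdb(c("ASP", "GLU", "LYS", "ARG", "GLY", "ALA", "HIS"))
  a <- coarse_grain_protein(path)
  b <- coarse_grain_protein(path)
  expect_identical(a[c("pos", "charge", "radius")],
                   b[c("pos", "charge", "radius")])
})

test_that("bead charges sum residue formal charges; unknowns warn", {
  expect_equal(assign_bead_charges(list(c("GLY", "GLY", "GLY"))), 0)
  expect_equal(assign_bead_charges(list(c("ASP", "GLU", "LYS"))), -1)
  expect_equal(assign_bead_charges(list(c("ARG", "LYS", "ARG"))), 3)
  expect_equal(assign_bead_charges(list(c("HIS", "HIS", "HIS"))), 0)
  expect_warning(q <- assign_bead_charges(list(c("XYZ", "LYS"))),
                 "nonstandard")
  expect_equal(q, 1)
})

test_that("CG net charge equals the summed residue charges of the range", {
  resids <- c("ASP", "GLU", "LYS", "ARG", "GLY", "ALA", "HIS", "GLU", "LYS",
              "LYS", "TRP")
  p <- coarse_grain_protein(write_test_pdb(resids))
  per_res <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1)[resids]
  expect_equal(sum(p$charge), sum(per_res, na.rm = TRUE))
})

test_that("ENM springs connect exactly the pairs within the cutoff", {
  p2 <- cg_protein(rbind(c(0, 0, 0), c(0.9, 0, 0)))
  p2 <- build_enm(p2, cutoff = 1.1, k = 500)
  expect_equal(nrow(p2$enm_bonds), 1)
  expect_equal(unname(p2$enm_bonds[1, 3]), 0.9)
  expect_equal(unname(p2$enm_bonds[1, 4]), 500)

  p3 <- cg_protein(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  p3 <- build_enm(p3, cutoff = 1.1)
  expect_equal(nrow(p3$enm_bonds), 2)  # the 2.0 nm pair is excluded
  expect_setequal(paste(p3$enm_bonds[, 1], p3$enm_bonds[, 2]),
                  c("1 2", "2 3"))
})

test_that("ENM equals the brute-force all-pairs cutoff graph", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:60, 1)
    pos <- matrix(runif(3 * n, 0, 3), n, 3)
    cutoff <- runif(1, 1.2, 2.2)
    got <- tryCatch(build_enm(cg_protein(pos), cutoff = cutoff),
                    error = function(e) NULL)
    # independent O(n^2) oracle
    expected <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= cutoff)
        expected <- expected + 1L
    if (is.null(got)) next  # disconnected draw; covered below
    expect_equal(nrow(got$enm_bonds), expected)
  }
})

test_that("a disconnected ENM graph is a hard error", {
  p <- cg_protein(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_error(build_enm(p, cutoff = 1.1), "disconnected")
})

test_that("pocket selection follows the warhead-distance rule", {
  path <- write_test_pdb(rep("GLY", 6))  # 2 beads, residues at x = 0..19 A
  p <- coarse_grain_protein(path)
  # warhead sits on residue 1's CA (x = 1.2 A): within 0.4 nm of bead 1 only
  p1 <- define_binding_pocket(p, path, warhead_xyz = c(0.12, 0, 0),
                              radius = 0.4)
  expect_equal(p1$pocket, 1L)
  # monotonicity: a larger radius returns a superset
  p2 <- define_binding_pocket(p, path, warhead_xyz = c(0.12, 0, 0),
                              radius = 0.5)
  expect_true(all(p1$pocket %in% p2$pocket))
  expect_error(define_binding_pocket(p, path, warhead_xyz = c(50, 50, 50),
                                     radius = 0.4), "empty")
})

test_that("synthetic pockets pass through unchanged", {
  p <- make_toy_protein(8, seed = 3)
  p <- set_pocket(p, c(2L, 5L))
  expect_identical(p$pocket, c(2L, 5L))
  expect_error(set_pocket(p, 99), "invalid")
})

test_that("PROTAC chain has the documented topology and geometry", {
  p6 <- build_protac(6)
  expect_equal(nrow(p6$pos), 8)            # the PROTAC (10) model
  expect_equal(p6$group[c(1, 8)], c("warhead_t", "warhead_e"))
  expect_equal(sum(p6$group == "linker"), 6)
  expect_equal(p6$charge, rep(0, 8))
  # adjacent bond rest lengths are sums of radii
  expect_equal(unname(p6$bonds[, 3]),
               c(0.575, rep(0.35, 5), 0.575), tolerance = 1e-12)

  p0 <- build_protac(0)
  expect_equal(nrow(p0$pos), 2)
  expect_equal(nrow(p0$bonds), 1)
  expect_equal(unname(p0$bonds[1, 3]), 0.8)
  expect_error(build_protac(-1), "n_linker")
})

test_that("linker contour lengths and the compound map match the series", {
  expect_equal(linker_contour_length(1), 0.35)   # 3.5 Angstrom
  expect_equal(linker_contour_length(6), 2.10)   # 21 Angstrom
  expect_equal(protac_compound(1:6),
               paste0("PROTAC (", c(1, 3, 5, 6, 8, 10), ")"))
  expect_error(protac_compound(7), "1..6")
})

test_that("ternary assembly conserves beads and anchors every pocket bead", {
  target <- make_toy_protein(10, seed = 1)
  e3 <- make_toy_protein(12, seed = 2)
  protac <- build_protac(3)
  sys <- assemble_ternary(target, e3, protac)
  expect_equal(nrow(sys$pos), 10 + 12 + 5)
  expect_true(sys$is_ternary)
  # group index sets partition the bead list
  expect_equal(sort(unlist(lapply(unique(sys$group),
                                  function(g) which(sys$group == g)))),
               seq_len(nrow(sys$pos)))
  # every pocket bead has exactly one anchor spring, to its warhead
  anchors <- sys$bonds[sys$bonds[, "kind"] == 3, , drop = FALSE]
  pocket_all <- c(sys$pocket$target, sys$pocket$e3)
  for (pb in pocket_all) {
    expect_equal(sum(anchors[, 1] == pb | anchors[, 2] == pb), 1)
  }
  # no bond crosses between the two proteins
  mol <- sys$molecule
  expect_false(any(mol[sys$bonds[, 1]] == "target" &
                     mol[sys$bonds[, 2]] == "e3"))
  expect_false(any(mol[sys$bonds[, 1]] == "e3" &
                     mol[sys$bonds[, 2]] == "target"))
})

test_that("the unshaken PROTAC starts fully extended", {
  target <- make_toy_protein(10, seed = 1)
  e3 <- make_toy_protein(12, seed = 2)
  protac <- build_protac(4)
  sys <- assemble_ternary(target, e3, protac, shake = FALSE)
  ip <- which(sys$molecule == "protac")
  ree <- sqrt(sum((sys$pos[ip[length(ip)], ] - sys$pos[ip[1], ])^2))
  expect_equal(ree, sum(protac$bonds[, 3]), tolerance = 1e-9)
})

test_that("binary derivation removes exactly one protein and its bonds", {
  sys <- make_toy_ternary(3, seed = 4)
  n_t <- sum(sys$molecule == "target")
  bin <- make_binary(sys, remove = "target")
  expect_equal(nrow(bin$pos), nrow(sys$pos) - n_t)
  expect_false(any(bin$molecule == "target"))
  # remaining coordinates unchanged
  keep <- sys$molecule != "target"
  expect_identical(bin$pos, sys$pos[keep, ])
  # anchors of the removed protein are gone; the other protein's remain
  expect_true(all(bin$bonds[, 1] <= nrow(bin$pos)))
  expect_error(make_binary(bin, remove = "target"), "not present")
  expect_error(make_binary(bin, remove = "e3"), "no other protein")
})
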