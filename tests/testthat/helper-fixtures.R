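# Shared helpers: synthetic PDB files and small reference systems, built in
# code at test time.

# Write a minimal synthetic PDB: one chain, `resids` residues in order, three
# heavy atoms per residue (N, CA, C) laid out along x (3.8 A per residue).
# Returns the path.
write_test_pdb <- function(resids, path = tempfile(fileext = ".pdb"),
                           jitter_seed = NULL) {
  lines <- character(0)
  ser <- 1L
  set.seed(if (is.null(jitter_seed)) 0 else jitter_seed)
  for (i in seq_along(resids)) {
    base <- c(3.8 * (i - 1), 0, 0)
    atoms <- list(N = c(0, 0.5, 0), CA = c(1.2, 0, 0), C = c(2.4, 0.3, 0))
    for (nm in names(atoms)) {
      xyz <- base + atoms[[nm]]
      ele <- substr(nm, 1, 1)
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ser, paste0(" ", nm), resids[i], "A", i, xyz[1], xyz[2], xyz[3],
        1, 0, ele))
      ser <- ser + 1L
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# a bare two-bead system with one harmonic bond (no nonbonded pairs)
dimer_system <- function(r0 = 1, k = 100) {
  structure(list(
    pos = rbind(c(0, 0, 0), c(r0, 0, 0)),
    radius = c(0.4, 0.4), charge = c(0, 0),
    group = c("target", "e3"), molecule = c("target", "e3"),
    bonds = cbind(i = 1, j = 2, r0 = r0, k = k, kind = 3),
    pocket = list(target = 1L, e3 = 2L), is_ternary = FALSE),
    class = "cg_system")
}

# a single free bead
free_bead_system <- function() {
  structure(list(
    pos = matrix(0, 1, 3), radius = 0.4, charge = 0,
    group = "target", molecule = "target",
    bonds = matrix(numeric(0), 0, 5, dimnames = list(NULL,
      c("i", "j", "r0", "k", "kind"))),
    pocket = list(), is_ternary = FALSE),
    class = "cg_system")
}

# an ideal (nearly non-interacting) harmonic chain of n_seg segments:
# freely jointed harmonic bonds, vanishing excluded volume
ideal_chain_system <- function(n_seg = 6, b = 0.35, k = 1000) {
  n <- n_seg + 1
  structure(list(
    pos = cbind(b * (seq_len(n) - 1), 0, 0),
    radius = rep(1e-4, n), charge = rep(0, n),
    group = rep("linker", n), molecule = rep("protac", n),
    bonds = cbind(i = seq_len(n - 1), j = seq_len(n - 1) + 1, r0 = b, k = k,
                  kind = 2),
    pocket = list(), is_ternary = FALSE),
    class = "cg_system")
}

# desk-scale sampling protocol shared by the heavier tests: tenfold time
# rescaling of the diffusion coefficient (the stationary ensemble of
# overdamped dynamics is independent of D)
test_iparams <- function(seed = 1L) {
  integrator_params(diffusion_coefficient = 2530, seed = seed)
}
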