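# Coarse-grained model construction: proteins, PROTACs, assembled systems.

# per-residue formal charges at pH 7; His treated as neutral, termini ignored
.residue_charges <- c(
  ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0, GLN = 0, GLU = -1, GLY = 0,
  HIS = 0, ILE = 0, LEU = 0, LYS = 1, MET = 0, PHE = 0, PRO = 0, SER = 0,
  THR = 0, TRP = 0, TYR = 0, VAL = 0
)

#' Construct a coarse-grained protein object
#'
#' Low-level constructor used by [coarse_grain_protein] and
#' [make_toy_protein].  Positions are in nm; one bead represents (by default)
#' three consecutive amino acids and has diameter 0.8 nm.
#'
#' @param pos numeric matrix (n x 3) of bead centers, nm.
#' @param radius bead radii, nm (recycled).
#' @param charge bead charges, elementary charges (recycled).
#' @param pocket integer indices of binding-pocket beads (may be empty until
#'   [define_binding_pocket] or [set_pocket] is called).
#' @param enm_bonds matrix with columns `i, j, r0, k` (indices, rest length
#'   nm, spring constant kT/nm^2), or `NULL` before [build_enm].
#' @param residues optional list (one element per bead) of residue labels the
#'   bead was mapped from.
#' @param source free-text provenance.
#' @return An object of class `cg_protein`.
#' @export
cg_protein <- function(pos, radius = SIGMA_PROTEIN / 2, charge = 0,
                       pocket = integer(), enm_bonds = NULL,
                       residues = NULL, source = "synthetic") {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3, n >= 1)
  radius <- rep_len(as.numeric(radius), n)
  charge <- rep_len(as.numeric(charge), n)
  if (any(radius <= 0)) stop("bead radii must be positive")
  pocket <- as.integer(pocket)
  if (length(pocket) && (any(pocket < 1) || any(pocket > n)))
    stop("pocket indices out of range")
  if (!is.null(enm_bonds)) .check_bonds(enm_bonds, n)
  structure(
    list(pos = pos, radius = radius, charge = charge, pocket = pocket,
         enm_bonds = enm_bonds, residues = residues, source = source),
    class = "cg_protein"
  )
}

.check_bonds <- function(b, n) {
  b <- as.matrix(b)
  stopifnot(ncol(b) >= 4)
  if (nrow(b) == 0) return(invisible(b))
  if (any(b[, 1] >= b[, 2])) stop("bonds must have i < j")
  if (any(b[, 1] < 1) || any(b[, 2] > n)) stop("bond indices out of range")
  if (any(b[, 3] <= 0)) stop("bond rest lengths must be positive")
  invisible(b)
}

#' @export
print.cg_protein <- function(x, ...) {
  cat("<cg_protein> ", nrow(x$pos), " beads",
      if (!is.null(x$enm_bonds)) paste0(", ", nrow(x$enm_bonds), " ENM bonds"),
      ", net charge ", sum(x$charge),
      ", pocket beads: ", if (length(x$pocket)) paste(x$pocket, collapse = " ")
      else "(none)", "\n  source: ", x$source, "\n", sep = "")
  invisible(x)
}

# masses of the elements occurring in protein heavy atoms
.atomic_mass <- function(elesy) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38)
  m <- tab[toupper(elesy)]
  if (anyNA(m)) {
    warning("unknown element symbol(s) assigned carbon mass: ",
            paste(unique(elesy[is.na(m)]), collapse = ", "))
    m[is.na(m)] <- tab[["C"]]
  }
  unname(m)
}

# heavy-atom table of a bio3d pdb: first model, first altloc, ATOM records
.heavy_atoms <- function(pdb) {
  a <- pdb$atom
  keep <- a$type == "ATOM" &
    (is.na(a$alt) | a$alt %in% c("", "A")) &
    !(a$elesy %in% c("H", "D"))
  a[keep, , drop = FALSE]
}

#' Coarse-grain a protein structure to a bead model
#'
#' Maps every `mapping_stride` consecutive residues (default three) onto one
#' bead of diameter 0.8 nm placed at the center of mass of the residues'
#' heavy atoms.  A trailing partial group forms its own bead.  Bead charges
#' are the summed formal residue charges of the group
#' (see [assign_bead_charges]).
#'
#' @param structure a `bio3d` `pdb` object or the path of a PDB file.  Only
#'   the first model and first alternate location are used; HETATM records
#'   are ignored.
#' @param residue_range optional numeric vector of residue numbers to model
#'   (e.g. `235:495`); `NULL` models every protein residue.
#' @param mapping_stride residues per bead.
#' @return A [cg_protein] (no ENM yet; call [build_enm]).
#' @examples
#' \dontrun{
#' p <- coarse_grain_protein("target.pdb", residue_range = 235:495)
#' p <- build_enm(p)
#' }
#' @export
coarse_grain_protein <- function(structure, residue_range = NULL,
                                 mapping_stride = 3) {
  if (is.character(structure)) structure <- bio3d::read.pdb(structure)
  a <- .heavy_atoms(structure)
  if (!is.null(residue_range)) a <- a[a$resno %in% residue_range, , drop = FALSE]
  if (nrow(a) == 0) stop("no protein atoms in the requested residue range")
  key <- paste(a$chain, a$resno, sep = "_")
  res_keys <- unique(key)  # structure-file order, numbering taken as-is
  n_res <- length(res_keys)
  if (n_res < mapping_stride)
    stop("need at least ", mapping_stride, " residues in range")
  bead_of <- ceiling(seq_len(n_res) / mapping_stride)
  n_beads <- max(bead_of)

  mass <- .atomic_mass(a$elesy)
  pos <- matrix(NA_real_, n_beads, 3)
  residues <- vector("list", n_beads)
  triplets <- vector("list", n_beads)
  for (b in seq_len(n_beads)) {
    keys <- res_keys[bead_of == b]
    rows <- key %in% keys
    xyz <- cbind(a$x[rows], a$y[rows], a$z[rows])
    if (anyNA(xyz))
      stop("missing coordinates for residues: ", paste(keys, collapse = ", "))
    m <- mass[rows]
    pos[b, ] <- colSums(xyz * m) / sum(m) / 10  # Angstrom -> nm
    residues[[b]] <- keys
    triplets[[b]] <- vapply(keys, function(k) a$resid[key == k][1], "")
  }
  charge <- assign_bead_charges(triplets)
  cg_protein(pos, radius = SIGMA_PROTEIN / 2, charge = charge,
             residues = residues,
             source = sprintf("pdb (%d residues, stride %d)", n_res,
                              mapping_stride))
}

#' Assign coarse-grained bead charges from residue groups
#'
#' Each bead carries the net formal charge of the residues it was mapped
#' from: Asp/Glu -1, Lys/Arg +1, all others (including His) 0.  Nonstandard
#' residue names contribute 0 with a warning.
#'
#' @param residue_triplets list of character vectors of three-letter residue
#'   names (one vector per bead), or a single character vector for one bead.
#' @return Numeric vector of bead charges.
#' @examples
#' assign_bead_charges(list(c("ASP", "GLU", "LYS")))  # -1
#' @export
assign_bead_charges <- function(residue_triplets) {
  if (is.character(residue_triplets)) residue_triplets <- list(residue_triplets)
  vapply(residue_triplets, function(rt) {
    rt <- toupper(rt)
    unknown <- setdiff(rt, names(.residue_charges))
    if (length(unknown))
      warning("nonstandard residues assigned charge 0: ",
              paste(unique(unknown), collapse = ", "))
    sum(.residue_charges[rt], na.rm = TRUE)
  }, numeric(1))
}

#' Build an elastic network model on a coarse-grained protein
#'
#' Places a harmonic spring between every bead pair within `cutoff`, with the
#' current distance as rest length.  The resulting bond graph must be
#' connected, otherwise the protein would fall apart in dynamics.
#'
#' @param protein a [cg_protein].
#' @param cutoff pair distance cutoff, nm.
#' @param k spring constant, kT/nm^2.
#' @return The protein with `enm_bonds` filled in.
#' @export
build_enm <- function(protein, cutoff = 1.1, k = 500) {
  stopifnot(inherits(protein, "cg_protein"), cutoff > 0, k > 0)
  n <- nrow(protein$pos)
  d <- as.matrix(stats::dist(protein$pos))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  bonds <- if (nrow(idx))
    cbind(i = idx[, 1], j = idx[, 2], r0 = d[idx], k = k)
  else matrix(numeric(0), 0, 4, dimnames = list(NULL, c("i", "j", "r0", "k")))
  if (n > 1) {
    comp <- .components(n, bonds[, 1:2, drop = FALSE])
    if (max(comp) > 1)
      stop("ENM graph is disconnected (", max(comp),
           " components); increase the cutoff")
  }
  protein$enm_bonds <- bonds
  protein
}

# connected components by union-find
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
  match(roots, unique(roots))
}

#' Define the binding pocket from warhead coordinates
#'
#' The pocket is the set of CG beads containing at least one residue with any
#' heavy atom within `radius` of any warhead atom, following the convention
#' of selecting residues within 4--5 Angstrom of the bound warhead in an
#' experimental structure (default 0.45 nm, the midpoint).
#'
#' @param protein a structure-derived [cg_protein] (needs its residue map).
#' @param structure the `bio3d` `pdb` object (or file) the protein was
#'   coarse-grained from.
#' @param warhead_xyz matrix (m x 3) of warhead atom coordinates, nm.
#' @param radius selection radius, nm (0.4 or 0.5 in the source convention).
#' @return The protein with `pocket` set.
#' @export
define_binding_pocket <- function(protein, structure, warhead_xyz,
                                  radius = 0.45) {
  stopifnot(inherits(protein, "cg_protein"), radius > 0)
  if (is.null(protein$residues))
    stop("protein has no residue map; for synthetic proteins use set_pocket()")
  if (is.character(structure)) structure <- bio3d::read.pdb(structure)
  warhead_xyz <- matrix(as.numeric(warhead_xyz), ncol = 3)
  a <- .heavy_atoms(structure)
  key <- paste(a$chain, a$resno, sep = "_")
  axyz <- cbind(a$x, a$y, a$z) / 10  # nm
  near <- rep(FALSE, nrow(axyz))
  for (w in seq_len(nrow(warhead_xyz))) {
    d2 <- (axyz[, 1] - warhead_xyz[w, 1])^2 +
      (axyz[, 2] - warhead_xyz[w, 2])^2 + (axyz[, 3] - warhead_xyz[w, 3])^2
    near <- near | d2 <= radius^2
  }
  hit_res <- unique(key[near])
  pocket <- which(vapply(protein$residues,
                         function(r) any(r %in% hit_res), logical(1)))
  if (!length(pocket))
    stop("empty binding pocket: no residue within ", radius,
         " nm of the warhead")
  protein$pocket <- pocket
  protein
}

#' Designate pocket beads directly (synthetic proteins)
#' @param protein a [cg_protein].
#' @param indices bead indices forming the pocket.
#' @return The protein with `pocket` set.
#' @export
set_pocket <- function(protein, indices) {
  stopifnot(inherits(protein, "cg_protein"))
  indices <- as.integer(indices)
  if (!length(indices) || any(indices < 1) || any(indices > nrow(protein$pos)))
    stop("invalid pocket indices")
  protein$pocket <- indices
  protein
}

#' Build a coarse-grained PROTAC chain
#'
#' Two warhead beads (diameter 0.8 nm) joined by `n_linker` linker beads
#' (diameter 0.35 nm, one PEG unit each) in a linear chain.  Adjacent beads
#' are bonded by harmonic springs with rest length equal to the sum of their
#' radii; linker beads carry no charge and no attractive affinity.  Linker
#' lengths 1--6 beads correspond to the PROTAC (1), (3), (5), (6), (8) and
#' (10) compound series.
#'
#' @param n_linker number of linker beads (>= 0).
#' @param k_bond chain spring constant, kT/nm^2.
#' @return An object of class `protac_model`; positions are the fully
#'   extended chain along +x starting at the origin.
#' @examples
#' build_protac(6)   # 8 beads: the PROTAC (10) model
#' @export
build_protac <- function(n_linker, k_bond = 1000) {
  n_linker <- as.integer(n_linker)
  if (is.na(n_linker) || n_linker < 0) stop("n_linker must be >= 0")
  n <- n_linker + 2L
  radius <- c(SIGMA_PROTEIN / 2, rep(SIGMA_LINKER / 2, n_linker),
              SIGMA_PROTEIN / 2)
  group <- c("warhead_t", rep("linker", n_linker), "warhead_e")
  r0 <- radius[-n] + radius[-1]  # rest length = sum of adjacent radii
  x <- c(0, cumsum(r0))
  pos <- cbind(x, 0, 0)
  bonds <- cbind(i = seq_len(n - 1), j = seq_len(n - 1) + 1, r0 = r0,
                 k = k_bond)
  structure(list(pos = pos, radius = radius, charge = rep(0, n),
                 group = group, bonds = bonds, n_linker = n_linker),
            class = "protac_model")
}

#' @export
print.protac_model <- function(x, ...) {
  cat("<protac_model> 2 warheads + ", x$n_linker, " linker beads; contour ",
      format(linker_contour_length(x)), " nm linker\n", sep = "")
  invisible(x)
}

#' Linker contour length of a PROTAC model
#'
#' `n_linker` beads of one PEG unit each: contour length
#' `n_linker * 0.35` nm (3.5 Angstrom per bead, so 1--6 beads span
#' approximately 3.5--21 Angstrom).
#' @param protac a [protac_model] or an integer linker bead count.
#' @return Length in nm.
#' @export
linker_contour_length <- function(protac) {
  n <- if (inherits(protac, "protac_model")) protac$n_linker
       else as.integer(protac)
  n * SIGMA_LINKER
}

#' Map linker bead counts to the PROTAC compound series
#' @param n_linker integer vector in 1..6.
#' @return Character labels "PROTAC (1)", ..., "PROTAC (10)".
#' @export
protac_compound <- function(n_linker) {
  series <- c("1", "3", "5", "6", "8", "10")
  if (any(n_linker < 1 | n_linker > 6)) stop("compound map covers 1..6 beads")
  paste0("PROTAC (", series[n_linker], ")")
}

# rotation matrix taking unit vector a to unit vector b (Rodrigues)
.rotation_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {  # antiparallel: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# orient protein so pocket-centroid axis points along `direction`, pocket
# centroid lands at `at`
.place_protein <- function(protein, direction, at) {
  g <- colMeans(protein$pos)
  cp <- colMeans(protein$pos[protein$pocket, , drop = FALSE])
  axis <- cp - g
  if (sqrt(sum(axis^2)) < 1e-9) axis <- direction  # pocket at centroid
  R <- .rotation_to(axis, direction)
  pos <- sweep(protein$pos, 2, g) %*% t(R)
  cp2 <- colMeans(pos[protein$pocket, , drop = FALSE])
  sweep(pos, 2, at - cp2, "+")
}

#' Assemble a target-PROTAC-E3 ternary complex
#'
#' Each protein is rotated so its pocket faces the other protein, warhead
#' beads are placed at the pocket centers, and the PROTAC is laid out fully
#' extended along the pocket-pocket axis.  Every pocket bead is connected to
#' its warhead bead by a harmonic anchor spring with rest length equal to the
#' placement distance.  A short deterministic steepest-descent shake (on a
#' near-fully-coupled soft-core potential) then relieves any steric overlap.
#'
#' @param target,e3 [cg_protein] objects with ENM bonds and pockets defined.
#' @param protac a [protac_model].
#' @param anchor_k anchor spring constant, kT/nm^2.
#' @param params force-field parameters used by the shake ([ff_params]).
#' @param shake logical; run the relaxation shake.
#' @param clash_tol hard-error threshold: after the shake no cross-protein
#'   pair may sit below `clash_tol * sigma_ij`.
#' @return An object of class `cg_system` (fields `pos`, `radius`, `charge`,
#'   `group`, `molecule`, `bonds` with a `kind` column, `pocket`,
#'   `is_ternary`).
#' @export
assemble_ternary <- function(target, e3, protac, anchor_k = 1000,
                             params = ff_params(), shake = TRUE,
                             clash_tol = 0.5) {
  stopifnot(inherits(target, "cg_protein"), inherits(e3, "cg_protein"),
            inherits(protac, "protac_model"))
  if (!length(target$pocket) || !length(e3$pocket))
    stop("both proteins need a nonempty binding pocket before assembly")
  if (is.null(target$enm_bonds) || is.null(e3$enm_bonds))
    stop("both proteins need ENM bonds (build_enm) before assembly")

  np <- nrow(protac$pos)
  wh_t <- protac$pos[1, ]
  wh_e <- protac$pos[np, ]
  pos_t <- .place_protein(target, direction = c(1, 0, 0), at = wh_t)
  pos_e <- .place_protein(e3, direction = c(-1, 0, 0), at = wh_e)

  nt <- nrow(pos_t); ne <- nrow(pos_e)
  pos <- rbind(pos_t, pos_e, protac$pos)
  radius <- c(target$radius, e3$radius, protac$radius)
  charge <- c(target$charge, e3$charge, protac$charge)
  group <- c(rep("target", nt), rep("e3", ne), protac$group)
  molecule <- c(rep("target", nt), rep("e3", ne), rep("protac", np))

  off_e <- nt
  off_p <- nt + ne
  bonds <- rbind(
    cbind(target$enm_bonds[, 1:4, drop = FALSE], kind = 1),
    cbind(sweep(e3$enm_bonds[, 1:4, drop = FALSE], 2,
                c(off_e, off_e, 0, 0), "+"), kind = 1),
    cbind(sweep(protac$bonds[, 1:4, drop = FALSE], 2,
                c(off_p, off_p, 0, 0), "+"), kind = 2)
  )
  # anchors: every pocket bead to its warhead, rest = placement distance
  anchor <- function(pocket_idx, wh_idx) {
    t(vapply(pocket_idx, function(i) {
      r0 <- sqrt(sum((pos[i, ] - pos[wh_idx, ])^2))
      ij <- sort(c(i, wh_idx))
      c(ij[1], ij[2], max(r0, 1e-6), anchor_k, 3)
    }, numeric(5)))
  }
  idx_wh_t <- off_p + 1L
  idx_wh_e <- off_p + np
  bonds <- rbind(bonds, anchor(target$pocket, idx_wh_t),
                 anchor(off_e + e3$pocket, idx_wh_e))
  colnames(bonds) <- c("i", "j", "r0", "k", "kind")

  sys <- structure(
    list(pos = pos, radius = radius, charge = charge, group = group,
         molecule = molecule, bonds = bonds,
         pocket = list(target = target$pocket, e3 = off_e + e3$pocket),
         is_ternary = TRUE),
    class = "cg_system"
  )
  if (shake) sys <- .shake(sys, params)
  .check_clash(sys, clash_tol)
  sys
}

.shake <- function(sys, params, n_iter = 400) {
  pr <- .pair_table(sys, decouple = "none")
  pos <- minimize_cpp(sys$pos, sys$bonds, pr, .ff_vector(params),
                      lambda_lj = 0.98, lambda_elec = 0, n_iter = n_iter,
                      gamma = 2e-4, max_step = 0.02)
  sys$pos <- pos
  sys
}

.check_clash <- function(sys, clash_tol) {
  it <- which(sys$molecule == "target")
  ie <- which(sys$molecule == "e3")
  if (!length(it) || !length(ie)) return(invisible())
  for (i in it) {
    d <- sqrt(rowSums(sweep(sys$pos[ie, , drop = FALSE], 2, sys$pos[i, ])^2))
    sig <- sys$radius[i] + sys$radius[ie]
    if (any(d < clash_tol * sig))
      stop("proteins overlap beyond resolvable clash after placement; ",
           "use a longer PROTAC or larger initial separation")
  }
  invisible()
}

#' @export
print.cg_system <- function(x, ...) {
  tab <- table(x$molecule)
  cat("<cg_system> ", if (x$is_ternary) "ternary" else "binary", ", ",
      nrow(x$pos), " beads (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "), ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Derive a binary complex from an assembled ternary complex
#'
#' Deletes one protein together with its ENM bonds and pocket anchor
#' springs; all remaining coordinates are unchanged.
#'
#' @param system a ternary `cg_system`.
#' @param remove `"target"` or `"e3"`.
#' @return A binary `cg_system`.
#' @export
make_binary <- function(system, remove = c("target", "e3")) {
  remove <- match.arg(remove)
  stopifnot(inherits(system, "cg_system"))
  if (!any(system$molecule == remove))
    stop("molecule '", remove, "' is not present in the system")
  keep_prot <- setdiff(c("target", "e3"), remove)
  if (!any(system$molecule == keep_prot))
    stop("cannot remove '", remove, "': no other protein would remain")
  keep <- which(system$molecule != remove)
  remap <- match(seq_along(system$molecule), keep)
  b <- system$bonds
  keep_b <- !is.na(remap[b[, 1]]) & !is.na(remap[b[, 2]])
  b <- b[keep_b, , drop = FALSE]
  b[, 1] <- remap[b[, 1]]
  b[, 2] <- remap[b[, 2]]
  structure(
    list(pos = system$pos[keep, , drop = FALSE],
         radius = system$radius[keep], charge = system$charge[keep],
         group = system$group[keep], molecule = system$molecule[keep],
         bonds = b,
         pocket = setNames(list(remap[system$pocket[[keep_prot]]]), keep_prot),
         is_ternary = FALSE),
    class = "cg_system"
  )
}
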