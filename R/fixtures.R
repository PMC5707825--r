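# Synthetic PDB-format structures with known geometric ground truth, and
# a brute-force clash oracle, so every module is testable offline.

new_structure <- function(atoms, source_id) {
  atoms$vdw <- radius_for(atoms$element)
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, source_id = source_id)
  class(out) <- "clash_structure"
  out
}

atom_row <- function(serial, name, resname, chain, resno, xyz,
                     element = substr(name, 1, 1), hetero = FALSE,
                     icode = "") {
  data.frame(serial = as.integer(serial), name = name, altloc = "",
             resname = resname, chain = chain, resno = as.integer(resno),
             icode = icode, x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
             element = element, hetero = hetero, stringsAsFactors = FALSE)
}

#' Ideal polyalanine helix fixture
#'
#' Builds an n-residue polyalanine chain at the requested backbone
#' torsions by sequential internal-coordinate placement (ideal bond
#' lengths and angles, omega fixed at 180). [backbone_torsions()] on the
#' output recovers (phi, psi) for interior residues. Each residue has N,
#' CA, C, O and CB.
#'
#' @param n number of residues (>= 3).
#' @param phi,psi backbone torsions, degrees (defaults: alpha helix).
#' @param res_type residue name given to every site.
#' @param chain chain identifier.
#' @return A `clash_structure`.
#' @export
make_helix <- function(n, phi = -57, psi = -47, res_type = "ALA",
                       chain = "A") {
  stopifnot(n >= 3)
  # first residue backbone in the xy-plane
  N <- list(c(0, 0, 0))
  ang <- (180 - 111.2) * pi / 180
  CA <- list(c(1.458, 0, 0))
  C <- list(CA[[1]] + 1.525 * c(cos(ang), sin(ang), 0))
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], 1.329, 116.2, psi)
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], 1.458, 121.7, 180)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], 1.525, 111.2, phi)
  }
  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    # carbonyl O anti to the next N: dihedral N-CA-C-O = psi + 180
    O <- place_atom(N[[i]], CA[[i]], C[[i]], 1.231, 122.7, psi + 180)
    atoms <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O)
    if (res_type != "GLY")
      atoms$CB <- build_cb(N[[i]], CA[[i]], C[[i]])
    for (nm in names(atoms)) {
      serial <- serial + 1L
      rows[[serial]] <- atom_row(serial, nm, res_type, chain, i, atoms[[nm]])
    }
  }
  new_structure(do.call(rbind, rows), sprintf("helix_%d", n))
}

#' Extended-residue fixture
#'
#' A Gly-X-Gly tripeptide in extended backbone conformation with the X
#' side chain built at all chi = 180 degrees; used for maximum-exposure
#' accessibility references and reach checks. With `isolated = TRUE` only
#' the central residue is emitted.
#'
#' @param res_type the central residue (three-letter).
#' @param phi,psi extended backbone torsions.
#' @param isolated drop the flanking glycines.
#' @return A `clash_structure`.
#' @export
make_extended_residue <- function(res_type, phi = -139, psi = 135,
                                  isolated = FALSE) {
  res_type <- toupper(res_type)
  base <- make_helix(3, phi = phi, psi = psi, res_type = "GLY")
  at <- base$atoms
  at$resname[at$resno == 2] <- res_type
  center <- get_site(new_structure(at, "tmp"), "A", 2)
  extra <- list()
  if (res_type != "GLY") {
    arity <- CHI_ARITY[[res_type]]
    sc <- build_side_chain(center, res_type, chi = rep(180, arity))
    extra <- lapply(seq_len(nrow(sc)), function(i)
      atom_row(100L + i, sc$name[i], res_type, "A", 2L,
               c(sc$x[i], sc$y[i], sc$z[i])))
  }
  if (isolated) at <- at[at$resno == 2, , drop = FALSE]
  atoms <- do.call(rbind, c(list(at[, names(atom_row(1, "N", "GLY", "A", 1, c(0, 0, 0)))]),
                            extra))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, paste0("extended_", res_type))
}

#' Enclosed-site ("cage") fixture
#'
#' One central alanine residue surrounded by a closed spherical shell of
#' carbon pseudo-atoms (HETATM records, so the ligand/heteroatom clash
#' path is exercised). The shell is centered on the central Cb at radius
#' `site_gap`; wall spacing is kept near 1 Angstrom. Small gaps force
#' every substitution with two or more side-chain atoms to clash; gaps
#' beyond the search cutoff leave every substitution free.
#'
#' @param site_gap shell radius from the Cb, Angstrom (> 0).
#' @param spacing approximate wall-atom spacing, Angstrom.
#' @return A `clash_structure`.
#' @export
make_cage <- function(site_gap, spacing = 1) {
  stopifnot(site_gap > 0)
  central <- make_helix(3, res_type = "ALA")$atoms
  central <- central[central$resno == 2, , drop = FALSE]
  central$resno <- 1L
  central$vdw <- NULL
  cb <- as.numeric(central[central$name == "CB", c("x", "y", "z")])
  n_wall <- max(60L, ceiling(4 * pi * site_gap^2 / spacing^2))
  pts <- sphere_points(n_wall) * site_gap
  pts <- sweep(pts, 2, cb, "+")
  wall <- lapply(seq_len(n_wall), function(i)
    atom_row(1000L + i, "C", "CAG", "A", 900L + i, pts[i, ],
             element = "C", hetero = TRUE))
  atoms <- do.call(rbind, c(list(central), wall))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, sprintf("cage_%.1f", site_gap))
}

#' Random-environment fixture
#'
#' A central alanine residue plus `n_atoms` pseudo-atoms (random elements
#' C/N/O/S, HETATM) scattered uniformly in a spherical shell around the
#' Ca. Seed-deterministic; used for oracle-equivalence sweeps.
#'
#' @param seed integer seed.
#' @param n_atoms number of environment atoms.
#' @param r_min,r_max shell radii around the Ca, Angstrom.
#' @return A `clash_structure`.
#' @export
make_blob <- function(seed, n_atoms = 40, r_min = 2.5, r_max = 12) {
  central <- make_helix(3, res_type = "ALA")$atoms
  central <- central[central$resno == 2, , drop = FALSE]
  central$resno <- 1L
  central$vdw <- NULL
  ca <- as.numeric(central[central$name == "CA", c("x", "y", "z")])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  dir <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- stats::runif(n_atoms, r_min, r_max)
  pts <- sweep(dir * r, 2, ca, "+")
  elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                     prob = c(0.55, 0.2, 0.2, 0.05))
  env <- lapply(seq_len(n_atoms), function(i)
    atom_row(100L + i, elements[i], "BLB", "A", 500L + i, pts[i, ],
             element = elements[i], hetero = TRUE))
  atoms <- do.call(rbind, c(list(central), env))
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, sprintf("blob_%d", seed))
}

#' Brute-force clash oracle
#'
#' All-pairs evaluation of a built side chain against every atom of the
#' structure except the site's own residue, with no neighbor cutoff and
#' no vectorization: one scalar [pair_overlap()] call per pair. Used as
#' the independent reference for the clash engine.
#'
#' @param structure a `clash_structure`.
#' @param site the substitution site.
#' @param sidechain data.frame from [build_side_chain()].
#' @param params a `clash_params`.
#' @param to_aa substituting residue (enables the cysteine rule).
#' @return List with `fits` and `clashes` in the same layout as
#'   [rotamer_fits()].
#' @export
brute_force_clash <- function(structure, site, sidechain,
                              params = clash_params(), to_aa = "ALA") {
  to_aa <- toupper(to_aa)
  at <- structure$atoms
  own <- !at$hetero & at$chain == site$chain & at$resno == site$resno &
    at$icode == site$icode
  env <- at[!own, , drop = FALSE]
  test <- sidechain[sidechain$name != "CB", , drop = FALSE]
  site_ca <- as.numeric(site$atoms[site$atoms$name == "CA", c("x", "y", "z")])
  clashes <- data.frame(overlap_A = numeric(), rule = character(),
                        atom = character(), partner_chain = character(),
                        partner_resno = integer(), partner_icode = character(),
                        partner_atom = character(), stringsAsFactors = FALSE)
  if (nrow(test)) test$vdw <- radius_for(test$element, params$radii)
  for (i in seq_len(nrow(test))) {
    a1 <- test[i, ]
    a1$resname <- to_aa
    for (j in seq_len(nrow(env))) {
      a2 <- env[j, ]
      ctx <- NULL
      if (to_aa == "CYS" && !a2$hetero && a2$resname == "CYS" &&
          a1$name %in% c("CB", "SG") && a2$name %in% c("CB", "SG")) {
        ca2 <- cys_ca(structure, a2$chain, a2$resno, a2$icode)
        if (!is.null(ca2)) ctx <- list(ca1 = site_ca, ca2 = ca2)
      }
      res <- pair_overlap(a1, a2, params, cys_context = ctx)
      if (res$clash)
        clashes <- rbind(clashes, data.frame(
          overlap_A = res$overlap_c, rule = res$rule, atom = a1$name,
          partner_chain = a2$chain, partner_resno = a2$resno,
          partner_icode = a2$icode, partner_atom = a2$name,
          stringsAsFactors = FALSE))
    }
  }
  list(fits = nrow(clashes) == 0, clashes = clashes)
}
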