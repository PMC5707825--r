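# Neighbor search around the substitution site and the van der Waals
# overlap test: c = r_atom1 + r_atom2 - d_atoms - d_allowed, with special
# handling for hydrogen-bond-capable pairs and cysteine-cysteine contacts.

#' Clash-test parameters
#'
#' Bundles the constants of the overlap test. `d_allowed` is the tolerated
#' overlap before a contact counts as a clash (default 0.4 A). For pairs in
#' which both elements can hydrogen-bond (N/O with N/O) the radius sum is
#' replaced by `hbond_radius_sum` = 2.5 A. For contacts between two
#' cysteine side chains (potential disulfides) the test is replaced by a
#' minimum Ca-Ca distance of `cys_ca_min` = 4 A. The neighbor-search cutoff
#' is the reach of a fully extended arginine (Ca to N-eta, all chi = 180)
#' plus the nitrogen van der Waals radius `nitrogen_vdw` = 1.64 A, plus the
#' largest tabulated radius and `d_allowed`, so no buildable side-chain
#' atom can clash with an atom outside the searched ball.
#'
#' @param d_allowed allowed overlap, Angstrom (>= 0).
#' @param hbond_radius_sum radius sum for hydrogen-bond-capable pairs, A.
#' @param cys_ca_min minimum Ca-Ca distance between cysteine side chains, A.
#' @param nitrogen_vdw nitrogen van der Waals radius used in the cutoff, A.
#' @param radii element radius table, default [default_radii()].
#' @return A `clash_params` list, including the derived `search_cutoff`.
#' @export
clash_params <- function(d_allowed = 0.4, hbond_radius_sum = 2.5,
                         cys_ca_min = 4.0, nitrogen_vdw = 1.64,
                         radii = default_radii()) {
  if (d_allowed < 0) stop("d_allowed must be nonnegative")
  p <- list(d_allowed = d_allowed,
            hbond_radius_sum = hbond_radius_sum,
            cys_ca_min = cys_ca_min,
            nitrogen_vdw = nitrogen_vdw,
            radii = radii,
            search_cutoff = arg_reach() + nitrogen_vdw +
              max(radii) + d_allowed)
  class(p) <- "clash_params"
  p
}

#' Reach of a fully extended arginine side chain
#'
#' Ca-to-NH1 distance of an ideal arginine built with all chi angles at
#' 180 degrees, the longest conformation any buildable side chain can
#' attain. Computed once from the ideal-geometry table and cached.
#'
#' @return Distance in Angstrom.
#' @export
arg_reach <- function() {
  if (!is.null(.pkg_cache$arg_reach)) return(.pkg_cache$arg_reach)
  site <- synthetic_site()
  sc <- build_side_chain(site, "ARG", chi = c(180, 180, 180, 180))
  ca <- as.numeric(site$atoms[site$atoms$name == "CA", c("x", "y", "z")])
  reach <- max(vapply(c("NH1", "NH2"), function(nm) {
    vnorm(as.numeric(sc[sc$name == nm, c("x", "y", "z")]) - ca)
  }, numeric(1)))
  .pkg_cache$arg_reach <- reach
  .pkg_cache$arg_reach
}

# A minimal standalone backbone triad used for reach computations.
synthetic_site <- function() {
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  ang <- (180 - 111.2) * pi / 180
  cc <- ca + 1.525 * c(cos(ang), sin(ang), 0)
  site <- list(chain = "A", resno = 1L, icode = "", res_type = "ALA",
               atoms = data.frame(
                 serial = 1:3, name = c("N", "CA", "C"), altloc = "",
                 resname = "ALA", chain = "A", resno = 1L, icode = "",
                 x = c(n[1], ca[1], cc[1]), y = c(n[2], ca[2], cc[2]),
                 z = c(n[3], ca[3], cc[3]), occ = 1,
                 element = c("N", "C", "C"), hetero = FALSE,
                 vdw = c(1.64, 1.88, 1.88), stringsAsFactors = FALSE),
               usable = TRUE)
  class(site) <- "residue_site"
  site
}

#' Atoms surrounding a substitution site
#'
#' All structure atoms (polymer, ligand and other hetero atoms alike)
#' within `params$search_cutoff` of the site's Ca, excluding the atoms of
#' the site residue itself -- its original side chain is conceptually
#' removed and its backbone anchors the rotamer. Backbone atoms of the
#' adjacent peptide units are retained. Implemented as a vectorized radius
#' query over the coordinate array; at single-site query volume this costs
#' the same as a spatial-index lookup and has no tree-build step.
#'
#' @param structure a `clash_structure`.
#' @param site a `residue_site` with a Ca atom.
#' @param params a `clash_params`.
#' @return data.frame of environment atoms (subset of `structure$atoms`).
#' @export
neighborhood <- function(structure, site, params = clash_params()) {
  at <- structure$atoms
  ca <- as.numeric(site$atoms[site$atoms$name == "CA", c("x", "y", "z")])
  if (!length(ca)) stop("site lacks a CA atom")
  d2 <- (at$x - ca[1])^2 + (at$y - ca[2])^2 + (at$z - ca[3])^2
  own <- !at$hetero & at$chain == site$chain & at$resno == site$resno &
    at$icode == site$icode
  at[d2 <= params$search_cutoff^2 & !own, , drop = FALSE]
}

#' Overlap test for one atom pair
#'
#' Computes the overlap `c = r1 + r2 - d - d_allowed` for two heavy atoms.
#' If both elements are nitrogen or oxygen the pair is treated as
#' hydrogen-bond capable and the radius sum is replaced by 2.5 A (rule
#' `"hbond"`). If both atoms are cysteine side-chain atoms (CB or SG of
#' distinct Cys residues) the criterion switches to the disulfide-geometry
#' rule: clash iff the Ca-Ca distance is below 4 A, with
#' `c = cys_ca_min - |Ca1 - Ca2|` (rule `"cysteine"`; requires
#' `cys_context`). The test is symmetric in its two atoms.
#'
#' @param atom1,atom2 single-row data.frames with columns name, resname,
#'   element, x, y, z, vdw (as in `clash_structure$atoms`; rotamer atoms
#'   may carry `resname` set to the substituting residue).
#' @param params a `clash_params`.
#' @param cys_context optional list with `ca1`, `ca2`: Ca coordinates of
#'   the two residues, needed only for the cysteine rule.
#' @return A `clash_result` list: `overlap_c` (A), `rule` ("normal",
#'   "hbond" or "cysteine"), `clash` (overlap_c > 0), `atom1`, `atom2`.
#' @export
pair_overlap <- function(atom1, atom2, params = clash_params(),
                         cys_context = NULL) {
  e1 <- toupper(atom1$element); e2 <- toupper(atom2$element)
  if (e1 %in% c("H", "D") || e2 %in% c("H", "D"))
    stop("hydrogen atoms must not reach the overlap test")
  p1 <- c(atom1$x, atom1$y, atom1$z)
  p2 <- c(atom2$x, atom2$y, atom2$z)
  d <- vnorm(p1 - p2)
  cys1 <- atom1$name %in% c("CB", "SG") && identical(atom1$resname, "CYS")
  cys2 <- atom2$name %in% c("CB", "SG") && identical(atom2$resname, "CYS")
  if (cys1 && cys2 && !is.null(cys_context)) {
    dca <- vnorm(cys_context$ca1 - cys_context$ca2)
    cval <- params$cys_ca_min - dca
    rule <- "cysteine"
  } else if (e1 %in% c("N", "O") && e2 %in% c("N", "O")) {
    cval <- params$hbond_radius_sum - d - params$d_allowed
    rule <- "hbond"
  } else {
    cval <- atom1$vdw + atom2$vdw - d - params$d_allowed
    rule <- "normal"
  }
  res <- list(overlap_c = cval, rule = rule, clash = cval > 0,
              atom1 = atom1, atom2 = atom2, d_atoms = d)
  class(res) <- "clash_result"
  res
}

#' Test whether a built rotamer fits its environment
#'
#' Applies the overlap test between every side-chain atom strictly after
#' Cb (Cb itself is never tested, so Ala can never clash) and every
#' environment atom. The verdict is `fits = TRUE` iff no pair has positive
#' overlap. With `full_report = FALSE` enumeration stops at the first
#' clash; otherwise all clashing pairs are reported.
#'
#' @param site the substitution site (supplies the Ca for the cysteine
#'   rule).
#' @param sidechain data.frame from [build_side_chain()].
#' @param env environment atoms from [neighborhood()] (or any atom table).
#' @param params a `clash_params`.
#' @param to_aa substituting residue (three-letter); enables the cysteine
#'   rule when it is CYS.
#' @param structure optional `clash_structure`, used to look up Ca
#'   positions of environment cysteines.
#' @param full_report report every clashing pair instead of stopping at
#'   the first.
#' @return List with `fits` (logical) and `clashes` (data.frame with
#'   overlap_A, rule, atom, partner_chain, partner_resno, partner_icode,
#'   partner_atom).
#' @export
rotamer_fits <- function(site, sidechain, env, params = clash_params(),
                         to_aa = "ALA", structure = NULL,
                         full_report = FALSE) {
  to_aa <- toupper(to_aa)
  test <- sidechain[sidechain$name != "CB", , drop = FALSE]
  empty <- data.frame(overlap_A = numeric(), rule = character(),
                      atom = character(), partner_chain = character(),
                      partner_resno = integer(), partner_icode = character(),
                      partner_atom = character(), stringsAsFactors = FALSE)
  if (!nrow(test) || !nrow(env))
    return(list(fits = TRUE, clashes = empty))
  ex <- env$x; ey <- env$y; ez <- env$z
  er <- env$vdw
  e_no <- env$element %in% c("N", "O")
  env_cys <- env$resname == "CYS" & env$name %in% c("CB", "SG") & !env$hetero
  sc_rad <- radius_for(test$element, params$radii)
  site_ca <- as.numeric(site$atoms[site$atoms$name == "CA", c("x", "y", "z")])
  clashes <- empty
  fits <- TRUE
  for (i in seq_len(nrow(test))) {
    d <- sqrt((ex - test$x[i])^2 + (ey - test$y[i])^2 + (ez - test$z[i])^2)
    rsum <- sc_rad[i] + er
    rule <- rep("normal", length(d))
    if (test$element[i] %in% c("N", "O")) {
      rsum[e_no] <- params$hbond_radius_sum
      rule[e_no] <- "hbond"
    }
    cval <- rsum - d - params$d_allowed
    if (to_aa == "CYS" && test$name[i] %in% c("CB", "SG") &&
        any(env_cys) && !is.null(structure)) {
      for (j in which(env_cys)) {
        ca2 <- cys_ca(structure, env$chain[j], env$resno[j], env$icode[j])
        if (is.null(ca2)) next
        cval[j] <- params$cys_ca_min - vnorm(site_ca - ca2)
        rule[j] <- "cysteine"
      }
    }
    hit <- which(cval > 0)
    if (length(hit)) {
      fits <- FALSE
      clashes <- rbind(clashes, data.frame(
        overlap_A = cval[hit], rule = rule[hit], atom = test$name[i],
        partner_chain = env$chain[hit], partner_resno = env$resno[hit],
        partner_icode = env$icode[hit], partner_atom = env$name[hit],
        stringsAsFactors = FALSE))
      if (!full_report) break
    }
  }
  list(fits = fits, clashes = clashes)
}

cys_ca <- function(structure, chain, resno, icode) {
  at <- structure$atoms
  i <- which(!at$hetero & at$chain == chain & at$resno == resno &
               at$icode == icode & at$name == "CA")
  if (!length(i)) return(NULL)
  as.numeric(at[i[1], c("x", "y", "z")])
}

#' @export
print.clash_params <- function(x, ...) {
  cat("clash_params: d_allowed = ", x$d_allowed,
      " A, hbond radius sum = ", x$hbond_radius_sum,
      " A, Cys Ca min = ", x$cys_ca_min,
      " A, search cutoff = ", round(x$search_cutoff, 2), " A\n", sep = "")
  invisible(x)
}
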