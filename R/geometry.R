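# Torsion angles, internal-coordinate atom placement, side-chain building.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-10) stop("degenerate geometry: zero-length vector")
  a / n
}

#' Signed dihedral angle of four points
#'
#' Standard signed torsion under the IUPAC convention: looking from `p2`
#' toward `p3`, a clockwise rotation of `p4` relative to `p1` is positive.
#' Satisfies `dihedral(p4, p3, p2, p1) == dihedral(p1, p2, p3, p4)`.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 1))  # 45
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8)
    stop("undefined torsion: three consecutive points are collinear")
  b2u <- vunit(b2)
  m <- vcross(n1, b2u)
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF-style) placement: returns the point `d` at bond
#' length `bond` from `a3`, bond angle `angle` at `a3` (between `a2`, `a3`,
#' `d`), and dihedral `torsion` for the chain `a1-a2-a3-d` (as measured by
#' [dihedral()]).
#'
#' @param a1,a2,a3 numeric 3-vectors, the three bonded ancestors
#'   (`a3` is the parent the new atom bonds to).
#' @param bond bond length, Angstrom.
#' @param angle bond angle, degrees.
#' @param torsion dihedral angle, degrees.
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a1, a2, a3, bond, angle, torsion) {
  ar <- angle * pi / 180
  tr <- -torsion * pi / 180
  d2 <- bond * c(-cos(ar), sin(ar) * cos(tr), sin(ar) * sin(tr))
  bc <- vunit(a3 - a2)
  n <- vunit(vcross(a2 - a1, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(a3 + m %*% d2)
}

# Improper dihedral C-N-CA-CB fixed for L-amino acids.
CB_IMPROPER <- 122.55
CB_BOND <- 1.53
CB_ANGLE <- 110.4  # N-CA-CB

#' Construct an ideal C-beta position from the backbone triad
#'
#' Places Cb at 1.53 A from Ca with the standard N-Ca-Cb angle and the
#' improper dihedral C-N-Ca-Cb = +122.55 degrees, the side consistent with
#' L-amino-acid chirality. Used both to host replacement side chains and to
#' give Gly sites a defined Cb direction.
#'
#' @param n,ca,c backbone N, C-alpha and C coordinates (3-vectors).
#' @return Cb coordinates (3-vector).
#' @export
build_cb <- function(n, ca, c) {
  place_atom(c, n, ca, CB_BOND, CB_ANGLE, CB_IMPROPER)
}

#' Build an ideal side chain at a residue site
#'
#' Generates the heavy atoms of the `to_aa` side chain in the site's actual
#' backbone frame: Cb from [build_cb()], then each further atom by
#' sequential internal-coordinate placement from the ideal-geometry table,
#' with chi-governed dihedrals taken from `chi` and ring/branch dihedrals
#' fixed at their ideal values.
#'
#' @param site a `residue_site` (see [get_site()]) with N, CA, C present.
#' @param to_aa three- or one-letter code of the substituting residue;
#'   anything but Gly.
#' @param chi numeric vector of chi angles (degrees), length equal to the
#'   residue's chi arity (0 for Ala).
#' @param geom ideal-geometry table, default [ideal_geometry()].
#' @return data.frame of atoms (name, element, x, y, z), Cb first.
#' @export
build_side_chain <- function(site, to_aa, chi = numeric(), geom = ideal_geometry()) {
  to_aa <- if (nchar(to_aa[1]) == 1) aa123(to_aa) else toupper(to_aa)
  if (to_aa == "GLY") stop("glycine has no side chain to build")
  arity <- CHI_ARITY[[to_aa]]
  if (length(chi) != arity)
    stop("chi arity mismatch for ", to_aa, ": expected ", arity,
         ", got ", length(chi))
  bb <- site_backbone(site)
  pos <- list(N = bb$N, CA = bb$CA, C = bb$C)
  pos$CB <- build_cb(bb$N, bb$CA, bb$C)
  rows <- geom[geom$res == to_aa, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tors <- if (r$chi > 0) chi[r$chi] + r$offset_deg else r$offset_deg
    anc <- pos[c(r$a1, r$a2, r$a3)]
    if (any(vapply(anc, is.null, logical(1))))
      stop("geometry table refers to unbuilt ancestor for ", to_aa, " ", r$atom)
    pos[[r$atom]] <- place_atom(anc[[1]], anc[[2]], anc[[3]],
                                r$bond_A, r$angle_deg, tors)
  }
  nm <- c("CB", rows$atom)
  xyz <- do.call(rbind, pos[nm])
  data.frame(name = nm,
             element = substr(nm, 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

site_backbone <- function(site) {
  at <- site$atoms
  get1 <- function(nm) {
    i <- which(at$name == nm)
    if (!length(i)) return(NULL)
    as.numeric(at[i[1], c("x", "y", "z")])
  }
  list(N = get1("N"), CA = get1("CA"), C = get1("C"))
}

#' Backbone phi/psi torsions for every residue site
#'
#' phi(i) = dihedral(C(i-1), N(i), CA(i), C(i)); psi(i) = dihedral(N(i),
#' CA(i), C(i), N(i+1)). Undefined (NA) at chain termini and across chain
#' breaks, where a break is a consecutive CA-CA distance above
#' `break_dist`.
#'
#' @param structure a `clash_structure`.
#' @param break_dist chain-break CA-CA distance threshold, Angstrom.
#' @return data.frame with chain, resno, icode, res_type, phi, psi.
#' @export
backbone_torsions <- function(structure, break_dist = 4.5) {
  sites <- residue_sites(structure)
  n <- length(sites)
  phi <- psi <- rep(NA_real_, n)
  if (n == 0) return(torsion_frame(sites, phi, psi))
  coords <- lapply(sites, site_backbone)
  chain <- vapply(sites, function(s) s$chain, character(1))
  ca_ok <- !vapply(coords, function(b) is.null(b$CA), logical(1))
  linked <- function(i, j) {
    # same chain, consecutive in file order, CA-CA within break_dist
    if (chain[i] != chain[j]) return(FALSE)
    if (!ca_ok[i] || !ca_ok[j]) return(FALSE)
    vnorm(coords[[i]]$CA - coords[[j]]$CA) <= break_dist
  }
  for (i in seq_len(n)) {
    b <- coords[[i]]
    if (is.null(b$N) || is.null(b$CA) || is.null(b$C)) next
    if (i > 1 && linked(i - 1, i) && !is.null(coords[[i - 1]]$C))
      phi[i] <- dihedral(coords[[i - 1]]$C, b$N, b$CA, b$C)
    if (i < n && linked(i, i + 1) && !is.null(coords[[i + 1]]$N))
      psi[i] <- dihedral(b$N, b$CA, b$C, coords[[i + 1]]$N)
  }
  torsion_frame(sites, phi, psi)
}

torsion_frame <- function(sites, phi, psi) {
  data.frame(
    chain = vapply(sites, function(s) s$chain, character(1)),
    resno = as.integer(vapply(sites, function(s) as.numeric(s$resno), numeric(1))),
    icode = vapply(sites, function(s) s$icode, character(1)),
    res_type = vapply(sites, function(s) s$res_type, character(1)),
    phi = phi, psi = psi,
    stringsAsFactors = FALSE
  )
}
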