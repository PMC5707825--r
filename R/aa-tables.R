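# Amino-acid bookkeeping tables shared across the package.

#' Standard amino acid codes
#'
#' Three-letter codes of the 20 standard amino acids, in one-letter
#' alphabetical order (A, C, D, ...). This fixed order is used whenever a
#' position-only variant is expanded to all 19 substitutions.
#'
#' @format Character vector of length 20, named by one-letter code.
#' @export
AA_THREE <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
  G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
  M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
  S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR"
)

#' @rdname AA_THREE
#' @format `AA_ONE` is the inverse map, named by three-letter code.
#' @export
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

#' Convert between one- and three-letter amino acid codes
#'
#' @param x character vector of codes. Case-insensitive.
#' @return Character vector of converted codes; unknown codes raise an error.
#' @examples
#' aa321("ARG")   # "R"
#' aa123("W")     # "TRP"
#' @export
aa321 <- function(x) {
  x <- toupper(x)
  out <- AA_ONE[x]
  if (anyNA(out)) stop("unknown amino acid code(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' @rdname aa321
#' @export
aa123 <- function(x) {
  x <- toupper(x)
  out <- AA_THREE[x]
  if (anyNA(out)) stop("unknown amino acid code(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Side-chain size and chi-angle counts
#'
#' `SIDECHAIN_SIZE` is the heavy-atom count of each side chain (Cb
#' onward; Gly has none) — the notion of "size" used by the
#' smaller-residue decision rule. `CHI_ARITY` is the number of chi
#' dihedrals parameterizing each side chain in the rotamer library.
#'
#' @format Named integer vectors over the three-letter residue codes.
#' @export
SIDECHAIN_SIZE <- c(
  GLY = 0L, ALA = 1L, SER = 2L, CYS = 2L, THR = 3L, VAL = 3L, PRO = 3L,
  ILE = 4L, LEU = 4L, ASP = 4L, ASN = 4L, MET = 4L,
  GLU = 5L, GLN = 5L, LYS = 5L, HIS = 6L, ARG = 7L,
  PHE = 7L, TYR = 8L, TRP = 10L
)

#' @rdname SIDECHAIN_SIZE
#' @export
CHI_ARITY <- c(
  GLY = 0L, ALA = 0L, SER = 1L, CYS = 1L, THR = 1L, VAL = 1L,
  PRO = 2L, ILE = 2L, LEU = 2L, ASP = 2L, ASN = 2L, HIS = 2L,
  PHE = 2L, TYR = 2L, TRP = 2L,
  MET = 3L, GLU = 3L, GLN = 3L,
  LYS = 4L, ARG = 4L
)

# Residue names treated as water and removed during cleanup.
WATER_NAMES <- c("HOH", "WAT", "DOD")

.pkg_cache <- new.env(parent = emptyenv())

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "rotaclash")
  if (!nzchar(path)) {
    # during development (pkgload) system.file resolves; this is a guard
    stop("packaged data file not found: ", file)
  }
  path
}

#' Van der Waals radii of protein heavy atoms
#'
#' Returns the packaged element-to-radius map (Angstrom). The set is a
#' published protein heavy-atom family (C 1.88, N 1.64, O 1.42, S 1.77);
#' the nitrogen value 1.64 also enters the neighbor-search cutoff
#' construction. Elements absent from the table fall back to
#' `default` when radii are assigned.
#'
#' @param path optional path to an alternative two-column table
#'   (element, radius_A; tab-separated, `#` comments allowed).
#' @return Named numeric vector, names are element symbols, plus an
#'   attribute `default` used for unlisted elements.
#' @export
default_radii <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_cache$radii)) return(.pkg_cache$radii)
    path <- pkg_extdata("vdw_radii.tsv")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  r <- stats::setNames(tab$radius_A, toupper(tab$element))
  if (any(r <= 0)) stop("van der Waals radii must be positive")
  fallback <- if ("*" %in% names(r)) unname(r["*"]) else 1.80
  r <- r[names(r) != "*"]
  attr(r, "default") <- fallback
  if (cache) .pkg_cache$radii <- r
  r
}

radius_for <- function(element, radii = default_radii()) {
  out <- radii[toupper(element)]
  out[is.na(out)] <- attr(radii, "default")
  unname(out)
}

#' Maximum side-chain solvent accessibility per residue type
#'
#' Theoretical maxima (Angstrom^2) of the side-chain solvent-accessible
#' surface area, computed with this package's Shrake-Rupley implementation
#' on extended Gly-X-Gly tripeptides built from the ideal-geometry table
#' (all chi = 180 degrees, probe 1.4 A, 960 points per atom). Used only by
#' the relative-accessibility decision rule, which thresholds at 0.5, so
#' modest differences from other published maxima rarely flip decisions.
#' Glycine has no side chain and is absent from the table.
#'
#' @param path optional alternative table (res, max_asa_A2; tab-separated).
#' @return Named numeric vector by three-letter residue code.
#' @export
max_sidechain_asa <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_cache$max_asa)) return(.pkg_cache$max_asa)
    path <- pkg_extdata("max_sidechain_asa.tsv")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  v <- stats::setNames(tab$max_asa_A2, toupper(tab$res))
  if (any(v <= 0)) stop("maximum accessibilities must be positive")
  if (cache) .pkg_cache$max_asa <- v
  v
}

#' Ideal side-chain internal-coordinate table
#'
#' One row per side-chain heavy atom beyond Cb, giving the three bonded
#' ancestors, the bond length to the parent, the bond angle at the parent,
#' and the dihedral rule: `chi` 1-4 means the atom's dihedral is the
#' corresponding rotamer chi angle plus `offset`; `chi` 0 means a fixed
#' dihedral equal to `offset` (ring closure, branch, terminal group).
#' Atoms are listed in buildable order (every ancestor precedes its
#' dependents). Bond lengths and angles follow standard ideal-geometry
#' compilations.
#'
#' @param path optional alternative table with columns
#'   res, atom, a1, a2, a3, bond_A, angle_deg, chi, offset_deg.
#' @return data.frame with the columns above.
#' @export
ideal_geometry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_cache$geom)) return(.pkg_cache$geom)
    path <- pkg_extdata("sidechain_geometry.tsv")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("res", "atom", "a1", "a2", "a3", "bond_A", "angle_deg", "chi", "offset_deg")
  if (!all(need %in% names(tab))) stop("geometry table lacks required columns")
  if (any(tab$bond_A < 1.2 | tab$bond_A > 1.9))
    stop("bond length outside [1.2, 1.9] A in geometry table")
  if (any(tab$angle_deg <= 0 | tab$angle_deg >= 180))
    stop("bond angle outside (0, 180) in geometry table")
  if (cache) .pkg_cache$geom <- tab
  tab
}
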