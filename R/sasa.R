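# Shrake-Rupley solvent-accessible surface area and the side-chain
# relative-accessibility ratio used by the fast decision rules.

# Deterministic quasi-uniform sphere points (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' Numerical SASA: each atom's sphere of radius `vdw + probe` is covered
#' with `n_points` quasi-uniform test points; the accessible area is the
#' fraction of points not buried inside any neighboring atom's probe-
#' expanded sphere. All atoms of the structure, including hetero atoms,
#' occlude each other.
#'
#' @param structure a `clash_structure`.
#' @param probe probe radius, Angstrom (water = 1.4).
#' @param n_points test points per atom; at least 16.
#' @return Numeric vector, one area (Angstrom^2) per row of
#'   `structure$atoms`.
#' @export
atom_sasa <- function(structure, probe = 1.4, n_points = 960) {
  if (n_points < 16) stop("n_points must be at least 16 for a usable quadrature")
  at <- structure$atoms
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- at$vdw + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rad[i]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ri + rad)^2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 >= rad[j]^2
    }
    out[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  out
}

#' Side-chain absolute accessibility per residue site
#'
#' Sums the per-atom SASA over each site's side-chain atoms (Cb onward;
#' Ca is counted as backbone). Glycine sites get 0.
#'
#' @inheritParams atom_sasa
#' @return data.frame with chain, resno, icode, res_type, sidechain_asa
#'   (Angstrom^2), in site order.
#' @export
sidechain_sasa <- function(structure, probe = 1.4, n_points = 960) {
  asa <- atom_sasa(structure, probe = probe, n_points = n_points)
  at <- structure$atoms
  backbone <- c("N", "CA", "C", "O", "OXT")
  sites <- residue_sites(structure)
  val <- vapply(sites, function(s) {
    i <- as.integer(rownames(s$atoms))
    sel <- !(s$atoms$name %in% backbone)
    if (s$res_type == "GLY" || !any(sel)) return(0)
    sum(asa[i[sel]])
  }, numeric(1))
  cbind(torsion_frame(sites, NA_real_, NA_real_)[, 1:4],
        sidechain_asa = val)
}

#' Relative side-chain accessibility
#'
#' Ratio between a side chain's absolute accessibility and the residue
#' type's maximum possible side-chain accessibility. Not clamped: values
#' slightly above 1 can occur and are meaningful only against the 0.5
#' decision threshold.
#'
#' @param abs_asa absolute side-chain SASA, Angstrom^2.
#' @param res_type three-letter residue code; Gly is refused (no side
#'   chain).
#' @param max_table maximum-accessibility table, default
#'   [max_sidechain_asa()].
#' @return Fraction (>= 0).
#' @export
relative_accessibility <- function(abs_asa, res_type,
                                   max_table = max_sidechain_asa()) {
  res_type <- toupper(res_type)
  if (res_type == "GLY")
    stop("glycine has no side chain: relative accessibility is undefined")
  mx <- max_table[res_type]
  if (is.na(mx)) stop("no maximum accessibility for residue type ", res_type)
  if (abs_asa < 0) stop("negative accessibility")
  unname(abs_asa / mx)
}
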