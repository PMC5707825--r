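# PDB-format reading/writing and the cleanup rules the method assumes:
# first model only, hydrogens dropped, waters removed, one altloc per atom,
# MSE mapped to Met, other nonstandard polymer residues treated as hetero.

#' Parse a PDB-format string into a cleaned structure
#'
#' Parsing is delegated to \pkg{bio3d}; this wrapper then applies the
#' cleanup the prediction method assumes: only the first MODEL is kept;
#' hydrogen (and deuterium) atoms are dropped; waters (HOH/WAT/DOD) are
#' removed entirely; for alternate locations the highest-occupancy
#' conformer is kept (ties broken toward altloc "A", then lexicographic);
#' selenomethionine (MSE) is mapped to Met and kept as polymer; all other
#' non-water HETATM records are retained as hetero atoms so ligands and
#' cofactors take part in clash testing. Van der Waals radii are assigned
#' per element from `radii`.
#'
#' @param text a single string (or character vector of lines) in PDB format.
#' @param source_id identifier stored on the structure (e.g. file name).
#' @param radii element radius table, default [default_radii()].
#' @return An object of class `clash_structure`: list with `atoms` (one row
#'   per heavy atom: serial, name, altloc, resname, chain, resno, icode,
#'   x, y, z, occ, element, vdw, hetero) and `source_id`.
#' @seealso [read_pdb()], [write_pdb()], [get_site()]
#' @export
parse_pdb <- function(text, source_id = "structure", radii = default_radii()) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  # keep first model only
  end <- grep("^ENDMDL", lines)
  if (length(end)) lines <- lines[seq_len(end[1] - 1L)]
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM records found in input")
  bad <- which(rec & (nchar(lines) < 54 |
                        is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
                        is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
                        is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad))
    stop("malformed ATOM/HETATM record at line ", bad[1], ": ",
         substr(lines[bad[1]], 1, 30))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = toupper(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             substr(trimws(at$elety), 1, 1), at$elesy)),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in input")
  # cleanup: hydrogens, waters
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  atoms <- atoms[!(atoms$resname %in% WATER_NAMES), , drop = FALSE]
  # altloc resolution: keep the highest-occupancy conformer per atom identity
  atoms <- resolve_altlocs(atoms)
  # MSE -> MET as polymer; other nonstandard polymer residues become hetero
  mse <- atoms$resname == "MSE"
  atoms$resname[mse] <- "MET"
  atoms$hetero[mse] <- FALSE
  nonstd <- !atoms$hetero & !(atoms$resname %in% AA_THREE)
  atoms$hetero[nonstd] <- TRUE
  if (!nrow(atoms) || all(atoms$hetero))
    stop("structure is empty after cleanup")
  atoms$vdw <- radius_for(atoms$element, radii)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id),
            class = "clash_structure")
}

resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
               atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- atoms[idx, ]
    best <- which(sub$occ == max(sub$occ))
    if (length(best) > 1L) {
      a <- which(sub$altloc[best] == "A")
      best <- if (length(a)) best[a[1]] else best[order(sub$altloc[best])[1]]
    }
    idx[best]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Read and clean a PDB file
#'
#' @param file path to a PDB-format file.
#' @param ... passed on to [parse_pdb()].
#' @return A `clash_structure`.
#' @export
read_pdb <- function(file, ...) {
  parse_pdb(readLines(file, warn = FALSE),
            source_id = sub("\\.pdb$", "", basename(file)), ...)
}

#' Serialize a structure back to PDB format
#'
#' Writes standard fixed-column ATOM/HETATM records (wwPDB v3.3 columns)
#' with a TER after the polymer and END at the end. Round-trips through
#' [parse_pdb()] preserving atom names, residue numbering, insertion codes
#' and coordinates to three decimals.
#'
#' @param structure a `clash_structure`.
#' @param file optional path; when given the text is also written there.
#' @return Character vector of PDB lines, invisibly when `file` is given.
#' @export
write_pdb <- function(structure, file = NULL) {
  at <- structure$atoms
  if (!nrow(at)) stop("cannot write an empty structure")
  ord <- order(at$hetero)
  at <- at[ord, , drop = FALSE]
  fmt_name <- function(nm, el) {
    # element symbols of one letter start in column 14
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
           ifelse(nchar(el) == 1, sprintf(" %-3s", nm), sprintf("%-4s", nm)))
  }
  lines <- sprintf(
    "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$hetero, "HETATM", "ATOM"),
    seq_len(nrow(at)),
    fmt_name(at$name, at$element), substr(paste0(at$altloc, " "), 1, 1),
    at$resname, ifelse(at$chain == "", "A", at$chain), at$resno,
    substr(paste0(at$icode, " "), 1, 1),
    at$x, at$y, at$z, at$occ, 0, at$element
  )
  npoly <- sum(!at$hetero)
  out <- c(lines[seq_len(npoly)], "TER",
           if (npoly < length(lines)) lines[(npoly + 1):length(lines)],
           "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Residue sites of a structure
#'
#' Groups the polymer (non-hetero) atoms into residue sites in file order.
#'
#' @param structure a `clash_structure`.
#' @return List of `residue_site` objects: chain, resno, icode, res_type
#'   (three-letter), atoms (data.frame), usable (has N, CA and C).
#' @export
residue_sites <- function(structure) {
  at <- structure$atoms[!structure$atoms$hetero, , drop = FALSE]
  if (!nrow(at)) return(list())
  key <- paste(at$chain, at$resno, at$icode, sep = "\r")
  idx <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  out <- lapply(idx, function(i) {
    sub <- at[i, , drop = FALSE]
    site <- list(
      chain = sub$chain[1],
      resno = sub$resno[1],
      icode = sub$icode[1],
      res_type = sub$resname[1],
      atoms = sub,
      usable = all(c("N", "CA", "C") %in% sub$name)
    )
    class(site) <- "residue_site"
    site
  })
  names(out) <- NULL
  out
}

#' Look up a residue site by author numbering
#'
#' Residue identity is (chain, author sequence number, insertion code)
#' exactly as in the PDB file; no renumbering is applied.
#'
#' @param structure a `clash_structure`.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param icode insertion code, default none.
#' @return A `residue_site`.
#' @export
get_site <- function(structure, chain, resno, icode = "") {
  sites <- residue_sites(structure)
  hit <- Filter(function(s) s$chain == chain && s$resno == resno &&
                  s$icode == icode, sites)
  if (!length(hit))
    stop("position not found in structure: ", chain, ":", resno, icode,
         " (check that variant numbering matches the structure)")
  s <- hit[[1]]
  if (!s$usable)
    stop("incomplete backbone (need N, CA, C) at ", chain, ":", resno, icode)
  s
}

#' @export
print.clash_structure <- function(x, ...) {
  at <- x$atoms
  sites <- residue_sites(x)
  cat("clash_structure '", x$source_id, "': ", length(sites),
      " residues, ", sum(!at$hetero), " polymer atoms, ",
      sum(at$hetero), " hetero atoms\n", sep = "")
  invisible(x)
}

#' @export
print.residue_site <- function(x, ...) {
  cat("residue_site ", x$chain, ":", x$resno, x$icode, " ", x$res_type,
      " (", nrow(x$atoms), " atoms)\n", sep = "")
  invisible(x)
}
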