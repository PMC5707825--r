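# Backbone-dependent rotamer library: loading, binning, ordered queries.

#' Load a backbone-dependent rotamer library
#'
#' Reads a whitespace/tab-separated table with columns `res phi psi freq
#' chi1 chi2 chi3 chi4` (unused chi columns given as `.`), bins rows by
#' (phi, psi) on a half-open grid of `bin_width` degrees, sorts each bin's
#' rotamers by descending frequency (ties by ascending chi1), and
#' aggregates a backbone-independent marginal per residue type for sites
#' whose phi or psi is undefined. The marginal merges rotamers across bins
#' by their chi tuple (1-degree resolution), averages the chi values and
#' renormalizes the summed frequencies.
#'
#' @param path library file.
#' @param bin_width bin width in degrees (the packaged minimal library uses
#'   30; full-resolution libraries typically 10).
#' @return An object of class `rotamer_library`.
#' @export
load_rotamer_library <- function(path, bin_width = 10) {
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = ".")
  need <- c("res", "phi", "psi", "freq", "chi1", "chi2", "chi3", "chi4")
  if (!all(need %in% names(raw))) stop("rotamer library lacks required columns")
  raw$res <- toupper(raw$res)
  bad <- which(!(raw$res %in% names(CHI_ARITY)))
  if (length(bad))
    stop("unknown residue name in rotamer library, row ", bad[1], ": ",
         raw$res[bad[1]])
  chim <- as.matrix(raw[, c("chi1", "chi2", "chi3", "chi4")])
  arity <- CHI_ARITY[raw$res]
  given <- rowSums(!is.na(chim))
  bad <- which(given != arity)
  if (length(bad))
    stop("chi arity mismatch in rotamer library, row ", bad[1], ": ",
         raw$res[bad[1]], " expects ", arity[bad[1]], " chi value(s), got ",
         given[bad[1]])
  if (any(is.na(raw$freq) | raw$freq < 0))
    stop("rotamer frequencies must be nonnegative")
  lib <- list(bin_width = bin_width, entries = list(), marginal = list())
  key <- paste(raw$res, angle_bin(raw$phi, bin_width),
               angle_bin(raw$psi, bin_width), sep = "|")
  for (k in unique(key)) {
    rows <- raw[key == k, , drop = FALSE]
    lib$entries[[k]] <- sort_rotamers(rows)
  }
  for (res in unique(raw$res)) {
    rows <- raw[raw$res == res, , drop = FALSE]
    nbin <- length(unique(key[raw$res == res]))
    sig <- apply(round(as.matrix(rows[, c("chi1", "chi2", "chi3", "chi4")])),
                 1, paste, collapse = ",")
    agg <- lapply(split(seq_len(nrow(rows)), sig), function(i) {
      r <- rows[i[1], , drop = FALSE]
      r[, c("chi1", "chi2", "chi3", "chi4")] <-
        t(colMeans(rows[i, c("chi1", "chi2", "chi3", "chi4"), drop = FALSE]))
      r$freq <- sum(rows$freq[i]) / nbin
      r
    })
    agg <- do.call(rbind, agg)
    agg$freq <- agg$freq / sum(agg$freq)
    lib$marginal[[res]] <- sort_rotamers(agg)
  }
  class(lib) <- "rotamer_library"
  lib
}

angle_bin <- function(x, width) {
  # half-open [lo, hi) bins covering (-180, 180]; 180 wraps into the
  # first bin so every angle maps to exactly one bin
  x <- ((x + 180) %% 360) - 180
  as.integer(floor((x + 180) / width))
}

sort_rotamers <- function(rows) {
  rows <- rows[order(-rows$freq, rows$chi1), , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    chi <- as.numeric(rows[i, c("chi1", "chi2", "chi3", "chi4")])
    rot <- list(res_type = rows$res[i],
                chi = chi[!is.na(chi)],
                frequency = rows$freq[i])
    class(rot) <- "rotamer"
    rot
  })
}

#' The packaged minimal rotamer library
#'
#' Loads (and caches) the embedded minimal library: canonical chi modes
#' with approximate literature frequencies in coarse 30-degree bins for the
#' helix and sheet backbone regions. It keeps the predictor fully
#' exercisable offline; substitute a full-resolution library via
#' [load_rotamer_library()] for production use.
#'
#' @return A `rotamer_library`.
#' @export
default_rotamer_library <- function() {
  if (is.null(.pkg_cache$rotlib))
    .pkg_cache$rotlib <- load_rotamer_library(
      pkg_extdata("rotamers_minimal.tsv"), bin_width = 30)
  .pkg_cache$rotlib
}

#' Candidate rotamers for a substitution, most frequent first
#'
#' Returns the rotamers of `res_type` for the backbone bin containing
#' (phi, psi), sorted by descending frequency. When phi or psi is
#' undefined (NA), or when the bin holds no entry for the residue, the
#' backbone-independent marginal list is returned. Rotamers below
#' `min_frequency` are dropped (default keeps all).
#'
#' @param lib a `rotamer_library`.
#' @param res_type three- or one-letter amino acid code with at least one
#'   chi angle (Gly and Ala are refused: they are placed directly).
#' @param phi,psi backbone torsions in degrees, or NA.
#' @param min_frequency frequency floor in [0, 1].
#' @return List of `rotamer` objects (possibly empty after filtering).
#' @export
candidate_rotamers <- function(lib, res_type, phi, psi, min_frequency = 0) {
  res_type <- if (nchar(res_type[1]) == 1) aa123(res_type) else toupper(res_type)
  if (CHI_ARITY[[res_type]] == 0L)
    stop(res_type, " has no rotamers; use direct placement")
  rots <- NULL
  if (!is.na(phi) && !is.na(psi)) {
    k <- paste(res_type, angle_bin(phi, lib$bin_width),
               angle_bin(psi, lib$bin_width), sep = "|")
    rots <- lib$entries[[k]]
  }
  if (is.null(rots)) rots <- lib$marginal[[res_type]]
  if (is.null(rots)) return(list())
  Filter(function(r) r$frequency >= min_frequency, rots)
}

#' @export
print.rotamer <- function(x, ...) {
  cat("rotamer ", x$res_type, " chi = [",
      paste(round(x$chi, 1), collapse = ", "),
      "] freq = ", signif(x$frequency, 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.rotamer_library <- function(x, ...) {
  cat("rotamer_library: ", length(x$entries), " backbone bins (",
      x$bin_width, " deg), ", length(x$marginal),
      " residue types\n", sep = "")
  invisible(x)
}
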