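# Variant-list parsing and the tabular report; the exec/ script wraps
# these for command-line use.

#' Parse a variant list, one variant per line
#'
#' Accepted line forms: `"123"` (position only, default chain: predicts
#' all 19 substitutions), `"A:123"` (chain and position), `"L123R"` or
#' `"A:L123R"` (explicit substitution, one-letter codes), each with an
#' optional insertion-code suffix directly after the number (`"123A"`,
#' `"A:L123AR"`). Blank lines and `#` comments are skipped.
#'
#' @param text a single string or character vector of lines.
#' @return List of `variant` objects.
#' @export
parse_variant_lines <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln)) next
    chain <- ""
    if (grepl(":", ln, fixed = TRUE)) {
      parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !nzchar(parts[1]))
        stop("cannot parse variant line ", i, ": '", lines[i], "'")
      chain <- parts[1]
      ln <- parts[2]
    }
    m <- regmatches(ln, regexec("^([A-Za-z]?)([0-9]+)([A-Za-z]?)([A-Za-z]?)$", ln))[[1]]
    if (!length(m))
      stop("cannot parse variant line ", i, ": '", lines[i], "'")
    from <- toupper(m[2]); pos <- as.integer(m[3])
    s1 <- toupper(m[4]); s2 <- toupper(m[5])
    # suffix letters: either "<icode>", "<to>", or "<icode><to>"
    if (nzchar(from) && !nzchar(s1))
      stop("cannot parse variant line ", i,
           ": substitution needs a target amino acid: '", lines[i], "'")
    icode <- ""; to <- NA_character_
    if (nzchar(s2)) {
      icode <- s1; to <- s2
    } else if (nzchar(s1)) {
      if (nzchar(from)) to <- s1 else icode <- s1
    }
    ok <- function(a) is.na(a) || a %in% names(AA_THREE)
    if (!ok(to) || (nzchar(from) && !(from %in% names(AA_THREE))))
      stop("invalid amino acid code on variant line ", i, ": '", lines[i], "'")
    out[[length(out) + 1L]] <- variant(
      chain = chain, resno = pos,
      to_aa = if (is.na(to)) NA else to,
      from_aa = if (nzchar(from)) from else NA,
      icode = icode)
  }
  out
}

#' Tabulate batch predictions as a report data.frame
#'
#' One row per (expanded) variant, deterministic order matching the
#' prediction list. Failed variants appear with verdict `"error"` and the
#' message in the warnings column.
#'
#' @param predictions list from [predict_substitutions()].
#' @param structure_id identifier placed in the first column.
#' @return data.frame with columns structure_id, chain, position, icode,
#'   from_aa, to_aa, verdict, decision_path, fitting_rotamer_chis,
#'   n_clashes, worst_overlap_A, clash_partners, warnings.
#' @export
prediction_report <- function(predictions, structure_id = "structure") {
  rows <- lapply(predictions, function(p) {
    if (inherits(p, "clash_error")) {
      v <- p$variant
      return(data.frame(
        structure_id = structure_id, chain = v$chain, position = v$resno,
        icode = v$icode, from_aa = "", to_aa = if (is.na(p$to_aa)) "" else
          aa321(p$to_aa),
        verdict = "error", decision_path = "", fitting_rotamer_chis = "",
        n_clashes = NA_integer_, worst_overlap_A = NA_real_,
        clash_partners = "", warnings = p$message,
        stringsAsFactors = FALSE))
    }
    v <- p$variant
    cl <- p$clashes
    data.frame(
      structure_id = structure_id, chain = v$chain, position = v$resno,
      icode = v$icode, from_aa = aa321(p$site_res), to_aa = aa321(v$to_aa),
      verdict = p$verdict, decision_path = p$decision_path,
      fitting_rotamer_chis = if (is.null(p$fitting_rotamer)) "" else
        paste(round(p$fitting_rotamer$chi, 1), collapse = ","),
      n_clashes = nrow(cl),
      worst_overlap_A = if (nrow(cl)) round(max(cl$overlap_A), 3) else NA_real_,
      clash_partners = if (nrow(cl)) paste(
        sprintf("%s:%d%s:%s", cl$partner_chain, cl$partner_resno,
                cl$partner_icode, cl$partner_atom), collapse = ";") else "",
      warnings = paste(p$warnings, collapse = "; "),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run a full clash scan: structure file + variant lines to TSV report
#'
#' Thin end-to-end driver used by the command-line script: reads and
#' cleans the structure, parses the variant list, predicts every
#' (expanded) variant and writes a tab-separated report. Deterministic:
#' identical inputs produce byte-identical reports.
#'
#' @param structure_file path to a PDB file.
#' @param variant_text variant list text or lines (see
#'   [parse_variant_lines()]).
#' @param out_file optional path for the TSV report.
#' @param d_allowed overlap tolerance, Angstrom.
#' @param rotamer_library_path optional path to a full rotamer library
#'   (default: the embedded minimal library).
#' @param rotamer_bin_width bin width for a loaded library, degrees.
#' @param exclude_hetero drop non-water hetero atoms before prediction.
#' @param strict_from fail variants whose `from_aa` mismatches the
#'   structure (default TRUE).
#' @return The report data.frame, invisibly when `out_file` is given.
#' @export
clash_scan <- function(structure_file, variant_text, out_file = NULL,
                       d_allowed = 0.4, rotamer_library_path = NULL,
                       rotamer_bin_width = 10, exclude_hetero = FALSE,
                       strict_from = TRUE) {
  structure <- read_pdb(structure_file)
  if (exclude_hetero)
    structure$atoms <- structure$atoms[!structure$atoms$hetero, , drop = FALSE]
  lib <- if (is.null(rotamer_library_path)) default_rotamer_library() else
    load_rotamer_library(rotamer_library_path, bin_width = rotamer_bin_width)
  variants <- parse_variant_lines(variant_text)
  preds <- predict_substitutions(structure, variants, lib = lib,
                                 cparams = clash_params(d_allowed = d_allowed),
                                 strict_from = strict_from)
  rep <- prediction_report(preds, structure_id = structure$source_id)
  if (!is.null(out_file)) {
    utils::write.table(rep, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
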