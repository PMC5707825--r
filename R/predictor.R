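# The decision cascade: fast assumptions about accessibility and size,
# then exhaustive rotamer testing in decreasing frequency order.

#' Variant description
#'
#' @param chain chain identifier ("" = structure's first chain).
#' @param resno author residue number.
#' @param to_aa target amino acid (one- or three-letter), or NA for a
#'   position-only variant (expands to all 19 substitutions).
#' @param from_aa expected original amino acid, or NA to skip the check.
#' @param icode insertion code.
#' @return A `variant` list.
#' @export
variant <- function(chain = "", resno, to_aa = NA, from_aa = NA, icode = "") {
  norm <- function(a) {
    if (is.na(a)) return(NA_character_)
    if (nchar(a) == 1) aa123(a) else toupper(a)
  }
  v <- list(chain = chain, resno = as.integer(resno), icode = icode,
            from_aa = norm(from_aa), to_aa = norm(to_aa))
  if (!is.na(v$from_aa) && !is.na(v$to_aa) && v$from_aa == v$to_aa)
    stop("variant must substitute a different amino acid")
  class(v) <- "variant"
  v
}

#' Fast-path decision parameters
#'
#' The assumption rules: (a) glycine fits everywhere; (b) if the original
#' side chain's relative accessibility is at least
#' `accessibility_threshold` (default 0.5) and it is at least
#' `min_sidechain_length` (default 3) heavy atoms long, all substitutions
#' fit; (c) a substitution to a smaller side chain fits, unless the target
#' is one of the short-but-branched `branched_exceptions` (default Val,
#' Leu, Ile, Thr), which must still pass rotamer testing. "Size" is the
#' side-chain heavy-atom count.
#'
#' @param accessibility_threshold fraction in [0, 1].
#' @param min_sidechain_length heavy atoms.
#' @param branched_exceptions character vector of three-letter codes.
#' @param min_frequency rotamer frequency floor passed to
#'   [candidate_rotamers()].
#' @return A `decision_params` list.
#' @export
decision_params <- function(accessibility_threshold = 0.5,
                            min_sidechain_length = 3L,
                            branched_exceptions = c("VAL", "LEU", "ILE", "THR"),
                            min_frequency = 0) {
  p <- list(accessibility_threshold = accessibility_threshold,
            min_sidechain_length = as.integer(min_sidechain_length),
            branched_exceptions = toupper(branched_exceptions),
            min_frequency = min_frequency,
            sidechain_size = SIDECHAIN_SIZE)
  class(p) <- "decision_params"
  p
}

#' Apply the fast-path assumptions to one substitution
#'
#' @param site a `residue_site`; its `rel_acc` field (set by
#'   [annotate_structure()] or supplied manually) feeds the accessibility
#'   rule. A missing `rel_acc` simply disables that rule.
#' @param to_aa substituting amino acid (three-letter).
#' @param params a `decision_params`.
#' @return `"glycine_rule"`, `"accessible_rule"`, `"smaller_rule"` (the
#'   substitution fits by assumption) or `NA` (unknown: rotamer testing is
#'   required).
#' @export
apply_assumptions <- function(site, to_aa, params = decision_params()) {
  to_aa <- toupper(to_aa)
  sz <- params$sidechain_size
  if (to_aa == "GLY") return("glycine_rule")
  rel <- site$rel_acc
  if (!is.null(rel) && !is.na(rel) &&
      sz[[site$res_type]] >= params$min_sidechain_length &&
      rel >= params$accessibility_threshold)
    return("accessible_rule")
  if (sz[[to_aa]] < sz[[site$res_type]] &&
      !(to_aa %in% params$branched_exceptions))
    return("smaller_rule")
  NA_character_
}

#' Annotate a structure's residue sites with torsions and accessibility
#'
#' Computes backbone phi/psi and side-chain relative accessibility once
#' for every site, for reuse across many predictions.
#'
#' @param structure a `clash_structure`.
#' @param probe,n_points passed to [sidechain_sasa()].
#' @return List of annotated `residue_site`s (fields `phi`, `psi`,
#'   `sidechain_asa`, `rel_acc` added; `rel_acc` is NA for Gly).
#' @export
annotate_structure <- function(structure, probe = 1.4, n_points = 960) {
  sites <- residue_sites(structure)
  tor <- backbone_torsions(structure)
  asa <- sidechain_sasa(structure, probe = probe, n_points = n_points)
  mx <- max_sidechain_asa()
  for (i in seq_along(sites)) {
    sites[[i]]$phi <- tor$phi[i]
    sites[[i]]$psi <- tor$psi[i]
    sites[[i]]$sidechain_asa <- asa$sidechain_asa[i]
    sites[[i]]$rel_acc <- if (sites[[i]]$res_type == "GLY") NA_real_ else
      relative_accessibility(asa$sidechain_asa[i], sites[[i]]$res_type, mx)
  }
  sites
}

#' Predict whether one substitution fits or clashes
#'
#' The decision cascade: (1) fast-path assumptions
#' ([apply_assumptions()]); (2) substitutions to Ala are placed directly
#' (the Cb is never clash-tested, so they always fit); (3) otherwise the
#' candidate rotamers for the site's (phi, psi) are built in decreasing
#' frequency order and clash-tested against the site's neighborhood; the
#' search stops at the first fitting rotamer. If no rotamer fits the
#' substitution is predicted to cause a clash, reporting the conflicts of
#' the best (least-clashing, ties to the more frequent) rotamer.
#' Substitutions to Pro carry a warning: only the side chain is modeled,
#' so clashes are over-predicted where the backbone would adjust.
#'
#' @param structure a `clash_structure`.
#' @param var a `variant` with a concrete `to_aa`.
#' @param lib rotamer library.
#' @param cparams clash parameters.
#' @param dparams decision parameters.
#' @param site optional pre-annotated site (from [annotate_structure()]);
#'   when NULL the site is located and annotated on the fly.
#' @param env optional precomputed [neighborhood()] for the site.
#' @return A `clash_prediction`: verdict ("fits"/"clash"), decision_path,
#'   fitting_rotamer, clashes, n_rotamers_tested, warnings, variant.
#' @export
predict_substitution <- function(structure, var, lib = default_rotamer_library(),
                                 cparams = clash_params(),
                                 dparams = decision_params(),
                                 site = NULL, env = NULL) {
  if (is.na(var$to_aa)) stop("variant has no target amino acid")
  if (var$chain == "") var$chain <- first_chain(structure)
  if (is.null(site)) {
    site <- get_site(structure, var$chain, var$resno, var$icode)
    tor <- backbone_torsions(structure)
    i <- which(tor$chain == site$chain & tor$resno == site$resno &
                 tor$icode == site$icode)[1]
    site$phi <- tor$phi[i]
    site$psi <- tor$psi[i]
    if (site$res_type != "GLY" &&
        SIDECHAIN_SIZE[[site$res_type]] >= dparams$min_sidechain_length) {
      asa <- sidechain_sasa(structure)
      j <- which(asa$chain == site$chain & asa$resno == site$resno &
                   asa$icode == site$icode)[1]
      site$rel_acc <- relative_accessibility(asa$sidechain_asa[j], site$res_type)
    } else site$rel_acc <- NA_real_
  }
  if (!is.na(var$from_aa) && var$from_aa != site$res_type)
    stop("variant/structure mismatch at ", site$chain, ":", site$resno,
         site$icode, ": structure has ", site$res_type, ", variant expects ",
         var$from_aa)
  if (var$to_aa == site$res_type)
    stop("identity substitution at ", site$chain, ":", site$resno, site$icode)
  warnings <- character()
  if (var$to_aa == "PRO")
    warnings <- "proline substitutions alter the backbone, which is held fixed here; clash over-prediction is likely"
  finish <- function(verdict, path, rot = NULL, clashes = NULL, tested = 0L) {
    out <- list(variant = var, verdict = verdict, decision_path = path,
                fitting_rotamer = rot,
                clashes = if (is.null(clashes))
                  data.frame(overlap_A = numeric(), rule = character(),
                             atom = character(), partner_chain = character(),
                             partner_resno = integer(),
                             partner_icode = character(),
                             partner_atom = character()) else clashes,
                n_rotamers_tested = tested,
                site_res = site$res_type, phi = site$phi, psi = site$psi,
                rel_acc = site$rel_acc, warnings = warnings)
    class(out) <- "clash_prediction"
    out
  }
  path <- apply_assumptions(site, var$to_aa, dparams)
  if (!is.na(path)) return(finish("fits", path))
  if (var$to_aa == "ALA")
    return(finish("fits", "alanine_direct"))
  if (is.null(env)) env <- neighborhood(structure, site, cparams)
  rots <- candidate_rotamers(lib, var$to_aa, site$phi, site$psi,
                             min_frequency = dparams$min_frequency)
  best <- NULL
  best_n <- Inf
  for (k in seq_along(rots)) {
    sc <- build_side_chain(site, var$to_aa, rots[[k]]$chi)
    sc$resname <- var$to_aa
    res <- rotamer_fits(site, sc, env, cparams, to_aa = var$to_aa,
                        structure = structure, full_report = TRUE)
    if (res$fits)
      return(finish("fits", "rotamer_fit", rot = rots[[k]], tested = k))
    if (nrow(res$clashes) < best_n) {
      best <- res$clashes
      best_n <- nrow(res$clashes)
    }
  }
  finish("clash", "no_rotamer_fits", clashes = best,
         tested = length(rots))
}

first_chain <- function(structure) {
  poly <- structure$atoms[!structure$atoms$hetero, , drop = FALSE]
  poly$chain[1]
}

#' Predict a batch of variants
#'
#' Expands position-only variants to all 19 non-identical substitutions
#' (fixed one-letter alphabetical order), annotates the structure once,
#' reuses each site's neighborhood across its substitutions, and isolates
#' per-variant errors so one bad position does not abort the batch.
#'
#' @param structure a `clash_structure`.
#' @param variants list of `variant` objects.
#' @param lib,cparams,dparams see [predict_substitution()].
#' @param strict_from check `from_aa` against the structure (default TRUE).
#' @return List of `clash_prediction` objects (failed variants yield
#'   `clash_error` entries carrying the message), in input order with
#'   position-only variants expanded in place.
#' @export
predict_substitutions <- function(structure, variants,
                                  lib = default_rotamer_library(),
                                  cparams = clash_params(),
                                  dparams = decision_params(),
                                  strict_from = TRUE) {
  sites <- annotate_structure(structure)
  site_key <- vapply(sites, function(s)
    paste(s$chain, s$resno, s$icode, sep = "\r"), character(1))
  env_cache <- new.env(parent = emptyenv())
  out <- list()
  position_error <- function(v, to, msg) {
    err <- list(variant = variant(v$chain, v$resno, to_aa = NA,
                                  icode = v$icode),
                to_aa = to, message = msg)
    class(err) <- "clash_error"
    err
  }
  for (v in variants) {
    if (v$chain == "") v$chain <- first_chain(structure)
    key <- paste(v$chain, v$resno, v$icode, sep = "\r")
    i <- match(key, site_key)
    if (is.na(i) || !sites[[i]]$usable) {
      msg <- if (is.na(i))
        paste0("position not found in structure: ", v$chain, ":", v$resno,
               v$icode) else
        paste0("incomplete backbone at ", v$chain, ":", v$resno, v$icode)
      out[[length(out) + 1L]] <- position_error(v, v$to_aa, msg)
      next
    }
    site <- sites[[i]]
    targets <- if (is.na(v$to_aa))
      setdiff(unname(AA_THREE), site$res_type) else v$to_aa
    for (to in targets) {
      res <- tryCatch({
        vv <- v
        vv$to_aa <- to
        if (!strict_from) vv$from_aa <- NA_character_
        ek <- gsub("\r", "_", key)
        if (is.null(env_cache[[ek]]))
          env_cache[[ek]] <- neighborhood(structure, site, cparams)
        predict_substitution(structure, vv, lib, cparams, dparams,
                             site = site, env = env_cache[[ek]])
      }, error = function(e) position_error(v, to, conditionMessage(e)))
      out[[length(out) + 1L]] <- res
    }
  }
  out
}

#' @export
print.clash_prediction <- function(x, ...) {
  v <- x$variant
  cat(sprintf("%s:%s%s %s -> %s : %s (%s)\n", v$chain, v$resno, v$icode,
              aa321(x$site_res), aa321(v$to_aa), x$verdict, x$decision_path))
  if (!is.null(x$fitting_rotamer))
    cat("  fitting rotamer chi = [",
        paste(round(x$fitting_rotamer$chi), collapse = ", "), "]\n")
  if (nrow(x$clashes))
    cat("  ", nrow(x$clashes), " clashing pair(s), worst overlap ",
        round(max(x$clashes$overlap_A), 2), " A\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
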