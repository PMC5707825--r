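test_that("fast-path assumptions fire per the rule definitions", {
  dp <- decision_params()
  site <- get_site(make_helix(5), "A", 3)  # Ala site
  site$rel_acc <- 0.1
  # glycine fits everywhere
  expect_equal(apply_assumptions(site, "GLY", dp), "glycine_rule")
  # exposed long side chain: everything fits
  lys <- site; lys$res_type <- "LYS"; lys$rel_acc <- 0.7
  expect_equal(apply_assumptions(lys, "TRP", dp), "accessible_rule")
  # buried Arg -> Val: branched target must still be rotamer-tested
  arg <- site; arg$res_type <- "ARG"; arg$rel_acc <- 0.1
  expect_true(is.na(apply_assumptions(arg, "VAL", dp)))
  expect_equal(apply_assumptions(arg, "ASN", dp), "smaller_rule")
  # exposed Ser: side chain too short for the accessibility rule
  ser <- site; ser$res_type <- "SER"; ser$rel_acc <- 0.9
  expect_true(is.na(apply_assumptions(ser, "ARG", dp)))
  # threshold boundary: exactly 0.5 qualifies
  leu <- site; leu$res_type <- "LEU"; leu$rel_acc <- 0.5
  expect_equal(apply_assumptions(leu, "TRP", dp), "accessible_rule")
})

test_that("substitutions to Gly and Ala fit at every site of every fixture", {
  fixtures <- list(make_helix(6), make_cage(2.0), make_blob(4),
                   make_extended_residue("LEU"))
  for (st in fixtures) {
    for (s in residue_sites(st)) {
      if (!s$usable) next
      for (aa in c("GLY", "ALA")) {
        if (s$res_type == aa) next
        p <- predict_substitution(st, variant(s$chain, s$resno, to_aa = aa,
                                              icode = s$icode))
        expect_equal(p$verdict, "fits")
      }
    }
  }
})

test_that("the cage forces clashes for all multi-atom side chains; open space fits", {
  tight <- make_cage(2.0)
  preds <- predict_substitutions(tight, list(variant("A", 1)))
  rep <- prediction_report(preds, "cage")
  expect_equal(nrow(rep), 19)
  multi <- rep$to_aa != "G" & SIDECHAIN_SIZE[aa123(rep$to_aa)] >= 2
  expect_true(all(rep$verdict[multi] == "clash"))
  expect_true(all(rep$decision_path[multi] == "no_rotamer_fits"))
  expect_true(all(rep$verdict[!multi] == "fits"))
  open <- make_cage(15)
  rep2 <- prediction_report(predict_substitutions(open, list(variant("A", 1))), "o")
  expect_true(all(rep2$verdict == "fits"))
})

test_that("clash verdicts report the best rotamer's conflicts", {
  tight <- make_cage(2.0)
  p <- predict_substitution(tight, variant("A", 1, to_aa = "R"))
  expect_equal(p$verdict, "clash")
  expect_equal(p$decision_path, "no_rotamer_fits")
  expect_gt(nrow(p$clashes), 0)
  expect_true(all(p$clashes$overlap_A > 0))
  expect_null(p$fitting_rotamer)
  lib <- default_rotamer_library()
  expect_equal(p$n_rotamers_tested, length(lib$marginal$ARG))
})

test_that("the first fitting rotamer ends the search", {
  h <- make_helix(12, res_type = "LEU")
  p <- predict_substitution(h, variant("A", 6, to_aa = "D"))
  expect_equal(p$verdict, "fits")
  expect_equal(p$decision_path, "rotamer_fit")
  expect_false(is.null(p$fitting_rotamer))
  # the reported rotamer is the most frequent fitting one: no earlier
  # (more frequent) candidate fits
  lib <- default_rotamer_library()
  rots <- candidate_rotamers(lib, "ASP", p$phi, p$psi)
  k <- p$n_rotamers_tested
  expect_equal(rots[[k]]$chi, p$fitting_rotamer$chi)
  if (k > 1) {
    cp <- clash_params()
    site <- get_site(h, "A", 6)
    env <- neighborhood(h, site, cp)
    for (j in seq_len(k - 1)) {
      sc <- build_side_chain(site, "ASP", rots[[j]]$chi)
      sc$resname <- "ASP"
      expect_false(rotamer_fits(site, sc, env, cp, to_aa = "ASP",
                                structure = h)$fits)
    }
  }
})

test_that("proline substitutions carry the backbone warning", {
  h <- make_helix(8)
  p <- predict_substitution(h, variant("A", 4, to_aa = "P"))
  expect_true(any(grepl("proline", p$warnings, ignore.case = TRUE)))
})

test_that("from_aa is validated strictly and identity substitutions refused", {
  h <- make_helix(8)
  expect_error(predict_substitution(h, variant("A", 4, to_aa = "R", from_aa = "L")),
               "mismatch")
  expect_error(predict_substitution(h, variant("A", 4, to_aa = "ALA")),
               "identity")
  p <- predict_substitution(h, variant("A", 4, to_aa = "R", from_aa = "A"))
  expect_s3_class(p, "clash_prediction")
})

test_that("raising d_allowed never converts fits to clash", {
  grid <- expand.grid(gap = c(3.6, 4.0, 4.4), d = c(0, 0.4, 0.8))
  fits <- matrix(NA, 3, 3)
  for (i in seq_len(nrow(grid))) {
    st <- make_cage(grid$gap[i])
    p <- predict_substitution(st, variant("A", 1, to_aa = "S"),
                              cparams = clash_params(d_allowed = grid$d[i]))
    fits[match(grid$gap[i], c(3.6, 4.0, 4.4)),
         match(grid$d[i], c(0, 0.4, 0.8))] <- p$verdict == "fits"
  }
  # per gap, the verdict is monotone non-decreasing in d_allowed
  for (r in 1:3) expect_true(all(diff(as.integer(fits[r, ])) >= 0))
  # the grid spans both verdicts, so the monotonicity check is non-vacuous
  expect_true(any(fits) && !all(fits))
})

test_that("widening the rotamer list never converts fits to clash", {
  h <- make_helix(10, res_type = "LEU")
  for (aa in c("D", "N", "K")) {
    v <- variant("A", 5, to_aa = aa)
    narrow <- predict_substitution(h, v, dparams = decision_params(min_frequency = 0.2))
    wide <- predict_substitution(h, v, dparams = decision_params(min_frequency = 0))
    if (narrow$verdict == "fits") expect_equal(wide$verdict, "fits")
  }
})

test_that("position-only variants expand to 19 ordered predictions", {
  h <- make_helix(6)
  preds <- predict_substitutions(h, list(variant("A", 3)))
  expect_length(preds, 19)
  rep <- prediction_report(preds, "h")
  expect_equal(rep$to_aa, setdiff(names(AA_THREE), "A"))  # site is Ala
  expect_length(predict_substitutions(h, list()), 0)
})

test_that("a bad position does not abort the batch", {
  h <- make_helix(6)
  preds <- predict_substitutions(h, list(
    variant("A", 99, to_aa = "R"),
    variant("A", 3, to_aa = "R")))
  expect_length(preds, 2)
  expect_s3_class(preds[[1]], "clash_error")
  expect_match(preds[[1]]$message, "not found")
  expect_s3_class(preds[[2]], "clash_prediction")
})

test_that("decision paths are mutually consistent with the rule definitions", {
  # cascade audit over a battery: any prediction decided by an assumption
  # was never rotamer-tested, and each path implies its preconditions
  battery <- list(make_helix(8, res_type = "LEU"), make_cage(2.0), make_blob(9))
  dp <- decision_params()
  for (st in battery) {
    sites <- annotate_structure(st)
    preds <- predict_substitutions(st, list(variant("A", sites[[1]]$resno,
                                                    icode = sites[[1]]$icode)))
    site <- sites[[1]]
    for (p in preds) {
      if (inherits(p, "clash_error")) next
      if (p$decision_path %in% c("glycine_rule", "accessible_rule", "smaller_rule"))
        expect_equal(p$n_rotamers_tested, 0)
      switch(p$decision_path,
        glycine_rule = expect_equal(p$variant$to_aa, "GLY"),
        accessible_rule = {
          expect_gte(site$rel_acc, dp$accessibility_threshold)
          expect_gte(SIDECHAIN_SIZE[[site$res_type]], dp$min_sidechain_length)
        },
        smaller_rule = {
          expect_lt(SIDECHAIN_SIZE[[p$variant$to_aa]],
                    SIDECHAIN_SIZE[[site$res_type]])
          expect_false(p$variant$to_aa %in% dp$branched_exceptions)
        },
        no_rotamer_fits = expect_equal(p$verdict, "clash"),
        NULL)
      if (p$verdict == "clash") expect_equal(p$decision_path, "no_rotamer_fits")
      if (!is.null(p$fitting_rotamer)) expect_equal(p$verdict, "fits")
    }
  }
})
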