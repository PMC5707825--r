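test_that("dihedral matches symmetry cases and the frozen oracle value", {
  # planar cis -> 0, trans -> 180
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(1, 1, 0) + c(2, 0, 0)), 0)
  expect_equal(abs(dihedral(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(3, -1, 0))), 180)
  # value frozen from an independent numpy implementation of the IUPAC
  # sign convention
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 1)), 45,
               tolerance = 1e-9)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("dihedral is antisymmetric under chain reversal and rigid motions", {
  set.seed(11)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- c(3, -2, 7)
  for (i in 1:25) {
    p <- lapply(1:4, function(j) rnorm(3))
    d <- try(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]), silent = TRUE)
    if (inherits(d, "try-error")) next
    expect_equal(dihedral(p[[4]], p[[3]], p[[2]], p[[1]]), d)
    q <- lapply(p, function(v) as.numeric(rot %*% v) + shift)
    expect_equal(dihedral(q[[1]], q[[2]], q[[3]], q[[4]]), d, tolerance = 1e-9)
  }
})

test_that("place_atom reproduces the requested internal coordinates", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(3); b <- a + rnorm(3); cc <- b + rnorm(3)
    bond <- runif(1, 1.2, 1.9); ang <- runif(1, 60, 150)
    tor <- runif(1, -179, 180)
    d <- place_atom(a, b, cc, bond, ang, tor)
    expect_equal(sqrt(sum((d - cc)^2)), bond, tolerance = 1e-9)
    v1 <- b - cc; v2 <- d - cc
    expect_equal(acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi,
                 ang, tolerance = 1e-7)
    expect_equal(dihedral(a, b, cc, d), tor, tolerance = 1e-7)
  }
})

test_that("backbone torsions recover the helix construction angles", {
  h <- make_helix(10, phi = -57, psi = -47)
  tor <- backbone_torsions(h)
  expect_true(all(abs(tor$phi[2:9] - (-57)) < 0.5))
  expect_true(all(abs(tor$psi[2:9] - (-47)) < 0.5))
  expect_true(is.na(tor$phi[1]))   # chain start
  expect_true(is.na(tor$psi[10]))  # chain end
})

test_that("no torsion is computed across a chain break", {
  h1 <- make_helix(4)
  h2 <- make_helix(4)
  h2$atoms[, c("x", "y", "z")] <- h2$atoms[, c("x", "y", "z")] + 50
  h2$atoms$resno <- h2$atoms$resno + 4
  both <- h1
  both$atoms <- rbind(h1$atoms, h2$atoms)
  rownames(both$atoms) <- NULL
  tor <- backbone_torsions(both)
  expect_true(is.na(tor$phi[5]))
  expect_true(is.na(tor$psi[4]))
  expect_false(is.na(tor$phi[6]))
})

test_that("build_cb sits on observed Cb positions and commits to L-chirality", {
  h <- make_helix(8)
  for (i in 2:7) {
    n <- atom_xyz(h, i, "N"); ca <- atom_xyz(h, i, "CA")
    cc <- atom_xyz(h, i, "C"); cb <- atom_xyz(h, i, "CB")
    built <- build_cb(n, ca, cc)
    expect_lt(sqrt(sum((built - cb)^2)), 0.25)
    expect_equal(sqrt(sum((built - ca)^2)), 1.53, tolerance = 1e-9)
  }
  # reflection of the backbone: the rule still builds the L side, so the
  # improper stays +122.55 and the built atom is NOT the mirror image
  n <- atom_xyz(h, 4, "N"); ca <- atom_xyz(h, 4, "CA"); cc <- atom_xyz(h, 4, "C")
  mirror <- function(p) c(p[1], p[2], -p[3])
  built_m <- build_cb(mirror(n), mirror(ca), mirror(cc))
  expect_equal(dihedral(mirror(cc), mirror(n), mirror(ca), built_m), 122.55,
               tolerance = 1e-6)
  expect_gt(sqrt(sum((built_m - mirror(build_cb(n, ca, cc)))^2)), 0.5)
})

test_that("built side chains honor the ideal-geometry table exactly", {
  h <- make_helix(6)
  site <- get_site(h, "A", 3)
  geom <- ideal_geometry()
  for (aa in c("SER", "ARG", "TRP", "ILE", "GLU")) {
    chi <- runif(CHI_ARITY[[aa]], -180, 180)
    sc <- build_side_chain(site, aa, chi)
    expect_equal(nrow(sc), SIDECHAIN_SIZE[[aa]])
    pos <- c(rotaclash:::site_backbone(site),
             stats::setNames(lapply(seq_len(nrow(sc)), function(i)
               as.numeric(sc[i, c("x", "y", "z")])), sc$name))
    rows <- geom[geom$res == aa, ]
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      d <- pos[[r$atom]]; p <- pos[[r$a3]]
      expect_equal(sqrt(sum((d - p)^2)), r$bond_A, tolerance = 1e-8)
      tor <- dihedral(pos[[r$a1]], pos[[r$a2]], p, d)
      want <- if (r$chi > 0) chi[r$chi] + r$offset_deg else r$offset_deg
      diff <- (tor - want + 180) %% 360 - 180
      expect_lt(abs(diff), 1e-6)
    }
  }
})

test_that("build_side_chain validates inputs", {
  site <- get_site(make_helix(5), "A", 3)
  expect_error(build_side_chain(site, "GLY"), "no side chain")
  expect_error(build_side_chain(site, "ARG", chi = c(180, 180)), "arity")
  sc <- build_side_chain(site, "ALA", chi = numeric())
  expect_equal(sc$name, "CB")
})

test_that("built side-chain internal distances are rigid-motion invariant", {
  h <- make_helix(5)
  site <- get_site(h, "A", 3)
  sc1 <- build_side_chain(site, "LYS", chi = c(-67, 180, 180, 180))
  set.seed(3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  h2 <- h
  xyz <- as.matrix(h2$atoms[, c("x", "y", "z")]) %*% t(rot)
  h2$atoms$x <- xyz[, 1] + 5; h2$atoms$y <- xyz[, 2] - 1; h2$atoms$z <- xyz[, 3]
  sc2 <- build_side_chain(get_site(h2, "A", 3), "LYS", chi = c(-67, 180, 180, 180))
  d1 <- dist(as.matrix(sc1[, c("x", "y", "z")]))
  d2 <- dist(as.matrix(sc2[, c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-6)
})

test_that("extended arginine reaches the cutoff-construction distance", {
  h <- make_helix(5)
  site <- get_site(h, "A", 3)
  sc <- build_side_chain(site, "ARG", chi = rep(180, 4))
  ca <- atom_xyz(h, 3, "CA")
  reach <- max(sqrt((sc$x - ca[1])^2 + (sc$y - ca[2])^2 + (sc$z - ca[3])^2))
  expect_equal(reach, arg_reach(), tolerance = 1e-6)
})
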