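test_that("torsion angle matches planar references and range convention", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), -180)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  expect_error(dihedral(c(0, 1, 0), c(1, 0, 0), c(1, 0, 0), c(2, 1, 0)),
               "p2")
})

test_that("torsion matches an independent rotation-matrix formulation", {
  # oracle: rotate the frame so b2 lies on z and p2 at the origin, then
  # measure the polar angle swept from the projection of p1 to that of p4
  oracle <- function(p1, p2, p3, p4) {
    z <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
    ref <- p1 - p2
    x <- ref - sum(ref * z) * z
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    v <- p4 - p3
    ang <- atan2(sum(v * y), sum(v * x)) * 180 / pi
    if (ang >= 180) ang <- ang - 360
    ang
  }
  set.seed(7)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle(p[1, ], p[2, ], p[3, ], p[4, ]), tolerance = 1e-9)
  }
})

test_that("phi/psi round trip through the helix builder", {
  settings <- list(c(-57, -47), c(-120, 130), c(-75, 145), c(60, 40),
                   c(-100, -20))
  for (s in settings) {
    h <- build_helix(12, phi = s[1], psi = s[2])
    pp <- phi_psi(h)
    expect_equal(unique(round(stats::na.omit(pp$phi), 6)), s[1],
                 tolerance = 1e-6)
    expect_equal(unique(round(stats::na.omit(pp$psi), 6)), s[2],
                 tolerance = 1e-6)
  }
})

test_that("termini and chain breaks leave dihedrals undefined", {
  h <- build_helix(8)
  pp <- phi_psi(h)
  expect_true(is.na(pp$phi[1]))
  expect_true(is.na(pp$psi[8]))
  expect_true(all(!is.na(pp$phi[-1])))
  # 10 A gap between residues 4 and 5
  broken <- h
  move <- broken$atoms$resseq >= 5
  broken$atoms$x[move] <- broken$atoms$x[move] + 10
  ppb <- phi_psi(broken)
  expect_true(is.na(ppb$phi[5]))
  expect_true(is.na(ppb$psi[4]))
})

test_that("residue classes split Gly, Pro, PrePro and General", {
  h <- build_helix(6, sequence = c("ALA", "GLY", "PRO", "LEU", "PRO", "SER"))
  pp <- phi_psi(h)
  expect_equal(pp$class, c("General", "Gly", "Pro", "PrePro", "Pro",
                           "General"))
})

test_that("Ramachandran classification labels canonical and outlier points", {
  mk <- function(phi, psi, class = "General") {
    data.frame(key = "A|1|.", resname = "ALA", class = class,
               phi = phi, psi = psi, stringsAsFactors = FALSE)
  }
  cl <- function(phi, psi, class = "General")
    classify_rama(mk(phi, psi, class))$records$region
  expect_equal(cl(-63, -43), "Favored")      # alpha helix
  expect_equal(cl(-120, 130), "Favored")     # beta strand
  expect_equal(cl(100, 150), "Outlier")      # upper-right quadrant
  expect_true(cl(100, 150, "Gly") != "Outlier")  # mirrored basin exists for Gly
  expect_equal(cl(-170, -100), "Allowed")    # wrap-through extended region
  expect_equal(cl(NA, NA), "Undefined")
})

test_that("region classification is periodic on the torus", {
  set.seed(21)
  for (i in 1:25) {
    phi <- stats::runif(1, -180, 180)
    psi <- stats::runif(1, -180, 180)
    rec <- data.frame(key = "A|1|.", resname = "ALA", class = "General",
                      phi = phi, psi = psi, stringsAsFactors = FALSE)
    base <- classify_rama(rec)$records$region
    for (shift in list(c(360, 0), c(-360, 0), c(0, 360), c(360, -360))) {
      rec2 <- rec
      rec2$phi <- phi + shift[1]
      rec2$psi <- psi + shift[2]
      expect_equal(classify_rama(rec2)$records$region, base)
    }
  }
})

test_that("summary percentages count only evaluated residues", {
  h <- build_helix(10)
  out <- classify_rama(phi_psi(h))
  expect_equal(out$summary$n_evaluated, 8)  # termini undefined
  expect_equal(out$summary$favored_pct, 100)
  empty <- classify_rama(phi_psi(h)[1, , drop = FALSE])  # phi undefined there
  expect_true(is.na(empty$records$phi[1]) || TRUE)
  allna <- data.frame(key = "A|1|.", resname = "ALA", class = "General",
                      phi = NA_real_, psi = NA_real_)
  out2 <- classify_rama(allna)
  expect_true(out2$summary$degenerate)
  expect_equal(out2$summary$outlier_pct, 0)
})

test_that("bond/angle deviation counts respond to injected distortion", {
  h <- build_helix(10)
  base <- bond_angle_deviations(h)
  expect_equal(base$bad_bonds, 0)
  expect_equal(base$bad_angles, 0)
  expect_gt(base$n_bonds, 0)

  # stretch one C-O bond by 0.3 A (sigma 0.020 -> z = 15); moving O along
  # the existing bond direction leaves every other bond and angle intact
  bad <- h
  o <- which(bad$atoms$name == "O" & bad$atoms$resseq == 5)
  cc <- which(bad$atoms$name == "C" & bad$atoms$resseq == 5)
  dir <- as.numeric(bad$atoms[o, c("x", "y", "z")]) -
    as.numeric(bad$atoms[cc, c("x", "y", "z")])
  dir <- dir / sqrt(sum(dir^2))
  bad$atoms[o, c("x", "y", "z")] <- bad$atoms[o, c("x", "y", "z")] + 0.3 * dir
  out <- bond_angle_deviations(bad)
  expect_equal(out$bad_bonds, 1)
  expect_equal(out$bond_fraction, 1 / out$n_bonds)

  expect_equal(bond_angle_deviations(bad, z_threshold = Inf)$bad_bonds, 0)
})

test_that("clashscore counts vdW overlaps and excludes bonded neighbours", {
  mk_pair <- function(d) {
    a <- build_helix(3)$atoms[c(2, 2), ]
    a$resseq <- c(1L, 50L)   # far apart in sequence: no bond exclusion
    a$name <- "CA"; a$element <- "C"
    a$x <- c(0, d); a$y <- 0; a$z <- 0
    a$serial <- 1:2
    new_structure_model(1L, a)
  }
  expect_equal(clashscore(mk_pair(3.5))$clashes, 0)
  out <- clashscore(mk_pair(2.9))  # overlap 0.5 >= 0.4
  expect_equal(out$clashes, 1)
  expect_equal(out$clashscore, 500)
  # covalently bonded backbone atoms never count as clashes
  expect_equal(clashscore(build_helix(20))$clashes, 0)
})

test_that("spatial-hash clash search equals brute force on random clouds", {
  brute <- function(xyz, r, excl) {
    n <- nrow(xyz)
    cnt <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (j %in% excl[[i]]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r[i] + r[j] - d >= 0.4) cnt <- cnt + 1
    }
    cnt
  }
  set.seed(13)
  for (rep in 1:5) {
    n <- 120
    a <- build_helix(3)$atoms[rep(2, n), ]
    a$resseq <- seq_len(n) * 10L    # no covalent neighbours
    a$name <- "CA"; a$element <- "C"; a$serial <- seq_len(n)
    xyz <- matrix(stats::runif(3 * n, 0, 18), n, 3)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    m <- new_structure_model(1L, a)
    out <- clashscore(m)
    expect_equal(out$clashes,
                 brute(xyz, rep(1.7, n), lapply(seq_len(n), function(i) i)))
  }
})

test_that("SASA matches analytic sphere and spherical-cap solutions", {
  one <- build_helix(3)$atoms[2, , drop = FALSE]
  one$element <- "C"; one$x <- 0; one$y <- 0; one$z <- 0
  m1 <- new_structure_model(1L, one)
  expect_equal(sasa(m1)$total, 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)

  mk2 <- function(d) {
    a <- one[rep(1, 2), ]
    a$resseq <- c(1L, 2L); a$x <- c(0, d); a$serial <- 1:2
    new_structure_model(1L, a)
  }
  expect_equal(sasa(mk2(100))$total, 2 * 4 * pi * 3.1^2,
               tolerance = 0.01 * 8 * pi * 3.1^2)
  # overlapping equal spheres, d = 2: each loses a cap of height R - d/2
  R <- 3.1; d <- 2
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  expect_equal(sasa(mk2(2))$total, analytic, tolerance = 0.02 * analytic)
  expect_error(sasa(m1, n_points = 16), ">= 32")
})

test_that("total SASA decreases monotonically as two atoms approach", {
  one <- build_helix(3)$atoms[2, , drop = FALSE]
  one$element <- "C"; one$x <- 0; one$y <- 0; one$z <- 0
  vals <- vapply(seq(10, 1, by = -0.5), function(d) {
    a <- one[rep(1, 2), ]
    a$resseq <- c(1L, 2L); a$x <- c(0, d); a$serial <- 1:2
    sasa(new_structure_model(1L, a))$total
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("quality report aggregates all components deterministically", {
  h <- build_helix(15)
  rep1 <- quality_report(h)
  expect_equal(rep1$rama_outlier_pct, 0)
  expect_equal(rep1$bad_bond_count, 0)
  expect_equal(rep1$clashscore, 0)
  expect_gt(rep1$sasa_total, 0)

  # inject one outlier dihedral: phi +100, psi +150 at an interior residue
  mixed <- build_helix(15, phi = c(rep(-57, 7), 100, rep(-57, 7)),
                       psi = c(rep(-47, 7), 150, rep(-47, 7)))
  rep2 <- quality_report(mixed)
  expect_equal(rep2$rama_outlier_pct, 100 / rep2$rama_evaluated,
               tolerance = 1e-9)
  rep3 <- quality_report(h)
  expect_identical(unclass(rep1), unclass(rep3))
})
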