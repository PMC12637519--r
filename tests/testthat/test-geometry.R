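test_that("chain builder places ideal backbone geometry", {
  set.seed(1)
  ch <- random_chain(2)
  ca <- ch$xyz[ch$name == "CA", ]
  expect_equal(sqrt(sum((ca[1, ] - ca[2, ])^2)), 3.80, tolerance = 0.05 / 3.8)
  one <- build_chain("A", cbind(0.1, 0.1))
  g <- backbone_geometry()
  d <- function(a, b) sqrt(sum((one$xyz[one$name == a, ] -
                                  one$xyz[one$name == b, ])^2))
  expect_equal(d("N", "CA"), unname(g$bonds["N_CA"]), tolerance = 1e-9)
  expect_equal(d("CA", "C"), unname(g$bonds["CA_C"]), tolerance = 1e-9)
  expect_error(build_chain("AA", cbind(1, 1, 180)[1, , drop = FALSE]),
               "one row per residue")
  expect_error(build_chain("AA", cbind(c(1, NaN), c(1, 1))), "non-finite")
  expect_error(build_chain("AA", cbind(c(1, 200), c(1, 1))), "-180, 180")
})

test_that("dihedral measurement inverts construction (property over random chains)", {
  set.seed(2)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    di <- random_dihedrals(n)
    ch <- build_chain(strrep("A", n), di)
    m <- measure_dihedrals(ch)
    expect_angles_equal(m[-1, "phi"], di[-1, 1])
    expect_angles_equal(m[-n, "psi"], di[-n, 2])
    expect_angles_equal(m[-1, "omega"], rep(180, n - 1))
    expect_true(is.na(m[1, "phi"]) && is.na(m[n, "psi"]))
  }
})

test_that("measured dihedrals rebuild the same coordinates", {
  set.seed(3)
  for (i in 1:10) {
    n <- 20
    di <- random_dihedrals(n)
    ch <- build_chain(strrep("A", n), di)
    m <- measure_dihedrals(ch)
    m[1, "phi"] <- di[1, 1]; m[n, "psi"] <- di[n, 2]; m[1, "omega"] <- 180
    ch2 <- build_chain(strrep("A", n), m)
    sp <- superpose(ch2$xyz, ch$xyz)
    expect_lt(max(abs(apply_transform(ch2$xyz, sp$transform) - ch$xyz)), 1e-5)
  }
})

test_that("degenerate and broken chains are reported", {
  one <- build_chain("A", cbind(0.1, 0.1))
  expect_error(measure_dihedrals(one), "at least 2 residues")
  set.seed(4)
  ch <- random_chain(8)
  rows <- ch$resno == 5
  ch$xyz[rows, ] <- ch$xyz[rows, ] + 10  # displace one residue by 10 A
  expect_error(measure_dihedrals(ch), "discontinuity")
})

test_that("superposition recovers constructed transforms", {
  set.seed(5)
  P <- matrix(rnorm(30), 10, 3)
  sp <- superpose(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$transform$rotation, diag(3), tolerance = 1e-9)
  sp2 <- superpose(P, sweep(P, 2, c(-5, 0, 0)))  # reference = mobile + 5x
  expect_equal(sp2$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp2$transform$translation, c(5, 0, 0), tolerance = 1e-9)
  # constructed rotation about a random axis
  ax <- c(1, 2, 3) / sqrt(14); th <- 0.7
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  Rstar <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sp3 <- superpose(P, P %*% t(Rstar))
  expect_lt(max(abs(sp3$transform$rotation - Rstar)), 1e-6)
  # and beats a random-rotation scan
  set.seed(6)
  Q <- matrix(rnorm(24), 8, 3)
  expect_lte(superpose(P[1:8, ], Q)$rmsd, memtether:::cpp_min_rmsd_rotscan(P[1:8, ], Q, 2000))
})

test_that("superposition rejects underdetermined inputs", {
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("hinge rotations are exact and side-preserving", {
  set.seed(7)
  ch <- random_chain(12)
  expect_equal(rotate_dihedral(ch, 6, "phi", 0)$xyz, ch$xyz)
  r360 <- rotate_dihedral(ch, 6, "psi", 360 - 1e-13)
  expect_lt(max(abs(r360$xyz - ch$xyz)), 1e-9)
  fwd <- rotate_dihedral(ch, 6, "phi", 37.5)
  back <- rotate_dihedral(fwd, 6, "phi", -37.5)
  expect_lt(max(abs(back$xyz - ch$xyz)), 1e-9)
  # distances among atoms on the same side of the hinge are untouched
  for (k in 1:10) {
    res <- sample(2:11, 1)
    kind <- sample(c("phi", "psi"), 1)
    delta <- runif(1, -170, 170)
    rot <- rotate_dihedral(ch, res, kind, delta)
    up <- ch$resno < res
    dn <- ch$resno > res
    expect_lt(max(abs(dist(rot$xyz[up, ]) - dist(ch$xyz[up, ]))), 1e-9)
    expect_lt(max(abs(dist(rot$xyz[dn, ]) - dist(ch$xyz[dn, ]))), 1e-9)
    expect_lt(max(abs(peptide_gaps(rot) - peptide_gaps(ch))), 1e-9)
  }
  expect_error(rotate_dihedral(ch, 99, "phi", 5), "not part")
  expect_error(rotate_dihedral(ch, 1, "phi", 5), "undefined")
})

test_that("clash detection matches the all-pairs oracle", {
  two <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(clash_check(two)), 0L)
  near <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(nrow(clash_check(near, clash_model(2.5))), 1L)
  set.seed(8)
  x <- matrix(runif(600, 0, 18), 200, 3)
  conf <- list(xyz = x, chain = sample(c("A", "B"), 200, TRUE),
               resno = sample(1:40, 200, TRUE),
               grp = sample(0:2, 200, TRUE))
  a <- clash_check(structure(conf, class = "chain_conf"), use_grid = TRUE)
  b <- clash_check(structure(conf, class = "chain_conf"), use_grid = FALSE)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_identical(key(a), key(b))
  # symmetric and order-independent
  perm <- sample(200)
  conf2 <- conf
  conf2$xyz <- x[perm, ]; conf2$chain <- conf$chain[perm]
  conf2$resno <- conf$resno[perm]; conf2$grp <- conf$grp[perm]
  a2 <- clash_check(structure(conf2, class = "chain_conf"))
  expect_equal(nrow(a2), nrow(a))
})

test_that("membrane heights are signed z distances", {
  pl <- membrane_plane(5)
  expect_equal(height_above_plane(c(0, 0, 5), pl), 0)
  expect_equal(height_above_plane(c(1, 2, 125), pl), 120)
  expect_equal(height_above_plane(c(0, 0, 2), pl), -3)
  m <- rbind(c(0, 0, 10), c(0, 0, 0))
  expect_equal(height_above_plane(m, pl), c(5, -5))
})
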