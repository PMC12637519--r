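test_that("dihedral library validates and round-trips through its text format", {
  lib <- default_dihedral_library()
  for (cl in names(lib)) {
    expect_equal(sum(lib[[cl]]$weight), 1, tolerance = 1e-9)
    expect_true(all(lib[[cl]]$phi > -180 & lib[[cl]]$phi <= 180))
  }
  path <- tempfile(fileext = ".yaml")
  write_dihedral_library(lib, path)
  lib2 <- read_dihedral_library(path)
  expect_equal(lib2$generic$phi, lib$generic$phi)
  bad <- lib
  bad$pro$weight[1] <- bad$pro$weight[1] + 0.1
  expect_error(dihedral_library(bad), "sum to")
})

test_that("residue classes follow Gly/Pro/pre-Pro rules", {
  expect_equal(residue_classes("APGSPA"),
               c("prepro", "pro", "gly", "prepro", "pro", "generic"))
  expect_equal(residue_classes("PPG"), c("pro", "pro", "gly"))
})

test_that("fragment sampling is seed-deterministic and class-faithful", {
  set.seed(11)
  f1 <- sample_fragment("ASDF")
  set.seed(11)
  f2 <- sample_fragment("ASDF")
  expect_identical(f1$xyz, f2$xyz)
  one <- sample_fragment("A")
  expect_equal(length(unique(one$resno)), 1L)
  # an all-glycine segment draws only from the glycine class
  lib <- default_dihedral_library()
  gly_pairs <- paste(round(lib$gly$phi), round(lib$gly$psi))
  gen_pairs <- paste(round(lib$generic$phi), round(lib$generic$psi))
  set.seed(12)
  drawn <- character()
  for (k in 1:25) {
    f <- sample_fragment(strrep("G", 40))
    m <- measure_dihedrals(f)
    ok <- !is.na(m[, "phi"]) & !is.na(m[, "psi"])
    drawn <- c(drawn, paste(round(m[ok, "phi"]), round(m[ok, "psi"])))
  }
  expect_gte(length(drawn), 900)
  expect_true(all(drawn %in% gly_pairs))
  expect_true(any(!drawn %in% gen_pairs))
})

test_that("hierarchical assembly degenerates to one fragment and keeps chains intact", {
  pol <- growth_policy(fragment_length = 10L)
  set.seed(13)
  a <- hierarchical_assemble("ASDFG", policy = pol)
  set.seed(13)
  b <- sample_fragment("ASDFG")
  expect_identical(a$xyz, b$xyz)
  set.seed(14)
  ch <- hierarchical_assemble(random_idr_sequence(60))
  expect_lt(max(abs(peptide_gaps(ch) - backbone_geometry()$bonds["C_N"])), 1e-6)
  expect_equal(nrow(clash_check(ch)), 0L)
  expect_silent(measure_dihedrals(ch))
})

test_that("membrane half-space acceptance holds for every accepted member", {
  base <- build_chain("AAA", cbind(rep(-75, 3), rep(145, 3)))
  tri <- base$xyz[base$resno == 2 & base$name %in% c("N", "CA", "C"), ]
  tri <- sweep(tri, 2, c(0, 0, 5 - tri[2, 3]), "+")  # pin the anchor at z = 5
  pol <- growth_policy(plane = membrane_plane(0))
  spec <- growth_spec(random_idr_sequence(60), anchor = "start",
                      anchor_triad = tri, segment_id = "wall_test")
  set.seed(15)
  ens <- grow_ensemble(spec, 100, policy = pol)
  minz <- vapply(ens$members, function(m) min(m$xyz[, 3]), numeric(1))
  expect_true(all(minz > 0))
})

test_that("rigid-body attachment is exact at the graft and matches the LSQ oracle", {
  set.seed(16)
  ch <- random_chain(20, chain_id = "U", resno_start = 101L)
  # a body whose overlap already coincides with the chain
  rows <- ch$resno >= 115
  body <- rigid_body(ch$xyz[rows, ], ch$name[rows], ch$chain[rows],
                     ch$resno[rows], body_id = "self")
  out <- attach_rigid_body(ch, body, at = 115L, side = "C")
  expect_equal(out$attachments[[1]]$overlap_rmsd, 0)
  tri_before <- ch$xyz[ch$resno == 115 & ch$name %in% c("N", "CA", "C"), ]
  tri_after <- out$xyz[out$resno == 115 & out$name %in% c("N", "CA", "C") &
                         out$grp == 0L, ]
  expect_lt(max(abs(tri_before - tri_after)), 1e-9)
  # generic LSQ attachment reproduces the plain superposition result
  set.seed(17)
  bd <- random_chain(8, chain_id = "U", resno_start = 113L)
  body2 <- rigid_body(bd$xyz, bd$name, bd$chain, bd$resno, body_id = "lsq")
  ov <- 113:117
  sel_b <- body2$resno %in% ov & body2$name %in% c("N", "CA", "C")
  sel_c <- ch$resno %in% ov & ch$name %in% c("N", "CA", "C")
  oracle <- superpose(body2$xyz[sel_b, ], ch$xyz[sel_c, ])
  out2 <- tryCatch(attach_rigid_body(ch, body2, side = "C", method = "lsq",
                                     overlap = ov, clash = NULL),
                   error = function(e) e)
  expect_false(inherits(out2, "error"))
  expect_equal(out2$attachments[[1]]$overlap_rmsd, oracle$rmsd,
               tolerance = 1e-6)
  # a body engineered to collide raises a clash error
  shifted <- ch$xyz[rows, ]
  shifted[body$resno[body$resno >= 115] > 116, ] <-
    matrix(ch$xyz[ch$resno == 105 & ch$name == "CA", ],
           sum(ch$resno[rows] > 116), 3, byrow = TRUE)
  body3 <- rigid_body(shifted, ch$name[rows], ch$chain[rows],
                      ch$resno[rows], body_id = "collider")
  expect_error(attach_rigid_body(ch, body3, at = 115L, side = "C"),
               class = "memtether_clash_error")
})

test_that("ensembles are bit-identical under a fixed seed", {
  spec <- growth_spec(random_idr_sequence(40), segment_id = "det")
  set.seed(18)
  e1 <- grow_ensemble(spec, 3)
  set.seed(18)
  e2 <- grow_ensemble(spec, 3)
  for (i in 1:3) expect_identical(e1$members[[i]]$xyz, e2$members[[i]]$xyz)
  expect_identical(e1$info, e2$info)
})

test_that("excluded volume expands virtual-bond chains", {
  # 64 bonds: long enough for a strong excluded-volume signal while whole
  # self-avoiding chains still regenerate at workable acceptance rates
  spec <- growth_spec(strrep("A", 65), geometry = "virtual_bond")
  r2 <- function(m) {
    ca <- m$xyz
    sum((ca[nrow(ca), ] - ca[1, ])^2)
  }
  set.seed(19)
  free <- grow_ensemble(spec, 800, policy = growth_policy(clash = NULL))
  saw <- grow_ensemble(spec, 800,
                       policy = growth_policy(clash = clash_model(2.5),
                                              retry_merge = 500L,
                                              max_attempts_factor = 5000L))
  v_free <- vapply(free$members, r2, numeric(1))
  v_saw <- vapply(saw$members, r2, numeric(1))
  tt <- t.test(v_saw, v_free, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})
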