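test_that("the core fixture carries its anchors at the specified geometry", {
  core <- make_core_fixture()
  expect_setequal(names(core$tags), c("FIP200_tip", "C927:SG", "C1003:SG"))
  s <- 3
  core2 <- make_core_fixture(sg_offset = s)
  d <- sqrt(sum((tag_coord(core2, "C927:SG") - tag_coord(core2, "C1003:SG"))^2))
  expect_equal(d, sqrt(8^2 + (4 + 2 * s)^2), tolerance = 1e-9)
  # ATG13 overlap stub and the ULK1 tether triad are present
  expect_true(all(c("N", "CA", "C") %in%
                    core$name[core$chain == "A" & core$resno == 362]))
  expect_silent(memtether:::.triad(core, "U", 831L))
  # rigid placement preserves the internal distance matrix
  set.seed(31)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- 1.1
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  tf <- rigid_transform(diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K,
                        c(4, -7, 12))
  moved <- apply_transform(core, tf)
  sub <- seq(1, nrow(core$xyz), by = 4)
  expect_lt(max(abs(dist(moved$xyz[sub, ]) - dist(core$xyz[sub, ]))), 1e-9)
})

test_that("the KD fixture spans the stated residues with a graftable overlap", {
  kd <- make_kd_fixture()
  expect_true(all(kd$resno <= 283))
  expect_true(all(277:283 %in% kd$resno[kd$name == "CA"]))
  expect_true(all(c("N", "CA", "C") %in% kd$name[kd$resno == 283]))
  kd2 <- make_kd_fixture()
  expect_identical(kd$xyz, kd2$xyz)  # deterministic
  set.seed(32)
  ch <- hierarchical_assemble(random_idr_sequence(30), chain_id = "U",
                              resno_start = 283L)
  out <- attach_rigid_body(ch, kd, at = 283L, side = "N", clash = NULL)
  expect_equal(out$attachments[[1]]$overlap_rmsd, 0)
})

test_that("the bound-pose fixture provides a rigid 428-450 peptide on the HORMA frame", {
  bp <- make_bound_pose_fixture()
  expect_identical(sort(unique(bp$pose$resno)), 428:450)
  expect_true(all(c("N", "CA", "C", "O") %in%
                    bp$pose$name[bp$pose$resno == 450]))
  expect_true("HORMA_site" %in% names(bp$horma$tags))
  expect_silent(memtether:::.triad(bp$horma, "A", 230L))
  # the pose is rigid under HORMA superposition
  set.seed(33)
  shift <- rigid_transform(diag(3), c(10, -3, 25))
  horma_w <- apply_transform(bp$horma, shift)
  sel <- bp$horma$chain == "H" & bp$horma$name == "CA"
  sp <- superpose(bp$horma$xyz[sel, ], horma_w$xyz[sel, ])
  pose_w <- apply_transform(bp$pose, sp$transform)
  expect_lt(max(abs(dist(pose_w$xyz) - dist(bp$pose$xyz))), 1e-9)
  bp2 <- make_bound_pose_fixture()
  expect_identical(bp$pose$xyz, bp2$pose$xyz)
})

test_that("toy loops come with a brute-force grid optimum", {
  set.seed(34)
  toy <- make_toy_loop(2)
  expect_lt(toy$grid_optimum, 0.5)  # reachable target: optimum near zero
  set.seed(34)
  toy2 <- make_toy_loop(2)
  expect_identical(toy$chain$xyz, toy2$chain$xyz)
  expect_identical(toy$grid_optimum, toy2$grid_optimum)
  far <- make_toy_loop(3, target = c(200, 0, 0))
  # an unreachable target leaves the geometric gap; the whole chain is
  # within ~25 A of the origin
  expect_gt(far$grid_optimum, 150)
  expect_lt(far$grid_optimum, 200)
  expect_error(make_toy_loop(9), "2..6")
})

test_that("packaged sequences have the stated lengths and composition generator matches", {
  seqs <- idr_sequences()
  expect_equal(nchar(seqs$atg13_230_363), 134L)
  expect_equal(nchar(seqs$ulk1_277_831), 555L)
  set.seed(35)
  s <- random_idr_sequence(5000)
  freq <- table(factor(strsplit(s, "")[[1]],
                       levels = names(memtether:::.IDR_COMPOSITION))) / 5000
  target <- memtether:::.IDR_COMPOSITION / sum(memtether:::.IDR_COMPOSITION)
  expect_lt(max(abs(freq - target)), 0.02)
  # class frequencies of the packaged synthetic ULK1 segment track the
  # composition table within 2 percentage points
  cls <- table(factor(residue_classes(seqs$ulk1_277_831),
                      levels = c("generic", "gly", "pro", "prepro"))) / 555
  expect_lt(abs(cls[["pro"]] - target[["P"]]), 0.02)
  expect_lt(abs(cls[["gly"]] - target[["G"]]), 0.02)
})

test_that("the ULK1C preset resolves against the packaged fixtures", {
  preset <- ulk1c_preset()
  core <- make_core_fixture()
  bp <- make_bound_pose_fixture()
  kd <- make_kd_fixture()
  expect_true(all(preset$anchors %in% names(core$tags)))
  expect_true(any(core$chain == "A" & core$resno == preset$core_boundary))
  expect_true(any(bp$horma$chain == "A" &
                    bp$horma$resno == preset$atg13_range[1]))
  expect_true(all(preset$bound_segment[1]:preset$bound_segment[2] %in%
                    bp$pose$resno))
  expect_true(any(kd$resno == preset$kd_boundary))
  seqs <- idr_sequences()
  expect_equal(nchar(seqs$ulk1_277_831),
               preset$ulk1_range[2] - preset$ulk1_range[1] + 1L)
})
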