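# objective recomputation used as the independent oracle for move decisions
.obj_point <- function(conf, task) {
  rows <- memtether:::.effector_rows(conf, task$effectors)
  sqrt(mean(rowSums((conf$xyz[rows, , drop = FALSE] - task$target)^2)))
}

test_that("a zero objective rejects every move and leaves the chain untouched", {
  set.seed(21)
  ch <- random_chain(8)
  eff <- data.frame(chain = "A", resno = 8, name = "CA")
  tgt <- ch$xyz[ch$resno == 8 & ch$name == "CA", , drop = FALSE]
  res <- ccd_minimize(ch, anchor_task(eff, "point", tgt),
                      ccd_params(anchor_tolerance = 1e-9, max_moves = 500L))
  expect_identical(res$conformation$xyz, ch$xyz)
  expect_equal(res$accepted, 0)
})

test_that("move acceptance agrees with explicit before/after recomputation", {
  set.seed(22)
  ch <- random_chain(6)
  eff <- data.frame(chain = "A", resno = 6, name = "CA")
  tgt <- ch$xyz[ch$resno == 6 & ch$name == "CA", , drop = FALSE] +
    matrix(c(4, -2, 3), 1, 3)
  task <- anchor_task(eff, "point", tgt)
  cur <- ch
  n_acc <- 0
  for (i in 1:500) {
    before <- .obj_point(cur, task)
    step <- ccd_move(cur, task)
    after <- .obj_point(step$chain, task)
    if (step$accepted) {
      expect_lt(after, before)
      expect_equal(nrow(clash_check(step$chain)), 0L)
      n_acc <- n_acc + 1
    } else {
      expect_identical(step$chain$xyz, cur$xyz)
    }
    cur <- step$chain
  }
  expect_gt(n_acc, 0)
})

test_that("hinge rotations are drawn from Normal(0, 1 degree)", {
  set.seed(23)
  ch <- random_chain(6)
  eff <- data.frame(chain = "A", resno = 6, name = "CA")
  task <- anchor_task(eff, "point", matrix(c(500, 0, 0), 1, 3))
  res <- ccd_minimize(ch, task,
                      ccd_params(anchor_tolerance = 1e-9, max_moves = 10000L,
                                 stall_limit = 0L), record_deltas = TRUE)
  expect_equal(length(res$deltas), 10000L)
  expect_lt(abs(mean(res$deltas)), 0.05)
  expect_lt(abs(sd(res$deltas) - 1), 0.05)
})

test_that("objective traces are monotone and bonds survive CCD exactly", {
  set.seed(24)
  ch <- random_chain(15)
  g0 <- peptide_gaps(ch)
  eff <- data.frame(chain = "A", resno = 15, name = "CA")
  tgt <- ch$xyz[ch$resno == 15 & ch$name == "CA", , drop = FALSE] +
    matrix(c(6, 4, -5), 1, 3)
  res <- ccd_minimize(ch, anchor_task(eff, "point", tgt),
                      ccd_params(anchor_tolerance = 0.2, max_moves = 40000L))
  expect_true(all(diff(res$trace) < 0))
  expect_lt(max(abs(peptide_gaps(res$conformation) - g0)), 1e-9)
})

test_that("plane-mode CCD pulls three effectors within tolerance of the headgroups", {
  set.seed(25)
  ch <- hierarchical_assemble(random_idr_sequence(30))
  z0 <- min(ch$xyz[, 3]) - 15  # effectors start 15 A or more above the plane
  eff <- data.frame(chain = "A", resno = c(24, 27, 30), name = "CA")
  task <- anchor_task(eff, "plane", membrane_plane(z0))
  res <- ccd_minimize(ch, task, ccd_params(anchor_tolerance = 5,
                                           max_moves = 150000L))
  expect_true(res$converged)
  rows <- memtether:::.effector_rows(res$conformation, eff)
  expect_true(all(abs(res$conformation$xyz[rows, 3] - z0) <= 5))
})

test_that("a zero move budget changes nothing and reports non-convergence", {
  set.seed(26)
  ch <- random_chain(6)
  eff <- data.frame(chain = "A", resno = 6, name = "CA")
  task <- anchor_task(eff, "point", matrix(c(100, 100, 100), 1, 3))
  res <- ccd_minimize(ch, task, ccd_params(max_moves = 0L))
  expect_false(res$converged)
  expect_identical(res$conformation$xyz, ch$xyz)
})

test_that("alignment closure compares coordinates in the common frame", {
  a <- matrix(rnorm(12), 4, 3)
  expect_true(alignment_close(a, a, 0.6))
  off <- sweep(a, 2, c(1, 0, 0), "+")
  cl <- alignment_close(a, off, 0.6)
  expect_false(cl)
  expect_equal(attr(cl, "rmsd"), 1.0, tolerance = 1e-12)
  # perturbation constructed with an exact RMSD r
  set.seed(27)
  for (r in c(0.3, 0.59, 0.61, 1.5)) {
    noise <- matrix(rnorm(12), 4, 3)
    noise <- noise * r / sqrt(mean(rowSums(noise^2)))
    res <- alignment_close(a, a + noise, 0.6)
    expect_identical(as.logical(res), r < 0.6)
    expect_equal(attr(res, "rmsd"), r, tolerance = 1e-9)
  }
  expect_error(alignment_close(a, a[1:3, ]), "unpaired")
})

test_that("toy closure reaches the exhaustive grid optimum", {
  set.seed(28)
  toy <- make_toy_loop(3)
  res <- ccd_minimize(toy$chain, toy$task,
                      ccd_params(anchor_tolerance = 1e-6,
                                 max_moves = 30000L, stall_limit = 4000L),
                      rotatable = toy$rotatable)
  expect_lte(res$objective, toy$grid_optimum + 0.5)
})
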