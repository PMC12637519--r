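# minimal hand-built member: KD backbone atoms at controlled heights
.fake_member <- function(z_kd, z_idr = 50) {
  n_kd <- 10L
  xyz <- rbind(cbind(seq_len(n_kd), 0, z_kd),
               cbind(seq_len(5), 5, z_idr))
  structure(list(
    xyz = xyz,
    name = c(rep(c("N", "CA"), n_kd / 2), rep("CA", 5)),
    chain = c(rep("U", n_kd), rep("U", 5)),
    resno = c(1:10, 500:504),
    grp = c(rep(1L, n_kd), rep(0L, 5)),
    idr_chain = "U"
  ), class = "chain_conf")
}

.fake_ensemble <- function(zs) {
  structure(list(members = lapply(zs * 10, .fake_member),
                 info = data.frame(member = seq_along(zs),
                                   condition = "unbound"),
                 plane = membrane_plane(0)),
            class = "tether_ensemble")
}

test_that("KD-membrane distance is the backbone centre height in nm", {
  pl <- membrane_plane(0)
  expect_equal(kd_membrane_distance(.fake_member(0), pl), 0)
  expect_equal(kd_membrane_distance(.fake_member(120), pl), 12)
  m <- .fake_member(73)
  rows <- memtether:::.kd_rows(m)
  oracle <- (mean(m$xyz[rows, 3]) - pl$z0) / 10
  expect_equal(kd_membrane_distance(m, pl), oracle, tolerance = 1e-9)
  expect_error(kd_membrane_distance(m, pl, kd_selection = integer()),
               "empty")
  # the selection ignores IDR atoms far above the membrane
  expect_equal(kd_membrane_distance(.fake_member(50, z_idr = 400), pl), 5)
})

test_that("distance summaries are exact on constructed ensembles", {
  one <- .fake_ensemble(7)
  s1 <- summarize_distances(one)
  expect_equal(s1$mean, 7)
  expect_equal(s1$sd, 0)
  expect_equal(s1$max, 7)
  s3 <- summarize_distances(.fake_ensemble(c(10, 20, 30)))
  expect_equal(s3$mean, 20)
  expect_equal(s3$max, 30)
  expect_equal(sum(s3$counts), 3L)
  expect_gte(s3$max, s3$mean)
})

test_that("summaries are permutation-invariant and deterministic", {
  zs <- c(3, 14, 9, 22, 17)
  a <- summarize_distances(.fake_ensemble(zs))
  b <- summarize_distances(.fake_ensemble(rev(zs)))
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, b$sd)
  expect_equal(a$counts, b$counts)
  expect_identical(a$breaks, seq(0, 23, by = 1))
})

test_that("accessible volume follows the hemisphere closed form", {
  expect_equal(accessible_volume(1)$volume, 2 * pi / 3, tolerance = 1e-12)
  expect_equal(accessible_volume(20)$volume, 2 / 3 * pi * 8000,
               tolerance = 1e-12)
  expect_error(accessible_volume(0), "positive")
  expect_error(accessible_volume(-3), "positive")
})

test_that("volume fold change is the cube law", {
  expect_identical(volume_fold_change(40, 20), 8)
  expect_identical(volume_fold_change(2, 1), 8)
  expect_equal(volume_fold_change(7, 7), 1)
  set.seed(41)
  for (k in 1:20) {
    r1 <- runif(1, 0.1, 60); r2 <- runif(1, 0.1, 60)
    expect_equal(volume_fold_change(r1, r2) * volume_fold_change(r2, r1), 1,
                 tolerance = 1e-12)
    expect_equal(volume_fold_change(r1, r2),
                 accessible_volume(r1)$volume / accessible_volume(r2)$volume,
                 tolerance = 1e-12)
  }
  expect_error(volume_fold_change(-1, 2), "positive")
})
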