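# shared helpers: small random chains and membrane systems built in code

random_dihedrals <- function(n) {
  cbind(runif(n, -179, 180), runif(n, -179, 180))
}

random_chain <- function(n, chain_id = "A", resno_start = 1L) {
  build_chain(strrep("A", n), random_dihedrals(n), chain_id = chain_id,
              resno_start = resno_start)
}

# C-N peptide-bond distances along the flexible chain
peptide_gaps <- function(conf) {
  res <- sort(unique(conf$resno[conf$grp == 0L & conf$chain == conf$idr_chain]))
  cm <- t(vapply(res, function(r)
    conf$xyz[which(conf$chain == conf$idr_chain & conf$resno == r &
                     conf$name == "C" & conf$grp == 0L)[1], ], numeric(3)))
  nm <- t(vapply(res, function(r)
    conf$xyz[which(conf$chain == conf$idr_chain & conf$resno == r &
                     conf$name == "N" & conf$grp == 0L)[1], ], numeric(3)))
  sqrt(rowSums((cm[-length(res), , drop = FALSE] -
                  nm[-1, , drop = FALSE])^2))
}

expect_angles_equal <- function(a, b, tol = 1e-6) {
  ok <- !is.na(a) & !is.na(b)
  expect_lt(max(angle_diff(a[ok], b[ok])), tol)
}
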