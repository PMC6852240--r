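rset <- function(idx) sprintf("A|%d|", idx)

test_that("precision/recall/F1 follow their definitions", {
  perfect <- prf(rset(1:10), rset(1:10))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  nothing <- prf(rset(1:5), rset(6:10))
  expect_equal(c(nothing$precision, nothing$recall, nothing$f1), c(0, 0, 0))
  half <- prf(rset(1:10), rset(6:15))
  expect_equal(c(half$precision, half$recall, half$f1), c(0.5, 0.5, 0.5))
  empty <- prf(character(0), rset(1:10))
  expect_equal(empty$precision, 0)
  expect_equal(empty$f1, 0)
  expect_equal(half$tp, 5)
  expect_equal(half$fp, 5)
  expect_equal(half$fn, 5)
})

test_that("F1 respects its analytic bounds and is monotone in the overlap", {
  set.seed(5)
  for (rep in 1:30) {
    np <- sample(1:20, 1); nt <- sample(1:20, 1)
    ov <- sample(0:min(np, nt), 1)
    m <- prf(rset(seq_len(np)), rset(seq(np - ov + 1, np - ov + nt)))
    p <- m$precision; r <- m$recall
    expect_gte(m$f1 + 1e-12, max(0, p + r - 1))
    mn <- min(p, r)
    expect_lte(m$f1, 2 * mn / (1 + mn) + 1e-12)
  }
  f1_at <- function(ov) prf(rset(1:10), rset(c(seq_len(ov), 100:(109 - ov))))$f1
  expect_true(all(diff(vapply(0:10, f1_at, numeric(1))) >= 0))
})

test_that("best_match finds the combination of patches that maximises F1", {
  ir <- list(IR1 = rset(1:20))
  patches <- list(p1 = rset(1:10), p2 = rset(11:20), p3 = rset(30:40))
  got <- best_match(patches, ir)
  expect_equal(got$f1, 1)
  expect_setequal(got$members[[1]], c("p1", "p2"))
  # a patch equal to the region wins on its own
  exact <- best_match(list(q = rset(1:20)), ir)
  expect_equal(exact$f1, 1)
  expect_equal(exact$members[[1]], "q")
  # exhaustive search at least matches any single patch
  single_best <- max(vapply(patches, function(p) prf(p, ir$IR1)$f1,
                            numeric(1)))
  expect_gte(got$f1, single_best)
  # no overlapping patch: region flagged missed
  miss <- best_match(list(p = rset(50:60)), ir)
  expect_true(miss$missed)
  expect_equal(miss$f1, 0)
})

test_that("coverage is the union fraction of the surface", {
  surface <- rset(1:100)
  expect_equal(coverage(list(rset(1:30)), surface), 0.3)
  expect_equal(coverage(list(rset(1:60), rset(41:100)), surface), 1)
  expect_equal(coverage(list(), surface), 0)
  expect_error(coverage(list(rset(1)), character(0)), "empty")
})

test_that("Kabsch superposition is rigid-invariant and matches the bio3d oracle", {
  set.seed(8)
  X <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_rmsd(X, X), 0, tolerance = 1e-10)
  # arbitrary rotation + translation leaves RMSD at 0
  ang <- c(0.4, 1.1, -0.7)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0,
                 sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  Y <- sweep(X %*% (Rx %*% Rz), 2, c(5, -3, 2), "+")
  expect_equal(kabsch_rmsd(X, Y), 0, tolerance = 1e-10)
  # independent oracle: bio3d least-squares fit on random noisy pairs
  for (rep in 1:10) {
    n <- sample(4:20, 1)
    A <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
    B <- sweep(A %*% Rx, 2, c(1, 2, 3), "+") + matrix(rnorm(3 * n, sd = 0.5),
                                                      ncol = 3)
    ours <- kabsch_rmsd(A, B)
    fitted <- suppressWarnings(bio3d::fit.xyz(
      fixed = as.vector(t(A)), mobile = as.vector(t(B))))
    Fm <- matrix(fitted, ncol = 3, byrow = TRUE)
    oracle <- sqrt(mean(rowSums((A - Fm)^2)))
    expect_lt(abs(ours - oracle), 1e-6)
  }
})

test_that("region RMSD averages per-homolog superpositions and is rigid-invariant", {
  q <- CX$structure
  ir <- TRUTH_A
  idmap <- setNames(ir, ir)
  # identical homolog: 0 A
  same <- list(h1 = list(structure = q, map = idmap))
  expect_equal(ir_rmsd(ir, q, same)$mean_rmsd, 0, tolerance = 1e-10)
  # rigidly rotated homolog: still 0 A
  rot <- q
  xyz <- as.matrix(rot[, c("x", "y", "z")])
  ang <- 0.8
  Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, byrow = TRUE)
  xyz <- sweep(xyz %*% Rz, 2, c(10, -4, 6), "+")
  rot$x <- xyz[, 1]; rot$y <- xyz[, 2]; rot$z <- xyz[, 3]
  expect_equal(ir_rmsd(ir, q, list(h = list(structure = rot, map = idmap)))$mean_rmsd,
               0, tolerance = 1e-10)
  # uniform coordinate noise gives an RMSD near the expected noise norm,
  # cross-checked against the oracle used above
  set.seed(21)
  noisy <- q
  noisy$x <- noisy$x + rnorm(nrow(noisy), 0, 1 / sqrt(3))
  noisy$y <- noisy$y + rnorm(nrow(noisy), 0, 1 / sqrt(3))
  noisy$z <- noisy$z + rnorm(nrow(noisy), 0, 1 / sqrt(3))
  got <- ir_rmsd(ir, q, list(h = list(structure = noisy, map = idmap)))
  expect_gt(got$mean_rmsd, 0.6)
  expect_lt(got$mean_rmsd, 1.4)
  # averaging over homologs
  two <- ir_rmsd(ir, q, list(a = list(structure = q, map = idmap),
                             b = list(structure = noisy, map = idmap)))
  expect_equal(two$mean_rmsd, mean(two$per_homolog$rmsd))
  expect_equal(nrow(two$per_homolog), 2)
  # fewer than 3 mappable residues: homolog skipped with a warning
  expect_warning(
    expect_error(ir_rmsd(ir[1:2], q, same), "no homolog"),
    "skipped")
})
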