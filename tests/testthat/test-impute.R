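make_rank2 <- function(nr = 18, nc = 8, seed = 5) {
  set.seed(seed)
  matrix(rnorm(nr * 2), nr) %*% matrix(rnorm(2 * nc), 2)
}

test_that("a complete matrix passes through untouched", {
  m <- make_rank2()
  out <- impute_gaps(m)
  expect_identical(unclass(out)[seq_along(m)], unclass(m)[seq_along(m)])
  expect_equal(attr(out, "iterations"), 0L)
})

test_that("rank-2 gaps are recovered and observed cells are bitwise intact", {
  m <- make_rank2()
  set.seed(6)
  miss <- sample(length(m), round(0.1 * length(m)))
  mm <- m
  mm[miss] <- NA
  out <- impute_gaps(mm, rank = 2, tol = 1e-9, max_iter = 5000)
  expect_lt(max(abs(out[miss] - m[miss])), 1e-4)
  obs <- setdiff(seq_along(m), miss)
  expect_identical(out[obs], m[obs])
})

test_that("the imputed grand mean is stable across random masks", {
  m <- make_rank2(20, 10, seed = 9) + 50
  means <- vapply(1:20, function(s) {
    set.seed(s)
    mm <- m
    mm[sample(length(m), 20)] <- NA
    mean(impute_gaps(mm, rank = 2, tol = 1e-8, max_iter = 5000))
  }, numeric(1))
  expect_lt((max(means) - min(means)) / abs(mean(m)), 0.01)
})

test_that("malformed imputation inputs are rejected", {
  m <- make_rank2(6, 4)
  m[, 2] <- NA
  expect_error(impute_gaps(m), "at least one observed")
  m2 <- make_rank2(6, 4)
  m2[3, ] <- NA
  expect_error(impute_gaps(m2), "at least one observed")
  m3 <- make_rank2(6, 4)
  m3[1, 1] <- NA
  expect_error(impute_gaps(m3, rank = 4), "rank")
})

test_that("non-convergence is reported, not hidden", {
  m <- make_rank2(10, 6) + matrix(rnorm(60, 0, 0.5), 10)
  set.seed(3)
  m[sample(60, 6)] <- NA
  expect_warning(out <- impute_gaps(m, rank = 2, tol = 1e-12, max_iter = 2),
                 "did not converge")
  expect_false(attr(out, "converged"))
})

test_that("antipodal yield categories sit at 180 degrees, orthogonal near 90", {
  set.seed(44)
  base <- rnorm(8, 0, 2)
  m <- cbind(A = base, B = -base, C = base * 0.98 + rnorm(8, 0, 0.1))
  bp <- ecg_biplot(m + 100)
  expect_equal(bp$angles["A", "B"], 180, tolerance = 1e-6)
  expect_lt(bp$angles["A", "C"], 15)

  # orthogonal-by-construction columns meet near 90 degrees
  u <- c(rep(1, 4), rep(-1, 4))
  v <- rep(c(1, -1), 4)
  m2 <- cbind(A = u, B = v, C = u + v, D = u - v) * 3
  bp2 <- ecg_biplot(m2)
  expect_equal(bp2$angles["A", "B"], 90, tolerance = 1)
})

test_that("PC variance fractions are the squared singular values, ordered", {
  set.seed(12)
  m <- matrix(rnorm(40, 10, 2), 10, 4)
  bp <- ecg_biplot(m)
  sv <- svd(scale(m, scale = FALSE))$d
  expect_equal(bp$pc_variance_fractions, sv^2 / sum(sv^2))
  expect_true(all(diff(bp$pc_variance_fractions) <= 1e-12))
  expect_equal(sum(bp$pc_variance_fractions), 1)
  expect_error(ecg_biplot(m[1:2, ]), "at least 3")
  expect_error(ecg_biplot(cbind(m, NA)), "gaps")
})
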