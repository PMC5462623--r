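test_that("centroid size matches closed form and is homogeneous", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  set.seed(1)
  conf <- matrix(rnorm(21), 7, 3)
  direct <- sqrt(sum(sweep(conf, 2, colMeans(conf))^2))
  expect_equal(centroid_size(conf), direct, tolerance = 1e-12)
  for (c_ in c(0.5, 3.7))
    expect_equal(centroid_size(conf * c_), c_ * centroid_size(conf),
                 tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("GPA aligns similarity-transformed copies onto one shape", {
  base <- make_landmarks(n = 1, k = 12, d = 3, noise = 0.1, seed = 2)
  co <- array(NA_real_, c(6, 12, 3))
  for (i in 1:6) co[i, , ] <- base$coords[1, , ]
  lms <- landmark_set(co)
  for (i in 1:6) lms <- transform_specimen(lms, i, seed = i + 10)
  fit <- gpa(lms)
  expect_true(fit$converged)
  for (i in 1:6)
    expect_lt(max(abs(fit$aligned[i, , ] - fit$consensus)), 1e-8)
  # aligned configurations are centred with unit centroid size
  for (i in 1:6) {
    ai <- fit$aligned[i, , ]
    expect_lt(sqrt(sum(colMeans(ai)^2)), 1e-9)
    expect_lt(abs(centroid_size(ai) - 1), 1e-9)
  }
})

test_that("GPA is invariant to specimen order and to input transforms", {
  lms <- make_landmarks(n = 7, k = 9, d = 2, seed = 5)
  fit <- gpa(lms)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  lp <- landmark_set(lms$coords[perm, , , drop = FALSE],
                     lms$specimen_ids[perm])
  fitp <- gpa(lp)
  expect_lt(max(abs(fitp$consensus - fit$consensus)), 1e-8)
  for (i in seq_along(perm))
    expect_lt(max(abs(fitp$aligned[i, , ] - fit$aligned[perm[i], , ])), 1e-8)
  # transforming one input specimen leaves its aligned shape unchanged
  lt <- transform_specimen(lms, 4, seed = 99)
  fitt <- gpa(lt)
  expect_lt(max(abs(fitt$aligned[4, , ] - fit$aligned[4, , ])), 1e-8)
  # recorded centroid sizes equal raw pre-alignment centroid sizes
  raw_cs <- vapply(1:7, function(i) centroid_size(lms$coords[i, , ]), numeric(1))
  expect_equal(unname(fit$centroid_sizes), raw_cs, tolerance = 1e-12)
})

test_that("GPA consensus beats random reference shapes on summed squared distance", {
  lms <- make_landmarks(n = 10, k = 8, d = 2, noise = 0.08, seed = 11)
  fit <- gpa(lms)
  ssd_to <- function(ref) {
    ref <- sweep(ref, 2, colMeans(ref))
    ref <- ref / centroid_size(ref)
    sum(vapply(1:10, function(i) {
      ai <- fit$aligned[i, , ]
      sum((ai %*% skullqtl:::.rotation_onto(ai, ref) - ref)^2)
    }, numeric(1)))
  }
  ssd_cons <- ssd_to(fit$consensus)
  set.seed(42)
  for (r in 1:100) {
    ref <- fit$consensus + matrix(rnorm(16, 0, 0.05), 8, 2)
    expect_lte(ssd_cons, ssd_to(ref) + 1e-12)
  }
})

test_that("allometric regression removes exact linear size effects", {
  set.seed(6)
  n <- 15; p <- 12
  x <- runif(n, 1, 3)
  B <- rnorm(p)
  Y <- outer(x, B) + matrix(rnorm(n * p, 0, 0), n, p)
  fit <- allometric_regression(Y, x, n_perm = 99, seed = 1)
  expect_equal(fit$pct_predicted, 100, tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # least-squares orthogonality of residuals to the predictor
  Yn <- Y + matrix(rnorm(n * p, 0, 0.3), n, p)
  fitn <- allometric_regression(Yn, x, n_perm = 99, seed = 1)
  xc <- x - mean(x)
  expect_lt(max(abs(crossprod(fitn$residuals, xc))), 1e-10)
  # pct_predicted invariant to affine rescaling of the predictor
  fit2 <- allometric_regression(Yn, 2.5 * x + 1, n_perm = 99, seed = 1)
  expect_equal(fit2$pct_predicted, fitn$pct_predicted, tolerance = 1e-10)
  expect_error(allometric_regression(Yn, rep(2, n), n_perm = 9, seed = 1),
               "constant")
})

test_that("allometry permutation p is calibrated under the null", {
  set.seed(77)
  n <- 20; p <- 6; reps <- 300
  pvals <- vapply(seq_len(reps), function(r) {
    Y <- matrix(rnorm(n * p), n, p)
    x <- runif(n, 1, 2)
    allometric_regression(Y, x, n_perm = 199, seed = r)$perm_p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 1 / 200)
})

test_that("shape PCA is orthonormal, complete, and finds planted directions", {
  set.seed(8)
  n <- 20; p <- 10
  # variation along a single direction
  v <- rnorm(p); v <- v / sqrt(sum(v^2))
  Y1 <- outer(rnorm(n), v)
  pc1 <- shape_pca(Y1)
  expect_equal(pc1$var_fraction[1], 1, tolerance = 1e-10)
  # general case: orthonormal loadings, completeness, variance accounting
  Y <- matrix(rnorm(n * p), n, p)
  pc <- shape_pca(Y)
  G <- crossprod(pc$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_equal(sum(pc$var_fraction), 1, tolerance = 1e-8)
  expect_true(all(diff(pc$var_fraction) <= 1e-12))
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_lt(max(abs(pc$scores %*% t(pc$loadings) - Yc)), 1e-8)
  expect_equal(sum(pc$var_fraction) * sum(svd(Yc)$d^2),
               sum(svd(Yc)$d^2), tolerance = 1e-8)
})

test_that("orient_pc makes the reference group score negative", {
  set.seed(9)
  Y <- rbind(matrix(rnorm(50, 2), 5, 10), matrix(rnorm(50, -2), 5, 10))
  pc <- shape_pca(Y)
  pc <- orient_pc(pc, reference = 1:5)
  expect_lt(mean(pc$scores[1:5, 1]), 0)
})

test_that("group PC test matches the pooled-t hand computation", {
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  res <- group_pc_test(c(x, y), rep(c("a", "b"), each = 3))
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- group_pc_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # shifting one group strictly increases |t|
  t0 <- abs(group_pc_test(c(x, y), rep(c("a", "b"), each = 3))$statistic)
  t1 <- abs(group_pc_test(c(x, y + 2), rep(c("a", "b"), each = 3))$statistic)
  expect_gt(t1, t0)
  expect_error(group_pc_test(1:4, rep("a", 4)), "two groups")
})

test_that("symmetrized configurations are reflection-invariant", {
  # build a config symmetric about axis 1 except for asymmetric noise
  set.seed(12)
  k <- 6
  right <- cbind(runif(3, 0.5, 1.5), runif(3, -1, 1))
  left <- cbind(-right[, 1], right[, 2])
  co <- array(NA_real_, c(2, k, 2))
  for (i in 1:2) co[i, , ] <- rbind(right, left) + matrix(rnorm(k * 2, 0, 0.05), k, 2)
  lms <- landmark_set(co)
  pairing <- cbind(4:6, 1:3)
  sym <- symmetrize_landmarks(lms, pairing, axis = 1)
  for (i in 1:2) {
    s <- sym$coords[i, , ]
    refl <- s
    refl[, 1] <- -refl[, 1]
    refl <- refl[c(4:6, 1:3), ]
    # symmetrised shape equals its own relabelled reflection after alignment
    sc <- sweep(s, 2, colMeans(s)); rc <- sweep(refl, 2, colMeans(refl))
    rc <- rc %*% skullqtl:::.rotation_onto(rc, sc)
    expect_lt(max(abs(sc - rc)), 1e-8)
  }
})
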