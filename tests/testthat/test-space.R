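# Acoustic space: PCA, per-baby maps, shrinkage test, discriminant axis.

test_that("PCA basis: planar data, determinism, sign convention", {
  set.seed(10)
  basis2 <- matrix(rnorm(2 * 40), 2, 40)
  X <- matrix(rnorm(30 * 2), 30, 2) %*% basis2 +
    matrix(rnorm(40), 30, 40, byrow = TRUE) * 0   # exactly planar
  pc <- fit_mps_pca(X, n_components = 5)
  expect_gt(sum(pc$explained_variance[1:2]), 0.999999)
  pc2 <- fit_mps_pca(X, n_components = 5)
  expect_identical(pc$rotation, pc2$rotation)
  for (k in seq_len(ncol(pc$rotation))) {
    expect_gt(pc$rotation[which.max(abs(pc$rotation[, k])), k], 0)
  }
  expect_error(fit_mps_pca(X[1:4, ], n_components = 5), "samples")
  # orthonormal loadings, non-increasing variance
  expect_equal(unname(crossprod(pc$rotation)), diag(ncol(pc$rotation)),
               tolerance = 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
})

test_that("projection of the fitted mean is the origin", {
  set.seed(11)
  X <- matrix(rnorm(20 * 15), 20, 15)
  pc <- fit_mps_pca(X, n_components = 3)
  centre_score <- project_mps(pc, matrix(colMeans(X), 1))
  expect_lt(max(abs(centre_score)), 1e-10)
})

test_that("per-baby map projects averages and drops incomplete babies", {
  ms <- small_mps()
  bm <- baby_average_mps(ms)
  basis <- fit_mps_pca(bm$X[bm$meta$condition == "discomfort", , drop = FALSE],
                       n_components = 5, fitted_on = "per-baby-average discomfort")
  map <- map_babies(bm, basis)
  expect_equal(nrow(map), 16)
  expect_true(all(c("PC1", "PC2") %in% names(map)))
  cen <- attr(map, "centroids")
  expect_equal(nrow(cen), 2)
  # dropping one baby's pain rows triggers a warning and exclusion
  keep <- !(bm$meta$baby_id == "B03" & bm$meta$condition == "pain")
  bm2 <- bm; bm2$X <- bm$X[keep, , drop = FALSE]; bm2$meta <- bm$meta[keep, ]
  expect_warning(map2 <- map_babies(bm2, basis), "B03")
  expect_false("B03" %in% map2$baby_id)
})

test_that("paired t on centroid distances matches a hand-computed value", {
  # 3 babies at known distances: discomfort 2,3,4 vs pain 1,1,1
  coords <- tibble::tibble(
    baby_id = rep(c("A", "B", "C"), 2),
    sex = "F",
    condition = rep(c("discomfort", "pain"), each = 3),
    PC1 = c(2, 3, 4, 1, 1, 1) + 5,   # distances realized along PC1 from centroid
    PC2 = 0
  )
  # construct a map with centroids at PC1 = 5 per condition by symmetrizing:
  # place mirrored points so each condition centroid is exactly (5, 0)
  mirror <- coords
  mirror$baby_id <- paste0(mirror$baby_id, "m")
  mirror$PC1 <- 10 - coords$PC1
  map <- structure(dplyr::bind_rows(coords, mirror),
                   centroids = tibble::tibble(condition = c("discomfort", "pain"),
                                              PC1 = 5, PC2 = 0),
                   class = c("acoustic_map", class(coords)))
  res <- centroid_shrinkage_test(map)
  d <- c(2, 3, 4, 2, 3, 4) - 1   # |disc - centroid| minus |pain - centroid| per baby
  tt <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(res$t, tt, tolerance = 1e-10)
  expect_equal(res$df, 5)
  expect_equal(res$mean_difference, mean(d))
})

test_that("identical condition coordinates give a null shrinkage test", {
  map <- structure(tibble::tibble(
    baby_id = rep(sprintf("B%d", 1:5), 2), sex = "F",
    condition = rep(c("discomfort", "pain"), each = 5),
    PC1 = rep(c(1, 2, 3, 4, 5), 2), PC2 = rep(c(2, 1, 0, -1, -2), 2)),
    centroids = tibble::tibble(condition = c("discomfort", "pain"),
                               PC1 = 3, PC2 = 0),
    class = c("acoustic_map", "tbl_df", "tbl", "data.frame"))
  res <- centroid_shrinkage_test(map)
  expect_equal(res$mean_difference, 0)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("distances are invariant to rigid rotation of the PC plane", {
  set.seed(12)
  pts <- matrix(rnorm(20), 10, 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  rot <- pts %*% R
  mk_map <- function(m) {
    structure(tibble::tibble(
      baby_id = rep(sprintf("B%d", 1:5), 2), sex = "F",
      condition = rep(c("discomfort", "pain"), each = 5),
      PC1 = m[, 1], PC2 = m[, 2]),
      centroids = dplyr::summarise(
        dplyr::group_by(tibble::tibble(condition = rep(c("discomfort", "pain"), each = 5),
                                       PC1 = m[, 1], PC2 = m[, 2]), condition),
        PC1 = mean(PC1), PC2 = mean(PC2), .groups = "drop"),
      class = c("acoustic_map", "tbl_df", "tbl", "data.frame"))
  }
  r1 <- centroid_shrinkage_test(mk_map(pts))
  r2 <- centroid_shrinkage_test(mk_map(rot))
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
  expect_equal(r1$mean_discomfort, r2$mean_discomfort, tolerance = 1e-10)
})

test_that("condition discriminant recovers a constructed separation direction", {
  set.seed(13)
  n <- 500
  p <- 6
  dir_true <- c(1, rep(0, p - 1))
  X <- rbind(matrix(rnorm(n / 2 * p, 0), n / 2, p),
             matrix(rnorm(n / 2 * p, 0), n / 2, p) +
               matrix(4 * dir_true, n / 2, p, byrow = TRUE))
  cond <- rep(c("discomfort", "pain"), each = n / 2)
  axis <- condition_discriminant(X, cond)
  angle <- acos(abs(sum(axis$loading * dir_true)) / sqrt(sum(dir_true^2)))
  expect_lt(angle * 180 / pi, 10)
  expect_gt(axis$class_means[["pain"]], axis$class_means[["discomfort"]])
  expect_equal(sum(axis$loading^2), 1, tolerance = 1e-10)

  # identical class distributions: small in-sample separation (the fitted
  # axis overfits a little, so the bound is statistical, not zero)
  set.seed(14)
  X0 <- matrix(rnorm(n * p), n, p)
  axis0 <- condition_discriminant(X0, cond)
  proj <- axis0$projections$projection
  pooled_sd <- sd(proj)
  expect_lt(abs(axis0$class_means[["pain"]] - axis0$class_means[["discomfort"]]),
            0.3 * pooled_sd)
  expect_error(condition_discriminant(X0[1:60, ], rep("pain", 60)), "both conditions")
})

test_that("trajectory correlations: exact, null, and constructed alignment", {
  # exact: y = x
  mk <- function(xd, xp, yd, yp) {
    map <- structure(tibble::tibble(
      baby_id = rep(sprintf("B%02d", seq_along(xd)), 2), sex = "F",
      condition = rep(c("discomfort", "pain"), each = length(xd)),
      PC1 = c(yd, yp), PC2 = 0),
      centroids = tibble::tibble(condition = c("discomfort", "pain"),
                                 PC1 = c(mean(yd), mean(yp)), PC2 = 0),
      class = c("acoustic_map", "tbl_df", "tbl", "data.frame"))
    axis <- structure(list(
      loading = 1,
      per_baby = tibble::tibble(
        baby_id = rep(sprintf("B%02d", seq_along(xd)), 2),
        condition = rep(c("discomfort", "pain"), each = length(xd)),
        projection = c(xd, xp))
    ), class = "discriminant_axis")
    trajectory_correlation(map, axis, pc = 1)
  }
  x <- seq_len(8)
  exact <- mk(x, 1.3 * x + 1, x, 1.3 * x + 1)
  expect_equal(tidy(exact)$r[1], 1, tolerance = 1e-10)
  expect_lt(tidy(exact)$p[1], 1e-6)

  # independent coordinates at n = 22: |r| mostly below 0.45
  set.seed(15)
  rs <- vapply(1:20, function(i) {
    tidy(mk(rnorm(22), rnorm(22), rnorm(22), rnorm(22)))$r[1]
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.45), 0.9)

  expect_error(mk(rep(1, 8), rep(1, 8), x, x), "zero variance")
  expect_error(mk(x[1:3], x[1:3], x[1:3], x[1:3]), "at least 5")
})

test_that("parameter-contracted pain maps shrink; rotated ones do not", {
  # constructed configuration: per-baby mean MPS-like vectors where pain is a
  # true contraction toward the centroid vs a rigid rotation of the cloud
  set.seed(16)
  n <- 12; p <- 40
  # identity signatures live in the first two dimensions
  disc <- cbind(matrix(rnorm(n * 2, sd = 3), n, 2),
                matrix(rnorm(n * (p - 2), sd = 0.3), n, p - 2))
  contracted <- disc * 0.4
  theta <- pi / 3
  rot_plane <- diag(p)
  rot_plane[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  rotated <- disc %*% rot_plane
  mk_set <- function(pain) {
    structure(list(
      X = rbind(disc, pain),
      meta = tibble::tibble(
        baby_id = rep(sprintf("B%02d", 1:n), 2), sex = "F",
        condition = rep(c("discomfort", "pain"), each = n),
        n_cries = 1L),
      temporal_modulations = seq_len(p), spectral_modulations = 1),
      class = "mps_set")
  }
  test_in_basis <- function(pain, fit_cond) {
    s <- mk_set(pain)
    basis <- fit_mps_pca(s$X[s$meta$condition == fit_cond, , drop = FALSE],
                         n_components = 2, fitted_on = fit_cond)
    centroid_shrinkage_test(map_babies(s, basis))
  }
  r_con_d <- test_in_basis(contracted, "discomfort")
  r_con_p <- test_in_basis(contracted, "pain")
  expect_lt(r_con_d$p, 0.05)          # true contraction shows in both bases
  expect_gt(r_con_d$mean_difference, 0)
  expect_lt(r_con_p$p, 0.05)
  expect_gt(r_con_p$mean_difference, 0)
  # a rotation of the signature plane is not a contraction: in the basis
  # fitted on the pain cries themselves it must not appear as shrinkage
  r_rot_p <- test_in_basis(rotated, "pain")
  expect_false(r_rot_p$p < 0.05 && r_rot_p$mean_difference > 0)
})
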