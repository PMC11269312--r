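# Low-dimensional acoustic space of the MPS: principal components, per-baby
# maps, the centroid-distance shrinkage test, the condition-discriminant axis,
# and the trajectory correlations between identity and condition dimensions.

#' Principal-component basis of MPS vectors
#'
#' Centered PCA with a reproducible sign convention: each loading is flipped
#' so its largest-magnitude element is positive.
#'
#' @param X Matrix of flattened MPS vectors (rows = cries or baby averages),
#'   or an `mps_set`.
#' @param n_components Number of components to retain.
#' @param fitted_on Free-text note on what the basis was fitted on (e.g.
#'   `"per-baby-average discomfort"`).
#' @return An `mps_pca`: `center`, `rotation` (p x k), `sdev`,
#'   `explained_variance` (fractions), `fitted_on`.
#' @export
fit_mps_pca <- function(X, n_components = 20L, fitted_on = "per-cry") {
  if (inherits(X, "mps_set")) X <- X$X
  if (nrow(X) <= n_components) abort("need more samples than components")
  n_components <- min(n_components, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  for (k in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) rot[, k] <- -rot[, k]
  }
  structure(list(
    center = pc$center, rotation = rot,
    sdev = pc$sdev[seq_len(n_components)],
    explained_variance = pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2),
    fitted_on = fitted_on
  ), class = "mps_pca")
}

#' @export
print.mps_pca <- function(x, ...) {
  cat(sprintf("<mps_pca> %d components fitted on %s; PC1-2 explain %.1f%%\n",
              ncol(x$rotation), x$fitted_on,
              100 * sum(x$explained_variance[1:min(2, length(x$explained_variance))])))
  invisible(x)
}

#' Project MPS vectors onto a fitted PC basis
#'
#' @param basis An `mps_pca`.
#' @param X Matrix of MPS vectors or an `mps_set`.
#' @return Matrix of scores (rows x components).
#' @export
project_mps <- function(basis, X) {
  if (inherits(X, "mps_set")) X <- X$X
  sweep(X, 2L, basis$center) %*% basis$rotation
}

#' Per-baby acoustic map in the PC1-PC2 plane
#'
#' Projects each baby x condition average MPS onto the first two components
#' of `basis` and records per-condition centroids. Babies missing one of the
#' conditions are dropped with a warning.
#'
#' @param baby_mps An `mps_set` of baby x condition averages
#'   (see [baby_average_mps()]); a per-cry `mps_set` is averaged first.
#' @param basis An `mps_pca`.
#' @return An `acoustic_map` tibble: `baby_id`, `sex`, `condition`, `PC1`,
#'   `PC2`, with centroids in `attr(, "centroids")`.
#' @export
map_babies <- function(baby_mps, basis) {
  stopifnot(inherits(baby_mps, "mps_set"), inherits(basis, "mps_pca"))
  if (!"n_cries" %in% names(baby_mps$meta)) baby_mps <- baby_average_mps(baby_mps)
  sc <- project_mps(basis, baby_mps$X)
  map <- baby_mps$meta %>%
    mutate(PC1 = sc[, 1], PC2 = sc[, 2])
  both <- map %>% count(.data$baby_id) %>% filter(.data$n == 2) %>% pull(.data$baby_id)
  dropped <- setdiff(unique(map$baby_id), both)
  if (length(dropped) > 0) {
    warning("dropping babies missing a condition: ", paste(dropped, collapse = ", "))
    map <- map %>% filter(.data$baby_id %in% both)
  }
  centroids <- map %>%
    group_by(.data$condition) %>%
    summarise(PC1 = mean(.data$PC1), PC2 = mean(.data$PC2), .groups = "drop")
  structure(map, centroids = centroids, class = c("acoustic_map", class(map)))
}

#' Centroid-distance shrinkage test
#'
#' For each baby and condition, the Euclidean distance between the baby's
#' average position and that condition's centroid in the PC1-PC2 plane; the
#' two conditions are compared with a two-sided paired t test across babies.
#' A positive mean difference (discomfort minus pain) indicates that pain
#' cries are more homogeneous across babies: the acoustic space has shrunk.
#'
#' @param map An `acoustic_map`.
#' @return A `shrinkage_result`: per-baby distances, condition means with
#'   +/- 2 SE, the paired t statistic with `df = n_babies - 1`, and p.
#' @export
centroid_shrinkage_test <- function(map) {
  stopifnot(inherits(map, "acoustic_map"))
  cen <- attr(map, "centroids")
  d <- map %>%
    left_join(cen %>% rename(cPC1 = "PC1", cPC2 = "PC2"), by = "condition") %>%
    mutate(distance = sqrt((.data$PC1 - .data$cPC1)^2 + (.data$PC2 - .data$cPC2)^2)) %>%
    select("baby_id", "condition", "distance") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "distance")
  if (nrow(d) < 3) abort("need at least 3 babies with both conditions")
  diffs <- d$discomfort - d$pain
  if (sd(diffs) < 1e-12) {  # degenerate: identical coordinates across conditions
    t_stat <- 0; p_val <- 1
  } else {
    tt <- t.test(d$discomfort, d$pain, paired = TRUE)
    t_stat <- unname(tt$statistic); p_val <- tt$p.value
  }
  two_se <- function(x) 2 * sd(x) / sqrt(length(x))
  structure(list(
    distances = d,
    mean_discomfort = mean(d$discomfort), discomfort_2se = two_se(d$discomfort),
    mean_pain = mean(d$pain), pain_2se = two_se(d$pain),
    mean_difference = mean(diffs),
    t = t_stat, df = nrow(d) - 1L, p = p_val
  ), class = "shrinkage_result")
}

#' @export
print.shrinkage_result <- function(x, ...) {
  cat(sprintf(
    "<shrinkage_result> distance to centroid: discomfort %.3f +/- %.3f, pain %.3f +/- %.3f [2SE]\n  paired t(%d) = %.3f, p = %.4g\n",
    x$mean_discomfort, x$discomfort_2se, x$mean_pain, x$pain_2se,
    x$df, x$t, x$p))
  invisible(x)
}

#' @export
glance.shrinkage_result <- function(x, ...) {
  tibble(mean_discomfort = x$mean_discomfort, discomfort_2se = x$discomfort_2se,
         mean_pain = x$mean_pain, pain_2se = x$pain_2se,
         mean_difference = x$mean_difference, t = x$t, df = x$df, p = x$p)
}

#' @export
tidy.shrinkage_result <- function(x, ...) {
  x$distances %>%
    tidyr::pivot_longer(c("discomfort", "pain"),
                        names_to = "condition", values_to = "distance")
}

#' Single discriminant axis separating the two conditions
#'
#' Two-class linear discriminant on per-cry PC scores; the unit-norm axis is
#' oriented so pain cries project positively on average.
#'
#' @param scores Matrix of per-cry PC scores (e.g. from [project_mps()]).
#' @param condition Character vector (`discomfort`/`pain`) per row.
#' @param baby_id Optional baby labels for per-baby mean projections.
#' @return A `discriminant_axis`: `loading` (unit norm, in PC space),
#'   per-cry `projections` tibble, per-baby means, class means.
#' @export
condition_discriminant <- function(scores, condition, baby_id = NULL) {
  condition <- as.character(condition)
  if (length(unique(condition)) < 2) abort("both conditions must be present")
  fit <- MASS::lda(scores, grouping = factor(condition))
  w <- as.numeric(fit$scaling[, 1])
  w <- w / sqrt(sum(w^2))
  proj <- as.numeric(scores %*% w)
  if (mean(proj[condition == "pain"]) < mean(proj[condition == "discomfort"])) {
    w <- -w
    proj <- -proj
  }
  per_cry <- tibble(condition = condition, projection = proj)
  if (!is.null(baby_id)) per_cry$baby_id <- baby_id
  per_baby <- if (!is.null(baby_id)) {
    per_cry %>% group_by(.data$baby_id, .data$condition) %>%
      summarise(projection = mean(.data$projection), .groups = "drop")
  } else NULL
  structure(list(
    loading = w,
    projections = per_cry,
    per_baby = per_baby,
    class_means = tapply(proj, condition, mean)
  ), class = "discriminant_axis")
}

#' @export
print.discriminant_axis <- function(x, ...) {
  cat(sprintf("<discriminant_axis> class means: discomfort %.3f, pain %.3f\n",
              x$class_means[["discomfort"]], x$class_means[["pain"]]))
  invisible(x)
}

#' Correlation between the condition axis and a PC coordinate
#'
#' Per baby, correlates the position along the condition-discriminant axis
#' (x) with the chosen PC coordinate (y), separately for discomfort means,
#' pain means, and the per-baby pairwise differences (discomfort - pain).
#' Also returns the arrow set (base = discomfort mean, tip = pain mean).
#'
#' @param map An `acoustic_map`.
#' @param axis A `discriminant_axis` fitted with `baby_id` labels.
#' @param pc Which PC coordinate of the map to use as y (1 or 2).
#' @return A `trajectory_stats`: tibble of Pearson r and p per contrast, plus
#'   the arrows tibble.
#' @export
trajectory_correlation <- function(map, axis, pc = 1) {
  stopifnot(inherits(map, "acoustic_map"), inherits(axis, "discriminant_axis"))
  if (is.null(axis$per_baby)) abort("axis must carry per-baby projections (pass baby_id)")
  pc_col <- paste0("PC", pc)
  wide_y <- map %>% select("baby_id", "condition", dplyr::all_of(pc_col)) %>%
    tidyr::pivot_wider(names_from = "condition", values_from = dplyr::all_of(pc_col))
  wide_x <- axis$per_baby %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "projection") %>%
    rename(x_discomfort = "discomfort", x_pain = "pain")
  d <- wide_y %>% left_join(wide_x, by = "baby_id")
  if (nrow(d) < 5) abort("need at least 5 babies")
  one <- function(x, y, label) {
    if (sd(x) == 0 || sd(y) == 0) abort("zero variance in a coordinate")
    ct <- cor.test(x, y)
    tibble(contrast = label, r = unname(ct$estimate), p = ct$p.value,
           n = length(x))
  }
  stats_tbl <- bind_rows(
    one(d$x_discomfort, d$discomfort, "discomfort"),
    one(d$x_pain, d$pain, "pain"),
    one(d$x_discomfort - d$x_pain, d$discomfort - d$pain, "difference")
  )
  arrows <- d %>%
    select("baby_id") %>%
    mutate(x0 = d$x_discomfort, y0 = d$discomfort,
           x1 = d$x_pain, y1 = d$pain)
  structure(list(stats = stats_tbl, arrows = arrows, pc = pc),
            class = "trajectory_stats")
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat(sprintf("<trajectory_stats> vs PC%d\n", x$pc))
  print(x$stats)
  invisible(x)
}

#' @export
tidy.trajectory_stats <- function(x, ...) x$stats
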