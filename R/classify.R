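# Supervised identification of baby identity from cry features under four
# train/test regimes: leave-one-out within discomfort, within a mixed pool,
# within pain, and a single cross-condition split (train on discomfort, test
# on pain). Feature spaces: the flattened MPS projected on its first 20
# training-fold PCs, the 22 PAFs, or the 10-feature spectral subset.

#' Eligibility thresholds for the classification corpus
#'
#' A baby enters the analysis with at least `min_discomfort_train` discomfort
#' cries available for training, at least `min_pain` pain cries, and at least
#' `min_total` cries overall. Schemes that hold out a discomfort cry under
#' leave-one-out need `extra_for_loo` additional discomfort cries.
#'
#' @param min_discomfort_train,min_pain,min_total,extra_for_loo Integer
#'   thresholds.
#' @return A list of class `eligibility_rule`.
#' @export
eligibility_rule <- function(min_discomfort_train = 5L, min_pain = 4L,
                             min_total = 10L, extra_for_loo = 1L) {
  stopifnot(min_discomfort_train >= 1, min_pain >= 1, min_total >= 1,
            extra_for_loo >= 0)
  structure(list(min_discomfort_train = as.integer(min_discomfort_train),
                 min_pain = as.integer(min_pain),
                 min_total = as.integer(min_total),
                 extra_for_loo = as.integer(extra_for_loo)),
            class = "eligibility_rule")
}

#' Select babies eligible for a classification scheme
#'
#' @param metadata Tibble with `baby_id` and `condition` per cry.
#' @param rule An [eligibility_rule()].
#' @param scheme One of `"within-discomfort"`, `"mixed"`, `"cross-condition"`,
#'   `"within-pain"`.
#' @return Character vector of eligible baby ids (sorted).
#' @export
select_eligible <- function(metadata, rule = eligibility_rule(),
                            scheme = c("within-discomfort", "mixed",
                                       "cross-condition", "within-pain")) {
  scheme <- match.arg(scheme)
  counts <- metadata %>%
    count(.data$baby_id, .data$condition) %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "n",
                       values_fill = 0L)
  if (!"discomfort" %in% names(counts)) counts$discomfort <- 0L
  if (!"pain" %in% names(counts)) counts$pain <- 0L
  need_disc <- rule$min_discomfort_train +
    if (scheme %in% c("within-discomfort", "mixed")) rule$extra_for_loo else 0L
  ok <- counts$discomfort >= need_disc &
    counts$pain >= rule$min_pain &
    (counts$discomfort + counts$pain) >= rule$min_total
  out <- sort(counts$baby_id[ok])
  if (length(out) == 0) {
    abort("no baby satisfies the eligibility thresholds; consider relaxing the rule")
  }
  out
}

# Regularized Gaussian discriminant (quadratic): per-class covariance with a
# ridge, needed because pain classes can have as few as 3-4 training
# exemplars in 20 dimensions.
fit_rqda <- function(x, y, ridge = 0.1) {
  y <- factor(y)
  classes <- levels(y)
  p <- ncol(x)
  mods <- lapply(classes, function(k) {
    xi <- x[y == k, , drop = FALSE]
    mu <- colMeans(xi)
    S <- if (nrow(xi) > 1) stats::cov(xi) else diag(p)
    lambda <- ridge * mean(diag(S)) + 1e-8
    S <- S + diag(lambda, p)
    ch <- chol(S)
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))),
         logprior = log(sum(y == k) / length(y)))
  })
  names(mods) <- classes
  structure(list(models = mods, classes = classes), class = "rqda")
}

predict_rqda <- function(fit, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  lp <- vapply(fit$models, function(m) {
    z <- backsolve(m$chol, t(sweep(newx, 2, m$mu)), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * m$logdet + m$logprior
  }, numeric(nrow(newx)))
  if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1, dimnames = list(NULL, fit$classes))
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp)
  post / rowSums(post)
}

# Fit one classifier on training scores and return posterior matrix for test
# rows, with columns for every class in `all_classes`.
fit_predict_posterior <- function(model, xtr, ytr, xte, all_classes) {
  ytr <- factor(ytr, levels = all_classes)
  if (is.null(dim(xte))) xte <- matrix(xte, nrow = 1)
  post <- switch(model,
    lda = {
      # collinearity warnings are routine for folds with p close to n; the
      # within-tolerance subspace fit is what the method calls for
      fit <- suppressWarnings(MASS::lda(xtr, grouping = ytr))
      pr <- predict(fit, xte)$posterior
      full <- matrix(0, nrow(xte), length(all_classes),
                     dimnames = list(NULL, all_classes))
      full[, colnames(pr)] <- pr
      full
    },
    qda = predict_rqda(fit_rqda(xtr, ytr), xte)[, all_classes, drop = FALSE],
    rf = {
      fit <- randomForest::randomForest(x = xtr, y = droplevels(ytr),
                                        ntree = 100)
      pr <- predict(fit, xte, type = "prob")
      full <- matrix(0, nrow(xte), length(all_classes),
                     dimnames = list(NULL, all_classes))
      full[, colnames(pr)] <- pr
      full
    },
    abort(paste0("unknown model: ", model))
  )
  post
}

# Leave-one-out PCA scores via the Gram matrix: for each held-out row the
# basis is refit on the remaining rows without touching the p-dimensional
# space again. Returns train scores and the held-out row's scores.
loo_pca_scores <- function(K, train_idx, test_idx, k) {
  G <- K[train_idx, train_idx, drop = FALSE]
  m <- nrow(G)
  rm_ <- rowMeans(G)
  gm <- mean(G)
  Gc <- G - outer(rm_, rep(1, m)) - outer(rep(1, m), rm_) + gm
  eg <- eigen(Gc, symmetric = TRUE)
  pos <- which(eg$values > 1e-8 * eg$values[1])
  k <- min(k, length(pos))
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  S <- sqrt(eg$values[seq_len(k)])
  train_scores <- U * rep(S, each = m)
  kv <- K[test_idx, train_idx, drop = FALSE]
  kc <- sweep(sweep(kv, 1, rowMeans(kv)), 2, rm_) + gm
  test_scores <- kc %*% U %*% diag(1 / S, k)
  list(train = train_scores, test = test_scores)
}

#' Classify baby identity from cry features
#'
#' Runs one classifier x feature-space x scheme combination. For the
#' leave-one-out schemes each cry is held out once and the whole
#' preprocessing (feature standardization, or the 20-component MPS PCA) plus
#' the classifier is refit on the remaining cries; for the cross-condition
#' scheme a single model is trained on all discomfort cries and tested on all
#' pain cries. Posterior probabilities over babies are aggregated into a
#' confusion matrix of mean posteriors by true baby; hard classification uses
#' the maximum posterior (ties broken by lowest baby label).
#'
#' @param x An `mps_set` (for `space = "mps-pc20"`) or a [paf_table()] tibble
#'   (for the PAF spaces).
#' @param model `"lda"`, `"qda"` (ridge-regularized), or `"rf"` (100 trees).
#' @param space `"mps-pc20"`, `"paf22"`, or `"paf10"`.
#' @param scheme CV scheme; see [select_eligible()].
#' @param rule An [eligibility_rule()].
#' @param n_components PCs retained in the MPS space.
#' @param seed Seed (used by the random-forest model).
#' @return An `identity_report`; see [glance.identity_report()].
#' @export
classify_identity <- function(x,
                              model = c("lda", "qda", "rf"),
                              space = c("mps-pc20", "paf22", "paf10"),
                              scheme = c("within-discomfort", "mixed",
                                         "cross-condition", "within-pain"),
                              rule = eligibility_rule(),
                              n_components = 20L,
                              seed = 1L) {
  model <- match.arg(model)
  space <- match.arg(space)
  scheme <- match.arg(scheme)
  if (space == "mps-pc20") {
    stopifnot(inherits(x, "mps_set"))
    meta <- x$meta
    feat <- x$X
  } else {
    stopifnot(is.data.frame(x))
    cols <- if (space == "paf22") paf_feature_names() else paf_subset10_names()
    missing_cols <- setdiff(cols, names(x))
    if (length(missing_cols) > 0) {
      abort(paste0("feature table lacks: ", paste(missing_cols, collapse = ", ")))
    }
    meta <- x
    feat <- as.matrix(x[, cols])
  }
  eligible <- select_eligible(meta, rule, scheme)
  if (length(eligible) < 2) abort("need at least 2 eligible babies")
  keep <- meta$baby_id %in% eligible
  meta <- meta[keep, ]
  feat <- feat[keep, , drop = FALSE]
  classes <- sort(eligible)
  is_disc <- meta$condition == "discomfort"
  sets <- switch(scheme,
    "within-discomfort" = list(train = which(is_disc), test = which(is_disc), loo = TRUE),
    "mixed" = list(train = seq_len(nrow(meta)), test = seq_len(nrow(meta)), loo = TRUE),
    "within-pain" = list(train = which(!is_disc), test = which(!is_disc), loo = TRUE),
    "cross-condition" = list(train = which(is_disc), test = which(!is_disc), loo = FALSE)
  )
  if (!all(meta$baby_id[sets$test] %in% meta$baby_id[sets$train])) {
    abort("every test baby must appear in the training set")
  }
  use_pca <- space == "mps-pc20"
  n_test <- length(sets$test)
  posterior <- matrix(NA_real_, n_test, length(classes),
                      dimnames = list(NULL, classes))
  truth <- meta$baby_id[sets$test]
  with_seed(seed, {
    if (sets$loo) {
      rows <- sets$train  # identical to test set
      if (use_pca) K <- tcrossprod(feat[rows, , drop = FALSE])
      for (j in seq_along(rows)) {
        tr <- rows[-j]
        te <- rows[j]
        if (use_pca) {
          sc <- loo_pca_scores(K, setdiff(seq_along(rows), j), j, n_components)
          xtr <- sc$train
          xte <- sc$test
        } else {
          mu <- colMeans(feat[tr, , drop = FALSE])
          sg <- apply(feat[tr, , drop = FALSE], 2, sd)
          sg[sg == 0] <- 1
          xtr <- sweep(sweep(feat[tr, , drop = FALSE], 2, mu), 2, sg, "/")
          xte <- matrix((feat[te, ] - mu) / sg, nrow = 1)
        }
        posterior[j, ] <- fit_predict_posterior(model, xtr, meta$baby_id[tr],
                                                xte, classes)
      }
    } else {
      tr <- sets$train
      te <- sets$test
      if (use_pca) {
        basis <- fit_mps_pca(feat[tr, , drop = FALSE], n_components,
                             fitted_on = "training split")
        xtr <- project_mps(basis, feat[tr, , drop = FALSE])
        xte <- project_mps(basis, feat[te, , drop = FALSE])
      } else {
        mu <- colMeans(feat[tr, , drop = FALSE])
        sg <- apply(feat[tr, , drop = FALSE], 2, sd)
        sg[sg == 0] <- 1
        xtr <- sweep(sweep(feat[tr, , drop = FALSE], 2, mu), 2, sg, "/")
        xte <- sweep(sweep(feat[te, , drop = FALSE], 2, mu), 2, sg, "/")
      }
      posterior[, ] <- fit_predict_posterior(model, xtr, meta$baby_id[tr],
                                             xte, classes)
    }
  })
  confusion <- rowsum(posterior, truth) / as.vector(table(truth)[sort(unique(truth))])
  confusion <- confusion[classes, classes]
  predicted <- classes[apply(posterior, 1, which.max)]  # first max = lowest label
  diag_post <- diag(confusion)
  structure(list(
    confusion = confusion,
    mean_diag_posterior = mean(diag_post),
    diag_posterior_2se = 2 * sd(diag_post) / sqrt(length(diag_post)),
    correct_count = sum(predicted == truth),
    total_count = n_test,
    chance = 1 / length(classes),
    n_babies = length(classes),
    model = model, space = space, scheme = scheme
  ), class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  cat(sprintf(
    "<identity_report> %s / %s / %s\n  mean diagonal posterior %.1f%% +/- %.1f%% [2SE] (chance %.1f%%)\n  correct %d/%d by max posterior\n",
    toupper(x$model), x$space, x$scheme,
    100 * x$mean_diag_posterior, 100 * x$diag_posterior_2se, 100 * x$chance,
    x$correct_count, x$total_count))
  invisible(x)
}

#' One-row summary of an identity classification run
#'
#' @param x An `identity_report`.
#' @param ... Unused.
#' @return Tibble with the mean diagonal posterior (+/- 2 SE), hard-count
#'   accuracy, chance level, and the exact binomial p against chance.
#' @export
glance.identity_report <- function(x, ...) {
  tibble(model = x$model, space = x$space, scheme = x$scheme,
         n_babies = x$n_babies,
         mean_diag_posterior = x$mean_diag_posterior,
         diag_posterior_2se = x$diag_posterior_2se,
         correct = x$correct_count, total = x$total_count,
         accuracy = x$correct_count / x$total_count,
         chance = x$chance,
         binomial_p = binomial_vs_chance(x$correct_count, x$total_count, x$chance))
}

#' @export
tidy.identity_report <- function(x, ...) {
  as_tibble(as.data.frame.table(x$confusion, responseName = "posterior")) %>%
    rename(true_baby = "Var1", predicted_baby = "Var2") %>%
    mutate(across(c("true_baby", "predicted_baby"), as.character))
}

#' Run all four classification regimes
#'
#' @inheritParams classify_identity
#' @return Tibble binding [glance.identity_report()] rows for the
#'   within-discomfort, mixed, cross-condition and within-pain schemes.
#' @export
classify_all_regimes <- function(x, model = "lda", space = "mps-pc20",
                                 rule = eligibility_rule(),
                                 n_components = 20L, seed = 1L) {
  schemes <- c("within-discomfort", "mixed", "cross-condition", "within-pain")
  bind_rows(lapply(schemes, function(s) {
    glance(classify_identity(x, model = model, space = space, scheme = s,
                             rule = rule, n_components = n_components,
                             seed = seed))
  }))
}

#' Fisher exact comparison of two correct/total counts
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[correct_a, n_a - correct_a], [correct_b, n_b - correct_b]]`.
#'
#' @param correct_a,n_a,correct_b,n_b Counts.
#' @return The two-sided p-value.
#' @export
fisher_compare <- function(correct_a, n_a, correct_b, n_b) {
  stopifnot(correct_a >= 0, correct_a <= n_a, correct_b >= 0, correct_b <= n_b)
  fisher.test(matrix(c(correct_a, n_a - correct_a,
                       correct_b, n_b - correct_b), nrow = 2, byrow = TRUE))$p.value
}

#' Exact binomial test of a correct count against chance
#'
#' Upper-tail probability of observing at least `correct` successes in `n`
#' trials at success probability `chance_p`.
#'
#' @param correct,n Counts.
#' @param chance_p Chance success probability in (0, 1).
#' @return The one-sided p-value.
#' @export
binomial_vs_chance <- function(correct, n, chance_p) {
  stopifnot(chance_p > 0, chance_p < 1, correct >= 0, correct <= n)
  binom.test(correct, n, p = chance_p, alternative = "greater")$p.value
}
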