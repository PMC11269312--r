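# Identity classification: eligibility, CV schemes, exact tests.

make_meta <- function(disc, pain) {
  tibble::tibble(
    baby_id = c(rep("B01", disc), rep("B01", pain)),
    condition = c(rep("discomfort", disc), rep("pain", pain))
  )
}

test_that("eligibility thresholds follow the counting rules", {
  meta <- dplyr::bind_rows(
    tibble::tibble(baby_id = "A", condition = c(rep("discomfort", 6), rep("pain", 4))),
    tibble::tibble(baby_id = "B", condition = c(rep("discomfort", 5), rep("pain", 5))),
    tibble::tibble(baby_id = "C", condition = c(rep("discomfort", 7), rep("pain", 3)))
  )
  # A: 6 discomfort + 4 pain -> eligible everywhere
  for (s in c("within-discomfort", "mixed", "cross-condition", "within-pain")) {
    expect_true("A" %in% select_eligible(meta, scheme = s))
  }
  # B: 5 discomfort -> cross-condition yes, LOO-within-discomfort no
  expect_true("B" %in% select_eligible(meta, scheme = "cross-condition"))
  expect_false("B" %in% select_eligible(meta, scheme = "within-discomfort"))
  # C: only 3 pain -> ineligible everywhere
  for (s in c("within-discomfort", "mixed", "cross-condition", "within-pain")) {
    expect_false("C" %in% select_eligible(meta, scheme = s))
  }
  expect_error(select_eligible(meta[meta$baby_id == "C", ],
                               scheme = "within-pain"), "relaxing")
})

# synthetic feature tables let classification behaviour be tested without audio
synthetic_paf_table <- function(n_babies = 6, n_disc = 6, n_pain = 4,
                                sep = 3, seed = 1) {
  set.seed(seed)
  feats <- paf_feature_names()
  rows <- lapply(seq_len(n_babies), function(b) {
    centre <- rnorm(length(feats), 0, sep)
    n <- n_disc + n_pain
    m <- matrix(rnorm(n * length(feats)), n, length(feats),
                dimnames = list(NULL, feats))
    m <- sweep(m, 2, centre, "+")
    dplyr::bind_cols(
      tibble::tibble(baby_id = sprintf("B%02d", b), sex = "F",
                     condition = c(rep("discomfort", n_disc), rep("pain", n_pain)),
                     sequence_id = sprintf("B%02d_%02d", b, seq_len(n))),
      tibble::as_tibble(m))
  })
  dplyr::bind_rows(rows)
}

test_that("well-separated babies are classified perfectly; posteriors are proper", {
  tab <- synthetic_paf_table(n_babies = 4, sep = 25, seed = 2)
  rep <- classify_identity(tab, model = "lda", space = "paf22",
                           scheme = "within-discomfort")
  expect_equal(rep$correct_count, rep$total_count)
  expect_gt(rep$mean_diag_posterior, 0.95)
  expect_equal(rep$chance, 1 / 4)
  expect_true(all(abs(rowSums(rep$confusion) - 1) < 1e-6))
  expect_true(rep$mean_diag_posterior >= 0 && rep$mean_diag_posterior <= 1)
  td <- tidy(rep)
  expect_equal(nrow(td), 16)
  g <- glance(rep)
  expect_equal(g$correct, rep$correct_count)
})

test_that("shuffled features classify at chance across seeds", {
  accs <- vapply(1:10, function(s) {
    tab <- synthetic_paf_table(n_babies = 5, sep = 4, seed = s)
    tab[paf_feature_names()] <- tab[sample(nrow(tab)), paf_feature_names()]
    rep <- classify_identity(tab, model = "lda", space = "paf22",
                             scheme = "within-discomfort")
    rep$correct_count / rep$total_count
  }, numeric(1))
  # binomial noise around chance 0.2 with 30 trials per run
  expect_lt(abs(mean(accs) - 0.2), 0.08)
})

test_that("all three models and all four schemes run and agree on strong signal", {
  tab <- synthetic_paf_table(n_babies = 4, sep = 25, seed = 3)
  for (m in c("lda", "qda", "rf")) {
    for (s in c("within-discomfort", "mixed", "cross-condition", "within-pain")) {
      rep <- classify_identity(tab, model = m, space = "paf10", scheme = s,
                               seed = 7)
      expect_gt(rep$correct_count / rep$total_count, 0.8)
    }
  }
})

test_that("the MPS-PC20 leave-one-out PCA matches a direct refit", {
  set.seed(21)
  n <- 30; p <- 100; k <- 5
  X <- matrix(rnorm(n * p), n, p)
  K <- tcrossprod(X)
  sc <- cryid:::loo_pca_scores(K, 2:n, 1, k)
  # direct: PCA on rows 2..n, project row 1
  pc <- prcomp(X[2:n, ], center = TRUE, rank. = k)
  direct_train <- unname(pc$x[, 1:k])
  direct_test <- unname(predict(pc, X[1, , drop = FALSE])[, 1:k, drop = FALSE])
  # scores agree up to per-component sign
  for (j in seq_len(k)) {
    s <- sign(sum(sc$train[, j] * direct_train[, j]))
    expect_equal(s * sc$train[, j], direct_train[, j], tolerance = 1e-8)
    expect_equal(s * sc$test[1, j], direct_test[1, j], tolerance = 1e-6)
  }
})

test_that("identity accuracy rises with identity dispersion (feature-level)", {
  acc_at <- function(sep) {
    mean(vapply(1:3, function(s) {
      tab <- synthetic_paf_table(n_babies = 6, sep = sep, seed = s + 40)
      rep <- classify_identity(tab, model = "lda", space = "paf22",
                               scheme = "within-discomfort")
      rep$correct_count / rep$total_count
    }, numeric(1)))
  }
  a <- acc_at(0.5); b <- acc_at(1.5); c <- acc_at(4)
  expect_lt(a, b)
  expect_lt(b, c)
})

test_that("cross-condition requires every test baby in training", {
  tab <- synthetic_paf_table(n_babies = 3, sep = 5, seed = 9)
  # remove one baby's discomfort rows but keep it above thresholds is not
  # possible via eligibility; check the guard directly on a crafted table
  tab2 <- tab[!(tab$baby_id == "B01" & tab$condition == "discomfort"), ]
  expect_error(select_eligible(tab2 %>% dplyr::filter(.data$baby_id == "B01"),
                               scheme = "cross-condition"), "relaxing")
})

test_that("fisher and binomial helpers reproduce closed-form cases", {
  expect_equal(fisher_compare(10, 20, 10, 20), 1)
  p_equal <- fisher_compare(50, 100, 50, 100)
  expect_equal(p_equal, 1)
  # a hand-checkable case: hypergeometric 2x2
  expect_equal(fisher_compare(3, 3, 0, 3),
               fisher.test(matrix(c(3, 0, 0, 3), 2))$p.value)
  # binomial: at the expectation; and an extreme
  expect_equal(binomial_vs_chance(4, 72, 1 / 18),
               sum(dbinom(4:72, 72, 1 / 18)), tolerance = 1e-12)
  expect_lt(abs(binomial_vs_chance(4, 72, 1 / 18) - 0.56), 0.03)
  expect_equal(binomial_vs_chance(72, 72, 1 / 18), (1 / 18)^72, tolerance = 1e-20)
  expect_error(binomial_vs_chance(5, 4, 0.5))
  expect_error(fisher_compare(5, 4, 1, 2))
})

test_that("binomial test against chance is calibrated under label shuffling", {
  set.seed(33)
  rejections <- vapply(1:100, function(i) {
    n <- 60; k <- 6
    correct <- rbinom(1, n, 1 / k)   # chance-level classification counts
    binomial_vs_chance(correct, n, 1 / k) < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.03)
})

test_that("argmax ties break toward the lowest baby label", {
  post <- matrix(c(0.5, 0.5, 0, 0.2, 0.2, 0.6), 2, 3, byrow = TRUE,
                 dimnames = list(NULL, c("A", "B", "C")))
  picked <- colnames(post)[apply(post, 1, which.max)]
  expect_equal(picked, c("A", "C"))
})
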