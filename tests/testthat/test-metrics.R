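test_that("Cohen's kappa matches hand-computed and limiting cases", {
  # 2x2 example embedded in the 5x5 frame: p_o = 0.7, p_e = 0.5
  cm <- matrix(0L, 5, 5)
  cm[1:2, 1:2] <- matrix(c(20L, 10L, 5L, 15L), 2, 2)
  expect_equal(cohens_kappa(cm), 0.4)

  # complete agreement
  expect_equal(cohens_kappa(diag(5) * 7), 1)

  # independent marginals (outer product of counts) -> chance only
  r <- c(10, 40, 20, 15, 15)
  cc <- c(30, 25, 20, 15, 10)
  expect_lt(abs(cohens_kappa(outer(r, cc))), 1e-12)

  # degenerate marginals: everything in one cell
  cm1 <- matrix(0, 5, 5); cm1[2, 2] <- 50
  expect_error(cohens_kappa(cm1), "p_e = 1")
})

test_that("weighted kappa agrees with a brute-force double-sum oracle", {
  withr::with_seed(101, {
    for (i in 1:300) {
      cm <- random_cm()
      for (scheme in c("paper-banded", "squared")) {
        w <- kappa_weights(scheme)
        expect_lt(abs(weighted_kappa(cm, w) - wkappa_oracle(cm, w)),
                  1e-12)
      }
    }
  })
})

test_that("weighted kappa with 0/1 weights reduces to Cohen's kappa", {
  w01 <- 1 - diag(5)
  withr::with_seed(202, {
    for (i in 1:1000) {
      cm <- random_cm()
      expect_lt(abs(weighted_kappa(cm, w01) - cohens_kappa(cm)), 1e-12)
    }
  })
})

test_that("weighted kappa scheme properties and validation", {
  # conventional squared weights: perfect agreement scores exactly 1
  expect_equal(weighted_kappa(diag(5) * 9, kappa_weights("squared")), 1)
  # the banded default weights are 1,4,9,16,25 by ordinal distance
  w <- kappa_weights("paper-banded")
  expect_equal(w[1, ], c(1, 4, 9, 16, 25))
  expect_identical(w, t(w))
  # asymmetric weights rejected
  bad <- kappa_weights(); bad[1, 2] <- 99
  expect_error(weighted_kappa(random_cm(), bad), "symmetric")
})

test_that("kappa statistics are invariant under matched permutations", {
  withr::with_seed(303, {
    for (i in 1:50) {
      cm <- random_cm()
      p <- sample(5)
      w <- kappa_weights("paper-banded")
      expect_lt(abs(cohens_kappa(cm[p, p]) - cohens_kappa(cm)), 1e-12)
      expect_lt(abs(weighted_kappa(cm[p, p], w[p, p]) -
                      weighted_kappa(cm, w)), 1e-12)
    }
  })
})

test_that("misclassification rate covers both readings", {
  expect_equal(misclassification_rate(diag(5) * 4, "overall"), 0)
  expect_equal(misclassification_rate(diag(5) * 4, "mean-per-class"), 0)
  cm <- matrix(0L, 5, 5)
  cm[1:2, 1:2] <- matrix(c(20L, 10L, 5L, 15L), 2, 2)
  expect_equal(misclassification_rate(cm, "overall"), 30)
  expect_warning(
    mpc <- misclassification_rate(cm, "mean-per-class"), "skipped")
  expect_equal(mpc, 30)
  expect_equal(misclassification_rate(matrix(3, 5, 5), "overall"), 80)
})

test_that("one-vs-rest AUC equals the exhaustive pair-count oracle", {
  withr::with_seed(404, {
    for (i in 1:200) {
      n <- sample(20:200, 1)
      obs <- as_density_state(sample(0:4, n, replace = TRUE))
      sc <- matrix(runif(n * 5), n, 5)
      sc <- sc / rowSums(sc)
      r <- roc_ovr(sc, obs)
      for (k in 1:5) {
        pos <- obs == state_levels()[k]
        if (r$auc$scorable[k]) {
          expect_lt(abs(r$auc$auc[k] - auc_oracle(sc[, k], pos)), 1e-12)
        } else {
          expect_true(sum(pos) == 0 || sum(!pos) == 0)
        }
      }
    }
  })
})

test_that("ROC curves are anchored and their trapezoidal area is the AUC", {
  withr::with_seed(505, {
    for (i in 1:50) {
      n <- 80
      obs <- as_density_state(sample(0:4, n, replace = TRUE,
                                     prob = c(.3, .3, .2, .1, .1)))
      sc <- matrix(runif(n * 5), n, 5); sc <- sc / rowSums(sc)
      r <- roc_ovr(sc, obs)
      for (st in unique(r$curves$state)) {
        cu <- r$curves[r$curves$state == st, ]
        expect_equal(c(cu$fpr[1], cu$tpr[1]), c(0, 0))
        expect_equal(c(cu$fpr[nrow(cu)], cu$tpr[nrow(cu)]), c(1, 1))
        trap <- sum(diff(cu$fpr) * (head(cu$tpr, -1) + tail(cu$tpr, -1)) / 2)
        expect_equal(trap, r$auc$auc[r$auc$state == st],
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("perfect separation gives AUC 1 and one-class input is flagged", {
  obs <- as_density_state(rep(0:4, each = 4))
  sc <- matrix(0.025, 20, 5)
  sc[cbind(seq_len(20), rep(1:5, each = 4))] <- 0.9
  r <- roc_ovr(sc, obs)
  expect_true(all(r$auc$auc == 1))
  expect_equal(r$macro_auc, 1)

  one <- roc_ovr(matrix(0.2, 6, 5), as_density_state(rep(1L, 6)))
  expect_true(all(!one$auc$scorable))
  expect_true(is.nan(one$macro_auc) || is.na(one$macro_auc))
})

test_that("label-independent scores give chance-level macro AUC and kappa", {
  withr::with_seed(606, {
    n <- 2000
    obs <- as_density_state(sample(0:4, n, replace = TRUE,
                                   prob = c(.145, .531, .173, .082, .069)))
    sc <- matrix(runif(n * 5), n, 5); sc <- sc / rowSums(sc)
    r <- roc_ovr(sc, obs)
    expect_lt(abs(r$macro_auc - 0.5), 0.04)
    pred <- as_density_state(max.col(sc) - 1L)
    expect_lt(abs(cohens_kappa(confusion_matrix(obs, pred))), 0.05)
  })
})

test_that("DeLong comparison behaves at its fixed points", {
  withr::with_seed(707, {
    lab <- rep(c(TRUE, FALSE), each = 40)
    s <- runif(80)
    same <- compare_roc(s, lab, s, lab, paired = TRUE)
    expect_equal(same$auc_diff, 0)
    expect_equal(same$p_value, 1)

    # AUC 1 vs chance, n = 200 per side
    lab2 <- rep(c(TRUE, FALSE), each = 100)
    perfect <- c(runif(100, 0.6, 1), runif(100, 0, 0.4))
    noise <- runif(200)
    out <- compare_roc(perfect, lab2, noise, lab2, paired = FALSE)
    expect_equal(out$auc_a, 1)
    expect_lt(out$p_value, 0.001)
  })
})

test_that("unpaired DeLong variance matches structural components", {
  withr::with_seed(808, {
    lab <- c(rep(TRUE, 7), rep(FALSE, 9))
    sa <- runif(16); sb <- runif(16)
    out <- compare_roc(sa, lab, sb, lab, paired = FALSE)
    # brute-force variance: var of per-positive and per-negative
    # placement means, each over its own sample size
    comp <- function(s) {
      x <- s[lab]; y <- s[!lab]
      psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
      var(rowMeans(psi)) / length(x) + var(colMeans(psi)) / length(y)
    }
    expect_lt(abs(out$var_diff - (comp(sa) + comp(sb))), 1e-12)
  })
})

test_that("paired DeLong agrees with the reference implementation", {
  withr::with_seed(909, {
    lab <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(.4, .6))
    sa <- runif(60) + lab * 0.5
    sb <- runif(60) + lab * 0.2
    mine <- compare_roc(sa, lab, sb, lab, paired = TRUE)
    ref <- pROC::roc.test(
      pROC::roc(lab, sa, quiet = TRUE, direction = "<"),
      pROC::roc(lab, sb, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE)
    expect_equal(unname(mine$z), unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  })
})

test_that("score_predictions returns a mutually consistent metric set", {
  withr::with_seed(111, {
    n <- 200
    obs <- as_density_state(sample(0:4, n, TRUE))
    sc <- matrix(runif(n * 5), n, 5); sc <- sc / rowSums(sc)
    dat <- tibble::as_tibble(as.data.frame(sc))
    names(dat) <- state_levels()
    dat$observed <- obs
    dat$predicted <- as_density_state(max.col(sc) - 1L)
    m <- score_predictions(dat)
    expect_equal(sum(m$confusion), n)
    # trace ties the overall misclassification to kappa's p_o
    po <- sum(diag(m$confusion)) / n
    expect_equal(m$misclassification_overall, 100 * (1 - po))
  })
})
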