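test_that("dice handles agreement, disjoint masks and the empty convention", {
  a <- array(0, dim = c(4, 4, 4)); a[1:2, 1, 1] <- 1
  expect_equal(dice(a, a), 1)
  b <- array(0, dim = c(4, 4, 4)); b[3:4, 4, 4] <- 1
  expect_equal(dice(a, b), 0)
  a4 <- array(0, dim = c(4, 4, 4)); a4[1:4, 1, 1] <- 1
  b4 <- array(0, dim = c(4, 4, 4)); b4[3:4, 1, 1] <- 1; b4[1:2, 2, 2] <- 1
  expect_equal(dice(a4, b4), 0.5)
  expect_equal(dice(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, array(0, c(3, 3, 3))), "shape")
})

test_that("confusion metrics reproduce the arithmetic-mean F1 convention", {
  # worked examples with printed precision/sensitivity pairs
  expect_equal(f1_paper(0.94, 1.00), 0.97)
  expect_equal(f1_paper(1.00, 0.97), 0.985)
  expect_equal(round(f1_paper(1.00, 0.97), 2), 0.98)

  out <- tibble::tibble(truth = rep(c(TRUE, FALSE), c(10, 10)),
                        score = rep(c(0.9, 0.1), c(10, 10)))
  m <- confusion_metrics(out, 0.61)
  expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1); expect_equal(m$f1_paper, 1)
  expect_equal(m$tp + m$fp + m$tn + m$fn, 20)

  mixed <- tibble::tibble(truth = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                          score = c(0.9, 0.7, 0.2, 0.8, 0.3))
  mm <- confusion_metrics(mixed, 0.61)
  expect_equal(mm$tp, 2); expect_equal(mm$fn, 1)
  expect_equal(mm$fp, 1); expect_equal(mm$tn, 1)
  expect_equal(mm$precision, 2 / 3)
  expect_equal(mm$f1_paper, (2 / 3 + 2 / 3) / 2)
  expect_equal(mm$f1_harmonic, 2 * (2 / 3) * (2 / 3) / (4 / 3))

  onecls <- tibble::tibble(truth = c(TRUE, TRUE), score = c(0.9, 0.2))
  oc <- confusion_metrics(onecls, 0.61)
  expect_true(is.na(oc$specificity))
  expect_false(is.na(oc$sensitivity))
})

test_that("rank AUROC matches pair enumeration, permutation null and pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # enumerate 4 pairs with one tie counting one half: 3.5/4
  expect_equal(roc_auc(c(0.9, 0.5, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               0.875)
  set.seed(21)
  sc <- runif(500); tr <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  expect_lt(abs(roc_auc(sc, tr) - 0.5), 0.05)
  # independent oracle
  expect_equal(roc_auc(sc, tr),
               as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("threshold-sweep curve integrates to the rank AUROC", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    sc <- round(runif(n), sample(1:3, 1))     # force ties
    tr <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    cv <- roc_curve(sc, tr)
    expect_equal(auc_from_curve(cv), roc_auc(sc, tr), tolerance = 1e-9)
    expect_equal(cv$tpr[1], 0); expect_equal(cv$fpr[1], 0)
    expect_equal(cv$tpr[nrow(cv)], 1); expect_equal(cv$fpr[nrow(cv)], 1)
  }
  # complement symmetry for tie-free scores
  sc <- sample(seq(0.01, 0.99, by = 0.01), 30)
  tr <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  if (any(tr) && any(!tr))
    expect_equal(roc_auc(sc, tr) + roc_auc(-sc, tr), 1)
})

test_that("localization criterion requires a single shared voxel", {
  gt <- array(0, dim = c(5, 5, 5)); gt[3, 3, 3] <- 1
  pr <- array(0, dim = c(5, 5, 5)); pr[3, 3, 3] <- 1; pr[1, 1, 1] <- 1
  expect_true(localization_hit(pr, gt))
  pr2 <- array(0, dim = c(5, 5, 5)); pr2[4, 3, 3] <- 1   # adjacent, disjoint
  expect_false(localization_hit(pr2, gt))
  expect_false(localization_hit(array(0, c(5, 5, 5)), gt))
  expect_error(localization_hit(pr, array(0, c(4, 4, 4))), "shapes")
})

test_that("cohort evaluation reports overall and small-tumor subgroup rows", {
  man <- tibble::tibble(case_id = sprintf("c%02d", 1:20),
                        patient_id = sprintf("p%02d", 1:20),
                        has_tumor = rep(c(TRUE, FALSE), each = 10),
                        diameter_mm = c(c(12, 15, 18, 14, 25, 30, 28, 26, 22, 35),
                                        rep(NA, 10)))
  out <- tibble::tibble(case_id = man$case_id, truth = man$has_tumor,
                        score = ifelse(man$has_tumor, 0.9, 0.1),
                        tumor_dsc = ifelse(man$has_tumor, 0.8, NA),
                        localization_hit = ifelse(man$has_tumor, TRUE, NA))
  rep <- evaluate_cohort(out, man, threshold = 0.61)
  expect_equal(rep$metrics$sensitivity, c(1, 1))
  expect_equal(rep$metrics$subgroup, c("all", "tumor_lt_20mm"))
  expect_equal(rep$metrics$n[2], 4 + 10)   # 4 small tumors vs all controls
  expect_equal(rep$auroc, 1)
  expect_equal(rep$dice_mean, 0.8)
  expect_equal(rep$localization_rate, 1)
  expect_error(evaluate_cohort(out[0, ], man), "empty")
})
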