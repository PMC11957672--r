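test_that("confusion counts partition the scored residues", {
  lab <- c(1, 0, 1, 0)
  expect_equal(confusion(lab, lab), list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  expect_equal(confusion(1 - lab, lab), list(TP = 0L, FP = 2L, TN = 0L, FN = 2L))
  expect_equal(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_error(confusion(c(1, 0), c(1, 0, 0)), "length")
})

test_that("metrics reproduce hand-computed values and degenerate guards", {
  perfect <- metrics(list(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)

  m <- metrics(list(TP = 3, FP = 1, FN = 2, TN = 4))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$mcc, (3 * 4 - 2 * 1) / sqrt(4 * 5 * 5 * 6))

  none <- metrics(list(TP = 0, FP = 0, FN = 0, TN = 5))
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_equal(none$f1, 0)
  expect_equal(none$mcc, 0)
})

test_that("metrics agree exactly with direct formula evaluation on small tables", {
  for (tp in 0:5) for (fp in 0:5) for (tn in 0:5) for (fn in 0:5) {
    expect_identical(metrics(list(TP = tp, FP = fp, TN = tn, FN = fn)),
                     direct_metrics(tp, fp, tn, fn))
  }
})

test_that("per-protein confidence intervals use the normal approximation", {
  ci <- per_protein_ci(c(0.5, 0.5, 0.5))
  expect_equal(ci$mean, 0.5)
  expect_equal(ci$ci_halfwidth, 0)

  ci <- per_protein_ci(c(0.4, 0.5, 0.6))
  expect_equal(ci$mean, 0.5)
  expect_equal(ci$ci_halfwidth, 1.96 * 0.1 / sqrt(3))

  single <- per_protein_ci(c(0.7))
  expect_equal(single$ci_halfwidth, 0)
  expect_true(single$single)

  withna <- per_protein_ci(c(0.4, NA, 0.6))
  expect_equal(withna$n, 2L)
  expect_equal(withna$n_undefined, 1L)
})

test_that("micro counts equal confusion on the concatenated residues", {
  set.seed(12)
  probs <- lapply(1:6, function(i) matrix(runif(30), 10, 3))
  labels <- lapply(1:6, function(i) matrix(rbinom(30, 1, 0.2), 10, 3))
  ms <- evaluate_predictions(probs, labels)
  allcalls <- do.call(rbind, lapply(probs, call_binding))
  alllabs <- do.call(rbind, labels)
  for (c in 1:3) {
    expect_equal(ms[[c]]$micro_counts, confusion(allcalls[, c], alllabs[, c]))
  }
  expect_equal(ms$binary$micro_counts,
               confusion(to_binary(allcalls), as.integer(rowSums(alllabs) > 0)))
})

test_that("proteins without observed or predicted positives are excluded from CIs", {
  # protein 1 has signal for metal; protein 2 is silent for metal entirely
  probs <- list(matrix(c(0.9, 0.1, 0.1, 0.1, 0.1, 0.1), 2, 3),
                matrix(0.1, 2, 3))
  labels <- list(matrix(c(1L, 0L, 0L, 0L, 0L, 0L), 2, 3),
                 matrix(0L, 2, 3))
  ms <- evaluate_predictions(probs, labels)
  expect_equal(ms$metal$per_protein$f1$n, 1L)
  expect_equal(ms$metal$per_protein$f1$n_undefined, 1L)
  expect_equal(ms$metal$per_protein$f1$mean, 1)
  # accuracy is always defined
  expect_equal(ms$metal$per_protein$accuracy$n, 2L)
  # zero-fill mode keeps every protein
  ms0 <- evaluate_predictions(probs, labels, exclude_undefined = FALSE)
  expect_equal(ms0$metal$per_protein$f1$n, 2L)
  expect_equal(ms0$metal$per_protein$f1$mean, 0.5)
})

test_that("threshold sweeps recover confusion at 0.5 and sane areas", {
  set.seed(23)
  # perfectly separated scores
  labels <- matrix(c(rep(1L, 20), rep(0L, 80)), ncol = 1)
  labels3 <- cbind(labels, 0L, 0L)
  probs3 <- cbind(ifelse(labels == 1, runif(100, 0.8, 0.99), runif(100, 0.01, 0.2)),
                  0.01, 0.01)
  sw <- pr_roc_sweep(probs3, labels3)
  expect_equal(attr(sw, "auroc"), 1, tolerance = 1e-9)

  # the 0.5 row equals a direct confusion computation
  row <- sw[abs(sw$threshold - 0.5) < 1e-9, ]
  cc <- confusion(as.integer(reliability(probs3) >= 0.5), as.vector(labels))
  expect_equal(row$TP, cc$TP)
  expect_equal(row$FP, cc$FP)

  # random scores vs random labels: area near 1/2
  n <- 20000
  probsr <- cbind(runif(n), 0.01, 0.01)
  labsr <- cbind(rbinom(n, 1, 0.1), 0L, 0L)
  swr <- pr_roc_sweep(probsr, labsr)
  expect_equal(attr(swr, "auroc"), 0.5, tolerance = 0.03)

  # cross-check the area against an independent ROC implementation
  ref <- suppressMessages(pROC::auc(as.vector(labels), reliability(probs3),
                                    quiet = TRUE))
  expect_equal(attr(sw, "auroc"), as.numeric(ref), tolerance = 1e-6)
})

test_that("reliability table reports coverage and precision above cutoffs", {
  probs <- cbind(c(0.95, 0.85, 0.6, 0.3, 0.9), 0.01, 0.01)
  labels <- cbind(c(1L, 1L, 1L, 0L, 0L), 0L, 0L)
  rt <- reliability_table(probs, labels, thresholds = c(0.5, 0.8))
  # above 0.8: scores 0.95, 0.85, 0.9 -> 2 of 3 observed binding covered
  r8 <- rt[rt$threshold == 0.8, ]
  expect_equal(r8$n_above, 3)
  expect_equal(r8$coverage, 2 / 3)
  expect_equal(r8$precision, 2 / 3)
  r5 <- rt[rt$threshold == 0.5, ]
  expect_equal(r5$coverage, 1)
  expect_equal(r5$precision, 3 / 4)
})

test_that("pLDDT correlation handles the exact and degenerate cases", {
  x <- seq(50, 100, length.out = 20)
  probs_up <- cbind((x - 50) / 50 * 0.98 + 0.01, 0.001, 0.001)
  expect_equal(plddt_correlation(x, probs_up), 1)
  probs_dn <- cbind(rev((x - 50) / 50 * 0.98 + 0.01), 0.001, 0.001)
  expect_equal(plddt_correlation(x, probs_dn), -1)
  expect_warning(r <- plddt_correlation(rep(70, 20), probs_up), "zero variance")
  expect_true(is.na(r))
})

test_that("permutation null interval excludes genuinely informative calls", {
  set.seed(2)
  labels <- rbinom(400, 1, 0.1)
  pi <- permutation_f1_interval(labels, labels, n_perm = 300, seed = 4)
  observed <- metrics(confusion(labels, labels))$f1   # perfect calls, F1 = 1
  expect_gt(observed, pi$upper)   # informative calls fall outside the null
  expect_gte(pi$lower, 0)
})
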