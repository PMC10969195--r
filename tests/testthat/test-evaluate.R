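test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2,
                                   dimnames = dimnames(cm)))
  perfect <- confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
  expect_true(all(unclass(perfect)[upper.tri(perfect) | lower.tri(perfect)] == 0))
  empty <- confusion_matrix(integer(), integer(), 3)
  expect_true(all(unclass(empty) == 0))
  expect_error(confusion_matrix(c(0, 1), c(0), 2), "length")
  expect_error(confusion_matrix(c(0, 2), c(0, 1), 2), "lie in")
})

test_that("metrics match the one-vs-rest definitions on a hand-worked matrix", {
  # binary matrix with TP = 2, FP = 1, FN = 1, TN = 6 for the positive class
  cm <- confusion_matrix(true_labels = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
                         predicted_labels = c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0), 2)
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision[2], 2 / 3)
  expect_equal(m$recall[2], 2 / 3)
  expect_equal(m$f1[2], 2 / 3)
  # accuracy equals the directly computed agreement fraction
  expect_equal(m$accuracy, mean(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0) ==
                                c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)))
  # macro = unweighted class mean
  expect_equal(m$macro_f1, mean(m$f1), tolerance = 1e-12)

  diag_cm <- confusion_matrix(c(0, 1, 2, 2), c(0, 1, 2, 2), 3)
  md <- metrics_from_confusion(diag_cm)
  expect_equal(md$accuracy, 1)
  expect_equal(md$macro_f1, 1)

  # a class never predicted gets P = F1 = 0, not NaN
  cm0 <- confusion_matrix(c(0, 1), c(0, 0), 2)
  m0 <- metrics_from_confusion(cm0)
  expect_identical(m0$precision[2], 0)
  expect_identical(m0$f1[2], 0)
  expect_error(metrics_from_confusion(confusion_matrix(integer(), integer(), 2)),
               "empty")
})

test_that("metrics accuracy equals direct agreement on random label vectors", {
  set.seed(9)
  for (i in 1:5) {
    tr <- sample(0:2, 40, replace = TRUE)
    pr <- sample(0:2, 40, replace = TRUE)
    m <- metrics_from_confusion(confusion_matrix(tr, pr, 3))
    expect_equal(m$accuracy, mean(tr == pr), tolerance = 1e-12)
  }
})

test_that("model comparison reproduces the pooled-variance t formula", {
  a <- c(0.91, 0.94, 0.89, 0.96, 0.92)
  b <- c(0.85, 0.88, 0.83, 0.90, 0.86)
  got <- compare_models(a, b)
  # textbook pooled-variance Student t, computed from scratch
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p_hand <- 2 * pt(-abs(t_hand), na + nb - 2)
  expect_equal(got$t_value, t_hand, tolerance = 1e-10)
  expect_equal(got$p_value, p_hand, tolerance = 1e-10)
  expect_equal(got$df, na + nb - 2)
  # paired variant against its defining formula
  b2 <- c(0.86, 0.88, 0.82, 0.91, 0.85)
  gp <- compare_models(a, b2, paired = TRUE)
  d <- a - b2
  t_p <- mean(d) / sqrt(var(d) / length(d))
  expect_equal(gp$t_value, t_p, tolerance = 1e-10)
  expect_equal(gp$df, length(d) - 1)
  # paired with a constant nonzero difference is degenerate too
  expect_error(compare_models(a, a - 0.06, paired = TRUE), "degenerate")
  # identical samples: t = 0, p = 1
  same <- compare_models(a, a)
  expect_equal(same$t_value, 0)
  expect_equal(same$p_value, 1)
  # zero variance in both samples with different means: degenerate
  expect_error(compare_models(c(0.9, 0.9), c(0.8, 0.8)), "degenerate")
})

test_that("ablation reports list all pairwise comparisons and round-trip", {
  mk_cv <- function(variant, accs) {
    cm <- confusion_matrix(c(0, 1), c(0, 1), 2)
    structure(list(fold_results = list(), accuracies = accs,
                   mean_accuracy = mean(accs),
                   variance = mean((accs - mean(accs))^2),
                   confusion = cm, metrics = metrics_from_confusion(cm),
                   variant = variant, task = "arousal", k = length(accs),
                   folds = NULL), class = "sttcnn_cv")
  }
  reports <- list(mk_cv("st-tcnn", c(0.9, 0.95, 0.92)),
                  mk_cv("st-t", c(0.88, 0.9, 0.91)),
                  mk_cv("s-t", c(0.7, 0.75, 0.72)),
                  mk_cv("t-t", c(0.8, 0.78, 0.83)))
  rep <- ablation_report(reports)
  expect_equal(nrow(rep$summary), 4)
  expect_equal(nrow(rep$comparisons), choose(4, 2))
  expect_equal(rep$summary$mean_accuracy,
               vapply(reports, function(r) r$mean_accuracy, 0))
  # single variant: no comparison table
  expect_null(ablation_report(reports[1])$comparisons)
  # mismatched tasks refuse to aggregate
  bad <- reports; bad[[2]]$task <- "valence"
  expect_error(ablation_report(bad), "mix tasks")
  # written tables parse back to the same values
  stem <- file.path(withr::local_tempdir(), "abl")
  write_ablation_report(rep, stem)
  back <- read.delim(paste0(stem, "_summary.tsv"))
  expect_equal(back$mean_accuracy, rep$summary$mean_accuracy, tolerance = 1e-12)
  expect_identical(back$variant, rep$summary$variant)
  cmp <- read.delim(paste0(stem, "_comparisons.tsv"))
  expect_equal(cmp$t_value, rep$comparisons$t_value, tolerance = 1e-12)
})
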