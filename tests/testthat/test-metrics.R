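fixture <- function(name)
  read_confusion_tsv(system.file("extdata", name, package = "somnograph"))

test_that("confusion matrix counts and conserves totals", {
  cm <- confusion(stage_levels(), stage_levels())
  expect_equal(unname(diag(cm)), rep(1L, 5))
  expect_equal(sum(cm), 5)

  set.seed(60)
  yt <- sample(stage_levels(), 200, replace = TRUE)
  yp <- sample(stage_levels(), 200, replace = TRUE)
  cm2 <- confusion(yt, yp)
  expect_equal(sum(cm2), 200)
  expect_equal(unname(rowSums(cm2)),
               as.vector(table(factor(yt, stage_levels()))))
  expect_error(confusion(c("W", "X9"), c("W", "W")), "outside")
  expect_error(confusion("W", c("W", "N1")), "same length")
})

test_that("bundled reference confusion matrices have the published margins", {
  cm <- fixture("confusion_sleepedf.tsv")
  expect_equal(unname(rowSums(cm)), c(7927, 2804, 17799, 5703, 7717))
  expect_equal(sum(cm), 41950)
  cm2 <- fixture("confusion_isruc.tsv")
  expect_equal(sum(cm2), 8889)
  expect_equal(unname(rowSums(cm2)), c(1817, 1248, 2678, 2035, 1111))
})

test_that("metric suite reproduces the published sleep-EDF evaluation digits", {
  ev <- evaluate_confusion(fixture("confusion_sleepedf.tsv"))
  expect_equal(round(100 * ev$accuracy, 1), 91.0)
  expect_equal(round(100 * ev$macro_precision, 1), 87.4)
  expect_equal(round(100 * ev$macro_recall, 1), 90.9)
  expect_equal(round(100 * ev$macro_F, 1), 89.0)
  expect_equal(round(ev$kappa, 2), 0.88)
  expect_equal(round(100 * ev$per_class$f1, 1),
               c(92.1, 79.7, 93.2, 88.2, 91.6))
  # the harmonic macro-P/macro-R variant differs in the first decimal
  expect_equal(round(100 * ev$macro_F_harmonic, 1), 89.2)
})

test_that("metric suite reproduces the published ISRUC-III evaluation digits", {
  ev <- evaluate_confusion(fixture("confusion_isruc.tsv"))
  expect_equal(round(100 * ev$accuracy, 1), 87.4)
  expect_equal(round(100 * ev$macro_precision, 1), 86.6)
  expect_equal(round(100 * ev$macro_recall, 1), 86.5)
  expect_equal(round(100 * ev$macro_F, 1), 86.5)
  expect_equal(round(ev$kappa, 2), 0.84)
  expect_equal(round(100 * ev$per_class$f1, 1),
               c(92.8, 71.7, 85.8, 92.6, 89.8))
})

test_that("kappa behaves at the analytic anchors", {
  perfect <- diag(c(10, 20, 30, 40, 50))
  dimnames(perfect) <- list(stage_levels(), stage_levels())
  ev <- evaluate_confusion(perfect)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$kappa, 1)
  expect_equal(ev$macro_F, 1)

  # constant predictor on uniform truth: accuracy 0.2, kappa 0
  cm <- matrix(0, 5, 5, dimnames = list(stage_levels(), stage_levels()))
  cm[, 1] <- 20
  ev2 <- evaluate_confusion(cm)
  expect_equal(ev2$accuracy, 0.2)
  expect_equal(ev2$kappa, 0)
  expect_true("N1" %in% ev2$degenerate)

  # kappa invariant under simultaneous row+column permutation
  set.seed(61)
  cm3 <- matrix(rpois(25, 30), 5, 5,
                dimnames = list(stage_levels(), stage_levels()))
  perm <- sample(5)
  expect_equal(evaluate_confusion(cm3[perm, perm])$kappa,
               evaluate_confusion(cm3)$kappa, tolerance = 1e-12)
})

test_that("macro metrics respond to prevalence rescaling only when imbalanced", {
  # balanced matrix: doubling every count leaves all metrics unchanged
  set.seed(62)
  blk <- matrix(c(8, 1, 1, 8), 2)
  cm <- kronecker(diag(c(1, 1)), blk) + 1
  cmq <- rbind(cbind(cm, 2), 2)
  dimnames(cmq) <- list(stage_levels(), stage_levels())
  expect_equal(evaluate_confusion(2 * cmq)$macro_F,
               evaluate_confusion(cmq)$macro_F, tolerance = 1e-12)
  # imbalanced rescaling of one class's row changes the macro metrics
  cm2 <- cmq; cm2[2, ] <- cm2[2, ] * 5
  expect_false(isTRUE(all.equal(evaluate_confusion(cm2)$macro_F,
                                evaluate_confusion(cmq)$macro_F)))
})

test_that("confusion TSV writer round-trips with labels", {
  cm <- fixture("confusion_isruc.tsv")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_confusion_tsv(cm, path)
  expect_equal(unclass(read_confusion_tsv(path)), unclass(cm))
})
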