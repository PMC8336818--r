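# Evaluation machinery: span matching, metrics, kappa, reconstruction,
# likelihood ratios, post-test probabilities.

sp <- function(starts, ends) {
  n <- length(starts)
  data.frame(char_start = starts, char_end = ends,
             status = rep("relevant", n), temporality = rep("current", n),
             polarity = rep("positive", n), stringsAsFactors = FALSE)
}

test_that("span matching separates exact and overlap regimes", {
  g <- sp(10, 21)  # "cut herself"
  p <- sp(10, 21)
  for (mode in c("exact", "overlap")) {
    ms <- match_spans(g, p, mode)
    expect_identical(ms$tp, 1L)
    expect_identical(ms$fp + ms$fn, 0L)
  }
  # partial span: TP under overlap, FP+FN under exact
  g <- sp(0, 19)   # "self-harming impulse"
  p <- sp(0, 12)   # "self-harming"
  ex <- match_spans(g, p, "exact")
  expect_identical(c(ex$tp, ex$fp, ex$fn), c(0L, 1L, 1L))
  ov <- match_spans(g, p, "overlap")
  expect_identical(c(ov$tp, ov$fp, ov$fn), c(1L, 0L, 0L))
  # greedy longest-overlap tie-break
  g <- sp(0, 10)
  p <- sp(c(0, 4), c(4, 10))
  ov <- match_spans(g, p, "overlap")
  expect_identical(ov$pairs$pred, 2L)  # 6-char overlap beats 4
})

test_that("empty-empty span sets score 1 by convention", {
  ms <- match_spans(sp(integer(0), integer(0)), sp(integer(0), integer(0)))
  expect_identical(c(ms$precision, ms$recall, ms$f), c(1, 1, 1))
  # but no predictions against real gold is recall 0
  ms2 <- match_spans(sp(0, 5), sp(integer(0), integer(0)))
  expect_identical(ms2$recall, 0)
})

test_that("attribute metrics match brute-force oracles on random label sets", {
  set.seed(401)
  for (trial in 1:1000) {
    n <- sample(2:12, 1)
    classes <- letters[seq_len(sample(2:4, 1))]
    gold <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    m <- attribute_metrics(gold, pred)
    o <- oracle_prf(gold, pred)
    expect_equal(m$micro[["precision"]], o$micro[["p"]], tolerance = 1e-12)
    expect_equal(m$micro[["recall"]], o$micro[["r"]], tolerance = 1e-12)
    expect_equal(m$macro[["f"]], o$macro[["f"]], tolerance = 1e-12)
    expect_equal(m$kappa, oracle_kappa(gold, pred), tolerance = 1e-12)
    # single-label identity: micro P = R = F = accuracy
    expect_equal(m$micro[["precision"]], mean(gold == pred), tolerance = 1e-12)
    expect_equal(m$micro[["f"]], m$micro[["recall"]], tolerance = 1e-12)
  }
})

test_that("kappa is bounded, 1 only at perfect multi-class agreement, ~0 at chance", {
  expect_identical(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  expect_identical(cohen_kappa(rep("a", 5), rep("a", 5)), 1)
  expect_error(cohen_kappa(c("a"), c("a", "b")), "length")
  set.seed(402)
  ks <- replicate(10000, {
    a <- sample(c("x", "y"), 8, replace = TRUE)
    b <- sample(c("x", "y"), 8, replace = TRUE)
    cohen_kappa(a, b)
  })
  expect_true(all(ks >= -1 & ks <= 1))
  expect_lt(abs(mean(ks)), 0.02)  # chance agreement averages out
})

test_that("pairwise agreement pools over annotator pairs", {
  a <- c("p", "p", "n", "n")
  pa <- pairwise_agreement(list(a, a, a))
  expect_identical(unname(pa$micro), c(1, 1, 1))
  expect_identical(pa$kappa, 1)
  expect_identical(pa$n_pairs, 3L)
  pb <- pairwise_agreement(list(a, c("p", "p", "n", "p")))
  expect_identical(unname(pb$micro[["precision"]]), 0.75)
})

test_that("confusion reconstruction inverts printed precision/recall", {
  cm <- reconstruct_confusion(152, 29, 29, 0.69, 0.69)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(20, 9, 9, 114))
  cm2 <- reconstruct_confusion(152, 29, 46, 0.57, 0.90)
  expect_identical(c(cm2$tp, cm2$fp, cm2$fn, cm2$tn), c(26, 20, 3, 103))
  cm3 <- reconstruct_confusion(10, 5, 5, 1.0, 1.0)
  expect_identical(c(cm3$tp, cm3$fp, cm3$fn, cm3$tn), c(5, 0, 0, 5))
  expect_error(reconstruct_confusion(152, 29, 29, 0.9, 0.3), "inconsistent")

  # round trip: random counts -> printed stats -> same counts
  set.seed(403)
  for (trial in 1:200) {
    tp <- sample(5:40, 1); fp <- sample(0:20, 1)
    fn <- sample(0:20, 1); tn <- sample(20:200, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    p2 <- round(tp / (tp + fp), 2); r2 <- round(tp / (tp + fn), 2)
    got <- tryCatch(
      reconstruct_confusion(tp + fp + fn + tn, tp + fn, tp + fp, p2, r2),
      error = function(e) NULL)
    if (!is.null(got)) {
      expect_identical(c(got$tp, got$fp, got$fn, got$tn),
                       as.numeric(c(tp, fp, fn, tn)))
    }
  }
})

test_that("likelihood ratios behave and flag perfect prediction", {
  cm <- confusion_matrix(20, 9, 9, 114)
  lr <- likelihood_ratios(cm)
  expect_equal(lr$lr_neg, (1 - 20 / 29) / (114 / 123), tolerance = 1e-12)
  # monotone in sensitivity at fixed specificity
  lr_hi <- likelihood_ratios(confusion_matrix(25, 9, 4, 114))
  expect_gt(lr_hi$lr_pos, lr$lr_pos)
  expect_lt(lr_hi$lr_neg, lr$lr_neg)
  # no false positives: infinite LR+, flagged
  perf <- likelihood_ratios(confusion_matrix(4, 0, 7, 48))
  expect_true(perf$perfect_prediction)
  expect_identical(perf$lr_pos, Inf)
  expect_false(perf$ci_pos_defined)
  expect_error(likelihood_ratios(confusion_matrix(0, 5, 0, 0)), "gold")
})

test_that("post-test probability is the odds transform and monotone in LR", {
  p <- 29 / 152
  expect_equal(post_test_probability(p, 1), p, tolerance = 1e-12)
  lrs <- c(0.1, 0.5, 1, 2, 5, 9.4, 50)
  post <- vapply(lrs, function(l) post_test_probability(p, l), 1.0)
  expect_true(all(diff(post) > 0))
  expect_identical(post_test_probability(p, Inf), 1)
})

test_that("evaluate_mentions pools span counts and scores attributes on pairs", {
  gold <- data.frame(doc_id = c("d1", "d1", "d2"),
                     char_start = c(0, 20, 5), char_end = c(10, 30, 9),
                     status = c("relevant", "non-relevant", "relevant"),
                     temporality = c("current", "current", "historical"),
                     polarity = c("positive", "positive", "negative"),
                     stringsAsFactors = FALSE)
  pred <- gold
  ev <- evaluate_mentions(gold, pred, "exact")
  expect_identical(ev$span$f, 1)
  expect_identical(ev$status$micro[["f"]], 1)
  expect_identical(ev$polarity$kappa, 1)
  # one attribute flip shows up only in that attribute
  pred2 <- pred; pred2$temporality[3] <- "current"
  ev2 <- evaluate_mentions(gold, pred2, "exact")
  expect_identical(ev2$span$f, 1)
  expect_identical(ev2$status$micro[["f"]], 1)
  expect_lt(ev2$temporality$micro[["f"]], 1)
})
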