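# Evaluation: span matching, micro/macro precision-recall-F, Cohen's
# kappa, confusion-matrix reconstruction from published per-class
# statistics, diagnostic likelihood ratios with log-transform confidence
# intervals, and post-test probabilities.

#' 2x2 confusion matrix
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return Object of class \code{sh_confusion}.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn), tn = as.numeric(tn)),
            class = "sh_confusion")
}

#' @export
print.sh_confusion <- function(x, ...) {
  cat(sprintf("<sh_confusion tp=%g fp=%g fn=%g tn=%g>\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

.prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  r <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f <- if (is.na(p) || is.na(r)) NA_real_
       else if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f = f)
}

#' Match predicted mention spans against gold spans
#'
#' One-to-one pairing of spans from the same document.  \code{exact} mode
#' requires identical character spans; \code{overlap} mode requires at
#' least one shared character and matches gold spans left-to-right to the
#' unmatched prediction with the largest overlap (leftmost on ties).
#' Unmatched gold spans count as false negatives, unmatched predictions
#' as false positives.  With both sides empty, span precision, recall and
#' F are 1 by convention.
#'
#' @param gold,pred data.frames with columns \code{char_start},
#'   \code{char_end} (0-based half-open) and attribute columns.
#' @param mode \code{"exact"} or \code{"overlap"}.
#' @return List with \code{pairs} (data.frame of row indices
#'   \code{gold}, \code{pred}), \code{tp}, \code{fp}, \code{fn}, and
#'   span-level \code{precision}, \code{recall}, \code{f}.
#' @export
match_spans <- function(gold, pred, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  ng <- nrow(gold); np <- nrow(pred)
  pairs <- data.frame(gold = integer(0), pred = integer(0))
  used <- rep(FALSE, np)
  if (ng && np) {
    ord <- order(gold$char_start, gold$char_end)
    for (g in ord) {
      if (mode == "exact") {
        hit <- which(!used & pred$char_start == gold$char_start[g] &
                       pred$char_end == gold$char_end[g])
        if (length(hit)) {
          used[hit[1L]] <- TRUE
          pairs <- rbind(pairs, data.frame(gold = g, pred = hit[1L]))
        }
      } else {
        ov <- pmin(pred$char_end, gold$char_end[g]) -
          pmax(pred$char_start, gold$char_start[g])
        ov[used] <- 0
        if (any(ov > 0)) {
          best <- which(ov == max(ov))[1L]
          used[best] <- TRUE
          pairs <- rbind(pairs, data.frame(gold = g, pred = best))
        }
      }
    }
  }
  tp <- nrow(pairs); fn <- ng - tp; fp <- np - tp
  if (ng == 0 && np == 0) {
    p <- r <- f <- 1  # empty-empty convention
  } else {
    prf <- .prf(tp, fp, fn)
    p <- prf[["precision"]]; r <- prf[["recall"]]; f <- prf[["f"]]
  }
  list(pairs = pairs, tp = tp, fp = fp, fn = fn,
       precision = p, recall = r, f = f)
}

#' Per-attribute metrics over matched mention pairs
#'
#' One-vs-rest precision, recall and F per class, micro-averaged figures
#' (pooled counts; for single-label classification over matched pairs
#' micro P = R = F = accuracy) and macro-averaged figures (unweighted
#' mean over the classes present in the gold labels), plus Cohen's kappa.
#'
#' @param gold_labels,pred_labels Equal-length label vectors (one entry
#'   per matched pair).
#' @return List of class \code{sh_metrics}: \code{per_class} (data.frame),
#'   \code{micro}, \code{macro} (named numeric: precision, recall, f),
#'   \code{kappa}, \code{n_items}.  All-empty input yields metrics of 1
#'   by the empty-empty convention.
#' @export
attribute_metrics <- function(gold_labels, pred_labels) {
  stopifnot(length(gold_labels) == length(pred_labels))
  n <- length(gold_labels)
  if (n == 0L) {
    return(structure(list(per_class = data.frame(), micro = c(precision = 1, recall = 1, f = 1),
                          macro = c(precision = 1, recall = 1, f = 1),
                          kappa = 1, n_items = 0L), class = "sh_metrics"))
  }
  classes <- sort(unique(c(gold_labels, pred_labels)))
  per <- lapply(classes, function(cl) {
    tp <- sum(gold_labels == cl & pred_labels == cl)
    fp <- sum(gold_labels != cl & pred_labels == cl)
    fn <- sum(gold_labels == cl & pred_labels != cl)
    c(tp = tp, fp = fp, fn = fn, .prf(tp, fp, fn))
  })
  per_class <- data.frame(class = classes,
                          do.call(rbind, per), stringsAsFactors = FALSE)
  rownames(per_class) <- NULL
  tp <- sum(per_class$tp); fp <- sum(per_class$fp); fn <- sum(per_class$fn)
  micro <- .prf(tp, fp, fn)
  in_gold <- per_class$class %in% gold_labels
  macro <- c(precision = mean(per_class$precision[in_gold], na.rm = TRUE),
             recall = mean(per_class$recall[in_gold], na.rm = TRUE),
             f = mean(per_class$f[in_gold], na.rm = TRUE))
  structure(list(per_class = per_class, micro = micro, macro = macro,
                 kappa = cohen_kappa(gold_labels, pred_labels),
                 n_items = n), class = "sh_metrics")
}

#' @export
print.sh_metrics <- function(x, ...) {
  cat(sprintf("<sh_metrics n=%d micro P/R/F %.3f/%.3f/%.3f macro F %.3f kappa %.3f>\n",
              x$n_items, x$micro[["precision"]], x$micro[["recall"]],
              x$micro[["f"]], x$macro[["f"]], x$kappa))
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two label vectors:
#' \eqn{(p_o - p_e) / (1 - p_e)} with expected agreement \eqn{p_e} from
#' the marginal products.  Identical vectors with \eqn{p_e = 1} (a single
#' realised class) return 1.
#'
#' @param a,b Equal-length label vectors.
#' @return Kappa in \eqn{[-1, 1]}.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  n <- length(a)
  if (n == 0L) stop("empty label vectors", call. = FALSE)
  a <- as.character(a); b <- as.character(b)
  po <- mean(a == b)
  classes <- unique(c(a, b))
  pe <- sum(vapply(classes, function(cl) mean(a == cl) * mean(b == cl), 1.0))
  if (abs(1 - pe) < 1e-12) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Micro-averaged pairwise agreement across several annotators
#'
#' Computes \code{\link{attribute_metrics}} for every unordered pair of
#' annotators and pools the per-pair counts (micro-averaging over pairs).
#'
#' @param annotations List (length >= 2) of equal-length label vectors.
#' @return List with pooled \code{micro} precision/recall/F and mean
#'   pairwise \code{kappa}.
#' @export
pairwise_agreement <- function(annotations) {
  stopifnot(is.list(annotations), length(annotations) >= 2L)
  combs <- utils::combn(length(annotations), 2L)
  agree <- 0; total <- 0; kap <- numeric(0)
  for (k in seq_len(ncol(combs))) {
    a <- annotations[[combs[1L, k]]]; b <- annotations[[combs[2L, k]]]
    stopifnot(length(a) == length(b))
    agree <- agree + sum(a == b); total <- total + length(a)
    kap <- c(kap, cohen_kappa(a, b))
  }
  acc <- agree / total
  list(micro = c(precision = acc, recall = acc, f = acc),
       kappa = mean(kap), n_pairs = ncol(combs))
}

#' Reconstruct a 2x2 confusion matrix from published per-class statistics
#'
#' Given the cohort size, the number of gold-positive users, the number of
#' flagged users, and the minority-class precision and recall as printed
#' (2 dp), recovers the underlying counts:
#' \code{tp = round(recall * n_gold_pos)}, \code{fp = n_flagged - tp},
#' \code{fn = n_gold_pos - tp}, \code{tn} the remainder.  The printed
#' precision must be consistent with the same \code{tp} up to rounding.
#'
#' @param n_total Total users.
#' @param n_gold_pos Gold-positive users.
#' @param n_flagged Users flagged by the classifier.
#' @param precision_min,recall_min Printed minority-class precision and
#'   recall.
#' @param digits Printed precision of the inputs (default 2).
#' @return \code{\link{confusion_matrix}}.
#' @export
reconstruct_confusion <- function(n_total, n_gold_pos, n_flagged,
                                  precision_min, recall_min, digits = 2L) {
  tp_r <- round(recall_min * n_gold_pos)
  tp_p <- round(precision_min * n_flagged)
  if (tp_r != tp_p) {
    stop(sprintf(paste0("inconsistent inputs: recall implies tp = %d but ",
                        "precision implies tp = %d"), tp_r, tp_p),
         call. = FALSE)
  }
  tp <- tp_r
  fp <- n_flagged - tp
  fn <- n_gold_pos - tp
  tn <- n_total - tp - fp - fn
  if (min(fp, fn, tn) < 0) stop("inputs yield negative counts", call. = FALSE)
  # the recovered counts must round back to the printed statistics
  if (round(tp / (tp + fn), digits) != round(recall_min, digits) ||
      round(tp / (tp + fp), digits) != round(precision_min, digits)) {
    stop("recovered counts do not reproduce the printed precision/recall",
         call. = FALSE)
  }
  confusion_matrix(tp, fp, fn, tn)
}

#' Binary metrics of a 2x2 confusion matrix
#'
#' Per-class (minority = positive, majority = negative) precision, recall
#' and F, macro averages, and kappa, mirroring a per-class evaluation
#' table.
#'
#' @param cm \code{\link{confusion_matrix}}.
#' @return Named list.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "sh_confusion"))
  minority <- .prf(cm$tp, cm$fp, cm$fn)
  majority <- .prf(cm$tn, cm$fn, cm$fp)
  labels_a <- c(rep("pos", cm$tp + cm$fn), rep("neg", cm$fp + cm$tn))
  labels_b <- c(rep("pos", cm$tp), rep("neg", cm$fn),
                rep("pos", cm$fp), rep("neg", cm$tn))
  list(minority = minority, majority = majority,
       macro = (minority + majority) / 2,
       kappa = cohen_kappa(labels_a, labels_b),
       sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$tn + cm$fp),
       prevalence = (cm$tp + cm$fn) / (cm$tp + cm$fp + cm$fn + cm$tn),
       n_flagged = cm$tp + cm$fp)
}

#' Diagnostic likelihood ratios with confidence intervals
#'
#' \eqn{LR^+ = sens / (1 - spec)} and \eqn{LR^- = (1 - sens) / spec},
#' with confidence intervals by the log-transform normal approximation:
#' \eqn{\exp(\ln LR \pm z \cdot SE)} where
#' \eqn{SE(\ln LR^+) = \sqrt{1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)}} and
#' symmetrically for \eqn{LR^-}.  With zero false positives the positive
#' ratio is infinite and flagged (\code{perfect_prediction}).
#'
#' @param cm \code{\link{confusion_matrix}} with \code{tp+fn > 0} and
#'   \code{fp+tn > 0}.
#' @param confidence Confidence level (default 0.95).
#' @return List with \code{lr_pos}, \code{lr_neg}, \code{ci_pos},
#'   \code{ci_neg} (length-2 vectors) and logical flags
#'   \code{perfect_prediction}, \code{ci_pos_defined},
#'   \code{ci_neg_defined}.
#' @export
likelihood_ratios <- function(cm, confidence = 0.95) {
  stopifnot(inherits(cm, "sh_confusion"))
  if (cm$tp + cm$fn <= 0 || cm$fp + cm$tn <= 0) {
    stop("need at least one gold-positive and one gold-negative", call. = FALSE)
  }
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  perfect <- cm$fp == 0
  if (perfect) {
    lr_pos <- Inf; ci_pos <- c(NA_real_, NA_real_); ci_pos_def <- FALSE
  } else {
    lr_pos <- sens / (1 - spec)
    se <- sqrt(1 / cm$tp - 1 / (cm$tp + cm$fn) + 1 / cm$fp - 1 / (cm$fp + cm$tn))
    ci_pos <- exp(log(lr_pos) + c(-1, 1) * z * se)
    ci_pos_def <- is.finite(lr_pos) && cm$tp > 0
  }
  if (cm$fn == 0) {
    lr_neg <- 0; ci_neg <- c(NA_real_, NA_real_); ci_neg_def <- FALSE
  } else {
    lr_neg <- (1 - sens) / spec
    se <- sqrt(1 / cm$fn - 1 / (cm$tp + cm$fn) + 1 / cm$tn - 1 / (cm$fp + cm$tn))
    ci_neg <- exp(log(lr_neg) + c(-1, 1) * z * se)
    ci_neg_def <- TRUE
  }
  list(lr_pos = lr_pos, lr_neg = lr_neg, ci_pos = ci_pos, ci_neg = ci_neg,
       perfect_prediction = perfect, ci_pos_defined = ci_pos_def,
       ci_neg_defined = ci_neg_def)
}

#' Post-test probability from a likelihood ratio
#'
#' Converts a pre-test prevalence to post-test probability via odds:
#' \eqn{odds_{post} = lr \cdot p/(1-p)}, returned as
#' \eqn{odds_{post}/(1+odds_{post})}.
#'
#' @param pretest_prevalence Pre-test probability in (0, 1).
#' @param lr Likelihood ratio (>= 0; \code{Inf} yields 1).
#' @return Post-test probability.
#' @export
post_test_probability <- function(pretest_prevalence, lr) {
  stopifnot(pretest_prevalence > 0, pretest_prevalence < 1, all(lr >= 0))
  if (any(is.infinite(lr))) {
    return(ifelse(is.infinite(lr), 1,
                  {o <- pretest_prevalence / (1 - pretest_prevalence) * lr
                   o / (1 + o)}))
  }
  odds <- pretest_prevalence / (1 - pretest_prevalence) * lr
  odds / (1 + odds)
}

#' Evaluate predictions against a gold standard
#'
#' Runs span matching per document, pools the span confusion counts, and
#' computes attribute metrics over the matched pairs for status,
#' temporality and polarity.
#'
#' @param gold,pred Mention tables (\code{\link{mention_table}} layout;
#'   gold needs at least \code{doc_id}, \code{char_start},
#'   \code{char_end}, plus the attribute columns).
#' @param mode Span-matching mode.
#' @return List with \code{span} (counts and P/R/F) and one
#'   \code{sh_metrics} per attribute.
#' @export
evaluate_mentions <- function(gold, pred, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  docs <- unique(c(as.character(gold$doc_id), as.character(pred$doc_id)))
  tp <- fp <- fn <- 0L
  g_lab <- list(status = character(0), temporality = character(0),
                polarity = character(0))
  p_lab <- g_lab
  for (d in docs) {
    g <- gold[gold$doc_id == d, , drop = FALSE]
    p <- pred[pred$doc_id == d, , drop = FALSE]
    ms <- match_spans(g, p, mode)
    tp <- tp + ms$tp; fp <- fp + ms$fp; fn <- fn + ms$fn
    if (nrow(ms$pairs)) {
      for (attr in names(g_lab)) {
        g_lab[[attr]] <- c(g_lab[[attr]], g[[attr]][ms$pairs$gold])
        p_lab[[attr]] <- c(p_lab[[attr]], p[[attr]][ms$pairs$pred])
      }
    }
  }
  span <- if (tp + fp + fn == 0) {
    list(tp = 0L, fp = 0L, fn = 0L, precision = 1, recall = 1, f = 1)
  } else {
    prf <- .prf(tp, fp, fn)
    list(tp = tp, fp = fp, fn = fn, precision = prf[["precision"]],
         recall = prf[["recall"]], f = prf[["f"]])
  }
  list(span = span,
       status = attribute_metrics(g_lab$status, p_lab$status),
       temporality = attribute_metrics(g_lab$temporality, p_lab$temporality),
       polarity = attribute_metrics(g_lab$polarity, p_lab$polarity))
}

#' User-level evaluation against gold flags
#'
#' @param gold_flags,pred_flags Logical vectors aligned on the same users.
#' @return List with the \code{\link{confusion_matrix}} and
#'   \code{\link{confusion_metrics}}.
#' @export
evaluate_users <- function(gold_flags, pred_flags) {
  stopifnot(length(gold_flags) == length(pred_flags))
  cm <- confusion_matrix(tp = sum(gold_flags & pred_flags),
                         fp = sum(!gold_flags & pred_flags),
                         fn = sum(gold_flags & !pred_flags),
                         tn = sum(!gold_flags & !pred_flags))
  list(cm = cm, metrics = confusion_metrics(cm))
}
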