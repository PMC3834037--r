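## Predictor evaluation: confusion metrics, ROC/AUC/partial AUC, DeLong
## comparison of correlated AUCs, stratified bootstrap CIs, threshold
## selection and per-residue region evaluation.
##
## Convention used throughout: a score >= threshold is a positive call
## (ties count as positive).

#' Construct a confusion matrix
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return An object of class `"confusion_matrix"` (named integer-ish
#'   vector with elements `tp`, `tn`, `fp`, `fn`).
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("confusion matrix is empty")
  structure(as.numeric(counts), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(x[c("tp", "fn", "fp", "tn")], 2, 2,
              dimnames = list(truth = c("amyloid", "non-amyloid"),
                              predicted = c("amyloid", "non-amyloid")))
  print(m)
  invisible(x)
}

#' Confusion matrix from scores at a threshold
#'
#' A score `>= threshold` is a positive prediction.
#'
#' @param scores numeric prediction scores.
#' @param labels binary truth labels (0/1).
#' @param threshold decision threshold.
#' @return A [confusion_matrix()].
#' @export
confusion_from_scores <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  labels <- coerce_label(labels)
  pred <- scores >= threshold
  confusion_matrix(tp = sum(pred & labels == 1),
                   tn = sum(!pred & labels == 0),
                   fp = sum(pred & labels == 0),
                   fn = sum(!pred & labels == 1))
}

#' Classification metrics from a confusion matrix
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/n, Matthews correlation coefficient
#' \eqn{(TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#' Q = (sensitivity+specificity)/2 and F1 = 2TP/(2TP+FP+FN).
#' A metric whose denominator is zero is returned as `NA` (a tagged
#' undefined value) rather than 0.
#'
#' @param cm a [confusion_matrix()], or `tp` if counts are given directly.
#' @param tn,fp,fn counts, when `cm` is the `tp` count.
#' @return A list with elements `acc`, `sensitivity`, `specificity`, `mcc`,
#'   `q`, `f1`.
#' @examples
#' classification_metrics(confusion_matrix(tp = 4, tn = 10, fp = 0, fn = 2))
#' @export
classification_metrics <- function(cm, tn = NULL, fp = NULL, fn = NULL) {
  if (!inherits(cm, "confusion_matrix")) {
    cm <- confusion_matrix(tp = cm, tn = tn, fp = fp, fn = fn)
  }
  tp <- cm[["tp"]]; tn <- cm[["tn"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]
  n <- tp + tn + fp + fn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ## products can exceed integer range; keep everything double
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  list(acc = safe_div(tp + tn, n),
       sensitivity = sens,
       specificity = spec,
       mcc = mcc,
       q = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
       f1 = safe_div(2 * tp, 2 * tp + fp + fn))
}

#' ROC curve of a score against binary labels
#'
#' One operating point per distinct score value (equal scores are grouped),
#' plus the all-negative endpoint, under the score-`>=`-threshold positive
#' convention.  The curve runs from (FPR, TPR) = (0, 0) to (1, 1).
#'
#' @inheritParams confusion_from_scores
#' @return An object of class `"roc_curve"`: a data frame with columns
#'   `threshold` (descending, first `Inf`), `sensitivity`, `specificity`,
#'   `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- coerce_label(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  if (anyNA(scores)) stop("scores contain NA")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1), 0) / npos
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0), 0) / nneg
  structure(data.frame(threshold = thr, sensitivity = sens,
                       specificity = spec, fpr = 1 - spec, tpr = sens),
            class = c("roc_curve", "data.frame"))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve with", nrow(x), "operating points; AUC =",
      format(auc(x), digits = 4), "\n")
  print.data.frame(utils::head(x, 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the [roc_curve()]; for finite data this equals
#' the Mann-Whitney concordance
#' \eqn{P(S_+ > S_-) + \frac{1}{2} P(S_+ = S_-)}
#' (see [auc_concordance()] for the direct rank-based estimator).
#'
#' @param x a `"roc_curve"`, or a numeric score vector.
#' @param labels binary labels, when `x` is a score vector.
#' @param ... unused.
#' @return The AUC, in `[0, 1]`.
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @export
auc.roc_curve <- function(x, ...) {
  o <- order(x$fpr, x$tpr)
  fpr <- x$fpr[o]; tpr <- x$tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
auc.default <- function(x, labels, ...) auc(roc_curve(x, labels))

#' Rank-based (Mann-Whitney) AUC estimator
#'
#' Direct concordance estimator of the AUC, computed from ranks with the
#' midrank tie correction.  Serves as an independent route to the same
#' quantity as the trapezoidal [auc()].
#'
#' @inheritParams confusion_from_scores
#' @return The AUC, in `[0, 1]`.
#' @export
auc_concordance <- function(scores, labels) {
  labels <- coerce_label(labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Partial area under the ROC curve
#'
#' Area under the ROC polyline restricted to a false-positive-rate band,
#' with linear interpolation at the band edges.  Reported unnormalized, so
#' a perfect classifier on the 0-20% band scores 0.2 and an uninformative
#' one 0.02.
#'
#' @inheritParams confusion_from_scores
#' @param fpr_lo,fpr_hi the FPR band, `0 <= fpr_lo < fpr_hi <= 1`.
#' @return The unnormalized partial AUC.
#' @export
partial_auc <- function(scores, labels, fpr_lo = 0, fpr_hi = 0.2) {
  if (!(fpr_lo >= 0 && fpr_lo < fpr_hi && fpr_hi <= 1)) {
    stop("need 0 <= fpr_lo < fpr_hi <= 1")
  }
  rc <- roc_curve(scores, labels)
  o <- order(rc$fpr, rc$tpr)
  fpr <- rc$fpr[o]; tpr <- rc$tpr[o]
  ## height of the polyline at a given FPR; vertical segments (duplicated
  ## fpr) contribute their topmost point
  interp <- function(at) {
    i <- max(which(fpr <= at))
    if (fpr[i] == at || i == length(fpr)) return(tpr[i])
    tpr[i] + (tpr[i + 1] - tpr[i]) * (at - fpr[i]) / (fpr[i + 1] - fpr[i])
  }
  xs <- c(fpr_lo, fpr[fpr > fpr_lo & fpr < fpr_hi], fpr_hi)
  ys <- c(interp(fpr_lo), tpr[fpr > fpr_lo & fpr < fpr_hi],
          interp(fpr_hi))
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

## DeLong placement values for one score vector: list(v10, v01, auc)
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores computed on the same instances (paired
#' design) using DeLong's placement-value variance of the AUC difference;
#' the p-value is two-sided normal.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary labels.
#' @return A list with `auc_a`, `auc_b`, `auc_diff` (`auc_a - auc_b`),
#'   `se`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- coerce_label(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stop("scores and labels must have the same length")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::var(pa$v10 - pb$v10)
  s01 <- stats::var(pa$v01 - pb$v01)
  var_diff <- s10 / m + s01 / n
  diff <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(diff) < .Machine$double.eps^0.5) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = 0,
                  se = 0, z = 0, p_value = 1))
    }
    stop("zero variance of the AUC difference with a nonzero difference")
  }
  se <- sqrt(var_diff)
  z <- diff / se
  list(auc_a = pa$auc, auc_b = pb$auc, auc_diff = diff, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Stratified bootstrap confidence interval
#'
#' Percentile interval for any statistic of (scores, labels), over
#' class-stratified resamples (positives and negatives are resampled
#' separately, so every replicate contains both classes).
#'
#' @param statistic function of `(scores, labels)` returning a scalar.
#' @inheritParams confusion_from_scores
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param level confidence level.
#' @param seed RNG seed; identical seeds give identical intervals.
#' @return A list with `low`, `high`, `estimate` (statistic on the original
#'   data) and `replicates` (the bootstrap distribution).
#' @examples
#' s <- c(rnorm(50, 1), rnorm(50)); y <- rep(1:0, each = 50)
#' bootstrap_ci(auc_concordance, s, y, n_boot = 200, seed = 1)[c("low", "high")]
#' @export
bootstrap_ci <- function(statistic, scores, labels, n_boot = 2000L,
                         level = 0.95, seed = 1L) {
  if (n_boot < 100L) stop("n_boot must be at least 100")
  labels <- coerce_label(labels)
  ipos <- which(labels == 1)
  ineg <- which(labels == 0)
  if (!length(ipos) || !length(ineg)) stop("both classes must be present")
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ipos, length(ipos), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      statistic(scores[idx], labels[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  list(low = qs[1], high = qs[2],
       estimate = statistic(scores, labels), replicates = reps)
}

#' Select a decision threshold from a score and labels
#'
#' Candidate thresholds are the distinct score values (plus `Inf`, the
#' predict-nothing cut).  Criteria:
#' \describe{
#'   \item{`"upper-left"`}{minimize the Euclidean distance
#'     \eqn{\sqrt{(1-sens)^2 + (1-spec)^2}} to the (0, 1) corner of the
#'     ROC plane;}
#'   \item{`"youden"`}{maximize Youden's J = sensitivity + specificity - 1;}
#'   \item{`"high-sensitivity"`}{the largest threshold with
#'     sensitivity >= `target`;}
#'   \item{`"high-specificity"`}{the smallest threshold with
#'     specificity >= `target`.}
#' }
#' Ties between equally optimal thresholds are broken towards the largest
#' threshold (the more specific cut).
#'
#' @inheritParams confusion_from_scores
#' @param criterion one of `"upper-left"`, `"youden"`, `"high-sensitivity"`,
#'   `"high-specificity"`.
#' @param target required sensitivity or specificity for the `high-*`
#'   criteria, in (0, 1).
#' @return The selected threshold (a score value).
#' @export
select_threshold <- function(scores, labels,
                             criterion = c("upper-left", "youden",
                                           "high-sensitivity",
                                           "high-specificity"),
                             target = NULL) {
  criterion <- match.arg(criterion)
  rc <- roc_curve(scores, labels)
  if (criterion %in% c("high-sensitivity", "high-specificity")) {
    if (is.null(target) || target <= 0 || target >= 1) {
      stop("the high-* criteria need a target in (0, 1)")
    }
  }
  finite <- is.finite(rc$threshold)
  switch(criterion,
    "upper-left" = {
      d <- (1 - rc$sensitivity)^2 + (1 - rc$specificity)^2
      max(rc$threshold[finite & d == min(d[finite])])
    },
    "youden" = {
      j <- rc$sensitivity + rc$specificity - 1
      max(rc$threshold[finite & j == max(j[finite])])
    },
    "high-sensitivity" = {
      ok <- finite & rc$sensitivity >= target
      if (!any(ok)) stop("unreachable sensitivity target ", target)
      max(rc$threshold[ok])
    },
    "high-specificity" = {
      ok <- finite & rc$specificity >= target
      if (!any(ok)) stop("unreachable specificity target ", target)
      min(rc$threshold[ok])
    })
}

## union-of-regions membership over residues 1..seq_len
region_mask <- function(regions, seq_len) {
  mask <- logical(seq_len)
  if (is.null(regions) || !nrow(regions)) return(mask)
  if (any(regions$start < 1L | regions$end > seq_len |
            regions$start > regions$end)) {
    stop("region out of bounds for sequence of length ", seq_len)
  }
  for (i in seq_len(nrow(regions))) {
    mask[regions$start[i]:regions$end[i]] <- TRUE
  }
  mask
}

#' Per-residue confusion counts for region predictions
#'
#' Classifies every residue of a protein by its membership in the union of
#' predicted regions versus the union of experimentally validated regions;
#' counts always sum to the sequence length (summed over proteins when
#' `seq_len` is a named vector and the region tables carry `sequence_id`).
#'
#' @param predicted,truth data frames with columns `start`, `end`
#'   (1-based inclusive) and, for multi-protein input, `sequence_id`.
#' @param seq_len sequence length, or a named vector of lengths keyed by
#'   `sequence_id`.
#' @return A [confusion_matrix()].
#' @export
per_residue_confusion <- function(predicted, truth, seq_len) {
  if (length(seq_len) > 1L || !is.null(names(seq_len))) {
    ids <- names(seq_len)
    tot <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (id in ids) {
      p <- predicted[predicted$sequence_id == id, , drop = FALSE]
      t <- truth[truth$sequence_id == id, , drop = FALSE]
      cm <- per_residue_confusion(p, t, unname(seq_len[id]))
      tot <- tot + unclass(cm)[names(tot)]
    }
    return(confusion_matrix(tp = tot["tp"], tn = tot["tn"],
                            fp = tot["fp"], fn = tot["fn"]))
  }
  pm <- region_mask(predicted, seq_len)
  tm <- region_mask(truth, seq_len)
  confusion_matrix(tp = sum(pm & tm), tn = sum(!pm & !tm),
                   fp = sum(pm & !tm), fn = sum(!pm & tm))
}
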