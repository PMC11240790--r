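#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A| + |B|)` between two binary masks of equal shape. Two empty
#' masks agree perfectly and score 1 by convention (a control case with no
#' predicted tumor); cohort-level mean Dice is averaged over tumor cases
#' only, so the convention never inflates it.
#'
#' @param a,b binary arrays of identical shape.
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dice: mask shapes differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Localization criterion: does the prediction touch the tumor?
#'
#' A detection counts as localized when the predicted tumor mask shares at
#' least one voxel with the ground-truth tumor.
#'
#' @param pred_mask,gt_tumor binary arrays of identical shape.
#' @return logical.
#' @export
localization_hit <- function(pred_mask, gt_tumor) {
  if (!all(dim(pred_mask) == dim(gt_tumor))) stop("localization_hit: shapes differ")
  any(pred_mask != 0 & gt_tumor != 0)
}

#' Case-level classification metrics at a threshold
#'
#' Calls are `score >= threshold` (inclusive). Reports sensitivity,
#' specificity, precision, accuracy, the arithmetic-mean F1
#' (`f1_paper = (precision + sensitivity) / 2`, the convention used in the
#' tables this package reproduces) and the standard harmonic F1 under a
#' separate name. Degenerate classes yield `NA`, never a silent 0.
#'
#' @param outcomes data frame with columns `truth` (logical) and `score`
#'   (fraction), one row per case; an optional `call` column overrides the
#'   thresholded call.
#' @param threshold case-score cutoff (default 0.61).
#' @return one-row tibble of counts and metrics.
#' @export
confusion_metrics <- function(outcomes, threshold = 0.61) {
  if (nrow(outcomes) == 0) stop("empty cohort")
  truth <- as.logical(outcomes$truth)
  call <- if (!is.null(outcomes[["call"]])) as.logical(outcomes[["call"]])
         else outcomes$score >= threshold
  tp <- sum(call & truth); fp <- sum(call & !truth)
  tn <- sum(!call & !truth); fn <- sum(!call & truth)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(tp, tp + fn); spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1p <- if (is.na(prec) || is.na(sens)) NA_real_ else (prec + sens) / 2
  f1h <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
         else 2 * prec * sens / (prec + sens)
  tibble::tibble(n = length(truth), tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, precision = prec,
                 f1_paper = f1p, f1_harmonic = f1h,
                 accuracy = (tp + tn) / length(truth), threshold = threshold)
}

#' Arithmetic-mean F1 from precision and recall
#' @param precision,sensitivity fractions.
#' @return `(precision + sensitivity) / 2`.
#' @export
f1_paper <- function(precision, sensitivity) (precision + sensitivity) / 2

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' case scores above a random negative one, ties counting one half. Agrees
#' with the threshold-sweep trapezoid of [roc_curve()] to numerical
#' precision.
#'
#' @param scores numeric case scores.
#' @param truths logical (or 0/1) case labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truths) {
  truths <- as.logical(truths)
  np <- sum(truths); nn <- sum(!truths)
  if (np == 0 || nn == 0) stop("roc_auc needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[truths]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve as (threshold, TPR, FPR) triples
#'
#' Sweeps every distinct score (plus an all-negative sentinel); suitable for
#' replotting fold-wise ROC figures. `auc_from_curve()` integrates it by
#' trapezoid over FPR.
#'
#' @inheritParams roc_auc
#' @return tibble with columns threshold, tpr, fpr, ordered by descending
#'   threshold.
#' @export
roc_curve <- function(scores, truths) {
  truths <- as.logical(truths)
  np <- sum(truths); nn <- sum(!truths)
  if (np == 0 || nn == 0) stop("roc_curve needs both classes")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores >= t & truths) / np, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !truths) / nn, numeric(1))
  tibble::tibble(threshold = th, tpr = tpr, fpr = fpr)
}

#' @rdname roc_curve
#' @param curve a tibble from [roc_curve()].
#' @export
auc_from_curve <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  f <- curve$fpr[o]; t <- curve$tpr[o]
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}

#' Cohort-level evaluation report
#'
#' Joins per-case outcomes with the cohort manifest and reports the overall
#' metric row, a small-tumor subgroup row (tumors below
#' `subgroup_diameter_mm` against all controls), the ROC curve, AUROC, and
#' mean +/- sd tumor Dice over positive cases.
#'
#' @param outcomes data frame with case_id, truth, score and optionally
#'   tumor_dsc, localization_hit.
#' @param manifest cohort manifest with case_id, has_tumor, diameter_mm.
#' @param threshold case-score cutoff.
#' @param subgroup_diameter_mm small-tumor cutoff (mm).
#' @return list: `metrics` (tibble, rows "all" and "small_tumor"), `auroc`,
#'   `roc` (curve tibble), `dice_mean`, `dice_sd`, `localization_rate`.
#' @export
evaluate_cohort <- function(outcomes, manifest, threshold = 0.61,
                            subgroup_diameter_mm = 20) {
  if (nrow(outcomes) == 0) stop("empty cohort")
  m <- merge(as.data.frame(outcomes), as.data.frame(manifest),
             by = "case_id", suffixes = c("", ".man"))
  if (nrow(m) == 0) stop("no overlap between outcomes and manifest")
  m$truth <- as.logical(m$truth)
  overall <- confusion_metrics(m, threshold)
  small <- m[!m$truth | (!is.na(m$diameter_mm) &
                           m$diameter_mm < subgroup_diameter_mm), ]
  rows <- overall
  rows$subgroup <- "all"
  if (any(small$truth) && any(!small$truth)) {
    sm <- confusion_metrics(small, threshold)
    sm$subgroup <- sprintf("tumor_lt_%gmm", subgroup_diameter_mm)
    rows <- rbind(rows, sm)
  }
  pos <- m[m$truth, ]
  dsc <- if (!is.null(m$tumor_dsc)) pos$tumor_dsc[!is.na(pos$tumor_dsc)] else numeric(0)
  loc <- if (!is.null(m$localization_hit)) {
    h <- pos$localization_hit[!is.na(pos$localization_hit)]
    if (length(h)) mean(h) else NA_real_
  } else NA_real_
  list(metrics = tibble::as_tibble(rows),
       auroc = roc_auc(m$score, m$truth),
       roc = roc_curve(m$score, m$truth),
       dice_mean = if (length(dsc)) mean(dsc) else NA_real_,
       dice_sd = if (length(dsc) > 1) sd(dsc) else NA_real_,
       localization_rate = loc)
}
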