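#' Overall multi-label performance measures
#'
#' Given observed labelsets \code{L_k} and predicted labelsets \code{L*_k}
#' for \code{N} samples over \code{M} possible labels, computes the five
#' set-overlap measures commonly reported for multi-label classifiers:
#' \describe{
#'   \item{aiming}{mean of \code{|L_k ∩ L*_k| / |L*_k|} (precision-like,
#'     normalised by the predicted set).}
#'   \item{coverage}{mean of \code{|L_k ∩ L*_k| / |L_k|} (recall-like,
#'     normalised by the observed set).}
#'   \item{accuracy}{mean Jaccard overlap \code{|∩| / |∪|}.}
#'   \item{absolute_true}{fraction of exact labelset matches (subset
#'     accuracy).}
#'   \item{absolute_false}{mean symmetric-difference size over \code{M};
#'     identical to the Hamming loss.}
#' }
#' For every sample, \code{absolute_true <= accuracy <= min(aiming,
#' coverage)} termwise, so the same chain holds for the means.
#'
#' @param true_sets list of observed integer labelsets (each nonempty).
#' @param pred_sets list of predicted integer labelsets.
#' @param M total number of labels.
#' @return An object of class \code{ec_overall}: list with the five
#'   measures plus \code{N} and \code{M}.
#' @export
overall_metrics <- function(true_sets, pred_sets, M) {
  N <- length(true_sets)
  if (N < 1L || length(pred_sets) != N) {
    stop_data("true and predicted label lists must have equal positive length")
  }
  if (any(lengths(true_sets) == 0L)) stop_data("observed labelsets must be nonempty")
  aim <- cov <- acc <- atr <- afl <- numeric(N)
  for (i in seq_len(N)) {
    tr <- unique(as.integer(true_sets[[i]]))
    pr <- unique(as.integer(pred_sets[[i]]))
    ii <- length(intersect(tr, pr))
    uu <- length(union(tr, pr))
    if (uu == 0L) stop_data("both labelsets empty at sample ", i)
    aim[i] <- if (length(pr) == 0L) 0 else ii / length(pr)
    cov[i] <- ii / length(tr)
    acc[i] <- ii / uu
    atr[i] <- as.numeric(uu == ii && length(tr) == length(pr))
    afl[i] <- (uu - ii) / M
  }
  structure(list(aiming = mean(aim), coverage = mean(cov),
                 accuracy = mean(acc), absolute_true = mean(atr),
                 absolute_false = mean(afl), N = N, M = as.integer(M)),
            class = "ec_overall")
}

#' @export
print.ec_overall <- function(x, ...) {
  v <- round(c(absolute_false = x$absolute_false, absolute_true = x$absolute_true,
               aiming = x$aiming, coverage = x$coverage, accuracy = x$accuracy), 4)
  print(v)
  invisible(x)
}

#' Per-class one-vs-rest performance measures
#'
#' Each class in turn is taken as the positive class (samples whose
#' observed labelset contains it) and all other samples as negatives.
#' Reports the confusion counts and accuracy, recall, precision,
#' F1-measure and the Matthews correlation coefficient; MCC with a zero
#' denominator is defined as 0, and precision/recall with an empty
#' denominator are reported as 0 with the \code{degenerate} flag set.
#' When a score matrix is supplied, AUROC and AUPR are added per class
#' (NA, flagged, when the class has no positive or no negative sample).
#'
#' @inheritParams overall_metrics
#' @param L number of classes.
#' @param scores optional n x L matrix of graded per-label scores.
#' @param label_names optional display names.
#' @return data.frame with one row per class.
#' @export
per_class_metrics <- function(true_sets, pred_sets, L, scores = NULL,
                              label_names = NULL) {
  N <- length(true_sets)
  stopifnot(length(pred_sets) == N, N >= 1L)
  label_names <- label_names %||% default_label_names(L)
  truth <- matrix(FALSE, N, L)
  pred <- matrix(FALSE, N, L)
  for (i in seq_len(N)) {
    truth[i, as.integer(true_sets[[i]])] <- TRUE
    pred[i, as.integer(pred_sets[[i]])] <- TRUE
  }
  out <- lapply(seq_len(L), function(j) {
    tp <- sum(truth[, j] & pred[, j]); fp <- sum(!truth[, j] & pred[, j])
    fn <- sum(truth[, j] & !pred[, j]); tn <- sum(!truth[, j] & !pred[, j])
    prec_deg <- (tp + fp) == 0L
    rec_deg <- (tp + fn) == 0L
    mcc_den <- sqrt(prod(as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))))
    mcc <- if (mcc_den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
    row <- data.frame(
      class = j, label = label_names[j],
      TP = tp, FP = fp, TN = tn, FN = fn,
      accuracy = (tp + tn) / N,
      recall = if (rec_deg) 0 else tp / (tp + fn),
      precision = if (prec_deg) 0 else tp / (tp + fp),
      f1 = if ((2 * tp + fp + fn) == 0L) 0 else 2 * tp / (2 * tp + fp + fn),
      mcc = mcc,
      degenerate = prec_deg || rec_deg,
      stringsAsFactors = FALSE)
    if (!is.null(scores)) {
      y <- as.integer(truth[, j])
      row$auroc <- if (any(y == 1L) && any(y == 0L)) auroc(scores[, j], y) else NA_real_
      row$aupr <- if (any(y == 1L)) aupr(scores[, j], y) else NA_real_
    }
    row
  })
  do.call(rbind, out)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic with mid-rank handling of
#' tied scores, so it is invariant under strictly monotone transforms of
#' the scores and equals 0.5 when all scores tie.
#'
#' @param scores numeric score vector.
#' @param truth 0/1 vector (or logical) of the same length.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  stopifnot(length(scores) == length(truth))
  np <- sum(truth == 1L); nn <- sum(truth == 0L)
  if (np == 0L || nn == 0L) stop_data("AUROC needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' \code{method = "average_precision"} (default, the headline number) is
#' the step-wise integral of precision over recall increments, summed at
#' distinct score thresholds; \code{method = "trapezoid"} integrates the
#' PR curve linearly between the same points. Both are exported because
#' curve integrators differ between toolkits.
#'
#' @inheritParams auroc
#' @param method integration rule.
#' @return AUPR in [0, 1].
#' @export
aupr <- function(scores, truth, method = c("average_precision", "trapezoid")) {
  method <- match.arg(method)
  truth <- as.integer(as.logical(truth))
  stopifnot(length(scores) == length(truth))
  P <- sum(truth == 1L)
  if (P == 0L) stop_data("AUPR needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  # evaluate the curve only at distinct thresholds (last index of each tie run)
  cut <- which(diff(s) != 0)
  cut <- c(cut, length(s))
  prec <- tp[cut] / (tp[cut] + fp[cut])
  rec <- tp[cut] / P
  if (method == "average_precision") {
    sum(diff(c(0, rec)) * prec)
  } else {
    prec0 <- c(prec[1L], prec)
    rec0 <- c(0, rec)
    sum(diff(rec0) * (prec0[-length(prec0)] + prec0[-1L]) / 2)
  }
}

#' Multiplicity degree of a label table
#'
#' The average number of labels per sample: total label assignments over
#' the number of distinct samples. Equals 1 for a purely single-label
#' table.
#'
#' @param labels an \code{ec_labels} object or plain list of labelsets.
#' @return numeric >= 1.
#' @export
multiplicity_degree <- function(labels) {
  if (length(labels) == 0L) stop_data("empty label table")
  sum(lengths(labels)) / length(labels)
}

#' Build a label table matching printed per-class counts
#'
#' Reconstructs a minimal label table whose per-class assignment counts
#' equal a published breakdown (e.g. a dataset table reporting the number
#' of enzymes per family class together with the number of distinct
#' enzymes). Proteins beyond the first \code{n_distinct} assignments are
#' realised as second labels on proteins of a different class; which
#' proteins carry them is immaterial to any count-level statistic such as
#' the multiplicity degree.
#'
#' @param class_counts integer vector of per-class assignment counts.
#' @param n_distinct number of distinct proteins; must satisfy
#'   \code{n_distinct <= sum(class_counts) <= 2 * n_distinct}.
#' @return An \code{ec_labels} object with \code{n_distinct} proteins.
#' @export
label_table_from_counts <- function(class_counts, n_distinct) {
  class_counts <- as.integer(class_counts)
  L <- length(class_counts)
  total <- sum(class_counts)
  if (total < n_distinct || total > 2L * n_distinct) {
    stop_data("counts not realisable with at most two labels per protein")
  }
  pool <- rep.int(seq_len(L), class_counts)
  primary <- pool[seq_len(n_distinct)]
  entries <- lapply(primary, identity)
  extras <- pool[seq_len(total - n_distinct) + n_distinct]
  free <- rep(TRUE, n_distinct)
  for (l in extras) {
    host <- which(free & primary != l)[1L]
    if (is.na(host)) stop_data("counts not realisable: no host protein left for class ", l)
    entries[[host]] <- c(entries[[host]], l)
    free[host] <- FALSE
  }
  names(entries) <- paste0("p", seq_len(n_distinct))
  label_table(entries, L)
}
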