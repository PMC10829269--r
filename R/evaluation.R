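#' Random near-equal K-fold partition
#'
#' @param ids character vector of protein IDs.
#' @param K number of folds (>= 2).
#' @param seed integer seed.
#' @return An object of class \code{ec_folds}: list with \code{fold_of}
#'   (named integer vector), \code{K}, \code{scheme}, \code{seed}.
#' @export
make_folds <- function(ids, K, seed) {
  K <- as.integer(K)
  if (K < 2L) stop_usage("K must be at least 2")
  if (length(ids) < K) stop_data("fewer samples than folds")
  set.seed(as.integer(seed))
  perm <- sample(ids)
  fold_of <- stats::setNames(rep_len(seq_len(K), length(ids)), perm)[ids]
  structure(list(fold_of = fold_of, K = K, scheme = "general",
                 seed = as.integer(seed)),
            class = "ec_folds")
}

# Group key used by the stratified scheme: the L exact-singleton groups,
# one group for exactly the designated label pair, and a remainder group.
stratum_of <- function(labelset, L, pair_group) {
  ls <- sort(unique(as.integer(labelset)))
  if (length(ls) == 1L) return(ls)
  if (identical(ls, sort(as.integer(pair_group)))) return(L + 1L)
  L + 2L
}

#' Stratified K-fold partition for a multi-label table
#'
#' Samples are first split into \code{L + 2} groups: one group per label
#' for samples carrying exactly that label, one group for samples carrying
#' exactly the designated label pair (default \{2, 3\}, transferases and
#' hydrolases — the dominant shared pair among human enzymes), and a
#' remainder group for every other combination. Each group is shuffled and
#' cut into K near-equal parts; part i of every group merges into fold i,
#' so fold label distributions track the whole dataset's.
#'
#' @param labels an \code{ec_labels} object (or named list of labelsets).
#' @param K number of folds.
#' @param seed integer seed.
#' @param pair_group length-2 integer vector naming the paired-label group.
#' @return An \code{ec_folds} object with \code{scheme = "stratified"} and
#'   a \code{stratum_of} named integer vector.
#' @export
make_folds_stratified <- function(labels, K, seed, pair_group = c(2L, 3L)) {
  K <- as.integer(K)
  if (K < 2L) stop_usage("K must be at least 2")
  L <- attr(labels, "L") %||% max(unlist(labels))
  ids <- names(labels)
  strata <- vapply(labels, stratum_of, integer(1), L = L, pair_group = pair_group)
  seeds <- derive_seeds(seed, L + 2L)
  fold_of <- stats::setNames(integer(length(ids)), ids)
  for (g in seq_len(L + 2L)) {
    gids <- ids[strata == g]
    if (length(gids) == 0L) next
    set.seed(seeds[g])
    perm <- sample(gids)
    fold_of[perm] <- rep_len(seq_len(K), length(gids))
  }
  structure(list(fold_of = fold_of, K = K, scheme = "stratified",
                 seed = as.integer(seed), pair_group = as.integer(pair_group),
                 stratum_of = strata),
            class = "ec_folds")
}

#' Leakage-safe K-fold cross-validation of the full pipeline
#'
#' For each fold, the domain-class profile is rebuilt from the K-1
#' training folds only, both partitions are encoded with that profile, a
#' RAKEL ensemble is fitted on the training encoding and applied to the
#' held-out fold. Per-fold recomputation of the profile is mandatory: the
#' encoding is a statistic of the training set, and computing it on the
#' full dataset would leak held-out label information into the features.
#'
#' @param dataset an \code{ec_dataset}.
#' @param folds an \code{ec_folds} over the same IDs.
#' @param k,m,base,threshold RAKEL configuration (see \code{\link{rakel_fit}}).
#' @param seed master seed; per-fold fitting seeds derive from it.
#' @param smoothing additive smoothing for \code{\link{build_profile}}.
#' @return An object of class \code{ec_cv}: per-fold overall metrics
#'   (\code{fold_metrics}), their \code{mean} and \code{sd}, pooled
#'   \code{per_class} metrics with AUROC/AUPR from the soft scores,
#'   out-of-fold \code{predictions} and \code{scores}, the \code{config}
#'   echo and the elapsed wall time.
#' @export
run_cv <- function(dataset, folds, k = 3, m = 10, base = base_rf(),
                   threshold = 0.5, seed = 1, smoothing = 0) {
  stopifnot(inherits(dataset, "ec_dataset"), inherits(folds, "ec_folds"))
  t0 <- proc.time()[["elapsed"]]
  ids <- dataset$ids
  if (!setequal(names(folds$fold_of), ids)) {
    stop_data("fold assignment and dataset do not share the same protein IDs")
  }
  K <- folds$K
  L <- dataset$L
  fseeds <- derive_seeds(seed, K)
  pred_sets <- stats::setNames(vector("list", length(ids)), ids)
  soft <- matrix(NA_real_, length(ids), L, dimnames = list(ids, NULL))
  fold_rows <- vector("list", K)
  for (f in seq_len(K)) {
    test_ids <- ids[folds$fold_of[ids] == f]
    train_ids <- ids[folds$fold_of[ids] != f]
    if (length(train_ids) == 0L) stop_data("fold ", f, " has an empty training part")
    if (length(test_ids) == 0L) next
    tr <- subset_dataset(dataset, train_ids)
    te <- subset_dataset(dataset, test_ids)
    profile <- build_profile(tr, smoothing)
    Xtr <- encode_dataset(tr, profile)
    Xte <- encode_dataset(te, profile)
    model <- rakel_fit(Xtr, tr$labels, L, k = k, m = m, base = base,
                       threshold = threshold, seed = fseeds[f])
    pr <- predict(model, Xte)
    pred_sets[test_ids] <- pr$sets
    soft[test_ids, ] <- rakel_scores_soft(model, Xte)
    om <- overall_metrics(te$labels, pr$sets, M = L)
    fold_rows[[f]] <- data.frame(fold = f,
                                 absolute_false = om$absolute_false,
                                 absolute_true = om$absolute_true,
                                 aiming = om$aiming,
                                 coverage = om$coverage,
                                 accuracy = om$accuracy,
                                 n_test = length(test_ids))
  }
  fold_metrics <- do.call(rbind, fold_rows)
  meas <- c("absolute_false", "absolute_true", "aiming", "coverage", "accuracy")
  summary_mean <- colMeans(fold_metrics[meas])
  summary_sd <- vapply(fold_metrics[meas], stats::sd, numeric(1))
  per_class <- per_class_metrics(dataset$labels, pred_sets, L,
                                 scores = soft, label_names = dataset$label_names)
  structure(list(fold_metrics = fold_metrics,
                 mean = summary_mean, sd = summary_sd,
                 per_class = per_class,
                 predictions = pred_sets, scores = soft,
                 config = list(K = K, scheme = folds$scheme,
                               fold_seed = folds$seed, k = k, m = m,
                               base = unclass(base), threshold = threshold,
                               seed = seed, smoothing = smoothing,
                               n = length(ids), L = L),
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "ec_cv")
}

#' @export
print.ec_cv <- function(x, ...) {
  cat(x$config$K, "-fold cross-validation (", x$config$scheme, " scheme), n = ",
      x$config$n, "\n", sep = "")
  print(round(x$mean, 4))
  invisible(x)
}

#' Serialize a cross-validation report to JSON
#'
#' Numbers are written at full precision. Wall time is excluded unless
#' requested, so reports from identical configurations and seeds are
#' byte-identical.
#'
#' @param report an \code{ec_cv} object.
#' @param path output path.
#' @param include_timing include the elapsed wall time.
#' @export
write_cv_report <- function(report, path, include_timing = FALSE) {
  stopifnot(inherits(report, "ec_cv"))
  out <- list(config = report$config,
              fold_metrics = report$fold_metrics,
              mean = as.list(report$mean),
              sd = as.list(report$sd),
              per_class = report$per_class,
              predictions = report$predictions)
  if (include_timing) out$elapsed_seconds <- report$elapsed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cross-validated grid search over RAKEL configurations
#'
#' Runs \code{\link{run_cv}} once per configuration on a fixed fold
#' assignment (folds are not re-randomised between lattice points, so the
#' comparison across configurations is paired) and ranks configurations by
#' accuracy (descending), ties broken by absolute true (descending) then
#' absolute false (ascending).
#'
#' @param dataset an \code{ec_dataset}.
#' @param folds an \code{ec_folds}.
#' @param grid list of configurations, each a list with elements \code{k},
#'   \code{m} and \code{base}; see \code{\link{default_grid}}.
#' @param seed master seed shared by all runs.
#' @param threshold vote threshold.
#' @return data.frame of ranked configurations with the five overall
#'   measures; the full \code{ec_cv} reports are attached as the
#'   \code{"reports"} attribute (in grid order).
#' @export
grid_search <- function(dataset, folds, grid, seed = 1, threshold = 0.5) {
  if (length(grid) == 0L) stop_usage("empty parameter grid")
  reports <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    g <- grid[[i]]
    cv <- run_cv(dataset, folds, k = g$k, m = g$m, base = g$base,
                 threshold = threshold, seed = seed)
    reports[[i]] <- cv
    rows[[i]] <- data.frame(config = i, k = g$k, m = g$m,
                            base = base_label(g$base),
                            absolute_false = cv$mean[["absolute_false"]],
                            absolute_true = cv$mean[["absolute_true"]],
                            aiming = cv$mean[["aiming"]],
                            coverage = cv$mean[["coverage"]],
                            accuracy = cv$mean[["accuracy"]],
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$accuracy, -tab$absolute_true, tab$absolute_false)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "reports") <- reports
  tab
}

#' Default parameter lattice
#'
#' Mirrors the canonical tuning ranges: \code{k} in \{3, 5, 7\} with
#' \code{m = 10}; random forests with tree counts spanning [80, 500]; SVMs
#' with \code{C} in \{0.5, 1, 3, 5, 7\} and the four kernels (polynomial
#' and normalised-polynomial exponents 1..3, RBF gamma in [0.1, 3]).
#' The full lattice is large; pass a subset for quick experiments.
#'
#' @param ks RAKEL subset sizes.
#' @param m ensemble size.
#' @param rf_trees random-forest tree counts.
#' @param svm_C SVM regularisation constants.
#' @param poly_e polynomial exponents.
#' @param rbf_gamma RBF widths.
#' @param include_svm include the SVM arm of the lattice.
#' @return list of configurations for \code{\link{grid_search}}.
#' @export
default_grid <- function(ks = c(3, 5, 7), m = 10,
                         rf_trees = c(80, 200, 350, 500),
                         svm_C = c(0.5, 1, 3, 5, 7),
                         poly_e = 1:3, rbf_gamma = c(0.1, 1, 3),
                         include_svm = TRUE) {
  grid <- list()
  for (k in ks) {
    for (tr in rf_trees) {
      grid[[length(grid) + 1L]] <- list(k = k, m = m, base = base_rf(tr))
    }
    if (include_svm) {
      for (C in svm_C) {
        for (e in poly_e) {
          grid[[length(grid) + 1L]] <- list(k = k, m = m, base = base_svm(C, "polynomial", degree = e))
          grid[[length(grid) + 1L]] <- list(k = k, m = m, base = base_svm(C, "normalized_polynomial", degree = e))
        }
        for (g in rbf_gamma) {
          grid[[length(grid) + 1L]] <- list(k = k, m = m, base = base_svm(C, "rbf", gamma = g))
        }
        grid[[length(grid) + 1L]] <- list(k = k, m = m, base = base_svm(C, "puk"))
      }
    }
  }
  grid
}

#' Performance stratified by annotation count
#'
#' Splits the proteins into the \code{n_extreme} most-annotated, the
#' \code{n_extreme} least-annotated and the remainder, and computes the
#' overall measures within each group. Proteins are sorted once by
#' ascending term count with ties broken by their order in the dataset, so
#' the grouping is deterministic.
#'
#' @param dataset an \code{ec_dataset}.
#' @param predictions named list of predicted labelsets covering the
#'   dataset IDs (e.g. \code{$predictions} of an \code{ec_cv}).
#' @param n_extreme group size for the two extreme groups;
#'   \code{2 * n_extreme} must be smaller than the dataset.
#' @return named list of \code{ec_overall} objects (\code{few},
#'   \code{middle}, \code{many}) with group IDs attached as the
#'   \code{"groups"} attribute.
#' @export
stratify_by_annotation_count <- function(dataset, predictions, n_extreme = 100) {
  stopifnot(inherits(dataset, "ec_dataset"))
  n <- length(dataset$ids)
  if (n_extreme < 1L || 2L * n_extreme >= n) {
    stop_usage("n_extreme must satisfy 1 <= n_extreme and 2 * n_extreme < n")
  }
  if (!all(dataset$ids %in% names(predictions))) {
    stop_data("predictions must cover every dataset protein")
  }
  counts <- lengths(dataset$annotations)
  asc <- order(counts)  # stable: ties keep dataset order
  few <- dataset$ids[asc[seq_len(n_extreme)]]
  many <- dataset$ids[asc[seq.int(n - n_extreme + 1L, n)]]
  middle <- setdiff(dataset$ids, c(few, many))
  groups <- list(few = few, middle = middle, many = many)
  out <- lapply(groups, function(g) {
    overall_metrics(dataset$labels[g], predictions[g], M = dataset$L)
  })
  attr(out, "groups") <- groups
  out
}
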