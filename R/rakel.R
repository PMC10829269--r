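#' Sample the random k-labelsets collection
#'
#' Draws \code{m} independent uniform size-\code{k} subsets of \code{1..L}
#' (duplicates across the collection permitted — with \code{k = L} the only
#' possible subset repeats). A collection is valid only if every label
#' appears in at least one subset; a draw missing some label is discarded
#' and the whole collection redrawn with an advanced seed, within a bounded
#' retry budget.
#'
#' @param L number of labels.
#' @param k subset size, \code{1 <= k <= L}.
#' @param m number of subsets; \code{m * k >= L} or coverage is impossible.
#' @param seed integer seed.
#' @param max_retries redraw budget.
#' @return An object of class \code{ec_labelsets}: list with \code{subsets}
#'   (list of sorted integer vectors), \code{k}, \code{m}, \code{L},
#'   \code{seed}, \code{coverage} (per-label count of covering subsets).
#' @export
sample_labelsets <- function(L, k, m, seed, max_retries = 1000L) {
  L <- as.integer(L); k <- as.integer(k); m <- as.integer(m)
  if (k < 1L || k > L) stop_usage("k must lie in [1, L]")
  if (m < 1L) stop_usage("m must be positive")
  if (m * k < L) stop_data("label coverage unattainable: m * k < L")
  for (attempt in 0:max_retries) {
    set.seed(as.integer(seed) + attempt)
    subsets <- lapply(seq_len(m), function(i) sort(sample.int(L, k)))
    cov <- tabulate(unlist(subsets), nbins = L)
    if (all(cov > 0L)) {
      return(structure(list(subsets = subsets, k = k, m = m, L = L,
                            seed = as.integer(seed), coverage = cov),
                       class = "ec_labelsets"))
    }
  }
  stop_data("could not draw a label-covering collection within ",
            max_retries, " retries (L=", L, ", k=", k, ", m=", m, ")")
}

#' Label-powerset transformation of a multi-label problem
#'
#' Projects each sample's labelset onto a subset of labels and treats every
#' observed projection (possibly the empty set) as one single-label class.
#' The class alphabet is built from observed projections only.
#'
#' @param Y list of integer labelsets (one per sample).
#' @param subset integer vector of labels defining the projection.
#' @return list with \code{classes} (factor of canonical labelset keys) and
#'   \code{mapping} (\code{forward}: key -> class index; \code{inverse}:
#'   list of integer labelsets per class).
#' @export
lp_transform <- function(Y, subset) {
  keys <- vapply(Y, function(y) labelset_key(intersect(y, subset)), character(1))
  lev <- sort(unique(keys))
  classes <- factor(keys, levels = lev)
  inverse <- lapply(lev, parse_labelset_key)
  names(inverse) <- lev
  list(classes = classes,
       mapping = list(forward = stats::setNames(seq_along(lev), lev),
                      inverse = inverse))
}

#' Fit a random k-labelsets ensemble
#'
#' Samples \code{m} size-\code{k} labelsets, label-powerset-transforms the
#' training labels on each, and fits one base classifier per subset. One
#' master seed derives the labelset-sampling seed and one fitting seed per
#' member, so a refit with the same data, parameters and seed reproduces
#' the model exactly.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param Y list of nonempty integer labelsets, one per row of \code{X}.
#' @param L number of labels.
#' @param k,m RAKEL parameters (subset size, ensemble size).
#' @param base an \code{ec_base} learner specification.
#' @param threshold vote fraction at or above which a label is predicted
#'   (default 0.5, predicting positive at equality).
#' @param seed integer master seed.
#' @return An object of class \code{rakel}.
#' @export
rakel_fit <- function(X, Y, L, k = 3, m = 10, base = base_rf(),
                      threshold = 0.5, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) != length(Y)) stop_data("X rows and Y length differ")
  if (any(lengths(Y) == 0L)) stop_data("every training labelset must be nonempty")
  if (threshold <= 0 || threshold > 1) stop_usage("threshold must lie in (0, 1]")
  stopifnot(inherits(base, "ec_base"))
  seeds <- derive_seeds(seed, m + 1L)
  labelsets <- sample_labelsets(L, k, m, seeds[1L])
  models <- vector("list", m)
  for (s in seq_len(m)) {
    subset <- labelsets$subsets[[s]]
    tr <- lp_transform(Y, subset)
    models[[s]] <- list(subset = subset,
                        mapping = tr$mapping,
                        fit = fit_lp(X, tr$classes, base, seeds[1L + s]))
  }
  structure(list(labelsets = labelsets, models = models,
                 threshold = threshold, L = as.integer(L),
                 k = as.integer(k), m = as.integer(m),
                 base = base, seed = as.integer(seed),
                 n_features = ncol(X), feature_names = colnames(X)),
            class = "rakel")
}

#' @export
print.rakel <- function(x, ...) {
  cat("RAKEL ensemble:", x$m, "label-powerset models, k =", x$k,
      ", L =", x$L, ", base", base_label(x$base), "\n")
  invisible(x)
}

check_predict_input <- function(object, X) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stop_data("feature count mismatch: model expects ", object$n_features,
              " columns, got ", ncol(X))
  }
  X
}

#' Predict label subsets with a RAKEL ensemble
#'
#' Each member predicts a label-powerset class over its subset, which is
#' inverse-mapped to a labelset. For label \code{l}, the hard score is the
#' fraction of covering members (those whose subset contains \code{l}) that
#' voted for \code{l}; \code{l} is predicted when the score reaches the
#' model threshold. A sample whose thresholded set would be empty receives
#' its single highest-scoring label (ties broken toward the lowest index),
#' so predictions are never empty.
#'
#' @param object a \code{rakel} model.
#' @param X feature matrix with the training column count.
#' @param ... unused.
#' @return list with \code{sets} (list of predicted integer labelsets) and
#'   \code{scores} (n x L hard vote-fraction matrix in [0, 1]).
#' @export
predict.rakel <- function(object, X, ...) {
  X <- check_predict_input(object, X)
  n <- nrow(X); L <- object$L
  votes <- matrix(0, n, L)
  for (mod in object$models) {
    keys <- predict_lp(mod$fit, X)
    # match() rather than name indexing: the empty-set key "" is a legal name
    sets <- mod$mapping$inverse[match(keys, names(mod$mapping$inverse))]
    for (l in mod$subset) {
      votes[, l] <- votes[, l] + vapply(sets, function(s) l %in% s, logical(1))
    }
  }
  scores <- sweep(votes, 2L, object$labelsets$coverage, "/")
  rownames(scores) <- rownames(X)
  sets <- apply_threshold(scores, object$threshold)
  if (!is.null(rownames(X))) names(sets) <- rownames(X)
  list(sets = sets, scores = scores)
}

# Threshold score rows into labelsets with the argmax fallback.
apply_threshold <- function(scores, threshold) {
  lapply(seq_len(nrow(scores)), function(i) {
    hit <- which(scores[i, ] >= threshold)
    if (length(hit) == 0L) hit <- which.max(scores[i, ])
    as.integer(hit)
  })
}

# Per-label probability mass of one LP member: for each covered label, the
# summed probability of the LP classes whose labelset contains it.
lp_mass_to_label_scores <- function(P, inverse, subset, L) {
  stopifnot(ncol(P) == length(inverse))
  out <- matrix(0, nrow(P), L)
  for (l in subset) {
    has <- vapply(inverse, function(s) l %in% s, logical(1))
    if (any(has)) out[, l] <- rowSums(P[, has, drop = FALSE])
  }
  out
}

#' Soft per-label scores from class-membership probabilities
#'
#' Label \code{l}'s score is the mean, over members covering \code{l}, of
#' the summed probability of the label-powerset classes whose labelset
#' contains \code{l}. These graded scores feed the ROC / precision-recall
#' analyses; set prediction always uses the hard vote fractions. Members
#' whose fitted learner cannot emit probabilities fall back to their hard
#' votes, with a warning.
#'
#' @param model a \code{rakel} model.
#' @param X feature matrix.
#' @return n x L numeric matrix with entries in [0, 1].
#' @export
rakel_scores_soft <- function(model, X) {
  X <- check_predict_input(model, X)
  n <- nrow(X); L <- model$L
  acc <- matrix(0, n, L)
  fell_back <- FALSE
  for (mod in model$models) {
    P <- predict_lp_prob(mod$fit, X)
    if (is.null(P)) {
      fell_back <- TRUE
      keys <- predict_lp(mod$fit, X)
      lev <- names(mod$mapping$inverse)
      P <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
      P[cbind(seq_len(n), match(keys, lev))] <- 1
    }
    acc <- acc + lp_mass_to_label_scores(P, mod$mapping$inverse, mod$subset, L)
  }
  if (fell_back) {
    warning("some ensemble members lack probability support; ",
            "their hard votes were used for the soft scores")
  }
  scores <- sweep(acc, 2L, model$labelsets$coverage, "/")
  rownames(scores) <- rownames(X)
  scores
}

#' Save / load a fitted RAKEL model bundle
#'
#' Writes a directory holding a JSON manifest (format version, dimensions,
#' parameters, labelsets and the training profile when supplied) next to
#' the serialized fitted members.
#'
#' @param model a \code{rakel} model.
#' @param dir bundle directory (created if needed).
#' @param profile optional \code{ec_profile} used to train the model; when
#'   present, prediction from raw annotation tables becomes possible.
#' @export
save_rakel <- function(model, dir, profile = NULL) {
  stopifnot(inherits(model, "rakel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = "ecfam-rakel", version = 1L,
                   L = model$L, k = model$k, m = model$m,
                   threshold = model$threshold, seed = model$seed,
                   base = unclass(model$base),
                   labelsets = model$labelsets$subsets,
                   n_features = model$n_features)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  if (!is.null(profile)) write_profile(profile, file.path(dir, "profile.tsv"))
  invisible(dir)
}

#' @rdname save_rakel
#' @return \code{load_rakel}: list with \code{model} and \code{profile}
#'   (NULL when the bundle has none).
#' @export
load_rakel <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_data("not a model bundle (missing manifest): ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "ecfam-rakel")) {
    stop_data("unrecognised model bundle format in ", dir)
  }
  model <- readRDS(file.path(dir, "model.rds"))
  prof_path <- file.path(dir, "profile.tsv")
  profile <- if (file.exists(prof_path)) read_profile(prof_path, manifest$L) else NULL
  list(model = model, profile = profile, manifest = manifest)
}
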