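# Base single-label learners plugged into the label-powerset problems.
# The contract is fit / predict-class / predict-probability; any learner
# honouring it can stand behind a RAKEL ensemble.

#' Base classifier specifications
#'
#' \code{base_rf} is a random forest with \code{ntree} decision trees.
#' \code{base_svm} is a support vector machine with one of four kernels:
#' \code{"polynomial"} ((x.y + 1)^e), \code{"normalized_polynomial"}
#' (the polynomial kernel normalised to unit self-similarity),
#' \code{"puk"} (the Pearson VII universal kernel with shape parameters
#' \code{omega} and \code{sigma}, both defaulting to 1) and \code{"rbf"}
#' (Gaussian, parameter \code{gamma}).
#'
#' @param ntree number of trees (random forest).
#' @param C SVM regularisation constant.
#' @param kernel SVM kernel name.
#' @param degree polynomial exponent \code{e}.
#' @param gamma RBF width.
#' @param omega,sigma Pearson VII shape parameters.
#' @return An object of class \code{ec_base} describing the learner.
#' @export
base_rf <- function(ntree = 500) {
  stopifnot(ntree >= 1)
  structure(list(algorithm = "random_forest", ntree = as.integer(ntree)),
            class = "ec_base")
}

#' @rdname base_rf
#' @export
base_svm <- function(C = 1,
                     kernel = c("rbf", "polynomial", "normalized_polynomial", "puk"),
                     degree = 1, gamma = 0.1, omega = 1, sigma = 1) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, degree >= 1, gamma > 0, omega > 0, sigma > 0)
  structure(list(algorithm = "svm", C = C, kernel = kernel,
                 degree = degree, gamma = gamma, omega = omega, sigma = sigma),
            class = "ec_base")
}

# Short human-readable tag used in grid-search tables and reports.
base_label <- function(base) {
  if (base$algorithm == "random_forest") {
    sprintf("rf(ntree=%d)", base$ntree)
  } else {
    switch(base$kernel,
      rbf = sprintf("svm(rbf, C=%g, gamma=%g)", base$C, base$gamma),
      polynomial = sprintf("svm(poly, C=%g, e=%g)", base$C, base$degree),
      normalized_polynomial = sprintf("svm(npoly, C=%g, e=%g)", base$C, base$degree),
      puk = sprintf("svm(puk, C=%g, omega=%g, sigma=%g)", base$C, base$omega, base$sigma))
  }
}

# kernlab kernel object for an SVM spec; the normalised-polynomial and
# Pearson VII kernels are supplied as custom kernel functions.
svm_kernel <- function(base) {
  switch(base$kernel,
    rbf = kernlab::rbfdot(sigma = base$gamma),
    polynomial = kernlab::polydot(degree = base$degree, scale = 1, offset = 1),
    normalized_polynomial = {
      d <- base$degree
      k <- function(x, y) {
        (sum(x * y) + 1)^d / sqrt(((sum(x * x) + 1)^d) * ((sum(y * y) + 1)^d))
      }
      class(k) <- "kernel"
      k
    },
    puk = {
      omega <- base$omega; sigma <- base$sigma
      cst <- (2 * sqrt(2^(1 / omega) - 1) / sigma)^2
      k <- function(x, y) {
        1 / (1 + cst * sum((x - y)^2))^omega
      }
      class(k) <- "kernel"
      k
    })
}

# Fit one label-powerset problem. A problem with a single observed class is
# fitted as a constant predictor rather than erroring.
fit_lp <- function(X, y, base, seed) {
  stopifnot(is.factor(y), nrow(X) == length(y))
  lv <- levels(y)
  if (length(lv) == 1L) {
    return(structure(list(level = lv), class = "lp_constant"))
  }
  set.seed(as.integer(seed))
  if (base$algorithm == "random_forest") {
    fit <- randomForest::randomForest(x = X, y = y, ntree = base$ntree)
    structure(list(fit = fit, levels = lv), class = "lp_rf")
  } else {
    fit <- tryCatch(
      kernlab::ksvm(as.matrix(X), y, kernel = svm_kernel(base), C = base$C,
                    prob.model = TRUE, scaled = FALSE),
      error = function(e) NULL, warning = function(w) NULL)
    has_prob <- !is.null(fit)
    if (is.null(fit)) {
      set.seed(as.integer(seed))
      fit <- kernlab::ksvm(as.matrix(X), y, kernel = svm_kernel(base),
                           C = base$C, prob.model = FALSE, scaled = FALSE)
    }
    structure(list(fit = fit, levels = lv, has_prob = has_prob),
              class = "lp_svm")
  }
}

# Hard class prediction: character vector of labelset keys.
predict_lp <- function(model, X) {
  switch(class(model)[1L],
    lp_constant = rep(model$level, nrow(X)),
    lp_rf = as.character(predict(model$fit, X)),
    lp_svm = as.character(predict(model$fit, as.matrix(X))),
    stop("unknown LP model class"))
}

# Class-membership probabilities (n x levels), or NULL when the fitted
# learner cannot provide them.
predict_lp_prob <- function(model, X) {
  switch(class(model)[1L],
    lp_constant = {
      P <- matrix(1, nrow = nrow(X), ncol = 1L,
                  dimnames = list(NULL, model$level))
      P
    },
    lp_rf = {
      P <- predict(model$fit, X, type = "prob")
      P[, match(model$levels, colnames(P)), drop = FALSE]
    },
    lp_svm = {
      if (!isTRUE(model$has_prob)) return(NULL)
      P <- tryCatch(
        predict(model$fit, as.matrix(X), type = "probabilities"),
        error = function(e) NULL)
      if (is.null(P)) return(NULL)
      P[, match(model$levels, colnames(P)), drop = FALSE]
    },
    NULL)
}
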