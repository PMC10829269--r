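#' Build the class-conditional domain profile from a training dataset
#'
#' For every functional-domain term seen in training, the profile records
#' \code{N}, the number of training proteins annotated by the term; the
#' per-class counts \code{N_j} (a protein with labels \{1,3\} increments
#' \code{N_1} and \code{N_3} but \code{N} only once); and the ratios
#' \code{R_j = N_j / N}, the proportion of the term's carriers that belong
#' to class \code{j}. The ratio matrix is the entire representation the
#' compact encoder needs, and the profile is strictly a function of the
#' training set: test data must never enter it (cross-validation rebuilds
#' it per fold).
#'
#' An optional additive smoothing constant \code{a} replaces the raw ratio
#' with \code{(N_j + a) / (N + 2a)}; the default \code{a = 0} keeps the raw
#' ratios.
#'
#' @param train an \code{ec_dataset}; every protein must carry at least one
#'   label and at least one protein must carry at least one term.
#' @param smoothing nonnegative additive smoothing constant (default 0).
#' @return An object of class \code{ec_profile} with components
#'   \code{vocabulary} (sorted term IDs), \code{N} (named integer),
#'   \code{Nj} and \code{R} (m x L matrices, rows = vocabulary),
#'   \code{L}, \code{n_train}, \code{label_names}, \code{smoothing}.
#' @export
build_profile <- function(train, smoothing = 0) {
  stopifnot(inherits(train, "ec_dataset"), smoothing >= 0)
  n <- length(train$ids)
  if (n == 0L) stop_data("empty training set")
  if (any(lengths(train$labels) == 0L)) {
    stop_data("every training protein must carry at least one label")
  }
  L <- train$L
  term_counts <- lengths(train$annotations)
  terms_all <- unlist(train$annotations, use.names = FALSE)
  if (length(terms_all) == 0L) stop_data("no annotated terms in the training set")
  vocab <- sort(unique(terms_all))
  m <- length(vocab)
  inc <- Matrix::sparseMatrix(i = match(terms_all, vocab),
                              j = rep.int(seq_len(n), term_counts),
                              x = 1, dims = c(m, n))
  Y <- matrix(0, nrow = n, ncol = L)
  Y[cbind(rep.int(seq_len(n), lengths(train$labels)),
          unlist(train$labels, use.names = FALSE))] <- 1
  N <- as.integer(Matrix::rowSums(inc))
  names(N) <- vocab
  Nj <- as.matrix(inc %*% Y)
  dimnames(Nj) <- list(vocab, paste0("N", seq_len(L)))
  R <- (Nj + smoothing) / (N + 2 * smoothing)
  colnames(R) <- paste0("R", seq_len(L))
  # Counting invariants: every carrier has >= 1 label, so the per-class
  # counts dominate N; raw ratios live in [0, 1].
  stopifnot(all(N >= 1L), all(Nj <= N), all(rowSums(Nj) >= N),
            all(R >= 0), all(R <= 1))
  structure(list(vocabulary = vocab, N = N, Nj = Nj, R = R,
                 L = L, n_train = n,
                 label_names = train$label_names,
                 smoothing = smoothing),
            class = "ec_profile")
}

#' @export
print.ec_profile <- function(x, ...) {
  cat("Domain-class profile:", length(x$vocabulary), "terms over",
      x$n_train, "training proteins, L =", x$L, "\n")
  excl <- sum(apply(x$R == 1, 1L, any) & rowSums(x$Nj > 0) == 1L)
  cat("  class-exclusive terms:", excl, "\n")
  invisible(x)
}

#' Encode one protein into the compact L-vector
#'
#' Component \code{j} is the maximum \code{R_j} over the protein's terms
#' that exist in the profile vocabulary. Terms unseen in training carry no
#' ratio and are skipped; a protein with no known term encodes to the zero
#' vector (flagged by \code{n_known_terms = 0}) rather than erroring, since
#' a classifier must still emit a prediction for it.
#'
#' @param p_terms character vector of term IDs.
#' @param profile an \code{ec_profile}.
#' @return list with \code{x} (length-L numeric, names \code{X1..XL}) and
#'   \code{n_known_terms}.
#' @export
encode_protein <- function(p_terms, profile) {
  stopifnot(inherits(profile, "ec_profile"))
  idx <- match(unique(as.character(p_terms)), profile$vocabulary)
  idx <- idx[!is.na(idx)]
  x <- if (length(idx) == 0L) {
    numeric(profile$L)
  } else if (length(idx) == 1L) {
    profile$R[idx, ]
  } else {
    apply(profile$R[idx, , drop = FALSE], 2L, max)
  }
  names(x) <- paste0("X", seq_len(profile$L))
  list(x = x, n_known_terms = length(idx))
}

#' Encode every protein of a dataset into a feature matrix
#'
#' Rows follow the dataset's ID order; columns are \code{X1..XL}.
#'
#' @param dataset an \code{ec_dataset}.
#' @param profile an \code{ec_profile} built from a training set.
#' @return numeric matrix (n x L) with protein IDs as row names and an
#'   \code{n_known_terms} integer attribute.
#' @export
encode_dataset <- function(dataset, profile) {
  stopifnot(inherits(dataset, "ec_dataset"))
  n <- length(dataset$ids)
  X <- matrix(0, nrow = n, ncol = profile$L,
              dimnames = list(dataset$ids, paste0("X", seq_len(profile$L))))
  known <- integer(n)
  for (i in seq_len(n)) {
    e <- encode_protein(dataset$annotations[[i]], profile)
    X[i, ] <- e$x
    known[i] <- e$n_known_terms
  }
  attr(X, "n_known_terms") <- known
  X
}

#' Binary functional-domain-composition vector
#'
#' The classical baseline representation: one 0/1 component per vocabulary
#' term, 1 iff the term is annotated to the protein. Its dimension equals
#' the training vocabulary size, which is what the compact encoding avoids.
#'
#' @param p_terms character vector of term IDs.
#' @param vocabulary ordered character vector of training terms.
#' @return integer 0/1 vector of length \code{length(vocabulary)}, named by
#'   the vocabulary.
#' @export
encode_binary_fdc <- function(p_terms, vocabulary) {
  v <- as.integer(vocabulary %in% p_terms)
  names(v) <- vocabulary
  v
}

#' Write / read a domain-class profile as TSV
#'
#' One row per term: \code{term<TAB>N<TAB>N_1..N_L<TAB>R_1..R_L}. This is
#' the exportable term-by-class ratio matrix suitable for heat-map style
#' inspection of class-exclusive terms.
#'
#' @param profile an \code{ec_profile}.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ec_profile"))
  df <- data.frame(term = profile$vocabulary,
                   N = profile$N,
                   profile$Nj,
                   profile$R,
                   check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param L number of classes expected in the file.
#' @param label_names optional display names.
#' @export
read_profile <- function(path, L, label_names = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("term", "N", paste0("N", seq_len(L)), paste0("R", seq_len(L)))
  if (!all(need %in% names(df))) stop_data("profile file lacks required columns for L = ", L)
  N <- as.integer(df$N); names(N) <- df$term
  Nj <- as.matrix(df[paste0("N", seq_len(L))])
  R <- as.matrix(df[paste0("R", seq_len(L))])
  rownames(Nj) <- rownames(R) <- df$term
  structure(list(vocabulary = df$term, N = N, Nj = Nj, R = R,
                 L = as.integer(L), n_train = NA_integer_,
                 label_names = label_names %||% default_label_names(L),
                 smoothing = NA_real_),
            class = "ec_profile")
}
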