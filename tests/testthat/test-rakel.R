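test_that("labelset sampling covers every label and honours degenerate cases", {
  # k = L: the only possible subset, repeated m times
  ls <- sample_labelsets(7, 7, 10, seed = 1)
  expect_true(all(vapply(ls$subsets, identical, logical(1), 1:7)))
  expect_equal(ls$coverage, rep(10L, 7))

  # k = 1, m = L: the only covering collection is the L singletons
  ls1 <- sample_labelsets(7, 1, 7, seed = 1)
  expect_setequal(unlist(ls1$subsets), 1:7)

  # general case: exhaustive membership check over many draws
  for (seed in 1:10) {
    ls3 <- sample_labelsets(7, 3, 10, seed = seed)
    expect_true(all(lengths(ls3$subsets) == 3L))
    expect_true(all(1:7 %in% unlist(ls3$subsets)))
  }

  expect_error(sample_labelsets(7, 3, 2, seed = 1), "unattainable")
  expect_error(sample_labelsets(7, 9, 2, seed = 1), "k must lie")
})

test_that("label-powerset transformation projects onto the subset", {
  tr <- lp_transform(list(1L, 2L, 1L), subset = c(1L, 2L))
  expect_equal(as.character(tr$classes), c("1", "2", "1"))
  expect_equal(nlevels(tr$classes), 2L)

  tr2 <- lp_transform(list(c(1L, 3L)), subset = c(1L, 2L))
  expect_equal(tr2$mapping$inverse[[as.character(tr2$classes[1])]], 1L)

  # projecting away every label yields the legitimate empty-set class
  tr3 <- lp_transform(list(3L, 1L), subset = c(1L, 2L))
  expect_equal(as.character(tr3$classes), c("{}", "1"))
  expect_equal(tr3$mapping$inverse[["{}"]], integer(0))
})

fit_toy_rakel <- function(ds, k, m, seed = 5, base = base_rf(50)) {
  prof <- build_profile(ds)
  X <- encode_dataset(ds, prof)
  list(X = X, model = rakel_fit(X, ds$labels, ds$L, k = k, m = m,
                                base = base, seed = seed))
}

test_that("the ensemble with k = L, m = 1 degenerates to plain label powerset", {
  ds <- separable_corpus(n = 120, seed = 2, multi_label_rate = 0.1)
  ft <- fit_toy_rakel(ds, k = 7, m = 1)
  pr <- predict(ft$model, ft$X)

  # independent LP: same transformation and the member's fitting seed
  seeds <- ecfam:::derive_seeds(5, 2)
  tr <- lp_transform(ds$labels, 1:7)
  lp_fit <- ecfam:::fit_lp(ft$X, tr$classes, base_rf(50), seeds[2])
  keys <- ecfam:::predict_lp(lp_fit, ft$X)
  lp_sets <- lapply(keys, ecfam:::parse_labelset_key)
  expect_equal(unname(pr$sets), lp_sets)
})

test_that("refitting with the same seed reproduces labelsets and predictions", {
  ds <- separable_corpus(n = 100, seed = 3)
  a <- fit_toy_rakel(ds, k = 3, m = 6, seed = 11)
  b <- fit_toy_rakel(ds, k = 3, m = 6, seed = 11)
  expect_identical(a$model$labelsets$subsets, b$model$labelsets$subsets)
  expect_identical(predict(a$model, a$X)$sets, predict(b$model, b$X)$sets)
})

test_that("a separable corpus is learned exactly on its training set", {
  ds <- separable_corpus(n = 150, seed = 4, multi_label_rate = 0)
  ft <- fit_toy_rakel(ds, k = 7, m = 1)
  pr <- predict(ft$model, ft$X)
  om <- overall_metrics(ds$labels, pr$sets, M = 7)
  expect_equal(om$absolute_true, 1)
})

# Hand-assembled ensemble of constant members: votes are exactly countable.
constant_rakel <- function(levels_per_member, subsets, L, threshold = 0.5) {
  m <- length(subsets)
  models <- lapply(seq_len(m), function(s) {
    lev <- sort(unique(levels_per_member[[s]]))
    inverse <- lapply(lev, ecfam:::parse_labelset_key)
    names(inverse) <- lev
    list(subset = subsets[[s]],
         mapping = list(forward = setNames(seq_along(lev), lev), inverse = inverse),
         fit = structure(list(level = levels_per_member[[s]][1]),
                         class = "lp_constant"))
  })
  cov <- tabulate(unlist(subsets), nbins = L)
  structure(list(labelsets = list(subsets = subsets, k = length(subsets[[1]]),
                                  m = m, L = L, seed = 0L, coverage = cov),
                 models = models, threshold = threshold, L = L,
                 k = length(subsets[[1]]), m = m, base = base_rf(1),
                 seed = 0L, n_features = 2L, feature_names = c("X1", "X2")),
            class = "rakel")
}

test_that("per-label scores are vote fractions over covering members", {
  # label 1 covered by three members voting (yes, no, yes) -> score 2/3
  model <- constant_rakel(levels_per_member = list("1", "2", "1"),
                          subsets = list(c(1L, 2L), c(1L, 2L), c(1L, 2L)),
                          L = 2)
  X <- matrix(0, 1, 2, dimnames = list("s1", c("X1", "X2")))
  pr <- predict(model, X)
  expect_equal(unname(pr$scores[1, ]), c(2 / 3, 1 / 3))
  expect_equal(pr$sets[[1]], 1L)

  # hard scores live on the grid {0, 1/c, ..., 1}
  expect_true(all(abs(pr$scores * 3 - round(pr$scores * 3)) < 1e-12))
})

test_that("predicted labelsets are never empty (argmax fallback)", {
  # every member predicts the empty projection: all scores are zero
  model <- constant_rakel(levels_per_member = list("{}", "{}"),
                          subsets = list(c(1L, 2L), c(1L, 2L)),
                          L = 2)
  X <- matrix(0, 3, 2, dimnames = list(NULL, c("X1", "X2")))
  pr <- predict(model, X)
  expect_true(all(lengths(pr$sets) >= 1L))

  ds <- separable_corpus(n = 80, seed = 6)
  ft <- fit_toy_rakel(ds, k = 3, m = 5)
  pr2 <- predict(ft$model, matrix(stats::runif(35), 5, 7,
                                  dimnames = list(NULL, paste0("X", 1:7))))
  expect_true(all(lengths(pr2$sets) >= 1L))
})

test_that("soft scores sum the probability mass of label-containing classes", {
  P <- matrix(c(0.7, 0.2, 0.1), 1, 3,
              dimnames = list(NULL, c("1", "1,2", "{}")))
  inverse <- list("1" = 1L, "1,2" = c(1L, 2L), "{}" = integer(0))
  S <- ecfam:::lp_mass_to_label_scores(P, inverse, subset = c(1L, 2L), L = 2)
  expect_equal(unname(S[1, ]), c(0.9, 0.2))
})

test_that("soft scores equal hard votes for deterministic members and stay in [0,1]", {
  model <- constant_rakel(levels_per_member = list("1", "2", "1"),
                          subsets = list(c(1L, 2L), c(1L, 2L), c(1L, 2L)),
                          L = 2)
  X <- matrix(0, 2, 2, dimnames = list(NULL, c("X1", "X2")))
  expect_equal(rakel_scores_soft(model, X), predict(model, X)$scores,
               ignore_attr = TRUE)

  ds <- separable_corpus(n = 100, seed = 8, multi_label_rate = 0.1)
  ft <- fit_toy_rakel(ds, k = 3, m = 5)
  S <- rakel_scores_soft(ft$model, ft$X)
  expect_true(all(S >= 0 & S <= 1 + 1e-12))
})

test_that("an SVM base with each kernel fits and predicts nonempty labelsets", {
  ds <- separable_corpus(n = 80, seed = 9)
  prof <- build_profile(ds)
  X <- encode_dataset(ds, prof)
  for (kern in c("rbf", "polynomial", "normalized_polynomial", "puk")) {
    ft <- rakel_fit(X, ds$labels, 7, k = 7, m = 1,
                    base = base_svm(C = 1, kernel = kern), seed = 2)
    pr <- predict(ft, X)
    expect_true(all(lengths(pr$sets) >= 1L))
    om <- overall_metrics(ds$labels, pr$sets, M = 7)
    expect_gt(om$accuracy, 0.8)
  }
})

test_that("model bundles round-trip through save/load", {
  ds <- separable_corpus(n = 80, seed = 10)
  prof <- build_profile(ds)
  X <- encode_dataset(ds, prof)
  model <- rakel_fit(X, ds$labels, 7, k = 3, m = 5, base = base_rf(30), seed = 4)
  dir <- withr::local_tempdir()
  save_rakel(model, dir, profile = prof)
  back <- load_rakel(dir)
  expect_identical(predict(back$model, X)$sets, predict(model, X)$sets)
  expect_equal(back$profile$vocabulary, prof$vocabulary)
  expect_error(load_rakel(withr::local_tempdir()), "manifest")
})
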