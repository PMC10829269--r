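test_that("general folds partition the IDs into near-equal parts", {
  ids <- sprintf("p%03d", 1:100)
  f <- make_folds(ids, 10, seed = 1)
  expect_equal(unname(table(f$fold_of)), rep(10L, 10), ignore_attr = TRUE)

  f2 <- make_folds(sprintf("p%03d", 1:101), 10, seed = 1)
  sizes <- sort(as.integer(table(f2$fold_of)))
  expect_equal(sizes, c(rep(10L, 9), 11L))

  expect_identical(make_folds(ids, 10, seed = 3)$fold_of,
                   make_folds(ids, 10, seed = 3)$fold_of)
  expect_error(make_folds(ids[1:5], 10, seed = 1), "fewer samples")

  # partition correctness on fuzzed inputs
  for (seed in 1:5) {
    n <- sample(20:80, 1)
    ids <- sprintf("q%03d", seq_len(n))
    f <- make_folds(ids, 7, seed = seed)
    expect_setequal(names(f$fold_of), ids)
    expect_true(all(f$fold_of %in% 1:7))
    expect_lte(diff(range(table(factor(f$fold_of, levels = 1:7)))), 1L)
  }
})

test_that("stratified folds group by exact labelset membership", {
  labs <- label_table(list(a = 1L, b = c(2L, 3L), c = c(1L, 4L), d = 2L,
                           e = c(2L, 3L), f = 7L), L = 7)
  f <- make_folds_stratified(labs, 2, seed = 1)
  # exactly {2,3} -> the pair group (index L+1); {1,4} -> remainder (L+2)
  expect_equal(unname(f$stratum_of[c("b", "e")]), c(8L, 8L))
  expect_equal(unname(f$stratum_of["c"]), 9L)
  expect_equal(unname(f$stratum_of[c("a", "d", "f")]), c(1L, 2L, 7L))

  # configurable pair group
  f2 <- make_folds_stratified(labs, 2, seed = 1, pair_group = c(1L, 4L))
  expect_equal(unname(f2$stratum_of["c"]), 8L)
  expect_equal(unname(f2$stratum_of["b"]), 9L)
})

test_that("stratified per-group fold counts are within one of an equal split", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 120
    labs <- label_table(setNames(rand_labelsets(n, 5, p_multi = 0.2),
                                 sprintf("p%03d", 1:n)), L = 5)
    K <- 4
    f <- make_folds_stratified(labs, K, seed = rep)
    expect_setequal(names(f$fold_of), names(labs))
    for (g in unique(f$stratum_of)) {
      gids <- names(labs)[f$stratum_of == g]
      per_fold <- table(factor(f$fold_of[gids], levels = 1:K))
      expect_lte(max(per_fold) - min(per_fold), 1L)
      expect_gte(min(per_fold), floor(length(gids) / K))
    }
  }
})

test_that("a term confined to the held-out fold never reaches the training profile", {
  ds <- separable_corpus(n = 120, seed = 13)
  folds <- make_folds(ds$ids, 4, seed = 2)
  test_ids <- ds$ids[folds$fold_of[ds$ids] == 1]
  train_ids <- setdiff(ds$ids, test_ids)

  ds2 <- ds
  victim <- test_ids[1]
  ds2$annotations[[victim]] <- c(ds2$annotations[[victim]], "IPRSENTINEL")

  p1 <- build_profile(ecfam:::subset_dataset(ds, train_ids))
  p2 <- build_profile(ecfam:::subset_dataset(ds2, train_ids))
  expect_identical(p1, p2)
  expect_false("IPRSENTINEL" %in% p2$vocabulary)
  expect_identical(encode_dataset(ecfam:::subset_dataset(ds, train_ids), p1),
                   encode_dataset(ecfam:::subset_dataset(ds2, train_ids), p2))
})

test_that("cross-validation reports are reproducible and internally consistent", {
  ds <- separable_corpus(n = 150, seed = 14, multi_label_rate = 0.05)
  folds <- make_folds(ds$ids, 5, seed = 4)
  cv1 <- run_cv(ds, folds, k = 3, m = 4, base = base_rf(30), seed = 9)
  cv2 <- run_cv(ds, folds, k = 3, m = 4, base = base_rf(30), seed = 9)
  expect_identical(cv1$fold_metrics, cv2$fold_metrics)
  expect_identical(cv1$predictions, cv2$predictions)

  # summary rows recompute from the per-fold table
  expect_equal(unname(cv1$mean["accuracy"]), mean(cv1$fold_metrics$accuracy))
  expect_equal(unname(cv1$sd["accuracy"]), sd(cv1$fold_metrics$accuracy))
  # every protein predicted exactly once, out of fold
  expect_true(all(lengths(cv1$predictions) >= 1L))
  expect_true(all(is.finite(cv1$scores)))
})

test_that("high-signal synthetic corpora are recovered accurately under CV", {
  ds <- separable_corpus(n = 300, seed = 15, multi_label_rate = 0.03)
  folds <- make_folds(ds$ids, 5, seed = 5)
  cv <- run_cv(ds, folds, k = 7, m = 3, base = base_rf(60), seed = 10)
  expect_gte(cv$mean[["accuracy"]], 0.95)

  # accuracy is stable to the fold seed on this corpus
  cv2 <- run_cv(ds, make_folds(ds$ids, 5, seed = 99), k = 7, m = 3,
                base = base_rf(60), seed = 10)
  expect_lt(abs(cv$mean[["accuracy"]] - cv2$mean[["accuracy"]]), 0.02)
})

test_that("grid search ranks configurations by accuracy with documented tie-breaks", {
  ds <- separable_corpus(n = 120, seed = 16)
  folds <- make_folds(ds$ids, 3, seed = 6)
  single <- grid_search(ds, folds, list(list(k = 3, m = 3, base = base_rf(20))), seed = 2)
  expect_equal(nrow(single), 1L)
  expect_equal(single$rank, 1L)

  grid <- list(list(k = 2, m = 4, base = base_rf(10)),
               list(k = 7, m = 2, base = base_rf(40)),
               list(k = 3, m = 3, base = base_rf(20)))
  tab <- grid_search(ds, folds, grid, seed = 2)
  resorted <- order(-tab$accuracy, -tab$absolute_true, tab$absolute_false)
  expect_equal(resorted, seq_len(nrow(tab)))  # already in ranked order
  expect_setequal(tab$config, 1:3)

  ks <- unique(vapply(default_grid(), function(g) g$k, numeric(1)))
  expect_setequal(ks, c(3, 5, 7))
})

test_that("annotation-count strata slice deterministically and match subset metrics", {
  ds <- separable_corpus(n = 100, seed = 17)
  folds <- make_folds(ds$ids, 4, seed = 7)
  cv <- run_cv(ds, folds, k = 7, m = 2, base = base_rf(30), seed = 3)
  strat <- stratify_by_annotation_count(ds, cv$predictions, n_extreme = 10)
  groups <- attr(strat, "groups")
  expect_equal(lengths(groups)[c("few", "many")], c(few = 10L, many = 10L))
  expect_setequal(unlist(groups), ds$ids)
  for (g in names(groups)) {
    manual <- overall_metrics(ds$labels[groups[[g]]],
                              cv$predictions[groups[[g]]], M = 7)
    expect_equal(strat[[g]]$accuracy, manual$accuracy)
    expect_equal(strat[[g]]$absolute_false, manual$absolute_false)
  }

  # equal term counts: groups are ID-ordered slices
  ann <- annotation_table(setNames(lapply(1:9, function(i) "T1"),
                                   sprintf("p%d", 1:9)))
  labs <- label_table(setNames(rep(list(1L), 9), sprintf("p%d", 1:9)), L = 2)
  flat <- join_dataset(ann, labs)
  preds <- setNames(rep(list(1L), 9), flat$ids)
  st <- stratify_by_annotation_count(flat, preds, n_extreme = 2)
  gr <- attr(st, "groups")
  expect_equal(gr$few, flat$ids[1:2])
  expect_equal(gr$many, flat$ids[8:9])
  expect_equal(st$few$accuracy, 1)
  expect_equal(st$many$accuracy, 1)
})
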