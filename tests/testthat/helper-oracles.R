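# Independent brute-force oracles and random-instance generators used
# across the suite. The oracles deliberately use a different computation
# path (0/1 bit matrices and pair counting) than the package (set ops).

labelsets_to_bits <- function(sets, L) {
  B <- matrix(0L, length(sets), L)
  for (i in seq_along(sets)) B[i, sets[[i]]] <- 1L
  B
}

# Eqs.-level overall measures recomputed from bit matrices.
bf_overall <- function(true_sets, pred_sets, M) {
  Tm <- labelsets_to_bits(true_sets, M)
  Pm <- labelsets_to_bits(pred_sets, M)
  inter <- rowSums(Tm * Pm)
  uni <- rowSums(pmax(Tm, Pm))
  list(aiming = mean(inter / rowSums(Pm)),
       coverage = mean(inter / rowSums(Tm)),
       accuracy = mean(inter / uni),
       absolute_true = mean(apply(Tm == Pm, 1L, all)),
       absolute_false = mean(rowSums(abs(Tm - Pm)) / M))
}

# One-vs-rest confusion counts from bit matrices.
bf_confusion <- function(true_sets, pred_sets, L) {
  Tm <- labelsets_to_bits(true_sets, L)
  Pm <- labelsets_to_bits(pred_sets, L)
  lapply(seq_len(L), function(j) {
    list(TP = sum(Tm[, j] == 1L & Pm[, j] == 1L),
         FP = sum(Tm[, j] == 0L & Pm[, j] == 1L),
         TN = sum(Tm[, j] == 0L & Pm[, j] == 0L),
         FN = sum(Tm[, j] == 1L & Pm[, j] == 0L))
  })
}

# AUROC by exhaustive positive-negative pair counting (ties count 1/2).
bf_auroc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Random nonempty labelsets (small multi-label rate, like enzyme data).
rand_labelsets <- function(N, L, p_multi = 0.3) {
  lapply(seq_len(N), function(i) {
    size <- if (stats::runif(1) < p_multi) sample(2:min(3L, L), 1L) else 1L
    sort(sample.int(L, size))
  })
}

# Random joined dataset built through the public constructors.
rand_dataset <- function(n = 30, L = 4, n_terms = 12, seed = 1) {
  set.seed(seed)
  terms <- sprintf("IPR%06d", seq_len(n_terms))
  ids <- sprintf("q%03d", seq_len(n))
  ann <- lapply(seq_len(n), function(i) sample(terms, sample.int(min(5L, n_terms), 1L)))
  names(ann) <- ids
  labs <- rand_labelsets(n, L)
  names(labs) <- ids
  join_dataset(annotation_table(ann), label_table(labs, L))
}

# Quick separable synthetic corpus for classifier tests.
separable_corpus <- function(n = 200, seed = 1, multi_label_rate = 0) {
  generate_dataset(synth_config(n_proteins = n, exclusivity = 1,
                                noise_terms = 0,
                                multi_label_rate = multi_label_rate,
                                seed = seed))$dataset
}
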