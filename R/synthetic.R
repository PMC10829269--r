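#' Configuration of the synthetic annotation corpus
#'
#' The generator emulates the statistical structure the compact encoder
#' relies on: every class owns a pool of enriched domain terms, a fraction
#' of which (\code{1 - exclusivity}) leaks to one other class; a pool of
#' class-unspecific shared terms plus off-class terms enter proteins only
#' through the noise channel; class sizes are skewed (defaults
#' proportional to the human benchmark breakdown, where transferases
#' dominate and translocases are rare); a protein receives a second label
#' with probability \code{multi_label_rate} (default 0.026, matching a
#' multiplicity degree of about 1.03); and per-protein term counts follow
#' a truncated geometric distribution on \code{terms_per_protein} (default
#' 1..25), so most proteins carry fewer than ten terms.
#'
#' @param n_proteins corpus size.
#' @param L number of classes.
#' @param terms_per_class enriched vocabulary size per class.
#' @param n_shared_terms number of class-unspecific terms.
#' @param exclusivity probability an enriched term stays exclusive.
#' @param multi_label_rate probability of a second label.
#' @param terms_per_protein integer range \code{c(min, max)}.
#' @param label_skew per-class weights.
#' @param noise_terms probability a drawn term slot is replaced by a
#'   uniform draw from the whole vocabulary.
#' @param seed master seed; all sub-draws derive from it.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_proteins = 2000, L = 7, terms_per_class = 40,
                         n_shared_terms = 20, exclusivity = 0.9,
                         multi_label_rate = 0.026,
                         terms_per_protein = c(1, 25),
                         label_skew = c(288, 1080, 747, 113, 80, 86, 51),
                         noise_terms = 0.05, seed = 1) {
  stopifnot(n_proteins >= 1, L >= 2, terms_per_class >= 1, n_shared_terms >= 0,
            exclusivity >= 0, exclusivity <= 1,
            multi_label_rate >= 0, multi_label_rate <= 1,
            length(terms_per_protein) == 2L,
            terms_per_protein[1L] >= 1,
            terms_per_protein[2L] >= terms_per_protein[1L],
            length(label_skew) == L, all(label_skew >= 0), sum(label_skew) > 0,
            noise_terms >= 0, noise_terms <= 1)
  structure(list(n_proteins = as.integer(n_proteins), L = as.integer(L),
                 terms_per_class = as.integer(terms_per_class),
                 n_shared_terms = as.integer(n_shared_terms),
                 exclusivity = exclusivity,
                 multi_label_rate = multi_label_rate,
                 terms_per_protein = as.integer(terms_per_protein),
                 label_skew = label_skew,
                 noise_terms = noise_terms,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Truncated geometric draw on lo..hi (success rate q); keeps most proteins
# lightly annotated while allowing the configured maximum.
rtrunc_geom <- function(n, lo, hi, q = 0.25) {
  sizes <- lo:hi
  w <- (1 - q)^(sizes - lo)
  sample(sizes, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a synthetic annotation/label corpus
#'
#' Fully reproducible from the config seed. Returns the dataset together
#' with the ground-truth term map (each enriched term's primary class and,
#' for leaked terms, its secondary class).
#'
#' @param config a \code{synth_config}.
#' @return list with \code{dataset} (an \code{ec_dataset}) and
#'   \code{term_map} (data.frame: term, type, primary_class,
#'   secondary_class).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  L <- config$L
  n <- config$n_proteins
  seeds <- derive_seeds(config$seed, 4L)

  n_enriched <- L * config$terms_per_class
  term_ids <- sprintf("IPR%06d", seq_len(n_enriched + config$n_shared_terms))
  primary <- c(rep(seq_len(L), each = config$terms_per_class),
               rep(NA_integer_, config$n_shared_terms))
  type <- c(rep("enriched", n_enriched), rep("shared", config$n_shared_terms))

  # Leakage: a non-exclusive enriched term also characterises one other class.
  set.seed(seeds[1L])
  secondary <- rep(NA_integer_, length(term_ids))
  leaks <- which(type == "enriched" &
                 stats::runif(length(term_ids)) > config$exclusivity)
  if (length(leaks)) {
    secondary[leaks] <- vapply(primary[leaks], function(pc) {
      sample(setdiff(seq_len(L), pc), 1L)
    }, integer(1))
  }

  set.seed(seeds[2L])
  lab1 <- sample.int(L, n, replace = TRUE, prob = config$label_skew)
  second <- stats::runif(n) < config$multi_label_rate
  labels <- lapply(seq_len(n), function(i) {
    if (!second[i]) return(lab1[i])
    w <- config$label_skew
    w[lab1[i]] <- 0
    sort(c(lab1[i], sample.int(L, 1L, prob = w)))
  })

  set.seed(seeds[3L])
  t_count <- rtrunc_geom(n, config$terms_per_protein[1L], config$terms_per_protein[2L])

  set.seed(seeds[4L])
  annotations <- vector("list", n)
  for (i in seq_len(n)) {
    ls <- labels[[i]]
    pool <- term_ids[type == "enriched" &
                     (primary %in% ls | secondary %in% ls)]
    tt <- sample(pool, min(t_count[i], length(pool)))
    noisy <- which(stats::runif(length(tt)) < config$noise_terms)
    for (j in noisy) {
      cand <- setdiff(term_ids, tt)
      if (length(cand)) tt[j] <- sample(cand, 1L)
    }
    annotations[[i]] <- tt
  }
  ids <- sprintf("SYN%05d", seq_len(n))
  names(annotations) <- names(labels) <- ids
  dataset <- new_dataset(ids = ids,
                         annotations = annotations,
                         labels = labels,
                         L = L,
                         label_names = default_label_names(L))
  term_map <- data.frame(term = term_ids, type = type,
                         primary_class = primary, secondary_class = secondary,
                         stringsAsFactors = FALSE)
  list(dataset = dataset, term_map = term_map)
}

#' Tiny fixed worked-example corpus
#'
#' Eight proteins, three classes and five terms, small enough that the
#' domain-class profile, the compact encodings and the label-powerset
#' classes can be written out and checked by hand. The expected profile
#' and encodings are documented in the methods vignette and frozen in the
#' test suite.
#'
#' @return An \code{ec_dataset} with \code{L = 3}.
#' @export
generate_worked_example <- function() {
  terms <- list(
    p1 = "IPR000001",
    p2 = c("IPR000001", "IPR000002"),
    p3 = "IPR000002",
    p4 = c("IPR000002", "IPR000003"),
    p5 = "IPR000003",
    p6 = "IPR000004",
    p7 = c("IPR000004", "IPR000005"),
    p8 = c("IPR000001", "IPR000005"))
  labels <- list(
    p1 = 1L, p2 = 1L, p3 = 2L, p4 = 2L,
    p5 = c(2L, 3L), p6 = 3L, p7 = 3L, p8 = c(1L, 3L))
  new_dataset(ids = names(terms),
              annotations = terms,
              labels = labels,
              L = 3L,
              label_names = paste0("EC", 1:3))
}
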