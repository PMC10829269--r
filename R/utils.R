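# Internal helpers shared across modules.

# Display names of the seven enzyme family classes (first EC digit).
EC_CLASS_NAMES <- c("Oxidoreductases", "Transferases", "Hydrolases",
                    "Lyases", "Isomerases", "Ligases", "Translocases")

default_label_names <- function(L) {
  if (L == 7L) EC_CLASS_NAMES else paste0("class", seq_len(L))
}

# Condition constructors: "usage" maps to CLI exit 2, "data" to exit 1.
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecfam_data_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecfam_usage_error", "error")))
}

# One master seed -> n reproducible sub-seeds (kept below 2^31).
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Canonical string key for a labelset; the empty set maps to "{}" (a bare
# "" cannot serve as a factor level for every base learner).
labelset_key <- function(labels) {
  if (length(labels) == 0L) return("{}")
  paste(sort(unique(as.integer(labels))), collapse = ",")
}

parse_labelset_key <- function(key) {
  if (identical(key, "{}") || !nzchar(key)) return(integer(0))
  as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
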