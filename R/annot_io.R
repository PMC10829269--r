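#' Annotation tables: protein -> set of functional-domain terms
#'
#' An annotation table maps each protein ID to the set of functional-domain
#' accessions (InterPro-style \code{IPR######} identifiers, treated as opaque
#' strings) annotated to it. Term sets are deduplicated; a protein may carry
#' an empty set, which downstream joins can drop or keep explicitly.
#'
#' @param entries named list; names are protein IDs, elements are character
#'   vectors of term IDs.
#' @return An object of class \code{ec_annotations}: a named list of unique,
#'   order-preserving term-ID vectors.
#' @export
annotation_table <- function(entries) {
  ids <- names(entries)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop_data("annotation entries must be named by nonempty protein IDs")
  }
  if (anyDuplicated(ids)) {
    stop_data("duplicate protein IDs in annotation table: ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  entries <- lapply(entries, function(tt) {
    tt <- as.character(tt)
    tt <- tt[nzchar(tt)]
    unique(tt)
  })
  structure(entries, class = "ec_annotations")
}

#' @export
print.ec_annotations <- function(x, ...) {
  cat("Annotation table:", length(x), "proteins,",
      length(unique(unlist(x, use.names = FALSE))), "distinct terms\n")
  ne <- sum(lengths(x) == 0L)
  if (ne > 0L) cat("  (", ne, " proteins with empty term sets)\n", sep = "")
  invisible(x)
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an annotation table from a TSV file
#'
#' Two dialects are supported. \code{"long"} (canonical) has one
#' \code{protein_id<TAB>term_id} pair per line; duplicate pairs are merged.
#' \code{"wide"} has one protein per line, \code{protein_id<TAB>term;term;...};
#' a repeated protein row is an error, and an empty second field yields an
#' empty term set. Lines starting with \code{#} are skipped.
#'
#' @param path path to a UTF-8, tab-separated text file.
#' @param dialect \code{"long"} or \code{"wide"}.
#' @return An \code{ec_annotations} object.
#' @export
read_annotations <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) stop_data("no records in ", path)
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (dialect == "long") {
    bad <- which(lengths(parts) != 2L | vapply(parts, function(p) any(!nzchar(p)), logical(1)))
    if (length(bad)) {
      stop_data("malformed long-dialect line ", tl$lineno[bad[1L]], " in ", path)
    }
    prot <- vapply(parts, `[`, character(1), 1L)
    term <- vapply(parts, `[`, character(1), 2L)
    annotation_table(split(term, factor(prot, levels = unique(prot))))
  } else {
    nf <- lengths(parts)
    bad <- which(nf < 1L | nf > 2L |
                 !vapply(parts, function(p) nzchar(p[1L]), logical(1)))
    if (length(bad)) {
      stop_data("malformed wide-dialect line ", tl$lineno[bad[1L]], " in ", path)
    }
    prot <- vapply(parts, `[`, character(1), 1L)
    if (anyDuplicated(prot)) {
      stop_data("duplicate protein row in wide-dialect file: ",
                prot[duplicated(prot)][1L])
    }
    terms <- lapply(parts, function(p) {
      if (length(p) < 2L || !nzchar(p[2L])) character(0)
      else strsplit(p[2L], ";", fixed = TRUE)[[1L]]
    })
    names(terms) <- prot
    annotation_table(terms)
  }
}

#' Write an annotation table to TSV
#'
#' @param x an \code{ec_annotations} object.
#' @param path output path.
#' @param dialect \code{"long"} (one pair per line; cannot represent empty
#'   term sets) or \code{"wide"}.
#' @export
write_annotations <- function(x, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "ec_annotations"))
  if (dialect == "long") {
    if (any(lengths(x) == 0L)) {
      stop_data("long dialect cannot represent empty term sets; use dialect = \"wide\"")
    }
    prot <- rep(names(x), lengths(x))
    lines <- paste(prot, unlist(x, use.names = FALSE), sep = "\t")
  } else {
    lines <- paste(names(x),
                   vapply(x, paste, character(1), collapse = ";"),
                   sep = "\t")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Label tables: protein -> nonempty subset of the L family classes
#'
#' Labels are 1-based class indices (\code{1..L}); for \code{L = 7} the
#' default display names are the seven enzyme family classes
#' (Oxidoreductases ... Translocases), i.e. the first digit of an EC number.
#'
#' @param entries named list of integer vectors (each nonempty, in 1..L).
#' @param L number of classes (>= 2).
#' @param label_names optional length-L character vector of display names.
#' @return An object of class \code{ec_labels} with attributes \code{L} and
#'   \code{label_names}.
#' @export
label_table <- function(entries, L, label_names = NULL) {
  L <- as.integer(L)
  if (L < 2L) stop_data("L must be at least 2")
  ids <- names(entries)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop_data("label entries must be named by nonempty protein IDs")
  }
  if (anyDuplicated(ids)) stop_data("duplicate protein IDs in label table")
  entries <- lapply(entries, function(ll) sort(unique(as.integer(ll))))
  sizes <- lengths(entries)
  if (any(sizes == 0L)) {
    stop_data("empty label set for protein ", ids[which(sizes == 0L)[1L]])
  }
  rng <- range(unlist(entries, use.names = FALSE))
  if (rng[1L] < 1L || rng[2L] > L) {
    stop_data("label out of range [1, ", L, "]")
  }
  label_names <- label_names %||% default_label_names(L)
  stopifnot(length(label_names) == L)
  structure(entries, class = "ec_labels", L = L, label_names = label_names)
}

#' @export
print.ec_labels <- function(x, ...) {
  cat("Label table:", length(x), "proteins, L =", attr(x, "L"),
      "classes; multiplicity degree", round(multiplicity_degree(x), 3), "\n")
  invisible(x)
}

#' Read a label table from TSV
#'
#' Rows are \code{protein_id<TAB>l1;l2;...} with 1-based integer labels.
#'
#' @inheritParams read_annotations
#' @param L number of classes.
#' @param label_names optional display names.
#' @return An \code{ec_labels} object.
#' @export
read_labels <- function(path, L, label_names = NULL) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) stop_data("no records in ", path)
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  # a line ending in a tab parses to a single field: an empty label set
  empty <- lengths(parts) == 1L & grepl("\t", tl$lines, fixed = TRUE)
  if (any(empty)) {
    stop_data("empty label set at line ", tl$lineno[which(empty)[1L]], " in ", path)
  }
  bad <- which(lengths(parts) != 2L | vapply(parts, function(p) !nzchar(p[1L]), logical(1)))
  if (length(bad)) stop_data("malformed label line ", tl$lineno[bad[1L]], " in ", path)
  prot <- vapply(parts, `[`, character(1), 1L)
  labs <- lapply(seq_along(parts), function(i) {
    fld <- parts[[i]][2L]
    if (!nzchar(fld)) stop_data("empty label set at line ", tl$lineno[i], " in ", path)
    vals <- suppressWarnings(as.integer(strsplit(fld, ";", fixed = TRUE)[[1L]]))
    if (anyNA(vals)) stop_data("non-integer label at line ", tl$lineno[i], " in ", path)
    vals
  })
  names(labs) <- prot
  tryCatch(label_table(labs, L, label_names),
           ecfam_data_error = function(e) stop_data(conditionMessage(e), " (", path, ")"))
}

#' Write a label table to TSV
#' @param x an \code{ec_labels} object.
#' @param path output path.
#' @export
write_labels <- function(x, path) {
  stopifnot(inherits(x, "ec_labels"))
  lines <- paste(names(x),
                 vapply(x, paste, character(1), collapse = ";"),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Join annotations and labels into a modelling dataset
#'
#' Takes the intersection of the two protein-ID sets and reports every
#' dropped ID with its reason, so dataset-cleaning decisions stay auditable.
#' With \code{on_missing_terms = "drop"}, proteins without any domain
#' annotation are removed (mirroring benchmark-set cleaning where enzymes
#' without functional-domain information are discarded); with \code{"keep"}
#' they are retained with empty term sets and encode to the zero vector.
#'
#' @param annotations an \code{ec_annotations} object.
#' @param labels an \code{ec_labels} object.
#' @param on_missing_terms \code{"drop"} or \code{"keep"}.
#' @return An object of class \code{ec_dataset} with components \code{ids},
#'   \code{annotations}, \code{labels}, \code{L}, \code{label_names} and a
#'   \code{join_report} data frame (\code{protein_id}, \code{reason}).
#' @export
join_dataset <- function(annotations, labels, on_missing_terms = c("drop", "keep")) {
  on_missing_terms <- match.arg(on_missing_terms)
  stopifnot(inherits(annotations, "ec_annotations"), inherits(labels, "ec_labels"))
  aid <- names(annotations)
  lid <- names(labels)
  common <- intersect(lid, aid)
  report <- data.frame(
    protein_id = c(setdiff(lid, aid), setdiff(aid, lid)),
    reason = c(rep("no_annotation", length(setdiff(lid, aid))),
               rep("no_label", length(setdiff(aid, lid)))),
    stringsAsFactors = FALSE)
  if (on_missing_terms == "drop") {
    empty <- common[lengths(annotations[common]) == 0L]
    if (length(empty)) {
      report <- rbind(report, data.frame(protein_id = empty,
                                         reason = "empty_term_set",
                                         stringsAsFactors = FALSE))
      common <- setdiff(common, empty)
    }
  }
  if (length(common) == 0L) stop_data("no proteins shared by the two tables after joining")
  new_dataset(ids = common,
              annotations = annotations[common],
              labels = labels[common],
              L = attr(labels, "L"),
              label_names = attr(labels, "label_names"),
              join_report = report)
}

# Internal dataset constructor (also used by the synthetic generator).
new_dataset <- function(ids, annotations, labels, L, label_names,
                        join_report = NULL) {
  structure(list(ids = ids,
                 annotations = annotations,
                 labels = labels,
                 L = as.integer(L),
                 label_names = label_names,
                 join_report = join_report),
            class = "ec_dataset")
}

#' @export
print.ec_dataset <- function(x, ...) {
  cat("Dataset:", length(x$ids), "proteins, L =", x$L, "classes,",
      length(unique(unlist(x$annotations, use.names = FALSE))), "distinct terms\n")
  if (!is.null(x$join_report) && nrow(x$join_report) > 0L) {
    cat("  join dropped", nrow(x$join_report), "proteins (see $join_report)\n")
  }
  invisible(x)
}

# Restrict a dataset to a subset of its IDs, preserving the given order.
subset_dataset <- function(dataset, ids) {
  stopifnot(all(ids %in% dataset$ids))
  new_dataset(ids = ids,
              annotations = dataset$annotations[ids],
              labels = dataset$labels[ids],
              L = dataset$L,
              label_names = dataset$label_names)
}
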