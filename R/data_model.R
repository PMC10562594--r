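#' Construct a study list
#'
#' A study list is an ordered set of unique words; the serial position of a
#' word is its 1-based index in `items`. Optionally, items can be tagged
#' with the identifier of a designated high-similarity pair, the structure
#' used to dissociate temporal from semantic contributions to recall.
#'
#' @param list_id character scalar naming the list.
#' @param items character vector of unique words, in study order.
#' @param pair_assignment optional vector (same length as `items`) giving,
#'   for each item, the identifier of its designated pair, or `NA` for
#'   filler items. Each non-`NA` identifier must occur exactly twice.
#' @return object of class `study_list` with fields `list_id`, `items`,
#'   `pair_assignment`.
#' @export
study_list <- function(list_id, items, pair_assignment = NULL) {
  stopifnot(is.character(items), length(items) >= 1L)
  list_id <- as.character(list_id)
  if (anyDuplicated(items)) {
    stop(sprintf("list '%s': duplicate word '%s'", list_id,
                 items[duplicated(items)][1L]))
  }
  if (!is.null(pair_assignment)) {
    if (length(pair_assignment) != length(items)) {
      stop(sprintf("list '%s': pair_assignment length mismatch", list_id))
    }
    tab <- table(pair_assignment[!is.na(pair_assignment)])
    if (length(tab) && any(tab != 2L)) {
      stop(sprintf("list '%s': pair '%s' has %d members (need 2)",
                   list_id, names(tab)[tab != 2L][1L], tab[tab != 2L][1L]))
    }
  }
  structure(
    list(list_id = list_id, items = items,
         pair_assignment = pair_assignment),
    class = "study_list"
  )
}

#' @export
print.study_list <- function(x, ...) {
  cat(sprintf("<study_list '%s'> %d items", x$list_id, length(x$items)))
  if (!is.null(x$pair_assignment)) {
    cat(sprintf(", %d designated pairs",
                length(unique(stats::na.omit(x$pair_assignment)))))
  }
  cat("\n")
  invisible(x)
}

#' Length of a study list
#' @param x a `study_list`.
#' @param ... unused.
#' @export
length.study_list <- function(x) length(x$items)

#' Construct a semantic similarity matrix
#'
#' Pairwise cosine-style similarities over a vocabulary, as produced by
#' vector-space models of word association. The matrix is validated to be
#' square with matching row/column vocabulary, symmetric (asymmetries up to
#' `tol` are averaged away, larger ones are an error), values in [0, 1],
#' and the diagonal is forced to 1.
#'
#' @param values square numeric matrix.
#' @param vocabulary character vector of words; defaults to the dimnames of
#'   `values`.
#' @param tol tolerance for symmetrisation (default 1e-9).
#' @return a `similarity_matrix`: a numeric matrix with word dimnames.
#' @export
similarity_matrix <- function(values, vocabulary = rownames(values),
                              tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop(sprintf("similarity matrix must be square (got %d x %d)",
                 nrow(values), ncol(values)))
  }
  if (is.null(vocabulary)) stop("similarity matrix needs a vocabulary")
  vocabulary <- as.character(vocabulary)
  if (length(vocabulary) != nrow(values) || anyDuplicated(vocabulary)) {
    stop("vocabulary must be unique and match the matrix dimension")
  }
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), vocabulary)) {
    stop("row/column vocabulary mismatch in similarity matrix")
  }
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop(sprintf("similarity matrix asymmetric beyond tolerance (max %.3g)",
                 asym))
  }
  values <- (values + t(values)) / 2
  diag(values) <- 1
  if (any(values < 0) || any(values > 1)) {
    bad <- values[values < 0 | values > 1][1L]
    stop(sprintf("similarity value %.4g outside [0, 1]", bad))
  }
  dimnames(values) <- list(vocabulary, vocabulary)
  class(values) <- c("similarity_matrix", "matrix", "array")
  values
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d words\n", nrow(x)))
  invisible(x)
}

#' Look up pairwise similarity values
#'
#' @param sim a `similarity_matrix`.
#' @param a,b words (character). Vectorised.
#' @return numeric similarity values.
#' @export
similarity <- function(sim, a, b) {
  miss <- setdiff(unique(c(a, b)), rownames(sim))
  if (length(miss)) {
    stop(sprintf("word(s) not in similarity vocabulary: %s",
                 paste(miss, collapse = ", ")))
  }
  sim[cbind(a, b)]
}

#' Construct a recall sequence
#'
#' One subject-by-condition transcript: the ordered raw responses typed
#' during the retrieval phase, optionally annotated (by
#' [resolve_responses()]) with the classification of each response as a
#' first-time correct recall, an extra-list intrusion (ELI), a prior-list
#' intrusion (PLI) or a repetition.
#'
#' @param subject_id,condition,condition_order identifiers; `condition` is
#'   one of `"same_context"`, `"different_context"`, `"control"`;
#'   `condition_order` (1 or 2) records which block came first.
#' @param responses character vector of raw typed responses, in output
#'   order, or a data.frame with columns `response` and optionally `type`
#'   and `serial_position`.
#' @param list_id optional id of the just-studied list this transcript
#'   refers to (used by cohort scoring to pick the right list).
#' @return object of class `recall_sequence`. The `responses` field is a
#'   data.frame with columns `output_position`, `response`, `type` (NA
#'   until resolved), `serial_position` (NA unless a correct recall).
#' @export
recall_sequence <- function(subject_id, condition, condition_order,
                            responses, list_id = NULL) {
  condition <- match.arg(condition,
                         c("same_context", "different_context", "control"))
  condition_order <- as.integer(condition_order)
  stopifnot(condition_order %in% c(1L, 2L))
  if (is.character(responses)) {
    responses <- data.frame(
      output_position = seq_along(responses),
      response = responses,
      type = NA_character_,
      serial_position = NA_integer_,
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(is.data.frame(responses), "response" %in% names(responses))
    responses$output_position <- seq_len(nrow(responses))
    if (is.null(responses$type)) responses$type <- NA_character_
    if (is.null(responses$serial_position)) {
      responses$serial_position <- NA_integer_
    }
  }
  if (nrow(responses) && any(!nzchar(trimws(responses$response)))) {
    stop("empty response string in transcript")
  }
  structure(
    list(subject_id = as.character(subject_id), condition = condition,
         condition_order = condition_order,
         list_id = if (is.null(list_id)) NA_character_ else
           as.character(list_id),
         responses = responses),
    class = "recall_sequence"
  )
}

#' @export
print.recall_sequence <- function(x, ...) {
  res <- if (all(is.na(x$responses$type))) "unresolved" else "resolved"
  cat(sprintf("<recall_sequence> subject %s, %s (block %d): %d responses (%s)\n",
              x$subject_id, x$condition, x$condition_order,
              nrow(x$responses), res))
  invisible(x)
}

RESPONSE_TYPES <- c("correct", "ELI", "PLI", "repetition")
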