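#' Read study lists from CSV
#'
#' Expects a UTF-8 CSV with header `list_id,serial_position,word`. Serial
#' positions within each list must be exactly 1..L (any positive integer
#' coding with no gaps or duplicates is normalised to 1-based).
#'
#' @param path file path.
#' @return named list of [study_list()] objects, keyed by `list_id`. If the
#'   file has a `pair_id` column it is carried into `pair_assignment`.
#' @export
read_study_lists <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("list_id", "serial_position", "word")
  if (!all(need %in% names(df))) {
    stop(sprintf("study-list file must have columns %s",
                 paste(need, collapse = ", ")))
  }
  out <- lapply(split(df, df$list_id), function(d) {
    pos <- as.integer(d$serial_position)
    if (anyDuplicated(pos)) {
      stop(sprintf("list '%s': duplicate serial position %d",
                   d$list_id[1L], pos[duplicated(pos)][1L]))
    }
    L <- length(pos)
    if (!setequal(pos, seq_len(L) + min(pos) - 1L)) {
      gap <- setdiff(seq(min(pos), max(pos)), pos)[1L]
      stop(sprintf("list '%s': serial-position gap at %d", d$list_id[1L], gap))
    }
    d <- d[order(pos), , drop = FALSE]
    pa <- if ("pair_id" %in% names(d)) {
      p <- as.character(d$pair_id)
      p[p %in% c("", "NA")] <- NA_character_
      p
    } else NULL
    study_list(d$list_id[1L], d$word, pa)
  })
  out[unique(df$list_id)]
}

#' Write study lists to CSV
#'
#' Inverse of [read_study_lists()].
#'
#' @param lists a `study_list` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_lists <- function(lists, path) {
  if (inherits(lists, "study_list")) lists <- list(lists)
  rows <- lapply(lists, function(sl) {
    data.frame(
      list_id = sl$list_id,
      serial_position = seq_along(sl$items),
      word = sl$items,
      pair_id = if (is.null(sl$pair_assignment)) NA_character_ else
        as.character(sl$pair_assignment),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (all(is.na(df$pair_id))) df$pair_id <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a similarity matrix from CSV
#'
#' First column and header row hold the vocabulary. The matrix is
#' validated and symmetrised by [similarity_matrix()].
#'
#' @param path file path.
#' @param vocabulary optional character vector to cross-validate against
#'   (e.g. the union of study-list words); a mismatch is an error.
#' @return a [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  vocab <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!identical(colnames(m), vocab)) {
    stop("row/column vocabulary mismatch in similarity matrix file")
  }
  rownames(m) <- vocab
  storage.mode(m) <- "double"
  sim <- similarity_matrix(m, vocab)
  if (!is.null(vocabulary)) {
    miss <- setdiff(vocabulary, vocab)
    if (length(miss)) {
      stop(sprintf("similarity matrix missing %d study word(s): %s",
                   length(miss), paste(utils::head(miss, 5L), collapse = ", ")))
    }
  }
  sim
}

#' Write a similarity matrix to CSV
#' @param sim a [similarity_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(sim, path) {
  df <- data.frame(word = rownames(sim), unclass(sim),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read recall transcripts from CSV
#'
#' Expects header `subject_id,condition,condition_order,output_position,`
#' `response`; optional `type` and `serial_position` columns (written by
#' [write_recalls()] after resolution) are carried through.
#'
#' @param path file path.
#' @return list of [recall_sequence()] objects, one per
#'   subject-by-condition transcript.
#' @export
read_recalls <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("subject_id", "condition", "condition_order",
            "output_position", "response")
  if (!all(need %in% names(df))) {
    stop(sprintf("recall file must have columns %s",
                 paste(need, collapse = ", ")))
  }
  key <- interaction(df$subject_id, df$condition, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$output_position), , drop = FALSE]
    resp <- data.frame(response = d$response, stringsAsFactors = FALSE)
    if ("type" %in% names(d)) resp$type <- d$type
    if ("serial_position" %in% names(d)) {
      resp$serial_position <- as.integer(d$serial_position)
    }
    recall_sequence(d$subject_id[1L], d$condition[1L],
                    d$condition_order[1L], resp,
                    list_id = if ("list_id" %in% names(d)) d$list_id[1L])
  })
  names(out) <- NULL
  out
}

#' Write recall transcripts to CSV
#' @param recalls a `recall_sequence` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recalls <- function(recalls, path) {
  if (inherits(recalls, "recall_sequence")) recalls <- list(recalls)
  rows <- lapply(recalls, function(rs) {
    data.frame(
      subject_id = rs$subject_id,
      condition = rs$condition,
      condition_order = rs$condition_order,
      list_id = rs$list_id,
      output_position = rs$responses$output_position,
      response = rs$responses$response,
      type = rs$responses$type,
      serial_position = rs$responses$serial_position,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (all(is.na(df$type))) {
    df$type <- NULL
    df$serial_position <- NULL
  }
  if (all(is.na(df$list_id))) df$list_id <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
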