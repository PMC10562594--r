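#' Classify raw recall responses
#'
#' Maps each typed response onto the study vocabulary and labels it as a
#' first-time correct recall, a repetition, a prior-list intrusion (PLI:
#' a word studied on a *different* list of the session) or an extra-list
#' intrusion (ELI: a word not studied on any list). Matching is
#' case-folded, whitespace-trimmed, and tolerant to typos up to
#' `max_edit_distance` Damerau-Levenshtein operations, restricted to the
#' known vocabulary. A response equidistant from several candidate words at
#' the minimal distance is ambiguous and conservatively labelled ELI.
#'
#' Classification is exhaustive and exclusive (every response gets exactly
#' one label) and the operation is idempotent: re-resolving a resolved
#' sequence reproduces the same labels.
#'
#' @param raw a [recall_sequence()] (resolved or not; labels are recomputed
#'   from the raw strings).
#' @param study the just-studied [study_list()] for this transcript.
#' @param session_lists all lists studied in the session (a list of
#'   `study_list`, typically including `study`); used to detect PLIs.
#' @param max_edit_distance maximum allowed edit distance (default 1; 0
#'   reduces matching to exact membership after case-folding).
#' @return the `recall_sequence` with `type` and `serial_position` filled.
#' @export
resolve_responses <- function(raw, study, session_lists = list(study),
                              max_edit_distance = 1L) {
  stopifnot(inherits(raw, "recall_sequence"), inherits(study, "study_list"))
  if (inherits(session_lists, "study_list")) {
    session_lists <- list(session_lists)
  }
  cur_words <- tolower(study$items)
  other_words <- tolower(unlist(lapply(session_lists, function(sl) {
    if (identical(sl$list_id, study$list_id)) character(0) else sl$items
  })))
  other_words <- setdiff(other_words, cur_words)

  resp <- raw$responses
  n <- nrow(resp)
  type <- character(n)
  spos <- rep(NA_integer_, n)
  credited <- integer(0)

  for (i in seq_len(n)) {
    w <- tolower(trimws(resp$response[i]))
    pos <- match_vocabulary(w, cur_words, max_edit_distance)
    if (!is.na(pos)) {
      if (pos %in% credited) {
        type[i] <- "repetition"
        spos[i] <- pos
      } else {
        type[i] <- "correct"
        spos[i] <- pos
        credited <- c(credited, pos)
      }
    } else if (!is.na(match_vocabulary(w, other_words, max_edit_distance))) {
      type[i] <- "PLI"
    } else {
      type[i] <- "ELI"
    }
  }
  resp$type <- type
  resp$serial_position <- spos
  raw$responses <- resp
  raw
}

# Index of the unique nearest vocabulary word within max_dist, else NA.
# An exact match always wins; ties at the minimal distance return NA.
match_vocabulary <- function(w, vocab, max_dist) {
  if (!length(vocab)) return(NA_integer_)
  exact <- which(vocab == w)
  if (length(exact) == 1L) return(exact)
  if (max_dist < 1L) return(NA_integer_)
  # cheap length prefilter before the dynamic programme
  cand <- which(abs(nchar(vocab) - nchar(w)) <= max_dist)
  if (!length(cand)) return(NA_integer_)
  d <- dl_distance(w, vocab[cand])
  dmin <- min(d)
  if (dmin > max_dist) return(NA_integer_)
  hits <- cand[d == dmin]
  if (length(hits) == 1L) hits else NA_integer_
}
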