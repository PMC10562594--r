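#' Score a cohort of recall transcripts
#'
#' Resolves (if needed) and scores every transcript, producing the
#' per-subject, per-condition measures that feed the statistics stage:
#' correct-recall count, temporal and semantic clustering factors,
#' intrusion and repetition counts, first-recall position, and the
#' serial-position indicator vector.
#'
#' @param recalls list of [recall_sequence()] objects.
#' @param study_lists named list of [study_list()] objects keyed by
#'   `list_id`. A transcript is matched to its list via its `list_id`
#'   field; when that is absent and a single list is supplied, that list
#'   is used.
#' @param sim optional [similarity_matrix()]; when `NULL` the semantic
#'   factor is `NA`.
#' @param max_edit_distance passed to [resolve_responses()].
#' @param semantic_possible passed to [transition_factor()].
#' @return object of class `cohort_result`: list with
#'   * `measures`: data.frame (`subject_id`, `condition`,
#'     `condition_order`, `list_id`, `n_correct`, `temporal_factor`,
#'     `semantic_factor`, `n_ELI`, `n_PLI`, `n_repetition`,
#'     `pfr_position`);
#'   * `spc`: 0/1 matrix, rows aligned with `measures`, columns 1..L;
#'   * `transitions`: list of per-transcript `transitions` objects;
#'   * `L`: list length.
#' @export
score_cohort <- function(recalls, study_lists, sim = NULL,
                         max_edit_distance = 1L,
                         semantic_possible = "available") {
  if (inherits(recalls, "recall_sequence")) recalls <- list(recalls)
  if (inherits(study_lists, "study_list")) {
    study_lists <- stats::setNames(list(study_lists), study_lists$list_id)
  }
  if (is.null(names(study_lists))) {
    names(study_lists) <- vapply(study_lists, `[[`, "", "list_id")
  }
  Ls <- vapply(study_lists, length, 0L)
  if (length(unique(Ls)) != 1L) stop("study lists differ in length")
  L <- Ls[[1L]]

  n <- length(recalls)
  meas <- data.frame(
    subject_id = character(n), condition = character(n),
    condition_order = integer(n), list_id = character(n),
    n_correct = integer(n), temporal_factor = NA_real_,
    semantic_factor = NA_real_, n_ELI = integer(n), n_PLI = integer(n),
    n_repetition = integer(n), pfr_position = NA_integer_,
    stringsAsFactors = FALSE
  )
  spc <- matrix(0L, n, L)
  trans <- vector("list", n)

  for (i in seq_len(n)) {
    rs <- recalls[[i]]
    lid <- rs$list_id
    if (is.na(lid)) {
      if (length(study_lists) == 1L) lid <- names(study_lists) else
        stop(sprintf("transcript %s/%s has no list_id and %d lists supplied",
                     rs$subject_id, rs$condition, length(study_lists)))
    }
    if (!lid %in% names(study_lists)) {
      stop(sprintf("unknown list_id '%s' in transcript %s/%s",
                   lid, rs$subject_id, rs$condition))
    }
    study <- study_lists[[lid]]
    if (all(is.na(rs$responses$type)) && nrow(rs$responses)) {
      rs <- resolve_responses(rs, study, study_lists, max_edit_distance)
    }
    resp <- rs$responses
    tr <- extract_transitions(rs, L)
    trans[[i]] <- tr
    correct_pos <- resp$serial_position[resp$type %in% "correct"]
    meas$subject_id[i] <- rs$subject_id
    meas$condition[i] <- rs$condition
    meas$condition_order[i] <- rs$condition_order
    meas$list_id[i] <- lid
    meas$n_correct[i] <- length(correct_pos)
    meas$temporal_factor[i] <- transition_factor(tr, "temporal")$mean
    if (!is.null(sim)) {
      meas$semantic_factor[i] <-
        transition_factor(tr, "semantic", sim = sim, study = study,
                          possible = semantic_possible)$mean
    }
    meas$n_ELI[i] <- sum(resp$type %in% "ELI")
    meas$n_PLI[i] <- sum(resp$type %in% "PLI")
    meas$n_repetition[i] <- sum(resp$type %in% "repetition")
    if (length(correct_pos)) meas$pfr_position[i] <- correct_pos[1L]
    spc[i, correct_pos] <- 1L
  }
  structure(list(measures = meas, spc = spc, transitions = trans,
                 L = as.integer(L)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d transcripts, L = %d\n",
              nrow(x$measures), x$L))
  print(table(x$measures$condition))
  invisible(x)
}

#' Condition-averaged lag-CRP curve
#'
#' Computes one lag-CRP curve per transcript and averages them pointwise
#' across transcripts (within a condition if given), using at each lag
#' only the transcripts for which that lag's CRP is defined.
#'
#' @param cohort a `cohort_result` from [score_cohort()].
#' @param condition optional condition label to subset on.
#' @return a `crp_curve` data.frame with columns `lag`, `crp` (mean across
#'   transcripts) and `n` (number of transcripts contributing at the lag).
#' @export
average_crp <- function(cohort, condition = NULL) {
  idx <- seq_along(cohort$transitions)
  if (!is.null(condition)) {
    idx <- idx[cohort$measures$condition == condition]
  }
  if (!length(idx)) stop("no transcripts to average")
  L <- cohort$L
  curves <- lapply(cohort$transitions[idx], lag_crp, L = L)
  mat <- vapply(curves, `[[`, numeric(2L * (L - 1L)), "crp")
  lags <- curves[[1L]]$lag
  structure(
    data.frame(lag = lags,
               crp = rowMeans(mat, na.rm = TRUE),
               n = rowSums(!is.na(mat))),
    L = L, class = c("crp_curve", "data.frame")
  )
}
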