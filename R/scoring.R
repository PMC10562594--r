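#' Extract recall-to-recall transitions
#'
#' Walks a resolved transcript and emits one record per consecutive pair
#' of responses. A transition is *valid* only when both endpoints are
#' first-time correct recalls; intrusions and repetitions invalidate the
#' transitions into and out of them (they contribute neither actual nor
#' possible counts downstream). At each valid transition the set of
#' possible targets is every serial position not yet credited as a correct
#' recall, excluding the position just recalled.
#'
#' @param seq a resolved [recall_sequence()].
#' @param L study-list length.
#' @return data.frame of class `transitions` with columns `from_output`,
#'   `to_output`, `from_position`, `to_position`, `lag`, `valid` and the
#'   list-column `possible_targets`; attribute `L` records the list length.
#' @examples
#' # recalls at study positions 5, 6, 2 have lags +1 and -4
#' @export
extract_transitions <- function(seq, L) {
  stopifnot(inherits(seq, "recall_sequence"))
  resp <- seq$responses
  if (nrow(resp) && all(is.na(resp$type))) {
    stop("transcript is unresolved; call resolve_responses() first")
  }
  n <- nrow(resp)
  empty <- data.frame(from_output = integer(0), to_output = integer(0),
                      from_position = integer(0), to_position = integer(0),
                      lag = integer(0), valid = logical(0))
  if (n < 2L) {
    empty$possible_targets <- list()
    return(structure(empty, L = as.integer(L),
                     class = c("transitions", "data.frame")))
  }
  correct <- resp$type == "correct"
  credited_after <- cumsum_positions(resp$serial_position, correct)
  from <- seq_len(n - 1L)
  to <- from + 1L
  valid <- correct[from] & correct[to]
  out <- data.frame(
    from_output = from, to_output = to,
    from_position = resp$serial_position[from],
    to_position = resp$serial_position[to],
    lag = resp$serial_position[to] - resp$serial_position[from],
    valid = valid
  )
  out$possible_targets <- lapply(from, function(i) {
    if (!valid[i]) return(integer(0))
    setdiff(seq_len(L), credited_after[[i]])
  })
  structure(out, L = as.integer(L), class = c("transitions", "data.frame"))
}

# credited_after[[i]]: serial positions credited as correct in outputs 1..i
cumsum_positions <- function(spos, correct) {
  acc <- integer(0)
  lapply(seq_along(spos), function(i) {
    if (correct[i]) acc <<- c(acc, spos[i])
    acc
  })
}

#' Lag conditional-response probability curve
#'
#' For every signed lag, the number of valid transitions actually made at
#' that lag divided by the number of valid transitions at which that lag
#' was possible (a lag is possible when the corresponding serial position
#' is still available, i.e. on the list and not yet recalled). Lags never
#' possible are undefined (`NA`) and excluded from averages.
#'
#' @param transitions a `transitions` object from [extract_transitions()].
#' @param L study-list length (defaults to the attribute on `transitions`).
#' @return data.frame of class `crp_curve` with columns `lag` (from
#'   `-(L-1)` to `L-1`, no 0), `actual`, `possible`, `crp`.
#' @export
lag_crp <- function(transitions, L = attr(transitions, "L")) {
  lags <- setdiff(-(L - 1L):(L - 1L), 0L)
  actual <- possible <- stats::setNames(integer(length(lags)),
                                        as.character(lags))
  tv <- transitions[transitions$valid, , drop = FALSE]
  for (k in seq_len(nrow(tv))) {
    a <- as.character(tv$lag[k])
    actual[a] <- actual[a] + 1L
    pl <- as.character(tv$possible_targets[[k]] - tv$from_position[k])
    possible[pl] <- possible[pl] + 1L
  }
  structure(
    data.frame(lag = lags, actual = unname(actual),
               possible = unname(possible),
               crp = ifelse(possible > 0, actual / possible, NA_real_)),
    L = as.integer(L), class = c("crp_curve", "data.frame")
  )
}

#' Percentile-rank temporal / semantic clustering factor
#'
#' For each valid transition, all possible targets are ranked by the
#' chosen key — temporal proximity (smallest absolute lag gets the highest
#' rank) or semantic similarity to the just-recalled word (most similar
#' gets the highest rank) — using average (fractional) ranks for ties.
#' With `R` the rank of the target actually recalled and `N` the number of
#' possible targets, the transition scores `(R - 1) / (N - 1)`; scores are
#' averaged within the transcript. A score of 0.5 is chance-level
#' organization; 1 means every transition went to the top-ranked available
#' target. Transitions with a single possible target (`N = 1`) are
#' excluded as unscorable.
#'
#' @param transitions a `transitions` object.
#' @param key `"temporal"` or `"semantic"`.
#' @param sim a [similarity_matrix()]; required for the semantic key.
#' @param study the [study_list()] the transcript refers to; required for
#'   the semantic key (maps serial positions to words).
#' @param possible `"available"` (default) restricts the candidate set to
#'   not-yet-recalled positions, mirroring the temporal score;
#'   `"all"` ranks against every list position except the just-recalled
#'   one, an alternative reading of the semantic denominator.
#' @return object of class `factor_score`: list with `kind`, per-transition
#'   `scores`, and their `mean` (`NA` when no transition is scorable).
#' @export
transition_factor <- function(transitions, key = c("temporal", "semantic"),
                              sim = NULL, study = NULL,
                              possible = c("available", "all")) {
  key <- match.arg(key)
  possible <- match.arg(possible)
  L <- attr(transitions, "L")
  if (key == "semantic") {
    if (is.null(sim)) stop("semantic factor needs a similarity matrix")
    if (is.null(study)) stop("semantic factor needs the study list")
  }
  tv <- transitions[transitions$valid, , drop = FALSE]
  scores <- numeric(0)
  for (k in seq_len(nrow(tv))) {
    from <- tv$from_position[k]
    cand <- if (possible == "available") tv$possible_targets[[k]] else
      setdiff(seq_len(L), from)
    N <- length(cand)
    if (N < 2L) next
    keyval <- if (key == "temporal") -abs(cand - from) else
      unname(similarity(sim, study$items[from], study$items[cand]))
    r <- rank(keyval, ties.method = "average")
    R <- r[cand == tv$to_position[k]]
    scores <- c(scores, (R - 1) / (N - 1))
  }
  structure(list(kind = key, scores = scores,
                 mean = if (length(scores)) mean(scores) else NA_real_),
            class = "factor_score")
}

#' @export
print.factor_score <- function(x, ...) {
  cat(sprintf("<factor_score %s> %d transitions, mean %s\n", x$kind,
              length(x$scores),
              if (is.na(x$mean)) "undefined" else sprintf("%.3f", x$mean)))
  invisible(x)
}

#' Chance level of the clustering factor scores
#'
#' The expected factor score when transitions are made uniformly at random
#' among the possible targets.
#'
#' @return 0.5
#' @export
chance_level <- function() 0.5

#' Adjacent vs. remote lag-CRP summary
#'
#' Averages the defined CRP values at absolute lags 1-2 ("adjacent") and
#' 3-16 ("remote"), separately for forward (positive) and backward
#' (negative) lags. Larger lags, when the list is long enough to have
#' them, enter neither cell. Cells with no defined CRP are `NA`.
#'
#' @param curve a `crp_curve` from [lag_crp()].
#' @param adjacent_lags,remote_lags absolute-lag ranges for the two groups.
#' @return named numeric vector: `forward_adjacent`, `forward_remote`,
#'   `backward_adjacent`, `backward_remote`.
#' @export
adjacent_remote_summary <- function(curve, adjacent_lags = 1:2,
                                    remote_lags = 3:16) {
  cell <- function(lags) {
    v <- curve$crp[curve$lag %in% lags]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  c(forward_adjacent = cell(adjacent_lags),
    forward_remote = cell(remote_lags),
    backward_adjacent = cell(-adjacent_lags),
    backward_remote = cell(-remote_lags))
}

#' Serial position curve and binned recall probabilities
#'
#' @param spc matrix of 0/1 recall indicators, one row per
#'   subject-by-condition transcript, one column per serial position.
#' @param n_bins number of equal serial-position bins (default 4, i.e.
#'   positions 1-8, 9-16, 17-24, 25-32 for a 32-item list); the list
#'   length must be divisible by `n_bins`.
#' @return list with `position_prob` (per-position recall probability
#'   across rows), `bin_means` (average probability per bin) and `bins`
#'   (the bin index of each position).
#' @export
serial_position_curve <- function(spc, n_bins = 4L) {
  spc <- as.matrix(spc)
  L <- ncol(spc)
  if (L %% n_bins != 0L) {
    stop(sprintf("list length %d not divisible by %d bins", L, n_bins))
  }
  prob <- colMeans(spc)
  bins <- rep(seq_len(n_bins), each = L %/% n_bins)
  list(position_prob = unname(prob),
       bin_means = as.vector(tapply(prob, bins, mean)),
       bins = bins)
}

#' Per-subject binned recall probabilities
#'
#' Bin-level recall probabilities for every transcript (row of `spc`),
#' the unit of analysis of the binned serial-position ANOVA.
#'
#' @inheritParams serial_position_curve
#' @return matrix, rows as in `spc`, one column per bin.
#' @export
binned_recall <- function(spc, n_bins = 4L) {
  spc <- as.matrix(spc)
  L <- ncol(spc)
  if (L %% n_bins != 0L) {
    stop(sprintf("list length %d not divisible by %d bins", L, n_bins))
  }
  bins <- rep(seq_len(n_bins), each = L %/% n_bins)
  t(apply(spc, 1L, function(row) tapply(row, bins, mean)))
}

#' Probability of first recall
#'
#' Distribution over serial positions of the first correctly recalled
#' item, across transcripts with at least one correct recall.
#'
#' @param pfr_positions integer vector of first-recall serial positions
#'   (`NA` for transcripts with no correct recall; dropped).
#' @param L study-list length.
#' @return numeric vector of length `L`, summing to 1.
#' @export
probability_of_first_recall <- function(pfr_positions, L) {
  p <- pfr_positions[!is.na(pfr_positions)]
  if (!length(p)) stop("no transcript has a correct first recall")
  tabulate(p, nbins = L) / length(p)
}
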