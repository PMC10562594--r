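#' Parameters of the synthetic recall-process generator
#'
#' The generator realises the cue trade-off the analysis pipeline is built
#' to detect: retrieval is driven by a mixture of a temporal-contiguity
#' cue (exponential in absolute lag, with forward asymmetry) and a
#' semantic-similarity cue, whose mixing weight `lambda` differs between
#' the two within-subject context conditions. Recovery failure `rho`
#' suppresses sampled items without output credit, emulating context
#' change reducing item recoverability; `epsilon` injects extra-list
#' intrusion tokens.
#'
#' @param L list length (default 32).
#' @param n_subjects subjects in a simulated study (default 141, the
#'   analysed main-experiment cohort size being emulated).
#' @param p_stop per-output stopping probability (default 0.07, giving a
#'   mean of roughly 12-14 outputs, matching observed recall counts).
#' @param tau temporal decay scale of the contiguity cue, in serial
#'   positions (default 1.5).
#' @param phi forward-asymmetry multiplier, >= 1 (default 1.5).
#' @param lambda_same,lambda_diff semantic cue weight in [0,1] per
#'   condition (defaults 0.15 and 0.45: semantic cues weigh more when the
#'   environmental context changes).
#' @param rho_same,rho_diff recovery-failure probability per condition
#'   (defaults 0.05 and 0.10).
#' @param epsilon intrusion probability per output event (default 0.02).
#' @param max_outputs cap on output events, from the 90 s recall window at
#'   1.5 s per output event (default 60).
#' @param seed optional RNG seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(L = 32L, n_subjects = 141L, p_stop = 0.07,
                       tau = 1.5, phi = 1.5,
                       lambda_same = 0.15, lambda_diff = 0.45,
                       rho_same = 0.05, rho_diff = 0.10,
                       epsilon = 0.02, max_outputs = 60L, seed = NULL) {
  probs <- c(p_stop, lambda_same, lambda_diff, rho_same, rho_diff, epsilon)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (tau <= 0) stop("tau must be positive")
  if (phi < 1) stop("phi must be >= 1")
  structure(list(L = as.integer(L), n_subjects = as.integer(n_subjects),
                 p_stop = p_stop, tau = tau, phi = phi,
                 lambda_same = lambda_same, lambda_diff = lambda_diff,
                 rho_same = rho_same, rho_diff = rho_diff,
                 epsilon = epsilon, max_outputs = as.integer(max_outputs),
                 seed = seed),
            class = "sim_params")
}

#' Generate a synthetic semantic similarity matrix
#'
#' Emulates the structure of a WAS-style similarity matrix over a study
#' vocabulary: `n_pairs` designated word pairs with similarity drawn
#' uniformly in [0.7, 0.95] and all other off-diagonal values drawn from
#' |Normal(0.1, 0.05)| truncated to [0, 0.3], so designated pairs are
#' cleanly separated from background relatedness.
#'
#' @param L vocabulary size (default 32).
#' @param n_pairs number of designated pairs (default 16; `2 * n_pairs`
#'   must not exceed `L`).
#' @param seed optional RNG seed.
#' @param vocabulary optional character vector of `L` words; defaults to
#'   synthetic tokens `w001`, `w002`, ...
#' @return a [similarity_matrix()] with attribute `pairs`: a data.frame of
#'   the designated pairs (`word1`, `word2`, `similarity`).
#' @export
generate_similarity <- function(L = 32L, n_pairs = 16L, seed = NULL,
                                vocabulary = NULL) {
  L <- as.integer(L); n_pairs <- as.integer(n_pairs)
  if (2L * n_pairs > L) stop("2 * n_pairs must not exceed L")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(vocabulary)) vocabulary <- sprintf("w%03d", seq_len(L))
  stopifnot(length(vocabulary) == L, !anyDuplicated(vocabulary))

  m <- matrix(pmin(abs(stats::rnorm(L * L, 0.1, 0.05)), 0.3), L, L)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  members <- sample.int(L, 2L * n_pairs)
  p1 <- members[seq_len(n_pairs)]
  p2 <- members[n_pairs + seq_len(n_pairs)]
  psim <- stats::runif(n_pairs, 0.7, 0.95)
  m[cbind(p1, p2)] <- psim
  m[cbind(p2, p1)] <- psim
  diag(m) <- 1
  sim <- similarity_matrix(m, vocabulary)
  attr(sim, "pairs") <- data.frame(word1 = vocabulary[p1],
                                   word2 = vocabulary[p2],
                                   similarity = psim,
                                   stringsAsFactors = FALSE)
  sim
}

#' Simulate one recall transcript
#'
#' Retrieval is a sequential sampler over the not-yet-retrieved list
#' items. The first recall is drawn from a recency-weighted distribution
#' (weight proportional to `exp((pos - L) / tau)`). Each subsequent
#' candidate `i` is sampled with weight
#' `(1 - lambda) * exp(-|pos_i - pos_prev| / tau) * (phi if forward)`
#' `+ lambda * similarity(prev, i)`.
#' A sampled item fails recovery with probability `rho` and is then
#' permanently dropped from the candidate pool without producing output (a
#' failed retrieval attempt). With probability `epsilon` an output event
#' is an extra-list intrusion token instead of a list word. Recall halts
#' with probability `p_stop` after each output event, when the candidate
#' pool is exhausted, or at `max_outputs` output events (the simulated
#' 90 s window).
#'
#' @param study a [study_list()].
#' @param sim a [similarity_matrix()] covering the list words.
#' @param params a [sim_params()].
#' @param condition `"same_context"` or `"different_context"` (selects
#'   `lambda` and `rho`); `"control"` uses the same-context values.
#' @param subject_id,condition_order transcript metadata.
#' @return an unresolved [recall_sequence()] (raw response strings only).
#' @export
simulate_recall <- function(study, sim, params,
                            condition = "same_context",
                            subject_id = "s1", condition_order = 1L) {
  L <- length(study)
  lambda <- if (condition == "different_context") params$lambda_diff else
    params$lambda_same
  rho <- if (condition == "different_context") params$rho_diff else
    params$rho_same
  words <- study$items
  simm <- unclass(sim)[words, words, drop = FALSE]

  available <- rep(TRUE, L)   # not yet output and not failed
  out <- character(0)
  prev <- NA_integer_         # position of last recalled list word
  n_out <- 0L
  n_intr <- 0L

  repeat {
    if (n_out >= params$max_outputs) break
    if (stats::runif(1) < params$epsilon) {
      n_intr <- n_intr + 1L
      out <- c(out, sprintf("xq%03d", n_intr))
      n_out <- n_out + 1L
      if (stats::runif(1) < params$p_stop) break
      next
    }
    if (!any(available)) break
    cand <- which(available)
    w <- if (is.na(prev)) {
      exp((cand - L) / params$tau)
    } else {
      temporal <- exp(-abs(cand - prev) / params$tau) *
        ifelse(cand > prev, params$phi, 1)
      (1 - lambda) * temporal + lambda * simm[prev, cand]
    }
    pick <- cand[sample.int(length(cand), 1L, prob = w)]
    available[pick] <- FALSE
    if (stats::runif(1) < rho) next  # recovery failure: attempt, no output
    out <- c(out, words[pick])
    prev <- pick
    n_out <- n_out + 1L
    if (stats::runif(1) < params$p_stop) break
  }
  recall_sequence(subject_id, condition, condition_order, out,
                  list_id = study$list_id)
}

#' Simulate a full within-subject context study
#'
#' Builds a session vocabulary and similarity matrix (two lists' worth of
#' designated pairs), constructs one non-adjacent ordering per list, and
#' simulates every subject in both conditions with counterbalanced block
#' order. The first block always studies list 1 and the second block list
#' 2, so counterbalancing the condition order also balances lists across
#' conditions.
#'
#' @param params a [sim_params()].
#' @param n_pairs_per_list designated pairs per 32-word list (default 16).
#' @return object of class `synthetic_cohort`: list with `study_lists`
#'   (named list of two [study_list()]s), `sim` (session-wide
#'   [similarity_matrix()]), `recalls` (list of unresolved
#'   [recall_sequence()]s, two per subject), and `ground_truth` (the
#'   generating parameters per condition).
#' @export
simulate_study <- function(params = sim_params(),
                           n_pairs_per_list = 16L) {
  if (!is.null(params$seed)) set.seed(params$seed)
  L <- params$L
  n_lists <- 2L
  vocabL <- n_lists * L
  sim <- generate_similarity(L = vocabL, n_pairs = n_lists * n_pairs_per_list,
                             seed = NULL)
  spec <- list_spec(L = L, n_pairs = n_pairs_per_list, n_orderings = 1L)
  lists <- make_study_lists(sim, n_lists = n_lists, spec = spec)
  study_lists <- stats::setNames(
    lapply(lists, `[[`, 1L),
    vapply(lists, function(x) x[[1L]]$list_id, "")
  )

  conditions <- c("same_context", "different_context")
  recalls <- vector("list", 2L * params$n_subjects)
  k <- 0L
  for (s in seq_len(params$n_subjects)) {
    same_first <- s %% 2L == 1L  # balanced to +/- 1
    order_group <- if (same_first) 1L else 2L
    order_of <- if (same_first) c(same_context = 1L, different_context = 2L)
    else c(same_context = 2L, different_context = 1L)
    for (cond in conditions) {
      blk <- order_of[[cond]]  # block index, also picks the studied list
      k <- k + 1L
      recalls[[k]] <- simulate_recall(
        study_lists[[blk]], sim, params, condition = cond,
        subject_id = sprintf("s%03d", s), condition_order = order_group
      )
    }
  }
  structure(
    list(study_lists = study_lists, sim = sim, recalls = recalls,
         ground_truth = list(
           same_context = list(lambda = params$lambda_same,
                               rho = params$rho_same),
           different_context = list(lambda = params$lambda_diff,
                                    rho = params$rho_diff),
           params = unclass(params))),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d transcripts, %d lists, %d-word vocabulary\n",
              length(x$recalls), length(x$study_lists), nrow(x$sim)))
  invisible(x)
}
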