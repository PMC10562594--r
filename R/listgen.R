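#' Specification for constrained study-list construction
#'
#' Captures the structural parameters of the list-building procedure:
#' lists of `L` words containing `n_pairs` designated high-similarity
#' pairs (within-pair similarity above `sim_threshold`), arranged so that
#' pair members never occupy adjacent serial positions, in `n_orderings`
#' alternative orderings per list.
#'
#' @param L list length (default 32).
#' @param n_pairs designated pairs per list (default 16; with the defaults
#'   every list word belongs to a pair).
#' @param sim_threshold minimum within-pair similarity, in (0,1)
#'   (default 0.7).
#' @param n_orderings ordering schemes per list (default 4).
#' @param seed optional RNG seed for reproducible selection/ordering.
#' @return object of class `list_spec`.
#' @export
list_spec <- function(L = 32L, n_pairs = 16L, sim_threshold = 0.7,
                      n_orderings = 4L, seed = NULL) {
  L <- as.integer(L); n_pairs <- as.integer(n_pairs)
  if (2L * n_pairs > L) stop("2 * n_pairs must not exceed L")
  if (!(sim_threshold > 0 && sim_threshold < 1)) {
    stop("sim_threshold must lie in (0, 1)")
  }
  structure(list(L = L, n_pairs = n_pairs, sim_threshold = sim_threshold,
                 n_orderings = as.integer(n_orderings), seed = seed),
            class = "list_spec")
}

#' Select disjoint high-similarity word pairs
#'
#' Greedy selection in descending similarity among all word pairs whose
#' similarity exceeds `spec$sim_threshold`; ties are broken by a
#' seed-controlled shuffle so the choice is reproducible. Pairs are
#' mutually disjoint in membership.
#'
#' @param sim a [similarity_matrix()].
#' @param spec a [list_spec()]; `n_pairs` pairs are returned.
#' @param n_pairs overrides `spec$n_pairs` (e.g. to draw pairs for several
#'   lists at once from a shared vocabulary).
#' @return data.frame with columns `word1`, `word2`, `similarity`, ordered
#'   by descending similarity.
#' @export
select_pairs <- function(sim, spec = list_spec(), n_pairs = spec$n_pairs) {
  stopifnot(inherits(sim, "similarity_matrix"))
  vocab <- rownames(sim)
  idx <- which(upper.tri(sim) & sim > spec$sim_threshold, arr.ind = TRUE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  vals <- sim[idx]
  ord <- order(-vals, sample.int(length(vals)))
  idx <- idx[ord, , drop = FALSE]
  vals <- vals[ord]

  used <- logical(length(vocab))
  keep <- integer(0)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      keep <- c(keep, k)
      if (length(keep) == n_pairs) break
    }
  }
  if (length(keep) < n_pairs) {
    feasible <- max_disjoint_pairs(idx)
    stop(sprintf("feasible pairs: %d < %d (similarity threshold %.3g)",
                 feasible, n_pairs, spec$sim_threshold))
  }
  data.frame(word1 = vocab[idx[keep, 1L]], word2 = vocab[idx[keep, 2L]],
             similarity = vals[keep], stringsAsFactors = FALSE)
}

# Maximum number of disjoint pairs among candidate edges (maximum matching,
# exact by branch and bound on the vertex of highest degree; candidate edge
# sets above threshold are small in practice).
max_disjoint_pairs <- function(edges) {
  if (!nrow(edges)) return(0L)
  recurse <- function(edges) {
    if (!nrow(edges)) return(0L)
    verts <- c(edges[, 1L], edges[, 2L])
    v <- as.integer(names(which.max(table(verts))))
    touching <- edges[, 1L] == v | edges[, 2L] == v
    # branch 1: leave v unmatched
    best <- recurse(edges[!touching, , drop = FALSE])
    # branch 2: match v along each incident edge
    for (k in which(touching)) {
      u <- setdiff(edges[k, ], v)
      drop <- edges[, 1L] %in% c(u, v) | edges[, 2L] %in% c(u, v)
      best <- max(best, 1L + recurse(edges[!drop, , drop = FALSE]))
    }
    best
  }
  recurse(edges)
}

#' Order list words with pair members non-adjacent
#'
#' Produces `spec$n_orderings` permutations of the `L` list words such
#' that no two adjacent words belong to the same designated pair
#' (optionally, in strict mode, such that no adjacent pair of words
#' exceeds the similarity threshold at all). Each ordering starts from a
#' seed-controlled shuffle; violating adjacencies are repaired by swapping
#' one member of the adjacency to a random position that removes the
#' violation, failing after 10,000 repair steps.
#'
#' @param pairs data.frame as returned by [select_pairs()] (columns
#'   `word1`, `word2`).
#' @param fillers character vector of unpaired words (may be empty).
#' @param spec a [list_spec()]; `pairs` and `fillers` must together contain
#'   `spec$L` distinct words.
#' @param strict if `TRUE`, additionally forbid any adjacency whose
#'   similarity in `sim` exceeds `spec$sim_threshold`.
#' @param sim similarity matrix, required when `strict = TRUE`.
#' @return list of `n_orderings` [study_list()]-ready orderings, each a
#'   character vector of length `L`, with a `pair_id` attribute mapping
#'   words to pair identifiers.
#' @export
order_list <- function(pairs, fillers = character(0), spec = list_spec(),
                       strict = FALSE, sim = NULL) {
  words <- c(pairs$word1, pairs$word2, fillers)
  if (length(words) != spec$L || anyDuplicated(words)) {
    stop(sprintf("pairs and fillers must contain exactly %d distinct words",
                 spec$L))
  }
  if (strict && is.null(sim)) stop("strict mode needs a similarity matrix")
  pair_of <- c(rep(seq_len(nrow(pairs)), 2L),
               rep(NA_integer_, length(fillers)))
  names(pair_of) <- words
  if (spec$L == 2L && nrow(pairs) == 1L) {
    stop("no valid ordering: a 2-word list cannot separate its only pair")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)

  violations <- function(ord) {
    p <- pair_of[ord]
    adj_pair <- !is.na(p[-length(p)]) & !is.na(p[-1L]) &
      p[-length(p)] == p[-1L]
    if (strict) {
      s <- sim[cbind(ord[-length(ord)], ord[-1L])]
      adj_pair <- adj_pair | s > spec$sim_threshold
    }
    which(adj_pair)
  }

  one_ordering <- function() {
    ord <- sample(words)
    steps <- 0L
    repeat {
      v <- violations(ord)
      if (!length(v)) return(ord)
      steps <- steps + 1L
      if (steps > 10000L) {
        stop("failed to order list after 10,000 repair steps")
      }
      i <- v[1L] + 1L  # second member of the first violating adjacency
      j <- sample(setdiff(seq_along(ord), i), 1L)
      cand <- ord
      cand[c(i, j)] <- cand[c(j, i)]
      if (length(violations(cand)) < length(v)) ord <- cand
    }
  }

  out <- replicate(spec$n_orderings, one_ordering(), simplify = FALSE)
  lapply(out, function(ord) {
    attr(ord, "pair_id") <- unname(pair_of[ord])
    ord
  })
}

#' Build study lists with designated semantic pairs
#'
#' Convenience wrapper: selects `n_lists * spec$n_pairs` disjoint
#' high-similarity pairs from the similarity matrix, partitions them into
#' lists, adds fillers if `2 * n_pairs < L`, and orders each list in
#' `spec$n_orderings` schemes.
#'
#' @param sim a [similarity_matrix()].
#' @param n_lists number of lists to build (default 3).
#' @param spec a [list_spec()].
#' @param reuse_pair_positions if `TRUE`, the alternative orderings of a
#'   list re-randomise only pair-member placement from a shared assignment
#'   of pairs to position slots; the default `FALSE` fully re-randomises
#'   each ordering.
#' @return named list of lists: element `"Lk"` holds the `n_orderings`
#'   [study_list()] objects for list k (ids `"Lk.o<j>"`).
#' @export
make_study_lists <- function(sim, n_lists = 3L, spec = list_spec(),
                             reuse_pair_positions = FALSE) {
  n_lists <- as.integer(n_lists)
  pairs <- select_pairs(sim, spec, n_pairs = n_lists * spec$n_pairs)
  unused <- setdiff(rownames(sim), c(pairs$word1, pairs$word2))
  n_fill <- spec$L - 2L * spec$n_pairs
  out <- vector("list", n_lists)
  names(out) <- paste0("L", seq_len(n_lists))
  for (k in seq_len(n_lists)) {
    pk <- pairs[seq_len(spec$n_pairs) + (k - 1L) * spec$n_pairs, ]
    fillers <- character(0)
    if (n_fill > 0L) {
      if (length(unused) < n_fill) {
        stop("not enough unpaired words for fillers")
      }
      fillers <- unused[seq_len(n_fill)]
      unused <- unused[-seq_len(n_fill)]
    }
    sp <- spec
    if (!is.null(spec$seed)) sp$seed <- (spec$seed + k) %% .Machine$integer.max
    orderings <- order_list(pk, fillers, sp)
    if (reuse_pair_positions && length(orderings) > 1L) {
      # keep the slot structure of the first ordering; permute which pair
      # occupies which slot pair, and which member comes first
      base <- orderings[[1L]]
      base_pid <- attr(base, "pair_id")
      orderings <- lapply(seq_along(orderings), function(j) {
        if (j == 1L) return(base)
        perm <- sample.int(nrow(pk))
        ord <- base
        for (p in seq_len(nrow(pk))) {
          slots <- which(base_pid == p)
          members <- c(pk$word1[perm[p]], pk$word2[perm[p]])
          ord[slots] <- sample(members)
        }
        attr(ord, "pair_id") <- base_pid
        ord
      })
    }
    out[[k]] <- lapply(seq_along(orderings), function(j) {
      ord <- orderings[[j]]
      study_list(sprintf("L%d.o%d", k, j), as.character(ord),
                 pair_assignment = ifelse(is.na(attr(ord, "pair_id")),
                                          NA_character_,
                                          paste0("p", attr(ord, "pair_id"))))
    })
  }
  out
}

#' Check the non-adjacency constraint of an ordering
#'
#' @param sl a [study_list()] with `pair_assignment`.
#' @return number of adjacent positions occupied by members of the same
#'   designated pair (0 for a valid ordering).
#' @export
count_adjacent_pair_violations <- function(sl) {
  p <- sl$pair_assignment
  if (is.null(p)) return(0L)
  sum(!is.na(p[-length(p)]) & !is.na(p[-1L]) &
        p[-length(p)] == p[-1L])
}
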