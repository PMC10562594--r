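# Independent brute-force oracles for transition scoring.
#
# These deliberately share no code with the package: validity, availability,
# ranks and tallies are recomputed by direct enumeration, with ranks via
# counting (R = #smaller + (#tied + 1)/2) rather than base rank().

# seq_types: character vector, each "C" (list word), "X" (intrusion); spos:
# serial position for "C" entries (may repeat -> later ones are repetitions)
oracle_score <- function(spos, types, L, simm = NULL) {
  n <- length(types)
  label <- character(n)
  seen <- integer(0)
  for (i in seq_len(n)) {
    if (types[i] == "X") {
      label[i] <- "ELI"
    } else if (spos[i] %in% seen) {
      label[i] <- "repetition"
    } else {
      label[i] <- "correct"
      seen <- c(seen, spos[i])
    }
  }
  lags <- setdiff(-(L - 1):(L - 1), 0)
  actual <- possible <- setNames(rep(0L, length(lags)), as.character(lags))
  tf <- sf <- numeric(0)
  credited <- integer(0)
  for (i in seq_len(n)) {
    if (label[i] == "correct") credited <- c(credited, spos[i])
    if (i == n) break
    if (label[i] != "correct" || label[i + 1] != "correct") next
    from <- spos[i]; to <- spos[i + 1]
    avail <- setdiff(seq_len(L), credited)  # from already credited
    actual[as.character(to - from)] <- actual[as.character(to - from)] + 1L
    for (t in avail) {
      possible[as.character(t - from)] <- possible[as.character(t - from)] + 1L
    }
    N <- length(avail)
    if (N >= 2) {
      key <- -abs(avail - from)
      ka <- -abs(to - from)
      R <- sum(key < ka) + (sum(key == ka) + 1) / 2
      tf <- c(tf, (R - 1) / (N - 1))
      if (!is.null(simm)) {
        key <- simm[from, avail]
        ka <- simm[from, to]
        R <- sum(key < ka) + (sum(key == ka) + 1) / 2
        sf <- c(sf, (R - 1) / (N - 1))
      }
    }
  }
  list(label = label, actual = actual, possible = possible,
       crp = ifelse(possible > 0, actual / possible, NA_real_),
       tf = tf, sf = sf)
}

# random small instance: L <= 8, responses with intrusions and repetitions
random_instance <- function(L = sample(4:8, 1)) {
  n <- sample(2:(L + 2), 1)
  types <- ifelse(runif(n) < 0.15, "X", "C")
  spos <- ifelse(types == "C", sample.int(L, n, replace = TRUE), NA)
  list(L = L, types = types, spos = as.integer(spos))
}

# build a resolved recall_sequence + study list for an instance
instance_to_sequence <- function(inst, subject = "s1") {
  words <- sprintf("word%02d", seq_len(inst$L))
  sl <- study_list("L1", words)
  resp <- ifelse(inst$types == "X",
                 sprintf("zzzz%02d", seq_along(inst$types)),
                 words[inst$spos])
  rs <- recall_sequence(subject, "same_context", 1L, resp, list_id = "L1")
  list(study = sl, seq = resolve_responses(rs, sl))
}

# position-similarity matrix for semantic oracle checks (indexed by
# serial position, mirroring sim[words[i], words[j]])
random_pos_sim <- function(L) {
  m <- matrix(runif(L * L), L, L)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# resolved transcript straight from serial positions (all correct recalls)
positions_to_sequence <- function(pos, L, condition = "same_context",
                                  subject = "s1", order = 1L,
                                  list_id = "L1") {
  words <- sprintf("word%02d", seq_len(L))
  resp <- data.frame(response = words[pos], type = "correct",
                     serial_position = as.integer(pos),
                     stringsAsFactors = FALSE)
  recall_sequence(subject, condition, order, resp, list_id = list_id)
}

# study list + similarity matrix pair used across scoring tests
fixture_list_sim <- function(L = 32, n_pairs = 16, seed = 404) {
  sim <- generate_similarity(L = L, n_pairs = n_pairs, seed = seed)
  sl <- study_list("L1", rownames(sim))
  list(study = sl, sim = sim)
}
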