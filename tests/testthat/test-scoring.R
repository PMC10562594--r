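test_that("transitions carry the worked lags and availability sets", {
  sl <- study_list("L1", sprintf("w%02d", 1:32))
  rs <- positions_to_sequence(c(5, 6, 2), 32)
  tr <- extract_transitions(rs, 32)
  expect_identical(tr$lag, c(1L, -4L))
  expect_true(all(tr$valid))

  # availability in L=4 after recalling 2 then 3 then 1
  rs4 <- positions_to_sequence(c(2, 3, 1), 4)
  tr4 <- extract_transitions(rs4, 4)
  expect_identical(tr4$possible_targets[[1]], c(1L, 3L, 4L))
  expect_identical(tr4$possible_targets[[2]], c(1L, 4L))
})

test_that("intrusions and repetitions invalidate adjacent transitions", {
  sl <- study_list("L1", sprintf("w%02d", 1:8))
  rs <- recall_sequence("s1", "same_context", 1L,
                        c("w03", "zebra", "w07"), list_id = "L1")
  rs <- resolve_responses(rs, sl)
  tr <- extract_transitions(rs, 8)
  expect_identical(sum(tr$valid), 0L)

  # repetition: w03 twice; both transitions around the repeat invalid
  rs2 <- resolve_responses(
    recall_sequence("s1", "same_context", 1L,
                    c("w03", "w04", "w03", "w06"), list_id = "L1"), sl)
  tr2 <- extract_transitions(rs2, 8)
  expect_identical(tr2$valid, c(TRUE, FALSE, FALSE))
  # the repeated item stays credited: 3 is unavailable at the first step
  expect_false(3L %in% tr2$possible_targets[[1]])
})

test_that("lag_crp reproduces the hand-enumerated curve and conserves counts", {
  tr <- extract_transitions(positions_to_sequence(c(2, 3, 1), 4), 4)
  curve <- lag_crp(tr)
  getc <- function(l) curve$crp[curve$lag == l]
  expect_equal(getc(1), 1 / 2)
  expect_equal(getc(-2), 1)
  expect_equal(getc(-1), 0)
  expect_equal(getc(2), 0)
  expect_identical(sum(curve$actual), 2L)
  expect_true(is.na(getc(3)))

  # no valid transitions -> all-undefined curve
  sl <- study_list("L1", sprintf("w%02d", 1:4))
  rs <- resolve_responses(
    recall_sequence("s1", "same_context", 1L, c("zeb", "qux"),
                    list_id = "L1"), sl)
  empty <- lag_crp(extract_transitions(rs, 4))
  expect_true(all(is.na(empty$crp)))
})

test_that("temporal factor matches the worked example and its limits", {
  tr <- extract_transitions(positions_to_sequence(c(2, 3, 1), 4), 4)
  fs <- transition_factor(tr, "temporal")
  expect_equal(fs$scores, c(0.75, 0))
  expect_equal(fs$mean, 0.375)

  # strictly forward recall of 1..10 from a 32-item list
  tr10 <- extract_transitions(positions_to_sequence(1:10, 32), 32)
  expect_identical(transition_factor(tr10, "temporal")$mean, 1)

  # chance constant
  expect_identical(chance_level(), 0.5)
})

test_that("N = 1 transitions are excluded and empty means are undefined", {
  # full recall of a 3-item list: the last transition has one target left
  tr <- extract_transitions(positions_to_sequence(c(1, 2, 3), 3), 3)
  fs <- transition_factor(tr, "temporal")
  expect_length(fs$scores, 1L)

  # only one valid transition and it is N = 1 -> undefined mean
  tr2 <- extract_transitions(positions_to_sequence(c(1, 2), 2), 2)
  expect_true(is.na(transition_factor(tr2, "temporal")$mean))
})

test_that("semantic factor is 1 when recall follows maximal similarity", {
  lsim <- fixture_list_sim(L = 8, n_pairs = 0, seed = 11)
  simm <- unclass(lsim$sim)
  # greedy most-similar path over available words starting at position 1
  path <- 1L
  avail <- 2:8
  while (length(avail) > 1L) {
    nxt <- avail[which.max(simm[path[length(path)], avail])]
    path <- c(path, nxt)
    avail <- setdiff(avail, nxt)
  }
  tr <- extract_transitions(positions_to_sequence(path, 8), 8)
  fs <- transition_factor(tr, "semantic", sim = lsim$sim,
                          study = lsim$study)
  expect_identical(fs$mean, 1)
  expect_error(transition_factor(tr, "semantic"), "similarity matrix")
})

test_that("the unrestricted semantic denominator ranks against all words", {
  lsim <- fixture_list_sim(L = 6, n_pairs = 3, seed = 12)
  tr <- extract_transitions(positions_to_sequence(c(1, 4, 2), 6), 6)
  simm <- unclass(lsim$sim)
  fs <- transition_factor(tr, "semantic", sim = lsim$sim,
                          study = lsim$study, possible = "all")
  # second transition from position 4: candidates all but 4, N = 5
  cand <- setdiff(1:6, 4)
  key <- simm[4, cand]
  R <- unname(rank(key)[cand == 2])
  expect_equal(fs$scores[2], (R - 1) / 4)
})

test_that("scoring agrees exactly with the brute-force enumerator", {
  set.seed(99)
  for (rep in 1:200) {
    inst <- random_instance()
    built <- instance_to_sequence(inst)
    possim <- random_pos_sim(inst$L)
    words <- built$study$items
    simm <- possim
    dimnames(simm) <- list(words, words)
    sim <- similarity_matrix(simm)

    orc <- oracle_score(inst$spos, inst$types, inst$L,
                        simm = possim)
    tr <- extract_transitions(built$seq, inst$L)
    curve <- lag_crp(tr)
    expect_identical(curve$actual, unname(as.integer(orc$actual)))
    expect_identical(curve$possible, unname(as.integer(orc$possible)))
    expect_equal(curve$crp, unname(orc$crp))
    expect_equal(transition_factor(tr, "temporal")$scores, orc$tf)
    expect_equal(transition_factor(tr, "semantic", sim = sim,
                                   study = built$study)$scores, orc$sf)
  }
})

test_that("adjacent/remote summary averages the right cells", {
  lags <- setdiff(-31:31, 0)
  crp <- rep(0, length(lags))
  crp[lags == 1] <- 0.4
  crp[lags == 2] <- 0.2
  curve <- structure(data.frame(lag = lags, actual = 0, possible = 1,
                                crp = crp),
                     L = 32L, class = c("crp_curve", "data.frame"))
  s <- adjacent_remote_summary(curve)
  expect_equal(unname(s["forward_adjacent"]), 0.3)
  expect_equal(unname(s["forward_remote"]), 0)

  curve$crp <- NA_real_
  expect_true(all(is.na(adjacent_remote_summary(curve))))
})

test_that("serial position curve bins and errors as specified", {
  spc <- matrix(0L, 5, 32)
  spc[, 1:8] <- 1L
  sp <- serial_position_curve(spc)
  expect_equal(sp$bin_means, c(1, 0, 0, 0))
  expect_error(serial_position_curve(spc, n_bins = 5), "not divisible")

  set.seed(5)
  rnd <- t(replicate(4000, {
    v <- integer(32); v[sample.int(32, 12)] <- 1L; v
  }))
  expect_equal(serial_position_curve(rnd)$bin_means, rep(12 / 32, 4),
               tolerance = 0.02)
  br <- binned_recall(rnd[1:3, ])
  expect_identical(dim(br), c(3L, 4L))
  expect_equal(rowSums(br) * 8, rowSums(rnd[1:3, ]))
})

test_that("probability of first recall is a distribution over positions", {
  expect_equal(probability_of_first_recall(rep(32L, 7), 32),
               c(rep(0, 31), 1))
  set.seed(6)
  p <- probability_of_first_recall(sample.int(32, 3000, replace = TRUE), 32)
  expect_equal(sum(p), 1)
  expect_lt(max(abs(p - 1 / 32)), 0.02)
  expect_error(probability_of_first_recall(NA_integer_, 32), "no transcript")
})

test_that("average_crp pools per-subject curves over defined lags", {
  lsim <- fixture_list_sim(L = 8, n_pairs = 4, seed = 21)
  p <- sim_params(L = 8, n_subjects = 4, seed = 21, epsilon = 0)
  recalls <- lapply(1:4, function(s) {
    simulate_recall(lsim$study, lsim$sim, p, subject_id = paste0("s", s))
  })
  coh <- score_cohort(recalls, lsim$study, lsim$sim)
  av <- average_crp(coh)
  man <- vapply(coh$transitions,
                function(tr) lag_crp(tr, 8)$crp[lag_crp(tr, 8)$lag == 1],
                0)
  expect_equal(av$crp[av$lag == 1], mean(man, na.rm = TRUE))
  expect_true(all(av$crp >= 0 & av$crp <= 1, na.rm = TRUE))
})
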