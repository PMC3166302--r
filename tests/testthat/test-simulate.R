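test_that("markov_background honours transition tables and seeds", {
  # degenerate order-1 chain: next base always equals the previous one
  ident <- diag(4)
  dimnames(ident) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  s <- markov_background(5, 30, order = 1, transitions = ident,
                         initial = c(1, 0, 0, 0), seed = 61)
  expect_true(all(s == strrep("A", 30)))
  # same seed, same output
  a <- markov_background(10, 50, order = 3, seed = 62)
  b <- markov_background(10, 50, order = 3, seed = 62)
  expect_identical(a, b)
  # order-0 uniform: base frequencies within 3 standard errors
  u <- markov_background(200, 200, order = 0, seed = 63)
  codes <- unlist(lapply(u, tpwm:::seq_to_int))
  freq <- tabulate(codes, 4) / length(codes)
  se <- sqrt(0.25 * 0.75 / length(codes))
  expect_true(all(abs(freq - 0.25) < 3 * se))
  # malformed table is rejected with its context named
  bad <- uniform_transitions(1)
  bad["C", ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(markov_background(1, 10, order = 1, transitions = bad),
               "context 'C'")
})

test_that("sample_site respects column and block supports", {
  # probability-1 columns: always the consensus
  cols <- matrix(0, 4, 3); cols[cbind(c(1, 2, 3), 1:3)] <- 1
  m <- motif_model(cols)
  expect_true(all(sample_site(m, 20, seed = 64) == "ACG"))
  # block support: only AA or CC at the correlated positions
  joint <- array(0, c(4, 4)); joint[1, 1] <- 0.5; joint[2, 2] <- 0.5
  mb <- motif_model(matrix(0.25, 4, 4),
                    blocks = list(list(positions = c(2, 4), joint = joint)))
  words <- sample_site(mb, 200, seed = 65)
  pair <- paste0(substr(words, 2, 2), substr(words, 4, 4))
  expect_true(all(pair %in% c("AA", "CC")))
  # empirical block frequencies within 3 standard errors of the table
  n <- 10000
  words <- sample_site(mb, n, seed = 66)
  phat <- mean(paste0(substr(words, 2, 2), substr(words, 4, 4)) == "AA")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("motif_model validates blocks and computes marginals", {
  joint <- array(0, c(4, 4)); joint[1, 2] <- 0.6; joint[3, 4] <- 0.4
  m <- motif_model(matrix(0.25, 4, 3),
                   blocks = list(list(positions = c(1, 3), joint = joint)))
  marg <- motif_marginal(m)$probs
  expect_equal(unname(marg[, 1]), c(0.6, 0, 0.4, 0))   # rows of the joint
  expect_equal(unname(marg[, 3]), c(0, 0.6, 0, 0.4))   # columns
  expect_equal(unname(marg[, 2]), rep(0.25, 4))
  expect_error(motif_model(matrix(0.25, 4, 3),
                           blocks = list(list(positions = c(1, 5),
                                              joint = joint))),
               "within 1..width")
  expect_error(motif_model(matrix(0.25, 4, 3),
                           blocks = list(list(positions = c(1, 3),
                                              joint = joint * 2))),
               "probability distribution")
})

test_that("implant follows the abundance scheme and records the truth", {
  mod <- builtin_motif("strong10")
  seqs <- markov_background(50, 60, order = 0, seed = 67)
  all_in <- implant(seqs, mod, abundance = 1, seed = 68)
  expect_true(all(all_in$truth$has_site))
  expect_true(all(all_in$truth$start >= 0 & all_in$truth$start <= 50))
  # implanted words sit where the truth says
  got <- substr(all_in$sequences, all_in$truth$start + 1,
                all_in$truth$start + 10)
  expect_identical(got, all_in$truth$site_word)
  none <- implant(seqs, mod, abundance = 0, seed = 69)
  expect_identical(none$sequences, seqs)
  expect_false(any(none$truth$has_site))
  # binomial bound on the site count at abundance 0.8
  big <- implant(markov_background(3000, 30, order = 0, seed = 70),
                 mod, abundance = 0.8, seed = 71)
  expect_lt(abs(sum(big$truth$has_site) - 2400), 3 * sqrt(3000 * 0.8 * 0.2))
})

test_that("shuffling preserves composition while destroying position", {
  expect_identical(shuffle_negatives("A", seed = 72), "A")
  set.seed(73)
  seqs <- markov_background(20, 50, order = 0)
  shuf <- shuffle_negatives(seqs, seed = 74)
  for (i in seq_along(seqs)) {
    expect_identical(sort(strsplit(shuf[i], "")[[1]]),
                     sort(strsplit(seqs[i], "")[[1]]))
  }
  # a planted word rarely survives at its offset
  planted <- vapply(1:10, function(i) {
    s <- paste(rep("A", 190), collapse = "")
    s <- paste0(substr(s, 1, 90), "TGACTCAGGT", substr(s, 91, 190))
    substr(shuffle_negatives(s), 91, 100) == "TGACTCAGGT"
  }, logical(1L))
  expect_lte(sum(planted), 1)
})

test_that("make_dataset composes the pipeline reproducibly", {
  mod <- builtin_motif("dep10")
  d1 <- make_dataset(n = 40, length = 80, model = mod, abundance = 0.8,
                     seed = 75)
  expect_length(d1$pos, 40)
  expect_length(d1$neg, 40)
  expect_equal(nrow(d1$truth), 40)
  d2 <- make_dataset(n = 40, length = 80, model = mod, abundance = 0.8,
                     seed = 75)
  expect_identical(d1, d2)
  # negatives are per-sequence shuffles of the positives
  expect_identical(sort(strsplit(unname(d1$neg[1]), "")[[1]]),
                   sort(strsplit(unname(d1$pos[1]), "")[[1]]))
})

test_that("negatives lose the positional signal the positives carry", {
  set.seed(76)
  mod <- builtin_motif("strong10")
  truth_pwm <- tpwm:::new_pwm(motif_marginal(mod)$probs)
  wins <- vapply(1:10, function(i) {
    d <- make_dataset(n = 60, length = 100, model = mod, abundance = 0.8,
                      seed = 760 + i)
    mean(best_hits(truth_pwm, d$pos)$score) >
      mean(best_hits(truth_pwm, d$neg)$score)
  }, logical(1L))
  expect_true(all(wins))
})

test_that("built-in motif models are well-formed", {
  for (nm in c("strong10", "weak10", "strong20", "weak20", "dep10",
               "dep20c4", "dep20c6")) {
    m <- builtin_motif(nm)
    marg <- motif_marginal(m)
    expect_equal(colSums(marg$probs), rep(1, m$width), tolerance = 1e-9,
                 info = nm)
  }
  # conservation levels measured by information content, in bits/column
  expect_gt(information_content(builtin_motif("strong10")) / 10, 1.4)
  expect_lt(information_content(builtin_motif("weak10")) / 10, 1.1)
})
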