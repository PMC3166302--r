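test_that("mcc matches direct arithmetic and the zero convention", {
  expect_equal(mcc(50, 50, 0, 0), 1)
  expect_equal(mcc(0, 0, 50, 50), -1)
  expect_equal(mcc(45, 30, 20, 5), 1250 / sqrt(65 * 50 * 50 * 35))
  expect_equal(mcc(0, 10, 0, 10), 0)  # zero factor in the denominator
})

test_that("pwm_kld is a symmetric divergence with hand-checked values", {
  a <- tpwm:::new_pwm(matrix(c(0.5, 0.5, 1e-6, 1e-6) / (1 + 2e-6), 4))
  u <- tpwm:::new_pwm(matrix(0.25, 4, 1))
  expect_equal(pwm_kld(a, a), 0)
  expect_equal(pwm_kld(a, u), pwm_kld(u, a))
  # direct two-term arithmetic for width 1
  p <- a$probs[, 1]; q <- u$probs[, 1]
  expect_equal(pwm_kld(a, u),
               sum(0.5 * (p * log(p / q) + q * log(q / p))))
  set.seed(51)
  b <- estimate_pwm(random_alignment(30, 3), pseudocount = 1)
  c_ <- estimate_pwm(random_alignment(30, 3), pseudocount = 1)
  expect_equal(pwm_kld(b, c_), pwm_kld(c_, b))
  expect_error(pwm_kld(b, estimate_pwm(random_alignment(10, 4))), "widths")
  z <- tpwm:::new_pwm(matrix(c(1, 0, 0, 0), 4))
  expect_error(pwm_kld(z, u), "pseudocount")
})

test_that("tpd_config validates the grid and tolerances", {
  expect_error(tpd_config(fpr_grid = numeric(0)), "non-empty")
  expect_error(tpd_config(fpr_grid = c(0.1, 0.05)), "ascending")
  expect_error(tpd_config(fpr_grid = c(0.1, 1.2)), "in \\(0, 1\\)")
  cfg <- tpd_config(fpr_grid = c(0.05, 0.2), kld_tol = 0.01)
  expect_s3_class(cfg, "tpd_config")
})

test_that("tpd recovers a planted motif and keeps its bookkeeping honest", {
  set.seed(52)
  mod <- builtin_motif("strong10")
  sim <- make_dataset(n = 300, length = 120, model = mod, abundance = 0.8,
                      seed = 520)
  init <- consensus_to_pwm(motif_consensus(mod))
  cfg <- tpd_config(fpr_grid = c(0.02, 0.1, 0.3))
  fit <- tpd(sim$pos, sim$neg, init, cfg)

  # selection invariant, exactly
  mccs <- vapply(fit$per_fpr_trace, `[[`, numeric(1L), "mcc")
  expect_identical(fit$best_mcc, max(mccs))
  expect_identical(fit$best_fpr, cfg$fpr_grid[which.max(mccs)])
  # convergence bookkeeping: kld below tolerance unless the cap was hit
  for (t in fit$per_fpr_trace) {
    if (!t$failed && t$iterations < cfg$max_inner_iter) {
      expect_lt(t$final_kld, cfg$kld_tol)
    }
    expect_equal(t$confusion$tp + t$confusion$fn, length(sim$pos))
    expect_equal(t$confusion$tn + t$confusion$fp, length(sim$neg))
  }
  # the recovered marginal pattern is close to the truth
  expect_lt(pattern_accuracy(mod, fit$best_model)$delta, 1.5)
  expect_equal(fit$tpr,
               fit$per_fpr_trace[[which.max(mccs)]]$confusion$tp /
                 length(sim$pos))

  # training is deterministic: identical rerun, identical result
  fit2 <- tpd(sim$pos, sim$neg, init, cfg)
  expect_identical(fit2$best_mcc, fit$best_mcc)
  expect_identical(marginal_pwm(fit2$best_model)$probs,
                   marginal_pwm(fit$best_model)$probs)
})

test_that("no-signal data yields a near-zero MCC", {
  # identical positive and negative sets: best-hit scores coincide, so
  # tp = fp at every cutoff and the MCC is exactly zero
  seqs <- markov_background(150, 100, order = 0, seed = 530)
  init <- consensus_to_pwm("TGACTCAGGT")
  fit <- tpd(seqs, seqs, init, tpd_config(fpr_grid = c(0.1, 0.3)))
  expect_equal(fit$best_mcc, 0)
  # motif-free positives vs their shuffles: only small-sample fluctuation
  pos <- markov_background(500, 100, order = 0, seed = 531)
  neg <- shuffle_negatives(pos, seed = 532)
  fit2 <- tpd(pos, neg, init, tpd_config(fpr_grid = c(0.05, 0.1, 0.3)))
  expect_lt(abs(fit2$best_mcc), 0.15)
})

test_that("rates that align no sites fail softly, all-failure errors", {
  # positives identical to negatives: with k = 0 the cutoff exceeds every
  # best-hit score and no site can be aligned
  seqs <- markov_background(20, 40, order = 0, seed = 54)
  init <- consensus_to_pwm("ACGTACGT")
  res <- tpd_fit_at_fpr(seqs, seqs, init, r = 0.01)
  expect_true(res$trace$failed)
  expect_identical(res$trace$mcc, -Inf)
  expect_error(tpd(seqs, seqs, init, tpd_config(fpr_grid = 0.01)),
               "no model discriminates")
})
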