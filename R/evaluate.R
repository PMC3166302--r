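# Evaluation metrics: pattern prediction accuracy (L1 distance between
# true and estimated marginal matrices), sequence-level ROC/AUC from
# best-hit scores with a two-fold cross-validation driver, and
# information content.

#' Pattern prediction accuracy
#'
#' Sum over positions and nucleotides of the absolute differences between
#' the true (marginal) probabilities and their estimates:
#' `delta = sum_i sum_a | p_ia - phat_ia |`.  Smaller is better; the range
#' is `[0, 2 * width]`.  Because a motif can be recovered in either
#' orientation, the estimate is compared both as-is and
#' reverse-complemented and the smaller distance is reported together
#' with the orientation used.
#'
#' @param truth A [motif_model()], `pwm` or `tpwm` giving the true
#'   distribution (marginalized as needed).
#' @param estimate The estimated `pwm` (or `tpwm`/`motif_model`,
#'   marginalized).
#' @return List with `delta` and `orientation` (`"forward"` or
#'   `"revcomp"`).
#' @export
pattern_accuracy <- function(truth, estimate) {
  as_marginal <- function(x) {
    if (inherits(x, "tpwm")) marginal_pwm(x)
    else if (inherits(x, "motif_model")) motif_marginal(x)
    else if (inherits(x, "pwm")) x
    else stop("expected a pwm, tpwm or motif_model", call. = FALSE)
  }
  t_ <- as_marginal(truth)
  e_ <- as_marginal(estimate)
  if (t_$width != e_$width) {
    stop(sprintf("width mismatch: truth %d vs estimate %d",
                 t_$width, e_$width), call. = FALSE)
  }
  d_fwd <- sum(abs(t_$probs - e_$probs))
  d_rev <- sum(abs(t_$probs - reverse_complement_pwm(e_)$probs))
  if (d_fwd <= d_rev) list(delta = d_fwd, orientation = "forward")
  else list(delta = d_rev, orientation = "revcomp")
}

#' Sequence-level ROC curve and AUC from best-hit scores
#'
#' Sweeps a threshold over the pooled scores; a sequence is called
#' positive when its best-hit score is at or above the threshold.  The
#' area under the curve is the trapezoidal integral of the stored points,
#' which for this construction equals the Mann-Whitney statistic with
#' ties counted one half.
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors (`NA`
#'   treated as `-Inf`).
#' @return An object of class `roc_curve`: `thresholds`, `fpr`, `tpr`
#'   (each from the (0,0) to the (1,1) end of the curve) and `auc`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both score lists must be non-empty", call. = FALSE)
  }
  pos <- as.numeric(pos_scores); pos[is.na(pos)] <- -Inf
  neg <- as.numeric(neg_scores); neg[is.na(neg)] <- -Inf
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1L))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1L))
  thresholds <- c(Inf, th)
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Write a ROC curve as TSV plus a JSON summary
#'
#' @param roc A `roc_curve`.
#' @param path Output TSV (columns threshold, fpr, tpr); a JSON summary
#'   `{"auc": ...}` is written next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(roc, path) {
  write.table(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                         tpr = roc$tpr),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(auc = roc$auc),
                       paste0(sub("\\.tsv$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Two-fold cross-validated motif enrichment
#'
#' Splits the positive set into random halves (seeded), derives each
#' fold's negatives by Fisher-Yates shuffling of its own positives,
#' trains on one half and scores the held-out half's positives and
#' negatives, then swaps the folds.  Enrichment is summarized by the
#' per-fold [roc_auc()] of the best-hit scores under the trained model.
#'
#' @param pos_seqs Character vector of at least 4 positive sequences.
#' @param trainer Function `(pos, neg) -> model` (a `pwm` or `tpwm`), e.g.
#'   a closure around [tpd()] returning `$best_model`.
#' @param seed Integer seed for the fold split and the shuffles.
#' @param neg_factory Function `(sequences) -> negatives`; default
#'   [shuffle_negatives()].
#' @param background,both_strands Scoring settings, as in [best_hits()].
#' @return List with `folds` (two `roc_curve`s) and `mean_auc`.
#' @export
crossval_enrichment <- function(pos_seqs, trainer, seed = 1L,
                                neg_factory = shuffle_negatives,
                                background = NULL, both_strands = TRUE) {
  n <- length(pos_seqs)
  if (n < 4L) stop("need at least 4 positive sequences", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n)
  half <- idx[seq_len(n %/% 2L)]
  folds <- list(list(train = pos_seqs[half], test = pos_seqs[-half]),
                list(train = pos_seqs[-half], test = pos_seqs[half]))
  curves <- lapply(folds, function(f) {
    train_neg <- neg_factory(f$train)
    model <- trainer(f$train, train_neg)
    test_neg <- neg_factory(f$test)
    ps <- best_hits(model, f$test, background, both_strands)$score
    ns <- best_hits(model, test_neg, background, both_strands)$score
    roc_auc(ps, ns)
  })
  list(folds = curves,
       mean_auc = mean(vapply(curves, `[[`, numeric(1L), "auc")))
}

#' Information content of a PWM
#'
#' `sum_i (2 + sum_a p_ia log2 p_ia)` in bits, with `0 log 0 := 0`; the
#' standard measure of motif conservation (0 for uniform columns, 2 per
#' fully conserved column).
#'
#' @param pwm A `pwm` (or `tpwm`/`motif_model`, whose marginal is used).
#' @return Total information content in bits.
#' @export
information_content <- function(pwm) {
  if (inherits(pwm, "tpwm")) pwm <- marginal_pwm(pwm)
  if (inherits(pwm, "motif_model")) pwm <- motif_marginal(pwm)
  p <- pwm$probs
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + colSums(plogp))
}
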