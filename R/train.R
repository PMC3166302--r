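# TPD: discriminative construction of a TPWM from a positive and a
# negative sequence set, starting from an initial PWM.  For each false
# positive rate r on a grid, the inner loop alternates (a) calibrating a
# score cutoff on the negative set under the current model, (b) collecting
# the best-hit word of every positive sequence clearing the cutoff into an
# alignment, and (c) rebuilding the TPWM from that alignment, until the
# symmetrized Kullback-Leibler divergence between the marginal PWMs of
# consecutive models falls below a tolerance.  The model with the largest
# Matthews correlation coefficient across the grid wins.

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; defined as 0
#' when any factor of the denominator is 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Value in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Symmetrized Kullback-Leibler divergence between two PWMs
#'
#' Position-averaged symmetric KL divergence (natural log):
#' `(1/W) sum_i sum_a 0.5 * (p log(p/q) + q log(q/p))`.  Used as the
#' convergence measure of the TPD inner loop.
#'
#' @param a,b `pwm` objects of equal width with strictly positive cells
#'   (build with a pseudocount, or clamp, to avoid zeros).
#' @return Non-negative scalar; 0 iff the matrices are identical.
#' @export
pwm_kld <- function(a, b) {
  if (a$width != b$width) {
    stop(sprintf("PWM widths differ: %d vs %d", a$width, b$width),
         call. = FALSE)
  }
  p <- a$probs; q <- b$probs
  if (any(p == 0) || any(q == 0)) {
    stop("PWM has zero cells; rebuild with a positive pseudocount",
         call. = FALSE)
  }
  sum(0.5 * (p * log(p / q) + q * log(q / p))) / a$width
}

# Zero-tolerant variant used internally for convergence checks on marginal
# PWMs, whose branch-probability factors may contain honest zeros.
kld_safe <- function(a, b, eps = 1e-9) {
  clamp <- function(m) {
    m <- pmax(m, eps)
    sweep(m, 2L, colSums(m), "/")
  }
  pwm_kld(new_pwm(clamp(a$probs)), new_pwm(clamp(b$probs)))
}

#' Training configuration for TPD
#'
#' @param fpr_grid Ascending false positive rates in `(0, 1)` to profile;
#'   default `c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3)`.
#' @param kld_tol Convergence tolerance on the position-averaged symmetric
#'   KL divergence between consecutive marginal PWMs; default 0.001.
#' @param max_inner_iter Safety cap on inner iterations per rate
#'   (default 50); hitting it raises a warning and keeps the last model.
#' @param min_leaf,dep_threshold,pseudocount Passed to [build_tpwm()].
#' @param both_strands Scan both orientations (default TRUE).
#' @param seed Unused by training (which is deterministic); echoed for run
#'   provenance.
#' @return An object of class `tpd_config`.
#' @export
tpd_config <- function(fpr_grid = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3),
                       kld_tol = 0.001, max_inner_iter = 50L,
                       min_leaf = 100L, dep_threshold = 0.1,
                       pseudocount = 0.5, both_strands = TRUE,
                       seed = NULL) {
  fpr_grid <- as.numeric(fpr_grid)
  if (length(fpr_grid) == 0L || any(fpr_grid <= 0) || any(fpr_grid >= 1)) {
    stop("fpr_grid must be non-empty with values strictly in (0, 1)",
         call. = FALSE)
  }
  if (is.unsorted(fpr_grid, strictly = TRUE)) {
    stop("fpr_grid must be sorted ascending without duplicates",
         call. = FALSE)
  }
  stopifnot(kld_tol > 0, max_inner_iter >= 1, min_leaf >= 1,
            dep_threshold >= 0, pseudocount >= 0)
  structure(list(fpr_grid = fpr_grid, kld_tol = kld_tol,
                 max_inner_iter = as.integer(max_inner_iter),
                 min_leaf = as.integer(min_leaf),
                 dep_threshold = dep_threshold, pseudocount = pseudocount,
                 both_strands = isTRUE(both_strands), seed = seed),
            class = "tpd_config")
}

# Pre-encoded training context shared by every scan pass of a run.
tpd_context <- function(pos_seqs, neg_seqs, background, both_strands) {
  list(pos_seqs = pos_seqs, neg_seqs = neg_seqs,
       pos_codes = lapply(pos_seqs, seq_to_int),
       neg_codes = lapply(neg_seqs, seq_to_int),
       background = background, both_strands = both_strands)
}

# One full scan pass under `model`: negative cutoff at rate r, positive
# best hits, aligned words and confusion counts.
tpd_scan_pass <- function(model, ctx, r) {
  neg <- scan_codes(model, ctx$neg_codes, ctx$background, ctx$both_strands)
  cut <- cutoff_at_fpr(neg$score, r)
  pos <- scan_codes(model, ctx$pos_codes, ctx$background, ctx$both_strands)
  pos_score <- ifelse(is.na(pos$score), -Inf, pos$score)
  called <- which(pos_score >= cut$cutoff & pos$strand > 0L)
  tp <- sum(pos_score >= cut$cutoff)
  fp <- cut$k
  list(cutoff = cut,
       words = hit_words(ctx$pos_seqs[called], pos$start[called],
                         pos$strand[called], model$width),
       confusion = list(tp = tp, fn = length(ctx$pos_codes) - tp,
                        fp = fp, tn = length(ctx$neg_codes) - fp))
}

#' Fit a TPWM at one false positive rate
#'
#' Runs the TPD inner loop at a single rate `r`.  Iteration 1 scans with
#' the flat initial PWM; each subsequent iteration recalibrates the
#' negative-set cutoff under the current model, realigns the positive best
#' hits clearing it, and rebuilds the tree.  Convergence is declared when
#' the symmetric KLD between consecutive marginal PWMs drops below
#' `cfg$kld_tol` (default 0.001).  Confusion counts are reported under the
#' final model and its cutoff.
#'
#' @param pos_seqs,neg_seqs Character vectors of DNA sequences (positive /
#'   negative set).
#' @param init_pwm Initial `pwm` (e.g. from [read_transfac()] or
#'   [consensus_to_pwm()]).
#' @param r False positive rate in `(0, 1)`.
#' @param cfg A [tpd_config()].
#' @param background A [background_model()]; default uniform.
#' @return List with `model` (the fitted `tpwm`, or `NULL` on failure),
#'   `trace` (fpr, iterations, final_kld, confusion, mcc, n_aligned_sites,
#'   cutoff, failed flag) and `aligned_sites`.
#' @export
tpd_fit_at_fpr <- function(pos_seqs, neg_seqs, init_pwm, r, cfg = tpd_config(),
                           background = NULL) {
  ctx <- tpd_context(pos_seqs, neg_seqs, as_background(background),
                     cfg$both_strands)
  tpd_fit_ctx(ctx, init_pwm, r, cfg)
}

tpd_fit_ctx <- function(ctx, init_pwm, r, cfg) {
  stopifnot(length(ctx$pos_codes) > 0, length(ctx$neg_codes) > 0,
            inherits(init_pwm, "pwm"))
  failed <- function(iterations, kld) {
    list(model = NULL, aligned_sites = NULL,
         trace = list(fpr = r, iterations = iterations, final_kld = kld,
                      confusion = list(tp = NA, fn = NA, fp = NA, tn = NA),
                      mcc = -Inf, n_aligned_sites = 0L, cutoff = NA_real_,
                      failed = TRUE))
  }
  model <- init_pwm
  iterations <- 0L
  kld <- Inf
  repeat {
    pass <- tpd_scan_pass(model, ctx, r)
    if (length(pass$words) == 0L) return(failed(iterations, kld))
    iterations <- iterations + 1L
    new_model <- build_tpwm(site_alignment(pass$words),
                            min_leaf = cfg$min_leaf,
                            threshold = cfg$dep_threshold,
                            pseudocount = cfg$pseudocount)
    kld <- kld_safe(marginal_pwm(new_model), marginal_pwm(model))
    model <- new_model
    if (kld < cfg$kld_tol) break
    if (iterations >= cfg$max_inner_iter) {
      warning(sprintf(
        "inner loop at fpr %g stopped at max_inner_iter=%d (kld %.3g)",
        r, cfg$max_inner_iter, kld), call. = FALSE)
      break
    }
  }
  # confusion and alignment under the final model and its own cutoff
  final <- tpd_scan_pass(model, ctx, r)
  if (length(final$words) == 0L) return(failed(iterations, kld))
  cc <- final$confusion
  list(model = model,
       aligned_sites = site_alignment(final$words),
       trace = list(fpr = r, iterations = iterations, final_kld = kld,
                    confusion = cc,
                    mcc = mcc(cc$tp, cc$tn, cc$fp, cc$fn),
                    n_aligned_sites = length(final$words),
                    cutoff = final$cutoff$cutoff, failed = FALSE))
}

#' TPD: discriminative TPWM training over a false-positive-rate grid
#'
#' Runs [tpd_fit_at_fpr()] for every rate in `cfg$fpr_grid` and returns
#' the model with the largest Matthews correlation coefficient (lowest
#' rate on ties).  Rates whose inner loop loses all aligned sites are
#' marked failed and excluded from selection.
#'
#' @inheritParams tpd_fit_at_fpr
#' @return An object of class `tpd_result`: `best_model` (`tpwm`),
#'   `best_fpr`, `best_mcc`, `cutoff`, `tpr` (predicted true positive rate
#'   `tp / (tp + fn)`), `aligned_sites`, and `per_fpr_trace` (one entry
#'   per grid rate).
#' @examples
#' \donttest{
#' sim <- make_dataset(n = 200, length = 100, model = builtin_motif("strong10"),
#'                     abundance = 0.8, seed = 1)
#' init <- consensus_to_pwm(motif_consensus(builtin_motif("strong10")))
#' fit <- tpd(sim$pos, sim$neg, init, tpd_config(fpr_grid = c(0.05, 0.2)))
#' fit$best_mcc
#' }
#' @export
tpd <- function(pos_seqs, neg_seqs, init_pwm, cfg = tpd_config(),
                background = NULL) {
  ctx <- tpd_context(pos_seqs, neg_seqs, as_background(background),
                     cfg$both_strands)
  fits <- lapply(cfg$fpr_grid, function(r) {
    tpd_fit_ctx(ctx, init_pwm, r, cfg)
  })
  traces <- lapply(fits, `[[`, "trace")
  mccs <- vapply(traces, function(t) t$mcc, numeric(1L))
  if (all(!is.finite(mccs))) {
    stop("no model discriminates: every false positive rate failed",
         call. = FALSE)
  }
  best <- which.max(mccs)  # first (= lowest fpr) on ties
  bt <- traces[[best]]
  cc <- bt$confusion
  structure(list(best_model = fits[[best]]$model,
                 best_fpr = cfg$fpr_grid[best],
                 best_mcc = bt$mcc,
                 cutoff = bt$cutoff,
                 tpr = cc$tp / (cc$tp + cc$fn),
                 aligned_sites = fits[[best]]$aligned_sites,
                 per_fpr_trace = traces,
                 config = cfg),
            class = "tpd_result")
}

#' @export
print.tpd_result <- function(x, ...) {
  cat(sprintf(
    "tpd_result: best fpr %g, MCC %.4f, predicted TP rate %.3f, %d site(s)\n",
    x$best_fpr, x$best_mcc, x$tpr, x$aligned_sites$count))
  print(trace_df(x))
  invisible(x)
}

# Per-rate trace as a data.frame (also the on-disk trace TSV layout).
trace_df <- function(result) {
  do.call(rbind, lapply(result$per_fpr_trace, function(t) {
    data.frame(fpr = t$fpr, iterations = t$iterations,
               final_kld = t$final_kld, tp = t$confusion$tp,
               fn = t$confusion$fn, fp = t$confusion$fp,
               tn = t$confusion$tn, mcc = t$mcc,
               n_sites = t$n_aligned_sites)
  }))
}

#' Write the per-rate training trace as TSV
#' @param result A `tpd_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(result, path) {
  write.table(trace_df(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
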