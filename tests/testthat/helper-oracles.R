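# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; the oracles deliberately avoid the code paths they
# check (enumeration and direct arithmetic instead of tree traversal or
# the compiled scanner).

# All 4^width ACGT words of a given width (width <= 8).
enumerate_words <- function(width) {
  g <- do.call(expand.grid,
               rep(list(c("A", "C", "G", "T")), width))[, width:1, drop = FALSE]
  apply(g, 1L, paste, collapse = "")
}

# Random site alignment drawn from a two-subtype mixture so that built
# trees have real splits (and, with small subsets, missing branches).
random_correlated_alignment <- function(n, width) {
  cols1 <- replicate(width, as.numeric(stats::rgamma(4, 1)))
  cols1 <- sweep(cols1, 2L, colSums(cols1), "/")
  cols2 <- replicate(width, as.numeric(stats::rgamma(4, 1)))
  cols2 <- sweep(cols2, 2L, colSums(cols2), "/")
  z <- stats::runif(n) < 0.5
  m <- matrix(0L, n, width)
  for (j in seq_len(width)) {
    m[z, j] <- sample.int(4L, sum(z), replace = TRUE, prob = cols1[, j])
    m[!z, j] <- sample.int(4L, sum(!z), replace = TRUE, prob = cols2[, j])
  }
  letters4 <- c("A", "C", "G", "T")
  site_alignment(apply(m, 1L, function(r) paste(letters4[r], collapse = "")))
}

# Random uniform alignment (independent columns).
random_alignment <- function(n, width) {
  letters4 <- c("A", "C", "G", "T")
  site_alignment(vapply(seq_len(n), function(i) {
    paste(sample(letters4, width, replace = TRUE), collapse = "")
  }, ""))
}

# Brute-force best hit: every offset and strand via score_window(); exact
# reference for the compiled scanner.
brute_best_hit <- function(model, sequence, background = NULL,
                           both_strands = TRUE) {
  W <- model$width
  L <- nchar(sequence)
  best <- NULL
  for (start in 0:(L - W)) {
    w <- substr(sequence, start + 1L, start + W)
    if (grepl("[^ACGT]", w)) next
    cand <- list(list(word = w, strand = "+"))
    if (both_strands) {
      cand <- c(cand, list(list(word = reverse_complement(w), strand = "-")))
    }
    for (cc in cand) {
      sc <- score_window(model, cc$word, background)
      if (is.null(best) || sc > best$score) {
        best <- list(start = start, strand = cc$strand, score = sc,
                     word = cc$word)
      }
    }
  }
  best
}

# Mann-Whitney AUC with ties counted one half (rank-sum identity).
rank_sum_auc <- function(pos, neg) {
  pos[is.na(pos)] <- -Inf
  neg[is.na(neg)] <- -Inf
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# Small random probability column.
random_column <- function() {
  x <- as.numeric(stats::rgamma(4, 1)) + 1e-3
  x / sum(x)
}
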