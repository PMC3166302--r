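# Hand-assembled two-level tree used in several blocks below: width 2,
# root split at position 1 with branch probabilities (.5, .3, .15, .05),
# children only for A and C, so G and T route through the fallback PWM.
make_fixture_tree <- function() {
  leaf_pwm <- function(col2) {
    tpwm:::new_pwm(matrix(c(0.25, 0.25, 0.25, 0.25, col2), 4))
  }
  root <- list(
    node_id = 1L, is_leaf = FALSE, n_sites = 100L,
    fixed = setNames(integer(0), character(0)),
    split_position = 1L,
    branch_probs = setNames(c(0.5, 0.3, 0.15, 0.05), c("A", "C", "G", "T")),
    children = list(
      A = list(node_id = 2L, is_leaf = TRUE, n_sites = 50L,
               fixed = c("1" = 1L),
               leaf_pwm = leaf_pwm(c(0.7, 0.1, 0.1, 0.1))),
      C = list(node_id = 3L, is_leaf = TRUE, n_sites = 30L,
               fixed = c("1" = 2L),
               leaf_pwm = leaf_pwm(c(0.25, 0.25, 0.25, 0.25)))),
    fallback_pwm = leaf_pwm(c(0.1, 0.2, 0.3, 0.4)))
  structure(list(width = 2L, root = root, min_leaf = 20L,
                 dep_threshold = 0.1, pseudocount = 0.5, n_sites = 100L),
            class = "tpwm")
}

# Width-4 alignment whose positions 1,2 are jointly {AA: .5, CC: .5} while
# positions 3,4 are uniform and independent.  Because positions 1 and 2
# carry identical letters, their dependency sums tie exactly and the
# documented tie-break selects position 1.  Uniform columns carry the
# largest sampling noise in the dependency statistic (~2.4/sqrt(n) under
# the null), so n is kept large enough that the 0.1 gate is quiet.
correlated_pair_alignment <- function(n) {
  z <- runif(n) < 0.5
  head2 <- ifelse(z, "AA", "CC")
  tail2 <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = "")
  }, "")
  site_alignment(paste0(head2, tail2))
}

test_that("build_tpwm splits jointly correlated positions and only those", {
  set.seed(31)
  tree <- build_tpwm(correlated_pair_alignment(4000), min_leaf = 400)
  expect_false(tree$root$is_leaf)
  expect_identical(tree$root$split_position, 1L)
  expect_setequal(names(tree$root$children), c("A", "C"))
  expect_true(all(vapply(tree$root$children, `[[`, TRUE, "is_leaf")))
})

test_that("column-independent sites give a single-leaf tree", {
  set.seed(32)
  aln <- random_alignment(3000, 6)
  tree <- build_tpwm(aln, min_leaf = 300)
  expect_true(tree$root$is_leaf)
  expect_identical(tpwm_n_splits(tree), 0L)
  # composite then reduces to the plain PWM column product
  p <- estimate_pwm(aln, pseudocount = 0.5)
  for (w in c("ACGTAC", "TTTTTT")) {
    expect_equal(composite_probability(tree, w),
                 composite_probability(p, w))
  }
})

test_that("build_tpwm is deterministic and respects structural invariants", {
  set.seed(33)
  aln <- random_correlated_alignment(500, 5)
  t1 <- build_tpwm(aln, min_leaf = 30, threshold = 0.05)
  t2 <- build_tpwm(aln, min_leaf = 30, threshold = 0.05)
  expect_identical(t1, t2)

  # distinct split positions along every root-to-leaf path; height <= width
  check_paths <- function(node, fixed_positions, depth) {
    expect_lte(depth, t1$width)
    if (node$is_leaf) return(invisible())
    expect_false(node$split_position %in% fixed_positions)
    expect_gte(length(node$children), 1L)
    expect_lte(length(node$children), 4L)
    expect_lte(sum(vapply(node$children, `[[`, 1L, "n_sites")),
               node$n_sites)
    for (ch in node$children) {
      expect_gte(ch$n_sites, 30L)
      check_paths(ch, c(fixed_positions, node$split_position), depth + 1L)
    }
  }
  check_paths(t1$root, integer(0), 0L)
})

test_that("a correlated-pair motif splits at one of its two positions", {
  set.seed(37)
  sites <- sample_site(builtin_motif("dep10"), 800)
  tree <- build_tpwm(site_alignment(sites), min_leaf = 100)
  expect_false(tree$root$is_leaf)
  expect_true(tree$root$split_position %in% c(3L, 8L))
  expect_true(all(tpwm_split_positions(tree) %in% c(3L, 8L)))
})

test_that("raising the threshold only prunes the root split", {
  set.seed(34)
  for (rep in 1:10) {
    aln <- random_correlated_alignment(300, 4)
    lo <- build_tpwm(aln, min_leaf = 20, threshold = 0.05)
    hi <- build_tpwm(aln, min_leaf = 20, threshold = 0.3)
    if (!hi$root$is_leaf) expect_false(lo$root$is_leaf)
  }
})

test_that("composite probabilities of the fixture tree match hand arithmetic", {
  tree <- make_fixture_tree()
  expect_equal(composite_probability(tree, "AA"), 0.5 * 0.7)
  expect_equal(composite_probability(tree, "AT"), 0.5 * 0.1)
  expect_equal(composite_probability(tree, "CG"), 0.3 * 0.25)
  # absent branches fall back to the node-wide PWM over position 2
  expect_equal(composite_probability(tree, "GA"), 0.15 * 0.1)
  expect_equal(composite_probability(tree, "TT"), 0.05 * 0.4)
  expect_error(composite_probability(tree, "A"), "length")
  expect_error(composite_probability(tree, "AN"), "non-ACGT")
})

test_that("composite model is a proper distribution and marginals agree", {
  set.seed(35)
  trees <- c(list(make_fixture_tree()), lapply(1:6, function(i) {
    w <- sample(3:6, 1)
    build_tpwm(random_correlated_alignment(250, w),
               min_leaf = sample(c(15L, 40L), 1), threshold = 0.05)
  }))
  for (tree in trees) {
    words <- enumerate_words(tree$width)
    probs <- vapply(words, function(w) composite_probability(tree, w),
                    numeric(1L))
    expect_equal(sum(probs), 1, tolerance = 1e-9)
    # brute-force marginalization over all words vs path traversal
    m <- marginal_pwm(tree)$probs
    codes <- tpwm:::sites_to_int(words)
    for (j in seq_len(tree$width)) {
      brute <- vapply(1:4, function(a) sum(probs[codes[, j] == a]),
                      numeric(1L))
      expect_equal(unname(m[, j]), brute, tolerance = 1e-9)
    }
    # path weights themselves form a distribution
    expect_equal(sum(tpwm:::tpwm_paths(tree)$weights), 1, tolerance = 1e-12)
  }
})

test_that("pseudocount-free marginals reproduce raw column frequencies", {
  # The law-of-total-probability identity holds exactly when every
  # positive-probability branch became a child: absent branches are
  # re-routed through the node-wide fallback PWM, which deliberately
  # replaces (not reproduces) the below-min_leaf conditional frequencies.
  set.seed(36)
  aln <- correlated_pair_alignment(4000)
  tree <- build_tpwm(aln, min_leaf = 400, pseudocount = 0)
  expect_false(tree$root$is_leaf)
  raw <- estimate_pwm(aln, pseudocount = 0)$probs
  expect_equal(marginal_pwm(tree)$probs, raw, tolerance = 1e-9)
  # single-leaf tree: marginal is the leaf PWM itself
  aln2 <- random_correlated_alignment(300, 4)
  leafy <- build_tpwm(aln2, min_leaf = 20, threshold = 2)
  expect_true(leafy$root$is_leaf)
  expect_equal(marginal_pwm(leafy)$probs, leafy$root$leaf_pwm$probs)
})
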