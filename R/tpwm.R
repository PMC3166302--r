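# Tree-based PWM (TPWM).
#
# A TPWM is a rooted tree built by recursive maximal-dependence
# subdivision of an aligned site set.  Each internal node records the motif
# position with the largest dependency sum among its sites, the raw
# nucleotide fractions at that position (branch probabilities), and up to
# four children, one per nucleotide subset that retains at least `min_leaf`
# sites.  Each leaf carries a conditional PWM fitted to the sites reaching
# it.  The composite distribution over motif words multiplies branch
# probabilities down the tree and leaf PWM columns over the unfixed
# positions; subsets too small to become children are routed through the
# parent's fallback PWM so the composite model stays a proper distribution
# over all 4^width words.

#' Build a tree-based PWM by maximal-dependence subdivision
#'
#' Recursively partitions the aligned sites: at each node the dependency
#' matrix over the not-yet-fixed positions is computed, the maximal
#' dependent position (see [maximal_dependent_position()]) is chosen, and
#' the sites are split into up to four subsets by the nucleotide at that
#' position.  Only subsets with at least `min_leaf` sites become children;
#' a node with no dependent position or no large-enough subset becomes a
#' leaf and stores a PWM fitted to its sites.
#'
#' @param sites A [site_alignment()].
#' @param min_leaf Minimum number of sites a subset must keep to become a
#'   child node (guards against unreliable conditional estimates).
#'   Default 100.
#' @param threshold Dependency gate passed to
#'   [maximal_dependent_position()]; default 0.1 on the L1 scale.
#' @param pseudocount Pseudocount for the leaf (and fallback) PWMs; branch
#'   probabilities always use raw fractions so observed absence stays
#'   absent in the routing logic.  Default 0.5.
#' @return An object of class `tpwm`.
#' @examples
#' sites <- c(rep("AACA", 5), rep("CCGA", 5))
#' build_tpwm(site_alignment(sites), min_leaf = 2, threshold = 0.1)
#' @export
build_tpwm <- function(sites, min_leaf = 100, threshold = 0.1,
                       pseudocount = 0.5) {
  if (!inherits(sites, "site_alignment")) sites <- site_alignment(sites)
  stopifnot(min_leaf >= 1, threshold >= 0, pseudocount >= 0)
  mat <- sites_to_int(sites)
  width <- sites$width
  counter <- new.env(parent = emptyenv())
  counter$id <- 0L

  fit_pwm_int <- function(m) {
    counts <- vapply(seq_len(width),
                     function(j) tabulate(m[, j], nbins = 4L), numeric(4L))
    probs <- (counts + pseudocount) / (nrow(m) + 4 * pseudocount)
    new_pwm(probs, counts = counts, pseudocount = pseudocount)
  }

  grow <- function(m, fixed) {
    counter$id <- counter$id + 1L
    id <- counter$id
    free <- setdiff(seq_len(width), as.integer(names(fixed)))
    split <- NA_integer_
    if (length(free) >= 2L) {
      dep <- dependency_matrix_int(m, free)
      split <- maximal_dependent_position(dep, threshold)
    }
    if (is.na(split)) {
      return(list(node_id = id, is_leaf = TRUE, n_sites = nrow(m),
                  fixed = fixed, leaf_pwm = fit_pwm_int(m)))
    }
    groups <- tabulate(m[, split], nbins = 4L)
    keep <- which(groups >= min_leaf)
    if (length(keep) == 0L) {
      return(list(node_id = id, is_leaf = TRUE, n_sites = nrow(m),
                  fixed = fixed, leaf_pwm = fit_pwm_int(m)))
    }
    branch_probs <- setNames(groups / nrow(m), DNA_LETTERS)
    fallback <- fit_pwm_int(m)
    children <- list()
    for (b in keep) {  # A < C < G < T order
      sub <- m[m[, split] == b, , drop = FALSE]
      child_fixed <- c(fixed, setNames(b, as.character(split)))
      children[[DNA_LETTERS[b]]] <- grow(sub, child_fixed)
    }
    list(node_id = id, is_leaf = FALSE, n_sites = nrow(m), fixed = fixed,
         split_position = split, branch_probs = branch_probs,
         children = children, fallback_pwm = fallback)
  }

  root <- grow(mat, setNames(integer(0), character(0)))
  structure(list(width = width, root = root, min_leaf = min_leaf,
                 dep_threshold = threshold, pseudocount = pseudocount,
                 n_sites = sites$count),
            class = "tpwm")
}

#' @export
print.tpwm <- function(x, ...) {
  cat(sprintf(
    "tpwm: width %d, %d sites, %d split node(s) (min_leaf %g, threshold %g)\n",
    x$width, x$n_sites, tpwm_n_splits(x), x$min_leaf, x$dep_threshold))
  show_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$is_leaf) {
      cat(sprintf("%sleaf (n=%d)\n", pad, node$n_sites))
    } else {
      cat(sprintf("%ssplit at position %d (n=%d)\n",
                  pad, node$split_position, node$n_sites))
      for (b in names(node$children)) {
        cat(sprintf("%s %s:\n", pad, b))
        show_node(node$children[[b]], indent + 1L)
      }
    }
  }
  show_node(x$root, 1L)
  invisible(x)
}

# All split positions used anywhere in the tree (may repeat across
# different branches, never along one root-to-leaf path).
#' Split positions of a TPWM
#'
#' @param model A `tpwm`.
#' @return Integer vector of the split positions at every internal node, in
#'   preorder; empty for a single-leaf tree.
#' @export
tpwm_split_positions <- function(model) {
  out <- integer(0)
  walk <- function(node) {
    if (!node$is_leaf) {
      out <<- c(out, node$split_position)
      for (ch in node$children) walk(ch)
    }
  }
  walk(model$root)
  out
}

#' Number of split (internal) nodes in a TPWM
#' @param model A `tpwm`.
#' @return Integer count; 0 means the model degenerates to a plain PWM.
#' @export
tpwm_n_splits <- function(model) length(tpwm_split_positions(model))

check_word <- function(word, width) {
  if (nchar(word) != width) {
    stop(sprintf("word length %d != model width %d", nchar(word), width),
         call. = FALSE)
  }
  codes <- seq_to_int(word)
  if (any(codes == 0L)) {
    stop("word contains non-ACGT letters", call. = FALSE)
  }
  codes
}

#' Composite probability of a motif word under a TPWM
#'
#' Walks the tree from the root: at each internal node the probability is
#' multiplied by the branch probability of the word's nucleotide at the
#' split position.  If that nucleotide has a child, descent continues;
#' otherwise the remaining unfixed positions are scored under the node's
#' fallback PWM.  At a leaf, the leaf PWM columns of all positions not
#' fixed on the path are multiplied in.  Summed over all `4^width` words
#' the result is exactly 1.
#'
#' @param model A `tpwm` (a plain `pwm` is accepted and scored as the
#'   product of its columns).
#' @param word ACGT string of length `model$width`.
#' @return Probability in `[0, 1]`.
#' @export
composite_probability <- function(model, word) {
  if (inherits(model, "pwm")) {
    codes <- check_word(word, model$width)
    return(prod(model$probs[cbind(codes, seq_len(model$width))]))
  }
  stopifnot(inherits(model, "tpwm"))
  codes <- check_word(word, model$width)
  p <- 1
  node <- model$root
  repeat {
    if (node$is_leaf) {
      free <- setdiff(seq_len(model$width), as.integer(names(node$fixed)))
      if (length(free) > 0L) {
        p <- p * prod(node$leaf_pwm$probs[cbind(codes[free], free)])
      }
      return(p)
    }
    sp <- node$split_position
    b <- codes[sp]
    p <- p * node$branch_probs[[b]]
    child <- node$children[[DNA_LETTERS[b]]]
    if (is.null(child)) {
      # absent branch: score remaining unfixed positions (split position
      # excluded -- the branch probability already covered it) under the
      # node-wide fallback PWM
      if (p == 0) return(0)
      free <- setdiff(seq_len(model$width),
                      c(as.integer(names(node$fixed)), sp))
      if (length(free) > 0L) {
        p <- p * prod(node$fallback_pwm$probs[cbind(codes[free], free)])
      }
      return(p)
    }
    node <- child
  }
}

# Decompose a model into disjoint scoring paths.  Each path has a weight
# (product of branch probabilities down to a leaf or into an absent branch)
# and a 4 x width column-stochastic matrix: indicator columns at the
# positions fixed by the path, PWM columns elsewhere.  The composite
# probability of a word is sum_k w_k prod_i M_k[word_i, i]; weights sum
# to 1.  Used by the scanner kernel and by marginal_pwm().
tpwm_paths <- function(model) {
  if (inherits(model, "pwm")) {
    return(list(weights = 1, mats = list(model$probs)))
  }
  stopifnot(inherits(model, "tpwm"))
  width <- model$width
  weights <- numeric(0)
  mats <- list()
  indicator <- function(code) { v <- numeric(4L); v[code] <- 1; v }

  emit <- function(w, fixed, pwm_probs) {
    m <- pwm_probs
    for (k in seq_along(fixed)) {
      m[, as.integer(names(fixed)[k])] <- indicator(fixed[[k]])
    }
    weights[[length(weights) + 1L]] <<- w
    mats[[length(mats) + 1L]] <<- m
  }

  walk <- function(node, w) {
    if (w == 0) return(invisible())
    if (node$is_leaf) {
      emit(w, node$fixed, node$leaf_pwm$probs)
      return(invisible())
    }
    sp <- node$split_position
    for (b in 1:4) {
      bw <- w * node$branch_probs[[b]]
      if (bw == 0) next
      child <- node$children[[DNA_LETTERS[b]]]
      if (is.null(child)) {
        emit(bw, c(node$fixed, setNames(b, as.character(sp))),
             node$fallback_pwm$probs)
      } else {
        walk(child, bw)
      }
    }
  }
  walk(model$root, 1)
  list(weights = unlist(weights), mats = mats)
}

#' Position-wise marginal PWM of a TPWM
#'
#' Marginalizes the composite distribution position by position by
#' traversing root-to-leaf (and absent-branch) paths with their path
#' weights, without enumerating words.  For a tree built with pseudocount 0
#' this reproduces the raw column frequencies of the training alignment.
#'
#' @param model A `tpwm` (or a `pwm`, returned unchanged).
#' @return A `pwm` holding the marginal column distributions.
#' @export
marginal_pwm <- function(model) {
  if (inherits(model, "pwm")) return(model)
  paths <- tpwm_paths(model)
  probs <- Reduce(`+`, Map(function(w, m) w * m, paths$weights, paths$mats))
  new_pwm(probs, pseudocount = 0)
}
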