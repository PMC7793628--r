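## Fitch parsimony, per-character homoplasy, and a seeded implied-weights
## heuristic search (random-addition starts + SPR) standing in for a TNT
## implied-weights analysis with concavity constant k.

## Core Fitch pass over bitmask state sets, vectorized across characters.
## `tipmask`: ntip x nchar integer bitmasks with missing/inapplicable already
## widened to the full uncertainty set. Multifurcations are folded
## sequentially (exact for binary trees incl. a degree-3 root).
fitch_core <- function(pt, tipmask) {
  kids <- pt_children(pt)
  nchar_ <- ncol(tipmask)
  nodemask <- matrix(0L, length(pt$parent), nchar_)
  live_tips <- which(seq_len(pt$ntip) %in% c(which(pt$parent > 0L), pt$root))
  nodemask[live_tips, ] <- tipmask[live_tips, , drop = FALSE]
  steps <- integer(nchar_)
  for (v in pt_postorder(pt, kids)) {
    ch <- kids[[v]]
    acc <- nodemask[ch[1L], ]
    for (c2 in ch[-1L]) {
      m2 <- nodemask[c2, ]
      a <- bitwAnd(acc, m2)
      zero <- a == 0L
      steps <- steps + zero
      acc <- ifelse(zero, bitwOr(acc, m2), a)
    }
    nodemask[v, ] <- acc
  }
  steps
}

## Widen missing/inapplicable cells to the character's full uncertainty set
## (union of observed states; all-missing characters become all-ones and
## contribute zero steps).
fitch_tipmask <- function(mm) {
  u <- state_union(mm)
  u[u == 0L] <- 1L
  m <- mm$mask
  wide <- is.na(m) | m == INAPP_CODE
  m[wide] <- rep(u, each = nrow(m))[wide]
  m
}

#' Fitch parsimony steps of one character on a topology
#'
#' Minimum number of unordered state changes of a single character on the
#' given tree. Missing (`?`) and inapplicable (`-`) cells, and polymorphic
#' state sets, enter as their uncertainty sets.
#'
#' @param tree An `ape::phylo` (rooted or unrooted binary).
#' @param character Named character vector of cell tokens (`"0"`, `"?"`,
#'   `"-"`, `"{01}"`, ...), names = taxon labels; every tip of `tree` must
#'   be present.
#' @param symbols Symbol alphabet (position i = state i-1).
#' @return Integer step count.
#' @export
fitch_steps <- function(tree, character, symbols = as.character(0:9)) {
  miss <- setdiff(tree$tip.label, names(character))
  if (length(miss)) {
    stop("tip(s) absent from character data: ", paste(miss, collapse = ", "))
  }
  cells <- vapply(tree$tip.label, function(tx) {
    parse_cell_string(character[[tx]], symbols, "?", "-", tx)
  }, integer(1))
  mm <- morph_matrix(matrix(cells, ncol = 1L), tree$tip.label,
                     symbols = symbols)
  fitch_steps_matrix(tree, mm)[1L]
}

#' Fitch step counts for every character of a matrix
#'
#' @param tree An `ape::phylo`; tip labels must match the matrix's taxa.
#' @param mm A [morph_matrix()].
#' @return Integer vector of steps, one per character.
#' @export
fitch_steps_matrix <- function(tree, mm) {
  if (!setequal(tree$tip.label, mm$taxa)) {
    stop("tree tips and matrix taxa differ")
  }
  pt <- phylo_to_pt(tree)
  tipmask <- fitch_tipmask(mm)[match(tree$tip.label, mm$taxa), , drop = FALSE]
  fitch_core(pt, tipmask)
}

#' Per-character homoplasy on a tree
#'
#' Extra steps beyond the character's minimum: Fitch steps minus
#' (observed state count - 1), clipped at zero.
#'
#' @inheritParams fitch_steps_matrix
#' @return Integer vector of homoplasy values.
#' @export
homoplasy <- function(tree, mm) {
  steps <- fitch_steps_matrix(tree, mm)
  pmax(steps - pmax(state_counts(mm) - 1L, 0L), 0L)
}

#' Implied-weights score of a tree
#'
#' Goloboff fit penalty `sum_c h_c / (h_c + k)` with `h_c` the homoplasy of
#' character `c` on the tree and concavity constant `k`; lower is better.
#'
#' @inheritParams fitch_steps_matrix
#' @param k Concavity constant (positive; default 10).
#' @return Numeric score.
#' @export
implied_weights_score <- function(tree, mm, k = 10) {
  if (k <= 0) stop("concavity constant k must be > 0")
  h <- homoplasy(tree, mm)
  sum(h / (h + k))
}

iw_score_pt <- function(pt, tipmask, minlen, k) {
  h <- pmax(fitch_core(pt, tipmask) - minlen, 0L)
  sum(h / (h + k))
}

#' Search configuration for the implied-weights heuristic
#'
#' @param k Concavity constant (default 10).
#' @param n_starts Number of random-addition starting trees.
#' @param spr_rounds Maximum SPR improvement rounds per start (`Inf` = to
#'   convergence).
#' @param seed RNG seed making the search deterministic.
#' @return A `parsimony_config` list.
#' @export
parsimony_config <- function(k = 10, n_starts = 10, spr_rounds = Inf,
                             seed = 1L) {
  stopifnot(k > 0, n_starts >= 1)
  structure(list(k = k, n_starts = n_starts, spr_rounds = spr_rounds,
                 seed = as.integer(seed)),
            class = "parsimony_config")
}

#' Heuristic implied-weights parsimony search
#'
#' Random-addition-sequence starting trees improved by SPR hill-climbing
#' under the implied-weights score. Deterministic for a given seed; ties are
#' kept at the first-found tree in the seeded evaluation order.
#'
#' @param mm A [morph_matrix()] with at least 4 taxa.
#' @param config A [parsimony_config()].
#' @return List: `tree` (ape `phylo`, unrooted semantics), `score`,
#'   `homoplasy` (per-character vector on the best tree), `steps`.
#' @export
implied_weights_search <- function(mm, config = parsimony_config()) {
  ntip <- n_taxa(mm)
  if (ntip < 4L) stop("implied-weights search needs at least 4 taxa")
  tipmask <- fitch_tipmask(mm)
  minlen <- pmax(state_counts(mm) - 1L, 0L)
  k <- config$k

  rng <- local_rng(config$seed)
  best <- NULL
  for (start in seq_len(config$n_starts)) {
    ord <- sample.int(ntip)
    pt <- pt_new3(ord[1L], ord[2L], ord[3L], ntip)
    nextint <- ntip + 3L
    for (tip in ord[-(1:3)]) {
      cand <- pt_edges(pt)
      sc <- vapply(cand, function(e) {
        iw_score_pt(pt_attach(pt, tip, e, nextint), tipmask, minlen, k)
      }, numeric(1))
      pt <- pt_attach(pt, tip, cand[which.min(sc)], nextint)
      nextint <- nextint + 1L
    }
    res <- spr_hillclimb(pt, tipmask, minlen, k, config$spr_rounds)
    if (is.null(best) || res$score < best$score - 1e-12) best <- res
  }
  rng()

  steps <- fitch_core(best$pt, tipmask)
  h <- pmax(steps - minlen, 0L)
  list(tree = pt_to_phylo(best$pt, mm$taxa), score = best$score,
       homoplasy = h, steps = steps)
}

spr_hillclimb <- function(pt, tipmask, minlen, k, max_rounds) {
  score <- iw_score_pt(pt, tipmask, minlen, k)
  round <- 0
  repeat {
    round <- round + 1
    improved <- FALSE
    kids <- pt_children(pt)
    for (v in pt_edges(pt)) {
      sub <- pt_subtree(pt, v, kids)
      ## pruning v must leave >= 3 nodes (2 tips) behind
      if (length(sub) >= 2L * pt$ntip - 3L) next
      det <- pt_detach(pt, v)
      base <- det$pt
      for (e in setdiff(pt_edges(base), sub)) {
        if (e == det$sib && base$parent[e] == base$parent[det$sib]) {
          ## reattaching to the sibling edge rebuilds the original tree
        }
        cand <- pt_attach(base, v, e, det$freed)
        sc <- iw_score_pt(cand, tipmask, minlen, k)
        if (sc < score - 1e-12) {
          pt <- cand
          score <- sc
          improved <- TRUE
          break
        }
      }
      if (improved) break
      ## restore original attachment
      pt <- pt_attach(base, v, det$sib, det$freed)
      kids <- pt_children(pt)
    }
    if (!improved || round >= max_rounds) break
  }
  list(pt = pt, score = score)
}

#' Lower-value homoplasy for variable-homology characters
#'
#' Characters whose homoplasy depends on the homology state are assigned the
#' lower value: the element-wise minimum across the per-state homoplasy
#' vectors.
#'
#' @param ... Integer vectors of per-character homoplasy, one per homology
#'   state (equal lengths), or a single list of such vectors.
#' @return Integer vector of element-wise minima.
#' @export
homology_min_homoplasy <- function(...) {
  vecs <- list(...)
  if (length(vecs) == 1L && is.list(vecs[[1L]])) vecs <- vecs[[1L]]
  lens <- vapply(vecs, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("per-state homoplasy vectors have unequal lengths: ",
         paste(lens, collapse = ", "))
  }
  do.call(pmin, vecs)
}

## Seeded RNG scope: snapshots the global RNG state, seeds, and returns a
## restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}
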