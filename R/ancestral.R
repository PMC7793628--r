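## Ancestral phenotype sampling: joint draws of all character states at a
## focal node (the MRCA of a constrained clade), one per posterior sample,
## under the active homology alignment. Conditional node-state
## probabilities come from re-rooting the pruning pass at the focal node:
## with a reversible model and uniform root frequencies, P(state at v |
## data) is proportional to the re-rooted root partial.

## Traversal of the tree re-rooted at `node`: new parent orientation, the
## expected-substitution length of the edge above each node (before
## partition-rate scaling), and a postorder over nodes with children.
reroot_traversal <- function(tt, subs_base, node) {
  n <- length(tt$parent)
  nbr <- vector("list", n)
  wt <- vector("list", n)
  for (v in seq_len(n)) {
    p <- tt$parent[v]
    if (p > 0L) {
      nbr[[v]] <- c(nbr[[v]], p); wt[[v]] <- c(wt[[v]], subs_base[v])
      nbr[[p]] <- c(nbr[[p]], v); wt[[p]] <- c(wt[[p]], subs_base[v])
    }
  }
  parent2 <- integer(n)
  elen2 <- numeric(n)
  seen <- logical(n)
  queue <- node
  seen[node] <- TRUE
  order_bfs <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    order_bfs <- c(order_bfs, v)
    for (ii in seq_along(nbr[[v]])) {
      w <- nbr[[v]][ii]
      if (!seen[w]) {
        seen[w] <- TRUE
        parent2[w] <- v
        elen2[w] <- wt[[v]][ii]
        queue <- c(queue, w)
      }
    }
  }
  kids2 <- vector("list", n)
  for (v in order_bfs) {
    p <- parent2[v]
    if (p > 0L) kids2[[p]] <- c(kids2[[p]], v)
  }
  post <- rev(order_bfs)
  post <- post[vapply(kids2[post], length, integer(1)) > 0L]
  child_ids <- unlist(kids2[post], use.names = FALSE)
  child_ptr <- c(0L, cumsum(vapply(kids2[post], length, integer(1))))
  list(postorder = post, child_ptr = child_ptr, child_ids = child_ids,
       elen = elen2)
}

## Per-character conditional state probabilities at `node` for one prepared
## data bundle (mkd); returns a list of k x nchar probability matrices per
## non-NULL partition.
node_probs_mkd <- function(rt, mkd, rates, node) {
  out <- vector("list", length(mkd$parts))
  for (p in seq_along(mkd$parts)) {
    pp <- mkd$parts[[p]]
    if (is.null(pp)) next
    part <- mk_prune_partials(rt$postorder, rt$child_ptr, rt$child_ids,
                              rt$elen * rates[p], pp$tippart, pp$k,
                              mkd$ntip, length(rt$elen))
    out[[p]] <- sweep(part, 2L, colSums(part), "/")
  }
  out
}

#' Conditional ancestral state probabilities at a clade's MRCA
#'
#' @param state A `model_state`.
#' @param model A `dynhom_model`.
#' @param focal_clade Character vector of taxon labels; must be
#'   monophyletic in the current tree.
#' @return List: `probs` (per composite character, named numeric vector of
#'   state probabilities on the actual state labels), `node`, `h`.
#' @export
ancestral_state_probs <- function(state, model, focal_clade) {
  tt <- state$tree
  tips <- match(focal_clade, tt$taxa)
  if (anyNA(tips)) {
    stop("unknown focal taxa: ",
         paste(focal_clade[is.na(tips)], collapse = ", "))
  }
  node <- mrca_node(tt, tips)
  if (!identical(clade_tips(tt, node), sort(tips))) {
    stop("focal clade is not monophyletic in the current tree")
  }
  kin <- tt_kernel_inputs(tt)
  rt <- reroot_traversal(tt, state_subs_base(state, kin), node)

  mkds <- c(list(model$mkd_fixed),
            lapply(seq_along(model$blocks), function(bi) {
              model$mkd_blocks[[bi]][[state$h[bi] + 1L]]
            }))
  offsets <- cumsum(c(0L, vapply(mkds, function(m) m$nchar, integer(1))))
  nchar_total <- offsets[length(offsets)]
  probs <- vector("list", nchar_total)
  for (mi in seq_along(mkds)) {
    mkd <- mkds[[mi]]
    pr <- node_probs_mkd(rt, mkd, state$rates, node)
    for (p in seq_along(mkd$parts)) {
      pp <- mkd$parts[[p]]
      if (is.null(pp)) next
      for (ci in seq_along(pp$chars)) {
        probs[[offsets[mi] + pp$chars[ci]]] <-
          stats::setNames(pr[[p]][, ci], pp$remap[[ci]])
      }
    }
  }
  list(probs = probs, node = node, h = state$h)
}

#' Draw a joint ancestral state vector at a clade's MRCA
#'
#' One coherent phenotype draw (all characters) from the conditional
#' distribution at the focal node given the tips, tree and parameters,
#' using the composite alignment of the active homology state. Characters
#' with no scored cell among the clade's tips are drawn from the node's
#' marginal (informed only by the rest of the tree) and flagged.
#'
#' @inheritParams ancestral_state_probs
#' @return An `ancestor_sample` list: `states` (integer vector of drawn
#'   state labels), `informed` (logical: any data among clade tips), `h`.
#' @export
sample_ancestral_states <- function(state, model, focal_clade) {
  ap <- ancestral_state_probs(state, model, focal_clade)
  states <- vapply(ap$probs, function(pv) {
    as.integer(names(pv)[sample.int(length(pv), 1L, prob = pv)])
  }, integer(1))

  tt <- state$tree
  tips <- sort(match(focal_clade, tt$taxa))
  clade <- clade_tips(tt, ap$node)
  masks <- model$fixed$mask[clade, , drop = FALSE]
  for (bi in seq_along(model$blocks)) {
    cod <- model$blocks[[bi]]$codings[[state$h[bi] + 1L]]
    masks <- cbind(masks,
                   cod$mask[match(tt$taxa[clade], cod$taxa), , drop = FALSE])
  }
  informed <- apply(masks, 2L, function(col) any(!is.na(col) & col != 0L))

  structure(list(states = states, informed = informed, h = state$h),
            class = "ancestor_sample")
}

#' Posterior state summaries across ancestor samples
#'
#' Per character, the frequency of each drawn state across samples, the
#' modal state with its posterior probability, and the fraction of samples
#' where the character had no data in the clade context.
#'
#' @param samples List of `ancestor_sample` objects (>= 1).
#' @param char_names Optional character names.
#' @return Data frame (character, modal_state, pp, p_flagged) with the full
#'   per-state frequency matrix as attribute `"freq"`.
#' @export
ancestral_state_posteriors <- function(samples, char_names = NULL) {
  if (length(samples) < 1L) stop("need at least one ancestor sample")
  S <- do.call(rbind, lapply(samples, function(s) s$states))
  Fl <- do.call(rbind, lapply(samples, function(s) !s$informed))
  nchar_ <- ncol(S)
  freq <- matrix(0, nchar_, 10L, dimnames = list(NULL, as.character(0:9)))
  for (j in seq_len(nchar_)) {
    tab <- tabulate(S[, j] + 1L, nbins = 10L)
    freq[j, ] <- tab / nrow(S)
  }
  modal <- max.col(freq, ties.method = "first") - 1L
  pp <- freq[cbind(seq_len(nchar_), modal + 1L)]
  out <- data.frame(
    character = if (is.null(char_names)) seq_len(nchar_) else char_names,
    modal_state = modal, pp = pp, p_flagged = colMeans(Fl))
  attr(out, "freq") <- freq
  out
}

#' Write ancestor samples as TSV
#'
#' One row per retained sample: generation, homology state(s), then the
#' drawn state vector.
#'
#' @param run A `dynhom_mcmc` run with ancestor logging.
#' @param path Output path.
#' @param retain Sample indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_ancestors <- function(run, path, retain = NULL) {
  if (is.null(run$ancestors)) stop("run has no ancestor log")
  if (is.null(retain)) retain <- seq_along(run$ancestors)
  S <- do.call(rbind, lapply(run$ancestors[retain], function(s) s$states))
  hs <- do.call(rbind, lapply(run$ancestors[retain],
                              function(s) as.integer(s$h)))
  df <- data.frame(gen = run$trace$gen[retain])
  if (ncol(hs)) {
    for (bi in seq_len(ncol(hs))) df[[paste0("h_", bi)]] <- hs[, bi]
  }
  colnames(S) <- paste0("char_", seq_len(ncol(S)))
  df <- cbind(df, S)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
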