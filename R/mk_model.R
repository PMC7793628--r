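## Mk substitution model (Lewis' k-state symmetric CTMC) and the pruning
## log-likelihood for partitioned morphological matrices on dated trees.

#' Mk transition probability matrix
#'
#' Closed form for the k-state symmetric model at expected substitution
#' distance `d`: `P_same = 1/k + (k-1)/k exp(-k d/(k-1))`,
#' `P_diff = 1/k - 1/k exp(-k d/(k-1))`.
#'
#' @param k Number of states (>= 2).
#' @param d Expected substitutions (>= 0).
#' @return `k x k` probability matrix.
#' @export
mk_transition_prob <- function(k, d) {
  if (d < 0) stop("expected substitution distance d must be >= 0")
  if (k < 2) stop("Mk model needs k >= 2 states")
  e <- exp(-k * d / (k - 1))
  p_same <- 1 / k + (k - 1) / k * e
  p_diff <- 1 / k - e / k
  P <- matrix(p_diff, k, k)
  diag(P) <- p_same
  P
}

#' Per-partition Mk rates with the weighted-mean-one constraint
#'
#' @param rates Positive per-partition mutation rates.
#' @param weights Character counts per partition.
#' @param tol Tolerance on the constraint.
#' @return The rates, invisibly; errors if `sum(w r)/sum(w) != 1`.
#' @export
check_rate_constraint <- function(rates, weights, tol = 1e-9) {
  wm <- sum(weights * rates) / sum(weights)
  if (abs(wm - 1) > tol) {
    stop("weighted mean of partition rates is ", format(wm),
         ", must equal 1")
  }
  invisible(rates)
}

## Per-partition likelihood inputs for a matrix under a partition scheme:
## model state count (>= 2), character indices, and the (ntip*k) x nchar tip
## partial matrix with each character's observed states remapped to 0..k-1.
## Missing/inapplicable cells contribute all-ones partials.
mk_data <- function(mm, scheme = NULL) {
  sc <- state_counts(mm)
  if (is.null(scheme)) scheme <- partition_characters(sc, integer(n_char(mm)))
  mk_data_core(mm, scheme$assignment, scheme$key$nstates)
}

## Core builder taking a (possibly global) partition assignment per
## character and the per-partition declared state counts. Partitions with
## no member characters in `mm` are left NULL. `remap` records, per
## character, which actual state label each model state 0..k-1 stands for.
mk_data_core <- function(mm, assignment, key_nstates) {
  ntip <- n_taxa(mm)
  parts <- vector("list", length(key_nstates))
  for (p in sort(unique(assignment))) {
    chars <- which(assignment == p)
    k <- max(2L, key_nstates[p])
    tippart <- matrix(0, ntip * k, length(chars))
    remap <- vector("list", length(chars))
    for (ci in seq_along(chars)) {
      j <- chars[ci]
      cells <- mm$mask[, j]
      cells[is.na(cells)] <- 0L
      obs <- states_of_mask(Reduce(bitwOr, cells, 0L))
      if (length(obs) < k) obs <- c(obs, setdiff(0:9, obs))[seq_len(k)]
      remap[[ci]] <- obs
      for (t in seq_len(ntip)) {
        cell <- mm$mask[t, j]
        rows <- (t - 1L) * k + seq_len(k)
        if (is.na(cell) || cell == INAPP_CODE) {
          tippart[rows, ci] <- 1
        } else {
          member <- states_of_mask(cell)
          tippart[rows, ci] <- as.numeric(obs %in% member)
        }
      }
    }
    parts[[p]] <- list(k = k, chars = chars, tippart = tippart,
                       remap = remap, weight = length(chars))
  }
  list(parts = parts, ntip = ntip, taxa = mm$taxa, nchar = n_char(mm))
}

## Kernel traversal inputs for a timetree: postorder internal nodes,
## flattened child lists, per-node edge durations (Ma). Fully vectorized
## (hot path of the sampler).
tt_kernel_inputs <- function(tt) {
  post <- tt_postorder(tt)
  n <- length(tt$parent)
  pos <- integer(n)
  pos[post] <- seq_along(post)
  ch <- which(tt$parent > 0L)
  ppos <- pos[tt$parent[ch]]
  o <- order(ppos)
  child_ids <- ch[o]
  child_ptr <- c(0L, cumsum(tabulate(ppos, nbins = length(post))))
  dur <- tt$age[tt$parent[ch]] - tt$age[ch]
  durv <- numeric(n)
  durv[ch] <- pmax(dur, 0)
  list(postorder = post, child_ptr = child_ptr,
       child_ids = child_ids, dur = durv)
}

## Low-level partitioned log-likelihood given prepared data and per-node
## expected substitutions before partition-rate scaling.
mk_loglik_prepared <- function(kin, mkd, rates, subs_base, mkv = FALSE,
                               per_partition = FALSE) {
  parts <- mkd$parts
  out <- numeric(length(parts))
  for (p in seq_along(parts)) {
    pp <- parts[[p]]
    if (is.null(pp)) next
    tp <- pp$tippart
    if (mkv) {
      ## k pseudo-characters, one constant pattern per state
      const <- matrix(0, nrow(tp), pp$k)
      for (t in seq_len(mkd$ntip)) {
        for (s in seq_len(pp$k)) const[(t - 1L) * pp$k + s, s] <- 1
      }
      tp <- cbind(tp, const)
    }
    ll <- mk_prune_kernel(kin$postorder, kin$child_ptr, kin$child_ids,
                          subs_base * rates[p], tp, pp$k, mkd$ntip,
                          length(subs_base))
    if (mkv) {
      nchar_p <- ncol(pp$tippart)
      ll_const <- ll[nchar_p + seq_len(pp$k)]
      corr <- log1p(-sum(exp(ll_const)))
      out[p] <- sum(ll[seq_len(nchar_p)]) - nchar_p * corr
    } else {
      out[p] <- sum(ll)
    }
  }
  if (per_partition) out else sum(out)
}

#' Pruning log-likelihood of a matrix on a dated tree
#'
#' Felsenstein pruning under the Mk model with uniform root frequencies and
#' per-partition mutation rates. The expected substitutions on the edge
#' above node `v` are `duration(v) * clock_rate * branch_mult[v] * r_p`.
#'
#' @param tt A [timetree()].
#' @param mm A [morph_matrix()] with a data row for every tip.
#' @param scheme Optional [partition_characters()] scheme; default is one
#'   partition per observed-state count with zero homoplasy key.
#' @param rates Per-partition rates (default all 1, which satisfies the
#'   weighted-mean-one constraint).
#' @param clock_rate Mean clock rate (substitutions per character per Ma).
#' @param branch_mult Per-node branch-rate multipliers (default 1).
#' @param mkv If `TRUE`, condition on characters being variable (Lewis'
#'   Mkv correction); default `FALSE` (plain Mk).
#' @param per_partition Return the per-partition breakdown instead of the
#'   total.
#' @return Log-likelihood (or per-partition vector).
#' @export
pruning_loglik <- function(tt, mm, scheme = NULL, rates = NULL,
                           clock_rate = 1, branch_mult = NULL, mkv = FALSE,
                           per_partition = FALSE) {
  miss <- setdiff(tt$taxa, mm$taxa)
  if (length(miss)) {
    stop("tip(s) without a data row: ", paste(miss, collapse = ", "))
  }
  mm <- morph_matrix(mm$mask[match(tt$taxa, mm$taxa), , drop = FALSE],
                     tt$taxa, mm$ordered, mm$symbols)
  mkd <- mk_data(mm, scheme)
  if (is.null(rates)) rates <- rep(1, length(mkd$parts))
  if (is.null(branch_mult)) branch_mult <- rep(1, length(tt$parent))
  kin <- tt_kernel_inputs(tt)
  subs_base <- kin$dur * clock_rate * branch_mult
  mk_loglik_prepared(kin, mkd, rates, subs_base, mkv = mkv,
                     per_partition = per_partition)
}
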