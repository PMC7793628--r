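## The homology multiplexer: per-homology-state composite alignments each
## have their own tree likelihood; the sampled integer homology parameter
## selects which one enters the posterior. Inactive states' likelihoods are
## refreshed lazily at log points so per-state traces are estimable.

#' Build a homology likelihood bank
#'
#' Prepares the composite alignment (fixed + block coding h) and its
#' partitioned likelihood inputs for every homology state. Partition
#' assignment uses the min-homoplasy key, so partition rates do not switch
#' with the homology state.
#'
#' @param fixed [morph_matrix()] of fixed-homology characters.
#' @param block A [homology_block()].
#' @param homoplasy_by_char Optional integer vector (one per composite
#'   character, block characters carrying their lower-value homoplasy) used
#'   for partitioning; default all zero (partition by state count only).
#' @param mkv Condition on variable characters.
#' @return An object of class `homology_bank`.
#' @export
homology_bank <- function(fixed, block, homoplasy_by_char = NULL,
                          mkv = FALSE) {
  N <- n_states(block)
  states <- vector("list", N)
  for (h in seq_len(N) - 1L) {
    comp <- compose_matrix(fixed, block, h)
    sc <- state_counts(comp)
    hv <- if (is.null(homoplasy_by_char)) integer(n_char(comp)) else
      homoplasy_by_char
    scheme <- partition_characters(sc, hv)
    states[[h + 1L]] <- list(mm = comp, mkd = mk_data(comp, scheme),
                             scheme = scheme)
  }
  structure(list(states = states, N = N, mkv = mkv,
                 loglik = rep(NA_real_, N), dirty = rep(TRUE, N),
                 label = block$label),
            class = "homology_bank")
}

## Recompute the cached likelihood of homology state h (0-based) for the
## given tree and rates; marks it clean.
bank_refresh <- function(bank, h, kin, subs_base, rates) {
  st <- bank$states[[h + 1L]]
  bank$loglik[h + 1L] <- mk_loglik_prepared(kin, st$mkd, rates, subs_base,
                                            mkv = bank$mkv)
  bank$dirty[h + 1L] <- FALSE
  bank
}

bank_invalidate <- function(bank) {
  bank$dirty[] <- TRUE
  bank
}

#' Multiplexed log-likelihood
#'
#' Returns the stored tree log-likelihood of the active homology state;
#' other states' values are retained for logging.
#'
#' @param bank A [homology_bank()] with a clean cache for state `h`.
#' @param h Active homology state (0-based).
#' @return Log-likelihood of state `h`'s composite alignment.
#' @export
multiplexed_loglik <- function(bank, h) {
  if (h < 0L || h >= bank$N) {
    stop("homology state ", h, " out of range [0, ", bank$N - 1L, "]")
  }
  if (bank$dirty[h + 1L]) {
    stop("likelihood cache for homology state ", h, " is stale")
  }
  bank$loglik[h + 1L]
}

#' Homology-state posterior on a fixed tree
#'
#' With the tree and all other parameters fixed and a uniform prior over
#' homology states, the posterior over states is the softmax of the
#' per-state log-likelihoods: `P(h) = exp(l_h) / sum_j exp(l_j)`.
#'
#' @param tt A [timetree()].
#' @param fixed Fixed-homology [morph_matrix()].
#' @param block A [homology_block()].
#' @param rates,clock_rate,branch_mult,mkv Passed to [pruning_loglik()].
#' @return Named list: `posterior` (per-state probabilities), `loglik`
#'   (per-state log-likelihoods).
#' @export
homology_posterior_fixed_tree <- function(tt, fixed, block, rates = NULL,
                                          clock_rate = 1, branch_mult = NULL,
                                          mkv = FALSE) {
  N <- n_states(block)
  ll <- vapply(seq_len(N) - 1L, function(h) {
    pruning_loglik(tt, compose_matrix(fixed, block, h), rates = rates,
                   clock_rate = clock_rate, branch_mult = branch_mult,
                   mkv = mkv)
  }, numeric(1))
  list(posterior = softmax(ll), loglik = ll)
}

softmax <- function(ll) {
  w <- exp(ll - max(ll))
  w / sum(w)
}

#' Posterior homology-state frequencies from a trace
#'
#' @param h Integer vector of sampled homology states (one per retained
#'   sample).
#' @param N Number of homology states.
#' @return Numeric vector of length `N`: the frequency of each state.
#' @export
homology_state_frequencies <- function(h, N) {
  tabulate(h + 1L, nbins = N) / length(h)
}
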