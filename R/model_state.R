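## Full MCMC model state and the prepared inference model (data, partition
## scheme, per-homology-state likelihood inputs).

#' Prepare an inference model from data
#'
#' Runs the implied-weights parsimony step on the composite matrix (fixed
#' columns plus every homology coding's columns), applies the lower-value
#' rule to variable-homology characters, partitions characters by (state
#' count, homoplasy), and precomputes per-partition likelihood inputs for
#' every homology state.
#'
#' @param fixed [morph_matrix()] of fixed-homology characters.
#' @param blocks List of [homology_block()]s (may be empty).
#' @param sites Optional [site_table()] of fossil-site age bounds; taxa not
#'   listed in any site keep their initial ages fixed.
#' @param constraints List of taxon-label vectors constrained to be clades.
#' @param partition_by_homoplasy If `FALSE`, partition by state count only
#'   (no parsimony step).
#' @param parsimony A [parsimony_config()] for the homoplasy search.
#' @param homoplasy_bin Optional bin width for homoplasy keys (default:
#'   each distinct value is its own key).
#' @param mkv Condition the Mk likelihood on variable characters.
#' @param rho Extant sampling probability of the tree prior.
#' @return A `dynhom_model` object.
#' @export
prepare_inference <- function(fixed, blocks = list(), sites = NULL,
                              constraints = list(),
                              partition_by_homoplasy = TRUE,
                              parsimony = parsimony_config(),
                              homoplasy_bin = NULL, mkv = FALSE, rho = 0) {
  if (inherits(blocks, "homology_block")) blocks <- list(blocks)
  nfix <- n_char(fixed)
  blk_nchar <- vapply(blocks, function(b) n_char(b$codings[[1L]]), integer(1))

  ## state counts of composite columns (block chars: max across codings)
  sc_fixed <- state_counts(fixed)
  sc_blocks <- lapply(blocks, function(b) {
    do.call(pmax, lapply(b$codings, state_counts))
  })
  sc_all <- c(sc_fixed, unlist(sc_blocks))

  if (partition_by_homoplasy) {
    search_mm <- fixed
    for (b in blocks) {
      for (cod in b$codings) {
        cod2 <- morph_matrix(cod$mask[match(fixed$taxa, cod$taxa), ,
                                      drop = FALSE],
                             fixed$taxa, cod$ordered, cod$symbols)
        search_mm <- morph_matrix(cbind(search_mm$mask, cod2$mask),
                                  fixed$taxa,
                                  c(search_mm$ordered, cod2$ordered),
                                  fixed$symbols)
      }
    }
    sr <- implied_weights_search(search_mm, parsimony)
    hv_fixed <- sr$homoplasy[seq_len(nfix)]
    off <- nfix
    hv_blocks <- list()
    for (bi in seq_along(blocks)) {
      per_state <- list()
      for (s in seq_len(n_states(blocks[[bi]]))) {
        per_state[[s]] <- sr$homoplasy[off + seq_len(blk_nchar[bi])]
        off <- off + blk_nchar[bi]
      }
      hv_blocks[[bi]] <- homology_min_homoplasy(per_state)
    }
    hv <- c(hv_fixed, unlist(hv_blocks))
    iw_tree <- sr$tree
  } else {
    hv <- integer(length(sc_all))
    iw_tree <- NULL
  }
  if (!is.null(homoplasy_bin)) hv <- (hv %/% homoplasy_bin) * homoplasy_bin

  scheme <- partition_characters(sc_all, hv)
  asn_fixed <- scheme$assignment[seq_len(nfix)]
  mkd_fixed <- mk_data_core(fixed, asn_fixed, scheme$key$nstates)
  mkd_blocks <- list()
  off <- nfix
  for (bi in seq_along(blocks)) {
    asn_b <- scheme$assignment[off + seq_len(blk_nchar[bi])]
    mkd_blocks[[bi]] <- lapply(blocks[[bi]]$codings, function(cod) {
      cod2 <- morph_matrix(cod$mask[match(fixed$taxa, cod$taxa), ,
                                    drop = FALSE],
                           fixed$taxa, cod$ordered, cod$symbols)
      mk_data_core(cod2, asn_b, scheme$key$nstates)
    })
    off <- off + blk_nchar[bi]
  }

  structure(list(fixed = fixed, blocks = blocks, sites = sites,
                 constraints = constraints, scheme = scheme,
                 mkd_fixed = mkd_fixed, mkd_blocks = mkd_blocks,
                 homoplasy = hv, iw_tree = iw_tree, mkv = mkv, rho = rho,
                 taxa = fixed$taxa),
            class = "dynhom_model")
}

#' @export
print.dynhom_model <- function(x, ...) {
  cat("dynhom_model: ", length(x$taxa), " taxa, ", n_char(x$fixed),
      " fixed + ", sum(vapply(x$blocks, function(b) n_char(b$codings[[1]]),
                              integer(1))),
      " variable-homology characters, ", n_partitions(x$scheme),
      " partitions, ", length(x$blocks), " homology block(s)\n", sep = "")
  invisible(x)
}

#' Initialize a model state
#'
#' Builds a constraint-compatible starting tree and prior-compatible scalar
#' parameters.
#'
#' @param model A `dynhom_model` from [prepare_inference()].
#' @param spec A [prior_spec()].
#' @param tip_ages Named numeric vector of initial tip ages (Ma); defaults
#'   to site-table midpoints, 0 elsewhere.
#' @return A `model_state` list.
#' @export
init_model_state <- function(model, spec = prior_spec(), tip_ages = NULL) {
  taxa <- model$taxa
  ages <- stats::setNames(rep(0, length(taxa)), taxa)
  site_of_tip <- rep(NA_integer_, length(taxa))
  site_age <- numeric(0)
  if (!is.null(model$sites)) {
    st <- model$sites
    site_age <- (st$min_ma + st$max_ma) / 2
    for (si in seq_along(st$site)) {
      ages[st$taxa[[si]]] <- site_age[si]
      site_of_tip[match(st$taxa[[si]], taxa)] <- si
    }
  }
  if (!is.null(tip_ages)) ages[names(tip_ages)] <- tip_ages
  tt <- build_start_tree(taxa, ages, model$constraints,
                         eps = max(1, diff(range(ages)) / length(taxa)))
  nnode <- length(tt$parent)
  state <- list(
    tree = tt,
    origin = tt$age[tt$root] + max(1, 0.1 * tt$age[tt$root]),
    lambda = exp(spec$birth_meanlog), mu = spec$death_mean,
    psi = spec$sampling_mean, rho = model$rho,
    clock_mean = exp(spec$clock_meanlog), clock_sd = 0.5,
    branch_mult = rep(1, nnode),
    rates = rep(1, n_partitions(model$scheme)),
    weights = model$scheme$key$weight,
    site_age = site_age, site_of_tip = site_of_tip,
    h = vapply(model$blocks, function(b) 0L, integer(1)),
    N_h = vapply(model$blocks, n_states, integer(1)))
  state
}

## Expected substitutions on the edge above each node, before
## partition-rate scaling.
state_subs_base <- function(state, kin) {
  kin$dur * state$clock_mean * state$branch_mult
}

## Total data log-likelihood of a state (active homology codings).
state_loglik <- function(state, model, kin = NULL) {
  if (is.null(kin)) kin <- tt_kernel_inputs(state$tree)
  subs <- state_subs_base(state, kin)
  ll <- mk_loglik_prepared(kin, model$mkd_fixed, state$rates, subs,
                           mkv = model$mkv)
  for (bi in seq_along(model$blocks)) {
    ll <- ll + mk_loglik_prepared(kin, model$mkd_blocks[[bi]][[state$h[bi] + 1L]],
                                  state$rates, subs, mkv = model$mkv)
  }
  ll
}

## Per-homology-state total log-likelihoods (block bi varied, other blocks
## held at their active states).
state_loglik_by_h <- function(state, model, bi = 1L, kin = NULL) {
  if (is.null(kin)) kin <- tt_kernel_inputs(state$tree)
  subs <- state_subs_base(state, kin)
  base <- mk_loglik_prepared(kin, model$mkd_fixed, state$rates, subs,
                             mkv = model$mkv)
  for (bj in seq_along(model$blocks)) {
    if (bj == bi) next
    base <- base + mk_loglik_prepared(
      kin, model$mkd_blocks[[bj]][[state$h[bj] + 1L]], state$rates, subs,
      mkv = model$mkv)
  }
  vapply(seq_len(state$N_h[bi]), function(s) {
    base + mk_loglik_prepared(kin, model$mkd_blocks[[bi]][[s]], state$rates,
                              subs, mkv = model$mkv)
  }, numeric(1))
}
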