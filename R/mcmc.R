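## Metropolis-Hastings sampler over (tree, ages, clock, partition rates,
## birth-death-sampling parameters, fossil-site ages, homology states).

#' MCMC run configuration
#'
#' @param generations Chain length (proposals).
#' @param sample_every Sampling interval; the initial state is logged as
#'   sample 0, giving `generations / sample_every + 1` samples.
#' @param burnin_frac Fraction of samples discarded as burn-in by
#'   [retained_samples()] (floor rule).
#' @param seed RNG seed; runs are deterministic given the seed.
#' @param likelihood_off If `TRUE`, sample from the prior only.
#' @param tree_prior_off If `TRUE`, additionally hold the tree-conditional
#'   birth-death factor out of the target (parameter-prior validation
#'   mode: hyperparameters then sample from their stated priors exactly).
#' @param adapt If `TRUE`, tune scale operators toward 23.4% acceptance
#'   during burn-in, then freeze.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(generations = 10000, sample_every = 100,
                        burnin_frac = 0.1, seed = 1L,
                        likelihood_off = FALSE, tree_prior_off = FALSE,
                        adapt = TRUE) {
  stopifnot(generations >= 1, sample_every >= 1,
            burnin_frac >= 0, burnin_frac < 1,
            generations %% sample_every == 0)
  structure(list(generations = generations, sample_every = sample_every,
                 burnin_frac = burnin_frac, seed = as.integer(seed),
                 likelihood_off = likelihood_off,
                 tree_prior_off = tree_prior_off, adapt = adapt),
            class = "mcmc_config")
}

#' Number of samples logged and retained for a chain setting
#'
#' The initial state counts as sample 0, so a chain of `generations`
#' sampled every `sample_every` logs `generations/sample_every + 1`
#' samples; burn-in discards `floor(burnin_frac * n_samples)` of them.
#'
#' @param generations,sample_every,burnin_frac As in [mcmc_config()].
#' @return List with `n_samples` and `n_retained`.
#' @export
sample_counts <- function(generations, sample_every, burnin_frac) {
  n <- generations %/% sample_every + 1
  list(n_samples = n, n_retained = n - floor(burnin_frac * n))
}

#' Run the MCMC sampler
#'
#' @param model A `dynhom_model` from [prepare_inference()].
#' @param config An [mcmc_config()].
#' @param spec A [prior_spec()].
#' @param init Optional initial `model_state`; default
#'   [init_model_state()].
#' @param operators Optional operator list; default [default_operators]
#'   internally.
#' @param fixed_tree If `TRUE`, disable all tree/age operators (used for
#'   fixed-tree homology sampling).
#' @param focal_clade Optional taxon-label vector: when set, a joint
#'   ancestral state vector is drawn at the clade's MRCA at every sampled
#'   generation.
#' @return A `dynhom_mcmc` object: `trace` (data frame), `trees` (list of
#'   [timetree()]s at sample points), `ancestors` (list of ancestor draws
#'   or NULL), `acceptance` (per-operator rates), `config`.
#' @export
run_mcmc <- function(model, config = mcmc_config(), spec = prior_spec(),
                     init = NULL, operators = NULL, fixed_tree = FALSE,
                     focal_clade = NULL) {
  restore <- local_rng(config$seed)
  on.exit(restore())

  state <- if (is.null(init)) init_model_state(model, spec) else init
  ops <- if (is.null(operators)) default_operators(model, state) else operators
  if (fixed_tree) {
    ## site-age moves stay enabled: tip ages carry their own priors
    tree_ops <- c("node_age", "root_age", "wilson_balding", "narrow_exchange",
                  "leaf_sa_jump", "homology_sa_wilson_balding",
                  "homology_sa_exchange", "origin", "scale_origin")
    ops <- Filter(function(o) !(o$name %in% tree_ops), ops)
  }
  opw <- vapply(ops, function(o) o$weight, numeric(1))
  opp <- opw / sum(opw)
  ctx <- list(model = model, spec = spec)

  lp_fun <- function(st) {
    prior_log_density(st, spec, model$constraints, model$sites,
                      include_tree = !config$tree_prior_off)
  }
  lp_cur <- lp_fun(state)
  if (!is.finite(lp_cur)) {
    stop("non-finite prior at initialization; start from a ",
         "prior-compatible state")
  }
  kin_cur <- tt_kernel_inputs(state$tree)
  ll_cur <- if (config$likelihood_off) 0 else state_loglik(state, model,
                                                           kin_cur)
  if (!is.finite(ll_cur)) {
    stop("non-finite likelihood at initialization")
  }
  tree_changing <- c("node_age", "root_age", "wilson_balding",
                     "narrow_exchange", "leaf_sa_jump", "site_age",
                     "homology_sa_wilson_balding", "homology_sa_exchange")

  n_samp <- config$generations %/% config$sample_every + 1L
  nb <- length(state$h)
  ll_by_h <- function(st) {
    if (nb == 0L || config$likelihood_off) return(NULL)
    unlist(lapply(seq_len(nb), function(bi) {
      state_loglik_by_h(st, model, bi, kin_cur)
    }))
  }
  hcols <- if (nb > 0L) {
    unlist(lapply(seq_len(nb), function(bi) {
      paste0("ll_b", bi, "_h", seq_len(state$N_h[bi]) - 1L)
    }))
  } else character(0)

  trace <- vector("list", n_samp)
  trees <- vector("list", n_samp)
  ancestors <- if (!is.null(focal_clade)) vector("list", n_samp) else NULL
  si <- 0L
  log_sample <- function(gen) {
    si <<- si + 1L
    row <- c(gen = gen, posterior = lp_cur + ll_cur, likelihood = ll_cur,
             prior = lp_cur, lambda = state$lambda, mu = state$mu,
             psi = state$psi, clock_mean = state$clock_mean,
             clock_sd = state$clock_sd, origin = state$origin,
             root_age = state$tree$age[state$tree$root])
    if (length(state$rates)) {
      row <- c(row, stats::setNames(state$rates,
                                    paste0("rate_", seq_along(state$rates))))
    }
    if (length(state$site_age)) {
      row <- c(row, stats::setNames(state$site_age,
                                    paste0("site_age_",
                                           seq_along(state$site_age))))
    }
    if (nb > 0L) {
      row <- c(row, stats::setNames(as.numeric(state$h),
                                    paste0("h_", seq_len(nb))))
      lh <- ll_by_h(state)
      if (!is.null(lh)) row <- c(row, stats::setNames(lh, hcols))
    }
    trace[[si]] <<- row
    trees[[si]] <<- state$tree
    if (!is.null(ancestors)) {
      ancestors[[si]] <<- sample_ancestral_states(state, model, focal_clade)
    }
  }

  log_sample(0L)
  burnin_gen <- config$generations * config$burnin_frac
  for (gen in seq_len(config$generations)) {
    oi <- sample.int(length(ops), 1L, prob = opp)
    op <- ops[[oi]]
    op$env$n <- op$env$n + 1L
    prop <- op$propose(state, ctx, op$env)
    accept <- FALSE
    if (!is.null(prop)) {
      lp_new <- lp_fun(prop$state)
      if (is.finite(lp_new)) {
        kin_new <- if (op$name %in% tree_changing) {
          tt_kernel_inputs(prop$state$tree)
        } else {
          kin_cur
        }
        ll_new <- if (config$likelihood_off) 0 else
          state_loglik(prop$state, model, kin_new)
        loga <- (lp_new + ll_new) - (lp_cur + ll_cur) + prop$log_hr
        if (is.finite(loga) && log(runif(1)) < loga) {
          state <- prop$state
          lp_cur <- lp_new
          ll_cur <- ll_new
          kin_cur <- kin_new
          accept <- TRUE
        }
      }
    }
    if (accept) op$env$n_acc <- op$env$n_acc + 1L
    if (config$adapt && op$tunable && gen <= burnin_gen &&
        op$env$n %% 50L == 0L) {
      rate <- op$env$n_acc / op$env$n
      op$env$scale <- op$env$scale * exp(0.5 * (rate - 0.234))
      op$env$scale <- min(max(op$env$scale, 1e-4), 20)
    }
    if (gen %% config$sample_every == 0L) log_sample(gen)
  }

  acc <- data.frame(
    operator = vapply(ops, function(o) o$name, character(1)),
    proposed = vapply(ops, function(o) o$env$n, integer(1)),
    accepted = vapply(ops, function(o) o$env$n_acc, integer(1)))
  acc$rate <- ifelse(acc$proposed > 0, acc$accepted / acc$proposed, NA)

  structure(list(trace = as.data.frame(do.call(rbind, trace)),
                 trees = trees, ancestors = ancestors, acceptance = acc,
                 config = config, model = model, final_state = state),
            class = "dynhom_mcmc")
}

#' @export
print.dynhom_mcmc <- function(x, ...) {
  cat("dynhom_mcmc: ", x$config$generations, " generations, ",
      nrow(x$trace), " samples (every ", x$config$sample_every, ")\n",
      sep = "")
  invisible(x)
}

#' Indices of post-burn-in samples
#'
#' @param run A `dynhom_mcmc` (or an integer sample count).
#' @param burnin_frac Burn-in fraction; defaults to the run's config.
#' @return Integer vector of retained sample indices.
#' @export
retained_samples <- function(run, burnin_frac = NULL) {
  n <- if (is.numeric(run)) as.integer(run) else nrow(run$trace)
  if (is.null(burnin_frac)) {
    burnin_frac <- if (is.numeric(run)) 0.1 else run$config$burnin_frac
  }
  (floor(burnin_frac * n) + 1L):n
}

#' Effective sample size of a trace column
#'
#' Autocorrelation-time based ESS (spectral density at frequency zero),
#' clamped to the number of samples; anti-correlated chains can otherwise
#' report more independent draws than samples exist. Constant traces are
#' flagged as `NA`.
#'
#' @param x Numeric vector of sampled values (>= 10).
#' @return ESS (numeric), or `NA` for a constant trace.
#' @export
ess <- function(x) {
  if (length(x) < 10L) stop("need at least 10 samples for an ESS estimate")
  if (stats::sd(x) == 0) {
    warning("constant trace: ESS undefined")
    return(NA_real_)
  }
  min(unname(coda::effectiveSize(coda::mcmc(x))), length(x))
}

#' Write a trace data frame as TSV
#' @param run A `dynhom_mcmc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path) {
  write.table(run$trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
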