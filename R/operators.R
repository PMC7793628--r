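## Metropolis-Hastings proposal kernels. Each operator takes the current
## model state and returns list(state = proposed state, log_hr = log
## Hastings ratio) or NULL for an immediate rejection (invalid draw).
## Topology moves are restricted so that sampled-ancestor flags are never
## changed as a side effect; the dedicated reversible-jump toggle
## (op_leaf_sa_jump) is the only move that creates or destroys a sampled
## ancestor.

new_operator <- function(name, propose, weight = 1, tunable = FALSE,
                         scale = 0.5) {
  env <- new.env(parent = emptyenv())
  env$scale <- scale
  env$n <- 0L
  env$n_acc <- 0L
  list(name = name, propose = propose, weight = weight, tunable = tunable,
       env = env)
}

## --- scalar scale moves ---------------------------------------------------

op_scale_param <- function(field, weight = 1, scale = 0.5) {
  force(field)
  new_operator(paste0("scale_", field), function(state, ctx, env) {
    f <- exp(env$scale * (runif(1) - 0.5))
    state[[field]] <- state[[field]] * f
    list(state = state, log_hr = log(f))
  }, weight = weight, tunable = TRUE, scale = scale)
}

op_scale_branch_mult <- function(weight = 1, scale = 0.7) {
  new_operator("scale_branch_mult", function(state, ctx, env) {
    nn <- length(state$branch_mult)
    v <- sample.int(nn, 1L)
    if (v == state$tree$root) return(NULL)
    f <- exp(env$scale * (runif(1) - 0.5))
    state$branch_mult[v] <- state$branch_mult[v] * f
    list(state = state, log_hr = log(f))
  }, weight = weight, tunable = TRUE, scale = scale)
}

## --- partition rates: delta exchange conserving sum(w r) ------------------

op_rate_exchange <- function(weight = 1, scale = 0.2) {
  new_operator("rate_exchange", function(state, ctx, env) {
    np <- length(state$rates)
    if (np < 2L) return(NULL)
    ij <- sample.int(np, 2L)
    delta <- runif(1, 0, env$scale)
    r <- state$rates
    w <- state$weights
    r[ij[1L]] <- r[ij[1L]] - delta / w[ij[1L]]
    r[ij[2L]] <- r[ij[2L]] + delta / w[ij[2L]]
    if (any(r[ij] <= 0)) return(NULL)
    state$rates <- r
    list(state = state, log_hr = 0)
  }, weight = weight, tunable = TRUE, scale = scale)
}

## --- node age moves -------------------------------------------------------

## Internal nodes whose age is tied to a sampled-ancestor tip.
sa_attachment_nodes <- function(tt) unique(tt$parent[sampled_ancestors(tt)])

op_node_age <- function(weight = 1) {
  new_operator("node_age", function(state, ctx, env) {
    tt <- state$tree
    ok <- rep(TRUE, length(tt$parent))
    ok[seq_len(tt$ntip)] <- FALSE
    ok[tt$root] <- FALSE
    ok[sa_attachment_nodes(tt)] <- FALSE
    cand <- which(ok)
    if (!length(cand)) return(NULL)
    v <- cand[sample.int(length(cand), 1L)]
    kids <- which(tt$parent == v)
    lo <- max(tt$age[kids])
    hi <- tt$age[tt$parent[v]]
    if (hi <= lo) return(NULL)
    tt$age[v] <- runif(1, lo, hi)
    state$tree <- tt
    list(state = state, log_hr = 0)
  }, weight = weight)
}

op_root_age <- function(weight = 1) {
  new_operator("root_age", function(state, ctx, env) {
    tt <- state$tree
    if (tt$root %in% sa_attachment_nodes(tt)) return(NULL)
    kids <- which(tt$parent == tt$root)
    lo <- max(tt$age[kids])
    hi <- state$origin
    if (hi <= lo) return(NULL)
    tt$age[tt$root] <- runif(1, lo, hi)
    state$tree <- tt
    list(state = state, log_hr = 0)
  }, weight = weight)
}

op_origin <- function(weight = 1) {
  new_operator("origin", function(state, ctx, env) {
    lo <- state$tree$age[state$tree$root]
    hi <- ctx$spec$origin_max
    if (hi <= lo) return(NULL)
    state$origin <- runif(1, lo, hi)
    list(state = state, log_hr = 0)
  }, weight = weight)
}

## --- fossil-site age move -------------------------------------------------

op_site_age <- function(weight = 1) {
  new_operator("site_age", function(state, ctx, env) {
    ns <- length(state$site_age)
    if (ns == 0L) return(NULL)
    si <- sample.int(ns, 1L)
    st <- ctx$model$sites
    a <- runif(1, st$min_ma[si], st$max_ma[si])
    tt <- state$tree
    tips <- which(state$site_of_tip == si)
    sa <- intersect(tips, sampled_ancestors(tt))
    tt$age[tips] <- a
    for (t in sa) {
      p <- tt$parent[t]
      sib <- setdiff(which(tt$parent == p), t)
      if (tt$age[sib] > a + SA_TOL) return(NULL)
      g <- tt$parent[p]
      if (g > 0L && tt$age[g] < a - SA_TOL) return(NULL)
      if (g == 0L && state$origin < a) return(NULL)
      tt$age[p] <- a
    }
    free <- setdiff(tips, sa)
    if (any(tt$age[tt$parent[free]] < a - SA_TOL)) return(NULL)
    kids_of <- function(v) which(tt$parent == v)
    for (v in unique(tt$parent[tips])) {
      if (tt$age[v] < max(tt$age[kids_of(v)]) - SA_TOL) return(NULL)
    }
    state$tree <- tt
    state$site_age[si] <- a
    list(state = state, log_hr = 0)
  }, weight = weight)
}

## Independence proposal from a parameter's own prior; the Hastings ratio
## cancels the prior ratio, so acceptance is driven by the likelihood and
## tree factor alone (and is 1 in parameter-prior validation mode).
op_prior_redraw <- function(field, rdraw, ldens, weight = 1) {
  force(field); force(rdraw); force(ldens)
  new_operator(paste0("prior_redraw_", field), function(state, ctx, env) {
    old <- state[[field]]
    state[[field]] <- rdraw(ctx$spec)
    list(state = state, log_hr = ldens(old, ctx$spec) -
           ldens(state[[field]], ctx$spec))
  }, weight = weight)
}

op_prior_redraw_lambda <- function(weight = 1) {
  op_prior_redraw("lambda",
                  function(sp) stats::rlnorm(1, sp$birth_meanlog,
                                             sp$birth_sdlog),
                  function(x, sp) dlnorm(x, sp$birth_meanlog, sp$birth_sdlog,
                                         log = TRUE),
                  weight = weight)
}

## --- reversible-jump leaf <-> sampled ancestor ----------------------------

op_leaf_sa_jump <- function(weight = 1) {
  new_operator("leaf_sa_jump", function(state, ctx, env) {
    tt <- state$tree
    cand <- which(tt$age[seq_len(tt$ntip)] > 1e-8)  # fossil tips only
    if (!length(cand)) return(NULL)
    t1 <- cand[sample.int(length(cand), 1L)]
    p <- tt$parent[t1]
    sib <- setdiff(which(tt$parent == p), t1)
    g <- tt$parent[p]
    upper <- if (g > 0L) tt$age[g] else state$origin
    is_sa <- abs(tt$age[p] - tt$age[t1]) <= SA_TOL
    if (is_sa) {
      ## SA -> leaf: draw a positive pendant duration for the parent
      if (upper <= tt$age[t1]) return(NULL)
      tt$age[p] <- runif(1, tt$age[t1], upper)
      log_hr <- log(upper - tt$age[t1])
    } else {
      ## leaf -> SA: parent collapses onto the tip's age
      if (tt$age[sib] > tt$age[t1] + SA_TOL) return(NULL)
      if (upper < tt$age[t1]) return(NULL)
      tt$age[p] <- tt$age[t1]
      log_hr <- -log(upper - tt$age[t1])
    }
    state$tree <- tt
    list(state = state, log_hr = log_hr)
  }, weight = weight)
}

## --- Wilson-Balding (sampled-ancestor aware) ------------------------------

## Prune the subtree above node i, splice out its parent, and reattach on
## the edge above node j at a fresh uniform age. i and j are drawn
## uniformly from fixed-size pools; invalid draws reject, preserving
## detailed balance.
propose_wilson_balding <- function(state, ctx) {
  tt <- state$tree
  n <- length(tt$parent)
  i <- sample.int(n, 1L)
  if (i == tt$root) return(NULL)
  if (i <= tt$ntip && abs(tt$age[tt$parent[i]] - tt$age[i]) <= SA_TOL) {
    return(NULL)  # never move a sampled ancestor directly
  }
  p <- tt$parent[i]
  sib <- setdiff(which(tt$parent == p), i)
  if (sib <= tt$ntip && abs(tt$age[p] - tt$age[sib]) <= SA_TOL) {
    return(NULL)  # splicing p out would free its sampled ancestor
  }
  g <- tt$parent[p]

  j <- sample.int(n, 1L)
  in_sub <- function(v) {
    while (v != 0L) {
      if (v == i) return(TRUE)
      v <- tt$parent[v]
    }
    FALSE
  }
  if (j == i || j == p || in_sub(j)) return(NULL)
  pj <- tt$parent[j]
  if (pj == p) pj <- g  # p is spliced out; j's effective parent becomes g
  ## pj == 0 means p reattaches above the (new) root, bounded by the origin
  upper_new <- if (pj == 0L) state$origin else tt$age[pj]
  lower_new <- max(tt$age[i], tt$age[j])
  if (upper_new <= lower_new) return(NULL)

  upper_old <- if (g == 0L) state$origin else tt$age[g]
  lower_old <- max(tt$age[i], tt$age[sib])

  ## splice p out, then reattach it between j and j's (post-splice) parent
  tt$parent[sib] <- g
  tt$parent[p] <- pj
  tt$parent[j] <- p
  tt$root <- which(tt$parent == 0L)
  tt$age[p] <- runif(1, lower_new, upper_new)
  state$tree <- tt
  list(state = state,
       log_hr = log(upper_new - lower_new) - log(upper_old - lower_old))
}

op_wilson_balding <- function(weight = 1) {
  new_operator("wilson_balding", function(state, ctx, env) {
    propose_wilson_balding(state, ctx)
  }, weight = weight)
}

## --- narrow exchange ------------------------------------------------------

propose_narrow_exchange <- function(state, ctx) {
  tt <- state$tree
  internals <- (tt$ntip + 1L):length(tt$parent)
  cand <- setdiff(internals, tt$root)
  p <- cand[sample.int(length(cand), 1L)]
  g <- tt$parent[p]
  u <- setdiff(which(tt$parent == g), p)  # uncle
  kids <- which(tt$parent == p)
  cnode <- kids[sample.int(2L, 1L)]
  ## keep sampled-ancestor attachments intact
  if (u <= tt$ntip && abs(tt$age[g] - tt$age[u]) <= SA_TOL) return(NULL)
  if (cnode <= tt$ntip && abs(tt$age[p] - tt$age[cnode]) <= SA_TOL) {
    return(NULL)
  }
  if (tt$age[u] > tt$age[p] - SA_TOL) return(NULL)
  tt$parent[u] <- p
  tt$parent[cnode] <- g
  state$tree <- tt
  list(state = state, log_hr = 0)
}

op_narrow_exchange <- function(weight = 1) {
  new_operator("narrow_exchange", function(state, ctx, env) {
    propose_narrow_exchange(state, ctx)
  }, weight = weight)
}

## --- homology operators ---------------------------------------------------

redraw_homology <- function(state) {
  nb <- length(state$h)
  if (nb == 0L) return(NULL)
  bi <- sample.int(nb, 1L)
  others <- setdiff(seq_len(state$N_h[bi]) - 1L, state$h[bi])
  state$h[bi] <- if (length(others) == 1L) others else
    others[sample.int(length(others), 1L)]
  state
}

op_homology_flip <- function(weight = 1) {
  new_operator("homology_flip", function(state, ctx, env) {
    s2 <- redraw_homology(state)
    if (is.null(s2)) return(NULL)
    list(state = s2, log_hr = 0)
  }, weight = weight)
}

## Joint tree + homology moves: correlated tree- and homology-space is
## traversed by proposing both changes in one step.
op_homology_wilson_balding <- function(weight = 1) {
  new_operator("homology_sa_wilson_balding", function(state, ctx, env) {
    res <- propose_wilson_balding(state, ctx)
    if (is.null(res)) return(NULL)
    if (length(res$state$h)) {
      s2 <- redraw_homology(res$state)
      if (!is.null(s2)) res$state <- s2
    }
    res
  }, weight = weight)
}

op_homology_exchange <- function(weight = 1) {
  new_operator("homology_sa_exchange", function(state, ctx, env) {
    res <- propose_narrow_exchange(state, ctx)
    if (is.null(res)) return(NULL)
    if (length(res$state$h)) {
      s2 <- redraw_homology(res$state)
      if (!is.null(s2)) res$state <- s2
    }
    res
  }, weight = weight)
}

## Default operator schedule for a model/state.
default_operators <- function(model, state) {
  ops <- list(
    op_scale_param("lambda"), op_scale_param("mu"), op_scale_param("psi"),
    op_scale_param("clock_mean"), op_scale_param("clock_sd"),
    op_scale_param("origin", weight = 0.5),
    op_scale_branch_mult(weight = 3),
    op_node_age(weight = 3), op_root_age(), op_origin(weight = 0.5),
    op_wilson_balding(weight = 3), op_narrow_exchange(weight = 2),
    op_leaf_sa_jump(weight = 1))
  if (length(state$rates) > 1L) ops <- c(ops, list(op_rate_exchange()))
  if (length(state$site_age) > 0L) ops <- c(ops, list(op_site_age(weight = 2)))
  if (length(state$h) > 0L) {
    ops <- c(ops, list(op_homology_flip(weight = 2),
                       op_homology_wilson_balding(weight = 1),
                       op_homology_exchange(weight = 1)))
  }
  ops
}
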