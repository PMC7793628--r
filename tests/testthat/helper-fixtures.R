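## Shared builders and independent oracles for the suite. Oracles are
## deliberately naive (full enumeration) and independent of the package's
## pruning/search code paths.

## morph_matrix from an integer state matrix (NA allowed)
mm_from_states <- function(M, taxa = rownames(M)) {
  mk <- matrix(bitwShiftL(1L, M), nrow(M), ncol(M))
  mk[is.na(M)] <- NA_integer_
  morph_matrix(mk, taxa)
}

## dated tree from newick with branch lengths
tt_from_text <- function(text) as_timetree(ape::read.tree(text = text))

## equal-branch dated tree from a topology-only newick
tt_from_topology <- function(text, brlen = 1) {
  phy <- ape::read.tree(text = text)
  phy$edge.length <- rep(brlen, nrow(phy$edge))
  as_timetree(phy)
}

## write a small NEXUS file, returning its path
write_nexus_text <- function(lines) {
  path <- tempfile(fileext = ".nex")
  writeLines(lines, path)
  path
}

## Oracle: log-likelihood by exhaustive summation over all internal-node
## and uncertain-tip state assignments (uniform root frequencies).
enum_loglik <- function(tt, mm, clock = 1) {
  ## align matrix rows with the tree's tip indexing
  mm <- morph_matrix(mm$mask[match(tt$taxa, mm$taxa), , drop = FALSE],
                     tt$taxa, mm$ordered, mm$symbols)
  kin <- dynhom:::tt_kernel_inputs(tt)
  n <- length(tt$parent)
  internals <- (tt$ntip + 1L):n
  total <- 0
  for (j in seq_len(ncol(mm$mask))) {
    cells <- mm$mask[, j]
    cells[is.na(cells)] <- 0L
    obs <- dynhom:::states_of_mask(Reduce(bitwOr, cells, 0L))
    k <- max(2L, length(obs))
    if (length(obs) < k) obs <- c(obs, setdiff(0:9, obs))[seq_len(k)]
    tipsets <- lapply(seq_len(tt$ntip), function(t) {
      cell <- mm$mask[t, j]
      if (is.na(cell) || cell == 0L) obs else
        intersect(dynhom:::states_of_mask(cell), obs)
    })
    Ps <- lapply(seq_len(n), function(v) {
      mk_transition_prob(k, kin$dur[v] * clock)
    })
    grid <- as.matrix(do.call(expand.grid, rep(list(obs), length(internals))))
    tipgrid <- as.matrix(do.call(expand.grid, tipsets))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      stv <- integer(n)
      stv[internals] <- grid[g, ]
      for (tg in seq_len(nrow(tipgrid))) {
        stv[seq_len(tt$ntip)] <- tipgrid[tg, ]
        p <- 1 / k
        for (v in seq_len(n)) {
          if (v == tt$root) next
          p <- p * Ps[[v]][match(stv[tt$parent[v]], obs),
                           match(stv[v], obs)]
        }
        tot <- tot + p
      }
    }
    total <- total + log(tot)
  }
  total
}

## Oracle: Fitch steps by exhaustive minimization over internal labelings.
enum_fitch <- function(tt_or_phy, states_by_tip, alphabet) {
  phy <- if (inherits(tt_or_phy, "phylo")) tt_or_phy else
    tt_to_phylo(tt_or_phy)
  pt <- dynhom:::phylo_to_pt(phy)
  n <- length(pt$parent)
  live <- sort(unique(c(which(pt$parent > 0L), pt$root)))
  internals <- setdiff(live, seq_len(pt$ntip))
  tipsets <- states_by_tip[phy$tip.label]
  grids <- c(tipsets, rep(list(alphabet), length(internals)))
  grid <- as.matrix(do.call(expand.grid, grids))
  nodes <- c(seq_len(pt$ntip), internals)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    stv <- integer(n)
    stv[nodes] <- grid[g, ]
    steps <- 0L
    for (v in live) {
      if (v == pt$root) next
      steps <- steps + (stv[v] != stv[pt$parent[v]])
    }
    best <- min(best, steps)
  }
  best
}

## Oracle: conditional state probabilities at a node by enumeration.
enum_node_probs <- function(tt, mm, node, clock = 1) {
  mm <- morph_matrix(mm$mask[match(tt$taxa, mm$taxa), , drop = FALSE],
                     tt$taxa, mm$ordered, mm$symbols)
  kin <- dynhom:::tt_kernel_inputs(tt)
  n <- length(tt$parent)
  internals <- (tt$ntip + 1L):n
  out <- list()
  for (j in seq_len(ncol(mm$mask))) {
    cells <- mm$mask[, j]
    cells[is.na(cells)] <- 0L
    obs <- dynhom:::states_of_mask(Reduce(bitwOr, cells, 0L))
    k <- max(2L, length(obs))
    if (length(obs) < k) obs <- c(obs, setdiff(0:9, obs))[seq_len(k)]
    tipsets <- lapply(seq_len(tt$ntip), function(t) {
      cell <- mm$mask[t, j]
      if (is.na(cell) || cell == 0L) obs else
        intersect(dynhom:::states_of_mask(cell), obs)
    })
    pr <- stats::setNames(numeric(k), obs)
    grid <- as.matrix(do.call(expand.grid,
                              c(tipsets, rep(list(obs), length(internals)))))
    for (g in seq_len(nrow(grid))) {
      stv <- integer(n)
      stv[c(seq_len(tt$ntip), internals)] <- grid[g, ]
      p <- 1 / k
      for (v in seq_len(n)) {
        if (v == tt$root) next
        P <- mk_transition_prob(k, kin$dur[v] * clock)
        p <- p * P[match(stv[tt$parent[v]], obs), match(stv[v], obs)]
      }
      pr[as.character(stv[node])] <- pr[as.character(stv[node])] + p
    }
    out[[j]] <- pr / sum(pr)
  }
  out
}

## random small morph_matrix
random_mm <- function(ntip, nchar, kmax = 2, missing = 0,
                      taxa = paste0("t", seq_len(ntip))) {
  M <- matrix(sample(0:(kmax - 1), ntip * nchar, TRUE), ntip, nchar)
  if (missing > 0) M[matrix(runif(ntip * nchar) < missing, ntip)] <- NA
  mm_from_states(M, taxa)
}
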