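## Minimal rooted-binary tree representation used by the parsimony search:
## tips 1..ntip, internal nodes ntip+1..2*ntip-1, `parent` vector with 0 at
## the root. The root has degree 2, so the structure encodes an unrooted
## topology with a marked edge. ape::phylo is used at the boundaries.

pt_new3 <- function(t1, t2, t3, ntip) {
  parent <- integer(2L * ntip - 1L)
  root <- ntip + 1L
  v <- ntip + 2L
  parent[root] <- 0L
  parent[t1] <- root
  parent[v] <- root
  parent[t2] <- v
  parent[t3] <- v
  list(ntip = ntip, parent = parent, root = root, nnode = v)
}

pt_children <- function(pt) {
  kids <- vector("list", length(pt$parent))
  for (i in seq_along(pt$parent)) {
    p <- pt$parent[i]
    if (p > 0L && i != pt$root) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

## Postorder sequence of internal (non-tip) nodes, root last.
pt_postorder <- function(pt, kids = pt_children(pt)) {
  out <- integer(0)
  stack <- pt$root
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    ch <- kids[[v]]
    stack <- c(stack, ch[ch > pt$ntip])
  }
  rev(visit)
}

## Nodes inside the subtree rooted at v (including v).
pt_subtree <- function(pt, v, kids = pt_children(pt)) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, x)
    stack <- c(stack, kids[[x]])
  }
  out
}

## Insert tip (or subtree root) `node` on the edge above `at`, reusing
## internal id `newint`.
pt_attach <- function(pt, node, at, newint) {
  p <- pt$parent[at]
  pt$parent[newint] <- p
  pt$parent[at] <- newint
  pt$parent[node] <- newint
  if (p == 0L) pt$root <- newint
  pt
}

## Remove subtree rooted at v; its parent p is spliced out and returned for
## id reuse. The root never sits inside the pruned subtree.
pt_detach <- function(pt, v) {
  p <- pt$parent[v]
  sib <- setdiff(which(pt$parent == p), v)
  g <- pt$parent[p]
  pt$parent[sib] <- g
  if (g == 0L) pt$root <- sib
  pt$parent[p] <- 0L
  pt$parent[v] <- 0L
  list(pt = pt, freed = p, sib = sib)
}

## Candidate attachment edges, one per unrooted edge: every non-root node
## except the root's second child (the two root edges are the same unrooted
## edge).
pt_edges <- function(pt) {
  rc <- which(pt$parent == pt$root)
  setdiff(which(pt$parent > 0L), rc[2L])
}

pt_to_phylo <- function(pt, taxa) {
  live <- which(pt$parent > 0L)
  nodes <- sort(unique(c(live, pt$root)))
  internals <- nodes[nodes > pt$ntip]
  remap <- integer(length(pt$parent))
  remap[seq_len(pt$ntip)] <- seq_len(pt$ntip)
  ## ape convention: root gets ntip+1
  remap[pt$root] <- pt$ntip + 1L
  rest <- setdiff(internals, pt$root)
  remap[rest] <- pt$ntip + 1L + seq_along(rest)
  child <- setdiff(nodes, pt$root)
  edge <- cbind(remap[pt$parent[child]], remap[child])
  phy <- list(edge = edge, tip.label = taxa, Nnode = length(internals))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

phylo_to_pt <- function(phy) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  parent <- integer(nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  list(ntip = ntip, parent = parent, root = root, taxa = phy$tip.label)
}

## Enumerate every unrooted binary topology on the given number of tips by
## recursive stepwise addition (3 tips: 1; 4: 3; 5: 15; 6: 105).
all_topologies <- function(ntip) {
  stopifnot(ntip >= 3L)
  base <- pt_new3(1L, 2L, 3L, ntip)
  base$nextint <- ntip + 3L
  grow <- function(pt, tip) {
    if (tip > ntip) return(list(pt))
    out <- list()
    for (e in pt_edges(pt)) {
      pt2 <- pt_attach(pt, tip, e, pt$nextint)
      pt2$nextint <- pt$nextint + 1L
      out <- c(out, grow(pt2, tip + 1L))
    }
    out
  }
  grow(base, 4L)
}
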