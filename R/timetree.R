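## Rooted, dated binary trees permitting sampled ancestors. Node ages are in
## Ma before present and increase rootward. A sampled ancestor is a tip
## whose pendant edge has zero duration (its age equals its parent's age):
## the host branch is bisected and the fossil sits on the lineage.

SA_TOL <- 1e-9

#' Construct a dated tree
#'
#' Tips are nodes `1..ntip`, internal nodes `ntip+1..2*ntip-1`; `parent` is
#' 0 at the root. Every internal node has exactly two children.
#'
#' @param parent Integer parent vector.
#' @param age Numeric node ages (Ma before present), `age[parent] >=
#'   age[child]`.
#' @param taxa Tip labels (length ntip).
#' @return An object of class `timetree`.
#' @export
timetree <- function(parent, age, taxa) {
  ntip <- length(taxa)
  tt <- structure(list(ntip = ntip, taxa = as.character(taxa),
                       parent = as.integer(parent), age = as.numeric(age),
                       root = which(parent == 0L)),
                  class = "timetree")
  validate_timetree(tt)
  tt
}

validate_timetree <- function(tt) {
  n <- 2L * tt$ntip - 1L
  if (length(tt$parent) != n || length(tt$age) != n) {
    stop("parent/age vectors must have length 2*ntip-1")
  }
  if (length(tt$root) != 1L || tt$root <= tt$ntip) {
    stop("tree must have exactly one (internal) root")
  }
  kid_counts <- tabulate(tt$parent, nbins = n)
  if (any(kid_counts[(tt$ntip + 1L):n] != 2L)) {
    stop("every internal node must have exactly two children")
  }
  nonroot <- setdiff(seq_len(n), tt$root)
  if (any(tt$age[tt$parent[nonroot]] < tt$age[nonroot] - SA_TOL)) {
    stop("node older than its parent")
  }
  if (anyDuplicated(tt$taxa)) stop("duplicate taxon labels")
  invisible(tt)
}

#' @export
print.timetree <- function(x, ...) {
  cat("timetree: ", x$ntip, " tips, root age ",
      format(x$age[x$root], digits = 6), " Ma, ",
      length(sampled_ancestors(x)), " sampled ancestor(s)\n", sep = "")
  invisible(x)
}

tt_children <- function(tt) {
  n <- length(tt$parent)
  has_p <- tt$parent > 0L
  kids <- vector("list", n)
  kids[] <- list(integer(0))
  sp <- split(which(has_p), tt$parent[has_p])
  kids[as.integer(names(sp))] <- sp
  kids
}

## Internal nodes, children before parents (root last). Sorting internal
## nodes by age gives a valid order (child age <= parent age); the rare
## exact-tie case falls back to an explicit traversal.
tt_postorder <- function(tt, kids = tt_children(tt)) {
  internals <- (tt$ntip + 1L):length(tt$parent)
  ord <- internals[order(tt$age[internals])]
  pos <- integer(length(tt$parent))
  pos[ord] <- seq_along(ord)
  par <- tt$parent[ord]
  ok <- par == 0L | pos[pmax(par, 1L)] > pos[ord]
  if (all(ok)) return(ord)
  ## fallback: reverse preorder
  visit <- integer(0)
  stack <- tt$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    ch <- kids[[v]]
    stack <- c(stack, ch[ch > tt$ntip])
  }
  rev(visit)
}

#' Sampled-ancestor tips of a tree
#' @param tt A [timetree()].
#' @return Integer vector of tip indices placed as sampled ancestors.
#' @export
sampled_ancestors <- function(tt) {
  tips <- seq_len(tt$ntip)
  tips[abs(tt$age[tt$parent[tips]] - tt$age[tips]) <= SA_TOL]
}

#' Tips descended from a node
#' @param tt A [timetree()].
#' @param node Node index.
#' @return Integer tip indices.
#' @export
clade_tips <- function(tt, node) {
  if (node <= tt$ntip) return(node)
  kids <- tt_children(tt)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= tt$ntip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  sort(out)
}

#' Most recent common ancestor of a taxon set
#' @param tt A [timetree()].
#' @param taxa Character vector of tip labels (or integer tip indices).
#' @return Internal node index (or the tip itself for a single taxon).
#' @export
mrca_node <- function(tt, taxa) {
  tips <- if (is.character(taxa)) match(taxa, tt$taxa) else as.integer(taxa)
  if (anyNA(tips)) {
    stop("unknown taxa: ",
         paste(taxa[is.na(match(taxa, tt$taxa))], collapse = ", "))
  }
  if (length(tips) == 1L) return(tips)
  path_to_root <- function(v) {
    out <- v
    while (tt$parent[v] != 0L) {
      v <- tt$parent[v]
      out <- c(out, v)
    }
    out
  }
  anc <- path_to_root(tips[1L])
  for (t2 in tips[-1L]) anc <- intersect(anc, path_to_root(t2))
  anc[1L]
}

#' Check monophyly constraints
#'
#' @param tt A [timetree()].
#' @param constraints List of character vectors of taxon labels.
#' @return `TRUE` iff every constraint set forms a clade.
#' @export
check_monophyly <- function(tt, constraints) {
  for (cs in constraints) {
    tips <- match(cs, tt$taxa)
    if (anyNA(tips)) {
      stop("constraint names unknown taxa: ",
           paste(cs[is.na(tips)], collapse = ", "))
    }
    if (length(tips) <= 1L) next
    if (!identical(clade_tips(tt, mrca_node(tt, tips)), sort(tips))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Convert a timetree to ape::phylo
#'
#' Edge lengths are durations (Ma); sampled-ancestor pendant edges have
#' length zero. Node ages are attached as the `node.age` attribute (ordered
#' by phylo node index).
#'
#' @param tt A [timetree()].
#' @return An `ape::phylo`.
#' @export
tt_to_phylo <- function(tt) {
  n <- length(tt$parent)
  remap <- integer(n)
  remap[seq_len(tt$ntip)] <- seq_len(tt$ntip)
  remap[tt$root] <- tt$ntip + 1L
  rest <- setdiff((tt$ntip + 1L):n, tt$root)
  remap[rest] <- tt$ntip + 1L + seq_along(rest)
  child <- setdiff(seq_len(n), tt$root)
  edge <- cbind(remap[tt$parent[child]], remap[child])
  len <- tt$age[tt$parent[child]] - tt$age[child]
  phy <- list(edge = edge, edge.length = pmax(len, 0),
              tip.label = tt$taxa, Nnode = tt$ntip - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  age <- numeric(n)
  age[remap] <- tt$age
  attr(phy, "node.age") <- age
  phy
}

#' Convert an ape::phylo with branch lengths to a timetree
#'
#' @param phy A rooted binary `ape::phylo` with edge lengths (durations).
#' @param tip_ages Optional named numeric vector of tip ages (Ma); defaults
#'   to anchoring the youngest tip at 0.
#' @return A [timetree()].
#' @export
as_timetree <- function(phy, tip_ages = NULL) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  parent <- integer(n)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  depth <- numeric(n)  # distance from root
  for (i in seq_len(nrow(phy$edge))) {
    depth[phy$edge[i, 2L]] <- depth[phy$edge[i, 1L]] + phy$edge.length[i]
  }
  age <- max(depth[seq_len(ntip)]) - depth
  if (!is.null(tip_ages)) {
    shift <- mean(tip_ages[phy$tip.label] - age[seq_len(ntip)])
    age <- age + shift
  }
  timetree(parent, age, phy$tip.label)
}

#' Serialize a timetree as Newick
#' @param tt A [timetree()].
#' @return Newick string with branch durations (zero for sampled ancestors).
#' @export
tt_newick <- function(tt) ape::write.tree(tt_to_phylo(tt))

## Deterministic starting tree honoring monophyly constraints and tip ages:
## caterpillar within each (nested) constraint group, then over the rest.
## Internal node ages strictly above the oldest descendant tip.
build_start_tree <- function(taxa, tip_ages, constraints = list(),
                             eps = 1) {
  ntip <- length(taxa)
  age <- numeric(2L * ntip - 1L)
  age[seq_len(ntip)] <- tip_ages[taxa]
  parent <- integer(2L * ntip - 1L)
  nextint <- ntip + 1L

  ## order constraints small-to-large so nested sets resolve inside-out
  cons <- constraints[order(vapply(constraints, length, integer(1)))]
  group_of <- rep(0L, ntip)  # node id currently representing each tip
  rep_node <- as.list(seq_len(ntip))
  names(rep_node) <- taxa

  join <- function(a, b) {
    v <- nextint
    nextint <<- nextint + 1L
    parent[a] <<- v
    parent[b] <<- v
    age[v] <<- max(age[a], age[b]) + eps
    v
  }

  ## a "unit" is a currently-unmerged subtree root; merge sets of units
  units <- stats::setNames(as.list(seq_len(ntip)), taxa)
  merge_units <- function(keys) {
    ids <- unlist(units[keys], use.names = FALSE)
    acc <- ids[1L]
    for (x in ids[-1L]) acc <- join(acc, x)
    units[keys] <<- NULL
    key <- paste(keys, collapse = "|")
    units[[key]] <<- acc
    key
  }
  covered <- lapply(cons, function(cs) cs)
  keymap <- stats::setNames(taxa, taxa)  # taxon -> unit key containing it
  for (cs in covered) {
    keys <- unique(unname(keymap[cs]))
    newkey <- merge_units(keys)
    keymap[cs] <- newkey
  }
  merge_units(unique(unname(keymap)))
  tt <- timetree(parent, age, taxa)
  tt
}
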