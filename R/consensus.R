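## Majority-rule consensus with time annotation: clades retained at
## frequency strictly greater than the threshold, each annotated with its
## posterior frequency and the mean MRCA age across the trees containing
## it. Mean heights of nested clades are not forced to be monotone (the
## usual caveat of mean-height annotation).

#' Majority-rule consensus of dated trees
#'
#' @param trees List of [timetree()]s over an identical tip set.
#' @param threshold Clade-frequency threshold; clades are kept iff their
#'   frequency is strictly greater (default 0.5).
#' @return An `ape::phylo` (possibly multifurcating) with `node.label` =
#'   clade frequency; attributes `node.age` (mean MRCA ages, tips first)
#'   and `clades` (data frame of clade, frequency, mean age).
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (length(trees) < 1L) stop("need at least one tree")
  taxa <- sort(trees[[1L]]$taxa)
  counts <- new.env(parent = emptyenv())
  ages <- new.env(parent = emptyenv())
  tip_age_sum <- stats::setNames(numeric(length(taxa)), taxa)

  for (tt in trees) {
    if (!identical(sort(tt$taxa), taxa)) {
      stop("trees have different tip sets")
    }
    tip_age_sum <- tip_age_sum + tt$age[match(taxa, tt$taxa)]
    kids <- tt_children(tt)
    ## clade tip sets bottom-up
    sets <- vector("list", length(tt$parent))
    for (t in seq_len(tt$ntip)) sets[[t]] <- tt$taxa[t]
    for (v in tt_postorder(tt, kids)) {
      sets[[v]] <- sort(unlist(sets[kids[[v]]], use.names = FALSE))
    }
    for (v in (tt$ntip + 1L):length(tt$parent)) {
      key <- paste(sets[[v]], collapse = "\t")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      ages[[key]] <- (if (is.null(ages[[key]])) 0 else ages[[key]]) +
        tt$age[v]
    }
  }

  ntree <- length(trees)
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]] / ntree, numeric(1))
  mage <- vapply(keys, function(k) ages[[k]] / counts[[k]], numeric(1))
  keep <- freq > threshold
  keys <- keys[keep]; freq <- freq[keep]; mage <- mage[keep]
  sets <- strsplit(keys, "\t", fixed = TRUE)
  sizes <- vapply(sets, length, integer(1))
  ord <- order(-sizes)
  sets <- sets[ord]; freq <- freq[ord]; mage <- mage[ord]
  sizes <- sizes[ord]

  ntip <- length(taxa)
  ncl <- length(sets)
  node_id <- ntip + seq_len(ncl)  # root (largest clade) first
  ## parent of clade i = smallest kept clade strictly containing it
  parent <- integer(ntip + ncl)
  for (i in seq_len(ncl)) {
    best <- 0L
    for (j in seq_len(ncl)) {
      if (j == i || sizes[j] <= sizes[i]) next
      if (all(sets[[i]] %in% sets[[j]])) {
        if (best == 0L || sizes[j] < sizes[best]) best <- j
      }
    }
    parent[node_id[i]] <- if (best > 0L) node_id[best] else 0L
  }
  for (t in seq_len(ntip)) {
    best <- 0L
    for (j in seq_len(ncl)) {
      if (taxa[t] %in% sets[[j]]) {
        if (best == 0L || sizes[j] < sizes[best]) best <- j
      }
    }
    parent[t] <- node_id[best]
  }

  child <- which(parent > 0L)
  edge <- cbind(parent[child], child)
  age <- c(tip_age_sum / ntree, mage)
  phy <- list(edge = edge,
              edge.length = pmax(age[edge[, 1L]] - age[edge[, 2L]], 0),
              tip.label = taxa, Nnode = ncl,
              node.label = sprintf("%.3f", freq))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "node.age") <- age
  attr(phy, "clades") <- data.frame(
    clade = vapply(sets, paste, character(1), collapse = ","),
    frequency = freq, mean_age = mage)
  phy
}
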