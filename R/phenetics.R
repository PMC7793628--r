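## Phenetics: maximum observable rescaled distances (MORD; the Gower
## coefficient for fully unordered data), principal coordinates, and
## nearest-taxon-to-ancestor summaries.

## Coerce a row of cell tokens / states / masks into bitmask form.
as_cell_masks <- function(x, symbols = as.character(0:9)) {
  if (is.character(x)) {
    return(vapply(seq_along(x), function(i) {
      parse_cell_string(x[i], symbols, "?", "-", paste0("cell", i))
    }, integer(1)))
  }
  as.integer(x)
}

state_vector_to_masks <- function(states) {
  m <- bitwShiftL(1L, as.integer(states))
  m[is.na(states)] <- NA_integer_
  m
}

## Pairwise MORD between two bitmask rows. Unordered characters: 0/1
## mismatch with maximum dissimilarity 1; ordered characters: minimum
## absolute state difference between the two cells' sets, rescaled by the
## pair's observable range.
mord_pair <- function(a, b, ordered, polymorphism = "overlap") {
  comp <- !is.na(a) & !is.na(b) & a != INAPP_CODE & b != INAPP_CODE
  n_comp <- sum(comp)
  if (n_comp == 0L) {
    return(list(d = NA_real_, n_comp = 0L))
  }
  num <- 0
  den <- 0
  for (j in which(comp)) {
    sa <- states_of_mask(a[j]); sb <- states_of_mask(b[j])
    if (ordered[j]) {
      dd <- min(abs(outer(sa, sb, "-")))
      mx <- max(diff(range(c(sa, sb))), 1L)
      num <- num + dd / mx
      den <- den + 1
    } else {
      same <- if (polymorphism == "overlap") {
        bitwAnd(a[j], b[j]) != 0L
      } else {
        a[j] == b[j]
      }
      num <- num + as.numeric(!same)
      den <- den + 1
    }
  }
  list(d = num / den, n_comp = n_comp)
}

#' Maximum observable rescaled distance between two character rows
#'
#' Pairwise dissimilarity over mutually scored characters rescaled by the
#' maximum possible dissimilarity over those characters; for unordered
#' characters this is the Gower coefficient. Missing and inapplicable
#' cells are excluded pairwise. Polymorphic cells count as matching when
#' their state sets intersect (set `polymorphism = "strict"` for exact
#' set equality).
#'
#' @param a,b Rows as cell-token vectors (`"0"`, `"?"`, `"{01}"`, ...), or
#'   integer state-set bitmasks.
#' @param ordered Logical vector of per-character ordered flags (default
#'   all unordered).
#' @param polymorphism `"overlap"` (default) or `"strict"`.
#' @return Distance in `[0, 1]` with attribute `n_comparable`; `NA` (with
#'   `n_comparable = 0`) when no characters are mutually scored.
#' @export
mord_distance <- function(a, b, ordered = NULL, polymorphism = "overlap") {
  am <- as_cell_masks(a); bm <- as_cell_masks(b)
  if (length(am) != length(bm)) stop("rows have different lengths")
  if (is.null(ordered)) ordered <- rep(FALSE, length(am))
  r <- mord_pair(am, bm, ordered, polymorphism)
  structure(r$d, n_comparable = r$n_comp)
}

#' Pairwise MORD distance matrix
#'
#' @param mm A [morph_matrix()], or an integer bitmask matrix with row
#'   names.
#' @param polymorphism Passed to [mord_distance()].
#' @return A `mord_dist` object: `labels`, `d` (symmetric matrix, zero
#'   diagonal, `NA` where no characters are comparable), `n_comp`.
#' @export
mord_matrix <- function(mm, polymorphism = "overlap") {
  if (inherits(mm, "morph_matrix")) {
    masks <- mm$mask
    ordered <- mm$ordered
    labels <- mm$taxa
  } else {
    masks <- mm
    ordered <- rep(FALSE, ncol(mm))
    labels <- rownames(mm)
  }
  n <- nrow(masks)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  ncp <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(ncp) <- ncol(masks)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- mord_pair(masks[i, ], masks[j, ], ordered, polymorphism)
      d[i, j] <- d[j, i] <- r$d
      ncp[i, j] <- ncp[j, i] <- r$n_comp
    }
  }
  structure(list(labels = labels, d = d, n_comp = ncp), class = "mord_dist")
}

#' @export
print.mord_dist <- function(x, ...) {
  cat("mord_dist: ", length(x$labels), " rows, ",
      sum(is.na(x$d[upper.tri(x$d)])), " undefined pair(s)\n", sep = "")
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: eigendecomposition of the
#' double-centred `-D^2/2`, coordinates scaled by the square roots of the
#' positive eigenvalues. All eigenvalues (including negative ones) are
#' reported.
#'
#' @param dist A `mord_dist`, `dist` or symmetric matrix, with no
#'   undefined entries.
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return List: `coordinates` (rows = objects), `eigenvalues`,
#'   `variance_explained` (relative eigenvalues), `correction`.
#' @export
pco <- function(dist, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  if (inherits(dist, "mord_dist")) {
    if (anyNA(dist$d)) {
      bad <- which(is.na(dist$d) & upper.tri(dist$d), arr.ind = TRUE)
      stop("undefined distances for pairs: ",
           paste(dist$labels[bad[, 1L]], dist$labels[bad[, 2L]],
                 sep = "~", collapse = ", "))
    }
    D <- dist$d
  } else {
    D <- as.matrix(dist)
    if (anyNA(D)) stop("distance matrix has undefined entries")
  }
  res <- ape::pcoa(D, correction = if (correction == "none") "none" else
    "cailliez")
  vals <- res$values
  eig <- vals$Eigenvalues
  rel <- if (!is.null(vals$Rel_corr_eig)) vals$Rel_corr_eig else
    vals$Relative_eig
  coords <- res$vectors
  rownames(coords) <- rownames(D)
  list(coordinates = coords, eigenvalues = eig, variance_explained = rel,
       correction = correction)
}

#' Nearest taxon to a reconstructed ancestor
#'
#' MORD distance from an ancestral phenotype vector to every taxon row,
#' under the homology alignment matching the ancestor's sampled homology
#' state; ties are broken by taxon order and flagged.
#'
#' @param ancestor An `ancestor_sample`, or an integer vector of single
#'   states (NA = unscored), length = number of characters of `taxa_mm`.
#' @param taxa_mm A [morph_matrix()] of the taxa, coded under the same
#'   homology alignment.
#' @param groups Optional named vector mapping taxon labels to group
#'   labels.
#' @return List: `taxon`, `distance`, `group` (or NA), `tie` (logical).
#' @export
nearest_taxon <- function(ancestor, taxa_mm, groups = NULL) {
  states <- if (inherits(ancestor, "ancestor_sample")) ancestor$states else
    ancestor
  if (length(states) != n_char(taxa_mm)) {
    stop("ancestor vector length (", length(states),
         ") != matrix characters (", n_char(taxa_mm), ")")
  }
  am <- state_vector_to_masks(states)
  dists <- vapply(seq_len(n_taxa(taxa_mm)), function(i) {
    mord_pair(am, taxa_mm$mask[i, ], taxa_mm$ordered)$d
  }, numeric(1))
  if (all(is.na(dists))) stop("all ancestor-taxon distances are undefined")
  best <- which.min(dists)
  tie <- sum(abs(dists - dists[best]) < 1e-12, na.rm = TRUE) > 1L
  list(taxon = taxa_mm$taxa[best], distance = dists[best],
       group = if (is.null(groups)) NA_character_ else
         unname(groups[taxa_mm$taxa[best]]),
       tie = tie)
}

#' Nearest-taxon frequencies over a posterior sample of ancestors
#'
#' For each retained ancestor draw, finds the closest taxon using the
#' composite alignment of that draw's homology state, then tabulates
#' nearest-taxon (and group) frequencies.
#'
#' @param run A `dynhom_mcmc` with ancestor logging.
#' @param model The `dynhom_model` used for the run.
#' @param groups Optional named vector taxon -> group.
#' @param retain Sample indices (default post-burn-in).
#' @return Data frame (gen, taxon, distance, group, tie) with attribute
#'   `"group_freq"`.
#' @export
nearest_taxon_posterior <- function(run, model, groups = NULL,
                                    retain = NULL) {
  if (is.null(run$ancestors)) stop("run has no ancestor log")
  if (is.null(retain)) retain <- retained_samples(run)
  rows <- lapply(retain, function(i) {
    anc <- run$ancestors[[i]]
    mm <- compose_matrix(model$fixed, model$blocks, anc$h)
    nt <- nearest_taxon(anc, mm, groups)
    data.frame(gen = run$trace$gen[i], taxon = nt$taxon,
               distance = nt$distance,
               group = if (is.null(groups)) NA_character_ else nt$group,
               tie = nt$tie)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_freq") <- if (is.null(groups)) {
    table(out$taxon) / nrow(out)
  } else {
    table(out$group) / nrow(out)
  }
  out
}

#' Subsample reconstructed ancestors for ordination
#'
#' Keeps every `every`-th retained sample, after excluding samples whose
#' homology state is not the modal state. The count depends on whether the
#' thinning is applied before or after the exclusion; both are reported so
#' the ambiguity is explicit.
#'
#' @param run A `dynhom_mcmc` with ancestor logging.
#' @param every Thinning interval (default 20, i.e. a 5% subsample).
#' @param retain Sample indices (default post-burn-in).
#' @return List: `indices` (exclusion first, then thinning), `n`,
#'   `n_thin_first` (the alternative arithmetic), `modal_h`,
#'   `n_excluded`.
#' @export
subsample_ancestors <- function(run, every = 20L, retain = NULL) {
  if (is.null(run$ancestors)) stop("run has no ancestor log")
  if (is.null(retain)) retain <- retained_samples(run)
  hs <- vapply(run$ancestors[retain],
               function(s) if (length(s$h)) s$h[1L] else 0L, integer(1))
  tab <- table(hs)
  modal <- as.integer(names(tab)[which.max(tab)])
  keep <- retain[hs == modal]
  idx <- keep[seq(1L, length(keep), by = every)]
  thin_first <- retain[seq(1L, length(retain), by = every)]
  n_alt <- sum(vapply(run$ancestors[thin_first],
                      function(s) if (length(s$h)) s$h[1L] else 0L,
                      integer(1)) == modal)
  list(indices = idx, n = length(idx), n_thin_first = n_alt,
       modal_h = modal, n_excluded = length(retain) - length(keep))
}
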