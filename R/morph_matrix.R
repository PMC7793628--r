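## Discrete morphological matrices.
##
## Cells are stored as integer bitmasks over the symbol alphabet: bit s set
## means state s is present in the cell's state set (polymorphisms have
## several bits set). Two special codes: NA = missing ('?'), 0L =
## inapplicable ('-'). Missing and inapplicable are distinct in the data
## model and in round-trip I/O, but are treated identically downstream
## (full-uncertainty in likelihood and parsimony, excluded from distances).

MISSING_CODE <- NA_integer_
INAPP_CODE <- 0L

#' Construct a morphological character matrix
#'
#' @param mask Integer matrix (taxa x characters) of state-set bitmasks
#'   (bit `s` = state `s` present); `NA` encodes missing ('?'), `0L`
#'   inapplicable ('-'). Row names, if present, become the taxon labels.
#' @param taxa Character vector of taxon labels (unique, one per row).
#' @param ordered Logical vector, one per character; `FALSE` (unordered) is
#'   the default for every character.
#' @param symbols Character vector of state symbols; position `i` is state
#'   `i - 1`.
#'
#' @return An object of class `morph_matrix`.
#' @export
morph_matrix <- function(mask, taxa = rownames(mask), ordered = NULL,
                         symbols = as.character(0:9)) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  if (is.null(taxa)) stop("taxon labels are required")
  if (is.null(ordered)) ordered <- rep(FALSE, ncol(mask))
  rownames(mask) <- taxa
  x <- structure(
    list(mask = mask, taxa = as.character(taxa), ordered = ordered,
         symbols = symbols),
    class = "morph_matrix")
  validate_morph_matrix(x)
  x
}

validate_morph_matrix <- function(x) {
  stopifnot(inherits(x, "morph_matrix"))
  if (anyDuplicated(x$taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(x$taxa[duplicated(x$taxa)]), collapse = ", "))
  }
  if (nrow(x$mask) != length(x$taxa)) {
    stop("mask rows (", nrow(x$mask), ") != number of taxa (",
         length(x$taxa), ")")
  }
  if (length(x$ordered) != ncol(x$mask)) {
    stop("ordered flags length != number of characters")
  }
  full <- bitwShiftL(1L, length(x$symbols)) - 1L
  bad <- !is.na(x$mask) & (x$mask < 0L | x$mask > full)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop("cell (", x$taxa[ij[1L]], ", char ", ij[2L],
         ") holds states outside the declared symbol alphabet")
  }
  invisible(x)
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat("morph_matrix: ", n_taxa(x), " taxa x ", n_char(x), " characters\n",
      sep = "")
  sc <- state_counts(x)
  cat("  observed state counts: ",
      paste(names(table(sc)), "states:", table(sc), collapse = "; "), "\n",
      sep = "")
  nm <- sum(is.na(x$mask))
  ni <- sum(!is.na(x$mask) & x$mask == INAPP_CODE)
  cat("  missing cells: ", nm, ", inapplicable: ", ni, "\n", sep = "")
  invisible(x)
}

#' Number of taxa / characters
#' @param x A `morph_matrix`.
#' @return Integer count.
#' @export
n_taxa <- function(x) length(x$taxa)

#' @rdname n_taxa
#' @export
n_char <- function(x) ncol(x$mask)

popcount <- local({
  tab <- vapply(0:1023, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:9)) != 0L),
                integer(1))
  function(m) tab[m + 1L]
})

#' Observed state counts per character
#'
#' The number of distinct states in the union of all scored (non-missing,
#' applicable) state sets of each character. All-missing characters count 0.
#'
#' @param x A `morph_matrix`.
#' @return Integer vector, one entry per character.
#' @export
state_counts <- function(x) {
  m <- x$mask
  m[is.na(m)] <- 0L
  un <- integer(ncol(m))
  for (j in seq_len(ncol(m))) un[j] <- Reduce(bitwOr, m[, j], 0L)
  popcount(un)
}

## Bitmask of the observed-state union per character.
state_union <- function(x) {
  m <- x$mask
  m[is.na(m)] <- 0L
  vapply(seq_len(ncol(m)), function(j) Reduce(bitwOr, m[, j], 0L), integer(1))
}

mask_to_token <- function(m, symbols) {
  if (is.na(m)) return("?")
  if (m == INAPP_CODE) return("-")
  st <- which(bitwAnd(m, bitwShiftL(1L, seq_along(symbols) - 1L)) != 0L)
  if (length(st) == 1L) return(symbols[st])
  paste0("{", paste0(symbols[st], collapse = ""), "}")
}

states_of_mask <- function(m) which(bitwAnd(m, bitwShiftL(1L, 0:9)) != 0L) - 1L

mask_of_states <- function(states) {
  if (length(states) == 0L) return(INAPP_CODE)
  Reduce(bitwOr, bitwShiftL(1L, as.integer(states)))
}

#' Convert a morphological matrix to display tokens
#'
#' @param x A `morph_matrix`.
#' @param ... Unused.
#' @return Character matrix of NEXUS-style tokens (`"0"`, `"{01}"`, `"?"`,
#'   `"-"`).
#' @export
as.matrix.morph_matrix <- function(x, ...) {
  out <- matrix("", n_taxa(x), n_char(x), dimnames = list(x$taxa, NULL))
  for (i in seq_len(n_taxa(x))) {
    out[i, ] <- vapply(x$mask[i, ], mask_to_token, character(1),
                       symbols = x$symbols)
  }
  out
}

#' Select a subset of characters
#' @param x A `morph_matrix`.
#' @param j Character (column) indices.
#' @return A `morph_matrix` with the selected columns.
#' @export
subset_chars <- function(x, j) {
  morph_matrix(x$mask[, j, drop = FALSE], x$taxa, x$ordered[j], x$symbols)
}
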