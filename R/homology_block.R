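## Homology blocks: N alternative codings ("homology alignments") of the
## same anatomical features, indexed by an integer homology state h in
## 0..(N-1). A block's codings share the taxon set and character count.

#' Construct a homology block
#'
#' @param codings List of [morph_matrix()] objects, one per homology state
#'   (at least 2), with identical taxa and character counts.
#' @param label Text label for the block.
#' @return An object of class `homology_block`.
#' @export
homology_block <- function(codings, label = "block") {
  if (length(codings) < 2L) stop("a homology block needs at least 2 codings")
  taxa0 <- codings[[1L]]$taxa
  nc0 <- n_char(codings[[1L]])
  for (i in seq_along(codings)) {
    if (!identical(codings[[i]]$taxa, taxa0)) {
      stop("coding ", i - 1L, " of block '", label,
           "' has a different taxon set")
    }
    if (n_char(codings[[i]]) != nc0) {
      stop("coding ", i - 1L, " of block '", label, "' has ",
           n_char(codings[[i]]), " characters, expected ", nc0)
    }
  }
  structure(list(codings = codings, label = label), class = "homology_block")
}

#' Number of homology states of a block
#' @param block A [homology_block()].
#' @return Integer N >= 2.
#' @export
n_states <- function(block) length(block$codings)

#' @export
print.homology_block <- function(x, ...) {
  cat("homology_block '", x$label, "': ", n_states(x), " states x ",
      n_char(x$codings[[1L]]), " characters, ",
      length(x$codings[[1L]]$taxa), " taxa\n", sep = "")
  invisible(x)
}

#' Compose the homology alignment for a given homology state
#'
#' Concatenates the fixed-homology columns with the block's coding `h`
#' (fixed columns first, block columns in declared order). This is the
#' alignment whose tree likelihood enters the posterior when the homology
#' parameter is at `h`.
#'
#' @param fixed [morph_matrix()] of fixed-homology characters.
#' @param block A [homology_block()] (or a list of blocks).
#' @param h Integer homology state in `0..N-1` (or a vector, one per block).
#' @return A [morph_matrix()].
#' @export
compose_matrix <- function(fixed, block, h) {
  if (inherits(block, "homology_block")) block <- list(block)
  if (length(h) != length(block)) {
    stop("need one homology state per block (", length(block), " blocks, ",
         length(h), " states given)")
  }
  out <- fixed
  for (i in seq_along(block)) {
    b <- block[[i]]
    if (h[i] < 0L || h[i] >= n_states(b)) {
      stop("homology state ", h[i], " out of range [0, ", n_states(b) - 1L,
           "] for block '", b$label, "'")
    }
    cod <- b$codings[[h[i] + 1L]]
    if (!setequal(cod$taxa, out$taxa)) {
      stop("taxon mismatch between fixed matrix and block '", b$label,
           "': ", paste(c(setdiff(cod$taxa, out$taxa),
                          setdiff(out$taxa, cod$taxa)), collapse = ", "))
    }
    cod_mask <- cod$mask[match(out$taxa, cod$taxa), , drop = FALSE]
    out <- morph_matrix(cbind(out$mask, cod_mask), out$taxa,
                        c(out$ordered, cod$ordered), out$symbols)
  }
  out
}
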