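## Homoplasy-based partition assignment: one partition per distinct
## (observed state count, homoplasy) pair, each later given its own Mk
## mutation-rate parameter.

#' Partition characters by state count and homoplasy
#'
#' @param state_counts Integer vector: observed state count per character.
#' @param homoplasy Integer vector (same length): homoplasy per character,
#'   i.e. parsimony steps on the reference tree minus (states - 1).
#' @return An object of class `partition_scheme`: list with `assignment`
#'   (character index -> partition id), `key` (data frame: partition id,
#'   `nstates`, `homoplasy`, `weight` = member count).
#' @export
partition_characters <- function(state_counts, homoplasy) {
  if (length(state_counts) != length(homoplasy)) {
    stop("state_counts and homoplasy must have equal length")
  }
  if (any(homoplasy < 0)) stop("homoplasy values must be >= 0")
  key <- paste(state_counts, homoplasy, sep = "/")
  ord <- order(state_counts, homoplasy)
  levels <- unique(key[ord])
  assignment <- match(key, levels)
  tab <- tabulate(assignment, nbins = length(levels))
  parts <- do.call(rbind, strsplit(levels, "/"))
  scheme <- structure(
    list(assignment = assignment,
         key = data.frame(partition = seq_along(levels),
                          nstates = as.integer(parts[, 1L]),
                          homoplasy = as.integer(parts[, 2L]),
                          weight = tab)),
    class = "partition_scheme")
  scheme
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("partition_scheme: ", nrow(x$key), " partitions over ",
      length(x$assignment), " characters\n", sep = "")
  print(x$key, row.names = FALSE)
  invisible(x)
}

#' Number of partitions in a scheme
#' @param scheme A `partition_scheme`.
#' @return Integer.
#' @export
n_partitions <- function(scheme) nrow(scheme$key)

#' Export a partition key table as TSV
#' @param scheme A `partition_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_table <- function(scheme, path) {
  write.table(x = scheme$key, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
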