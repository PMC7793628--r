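## NEXUS I/O for morphological matrices.
##
## Standard NEXUS has no syntax for dynamic homology, so alternative codings
## are declared in a sidecar config: the NEXUS file carries all columns
## (fixed plus every homology state's columns) and the config names, per
## block and homology state, the character set holding that coding.

#' Read a morphological matrix from a NEXUS file
#'
#' Parses a DATA or CHARACTERS block. Supported cell tokens: single symbols,
#' `?` (missing), `-` (inapplicable), and polymorphic sets in `{}` or `()`.
#' Both sequential and interleaved matrices are accepted.
#'
#' @param path Path to a NEXUS file.
#' @return A [morph_matrix()].
#' @export
read_nexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  txt <- sub("\\[[^]]*\\]", "", txt)  # strip single-line comments
  joined <- paste(txt, collapse = "\n")
  if (!grepl("#NEXUS", joined, ignore.case = TRUE)) {
    stop("not a NEXUS file (missing #NEXUS header): ", path)
  }

  dim_m <- regmatches(joined, regexpr(
    "DIMENSIONS[^;]*;", joined, ignore.case = TRUE))
  if (length(dim_m) == 0L) stop("no DIMENSIONS statement in ", path)
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", dim_m,
                         ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dim_m,
                           ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchar_)) stop("could not parse NTAX/NCHAR in ", path)

  symbols <- as.character(0:9)
  missing_ch <- "?"; gap_ch <- "-"
  fmt_m <- regmatches(joined, regexpr("FORMAT[^;]*;", joined,
                                      ignore.case = TRUE))
  if (length(fmt_m) == 1L) {
    sy <- regmatches(fmt_m, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', fmt_m,
                                    ignore.case = TRUE))
    if (length(sy) == 1L) {
      sy <- sub('.*"([^"]*)".*', "\\1", sy)
      symbols <- strsplit(gsub("\\s", "", sy), "")[[1L]]
    }
    mi <- regmatches(fmt_m, regexpr("MISSING\\s*=\\s*\\S", fmt_m,
                                    ignore.case = TRUE))
    if (length(mi) == 1L) missing_ch <- substring(mi, nchar(mi))
    ga <- regmatches(fmt_m, regexpr("GAP\\s*=\\s*\\S", fmt_m,
                                    ignore.case = TRUE))
    if (length(ga) == 1L) gap_ch <- substring(ga, nchar(ga))
  }

  mat_at <- regexpr("MATRIX\\s", joined, ignore.case = TRUE)
  if (mat_at < 0L) stop("no MATRIX statement in ", path)
  body <- substring(joined, mat_at + attr(mat_at, "match.length"))
  body <- sub(";.*$", "", body)
  lines <- strsplit(body, "\n")[[1L]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  rows <- list()
  order_seen <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^('[^']+'|\"[^\"]+\"|\\S+)\\s+(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse matrix row: ", ln)
    taxon <- gsub("^['\"]|['\"]$", "", m[2L])
    cells <- gsub("\\s", "", m[3L])
    if (!taxon %in% order_seen) {
      order_seen <- c(order_seen, taxon)
      rows[[taxon]] <- cells
    } else {
      rows[[taxon]] <- paste0(rows[[taxon]], cells)  # interleaved
    }
  }
  if (length(rows) != ntax) {
    stop("expected NTAX=", ntax, " taxa but found ", length(rows))
  }

  mask <- matrix(NA_integer_, ntax, nchar_, dimnames = list(order_seen, NULL))
  for (taxon in order_seen) {
    cells <- parse_cell_string(rows[[taxon]], symbols, missing_ch, gap_ch,
                               taxon)
    if (length(cells) != nchar_) {
      stop("ragged row for taxon '", taxon, "': ", length(cells),
           " cells, expected ", nchar_)
    }
    mask[taxon, ] <- cells
  }
  morph_matrix(mask, order_seen, symbols = symbols)
}

## Tokenize one taxon's concatenated cell string into bitmask cells.
parse_cell_string <- function(s, symbols, missing_ch, gap_ch, taxon) {
  chars <- strsplit(s, "")[[1L]]
  out <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == missing_ch) {
      out <- c(out, MISSING_CODE); i <- i + 1L
    } else if (ch == gap_ch) {
      out <- c(out, INAPP_CODE); i <- i + 1L
    } else if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      states <- integer(0)
      while (j <= n && chars[j] != close) {
        idx <- match(chars[j], symbols)
        if (is.na(idx)) {
          stop("undeclared symbol '", chars[j], "' in polymorphism at position ",
               j, " of taxon '", taxon, "'")
        }
        states <- c(states, idx - 1L)
        j <- j + 1L
      }
      if (j > n) stop("unterminated polymorphism for taxon '", taxon, "'")
      if (length(states) == 0L) {
        stop("empty polymorphic state set for taxon '", taxon, "'")
      }
      out <- c(out, mask_of_states(states))
      i <- j + 1L
    } else {
      idx <- match(ch, symbols)
      if (is.na(idx)) {
        stop("undeclared symbol '", ch, "' at character ", length(out) + 1L,
             " of taxon '", taxon, "'")
      }
      out <- c(out, bitwShiftL(1L, idx - 1L))
      i <- i + 1L
    }
  }
  out
}

#' Write a morphological matrix to a NEXUS file
#'
#' @param x A [morph_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(x, path) {
  tok <- as.matrix(x)
  rows <- apply(tok, 1L, paste0, collapse = "")
  lab <- x$taxa
  quoted <- grepl("\\s", lab)
  lab[quoted] <- paste0("'", lab[quoted], "'")
  lab <- formatC(lab, width = max(nchar(lab)) + 2L, flag = "-")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(x), n_char(x)),
    sprintf('  FORMAT DATATYPE=STANDARD SYMBOLS="%s" MISSING=? GAP=-;',
            paste0(x$symbols, collapse = "")),
    "  MATRIX",
    paste0("    ", lab, rows),
    "  ;",
    "END;"), con)
  invisible(path)
}

#' Parse a NEXUS-style character-set expression
#'
#' Accepts whitespace-separated indices and ranges, e.g. `"1-6 9 12-14"`
#' (1-based, inclusive).
#'
#' @param s Character-set string.
#' @return Sorted integer vector of character indices.
#' @export
parse_charset <- function(s) {
  parts <- strsplit(trimws(as.character(s)), "\\s+")[[1L]]
  idx <- integer(0)
  for (p in parts) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-")[[1L]])
      idx <- c(idx, seq(ab[1L], ab[2L]))
    } else if (grepl("^[0-9]+$", p)) {
      idx <- c(idx, as.integer(p))
    } else {
      stop("cannot parse character-set token: '", p, "'")
    }
  }
  sort(unique(idx))
}

#' Read a matrix together with its homology-block declarations
#'
#' The NEXUS file holds every column (fixed-homology columns plus the columns
#' of each homology state's coding); the block config declares which columns
#' belong to which homology state of which block. Config structure (YAML):
#' a list under `blocks`, each entry with a `label` and `states`, the latter
#' a list of character-set strings, one per homology state, all of equal
#' length.
#'
#' @param nexus_path Path to the combined NEXUS matrix.
#' @param config Either a path to a YAML file or an already-parsed list.
#' @return A list with elements `fixed` (a [morph_matrix()] of the
#'   fixed-homology columns) and `blocks` (a list of [homology_block()]s).
#' @export
read_nexus_with_blocks <- function(nexus_path, config) {
  full <- read_nexus(nexus_path)
  if (is.character(config)) config <- yaml::read_yaml(config)
  decls <- config$blocks
  if (is.null(decls)) stop("block config has no 'blocks' entry")
  used <- integer(0)
  blocks <- list()
  for (d in decls) {
    sets <- lapply(d$states, parse_charset)
    lens <- vapply(sets, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("block '", d$label, "': homology states declare unequal ",
           "character counts (", paste(lens, collapse = ", "), ")")
    }
    codings <- lapply(sets, function(j) subset_chars(full, j))
    blocks[[d$label]] <- homology_block(codings, label = d$label)
    used <- c(used, unlist(sets))
  }
  if (anyDuplicated(used)) {
    stop("character columns assigned to more than one homology state: ",
         paste(unique(used[duplicated(used)]), collapse = ", "))
  }
  fixed <- subset_chars(full, setdiff(seq_len(n_char(full)), used))
  list(fixed = fixed, blocks = blocks)
}
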