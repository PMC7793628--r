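test_that("NEXUS cells map to state sets, missing and inapplicable codes", {
  path <- write_nexus_text(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=3;",
    'FORMAT DATATYPE=STANDARD SYMBOLS="0123" MISSING=? GAP=-;',
    "MATRIX", "A 01?", "B 0{12}-", ";", "END;"))
  mm <- read_nexus(path)
  expect_identical(mm$taxa, c("A", "B"))
  tok <- as.matrix(mm)
  expect_identical(unname(tok["B", ]), c("0", "{12}", "-"))
  expect_identical(unname(tok["A", ]), c("0", "1", "?"))
  expect_true(is.na(mm$mask["A", 3]))
  expect_identical(unname(mm$mask["B", 3]), 0L)   # inapplicable
  expect_identical(unname(mm$mask["B", 2]), 6L)   # {1,2} bitmask
  ## parenthesis polymorphism and interleaving
  path2 <- write_nexus_text(c(
    "#NEXUS", "BEGIN CHARACTERS;", "DIMENSIONS NTAX=2 NCHAR=4;",
    "FORMAT SYMBOLS=\"01\";", "MATRIX",
    "A 0(01)", "B 11", "A 10", "B 0?", ";", "END;"))
  mm2 <- read_nexus(path2)
  expect_identical(unname(as.matrix(mm2)["A", ]), c("0", "{01}", "1", "0"))
})

test_that("parse errors name the offending taxon and position", {
  ragged <- write_nexus_text(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=3;",
    "MATRIX", "A 010", "B 01", ";", "END;"))
  expect_error(read_nexus(ragged), "ragged row.*'B'")
  bad <- write_nexus_text(c(
    "#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=1 NCHAR=3;",
    'FORMAT SYMBOLS="01";', "MATRIX", "A 0X1", ";", "END;"))
  expect_error(read_nexus(bad), "undeclared symbol 'X'.*character 2.*'A'")
  expect_error(read_nexus(tempfile()), "file not found")
})

test_that("write/read round-trip reproduces cells exactly", {
  set.seed(31)
  for (rep in 1:5) {
    ntip <- sample(3:8, 1)
    nc <- sample(2:12, 1)
    mm <- random_mm(ntip, nc, kmax = 3, missing = 0.2)
    mm$mask[1, 1] <- 0L  # inapplicable
    mm$mask[min(2, ntip), 1] <- 5L  # {0,2}
    path <- tempfile(fileext = ".nex")
    write_nexus(mm, path)
    back <- read_nexus(path)
    expect_identical(back$mask, mm$mask)
    expect_identical(back$taxa, mm$taxa)
  }
})

test_that("observed state counts are union sizes over scored cells", {
  M <- matrix(c(0L, 1L, 2L,
                0L, NA, 1L,
                0L, 0L, 0L), 3, 3, byrow = TRUE)
  mm <- mm_from_states(M, c("a", "b", "c"))
  mm$mask[3, 3] <- 0L  # inapplicable
  expect_identical(state_counts(mm), c(1L, 2L, 2L))
  expect_identical(state_counts(mm_from_states(matrix(NA_integer_, 2, 1),
                                               c("a", "b"))), 0L)
})

test_that("compose_matrix selects codings and checks bounds", {
  fx <- make_fig2_fixture(2)
  comp0 <- compose_matrix(fx$fixed, fx$block, 0L)
  comp1 <- compose_matrix(fx$fixed, fx$block, 1L)
  expect_identical(n_char(comp0), 8L)
  expect_identical(n_char(comp1), 8L)
  ## block coding appears verbatim in the block columns
  expect_identical(comp0$mask[, 7:8], fx$block$codings[[1]]$mask)
  expect_identical(comp1$mask[, 7:8], fx$block$codings[[2]]$mask)
  ## fixed columns identical across h
  expect_identical(comp0$mask[, 1:6], comp1$mask[, 1:6])
  expect_error(compose_matrix(fx$fixed, fx$block, 2L), "out of range")
  ## taxon mismatch is reported with labels
  other <- morph_matrix(fx$fixed$mask, paste0("x", seq_len(11)))
  expect_error(compose_matrix(other, fx$block, 0L), "taxon mismatch")
})

test_that("homology blocks require aligned codings", {
  fx <- make_fig2_fixture(1)
  short <- subset_chars(fx$block$codings[[1]], 1)
  expect_error(homology_block(list(fx$block$codings[[1]], short)),
               "characters")
  expect_error(homology_block(list(fx$block$codings[[1]])), "at least 2")
})

test_that("block declarations via sidecar config split fixed and block columns", {
  fx <- make_fig2_fixture(2)
  comp_all <- morph_matrix(
    cbind(fx$fixed$mask, fx$block$codings[[1]]$mask,
          fx$block$codings[[2]]$mask),
    fx$fixed$taxa)
  path <- tempfile(fileext = ".nex")
  write_nexus(comp_all, path)
  cfg <- list(blocks = list(list(label = "jaws",
                                 states = list("7-8", "9-10"))))
  rd <- read_nexus_with_blocks(path, cfg)
  expect_identical(n_char(rd$fixed), 6L)
  expect_identical(length(rd$blocks), 1L)
  expect_identical(n_states(rd$blocks$jaws), 2L)
  expect_identical(rd$blocks$jaws$codings[[2]]$mask,
                   fx$block$codings[[2]]$mask)
  bad <- list(blocks = list(list(label = "jaws",
                                 states = list("7-8", "8-9"))))
  expect_error(read_nexus_with_blocks(path, bad), "more than one")
  uneq <- list(blocks = list(list(label = "jaws",
                                  states = list("7-8", "9"))))
  expect_error(read_nexus_with_blocks(path, uneq), "unequal")
})

test_that("characters partition by distinct (state count, homoplasy) keys", {
  p <- partition_characters(c(2, 2, 3), c(0, 0, 0))
  expect_identical(n_partitions(p), 2L)
  expect_identical(p$key$weight, c(2L, 1L))
  expect_identical(n_partitions(partition_characters(c(2, 2), c(1, 1))), 1L)
  expect_identical(n_partitions(partition_characters(c(2, 2), c(0, 1))), 2L)
  expect_error(partition_characters(c(2, 2), c(0, -1)), ">= 0")
  expect_error(partition_characters(c(2, 2), 0), "equal length")
  ## weights sum to total characters; assignment covers every character
  set.seed(4)
  sc <- sample(2:4, 30, TRUE)
  hv <- sample(0:3, 30, TRUE)
  p2 <- partition_characters(sc, hv)
  expect_identical(sum(p2$key$weight), 30L)
  expect_false(anyNA(p2$assignment))
  ## two characters share a partition iff they share both key parts
  same <- outer(seq_along(sc), seq_along(sc), function(i, j) {
    p2$assignment[i] == p2$assignment[j]
  })
  expect_identical(same, outer(seq_along(sc), seq_along(sc), function(i, j) {
    sc[i] == sc[j] & hv[i] == hv[j]
  }))
})
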