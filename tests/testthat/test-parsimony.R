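test_that("Fitch steps match hand examples and handle uncertainty", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(fitch_steps(tr, c(A = "0", B = "0", C = "0", D = "0")), 0L)
  expect_identical(fitch_steps(tr, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  expect_identical(fitch_steps(tr, c(A = "0", B = "?", C = "1", D = "1")), 1L)
  expect_identical(fitch_steps(tr, c(A = "0", B = "1", C = "0", D = "1")), 2L)
  expect_identical(fitch_steps(tr, c(A = "{01}", B = "1", C = "0",
                                     D = "-")), 1L)
  expect_error(fitch_steps(tr, c(A = "0", B = "0", C = "1")), "absent")
})

test_that("Fitch equals exhaustive minimum on small random instances", {
  set.seed(17)
  for (rep in 1:12) {
    ntip <- sample(4:6, 1)
    k <- sample(2:4, 1)
    taxa <- paste0("t", seq_len(ntip))
    tr <- ape::rtree(ntip, tip.label = taxa)
    states <- sample(0:(k - 1), ntip, TRUE)
    sets <- lapply(states, identity)
    names(sets) <- taxa
    ## sprinkle uncertainty
    sets[[1]] <- 0:(k - 1)
    if (ntip > 4) sets[[2]] <- sort(sample(0:(k - 1), 2))
    M <- mm_from_states(matrix(states, ncol = 1), taxa)
    for (t in seq_along(sets)) {
      M$mask[t, 1] <- dynhom:::mask_of_states(sets[[taxa[t]]])
    }
    mine <- fitch_steps_matrix(tr, M)[1]
    oracle <- enum_fitch(tr, sets, 0:(k - 1))
    expect_identical(as.integer(mine), as.integer(oracle))
  }
})

test_that("Fitch agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (rep in 1:8) {
    ntip <- sample(4:9, 1)
    nc <- sample(4:12, 1)
    taxa <- paste0("t", seq_len(ntip))
    tr <- ape::rtree(ntip, tip.label = taxa)
    M <- matrix(sample(0:1, ntip * nc, TRUE), ntip, nc,
                dimnames = list(taxa, NULL))
    mm <- mm_from_states(M, taxa)
    pd <- phangorn::phyDat(matrix(as.character(M), ntip, nc,
                                  dimnames = list(taxa, NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_identical(as.integer(sum(fitch_steps_matrix(tr, mm))),
                     as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("homoplasy is extra steps, non-negative, and reroot-invariant", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  mm <- mm_from_states(matrix(c(0L, 1L, 0L, 1L), 4, 1,
                              dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_identical(homoplasy(tr, mm), 1L)  # 2 steps - (2 - 1)
  ## all-missing character has zero homoplasy
  mm2 <- mm_from_states(matrix(NA_integer_, 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_identical(homoplasy(tr, mm2), 0L)
  ## constant character on any tree
  mm3 <- mm_from_states(matrix(0L, 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_identical(homoplasy(tr, mm3), 0L)
  set.seed(9)
  tr6 <- ape::rtree(6, tip.label = paste0("t", 1:6))
  mm6 <- random_mm(6, 8, kmax = 3)
  h1 <- homoplasy(tr6, mm6)
  for (og in c("t2", "t5")) {
    tr6b <- ape::root(ape::unroot(tr6), outgroup = og, resolve.root = TRUE)
    expect_identical(homoplasy(tr6b, mm6), h1)
  }
})

test_that("implied-weights score follows the concave fit penalty", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  mm0 <- mm_from_states(matrix(c(0L, 0L, 1L, 1L), 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_identical(implied_weights_score(tr, mm0, k = 10), 0)
  ## one character with homoplasy 5 under k = 10 contributes 5/15
  expect_equal(5 / (5 + 10), 1 / 3, tolerance = 1e-12)
  mmh <- mm_from_states(matrix(c(0L, 1L, 0L, 1L), 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(implied_weights_score(tr, mmh, k = 10), 1 / 11)
  expect_error(implied_weights_score(tr, mmh, k = 0), "k must be > 0")
  ## monotone non-decreasing in each character's homoplasy
  h <- 0:6
  fits <- h / (h + 10)
  expect_true(all(diff(fits) > 0))
})

test_that("search finds the exhaustive implied-weights optimum on 5 taxa", {
  set.seed(41)
  for (rep in 1:4) {
    mm <- random_mm(5, 8, kmax = 2)
    tops <- dynhom:::all_topologies(5)
    expect_length(tops, 15L)
    scores <- vapply(tops, function(pt) {
      implied_weights_score(dynhom:::pt_to_phylo(pt, mm$taxa), mm, k = 10)
    }, numeric(1))
    sr <- implied_weights_search(mm, parsimony_config(seed = rep))
    expect_equal(sr$score, min(scores), tolerance = 1e-9)
  }
})

test_that("search is deterministic per seed and exact on clean signal", {
  set.seed(6)
  mm <- random_mm(7, 12, kmax = 2)
  s1 <- implied_weights_search(mm, parsimony_config(seed = 99))
  s2 <- implied_weights_search(mm, parsimony_config(seed = 99))
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$score, s2$score)
  expect_identical(s1$homoplasy, s2$homoplasy)
  ## homoplasy-free matrix: perfectly nested binary characters
  M <- matrix(0L, 6, 4, dimnames = list(paste0("t", 1:6), NULL))
  M[1:2, 1] <- 1L; M[1:3, 2] <- 1L; M[4:6, 3] <- 1L; M[5:6, 4] <- 1L
  sr <- implied_weights_search(mm_from_states(M), parsimony_config(seed = 1))
  expect_identical(sr$homoplasy, rep(0L, 4))
  expect_identical(sr$score, 0)
  expect_error(implied_weights_search(random_mm(3, 4), parsimony_config()),
               "at least 4 taxa")
})

test_that("search never scores worse than random topologies", {
  set.seed(77)
  mm <- random_mm(7, 10, kmax = 3)
  sr <- implied_weights_search(mm, parsimony_config(seed = 2, n_starts = 3))
  for (s in 1:5) {
    set.seed(s)
    rnd <- ape::rtree(7, tip.label = mm$taxa)
    expect_lte(sr$score, implied_weights_score(rnd, mm, k = 10) + 1e-12)
  }
})

test_that("variable-homology characters take the lower homoplasy value", {
  expect_identical(homology_min_homoplasy(c(2L, 1L), c(1L, 3L)), c(1L, 1L))
  expect_identical(homology_min_homoplasy(c(4L, 0L), c(4L, 0L)), c(4L, 0L))
  expect_identical(homology_min_homoplasy(list(c(3L, 2L))), c(3L, 2L))
  expect_error(homology_min_homoplasy(c(1L, 2L), c(1L, 2L, 3L)),
               "unequal lengths")
})
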