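test_that("MORD matches hand counts and exclusion rules", {
  expect_identical(as.numeric(mord_distance(c("0", "1", "0"),
                                            c("0", "1", "0"))), 0)
  d <- mord_distance(c("0", "1", "?", "0"), c("0", "0", "?", "1"))
  expect_equal(as.numeric(d), 2 / 3, tolerance = 1e-12)
  expect_identical(attr(d, "n_comparable"), 3L)
  ## inapplicable excluded pairwise like missing
  d2 <- mord_distance(c("0", "-"), c("1", "1"))
  expect_identical(attr(d2, "n_comparable"), 1L)
  ## polymorphic overlap counts as a match by default, mismatch in strict mode
  expect_identical(as.numeric(mord_distance("{01}", "1")), 0)
  expect_identical(as.numeric(mord_distance("{01}", "1",
                                            polymorphism = "strict")), 1)
  ## no mutually scored characters: undefined flag
  und <- mord_distance(c("?", "-"), c("0", "1"))
  expect_true(is.na(und))
  expect_identical(attr(und, "n_comparable"), 0L)
  expect_error(mord_distance(c("0", "1"), c("0")), "different lengths")
})

test_that("MORD is a pseudo-metric on complete unordered matrices", {
  set.seed(71)
  for (rep in 1:5) {
    mm <- random_mm(6, 10, kmax = 3)
    md <- mord_matrix(mm)
    D <- md$d
    expect_true(all(diag(D) == 0))
    expect_identical(D, t(D))
    expect_true(all(D >= 0 & D <= 1))
    n <- nrow(D)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
    }
  }
})

test_that("PCO reproduces the closed form for three equidistant points", {
  D <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  pc <- pco(D)
  pos <- pc$eigenvalues[pc$eigenvalues > 1e-10]
  expect_length(pos, 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
  expect_equal(sum(pos), 1, tolerance = 1e-10)  # trace of the centred matrix
  dd <- as.matrix(stats::dist(pc$coordinates))
  expect_equal(unname(dd), unname(D), tolerance = 1e-9)
})

test_that("PCO conserves the eigenvalue sum and flags undefined input", {
  set.seed(13)
  mm <- random_mm(7, 15, kmax = 3)
  md <- mord_matrix(mm)
  pc <- pco(md)
  B <- -0.5 * md$d^2
  Bc <- sweep(sweep(B, 1, rowMeans(B)), 2, colMeans(B)) + mean(B)
  expect_equal(sum(pc$eigenvalues), sum(diag(Bc)), tolerance = 1e-8)
  ## duplicated rows land on coincident coordinates
  mm2 <- mm_from_states(rbind(a = c(0L, 1L, 0L), b = c(0L, 1L, 0L),
                              c = c(1L, 0L, 1L), d = c(1L, 1L, 0L)))
  pc2 <- pco(mord_matrix(mm2))
  expect_equal(unname(pc2$coordinates["a", ]),
               unname(pc2$coordinates["b", ]), tolerance = 1e-9)
  ## undefined pairs are reported with their labels
  mm3 <- mm_from_states(rbind(a = c(0L, NA), b = c(NA, 1L),
                              c = c(0L, 1L)))
  expect_error(pco(mord_matrix(mm3)), "a~b")
  ## round trip: Euclidean distances over all positive axes reproduce an
  ## embeddable distance matrix
  pts <- matrix(stats::rnorm(12), 4)
  DE <- as.matrix(stats::dist(pts))
  pcE <- pco(DE)
  keep <- pcE$eigenvalues > 1e-8
  dd <- as.matrix(stats::dist(pcE$coordinates[, seq_len(sum(keep))]))
  expect_equal(unname(dd), unname(DE), tolerance = 1e-8)
})

test_that("nearest taxon selection, tie flagging and group binning", {
  mm <- mm_from_states(rbind(t1 = c(0L, 0L, 0L, 0L, 1L),
                             t2 = c(0L, 0L, 1L, 1L, 0L),
                             t3 = c(1L, 1L, 1L, 0L, 0L)))
  anc <- c(0L, 0L, 0L, 0L, 1L)
  nt <- nearest_taxon(anc, mm)
  expect_identical(nt$taxon, "t1")
  expect_identical(nt$distance, 0)
  expect_false(nt$tie)
  ## hand-computed distances 0.2 / 0.4 / 0.8 pick t1; groups map through
  anc2 <- c(0L, 0L, 0L, 0L, 0L)
  nt2 <- nearest_taxon(anc2, mm, groups = c(t1 = "placoderm",
                                            t2 = "osteichthyan",
                                            t3 = "chondrichthyan"))
  expect_identical(nt2$taxon, "t1")
  expect_equal(nt2$distance, 0.2, tolerance = 1e-12)
  expect_identical(nt2$group, "placoderm")
  ## deterministic first-taxon tie break, flagged
  mm_tie <- mm_from_states(rbind(t1 = c(0L, 1L), t2 = c(1L, 0L)))
  nt3 <- nearest_taxon(c(0L, 0L), mm_tie)
  expect_identical(nt3$taxon, "t1")
  expect_true(nt3$tie)
  mm_und <- mm_from_states(rbind(t1 = c(NA, NA)))
  expect_error(nearest_taxon(c(0L, 1L), mm_und), "undefined")
  expect_error(nearest_taxon(c(0L), mm), "length")
})

test_that("ancestor subsampling excludes non-modal homology states and
           reports both thinning arithmetics", {
  mk <- function(h) structure(list(states = 0L, informed = TRUE, h = h),
                              class = "ancestor_sample")
  hs <- rep(1L, 100)
  hs[c(10, 50)] <- 0L
  run <- list(ancestors = lapply(hs, mk),
              trace = data.frame(gen = seq_along(hs)),
              config = list(burnin_frac = 0))
  class(run) <- "dynhom_mcmc"
  sub <- subsample_ancestors(run, every = 20L, retain = 1:100)
  expect_identical(sub$modal_h, 1L)
  expect_identical(sub$n_excluded, 2L)
  expect_identical(sub$n, 5L)  # 98 modal samples, every 20th
  expect_true(all(hs[sub$indices] == 1L))
  expect_true(is.numeric(sub$n_thin_first))
})
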