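test_that("timetree validity and sampled-ancestor bookkeeping", {
  tt <- timetree(c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
                 c(0.5, 2, 0.3, 0.9, 4, 2, 1.5), paste0("f", 1:4))
  expect_identical(sampled_ancestors(tt), 2L)  # age equals its parent's
  expect_identical(tt$root, 5L)
  expect_error(timetree(c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
                        c(0.5, 2, 0.3, 5, 4, 2, 1.5), paste0("f", 1:4)),
               "older than its parent")
  expect_error(timetree(c(6L, 6L, 6L, 7L, 0L, 5L, 5L),
                        c(0.5, 2, 0.3, 0.9, 4, 2, 1.5), paste0("f", 1:4)),
               "two children")
  ## phylo round trip preserves ages and zero-length SA edge
  phy <- tt_to_phylo(tt)
  expect_true(any(phy$edge.length == 0))
  back <- as_timetree(phy, tip_ages = stats::setNames(tt$age[1:4], tt$taxa))
  expect_equal(sort(back$age), sort(tt$age), tolerance = 1e-12)
  expect_match(tt_newick(tt), "f2:0")
})

test_that("monophyly checks follow clade membership", {
  tt <- tt_from_topology("(((A,B),C),D);")
  expect_true(check_monophyly(tt, list("A")))
  expect_true(check_monophyly(tt, list(c("A", "B"))))
  expect_true(check_monophyly(tt, list(c("A", "B"), c("A", "B", "C"))))
  expect_false(check_monophyly(tt_from_topology("((A,B),C);"),
                               list(c("A", "C"))))
  expect_error(check_monophyly(tt, list(c("A", "Z"))), "unknown taxa")
})

test_that("FBD density reduces to the birth-death form without fossils", {
  tt3 <- timetree(c(5L, 5L, 4L, 0L, 4L), c(0, 0, 0, 3, 1.5), c("A", "B", "C"))
  lambda <- 0.9; mu <- 0.4; x0 <- 4.2
  p1 <- function(t) {
    r <- lambda - mu
    r^2 * exp(-r * t) / (lambda + (lambda * 0 - mu) * exp(-r * t))^2
  }
  bd <- log(p1(x0)) + log(lambda * p1(3)) + log(lambda * p1(1.5))
  expect_equal(fbd_log_density(tt3, lambda, mu, psi = 0, rho = 1,
                               origin = x0), bd, tolerance = 1e-9)
})

test_that("FBD density is finite on valid fossil trees and guards support", {
  tt <- timetree(c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
                 c(0.5, 2, 0.3, 0.9, 4, 2, 1.5), paste0("f", 1:4))
  d <- fbd_log_density(tt, 0.8, 0.3, 0.25, rho = 0, origin = 5)
  expect_true(is.finite(d))
  ## tip (or root) older than origin is out of support
  expect_identical(fbd_log_density(tt, 0.8, 0.3, 0.25, rho = 0,
                                   origin = 3), -Inf)
  ## fossils require psi > 0; extant samples require rho > 0
  expect_identical(fbd_log_density(tt, 0.8, 0.3, 0, rho = 0, origin = 5),
                   -Inf)
  expect_error(fbd_log_density(tt, -1, 0.3, 0.25, rho = 0, origin = 5),
               "invalid rates")
})

test_that("rescaling ages and rates shifts the density by the event count", {
  tt <- timetree(c(6L, 6L, 7L, 7L, 0L, 5L, 5L),
                 c(0.5, 2, 0.3, 0.9, 4, 2, 1.5), paste0("f", 1:4))
  f1 <- fbd_log_density(tt, 0.8, 0.3, 0.25, rho = 0, origin = 5)
  a <- 2.7
  tts <- tt
  tts$age <- tts$age * a
  f2 <- fbd_log_density(tts, 0.8 / a, 0.3 / a, 0.25 / a, rho = 0,
                        origin = 5 * a)
  ## 2 birth events + 4 psi-sampling events = 6 rate factors
  expect_equal(f1 - f2, 6 * log(a), tolerance = 1e-9)
})

test_that("the total prior sums independent components and encodes support", {
  fx <- make_fig2_fixture(2)
  sites <- site_table("s1", 2, 6, list(c("C1", "C2", "C3")))
  model <- prepare_inference(fx$fixed, list(fx$block), sites = sites,
                             partition_by_homoplasy = FALSE, rho = 1)
  spec <- prior_spec()
  st <- init_model_state(model, spec)
  lp <- prior_log_density(st, spec, sites = model$sites)
  expect_true(is.finite(lp))
  ## site age outside its bounds is rejected
  st_bad <- st
  st_bad$site_age[1] <- 7
  expect_identical(prior_log_density(st_bad, spec, sites = model$sites),
                   -Inf)
  ## a partition rate at the prior mode contributes dnorm(1, 1, 2)
  st2 <- st
  st2$rates[1] <- 1
  delta <- prior_log_density(st2, spec, sites = model$sites) -
    prior_log_density(st, spec, sites = model$sites)
  expect_equal(delta, dnorm(1, 1, 2, log = TRUE) -
                 dnorm(st$rates[1], 1, 2, log = TRUE), tolerance = 1e-12)
  ## component-wise oracle: total = tree + sites + each parameter prior
  tt <- st$tree
  nonroot <- setdiff(seq_along(tt$parent), tt$root)
  manual <- fbd_log_density(tt, st$lambda, st$mu, st$psi, rho = st$rho,
                            origin = st$origin) -
    sum(log(sites$max_ma - sites$min_ma)) +
    dlnorm(st$lambda, spec$birth_meanlog, spec$birth_sdlog, log = TRUE) +
    dexp(st$mu, 1 / spec$death_mean, log = TRUE) +
    dexp(st$psi, 1 / spec$sampling_mean, log = TRUE) +
    dlnorm(st$clock_mean, spec$clock_meanlog, spec$clock_sdlog, log = TRUE) +
    dexp(st$clock_sd, 1 / spec$clock_sd_mean, log = TRUE) +
    sum(dlnorm(st$branch_mult[nonroot], -st$clock_sd^2 / 2, st$clock_sd,
               log = TRUE)) +
    sum(dnorm(st$rates, 1, 2, log = TRUE)) -
    log(spec$origin_max) - log(2)
  expect_equal(lp, manual, tolerance = 1e-10)
  ## violated monophyly constraint rejects
  expect_identical(
    prior_log_density(st, spec, constraints = list(c("A1", "B1")),
                      sites = model$sites), -Inf)
})

test_that("the lognormal prior parameterization converts real-space means", {
  spec <- prior_spec(birth_real_mean = 0.14, birth_sdlog = 0.9)
  set.seed(8)
  draws <- stats::rlnorm(2e5, spec$birth_meanlog, spec$birth_sdlog)
  expect_equal(mean(draws), 0.14, tolerance = 0.02)
  spec_log <- prior_spec(birth_real_mean = -2, birth_mean_space = "log")
  expect_identical(spec_log$birth_meanlog, -2)
})
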