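## a small fossil model reused across engine tests
engine_model <- function(n_chars = c("2" = 30), seed = 77) {
  taxa <- paste0("f", 1:8)
  tip_ages <- stats::setNames(seq(5, 40, length.out = 8), taxa)
  sites <- site_table(c("s1", "s2", "s3"), c(4, 14, 28), c(9, 22, 41),
                      list(c("f1", "f2", "f3"), c("f4", "f5"),
                           c("f6", "f7", "f8")))
  tts <- dynhom:::build_start_tree(taxa, tip_ages, list(), eps = 8)
  sim <- simulate_matrix(sim_spec(tts, clock_rate = 0.01,
                                  n_chars = n_chars, seed = seed))
  prepare_inference(sim, list(), sites = sites,
                    constraints = list(c("f1", "f2", "f3")),
                    partition_by_homoplasy = FALSE)
}

test_that("homology flip proposes uniformly among the other states", {
  st <- list(h = 0L, N_h = 3L)
  set.seed(12)
  draws <- replicate(4000, dynhom:::redraw_homology(st)$h)
  expect_true(all(draws %in% 1:2))
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.03)
  st2 <- list(h = 0L, N_h = 2L)
  expect_identical(unique(replicate(50, dynhom:::redraw_homology(st2)$h)), 1L)
})

test_that("rate delta exchange conserves the weighted mean", {
  st <- list(rates = c(1.6, 0.8), weights = c(10, 30))
  op <- dynhom:::op_rate_exchange()
  expect_equal(sum(st$weights * st$rates) / sum(st$weights), 1)
  set.seed(3)
  for (i in 1:50) {
    r <- op$propose(st, NULL, op$env)
    if (is.null(r)) next
    expect_equal(sum(r$state$weights * r$state$rates) / sum(r$state$weights),
                 1, tolerance = 1e-12)
    expect_identical(r$log_hr, 0)
  }
  ## single partition: operator disabled
  expect_null(op$propose(list(rates = 1, weights = 40), NULL, op$env))
  ## a delta driving a rate negative rejects
  op$env$scale <- 1e6
  set.seed(4)
  expect_null(op$propose(st, NULL, op$env))
})

test_that("chain sample counting includes the initial state", {
  expect_identical(sample_counts(8e8, 4e5, 0.1)$n_samples, 2001)
  expect_identical(sample_counts(8e8, 4e5, 0.1)$n_retained, 1801)
  expect_identical(sample_counts(1000, 100, 0)$n_samples, 11)
  expect_identical(sample_counts(1000, 100, 0)$n_retained, 11)
  expect_identical(sample_counts(1000, 100, 0.1)$n_retained, 10)
  expect_error(mcmc_config(generations = 1000, sample_every = 300),
               "divisible|TRUE")
})

test_that("runs are deterministic given a seed and leave the RNG restored", {
  model <- engine_model()
  cfg <- mcmc_config(generations = 1500, sample_every = 300, seed = 21)
  set.seed(1); before <- runif(1)
  set.seed(1)
  r1 <- run_mcmc(model, cfg, prior_spec())
  after <- runif(1)
  expect_identical(before, after)  # sampler does not disturb the session RNG
  r2 <- run_mcmc(model, cfg, prior_spec())
  expect_identical(r1$trace, r2$trace)
  expect_identical(vapply(r1$trees, tt_newick, character(1)),
                   vapply(r2$trees, tt_newick, character(1)))
  r3 <- run_mcmc(model, mcmc_config(generations = 1500, sample_every = 300,
                                    seed = 22), prior_spec())
  expect_false(identical(r1$trace$posterior, r3$trace$posterior))
})

test_that("accepted states always satisfy tree invariants and constraints", {
  model <- engine_model()
  run <- run_mcmc(model, mcmc_config(generations = 6000, sample_every = 30,
                                     seed = 5), prior_spec())
  keep <- retained_samples(run)
  for (tt in run$trees[keep]) {
    expect_silent(dynhom:::validate_timetree(tt))
    expect_true(check_monophyly(tt, model$constraints))
  }
  ## site ages stay inside their bounds and tips track their site age
  for (i in keep) {
    tt <- run$trees[[i]]
    a1 <- run$trace$site_age_1[i]
    expect_true(a1 >= 4 && a1 <= 9)
    expect_equal(unname(tt$age[1:3]), rep(a1, 3), tolerance = 1e-9)
  }
})

test_that("cached posterior components equal fresh recomputation", {
  model <- engine_model()
  cfg <- mcmc_config(generations = 3000, sample_every = 1000, seed = 8)
  run <- run_mcmc(model, cfg, prior_spec())
  st <- run$final_state
  last <- run$trace[nrow(run$trace), ]
  expect_equal(prior_log_density(st, prior_spec(), model$constraints,
                                 model$sites), last$prior,
               tolerance = 1e-9)
  expect_equal(dynhom:::state_loglik(st, model), last$likelihood,
               tolerance = 1e-9)
})

test_that("the sampler visits sampled-ancestor configurations", {
  model <- engine_model()
  run <- run_mcmc(model, mcmc_config(generations = 8000, sample_every = 20,
                                     seed = 13), prior_spec())
  keep <- retained_samples(run)
  nsa <- vapply(run$trees[keep], function(t) length(sampled_ancestors(t)),
                integer(1))
  expect_true(any(nsa > 0))
  expect_true(any(nsa == 0))
})

test_that("prior-only tree sampling is exchangeable over contemporaneous tips", {
  ## four exchangeable extant tips: by symmetry every tip pair is a
  ## cherry equally often; a detailed-balance defect would break this
  taxa <- paste0("x", 1:4)
  tip_ages <- stats::setNames(rep(0, 4), taxa)
  tts <- dynhom:::build_start_tree(taxa, tip_ages, list(), eps = 5)
  sim <- simulate_matrix(sim_spec(tts, clock_rate = 0, n_chars = c("2" = 4),
                                  seed = 2))
  model <- prepare_inference(sim, list(), partition_by_homoplasy = FALSE,
                             rho = 1)
  run <- run_mcmc(model, mcmc_config(generations = 40000, sample_every = 10,
                                     seed = 30, likelihood_off = TRUE),
                  prior_spec())
  keep <- retained_samples(run)
  pairs <- combn(taxa, 2)
  freq <- apply(pairs, 2, function(pr) {
    mean(vapply(run$trees[keep], function(tt) {
      m <- mrca_node(tt, pr)
      identical(clade_tips(tt, m), sort(match(pr, tt$taxa)))
    }, logical(1)))
  })
  ## all six pair-clade frequencies agree within Monte-Carlo error
  expect_lt(max(freq) - min(freq), 0.08)
  expect_gt(min(freq), 0.15)
})

test_that("joint homology+tree operators keep h uniform under the prior and
           change both components in one accepted move", {
  fx <- make_fig2_fixture(2)
  model <- prepare_inference(fx$fixed, list(fx$block),
                             partition_by_homoplasy = FALSE, rho = 1)
  run <- run_mcmc(model, mcmc_config(generations = 30000, sample_every = 10,
                                     seed = 44, likelihood_off = TRUE),
                  prior_spec(),
                  operators = list(dynhom:::op_homology_wilson_balding(),
                                   dynhom:::op_homology_exchange(),
                                   dynhom:::op_node_age(),
                                   dynhom:::op_root_age()))
  keep <- retained_samples(run)
  ph <- mean(run$trace$h_1[keep] == 1)
  expect_lt(abs(ph - 0.5), 0.05)
  ## consecutive trace points reflect joint changes of topology and h
  hflips <- which(diff(run$trace$h_1) != 0)
  expect_gt(length(hflips), 10)
})

test_that("ESS diagnostics follow known sampling regimes", {
  set.seed(5)
  x <- stats::rnorm(1000)
  expect_gt(ess(x), 850)
  expect_lte(ess(x), 1000)
  rho <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = rho), 20000))
  expect_equal(ess(ar), 20000 * (1 - rho) / (1 + rho), tolerance = 0.2)
  expect_identical(suppressWarnings(ess(rep(1, 100))), NA_real_)
  expect_warning(ess(rep(1, 100)), "constant")
  expect_lte(ess(rep(c(0, 1), 500)), 1000)  # clamped, not > n
  expect_error(ess(1:5), "at least 10")
})

test_that("majority-rule consensus keeps strict-majority clades with mean ages", {
  t1 <- tt_from_text("((A:1,B:1):1,(C:1,D:1):1):0;")
  t2 <- tt_from_text("((A:2,B:2):1,(C:2,D:2):1):0;")
  t3 <- tt_from_text("(((A:1,C:1):1,B:2):1,D:3):0;")
  ## identical inputs: the topology itself, all frequencies 1
  consA <- majority_rule_consensus(list(t1, t1, t1))
  cl <- attr(consA, "clades")
  expect_true(all(cl$frequency == 1))
  expect_setequal(cl$clade, c("A,B,C,D", "A,B", "C,D"))
  ## clade in 2 of 3 trees retained at 0.667 with mean MRCA age
  consB <- majority_rule_consensus(list(t1, t2, t3))
  clB <- attr(consB, "clades")
  ab <- clB[clB$clade == "A,B", ]
  expect_equal(ab$frequency, 2 / 3, tolerance = 1e-9)
  expect_equal(ab$mean_age, 1.5, tolerance = 1e-9)  # ages 1 and 2
  ## a clade in exactly half is excluded under the strict rule
  consC <- majority_rule_consensus(list(t1, t3))
  expect_identical(attr(consC, "clades")$clade, "A,B,C,D")
  expect_error(majority_rule_consensus(list(t1, tt_from_text(
    "((A:1,B:1):1,(C:1,E:1):1):0;"))), "different tip sets")
})
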