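test_that("identical configuration and seed reproduce outputs exactly", {
  cfg <- tiny_config()
  a <- run_scenario(cfg, seed = 42)
  b <- run_scenario(cfg, seed = 42)
  expect_identical(a$summary, b$summary)
  expect_identical(a$snapshot, b$snapshot)
  expect_identical(a$patches, b$patches)
  # replicates use distinct substreams
  s1 <- subset(a$summary, replicate == 1)
  s2 <- subset(a$summary, replicate == 2)
  expect_false(identical(s1$n_adults, s2$n_adults))
  # a different seed changes the realization
  expect_false(identical(run_scenario(cfg, seed = 43)$summary, a$summary))
})

test_that("a closed system conserves the adult roster", {
  # immortal adults, no surviving juveniles, no emigration: constant count
  cfg <- scenario_config("uninformed", "inaccurate", E = 0,
                         evolve_emigration = FALSE, evolve_np = FALSE,
                         S_J = 0, S_I = 0, S_A = 1, years = 40, replicates = 1,
                         init_adults = 10, summary_every = 1)
  sim <- run_scenario(cfg, seed = 1)
  expect_true(all(sim$summary$n_adults == 250))
  expect_true(all(sim$summary$deaths_adult == 0))
  expect_true(all(sim$summary$deaths_prospecting == 0))
})

test_that("the environment advances even with an empty roster", {
  cfg <- tiny_config(init_adults = 0, years = 20, summary_every = 5)
  sim <- run_scenario(cfg, seed = 9)
  expect_true(all(sim$summary$n_adults == 0))
  expect_equal(nrow(sim$patches), 2 * 4 * 25)
  expect_gt(var(sim$patches$Q), 0)
})

test_that("yearly bookkeeping balances births, deaths, recruits and survivors", {
  cfg <- scenario_config("personal", "accurate", M = 0.01,
                         evolve_emigration = TRUE, years = 150, replicates = 2,
                         summary_every = 1)
  sim <- run_scenario(cfg, seed = 11, record_patches = FALSE)
  for (r in 1:2) {
    s <- subset(sim$summary, replicate == r)
    n <- nrow(s)
    expect_equal(s$n_adults[-1],
                 s$n_adults[-n] + s$recruits[-1] - s$deaths_adult[-1] -
                   s$deaths_prospecting[-1])
    expect_equal(s$n_prebreeders[-1],
                 s$n_prebreeders[-n] - s$recruits[-1] - s$deaths_prebreeder[-1] +
                   s$births[-1] - s$deaths_juvenile[-1])
  }
  # snapshot tallies agree with the final summary row
  fin <- subset(sim$summary, year == 150)
  snap_adults <- with(subset(sim$snapshot, stage == "adult"), table(replicate))
  expect_equal(as.integer(snap_adults), fin$n_adults)
})

test_that("scenario grids enumerate the full strategy-process-cost cross", {
  g1 <- experiment1_grid(years = 10, replicates = 1)
  expect_length(g1, 18)
  expect_true(all(vapply(g1, function(cfg) identical(cfg$evolving, "Np"), TRUE)))
  g2 <- experiment2_grid(years = 10, replicates = 1)
  expect_length(g2, 18)
  combos <- unique(t(vapply(g2, function(cfg)
    c(cfg$strategy, cfg$process, cfg$M), character(3))))
  expect_equal(nrow(combos), 18)
  # evolving sets follow the strategy
  pp <- Filter(function(cfg) cfg$strategy == "personal_public", g2)[[1]]
  expect_setequal(pp$evolving, c("beta_succ", "alpha_succ", "beta_fail",
                                 "alpha_fail", "Np"))
})

test_that("invalid scenario parameters are rejected", {
  expect_error(scenario_config(S_A = 1.2), "probabilities")
  expect_error(scenario_config(M = 0.1), "M must")
  expect_error(scenario_config(autocorr = 1.5), "autocorr")
  expect_error(scenario_config(years = 0), "years")
})

test_that("fixed-emigration scenarios keep emigration loci constant", {
  cfg <- scenario_config("personal", "deterministic", evolve_emigration = FALSE,
                         years = 60, replicates = 1, summary_every = 30,
                         init_adults = 30)
  sim <- run_scenario(cfg, seed = 3, record_patches = FALSE)
  expect_true(all(sim$snapshot$E_succ == 0.05))
  expect_true(all(sim$snapshot$E_fail == 0.5))
  expect_gt(var(sim$snapshot$Np), 0)   # the prospecting locus does evolve
})

test_that("prospecting only pays in a predictable environment", {
  # with near-zero temporal autocorrelation this year's breeding success
  # carries no information about next year, and random dispersal dominates
  run_np <- function(ac) {
    cfg <- scenario_config("uninformed", "deterministic", M = 0.01,
                           evolve_emigration = FALSE, autocorr = ac,
                           years = 5000, replicates = 2, summary_every = 5000)
    sim <- run_scenario(cfg, seed = 31, record_patches = FALSE)
    attr(np_spectrum(sim), "mode")
  }
  expect_lte(run_np(0.05), 1)   # random dispersal (no prospecting)
  expect_gte(run_np(0.8), 2)    # costly prospecting still favoured
})
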