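test_that("emigration probabilities implement the three information regimes", {
  g <- list(E = 0.5, E_succ = 0.05, E_fail = 0.5,
            beta_succ = 0.05, alpha_succ = 0, beta_fail = 0.5, alpha_fail = -0.45)
  expect_equal(emigration_probability(g, "uninformed", "successful"), 0.5)
  expect_equal(emigration_probability(g, "personal", "successful"), 0.05)
  expect_equal(emigration_probability(g, "personal", "failed"), 0.5)
  expect_equal(emigration_probability(g, "personal", "recruit"), 0.5)
  # reaction norm of failed breeders at the fixed study values
  expect_equal(emigration_probability(g, "personal_public", "failed", lbs = 1), 0.05)
  expect_equal(emigration_probability(g, "personal_public", "failed", lbs = 0), 0.5)
  # raw values outside [0, 1] clamp at use
  g2 <- list(beta_fail = 0.2, alpha_fail = -0.45)
  expect_equal(emigration_probability(g2, "personal_public", "failed", lbs = 1), 0)
  expect_error(emigration_probability(g, "personal_public", "failed"), "lbs")
})

test_that("candidate patches exclude the current patch and the non-candidates", {
  occ <- rep(FALSE, 25); occ[c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19)] <- TRUE
  cand <- candidate_patches(5, occ)
  expect_length(cand, 9)
  expect_false(5 %in% cand)
  expect_true(all(occ[cand]))
  expect_length(candidate_patches(3, c(3)), 0)  # nowhere to go
})

test_that("prospected sets are uniform subsets of the right size", {
  expect_identical(draw_prospected_set(1:9, 0), integer(0))
  expect_setequal(draw_prospected_set(1:9, 24), 1:9)  # truncation to candidates
  set.seed(401)
  hits <- numeric(9)
  for (i in 1:4000) {
    s <- draw_prospected_set(1:9, 3)
    expect_length(s, 3)
    hits[s] <- hits[s] + 1
  }
  expect_true(all(abs(hits / 4000 - 1 / 3) < 0.03))
})

test_that("settlement probabilities match the three selection processes", {
  expect_equal(settlement_probabilities(c(0.2, 0.3, 0.5), "inaccurate"),
               c(0.2, 0.3, 0.5))
  expect_equal(settlement_probabilities(c(0, 0, 0), "inaccurate"), rep(1 / 3, 3))
  expect_equal(settlement_probabilities(c(0.1, 0.9, 0.4), "deterministic"),
               c(0, 1, 0))
  expect_equal(settlement_probabilities(c(0.5, 0.2, 0.5), "deterministic"),
               c(0.5, 0, 0.5))                      # uniform over ties
  # softmax with coefficient 50 on (0, 0.1)
  expect_equal(settlement_probabilities(c(0, 0.1), "accurate"),
               c(1, exp(5)) / (1 + exp(5)), tolerance = 1e-12)
  expect_error(settlement_probabilities(numeric(0)), "at least one")
})

test_that("settlement vectors are proper distributions with the right ordering", {
  set.seed(402)
  for (i in 1:50) {
    lbs <- runif(sample(1:8, 1))
    for (p in c("inaccurate", "accurate", "deterministic")) {
      pr <- settlement_probabilities(lbs, p)
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      expect_true(all(pr >= 0))
    }
    # accurate process: strictly increasing probability in LBS
    o <- order(lbs)
    expect_true(all(diff(settlement_probabilities(lbs, "accurate")[o]) >= 0))
  }
  # accuracy 0 degenerates to uniform
  expect_equal(settlement_probabilities(c(0.1, 0.7, 0.4), "accurate", accuracy = 0),
               rep(1 / 3, 3))
})

test_that("the engine's settlement sampler agrees with the settlement rule", {
  lbs_all <- c(0.1, 0.6, 0.3, 0.9, 0)
  pros <- c(0L, 1L, 3L)                 # engine-side patches are 0-based
  for (pcode in 0:1) {
    set.seed(410 + pcode)
    draws <- replicate(2e4, prospectsim:::.settlement_choose_cpp(
      pros, lbs_all, pcode, 50))
    emp <- tabulate(match(draws, pros), nbins = 3) / 2e4
    ref <- settlement_probabilities(lbs_all[pros + 1],
                                    c("inaccurate", "accurate")[pcode + 1])
    expect_true(all(abs(emp - ref) < 0.015))
  }
  det <- replicate(200, prospectsim:::.settlement_choose_cpp(pros, lbs_all, 2, 50))
  expect_true(all(det == 3L))           # deterministic: always the 0.9 patch
})

test_that("prospecting mortality is proportional to patches visited", {
  expect_true(all(prospecting_survival(rep(5, 100), M = 0)))
  expect_true(all(prospecting_survival(rep(0, 100), M = 0.04)))
  set.seed(403)
  dead <- 1 - mean(prospecting_survival(rep(24, 1e5), M = 0.01))
  expect_lt(abs(dead - 0.24), 0.005)
  expect_error(prospecting_survival(30, M = 0.05), "<= 1")
})

test_that("settlement picks among prospected patches, or at random without them", {
  # a single prospected patch is chosen regardless of its breeding success
  expect_equal(settle(1:9, prospected = 4, lbs = 0), 4)
  expect_equal(settle(1:9, prospected = c(2, 7), lbs = c(0.2, 0.8),
                      process = "deterministic"), 7)
  set.seed(404)
  picks <- replicate(9000, settle(1:9))
  expect_true(all(abs(tabulate(picks, 9) / 9000 - 1 / 9) < 0.03))
})

test_that("better-informed prospecting cannot lower the expected chosen quality", {
  # exact enumeration: expected maximum LBS of a uniform random k-subset
  lbs <- c(0.05, 0.2, 0.35, 0.5, 0.65, 0.9)
  exp_best <- sapply(1:6, function(k) {
    subs <- combn(6, k)
    mean(apply(subs, 2, function(s) max(lbs[s])))
  })
  expect_true(all(diff(exp_best) > 0))
  # simulated deterministic settlement matches the enumeration at k = 3
  set.seed(405)
  got <- replicate(4000, {
    s <- draw_prospected_set(1:6, 3)
    lbs[settle(1:6, s, lbs[s], process = "deterministic")]
  })
  expect_lt(abs(mean(got) - exp_best[3]), 0.01)
})
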