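test_that("prospecting spectra and modes are computed over the allele range", {
  r <- np_frequency_and_mode(rep(3L, 10))
  expect_equal(unname(r$freq[["3"]]), 1)
  expect_equal(r$mode, 3L)
  r2 <- np_frequency_and_mode(c(2L, 2L, 3L))
  expect_equal(unname(r2$freq[["2"]]), 2 / 3)
  expect_equal(unname(r2$freq[["3"]]), 1 / 3)
  expect_equal(r2$mode, 2L)
  expect_equal(sum(r2$freq), 1)
  # ties resolve to the smallest allele value
  expect_equal(np_frequency_and_mode(c(1L, 1L, 4L, 4L))$mode, 1L)
  expect_error(np_frequency_and_mode(integer(0)), "at least one")
})

test_that("evolved trait means average per replicate before pooling", {
  snap <- data.frame(replicate = rep(1:2, each = 4), stage = "adult",
                     E = c(rep(0.4, 4), rep(0.6, 4)))
  out <- evolved_trait_mean(snap, "E")
  expect_equal(out$mean, 0.5)
  expect_equal(out$se, sd(c(0.4, 0.6)) / sqrt(2))
  expect_equal(out$n_replicates, 2)
  # single replicate: mean defined, spread is not
  one <- evolved_trait_mean(snap[snap$replicate == 1, ], "E")
  expect_equal(one$mean, 0.4)
  expect_true(is.na(one$se))
  # pre-breeders never enter the adult summaries
  snap2 <- rbind(snap, data.frame(replicate = 1, stage = "pre_breeder", E = 99))
  expect_equal(evolved_trait_mean(snap2, "E")$mean, 0.5)
})

test_that("reaction norms are clamped lines through the mean alleles", {
  snap <- data.frame(replicate = 1, stage = "adult",
                     beta_fail = 0.5, alpha_fail = -0.45,
                     beta_succ = 0.05, alpha_succ = 0)[rep(1, 20), ]
  rn <- reaction_norm_summary(snap, lbs = c(0, 1))
  fl <- subset(rn$curves, status == "failed")
  expect_equal(fl$emigration, c(0.5, 0.05))
  expect_equal(rn$means$slope[rn$means$status == "failed"], -0.45)
  # segments leaving [0, 1] are clamped and flagged
  snap$beta_fail <- 0.2
  rn2 <- reaction_norm_summary(snap, lbs = c(0, 1))
  fl2 <- subset(rn2$curves, status == "failed")
  expect_equal(fl2$emigration, c(0.2, 0))
  expect_equal(fl2$clamped, c(FALSE, TRUE))
})

test_that("density-by-quality bins patch-years and drops empty bins", {
  pat <- data.frame(Q = c(-1, -1, 1, 1), N = c(10, 12, 180, 200))
  d <- density_by_quality(pat, bin_width = 0.5)
  expect_equal(nrow(d), 2)
  expect_equal(d$mean_N, c(11, 190))
  expect_equal(d$n, c(2L, 2L))
  expect_equal(d$se, c(sd(c(10, 12)) / sqrt(2), sd(c(180, 200)) / sqrt(2)))
})

test_that("summaries recomputed from the snapshot equal the engine's logs", {
  cfg <- tiny_config(years = 80, summary_every = 20, init_adults = 50)
  sim <- run_scenario(cfg, seed = 21)
  fin <- subset(sim$summary, year == 80)
  for (r in unique(fin$replicate)) {
    ad <- subset(sim$snapshot, replicate == r & stage == "adult")
    expect_equal(mean(ad$E), fin$mean_E[fin$replicate == r])
    expect_equal(mean(ad$Np), fin$mean_Np[fin$replicate == r])
  }
  # spectrum from the snapshot is a proper mean of per-replicate frequencies
  sp <- np_spectrum(sim)
  expect_equal(sum(sp$mean_freq), 1)
  expect_s3_class(sp, "data.frame")
})

test_that("summary tables round-trip through CSV unchanged", {
  cfg <- tiny_config(years = 40, summary_every = 20, init_adults = 30)
  sim <- run_scenario(cfg, seed = 22)
  dir <- tempfile("sumtab")
  paths <- write_summaries(sim, dir)
  expect_true(all(file.exists(c(file.path(dir, "np_spectrum.csv"),
                                file.path(dir, "trait_means.csv"),
                                file.path(dir, "density_by_quality.csv")))))
  back <- read.csv(file.path(dir, "np_spectrum.csv"))
  expect_equal(back$mean_freq, np_spectrum(sim)$mean_freq)
})
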