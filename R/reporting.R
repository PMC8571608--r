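#' Prospecting-allele frequency spectrum and mode
#'
#' Frequency of each value of the number-of-prospected-patches allele among
#' adults, and the modal value (smallest value on ties).
#'
#' @param np integer vector of adult `Np` alleles (length >= 1).
#' @param n_patches patch count; alleles range over `0..n_patches - 1`.
#' @return List with `freq` (named numeric vector over 0..n_patches-1,
#'   summing to 1) and `mode` (integer).
#' @export
np_frequency_and_mode <- function(np, n_patches = 25) {
  if (length(np) == 0) stop("at least one adult is required")
  if (any(np < 0 | np > n_patches - 1)) stop("Np out of range")
  freq <- tabulate(np + 1L, nbins = n_patches) / length(np)
  names(freq) <- 0:(n_patches - 1)
  list(freq = freq, mode = as.integer(which.max(freq) - 1L))
}

#' Mean prospecting spectrum across replicates
#'
#' Per-replicate adult `Np` frequencies, then cross-replicate mean and
#' standard error per allele value (frequencies are averaged per replicate,
#' not pooled).
#'
#' @param sim a [run_scenario()] result.
#' @return data.frame with `Np`, `mean_freq`, `se` (n-1 denominator), and
#'   the overall `mode` attribute of the mean spectrum.
#' @export
np_spectrum <- function(sim) {
  snap <- sim$snapshot[sim$snapshot$stage == "adult", ]
  npp <- sim$config$n_patches
  mats <- tapply(snap$Np, snap$replicate, function(v)
    tabulate(v + 1L, nbins = npp) / length(v))
  m <- do.call(rbind, mats)
  out <- data.frame(Np = 0:(npp - 1), mean_freq = colMeans(m),
                    se = apply(m, 2, .se))
  attr(out, "mode") <- as.integer(which.max(out$mean_freq) - 1L)
  out
}

.se <- function(x) {
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Evolved allele mean across replicates
#'
#' The final-year adult mean of a locus, computed per replicate and then
#' averaged across replicates with a standard error (n-1 denominator; NA
#' with a single replicate).
#'
#' @param snapshot the `snapshot` data.frame of a [run_scenario()] result
#'   (or the result itself).
#' @param locus locus name, e.g. `"E"` or `"E_fail"`.
#' @return data.frame with `locus`, `mean`, `se`, `n_replicates`.
#' @export
evolved_trait_mean <- function(snapshot, locus) {
  if (inherits(snapshot, "prospectsim")) snapshot <- snapshot$snapshot
  if (!locus %in% names(snapshot)) stop("unknown locus: ", locus)
  ad <- snapshot[snapshot$stage == "adult", ]
  per_rep <- tapply(ad[[locus]], ad$replicate, mean)
  data.frame(locus = locus, mean = mean(per_rep), se = .se(per_rep),
             n_replicates = length(per_rep))
}

#' Evolved emigration reaction norms
#'
#' Population means of the status-specific reaction-norm intercepts and
#' slopes, the mean emigration-probability curves over local breeding
#' success (clamped to \[0, 1\], with clamped segments flagged), and a
#' random sample of individual norms.
#'
#' @param sim a [run_scenario()] result from a `personal_public` scenario.
#' @param lbs grid of local-breeding-success values for the curves.
#' @param n_individuals number of individual norms to sample.
#' @return List with `means` (status, intercept, slope), `curves` (status,
#'   lbs, emigration, clamped), and `individuals` (replicate, individual,
#'   status-specific intercepts/slopes).
#' @export
reaction_norm_summary <- function(sim, lbs = seq(0, 1, by = 0.05),
                                  n_individuals = 20) {
  snap <- if (inherits(sim, "prospectsim")) sim$snapshot else sim
  ad <- snap[snap$stage == "adult", ]
  if (nrow(ad) == 0) stop("no adults in snapshot")
  per_rep <- function(col) mean(tapply(ad[[col]], ad$replicate, mean))
  means <- data.frame(
    status = c("failed", "successful"),
    intercept = c(per_rep("beta_fail"), per_rep("beta_succ")),
    slope = c(per_rep("alpha_fail"), per_rep("alpha_succ"))
  )
  curve_one <- function(b, a, status) {
    raw <- b + a * lbs
    data.frame(status = status, lbs = lbs, emigration = pmin(1, pmax(0, raw)),
               clamped = raw < 0 | raw > 1)
  }
  curves <- rbind(curve_one(means$intercept[1], means$slope[1], "failed"),
                  curve_one(means$intercept[2], means$slope[2], "successful"))
  pick <- sample.int(nrow(ad), min(n_individuals, nrow(ad)))
  individuals <- ad[pick, c("replicate", "beta_fail", "alpha_fail",
                            "beta_succ", "alpha_succ")]
  rownames(individuals) <- NULL
  list(means = means, curves = curves, individuals = individuals)
}

#' Adult density by environmental quality
#'
#' Bins patch-years by environmental quality and reports the mean (and
#' standard error, n-1 denominator) of the adult count per bin. Empty bins
#' are absent from the output rather than reported as zero.
#'
#' @param patches the `patches` data.frame of a [run_scenario()] result (or
#'   the result itself).
#' @param bin_width width of the quality bins.
#' @return data.frame with `Q_mid` (bin midpoint), `mean_N`, `se`, `n`.
#' @export
density_by_quality <- function(patches, bin_width = 0.5) {
  if (inherits(patches, "prospectsim")) patches <- patches$patches
  if (is.null(patches) || nrow(patches) == 0) stop("no patch records")
  mid <- (floor(patches$Q / bin_width) + 0.5) * bin_width
  agg <- split(patches$N, mid)
  out <- data.frame(
    Q_mid = as.numeric(names(agg)),
    mean_N = vapply(agg, mean, 0),
    se = vapply(agg, .se, 0),
    n = lengths(agg)
  )
  out <- out[order(out$Q_mid), ]
  rownames(out) <- NULL
  out
}

#' Write the standard summary tables
#'
#' Writes `np_spectrum.csv`, `trait_means.csv`, `reaction_norms.csv` (only
#' for personal+public scenarios) and `density_by_quality.csv` to a
#' directory. Standard errors use the n-1 denominator across replicates.
#'
#' @param sim a [run_scenario()] result.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_summaries <- function(sim, dir) {
  stopifnot(inherits(sim, "prospectsim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  w <- function(d, f) {
    p <- file.path(dir, f)
    utils::write.csv(d, p, row.names = FALSE)
    p
  }
  paths <- c(paths, w(np_spectrum(sim), "np_spectrum.csv"))
  tm <- do.call(rbind, lapply(c(.strategy_loci[[sim$config$strategy]], "Np"),
                              function(l) evolved_trait_mean(sim$snapshot, l)))
  paths <- c(paths, w(tm, "trait_means.csv"))
  if (sim$config$strategy == "personal_public") {
    rn <- reaction_norm_summary(sim)
    paths <- c(paths, w(rn$curves, "reaction_norms.csv"))
  }
  if (!is.null(sim$patches))
    paths <- c(paths, w(density_by_quality(sim$patches), "density_by_quality.csv"))
  invisible(paths)
}
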