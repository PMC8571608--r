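#' @keywords internal
.loci <- c("E", "E_succ", "E_fail", "beta_succ", "alpha_succ",
           "beta_fail", "alpha_fail", "Np")

#' Trait specifications for the dispersal loci
#'
#' Individuals are haploid and carry one locus per dispersal trait: the
#' uninformed emigration probability `E`; the status-conditional emigration
#' probabilities `E_succ` and `E_fail`; the reaction-norm intercepts and
#' slopes `beta_succ`, `alpha_succ`, `beta_fail`, `alpha_fail` (emigration
#' probability as a linear function of local breeding success); and the
#' number of prospected patches `Np` (discrete, 0 to `n_patches - 1`).
#' Loci not declared evolving are held at the scenario's constant.
#'
#' @param evolving character vector of evolving locus names (subset of
#'   `E, E_succ, E_fail, beta_succ, alpha_succ, beta_fail, alpha_fail, Np`).
#' @param fixed named list of constants for non-evolving loci; defaults are
#'   the fixed-emigration scenario constants.
#' @param mu per-locus mutation probability at offspring creation, in \[0,1\].
#' @param mut_sd standard deviation of the continuous mutation increment.
#' @param n_patches number of patches; bounds `Np` to `0..n_patches - 1`.
#' @return A data.frame with one row per locus: `locus`, `evolving`,
#'   `kernel` ("normal" or "pm1"), `init_lo`, `init_hi`, `fixed`.
#' @examples
#' trait_specs(evolving = c("E", "Np"))
#' @export
trait_specs <- function(evolving = "Np",
                        fixed = list(E = 0.5, E_succ = 0.05, E_fail = 0.5,
                                     beta_succ = 0.05, alpha_succ = 0,
                                     beta_fail = 0.5, alpha_fail = -0.45,
                                     Np = 0),
                        mu = 0.01, mut_sd = 0.1, n_patches = 25) {
  bad <- setdiff(evolving, .loci)
  if (length(bad)) stop("unknown loci: ", paste(bad, collapse = ", "))
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  defaults <- list(E = 0.5, E_succ = 0.05, E_fail = 0.5, beta_succ = 0.05,
                   alpha_succ = 0, beta_fail = 0.5, alpha_fail = -0.45, Np = 0)
  defaults[names(fixed)] <- fixed
  slopes <- c("alpha_succ", "alpha_fail")
  data.frame(
    locus = .loci,
    evolving = .loci %in% evolving,
    kernel = ifelse(.loci == "Np", "pm1", "normal"),
    init_lo = ifelse(.loci %in% slopes, -1, 0),
    init_hi = ifelse(.loci == "Np", n_patches - 1, ifelse(.loci %in% slopes, 0, 1)),
    fixed = unlist(defaults[.loci]),
    mu = mu, mut_sd = mut_sd,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Initialize genotypes
#'
#' Evolving continuous loci draw uniformly from their initialization
#' interval (\[0, 1\], except the reaction-norm slopes which start in
#' \[-1, 0\], assuming emigration declines with local breeding success).
#' An evolving `Np` draws uniformly on the integers `0..n_patches - 1`.
#' Fixed loci take their scenario constant.
#'
#' @param n number of genotypes to create.
#' @param specs a [trait_specs()] table.
#' @return A data.frame with `n` rows and one column per locus.
#' @export
init_genotypes <- function(n, specs = trait_specs()) {
  out <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    if (!s$evolving) return(rep(s$fixed, n))
    if (s$kernel == "pm1") {
      sample.int(s$init_hi - s$init_lo + 1L, n, replace = TRUE) - 1L + s$init_lo
    } else {
      stats::runif(n, s$init_lo, s$init_hi)
    }
  })
  names(out) <- specs$locus
  out$Np <- as.integer(out$Np)
  as.data.frame(out)
}

#' Maternal inheritance with mutation
#'
#' Each offspring copies its mother's haploid genotype; every evolving locus
#' then mutates independently with probability `mu`. Continuous loci gain a
#' `N(0, mut_sd)` increment; the discrete `Np` locus moves by +1 or -1 with
#' equal probability, clamped to `0..n_patches - 1`. Non-evolving loci are
#' exact copies. Mutated continuous alleles are truncated to their
#' initialization interval (\[0, 1\], or \[-1, 0\] for the reaction-norm
#' slopes): allele distributions then stay stationary under directional
#' selection toward a bound, instead of drifting without limit past it.
#'
#' @param mothers data.frame of maternal genotypes (one row per offspring;
#'   repeat rows for multiple offspring of one mother).
#' @param specs a [trait_specs()] table.
#' @return A data.frame of offspring genotypes, same shape as `mothers`.
#' @export
inherit_and_mutate <- function(mothers, specs = trait_specs()) {
  n <- nrow(mothers)
  kids <- mothers
  np_hi <- specs$init_hi[specs$locus == "Np"]
  for (i in which(specs$evolving)) {
    s <- specs[i, ]
    hit <- stats::runif(n) < s$mu
    if (!any(hit)) next
    if (s$kernel == "pm1") {
      step <- ifelse(stats::runif(sum(hit)) < 0.5, -1L, 1L)
      kids$Np[hit] <- pmin(pmax(kids$Np[hit] + step, 0L), as.integer(np_hi))
    } else {
      kids[[s$locus]][hit] <- pmin(pmax(
        kids[[s$locus]][hit] + stats::rnorm(sum(hit), 0, s$mut_sd),
        s$init_lo), s$init_hi)
    }
  }
  kids
}
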