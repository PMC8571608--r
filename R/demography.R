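#' Density-dependent mean fecundity
#'
#' Expected offspring per female in a patch with `N` adults and carrying
#' capacity `K`: `Off_max / (1 + (Off_max - 1) * N / K)`. At zero density it
#' equals `Off_max`; at `N = K` it equals 1 (replacement); it declines
#' strictly with `N` for `Off_max > 1`. A patch with `K <= 0` yields 0.
#'
#' @param N adult count(s) at the start of breeding, >= 0.
#' @param K carrying capacity (real-valued; may be 0).
#' @param Off_max maximum mean offspring per female, >= 1.
#' @return Numeric vector of expected offspring per female.
#' @examples
#' mean_fecundity(c(0, 100, 200), K = 100, Off_max = 2)  # 2 1 2/3
#' @export
mean_fecundity <- function(N, K, Off_max = 2) {
  if (any(N < 0)) stop("N must be >= 0")
  if (Off_max < 1) stop("Off_max must be >= 1")
  out <- ifelse(K > 0, Off_max / (1 + (Off_max - 1) * N / K), 0)
  as.numeric(out)
}

#' Reproduce the adults of one patch
#'
#' Each adult draws an offspring count from a Poisson distribution with the
#' patch's [mean_fecundity()]. Adults producing at least one offspring are
#' successful breeders, the rest failed; the status is assigned from the raw
#' draw, before any juvenile survival. Offspring are juveniles placed in the
#' natal patch, with genotypes from [inherit_and_mutate()] and a recruitment
#' age from [draw_recruitment_age()].
#'
#' @param mothers data.frame of adult genotypes in the patch (one row each).
#' @param K patch carrying capacity.
#' @param Off_max maximum mean offspring per female.
#' @param specs a [trait_specs()] table.
#' @param R mean recruitment age.
#' @return A list with `status` (character, "successful"/"failed", one per
#'   mother) and `offspring` (data.frame of genotypes plus `recruitment_age`).
#' @export
reproduce_patch <- function(mothers, K, Off_max = 2, specs = trait_specs(),
                            R = 5) {
  n <- nrow(mothers)
  if (n == 0) stop("patch must be occupied (N > 0)")
  mu_off <- mean_fecundity(n, K, Off_max)
  counts <- stats::rpois(n, mu_off)
  status <- ifelse(counts >= 1, "successful", "failed")
  idx <- rep(seq_len(n), counts)
  offspring <- inherit_and_mutate(mothers[idx, , drop = FALSE], specs)
  offspring$recruitment_age <- draw_recruitment_age(length(idx), R)
  rownames(offspring) <- NULL
  list(status = status, offspring = offspring)
}

#' Local breeding success
#'
#' Fraction of a patch's adults that bred successfully this year — the
#' public information prospectors read. Undefined for an empty patch.
#'
#' @param status character or logical vector of per-adult outcomes
#'   ("successful"/"failed", or TRUE/FALSE).
#' @return A single value in \[0, 1\].
#' @export
local_breeding_success <- function(status) {
  if (length(status) == 0) stop("LBS is undefined for an empty patch (N = 0)")
  if (is.character(status)) status <- status == "successful"
  mean(status)
}

#' Draw recruitment ages
#'
#' Age at which an individual attempts to breed for the first time, drawn at
#' birth from `Poisson(R)`; draws below 2 are raised to 2 so every
#' individual passes through the juvenile and pre-breeder stages. Recruits
#' choose their first breeding patch in the year before that age, so the
#' first breeding attempt happens at the drawn age.
#'
#' @param n number of draws.
#' @param R mean recruitment age, >= 0.
#' @return Integer vector of ages, all >= 2.
#' @export
draw_recruitment_age <- function(n, R = 5) {
  if (R < 0) stop("R must be >= 0")
  pmax(2L, stats::rpois(n, R))
}

#' Stage-specific survival and promotion
#'
#' Each individual survives an independent Bernoulli trial with its stage's
#' probability (`S_J` juveniles, `S_I` pre-breeders, `S_A` adults).
#' Surviving juveniles are promoted to pre-breeders; surviving pre-breeders
#' that will reach their recruitment age by the next breeding season are
#' promoted to adults (their first breeding attempt then falls at the drawn
#' recruitment age).
#'
#' @param individuals data.frame with columns `stage` (one of "juvenile",
#'   "pre_breeder", "adult"), `age`, `recruitment_age`.
#' @param S_J,S_I,S_A stage survival probabilities in \[0, 1\].
#' @return The surviving rows, with stages promoted.
#' @export
apply_survival <- function(individuals, S_J = 0.6, S_I = 0.7, S_A = 0.85) {
  probs <- c(juvenile = S_J, pre_breeder = S_I, adult = S_A)
  if (any(probs < 0 | probs > 1)) stop("survival probabilities must be in [0, 1]")
  p <- probs[individuals$stage]
  out <- individuals[stats::runif(nrow(individuals)) < p, , drop = FALSE]
  juv <- out$stage == "juvenile"
  out$stage[juv] <- "pre_breeder"
  recruit <- out$stage == "pre_breeder" & !juv & out$age + 1 >= out$recruitment_age
  out$stage[recruit] <- "adult"
  rownames(out) <- NULL
  out
}
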