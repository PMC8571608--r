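.strategies <- c("uninformed", "personal", "personal_public")
.processes <- c("inaccurate", "accurate", "deterministic")

# loci read by each emigration strategy
.strategy_loci <- list(
  uninformed = "E",
  personal = c("E_succ", "E_fail"),
  personal_public = c("beta_succ", "alpha_succ", "beta_fail", "alpha_fail")
)

#' Scenario configuration
#'
#' Collects every parameter of a simulation scenario: the demographic and
#' environmental constants, the emigration strategy and patch-selection
#' process, the prospecting cost, which loci evolve, and the run-length
#' controls. Defaults are the common parameterization of the model
#' (25 patches, K0 = 100, Off_max = 2, S_J = 0.6, S_I = 0.7, S_A = 0.85,
#' sigma = 1, autocorr = 0.8, R = 5, mu = 0.01), with the fixed emigration
#' constants of the prospecting-only experiment.
#'
#' In the prospecting-only experiment (`evolve_emigration = FALSE`) only the
#' `Np` locus evolves and emigration parameters are held at the scenario
#' constants. In the joint experiment (`evolve_emigration = TRUE`) the loci
#' read by the chosen strategy evolve alongside `Np`.
#'
#' @param strategy emigration strategy: `"uninformed"`, `"personal"`, or
#'   `"personal_public"`.
#' @param process patch-selection process: `"inaccurate"`, `"accurate"`, or
#'   `"deterministic"`.
#' @param M per-patch prospecting mortality cost (0 or 0.01 in the study
#'   designs).
#' @param evolve_emigration do the strategy's emigration loci evolve?
#' @param evolve_np does the number of prospected patches evolve?
#' @param years number of simulated years.
#' @param replicates number of independent replicates.
#' @param n_patches,K0,Off_max,S_J,S_I,S_A,sigma,autocorr,R,mu model
#'   constants (see above).
#' @param mut_sd continuous mutation-increment standard deviation.
#' @param accuracy softmax coefficient of the accurate process.
#' @param E,E_succ,E_fail,beta_succ,alpha_succ,beta_fail,alpha_fail fixed
#'   values used when the corresponding locus is not evolving.
#' @param Np_fixed fixed number of prospected patches if `evolve_np = FALSE`.
#' @param init_adults initial adults per patch (default `K0`).
#' @param summary_every cadence (years) of the yearly summary and patch log.
#' @param settlement_candidacy which patches an emigrant may settle in:
#'   `"all"` (any patch but the current one; a patch without breeders reads
#'   LBS = 0, so informed processes all but never pick it, while random
#'   settlement can recolonize it), `"present"` (patches holding any
#'   individual), or `"breeders"` (patches with breeding adults only; patch
#'   extinction is then nearly irreversible and the network erodes).
#' @param first_breeding `"at_recruitment_age"`: recruits choose their first
#'   patch in the year before the drawn recruitment age, so the first
#'   breeding attempt falls at that age; `"year_after"`: they settle in the
#'   year they reach the drawn age and first breed one year later.
#' @param recruit_year_survival survival probability applied in the
#'   settlement year of a recruit: `"pre_breeder"` (`S_I`; the individual
#'   reaches its recruitment age only at the end of that year) or `"adult"`
#'   (`S_A`).
#' @return A `scenario_config` list.
#' @examples
#' cfg <- scenario_config("personal", "accurate", M = 0.01,
#'                        evolve_emigration = TRUE, years = 500, replicates = 2)
#' @export
scenario_config <- function(strategy = c("uninformed", "personal", "personal_public"),
                            process = c("inaccurate", "accurate", "deterministic"),
                            M = 0, evolve_emigration = FALSE, evolve_np = TRUE,
                            years = 20000, replicates = 10,
                            n_patches = 25, K0 = 100, Off_max = 2,
                            S_J = 0.6, S_I = 0.7, S_A = 0.85,
                            sigma = 1, autocorr = 0.8, R = 5,
                            mu = 0.01, mut_sd = 0.1, accuracy = 50,
                            E = 0.5, E_succ = 0.05, E_fail = 0.5,
                            beta_succ = 0.05, alpha_succ = 0,
                            beta_fail = 0.5, alpha_fail = -0.45,
                            Np_fixed = 0, init_adults = NULL,
                            summary_every = 100,
                            settlement_candidacy = c("all", "present", "breeders"),
                            first_breeding = c("at_recruitment_age", "year_after"),
                            recruit_year_survival = c("pre_breeder", "adult")) {
  strategy <- match.arg(strategy)
  process <- match.arg(process)
  settlement_candidacy <- match.arg(settlement_candidacy)
  first_breeding <- match.arg(first_breeding)
  recruit_year_survival <- match.arg(recruit_year_survival)
  probs <- c(S_J = S_J, S_I = S_I, S_A = S_A, mu = mu)
  if (any(probs < 0 | probs > 1))
    stop("survival and mutation probabilities must be in [0, 1]")
  if (sigma < 0) stop("sigma must be >= 0")
  if (autocorr < 0 || autocorr > 1) stop("autocorr must be in [0, 1]")
  if (K0 <= 0) stop("K0 must be > 0")
  if (Off_max < 1) stop("Off_max must be >= 1")
  if (R < 0) stop("R must be >= 0")
  if (years < 1 || replicates < 1) stop("years and replicates must be >= 1")
  if (M < 0 || M * (n_patches - 1) > 1)
    stop("M must satisfy 0 <= M * (n_patches - 1) <= 1")
  if (Np_fixed < 0 || Np_fixed > n_patches - 1)
    stop("Np_fixed must be in 0..n_patches - 1")
  if (is.null(init_adults)) init_adults <- as.integer(round(K0))

  evolving <- if (evolve_emigration) .strategy_loci[[strategy]] else character(0)
  if (evolve_np) evolving <- c(evolving, "Np")

  structure(list(
    strategy = strategy, process = process, M = M,
    evolving = evolving, years = as.integer(years),
    replicates = as.integer(replicates),
    n_patches = as.integer(n_patches), K0 = K0, Off_max = Off_max,
    S_J = S_J, S_I = S_I, S_A = S_A, sigma = sigma, autocorr = autocorr,
    R = R, mu = mu, mut_sd = mut_sd, accuracy = accuracy,
    E = E, E_succ = E_succ, E_fail = E_fail,
    beta_succ = beta_succ, alpha_succ = alpha_succ,
    beta_fail = beta_fail, alpha_fail = alpha_fail,
    Np_fixed = as.integer(Np_fixed),
    init_adults = as.integer(init_adults),
    summary_every = as.integer(summary_every),
    settlement_candidacy = settlement_candidacy,
    first_breeding = first_breeding,
    recruit_year_survival = recruit_year_survival
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario: ", x$strategy, " emigration, ", x$process,
      " patch selection, M = ", x$M, "\n",
      "Evolving loci: ", paste(x$evolving, collapse = ", "), "\n",
      x$years, " years x ", x$replicates, " replicates, ",
      x$n_patches, " patches (K0 = ", x$K0, ")\n", sep = "")
  invisible(x)
}

#' Scenario grids for the two experiments
#'
#' The prospecting-only experiment crosses the three emigration strategies
#' (fixed at E = 0.5; E_succ = 0.05, E_fail = 0.5; beta_succ = 0.05,
#' alpha_succ = 0, beta_fail = 0.5, alpha_fail = -0.45) with the three
#' patch-selection processes and prospecting costs M = 0 and M = 0.01:
#' 18 scenarios in which only `Np` evolves. The joint experiment uses the
#' same grid but lets the strategy's emigration loci evolve with `Np`.
#'
#' @param M prospecting costs to cross (default both study values).
#' @param ... passed to [scenario_config()] (e.g. `years`, `replicates`).
#' @return A list of `scenario_config` objects.
#' @export
experiment1_grid <- function(M = c(0, 0.01), ...) {
  grid <- expand.grid(strategy = .strategies, process = .processes, M = M,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    scenario_config(strategy = grid$strategy[i], process = grid$process[i],
                    M = grid$M[i], evolve_emigration = FALSE, ...))
}

#' @rdname experiment1_grid
#' @export
experiment2_grid <- function(M = c(0, 0.01), ...) {
  grid <- expand.grid(strategy = .strategies, process = .processes, M = M,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    scenario_config(strategy = grid$strategy[i], process = grid$process[i],
                    M = grid$M[i], evolve_emigration = TRUE, ...))
}
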