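#' Emigration probability under the three information regimes
#'
#' * `uninformed`: every individual uses its `E` allele.
#' * `personal`: successful breeders use `E_succ`, failed breeders `E_fail`.
#' * `personal_public`: a status-specific linear reaction norm on the local
#'   breeding success, `beta_status + alpha_status * LBS`.
#'
#' New recruits have no breeding history and use the failed-breeder rule
#' with the breeding success of the patch they sit in. Raw values are
#' clamped to \[0, 1\] at use (alleles themselves are unrestricted).
#'
#' @param genotype data.frame or list of allele values (columns as in
#'   [trait_specs()]); vectorized over rows.
#' @param strategy one of `"uninformed"`, `"personal"`, `"personal_public"`.
#' @param status one of `"successful"`, `"failed"`, `"recruit"` (recycled).
#' @param lbs local breeding success in \[0, 1\]; required for
#'   `personal_public`.
#' @return Numeric vector of emigration probabilities in \[0, 1\].
#' @examples
#' g <- list(beta_fail = 0.5, alpha_fail = -0.45)
#' emigration_probability(g, "personal_public", "failed", lbs = 1)  # 0.05
#' @export
emigration_probability <- function(genotype,
                                   strategy = c("uninformed", "personal",
                                                "personal_public"),
                                   status, lbs = NULL) {
  strategy <- match.arg(strategy)
  ok <- c("successful", "failed", "recruit")
  if (!all(status %in% ok)) stop("status must be one of ", paste(ok, collapse = ", "))
  succ <- status == "successful"
  raw <- switch(strategy,
    uninformed = rep_len(genotype$E, length(status)),
    personal = ifelse(succ, rep_len(genotype$E_succ, length(status)),
                      rep_len(genotype$E_fail, length(status))),
    personal_public = {
      if (is.null(lbs)) stop("personal_public requires lbs")
      ifelse(succ,
             rep_len(genotype$beta_succ, length(status)) +
               rep_len(genotype$alpha_succ, length(status)) * lbs,
             rep_len(genotype$beta_fail, length(status)) +
               rep_len(genotype$alpha_fail, length(status)) * lbs)
    })
  pmin(1, pmax(0, raw))
}

#' Eligible destination patches
#'
#' An emigrant must settle in an occupied patch and cannot return to the
#' patch it is leaving. Occupancy is the pre-dispersal snapshot of the year,
#' so decisions do not depend on the order individuals move. An empty
#' result means the emigrant has nowhere to go and stays put.
#'
#' @param current current patch index.
#' @param occupied logical vector of snapshot occupancy, or an integer
#'   vector of occupied patch indices.
#' @return Integer vector of candidate patch indices (possibly empty).
#' @export
candidate_patches <- function(current, occupied) {
  idx <- if (is.logical(occupied)) which(occupied) else as.integer(occupied)
  setdiff(idx, current)
}

#' Draw the prospected set
#'
#' A uniform random subset of the candidates, without replacement, of size
#' `min(np, length(candidates))`. `np = 0` prospects nothing (settlement is
#' then random among candidates).
#'
#' @param candidates integer vector of candidate patches.
#' @param np number of patches to prospect, >= 0.
#' @return Integer vector of prospected patches.
#' @export
draw_prospected_set <- function(candidates, np) {
  if (np < 0) stop("np must be >= 0")
  k <- min(np, length(candidates))
  if (k == 0) return(integer(0))
  candidates[sample.int(length(candidates), k)]
}

#' Settlement probabilities over prospected patches
#'
#' Maps the breeding successes of the prospected patches to a probability
#' of settling in each, reflecting how well individuals discriminate:
#' * `inaccurate`: proportional weighting, `p_i = LBS_i / sum(LBS)`
#'   (uniform when every LBS is 0, the symmetric completion);
#' * `accurate`: softmax `p_i = exp(a * LBS_i) / sum(exp(a * LBS_j))` with
#'   accuracy coefficient `a` (default 50), strongly favouring the best
#'   patch; at `a = 0` it degenerates to uniform;
#' * `deterministic`: all mass on the highest-LBS patch, split uniformly
#'   over ties.
#'
#' @param lbs numeric vector of breeding successes in \[0, 1\], one per
#'   prospected patch (length >= 1).
#' @param process one of `"inaccurate"`, `"accurate"`, `"deterministic"`.
#' @param accuracy softmax coefficient for the accurate process.
#' @return Numeric probability vector summing to 1.
#' @examples
#' settlement_probabilities(c(0.1, 0.9, 0.4), "deterministic")  # 0 1 0
#' @export
settlement_probabilities <- function(lbs,
                                     process = c("inaccurate", "accurate",
                                                 "deterministic"),
                                     accuracy = 50) {
  process <- match.arg(process)
  if (length(lbs) == 0) stop("at least one prospected patch is required")
  if (any(lbs < 0 | lbs > 1)) stop("lbs values must be in [0, 1]")
  switch(process,
    inaccurate = {
      s <- sum(lbs)
      if (s <= 0) rep(1 / length(lbs), length(lbs)) else lbs / s
    },
    accurate = {
      w <- exp(accuracy * (lbs - max(lbs)))
      w / sum(w)
    },
    deterministic = {
      p <- as.numeric(lbs == max(lbs))
      p / sum(p)
    })
}

#' Prospecting survival
#'
#' Prospecting carries a mortality cost proportional to the number of
#' patches visited: an individual prospecting `np` patches dies with
#' probability `M * np` before settling. Individuals that do not prospect
#' pay nothing.
#'
#' @param np number(s) of prospected patches.
#' @param M per-patch mortality cost; `M * np` must not exceed 1.
#' @return Logical vector: `TRUE` if the individual survives.
#' @export
prospecting_survival <- function(np, M) {
  if (any(M * np > 1)) stop("M * np must be <= 1")
  if (any(M * np < 0)) stop("M * np must be >= 0")
  stats::runif(length(np)) >= M * np
}

#' Choose a settlement patch
#'
#' With no prospected set the emigrant settles uniformly among candidates
#' (random settlement); otherwise the destination is sampled from
#' [settlement_probabilities()] over the prospected patches. Prospecting a
#' single patch is equivalent to random settlement, whatever the process.
#'
#' @param candidates integer vector of eligible destinations (length >= 1).
#' @param prospected integer vector of prospected patches (may be empty).
#' @param lbs breeding successes aligned with `prospected`.
#' @param process,accuracy as in [settlement_probabilities()].
#' @return A single destination patch index.
#' @export
settle <- function(candidates, prospected = integer(0), lbs = NULL,
                   process = "inaccurate", accuracy = 50) {
  if (length(candidates) == 0) stop("settle requires at least one candidate")
  if (length(prospected) == 0)
    return(candidates[sample.int(length(candidates), 1)])
  p <- settlement_probabilities(lbs, process, accuracy)
  prospected[sample.int(length(prospected), 1, prob = p)]
}
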