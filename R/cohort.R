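#' Construct a synthetic cohort specification
#'
#' Defaults reproduce the scale of the longitudinal anti-VEGF study:
#' 6 deceased / 7 survivor / 12 control animals; baseline tumour Lac/Bic
#' means 11.08 (deceased), 10.77 (survivors), 13.57 (controls) with SDs
#' recovered from the reported standard errors (SE x sqrt(n)); 48-hour
#' multiplicative tumour effects 1.60 / 0.82 / 1.26 (the control effect
#' mirrors the deceased one); normal-brain Lac/Bic 6.2 with a null
#' 48-hour effect; non-survivor survival 13.5 +/- 1.7 days (SE 0.7 at
#' n = 6) censored at day 70; baseline tumour volumes near 135 mm^3 with
#' group growth factors 1.59 / 1.08 / 1.30. A latent per-animal
#' aggressiveness couples the Lac/Bic jitter to the growth jitter
#' (rho = 0.75), reproducing the positive growth-rate/Lac/Bic
#' correlation.
#'
#' @param nDeceased,nSurvivors,nControls group sizes
#' @param tumorBaseline,tumorBaselineSd named per-group baseline tumour
#'   Lac/Bic mean and SD
#' @param normalBaseline,normalBaselineSd normal-brain Lac/Bic mean, SD
#' @param tumorEffect named per-group multiplicative 48-h change
#' @param normalEffect 48-h multiplicative change in normal brain
#' @param effectSdLog lognormal jitter sd of the 48-h effects
#' @param survivalMeanD,survivalSdD survival distribution of
#'   non-survivors (days)
#' @param censorDay observation cutoff (days)
#' @param volBaseline,volBaselineSd named baseline volume mean, SD (mm^3)
#' @param volEffect named 48-h volume growth factors
#' @param volEffectSdLog lognormal jitter sd of the growth factor
#' @param couplingRho latent correlation of Lac/Bic and growth jitter
#' @param responseRate responder probability for randomized group
#'   assignment
#' @param seed RNG seed
#' @return a [CohortSpec-class]
#' @export
cohortSpec <- function(nDeceased = 6, nSurvivors = 7, nControls = 12,
                       tumorBaseline = c(deceased = 11.077,
                                         survivor = 10.767,
                                         control = 13.566),
                       tumorBaselineSd = c(deceased = 1.467 * sqrt(6),
                                           survivor = 1.183 * sqrt(7),
                                           control = 0.885 * sqrt(12)),
                       normalBaseline = 6.2,
                       normalBaselineSd = 0.539 * sqrt(6),
                       tumorEffect = c(deceased = 1.604,
                                       survivor = 0.823,
                                       control = 1.259),
                       normalEffect = 1.0, effectSdLog = 0.12,
                       survivalMeanD = 13.5,
                       survivalSdD = 0.7 * sqrt(6), censorDay = 70,
                       volBaseline = c(deceased = 136.8,
                                       survivor = 141.6,
                                       control = 129.5),
                       volBaselineSd = c(deceased = 24.4 * sqrt(6),
                                         survivor = 21.6 * sqrt(7),
                                         control = 22.9 * sqrt(12)),
                       volEffect = c(deceased = 1.588, survivor = 1.079,
                                     control = 1.297),
                       volEffectSdLog = 0.15, couplingRho = 0.75,
                       responseRate = 0.5, seed = 1L) {
  new("CohortSpec", nDeceased = as.integer(nDeceased),
      nSurvivors = as.integer(nSurvivors),
      nControls = as.integer(nControls), tumorBaseline = tumorBaseline,
      tumorBaselineSd = tumorBaselineSd, normalBaseline = normalBaseline,
      normalBaselineSd = normalBaselineSd, tumorEffect = tumorEffect,
      normalEffect = normalEffect, effectSdLog = effectSdLog,
      survivalMeanD = survivalMeanD, survivalSdD = survivalSdD,
      censorDay = censorDay, volBaseline = volBaseline,
      volBaselineSd = volBaselineSd, volEffect = volEffect,
      volEffectSdLog = volEffectSdLog, couplingRho = couplingRho,
      responseRate = responseRate, seed = as.integer(seed))
}

#' Generate a synthetic animal cohort
#'
#' Draws one record per animal: baseline tumour and normal-brain Lac/Bic
#' (truncated normal), 48-hour values (baseline times the group effect
#' with lognormal jitter), baseline tumour volume and 48-hour volume
#' (baseline times the group growth factor with jitter coupled to the
#' Lac/Bic jitter through a shared latent), and survival: non-survivors
#' draw from Normal(survivalMeanD, survivalSdD) truncated at 1 and
#' rounded to whole days; survivors and any draw past the cutoff are
#' censored at `censorDay` with event = 0. Deterministic given
#' `spec@seed`.
#'
#' With `randomizeGroups = TRUE` the treated animals
#' (nDeceased + nSurvivors) are instead assigned to the survivor group
#' independently with probability `responseRate`, emulating the
#' response-rate uncertainty of a treatment study.
#'
#' @param spec a [CohortSpec-class]
#' @param randomizeGroups assign treated animals by responseRate rather
#'   than fixed group sizes
#' @return data.frame with one row per animal: id, group,
#'   pre/post_lacbic_tumor, pre/post_lacbic_normal, vol_pre_mm3,
#'   vol_post_mm3, survival_day, event
#' @export
makeCohort <- function(spec, randomizeGroups = FALSE) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  nTreated <- spec@nDeceased + spec@nSurvivors
  nAll <- nTreated + spec@nControls
  if (nAll == 0) stop("empty-cohort: all group sizes are zero")
  withSeed(spec@seed, {
    if (randomizeGroups) {
      treatedGrp <- ifelse(stats::runif(nTreated) < spec@responseRate,
                           "survivor", "deceased")
    } else {
      treatedGrp <- rep(c("deceased", "survivor"),
                        c(spec@nDeceased, spec@nSurvivors))
    }
    group <- c(treatedGrp, rep("control", spec@nControls))
    n <- length(group)
    rtnorm <- function(n, mu, sd, lo) pmax(stats::rnorm(n, mu, sd), lo)
    preT <- rtnorm(n, spec@tumorBaseline[group],
                   spec@tumorBaselineSd[group], 1)
    preN <- rtnorm(n, spec@normalBaseline, spec@normalBaselineSd, 1)
    z <- stats::rnorm(n)          # latent per-animal aggressiveness
    eps <- stats::rnorm(n)        # independent growth noise
    postT <- preT * spec@tumorEffect[group] * exp(spec@effectSdLog * z)
    postN <- preN * spec@normalEffect *
      exp(spec@effectSdLog / 2 * stats::rnorm(n))
    volPre <- rtnorm(n, spec@volBaseline[group],
                     spec@volBaselineSd[group], 10)
    growth <- spec@volEffect[group] *
      exp(spec@volEffectSdLog * (spec@couplingRho * z +
                                   sqrt(1 - spec@couplingRho^2) * eps))
    volPost <- volPre * growth
    surv <- pmax(round(stats::rnorm(n, spec@survivalMeanD,
                                    spec@survivalSdD)), 1)
    day <- ifelse(group == "survivor", spec@censorDay,
                  pmin(surv, spec@censorDay))
    event <- as.integer(group != "survivor" & surv < spec@censorDay)
    data.frame(
      id = sprintf("%s%02d", substr(group, 1, 1), seq_len(n)),
      group = group,
      pre_lacbic_tumor = unname(preT), post_lacbic_tumor = unname(postT),
      pre_lacbic_normal = unname(preN),
      post_lacbic_normal = unname(postN),
      vol_pre_mm3 = unname(volPre), vol_post_mm3 = unname(volPost),
      survival_day = unname(day), event = unname(event),
      stringsAsFactors = FALSE)
  })
}
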