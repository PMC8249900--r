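#' Construct a SyntheticConfig
#'
#' Parameters of the seeded synthetic test/retest cohort generator. The
#' defaults describe the study conditions the package is designed around: a
#' cohort of 41 subjects over a 100-region parcellation, one shared group
#' connectivity pattern whose expression fluctuates mildly around a
#' per-subject level, a strong per-subject fingerprint component
#' (`fingerprintScale = 0.1` correlation units) reused by both sessions, and
#' moderate independent session noise (`sessionNoiseScale = 0.04`).
#'
#' @param nSubjects number of subjects, default 41.
#' @param nRegions number of regions, default 100.
#' @param nTimepoints timepoints per session for the time-series generator,
#'   default 300.
#' @param nGroupComponents number of shared group patterns, default 1.
#' @param groupScale loading scale of the group pattern(s), default 0.1.
#' @param fingerprintScale SD of the per-subject edge component, default 0.1.
#' @param sessionNoiseScale SD of independent per-session edge noise,
#'   default 0.04.
#' @param plantedMasks list of `list(positive=, negative=)` logical edge
#'   vectors, one per synthetic outcome (named); default none.
#' @param effectSizes list of `list(pos=, neg=)` scalars per outcome.
#' @param outcomeNoiseScale outcome noise SD in units of the noise-free
#'   outcome SD, default 0.5.
#' @param seed integer master seed.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSubjects = 41, nRegions = 100,
                            nTimepoints = 300, nGroupComponents = 1,
                            groupScale = 0.1, fingerprintScale = 0.1,
                            sessionNoiseScale = 0.04, plantedMasks = list(),
                            effectSizes = list(), outcomeNoiseScale = 0.5,
                            seed = 1) {
  new("SyntheticConfig",
      nSubjects = as.integer(nSubjects), nRegions = as.integer(nRegions),
      nTimepoints = as.integer(nTimepoints),
      nGroupComponents = as.integer(nGroupComponents),
      groupScale = as.numeric(groupScale),
      fingerprintScale = as.numeric(fingerprintScale),
      sessionNoiseScale = as.numeric(sessionNoiseScale),
      plantedMasks = plantedMasks, effectSizes = effectSizes,
      outcomeNoiseScale = as.numeric(outcomeNoiseScale),
      seed = as.integer(seed))
}

#' Synthetic parcellation with nine RSN blocks
#'
#' Splits `nRegions` regions into nine contiguous blocks, one per label in
#' [RSN_LEVELS], and places regions deterministically on a 70 mm sphere
#' (golden-spiral points) so brain-network export is exercisable without
#' real coordinates.
#'
#' @param nRegions number of regions (>= 9 to populate every network).
#' @return A [Parcellation-class].
#' @export
makeSyntheticParcellation <- function(nRegions) {
  nRegions <- as.integer(nRegions)
  stopifnot(nRegions >= 2L)
  labs <- RSN_LEVELS[ceiling(seq_len(nRegions) / nRegions * 9)]
  i <- seq_len(nRegions)
  phi <- acos(1 - 2 * (i - 0.5) / nRegions)
  theta <- pi * (1 + sqrt(5)) * i
  coords <- 70 * cbind(x = sin(phi) * cos(theta),
                       y = sin(phi) * sin(theta),
                       z = cos(phi))
  parcellation(sprintf("R%03d", i), labs, round(coords, 2))
}

# per-RSN-block baseline connectivity: higher within than between blocks
.blockBaseline <- function(parc) {
  ei <- edgeIndex(parc)
  same <- parc@rsnLabels[ei$i] == parc@rsnLabels[ei$j]
  ifelse(same, 0.25, 0.05)
}

#' Generate a synthetic paired test/retest connectome cohort
#'
#' Edge vectors are built additively, per subject i and session s:
#' baseline block structure + shared group pattern(s) scaled by a
#' per-subject expression weight with a small per-session fluctuation +
#' a per-subject fingerprint component (drawn once, identical in both
#' sessions) + per-session noise that is half spatially structured (20
#' shared patterns with independent per-session amplitudes, emulating
#' motion/physiology/drift residuals) and half independent per edge, with
#' total per-edge variance `sessionNoiseScale^2`; values are clipped to
#' \[-1, 1\] (configurations are chosen so clipping is rare). The group
#' pattern's expression level is subject-stable (drawn once per subject,
#' around 1) with a small session-to-session fluctuation (SD
#' `2 * sessionNoiseScale`), so zero session noise yields exactly identical
#' sessions. Under the uncentered identifiability sweep the subject-stable
#' structure spans exactly N dimensions, which is why differential
#' identifiability peaks at the cohort size N on these cohorts.
#'
#' When the config carries planted masks, outcomes are generated via
#' [generateOutcomes()] and included in the cohort.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [SyntheticCohort-class]; `groundTruth` holds the noise-free
#'   subject components, the group patterns, planted masks, true effect
#'   sizes and the config.
#' @examples
#' coh <- generateFCCohort(syntheticConfig(nSubjects = 6, nRegions = 15, seed = 3))
#' nSubjects(coh)
#' @export
generateFCCohort <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  N <- config@nSubjects; R <- config@nRegions
  E <- edgeCount(R)
  nG <- config@nGroupComponents
  if (config@fingerprintScale == 0 && config@sessionNoiseScale == 0 &&
      (nG == 0L || config@groupScale == 0))
    stop("scales produce all-constant edge columns; nothing to identify")
  parc <- makeSyntheticParcellation(R)
  mu <- .blockBaseline(parc)
  .withSeed(config@seed, {
    mu <- mu + rnorm(E, 0, 0.02)
    G <- if (nG) matrix(rnorm(E * nG, 0, config@groupScale), E, nG)
         else matrix(0, E, 0)
    wSubj <- matrix(rnorm(nG * N, 1, 0.3), nG, N)          # expression level
    etaSD <- 2 * config@sessionNoiseScale                  # session fluctuation
    etaA <- matrix(rnorm(nG * N, 0, etaSD), nG, N)
    etaB <- matrix(rnorm(nG * N, 0, etaSD), nG, N)
    f <- matrix(rnorm(E * N, 0, config@fingerprintScale), E, N)
    # session noise: 40% spatially structured (J shared patterns with
    # per-session amplitudes, like motion/respiration/drift residuals),
    # 60% independent per edge; total per-edge variance = sessionNoiseScale^2
    J <- 40L
    ns <- config@sessionNoiseScale
    H <- matrix(rnorm(E * J, 0, ns * sqrt(0.4 / J)), E, J)
    noise <- function() H %*% matrix(rnorm(J * N), J, N) +
      matrix(rnorm(E * N, 0, ns * sqrt(0.6)), E, N)
    subjComp <- mu + (if (nG) G %*% wSubj else 0) + f       # session-stable part
    restA <- pmin(pmax(subjComp + (if (nG) G %*% etaA else 0) + noise(), -1), 1)
    restB <- pmin(pmax(subjComp + (if (nG) G %*% etaB else 0) + noise(), -1), 1)
    ids <- sprintf("S%03d", seq_len(N))
    colnames(restA) <- colnames(restB) <- colnames(subjComp) <- ids
    coh <- new("SyntheticCohort", restA = restA, restB = restB,
               subjectIDs = ids, parcellation = parc,
               outcomes = data.frame(subject = ids),
               groundTruth = list(subjectComponents = subjComp,
                                  groupPatterns = G, edgeMeans = mu,
                                  plantedMasks = config@plantedMasks,
                                  effectSizes = config@effectSizes,
                                  config = config),
               timeSeries = list())
    if (length(config@plantedMasks))
      coh <- generateOutcomes(coh, seed = .childSeed(config@seed, 911L))
    coh
  })
}

#' Plant signed outcome-linked edge masks
#'
#' Draws disjoint positive and negative edge sets for one or more synthetic
#' outcomes. Positive edges are sampled from within-network edges and
#' negative edges from between-network edges of the parcellation's RSN
#' blocks, so the downstream enrichment tests have genuine structure to
#' find.
#'
#' @param parc a [Parcellation-class].
#' @param outcomes character vector of outcome names.
#' @param nPos,nNeg edges per mask side; default 30 each, reduced to half
#'   the available within-/between-network edge pool on small parcellations.
#' @param seed integer seed.
#' @return Named list (per outcome) of `list(positive=, negative=)` logical
#'   edge vectors.
#' @export
plantEdgeMasks <- function(parc, outcomes = "score", nPos = NULL, nNeg = NULL,
                           seed = 1) {
  ei <- edgeIndex(parc)
  within <- which(parc@rsnLabels[ei$i] == parc@rsnLabels[ei$j])
  between <- which(parc@rsnLabels[ei$i] != parc@rsnLabels[ei$j])
  E <- nrow(ei)
  nPos <- nPos %||% min(30L, length(within) %/% 2L)
  nNeg <- nNeg %||% min(30L, length(between) %/% 2L)
  stopifnot(nPos >= 1, nNeg >= 1,
            nPos <= length(within), nNeg <= length(between))
  .withSeed(seed, {
    out <- lapply(seq_along(outcomes), function(k) {
      pos <- logical(E); neg <- logical(E)
      pos[sample(within, nPos)] <- TRUE
      neg[sample(between, nNeg)] <- TRUE
      list(positive = pos, negative = neg)
    })
    setNames(out, outcomes)
  })
}

#' Generate outcomes linearly coupled to planted mask strengths
#'
#' Each subject's outcome is computed on the noise-free, session-stable part
#' of their connectome (so the planted signal is identical in restA and
#' restB): effect times the summed edge values over the planted positive
#' mask, minus effect times the sum over the planted negative mask, plus
#' Gaussian noise scaled to `outcomeNoiseScale` times the noise-free
#' outcome SD.
#'
#' @param cohort a [SyntheticCohort-class] from [generateFCCohort()].
#' @param plantedMasks,effectSizes,outcomeNoiseScale overrides; default to
#'   the cohort config's values (effect sizes default to pos = 1, neg = 1).
#' @param seed integer seed (defaults to a child of the config seed).
#' @return The cohort with its `outcomes` table filled in and ground truth
#'   extended (`trueEffects`, `noiseFreeOutcomes`).
#' @export
generateOutcomes <- function(cohort, plantedMasks = NULL, effectSizes = NULL,
                             outcomeNoiseScale = NULL, seed = NULL) {
  stopifnot(is(cohort, "SyntheticCohort"))
  cfg <- cohort@groundTruth$config
  plantedMasks <- plantedMasks %||% cfg@plantedMasks
  if (!length(plantedMasks)) stop("no planted masks to couple outcomes to")
  effectSizes <- effectSizes %||%
    (if (length(cfg@effectSizes)) cfg@effectSizes else
       setNames(rep(list(list(pos = 1, neg = 1)), length(plantedMasks)),
                names(plantedMasks)))
  outcomeNoiseScale <- outcomeNoiseScale %||% cfg@outcomeNoiseScale
  seed <- seed %||% .childSeed(cfg@seed, 911L)
  S <- cohort@groundTruth$subjectComponents
  if (is.null(S)) S <- (cohort@restA + cohort@restB) / 2
  N <- ncol(S)
  outcomes <- data.frame(subject = cohort@subjectIDs)
  noiseFree <- list()
  .withSeed(seed, {
    for (nm in names(plantedMasks)) {
      pm <- plantedMasks[[nm]]
      es <- effectSizes[[nm]]
      if (!any(pm$positive) && !any(pm$negative) &&
          (es$pos != 0 || es$neg != 0))
        stop("planted masks for '", nm, "' are empty but effects are nonzero")
      y0 <- es$pos * colSums(S[pm$positive, , drop = FALSE]) -
            es$neg * colSums(S[pm$negative, , drop = FALSE])
      noiseSD <- outcomeNoiseScale * sd(y0)
      outcomes[[nm]] <- y0 + rnorm(N, 0, noiseSD)
      noiseFree[[nm]] <- y0
    }
  })
  cohort@outcomes <- outcomes
  cohort@groundTruth$plantedMasks <- plantedMasks
  cohort@groundTruth$trueEffects <- effectSizes
  cohort@groundTruth$noiseFreeOutcomes <- noiseFree
  cohort
}

#' Generate a synthetic cohort at the time-series level
#'
#' Regional BOLD-like signals are linear mixtures of nine latent network
#' signals (one per RSN block, drawn fresh per session and shared across
#' subjects) through a mixing matrix with a subject-specific perturbation
#' that is identical in both sessions (the fingerprint), plus temporal
#' noise. Connectomes computed from these series via [computeConnectome()]
#' are valid correlation matrices by construction. `fingerprintScale` is
#' reused as the SD of the mixing perturbation and `sessionNoiseScale` as
#' the temporal noise SD (latent signals have unit SD).
#'
#' @param config a [SyntheticConfig-class]; `nTimepoints >= 2 * nRegions` is
#'   recommended for well-conditioned correlation estimates.
#' @return A [SyntheticCohort-class] whose `timeSeries` slot holds, per
#'   subject, a list of two [RegionalTimeSeries-class] sessions.
#' @export
generateTimeseriesCohort <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  N <- config@nSubjects; R <- config@nRegions; T <- config@nTimepoints
  if (T < 4L) stop("invalid dimensions: need at least 4 timepoints")
  parc <- makeSyntheticParcellation(R)
  L <- length(unique(parc@rsnLabels))
  block <- match(parc@rsnLabels, RSN_LEVELS)
  blockIdx <- match(block, sort(unique(block)))
  M0 <- matrix(0.15, R, L)
  M0[cbind(seq_len(R), blockIdx)] <- 1
  .withSeed(config@seed, {
    dM <- lapply(seq_len(N), function(i)
      matrix(rnorm(R * L, 0, config@fingerprintScale), R, L))
    ids <- sprintf("S%03d", seq_len(N))
    tsList <- setNames(vector("list", N), ids)
    edgeA <- edgeB <- matrix(NA_real_, edgeCount(R), N,
                             dimnames = list(NULL, ids))
    for (s in 1:2) {
      Z <- matrix(rnorm(T * L), T, L)       # latents shared across subjects
      for (i in seq_len(N)) {
        V <- Z %*% t(M0 + dM[[i]]) +
          matrix(rnorm(T * R, 0, config@sessionNoiseScale), T, R)
        ts <- regionalTimeSeries(V, ids[i],
                                 sessionLabel = c("restA", "restB")[s])
        tsList[[i]] <- c(tsList[[i]], list(ts))
        ev <- vectorizeConnectome(computeConnectome(ts))
        if (s == 1) edgeA[, i] <- ev else edgeB[, i] <- ev
      }
    }
    coh <- new("SyntheticCohort", restA = edgeA, restB = edgeB,
               subjectIDs = ids, parcellation = parc,
               outcomes = data.frame(subject = ids),
               groundTruth = list(mixingBase = M0, mixingPerturbations = dM,
                                  plantedMasks = config@plantedMasks,
                                  effectSizes = config@effectSizes,
                                  config = config),
               timeSeries = tsList)
    if (length(config@plantedMasks))
      coh <- generateOutcomes(coh, seed = .childSeed(config@seed, 911L))
    coh
  })
}
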