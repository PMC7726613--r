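## Generative model for the bacterial community:
##   log g       ~ N(0, BASE_SD^2)            global mean profile (per cohort)
##   log c_k     = log g + spread * z_k        site centroids
##   log x_i     = log c_site(i) + WITHIN_SD * e_i   per-sample composition
## followed by softmax normalisation; read counts are multinomial draws.
## `spread` controls the expected between-site share of squared Bray-Curtis
## distance; the lookup below maps a requested share to a spread. It was
## computed once by inst/scripts/calibrate_site_effect.R under the reference
## condition (n = 120 mosquitoes, 6 sites, 16S depth 6000, the <10-read
## global filter and the 5000-read sample floor applied).
COMMUNITY_BASE_SD <- 1.2
COMMUNITY_WITHIN_SD <- 0.6
N_COMMUNITY_ASV <- 60L

SITE_EFFECT_LOOKUP <- data.frame(
  spread = c(0, 0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 0.875, 1, 1.25, 1.5,
             1.75, 2, 2.5),
  r2 = c(0.0417, 0.0698, 0.1507, 0.2587, 0.3673, 0.4657, 0.5474, 0.6142,
         0.6670, 0.7446, 0.7951, 0.8293, 0.8537, 0.8854))

## monotone interpolation of the calibration table
spreadForEffect <- function(effect) {
  stopIfNot(effect >= 0 && effect < 1, "site_effect_size must lie in [0, 1)")
  if (effect == 0) return(0)
  tab <- SITE_EFFECT_LOOKUP
  if (effect <= tab$r2[1]) return(tab$spread[2] * effect / tab$r2[2])
  if (effect >= max(tab$r2))
    stop("site_effect_size ", effect, " exceeds the calibrated range (max ~",
         round(max(tab$r2), 2), ")")
  stats::approx(tab$r2, tab$spread, xout = effect, ties = "ordered")$y
}

SPECIES_LEVELS <- c("Anopheles_gambiae", "Anopheles_coluzzii",
                    "Anopheles_melas", "Anopheles_arabiensis",
                    "Anopheles_nili")
HYBRID_LABEL <- "Anopheles_coluzzii x Anopheles_gambiae"

## cohort composition mirrors the study: An. gambiae dominant, a handful of
## An. nili (rescued via cox1) and rare gambiae x coluzzii F1 hybrids
SPECIES_PROBS <- c(Anopheles_gambiae = 0.735, Anopheles_coluzzii = 0.11,
                   Anopheles_melas = 0.105, Anopheles_arabiensis = 0.015,
                   Anopheles_nili = 0.015, hybrid = 0.02)

KDR_PROBS <- list(
  Anopheles_gambiae    = c(RR = 0.80, RS = 0.12, SS = 0.08),
  Anopheles_coluzzii   = c(RR = 0.30, RS = 0.30, SS = 0.40),
  Anopheles_melas      = c(RR = 0.02, RS = 0.02, SS = 0.96),
  Anopheles_arabiensis = c(RR = 0.02, RS = 0.02, SS = 0.96),
  Anopheles_nili       = c(RR = 0.02, RS = 0.02, SS = 0.96),
  hybrid               = c(RR = 0.40, RS = 0.30, SS = 0.30))

BLOOD_FED_PROB <- 0.20
INFECTED_PROB <- 0.19
INFECTION_WEIGHTS <- c(Theileria_sp = 0.30, Parathelohania_anopheles = 0.25,
                       Setaria_labiatopapillosa = 0.12,
                       Plasmodium_falciparum = 0.10, Loa_loa = 0.08,
                       Anopheles_flavivirus_v1 = 0.08,
                       Anopheles_flavivirus_v2 = 0.07)

drawBloodMeal <- function() {
  kind <- sample(c("human", "cow", "sheep", "human_cow", "human_sheep"), 1,
                 prob = c(0.80, 0.07, 0.015, 0.10, 0.015))
  mix <- switch(kind,
    human = c(Homo_sapiens = 1),
    cow = c(Bos_indicus = 1),
    sheep = c(Ovis_aries = 1),
    human_cow = { w <- runif(1, 0.3, 0.7)
                  c(Homo_sapiens = w, Bos_indicus = 1 - w) },
    human_sheep = { w <- runif(1, 0.5, 0.9)
                    c(Homo_sapiens = w, Ovis_aries = 1 - w) })
  paste(sprintf("%s:%.6g", names(mix), mix), collapse = ";")
}

#' Simulate a wild-caught mosquito cohort with known ground truth
#'
#' Draws per-mosquito truth (collection site, species, kdr genotype,
#' blood-meal mixture, infections) and a site-structured bacterial community
#' whose expected between-site share of Bray-Curtis variance approximates
#' \code{siteEffectSize}, plus empty extraction controls.
#'
#' @param nSamples number of mosquitoes (excluding controls).
#' @param nSites number of collection sites (>= 2); samples are spread
#'   evenly across sites.
#' @param siteEffectSize planted between-site share of community variance,
#'   in [0, 1); 0 makes compositions exchangeable across sites.
#' @param nControls number of extraction-control samples (empty truth).
#' @param seed integer seed; identical arguments give identical truth.
#' @return A \linkS4class{CohortTruth}.
#' @examples
#' truth <- simulateCohort(24, nSites = 3, siteEffectSize = 0.2, seed = 1)
#' head(truthTable(truth))
#' @export
simulateCohort <- function(nSamples, nSites = 6L, siteEffectSize = 0.2,
                           nControls = 0L, seed = 1L) {
  spread <- spreadForEffect(siteEffectSize)
  simulateCohortSpread(nSamples, nSites, spread, nControls, seed,
                       effectLabel = siteEffectSize)
}

## internal: cohort draw parameterised by the raw centroid spread (used by
## the calibration script, which maps spread -> realised R2)
simulateCohortSpread <- function(nSamples, nSites, spread, nControls = 0L,
                                 seed = 1L, effectLabel = NA_real_) {
  stopIfNot(nSites >= 2L, "nSites must be >= 2")
  stopIfNot(nSamples >= nSites, "need at least one sample per site")
  set.seed(seed)

  ids <- sprintf("mosq_%03d", seq_len(nSamples))
  sites <- sample(rep_len(sprintf("site_%d", seq_len(nSites)), nSamples))
  spKey <- sample(names(SPECIES_PROBS), nSamples, replace = TRUE,
                  prob = SPECIES_PROBS)
  species <- ifelse(spKey == "hybrid", HYBRID_LABEL, spKey)
  kdr <- vapply(spKey, function(k)
    sample(names(KDR_PROBS[[k]]), 1, prob = KDR_PROBS[[k]]), character(1))
  fed <- runif(nSamples) < BLOOD_FED_PROB
  blood <- ifelse(fed, vapply(seq_len(nSamples), function(i) drawBloodMeal(),
                              character(1)), "")
  infected <- runif(nSamples) < INFECTED_PROB
  infections <- vapply(seq_len(nSamples), function(i) {
    if (!infected[i]) return("")
    k <- sample(1:2, 1, prob = c(0.85, 0.15))
    paste(sort(sample(names(INFECTION_WEIGHTS), k,
                      prob = INFECTION_WEIGHTS)), collapse = ";")
  }, character(1))

  asv <- sprintf("ASV_%03d", seq_len(N_COMMUNITY_ASV))
  logG <- rnorm(N_COMMUNITY_ASV, 0, COMMUNITY_BASE_SD)
  logC <- sapply(seq_len(nSites), function(k)
    logG + spread * rnorm(N_COMMUNITY_ASV))
  colnames(logC) <- sprintf("site_%d", seq_len(nSites))
  community <- sapply(seq_len(nSamples), function(i) {
    lx <- logC[, sites[i]] + COMMUNITY_WITHIN_SD * rnorm(N_COMMUNITY_ASV)
    x <- exp(lx - max(lx))
    x / sum(x)
  })
  dimnames(community) <- list(asv, ids)

  samples <- data.frame(
    sample_id = ids, site = sites, species = species, kdr_genotype = kdr,
    blood_meal = blood, infections = infections, is_control = FALSE,
    stringsAsFactors = FALSE)

  if (nControls > 0L) {
    cid <- sprintf("ctrl_%03d", seq_len(nControls))
    samples <- rbind(samples, data.frame(
      sample_id = cid, site = "", species = "", kdr_genotype = "",
      blood_meal = "", infections = "", is_control = TRUE))
    community <- cbind(community,
                       matrix(0, N_COMMUNITY_ASV, nControls,
                              dimnames = list(asv, cid)))
  }
  new("CohortTruth", samples = samples, community = community,
      siteEffect = effectLabel, seed = as.integer(seed))
}

#' Parse a truth blood-meal string into a named proportion vector
#' @param x a \code{blood_meal} entry of \code{truthTable()} (possibly "").
#' @return Named numeric vector of host proportions (empty if unfed).
#' @export
parseBloodMeal <- function(x) {
  if (is.na(x) || x == "") return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(as.numeric(vapply(parts, `[`, character(1), 2L)),
                  vapply(parts, `[`, character(1), 1L))
}

#' Per-sample analysis metadata from a simulated cohort
#'
#' Collapses the truth to the factor set used by the community variance
#' partition: site, species, kdr genotype, blood-meal status (fed or not)
#' and infection status. Controls are excluded.
#'
#' @param truth a \linkS4class{CohortTruth}.
#' @return data.frame keyed by \code{sample_id}.
#' @export
truthMetadata <- function(truth) {
  s <- truthTable(truth)
  s <- s[!s$is_control, , drop = FALSE]
  data.frame(sample_id = s$sample_id, site = s$site, species = s$species,
             kdr_genotype = s$kdr_genotype, fed = s$blood_meal != "",
             infected = s$infections != "", stringsAsFactors = FALSE)
}

#' Draw a bacterial 16S count table directly from cohort truth
#'
#' Shortcut past read simulation: multinomial read counts per sample at the
#' configured 16S depth, exactly the distribution an error-free FASTQ round
#' trip produces after demultiplexing and dereplication. Controls are
#' excluded (they carry no community template).
#'
#' @param truth a \linkS4class{CohortTruth}.
#' @param panel a \linkS4class{PanelDesign} supplying the ASV sequences.
#' @param meanDepth mean 16S reads per sample.
#' @param dispersion negative-binomial size for the per-sample depth draw;
#'   0 gives exact depths.
#' @param seed integer seed.
#' @return A \linkS4class{UniqueSeqTable} for locus \code{bact16S} with rows
#'   named by ASV.
#' @export
sampleCommunityCounts <- function(truth, panel, meanDepth = 11730,
                                  dispersion = 0, seed = 1L) {
  set.seed(seed)
  comp <- communityTruth(truth)
  keep <- !truthTable(truth)$is_control
  comp <- comp[, keep, drop = FALSE]
  n <- ncol(comp)
  depth <- if (dispersion == 0) rep(round(meanDepth), n)
           else rnbinom(n, mu = meanDepth, size = dispersion)
  counts <- vapply(seq_len(n), function(i)
    rmultinom(1, depth[i], comp[, i])[, 1], numeric(nrow(comp)))
  dimnames(counts) <- dimnames(comp)
  ins <- referenceInserts(panel, "bact16S")
  stopIfNot(all(rownames(counts) %in% names(ins)),
            "cohort ASVs missing from the panel 16S references")
  newUniqueSeqTable(counts, sequences = ins[rownames(counts)],
                    locus = "bact16S")
}
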