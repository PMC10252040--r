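#' U-shaped occurrence-probability profile
#'
#' Draws per-descriptor occurrence probabilities from a U-shaped
#' Beta(shape1, shape2) law with both shapes < 1: density is unbounded at 0
#' and 1, so some descriptors are effectively always present and some never
#' appear, while the frequencies remain spread over the whole unit interval
#' with both extremes over-represented — the structure of empirical sweat
#' descriptor occurrence histograms. The default is asymmetric (mean ~0.26)
#' because only a minority of the screening library is detected in any one
#' measurement: a symmetric U would imply half of all descriptors present
#' per measurement, far above the observed per-measurement non-zero counts.
#'
#' @param n_descriptors number of descriptors.
#' @param seed integer RNG seed.
#' @param shape1,shape2 Beta shape parameters; both must be < 1 for a U
#'   shape. Defaults 0.25 and 0.7.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
generate_occurrence_profile <- function(n_descriptors, seed, shape1 = 0.25,
                                        shape2 = 0.7) {
  stopifnot(n_descriptors >= 1, shape1 > 0, shape2 > 0)
  withr::with_seed(as.integer(seed), rbeta(n_descriptors, shape1, shape2))
}

#' Cohort generator configuration
#'
#' Bundles all knobs of the zero-inflated log-normal cohort simulator.
#' Presence of a descriptor in a sampling is Bernoulli; present areas are
#' log-normal with a per-measurement scale factor spanning
#' `area_scale_spread` orders of magnitude, so per-measurement area sums
#' spread like the real tables. A planted descriptor subset carries the
#' pre/post effect: a log-scale abundance shift of random per-descriptor
#' sign (`effect_size`) and an occurrence-probability shift
#' (`dropout_shift`), both applied in the `pre` status.
#'
#' Per-measurement non-zero descriptor counts are steered into
#' `nonzero_range` by a per-sampling richness scale: presence probabilities
#' are `min(1, q * s)` with `s` solved so the expected count hits a
#' per-sampling target. Targets are drawn from a normal law centered on the
#' range midpoint with sd = width/6, truncated to the central 80% of the
#' range: the configured extremes are treated as the observed min/max of a
#' cohort (approximately +/-3 sd tails), not as uniform bounds, so most
#' samplings sit near the center and the cohort still spans the envelope.
#' The scale preserves the shape of the profile; descriptors with
#' probability ~1 stay always-present and those with ~0 stay absent.
#'
#' @param n_subjects number of subjects (each sampled pre and post).
#' @param n_descriptors library size; default 761, the screening-library
#'   size of the sweat study the generator emulates.
#' @param site `"hand"` or `"breast"`.
#' @param replicates_per_sampling maximum technical replicates per sampling,
#'   in 1..4.
#' @param min_replicates minimum replicates per sampling; the count is drawn
#'   uniformly in `min_replicates:replicates_per_sampling`. Defaults to
#'   `replicates_per_sampling` (fixed count).
#' @param n_post_subjects number of subjects with a post-surgery sampling
#'   (subjects drop out after surgery); default all.
#' @param occurrence_profile per-descriptor occurrence probabilities; default
#'   [generate_occurrence_profile] under the config seed.
#' @param area_log_mean,area_log_sd natural-log mean and sd of present peak
#'   areas (arbitrary area units).
#' @param area_scale_spread per-measurement area-sum spread, in orders of
#'   magnitude (default 2).
#' @param batch_shift multiplicative log-scale offset of `column2` relative
#'   to `column1` (GC column replacement confound).
#' @param batch_jitter_sd per-descriptor log-scale jitter added to the batch
#'   shift; default `abs(batch_shift)/4`.
#' @param batch_fraction fraction of subjects assigned to `column2`
#'   (default 0: single batch).
#' @param planted_descriptors integer indices of descriptors carrying the
#'   pre/post effect.
#' @param effect_size log-scale abundance shift on planted descriptors in
#'   the `pre` status (random sign per descriptor).
#' @param dropout_shift occurrence-probability increase on planted
#'   descriptors in the `pre` status (clipped to \[0, 1\]).
#' @param nonzero_range length-2 target range of per-measurement non-zero
#'   counts.
#' @param replicate_noise_sd log-scale sd of replicate-to-replicate noise
#'   around the sampling-level areas (within-subject replicate correlation
#'   is not quantified in the source data; this knob exposes it).
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the config.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects,
                             n_descriptors = 761L,
                             site = "breast",
                             replicates_per_sampling = 4L,
                             min_replicates = replicates_per_sampling,
                             n_post_subjects = n_subjects,
                             occurrence_profile = NULL,
                             area_log_mean = 10,
                             area_log_sd = 1,
                             area_scale_spread = 2,
                             batch_shift = 0,
                             batch_jitter_sd = abs(batch_shift) / 4,
                             batch_fraction = 0,
                             planted_descriptors = integer(0),
                             effect_size = 0,
                             dropout_shift = 0,
                             nonzero_range = c(77L, 242L),
                             replicate_noise_sd = 0.25,
                             seed = 1L) {
  site <- match.arg(site, .voc_sites)
  stopifnot(n_subjects >= 1, n_descriptors >= 1,
            replicates_per_sampling >= 1, replicates_per_sampling <= 4,
            min_replicates >= 1, min_replicates <= replicates_per_sampling,
            n_post_subjects >= 0, n_post_subjects <= n_subjects,
            length(nonzero_range) == 2,
            nonzero_range[1] <= nonzero_range[2],
            nonzero_range[2] <= n_descriptors,
            batch_fraction >= 0, batch_fraction <= 1,
            area_scale_spread >= 0, replicate_noise_sd >= 0)
  planted_descriptors <- as.integer(planted_descriptors)
  if (length(planted_descriptors) &&
      (min(planted_descriptors) < 1 || max(planted_descriptors) > n_descriptors)) {
    stop("planted_descriptors out of range 1..", n_descriptors)
  }
  if (!is.null(occurrence_profile)) {
    stopifnot(length(occurrence_profile) == n_descriptors,
              all(occurrence_profile >= 0), all(occurrence_profile <= 1))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_descriptors = as.integer(n_descriptors),
    site = site, replicates_per_sampling = as.integer(replicates_per_sampling),
    min_replicates = as.integer(min_replicates),
    n_post_subjects = as.integer(n_post_subjects),
    occurrence_profile = occurrence_profile,
    area_log_mean = area_log_mean, area_log_sd = area_log_sd,
    area_scale_spread = area_scale_spread,
    batch_shift = batch_shift, batch_jitter_sd = batch_jitter_sd,
    batch_fraction = batch_fraction,
    planted_descriptors = planted_descriptors,
    effect_size = effect_size, dropout_shift = dropout_shift,
    nonzero_range = as.integer(nonzero_range),
    replicate_noise_sd = replicate_noise_sd,
    seed = as.integer(seed)), class = "generator_config")
}

# Solve sum(min(1, q * s)) = target over the richness scale s > 0
# (monotone non-decreasing in s, bounded above by the number of q > 0).
.presence_scale <- function(q, target) {
  f <- function(s) sum(pmin(1, q * s)) - target
  if (f(1e-6) > 0) return(1e-6)
  if (f(1e6) < 0) return(1e6)    # target above reachable mass
  uniroot(f, c(1e-6, 1e6), tol = 1e-8)$root
}

#' Generate a synthetic cohort
#'
#' Emits, for each subject, `pre` and (for the first `n_post_subjects`
#' subjects) `post` samplings with 1-4 technical replicates each, following
#' the zero-inflated log-normal model described in [generator_config].
#' Sampling-level abundances are drawn once per sampling and replicates add
#' log-scale noise around them, so technical replicates are correlated in
#' abundance; descriptor presence is drawn per replicate (each replicate is
#' a separate injection, and detection near the limit is stochastic per
#' chromatogram).
#'
#' @param config a [generator_config].
#' @return a raw [voc_dataset]; identical for identical configs (seed
#'   included).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    p <- config$n_descriptors
    lib <- voc_library(sprintf("d%03d", seq_len(p)))
    q <- config$occurrence_profile %||% rbeta(p, 0.25, 0.7)
    mu <- rnorm(p, 0, 1)                      # descriptor-level abundance offsets
    sgn <- sample(c(-1, 1), p, replace = TRUE) # planted effect direction
    bjit <- rnorm(p, 0, config$batch_jitter_sd)
    n2 <- round(config$batch_fraction * config$n_subjects)
    subj_batch <- rep(c("column2", "column1"),
                      c(n2, config$n_subjects - n2))[sample(config$n_subjects)]
    lo <- config$nonzero_range[1]; hi <- config$nonzero_range[2]
    mid <- (lo + hi) / 2; width <- hi - lo
    draw_target <- function() {
      t <- rnorm(1, mid, width / 6)
      min(max(t, lo + 0.1 * width), hi - 0.1 * width)
    }
    planted <- config$planted_descriptors
    rows <- list(); metas <- list()
    for (s in seq_len(config$n_subjects)) {
      statuses <- if (s <= config$n_post_subjects) c("pre", "post") else "pre"
      for (st in statuses) {
        target <- draw_target()
        s_rich <- .presence_scale(q, target)
        pi_s <- pmin(1, q * s_rich)
        if (st == "pre" && length(planted)) {
          # occurrence shift carries the same per-descriptor direction as the
          # abundance shift: a marker elevated pre-surgery is also detected
          # more often, a depleted one less often
          pi_s[planted] <- pmin(1, pmax(0, pi_s[planted] +
                                          sgn[planted] * config$dropout_shift))
        }
        la <- config$area_log_mean + mu + rnorm(p, 0, config$area_log_sd)
        if (st == "pre" && length(planted)) {
          la[planted] <- la[planted] + config$effect_size * sgn[planted]
        }
        if (subj_batch[s] == "column2") la <- la + config$batch_shift + bjit
        la <- la + runif(1, -config$area_scale_spread / 2,
                         config$area_scale_spread / 2) * log(10)
        n_rep <- if (config$min_replicates == config$replicates_per_sampling) {
          config$replicates_per_sampling
        } else {
          sample(config$min_replicates:config$replicates_per_sampling, 1)
        }
        for (r in seq_len(n_rep)) {
          # presence is drawn per replicate: peak detection near the limit is
          # stochastic per injection, while abundance is sampling-level
          present <- runif(p) < pi_s
          a <- exp(la + rnorm(p, 0, config$replicate_noise_sd)) * present
          rows[[length(rows) + 1L]] <- a
          metas[[length(metas) + 1L]] <- data.frame(
            subject_id = sprintf("S%03d", s), site = config$site, status = st,
            batch = subj_batch[s], replicate = r, stringsAsFactors = FALSE)
        }
      }
    }
    voc_dataset(do.call(rbind, rows), do.call(rbind, metas), lib, "raw")
  })
}

#' Generate a linked breast-like / hand-like cohort pair
#'
#' Two cohorts sized like the sweat study envelope (21 subjects pre-surgery,
#' 13 with a post-surgery sampling for the hand site; 20/12 for the breast
#' site; 3-4 technical replicates per sampling, so the pre class outnumbers
#' the post class), sharing a 761-descriptor library and a common U-shaped
#' occurrence profile. Each site carries its own planted marker set with a
#' configurable overlap fraction, and its own site-specific non-zero count
#' envelope (77-242 breast, 82-348 hand). Planted markers are drawn from
#' descriptors whose occurrence probability, after tilting the profile to
#' each site's typical non-zero count, lies in \[0.35, 0.9\] at both sites:
#' a biomarker must be detectable (but not saturated) to be discoverable,
#' so planting on effectively never-observed descriptors would encode no
#' signal.
#'
#' @param seed integer seed.
#' @param overlap fraction of the planted sets shared between sites, in
#'   \[0, 1\] (0 = disjoint markers, 1 = identical markers).
#' @param n_planted planted markers per site (default 40).
#' @param effect_size,dropout_shift planted-effect strength; defaults are a
#'   strong marker (about 12-fold abundance change plus a 0.25 occurrence
#'   shift), matching the clear pre/post separation the pipeline targets.
#' @param n_descriptors shared library size (default 761).
#' @return named list with `breast` and `hand` [voc_dataset]s; attributes
#'   `planted_breast` / `planted_hand` carry the planted index sets.
#' @export
make_study_cohort_pair <- function(seed = 1L, overlap = 0.2, n_planted = 40L,
                                 effect_size = 2.5, dropout_shift = 0.25,
                                 n_descriptors = 761L) {
  stopifnot(overlap >= 0, overlap <= 1, n_planted >= 1,
            2 * n_planted <= n_descriptors)
  seed <- as.integer(seed)
  q <- generate_occurrence_profile(n_descriptors, seed)
  detectable <- function(range) {
    s_mid <- .presence_scale(q, mean(range))
    pi_mid <- pmin(1, q * s_mid)
    which(pi_mid >= 0.35 & pi_mid <= 0.9)
  }
  eligible <- intersect(detectable(c(77, 242)), detectable(c(82, 348)))
  shared_n <- round(overlap * n_planted)
  if (length(eligible) < 2L * n_planted - shared_n) {
    stop("too few detectable descriptors to plant ", n_planted, " markers")
  }
  idx <- withr::with_seed(seed + 2L,
                          sample(eligible, 2L * n_planted - shared_n))
  planted_breast <- sort(idx[seq_len(n_planted)])
  planted_hand <- sort(c(idx[seq_len(shared_n)],
                         idx[seq.int(n_planted + 1L, length.out = n_planted - shared_n)]))
  breast <- generate_cohort(generator_config(
    n_subjects = 20L, n_post_subjects = 12L, n_descriptors = n_descriptors,
    site = "breast", replicates_per_sampling = 4L, min_replicates = 3L,
    occurrence_profile = q,
    nonzero_range = c(77L, 242L), planted_descriptors = planted_breast,
    effect_size = effect_size, dropout_shift = dropout_shift,
    seed = seed))
  hand <- generate_cohort(generator_config(
    n_subjects = 21L, n_post_subjects = 13L, n_descriptors = n_descriptors,
    site = "hand", replicates_per_sampling = 4L, min_replicates = 3L,
    occurrence_profile = q,
    nonzero_range = c(82L, 348L), planted_descriptors = planted_hand,
    effect_size = effect_size, dropout_shift = dropout_shift,
    seed = seed + 1L))
  structure(list(breast = breast, hand = hand),
            planted_breast = planted_breast, planted_hand = planted_hand)
}
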