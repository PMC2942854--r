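# default 21-IL genotype panel: introgressions on chromosomes
# 1, 2, 3, 5, 8, 10, 11, 12, with chromosome 12 carrying four lines
default_il_panel <- function() {
  c("1-1", "1-2",
    "2-1", "2-2", "2-3",
    "3-1", "3-2",
    "5-1", "5-2", "5-3",
    "8-1", "8-2", "8-3",
    "10-1", "10-2",
    "11-1", "11-2",
    "12-1-1", "12-1", "12-2", "12-3")
}

#' Specification for a synthetic introgression-line dataset
#'
#' Describes an IL-style profiling study with planted structure: `G`
#' co-regulated groups, each sharing a latent genotype profile; group
#' members follow the latent profile up to a within-group correlation,
#' plus replicate-level measurement noise and random replicate dropout
#' (which produces pseudo-zeros).  In `cross_relation_fraction` of the
#' groups the metabolite members anti-correlate with the transcripts
#' (sign -1), modelling cross relations (up-regulated transcripts with
#' down-regulated metabolites).  All remaining entities are unstructured
#' background.
#'
#' Defaults emulate the shape of a tomato IL fruit study: 21 genotypes
#' named by chromosome segment, 1385 transcripts and 71 metabolites,
#' tightly co-regulated groups (correlation 0.95),
#' ~12% CV technical replicate noise (sd 0.05 on the log10 scale),
#' 3 replicates, 5% replicate dropout.
#'
#' @param P number of genotypes; `genotype_names` must have length `P`.
#' @param genotype_names genotype identifiers with chromosome tags.
#' @param n_transcripts,n_metabolites entity counts.
#' @param G number of planted groups.
#' @param group_transcripts,group_metabolites members per group by kind
#'   (every group mixes kinds by default).
#' @param within_cor within-group correlation of member profiles, in
#'   (0, 1].
#' @param noise_sd replicate noise sd on the log10-ratio scale.
#' @param missing_rate per-replicate dropout probability, in [0, 1).
#' @param n_replicates replicates drawn per (entity, genotype).
#' @param cross_relation_fraction fraction of groups whose metabolites
#'   get sign -1.
#' @param amplitude root-mean-square log10 ratio of the latent profiles.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(P = 21L, genotype_names = default_il_panel(),
                       n_transcripts = 1385L, n_metabolites = 71L,
                       G = 6L, group_transcripts = 5L,
                       group_metabolites = 2L,
                       within_cor = 0.95, noise_sd = 0.05,
                       missing_rate = 0.05, n_replicates = 3L,
                       cross_relation_fraction = 1 / 3,
                       amplitude = 0.4, seed = 1L) {
  stopifnot(length(genotype_names) == P,
            within_cor > 0, within_cor <= 1,
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1,
            n_replicates >= 1L, G >= 1L,
            group_transcripts + group_metabolites >= 2L)
  if (G * group_transcripts > n_transcripts ||
      G * group_metabolites > n_metabolites)
    stopf("groups larger than the entity budget (%d groups x (%d t + %d m) vs %d t, %d m)",
          G, group_transcripts, group_metabolites, n_transcripts, n_metabolites)
  if (group_metabolites < 1L && group_transcripts < 1L)
    stopf("each group needs at least one member")
  structure(list(P = as.integer(P), genotype_names = genotype_names,
                 n_transcripts = as.integer(n_transcripts),
                 n_metabolites = as.integer(n_metabolites),
                 G = as.integer(G),
                 group_transcripts = as.integer(group_transcripts),
                 group_metabolites = as.integer(group_metabolites),
                 within_cor = within_cor, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 n_replicates = as.integer(n_replicates),
                 cross_relation_fraction = cross_relation_fraction,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic replicate-level dataset with planted groups
#'
#' Latent group profiles are drawn Gaussian and decorrelated
#' (orthonormalized), then scaled to the spec amplitude.  Member entity
#' profiles are `sign * (sqrt(rho) * latent + sqrt(1 - rho) * eta)`
#' with `eta` an independent profile of the same scale, giving expected
#' within-group correlation `rho`.  Background entities are pure `eta`.
#' Each (entity, genotype) yields `n_replicates` Bernoulli-thinned
#' replicate ratios `10^(profile + N(0, noise_sd))`; genotypes losing
#' too many replicates surface downstream as pseudo-zeros.
#'
#' @param spec a [synth_spec()].
#' @return list with `replicates` (data.frame `entity_id`, `kind`,
#'   `genotype`, `ratio`), `truth` (data.frame `entity_id`, `kind`,
#'   `group` (`NA` for background), `sign_in_group`, plus a
#'   `cross_group` flag), and `profiles` (the noise-free log10 entity
#'   profiles, entities x genotypes).
#' @export
synth_generate <- function(spec) {
  with_seed(spec$seed, {
    P <- spec$P
    ids <- c(sprintf("TR%04d", seq_len(spec$n_transcripts)),
             sprintf("MET%03d", seq_len(spec$n_metabolites)))
    kinds <- c(rep("transcript", spec$n_transcripts),
               rep("metabolite", spec$n_metabolites))
    n <- length(ids)

    # orthonormal latent profiles, scaled to per-component rms `amplitude`
    Q <- qr.Q(qr(matrix(stats::rnorm(P * spec$G), P, spec$G)))
    latent <- t(Q) * sqrt(P) * spec$amplitude   # G x P

    group <- rep(NA_integer_, n)
    sign_in_group <- rep(1, n)
    t_pool <- seq_len(spec$n_transcripts)
    m_pool <- spec$n_transcripts + seq_len(spec$n_metabolites)
    n_cross <- round(spec$G * spec$cross_relation_fraction)
    cross_groups <- seq_len(spec$G) <= n_cross
    for (g in seq_len(spec$G)) {
      ti <- t_pool[seq_len(spec$group_transcripts) +
                     (g - 1L) * spec$group_transcripts]
      mi <- m_pool[seq_len(spec$group_metabolites) +
                     (g - 1L) * spec$group_metabolites]
      group[c(ti, mi)] <- g
      if (cross_groups[g]) sign_in_group[mi] <- -1
    }

    rho <- spec$within_cor
    profiles <- matrix(0, n, P)
    for (i in seq_len(n)) {
      eta <- stats::rnorm(P, 0, spec$amplitude)
      profiles[i, ] <- if (is.na(group[i])) eta
        else sign_in_group[i] *
          (sqrt(rho) * latent[group[i], ] + sqrt(1 - rho) * eta)
    }

    total <- n * P * spec$n_replicates
    detected <- stats::runif(total) >= spec$missing_rate
    noise <- stats::rnorm(total, 0, spec$noise_sd)
    ent_idx <- rep(seq_len(n), each = P * spec$n_replicates)
    gen_idx <- rep(rep(seq_len(P), each = spec$n_replicates), times = n)
    ratio <- 10^(profiles[cbind(ent_idx, gen_idx)] + noise)
    replicates <- data.frame(
      entity_id = ids[ent_idx][detected],
      kind = kinds[ent_idx][detected],
      genotype = spec$genotype_names[gen_idx][detected],
      ratio = ratio[detected],
      stringsAsFactors = FALSE
    )
    truth <- data.frame(entity_id = ids, kind = kinds, group = group,
                        sign_in_group = sign_in_group,
                        cross_group = !is.na(group) & cross_groups[pmax(group, 1L)],
                        stringsAsFactors = FALSE)
    list(replicates = replicates, truth = truth, profiles = profiles)
  })
}
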