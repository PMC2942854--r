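#' Locate entities on a trained map
#'
#' Exact entity-identifier match first; if nothing matches, a
#' case-insensitive substring fallback (so `"aspartic"` finds
#' `"L-aspartic acid"`).  Both signs of a matched entity are reported.
#'
#' @param name entity identifier or fragment.
#' @param assignment a [assign_patterns()] result.
#' @param dataset the assigned [profile_dataset()].
#' @return data.frame with columns `entity_id`, `kind`, `sign`, `unit`;
#'   zero rows (with a message) when nothing matches.
#' @export
search_entities <- function(name, assignment, dataset) {
  hit <- dataset$entity_id == name
  if (!any(hit))
    hit <- grepl(tolower(name), tolower(dataset$entity_id), fixed = TRUE)
  if (!any(hit)) {
    message(sprintf("no entity matching '%s'", name))
    return(data.frame(entity_id = character(0), kind = character(0),
                      sign = character(0), unit = integer(0)))
  }
  data.frame(entity_id = dataset$entity_id[hit],
             kind = dataset$kind[hit],
             sign = dataset$sign[hit],
             unit = assignment$bmu[hit],
             stringsAsFactors = FALSE)
}

# units within Chebyshev grid radius vn of `unit` (square ring pooling)
pooled_units <- function(unit, map, vn) {
  if (vn == 0) return(unit)
  gc <- map$grid
  sel <- pmax(abs(gc[, "row"] - gc[unit, "row"]),
              abs(gc[, "col"] - gc[unit, "col"])) <= vn
  which(sel)
}

#' Classify the data-type composition of a neuron
#'
#' Pools membership over all units within Chebyshev grid radius `vn` of
#' the unit (the visualization neighborhood: pooled units are treated as
#' one group, including for counting whether both data types are
#' grouped), then classifies: `mixed` (black) when both transcripts and
#' metabolites are present, `transcripts_only` (red), `metabolites_only`
#' (blue), or `empty`.
#'
#' @param unit unit index.
#' @param assignment a [assign_patterns()] result.
#' @param dataset the assigned [profile_dataset()].
#' @param map the trained `som_map`.
#' @param vn visualization-neighborhood radius (non-negative integer).
#' @return One of `"empty"`, `"transcripts_only"`, `"metabolites_only"`,
#'   `"mixed"`.
#' @export
classify_composition <- function(unit, assignment, dataset, map, vn = 0L) {
  stopifnot(vn >= 0)
  members <- assignment$bmu %in% pooled_units(unit, map, vn)
  nt <- sum(members & dataset$kind == "transcript")
  nm <- sum(members & dataset$kind == "metabolite")
  if (nt == 0 && nm == 0) "empty"
  else if (nt > 0 && nm > 0) "mixed"
  else if (nt > 0) "transcripts_only"
  else "metabolites_only"
}

#' Intracluster cohesion of a neuron
#'
#' Mean squared Euclidean distance of the unit's member patterns to its
#' codebook vector; values close to 0 indicate a compact node.  With
#' pseudo-zeros, each member's squared distance is summed over its valid
#' components and rescaled by `P / n_valid` so that partially observed
#' members remain comparable to fully observed ones.
#'
#' @param unit unit index.
#' @param assignment a [assign_patterns()] result.
#' @param dataset the assigned [profile_dataset()].
#' @param map the trained `som_map`.
#' @return Non-negative scalar, or `NA_real_` for an empty unit
#'   (cohesion is undefined there, never 0).
#' @export
cohesion <- function(unit, assignment, dataset, map) {
  members <- which(assignment$bmu == unit)
  if (!length(members)) return(NA_real_)
  P <- n_genotypes(dataset)
  w <- map$codebook[unit, ]
  sq <- vapply(members, function(i) {
    v <- dataset$validity[i, ]
    sum(((dataset$values[i, ] - w)[v])^2) * P / sum(v)
  }, numeric(1))
  mean(sq)
}

#' Global map compactness
#'
#' Unweighted mean of the per-unit cohesions over nonempty units (empty
#' units have no defined cohesion and do not enter the average).
#'
#' @param cohesions numeric vector of per-unit cohesions, `NA` for
#'   empty units.
#' @return Non-negative scalar.
#' @export
global_compactness <- function(cohesions) {
  if (all(is.na(cohesions))) stopf("no nonempty unit")
  mean(cohesions, na.rm = TRUE)
}

#' Per-neuron membership and quality report
#'
#' One row per nonempty unit: grid position, member counts by kind,
#' composition at the requested pooling radius, cohesion, and the
#' member labels.
#'
#' @inheritParams classify_composition
#' @return data.frame with columns `unit`, `row`, `col`,
#'   `n_transcripts`, `n_metabolites`, `n_members`, `composition`,
#'   `cohesion`, `members`.
#' @export
neuron_report <- function(assignment, dataset, map, vn = 0L) {
  units <- sort(unique(assignment$bmu))
  lab <- pattern_labels(dataset$entity_id, dataset$sign)
  rows <- lapply(units, function(u) {
    m <- which(assignment$bmu == u)
    data.frame(
      unit = u,
      row = map$grid[u, "row"],
      col = map$grid[u, "col"],
      n_transcripts = sum(dataset$kind[m] == "transcript"),
      n_metabolites = sum(dataset$kind[m] == "metabolite"),
      n_members = length(m),
      composition = classify_composition(u, assignment, dataset, map, vn),
      cohesion = cohesion(u, assignment, dataset, map),
      members = paste(lab[m], collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-color per-genotype deviation map
#'
#' For every genotype dimension and every nonempty unit, the unit is
#' painted green when at least one member value (valid entries only)
#' exceeds the member mean plus one standard deviation in that
#' dimension; otherwise gray when at least one member value falls below
#' the mean minus one standard deviation; otherwise white.  Empty units
#' and single-member units (standard deviation 0, population form) are
#' white.  The classification is invariant under positive rescaling of
#' a genotype dimension.
#'
#' @param assignment a [assign_patterns()] result.
#' @param dataset the assigned [profile_dataset()].
#' @param map the trained `som_map`.
#' @return An object of class `three_color_map`: list with `colors`
#'   (character matrix, units x genotypes, entries in
#'   `{"green","gray","white"}`), `genotypes`, and the map grid.
#' @export
three_color_map <- function(assignment, dataset, map) {
  K <- nrow(map$codebook)
  P <- n_genotypes(dataset)
  colors <- matrix("white", K, P)
  for (u in unique(assignment$bmu)) {
    m <- which(assignment$bmu == u)
    for (p in seq_len(P)) {
      v <- dataset$values[m, p][dataset$validity[m, p]]
      if (length(v) < 1L) next
      mu <- mean(v)
      sd_pop <- sqrt(mean((v - mu)^2))
      colors[u, p] <-
        if (any(v > mu + sd_pop)) "green"
        else if (any(v < mu - sd_pop)) "gray"
        else "white"
    }
  }
  structure(list(colors = colors, genotypes = dataset$genotypes,
                 grid = map$grid), class = "three_color_map")
}

#' Units holding pseudo-zero patterns
#'
#' Lists every unit containing at least one pattern whose measurements
#' are invalid in some genotype but valid in at least one other (e.g. a
#' metabolite undetectable in a specific genotype while well measured
#' elsewhere).  Patterns invalid everywhere never reach the map; they
#' are dropped during preprocessing.
#'
#' @param assignment a [assign_patterns()] result.
#' @param dataset the assigned [profile_dataset()].
#' @return data.frame with columns `unit`, `entity_id`, `kind`, `sign`,
#'   `missing_genotypes` (semicolon-joined names).
#' @export
pseudo_zero_neurons <- function(assignment, dataset) {
  part <- which(apply(!dataset$validity, 1L, any) &
                apply(dataset$validity, 1L, any))
  if (!length(part))
    return(data.frame(unit = integer(0), entity_id = character(0),
                      kind = character(0), sign = character(0),
                      missing_genotypes = character(0)))
  out <- data.frame(
    unit = assignment$bmu[part],
    entity_id = dataset$entity_id[part],
    kind = dataset$kind[part],
    sign = dataset$sign[part],
    missing_genotypes = vapply(part, function(i)
      paste(dataset$genotypes[!dataset$validity[i, ]], collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE
  )
  out[order(out$unit), , drop = FALSE]
}

#' Restrict a dataset to the introgression lines of one chromosome
#'
#' Genotype names of the form `"12-1-1"` carry the chromosome as their
#' leading tag; this selects the genotype dimensions of one chromosome
#' (e.g. chromosome 12 keeps ILs 12-1-1, 12-1, 12-2, 12-3 on the
#' case-study naming), for per-IL three-color views.
#'
#' @param dataset a [profile_dataset()].
#' @param chromosome chromosome identifier (e.g. `"12"` or `12`).
#' @return A [profile_dataset()] restricted to those genotype
#'   dimensions (values are left as-is; re-normalize if the subset is to
#'   be re-trained).
#' @export
chromosome_subset <- function(dataset, chromosome) {
  chrom <- chromosome_of(dataset$genotypes)
  sel <- which(chrom == as.character(chromosome))
  if (!length(sel))
    stopf("no genotype on chromosome '%s'; available: %s", chromosome,
          paste(sort(unique(stats::na.omit(chrom))), collapse = ", "))
  profile_dataset(
    genotypes = dataset$genotypes[sel],
    entity_id = dataset$entity_id,
    kind = dataset$kind,
    sign = dataset$sign,
    values = dataset$values[, sel, drop = FALSE],
    validity = dataset$validity[, sel, drop = FALSE],
    raw_values = if (!is.null(dataset$raw_values))
      dataset$raw_values[, sel, drop = FALSE]
  )
}

#' Within-group co-location of known entity groups on the map
#'
#' Validation helper for datasets with known (e.g. planted) co-regulated
#' groups: the fraction of within-group entity pairs whose sign-aligned
#' patterns fall inside a common pooling neighborhood of radius `vn`
#' (grid Chebyshev distance at most `2 * vn`; at `vn = 0`, the same
#' unit).  Sign-aligned means the original pattern for members with
#' group sign +1 and the inverted twin for anti-correlated members, so
#' cross-relation groups are scored on the co-clustering the inversion
#' augmentation is designed to expose.
#'
#' @param assignment a [assign_patterns()] result.
#' @param dataset the assigned, inversion-closed [profile_dataset()].
#' @param map the trained `som_map`.
#' @param truth data.frame with columns `entity_id`, `group` (`NA` for
#'   ungrouped entities) and `sign_in_group` (+1/-1), as produced by
#'   [synth_generate()].
#' @param vn pooling radius.
#' @return list with `fraction` (co-located share of within-group
#'   pairs), `n_pairs`, and `per_group` (named fraction per group).
#' @export
group_colocation <- function(assignment, dataset, map, truth, vn = 1L) {
  truth <- truth[!is.na(truth$group), , drop = FALSE]
  groups <- sort(unique(truth$group))
  per_group <- numeric(length(groups))
  ok <- 0L; tot <- 0L
  for (gi in seq_along(groups)) {
    mem <- truth[truth$group == groups[gi], , drop = FALSE]
    bmu <- vapply(seq_len(nrow(mem)), function(k) {
      sgn <- if (mem$sign_in_group[k] >= 0) "original" else "inverted"
      i <- which(dataset$entity_id == mem$entity_id[k] &
                   dataset$sign == sgn)
      if (!length(i)) return(NA_integer_)  # filtered out upstream
      assignment$bmu[i[1L]]
    }, integer(1))
    bmu <- bmu[!is.na(bmu)]
    if (length(bmu) < 2L) { per_group[gi] <- NA_real_; next }
    g_ok <- 0L; g_tot <- 0L
    for (a in seq_along(bmu)) for (b in seq_along(bmu)) if (a < b) {
      cheb <- max(abs(map$grid[bmu[a], ] - map$grid[bmu[b], ]))
      g_tot <- g_tot + 1L
      if (cheb <= 2L * vn) g_ok <- g_ok + 1L
    }
    per_group[gi] <- g_ok / g_tot
    ok <- ok + g_ok; tot <- tot + g_tot
  }
  names(per_group) <- groups
  list(fraction = if (tot) ok / tot else NA_real_, n_pairs = tot,
       per_group = per_group)
}

# unit at the 180-degree-rotated grid position (rows+1-r, cols+1-c)
mirror_unit <- function(unit, map) {
  r <- map$config$rows; c <- map$config$cols
  unit_index(r + 1L - map$grid[unit, "row"],
             c + 1L - map$grid[unit, "col"], r)
}

#' Mirror symmetry of an inversion-closed map
#'
#' On inversion-closed data a converged map is negation-symmetric: the
#' top-right and bottom-left zones group the same data with opposite
#' sign, and each pattern's inverted twin should land on the
#' 180-degree-rotated image of the pattern's unit.  Reports the
#' fraction of original/inverted pairs whose BMUs are exact mirror
#' images, plus the per-pair Chebyshev grid displacement from the
#' perfect mirror position.
#'
#' @param assignment a [assign_patterns()] result.
#' @param dataset the assigned, inversion-closed [profile_dataset()].
#' @param map the trained `som_map`.
#' @return list with `fraction` (in `[0, 1]`), and `pairs` (data.frame
#'   `entity_id`, `unit_original`, `unit_inverted`, `mirror_of_original`,
#'   `displacement`).
#' @export
symmetry_report <- function(assignment, dataset, map) {
  if (!is_inversion_closed(dataset))
    stopf("symmetry_report requires an inversion-closed dataset")
  pairs <- inversion_pairs(dataset)
  u_o <- assignment$bmu[pairs$original]
  u_i <- assignment$bmu[pairs$inverted]
  mir <- vapply(u_o, mirror_unit, integer(1), map = map)
  disp <- pmax(abs(map$grid[u_i, "row"] - map$grid[mir, "row"]),
               abs(map$grid[u_i, "col"] - map$grid[mir, "col"]))
  list(
    fraction = mean(u_i == mir),
    pairs = data.frame(
      entity_id = dataset$entity_id[pairs$original],
      unit_original = u_o,
      unit_inverted = u_i,
      mirror_of_original = as.integer(mir),
      displacement = as.integer(disp),
      stringsAsFactors = FALSE
    )
  )
}
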