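# shared trained fixture: small inversion-closed dataset on a 4x4 map
fix_ds <- random_closed_dataset(n_transcripts = 8L, n_metabolites = 4L,
                                P = 5L, seed = 71)
fix_fit <- train_tiny(fix_ds)

test_that("search finds entities exactly, by substring, and on both signs", {
  res <- search_entities("MET001", fix_fit$assignment, fix_ds)
  expect_setequal(res$sign, c("original", "inverted"))
  expect_true(all(res$entity_id == "MET001"))
  i_orig <- which(fix_ds$entity_id == "MET001" & fix_ds$sign == "original")
  expect_true(fix_fit$assignment$bmu[i_orig] %in%
                res$unit[res$sign == "original"])
  # unknown names give an empty result with a message, not an error
  expect_message(res0 <- search_entities("nosuchthing",
                                         fix_fit$assignment, fix_ds),
                 "no entity matching")
  expect_identical(nrow(res0), 0L)
  # case-insensitive substring fallback
  ds <- tiny_dataset()
  fit <- train_tiny(augment_inverted(ds))
  res <- search_entities("aspartic", fit$assignment, augment_inverted(ds))
  expect_true(all(res$entity_id == "L-aspartic acid"))
  expect_identical(nrow(res), 2L)
})

test_that("composition pools over the Vn neighborhood and is monotone", {
  # hand-built assignment on a 3x3 map: 2 transcripts in unit 1,
  # 1 metabolite in unit 2 (grid-adjacent), nothing elsewhere
  cb <- matrix(0, 9, 2)
  map <- ilsom:::new_som_map(som_config(rows = 3L, cols = 3L, n_epochs = 1L,
                                        radius_schedule = 1), cb)
  ds <- profile_dataset(genotypes = c("IL_1", "IL_2"),
                        entity_id = c("t1", "t2", "m1"),
                        kind = c("transcript", "transcript", "metabolite"),
                        sign = "original",
                        values = matrix(rnorm(6), 3))
  asg <- structure(list(bmu = c(1L, 1L, 2L), distance = rep(0, 3)),
                   class = "som_assignment")
  expect_identical(classify_composition(1L, asg, ds, map, vn = 0L),
                   "transcripts_only")
  expect_identical(classify_composition(2L, asg, ds, map, vn = 0L),
                   "metabolites_only")
  expect_identical(classify_composition(1L, asg, ds, map, vn = 1L), "mixed")
  expect_identical(classify_composition(5L, asg, ds, map, vn = 0L), "empty")
  # Vn beyond the map diameter gives every unit the global composition
  for (u in 1:9)
    expect_identical(classify_composition(u, asg, ds, map, vn = 10L), "mixed")
  # monotonicity: growing Vn never turns mixed into non-mixed
  for (u in sort(unique(fix_fit$assignment$bmu))) {
    prev_mixed <- FALSE
    for (vn in 0:3) {
      comp <- classify_composition(u, fix_fit$assignment, fix_ds,
                                   fix_fit$map, vn)
      if (prev_mixed) expect_identical(comp, "mixed")
      prev_mixed <- comp == "mixed"
    }
  }
  # at Vn = 0 nonempty units partition into the three nonempty classes
  comps <- vapply(sort(unique(fix_fit$assignment$bmu)),
                  classify_composition, character(1),
                  assignment = fix_fit$assignment, dataset = fix_ds,
                  map = fix_fit$map, vn = 0L)
  expect_true(all(comps %in% c("transcripts_only", "metabolites_only",
                               "mixed")))
})

test_that("cohesion matches the hand example and brute force", {
  # members (0,0) and (2,0) around codebook (1,0): (1 + 1) / 2 = 1
  cb <- rbind(c(1, 0), c(5, 5))
  map <- ilsom:::new_som_map(som_config(rows = 2L, cols = 1L, n_epochs = 1L,
                                        radius_schedule = 1), cb)
  ds <- profile_dataset(genotypes = c("IL_1", "IL_2"),
                        entity_id = c("a", "b"), kind = "transcript",
                        sign = "original", values = rbind(c(0, 0), c(2, 0)))
  asg <- structure(list(bmu = c(1L, 1L), distance = c(1, 1)),
                   class = "som_assignment")
  expect_identical(cohesion(1L, asg, ds, map), 1)
  # empty unit: undefined, reported as NA (absent), never 0
  expect_identical(cohesion(2L, asg, ds, map), NA_real_)
  # members equal to the codebook give cohesion 0
  ds0 <- profile_dataset(genotypes = c("IL_1", "IL_2"),
                         entity_id = c("a", "b"), kind = "transcript",
                         sign = "original", values = rbind(c(1, 0), c(1, 0)))
  expect_identical(cohesion(1L, asg, ds0, map), 0)
  # random instances against the brute-force oracle (with masks)
  set.seed(81)
  for (rep in 1:20) {
    ds <- random_closed_dataset(P = 4L, seed = rep, missing_frac = 0.2)
    fit <- train_tiny(ds, rows = 3L, cols = 3L, n_epochs = 4L)
    for (u in unique(fit$assignment$bmu))
      expect_equal(cohesion(u, fit$assignment, ds, fit$map),
                   cohesion_bruteforce(u, fit$assignment$bmu, ds$values,
                                       ds$validity, fit$map$codebook))
  }
})

test_that("global compactness averages nonempty units, label-invariantly", {
  expect_identical(global_compactness(c(1, 3)), 2)
  expect_identical(global_compactness(c(NA, 1, NA, 3)), 2)
  expect_identical(global_compactness(c(0, 0, NA)), 0)
  set.seed(5)
  coh <- c(runif(6), NA, NA)
  expect_equal(global_compactness(sample(coh)), global_compactness(coh))
  expect_error(global_compactness(c(NA_real_, NA_real_)), "no nonempty")
})

test_that("the three-color rule paints green, gray, white as specified", {
  cb <- matrix(0, 4, 1)
  map <- ilsom:::new_som_map(som_config(rows = 2L, cols = 2L, n_epochs = 1L,
                                        radius_schedule = 1), cb)
  mk <- function(vals) profile_dataset(
    genotypes = "IL_1", entity_id = paste0("e", seq_along(vals)),
    kind = "transcript", sign = "original", values = matrix(vals))
  asg <- function(n) structure(list(bmu = rep(1L, n), distance = rep(0, n)),
                               class = "som_assignment")
  # {0, 0, 10}: 10 > mean + sd -> green
  tcm <- three_color_map(asg(3), mk(c(0, 0, 10)), map)
  expect_identical(tcm$colors[1, 1], "green")
  # all-equal members: sd 0, no exceedance -> white
  tcm <- three_color_map(asg(3), mk(c(2, 2, 2)), map)
  expect_identical(tcm$colors[1, 1], "white")
  # single member -> white
  tcm <- three_color_map(asg(1), mk(5), map)
  expect_identical(tcm$colors[1, 1], "white")
  # a low outlier without a high one -> gray
  tcm <- three_color_map(asg(4), mk(c(0, 0, 0.2, -10)), map)
  expect_identical(tcm$colors[1, 1], "gray")
  # empty units stay white, domain is exactly {green, gray, white}
  expect_true(all(tcm$colors %in% c("green", "gray", "white")))
  expect_true(all(tcm$colors[2:4, ] == "white"))
})

test_that("three-color classification is scale-equivariant per genotype", {
  tcm1 <- three_color_map(fix_fit$assignment, fix_ds, fix_fit$map)
  scaled <- fix_ds
  scaled$values[, 2] <- scaled$values[, 2] * 7
  tcm2 <- three_color_map(fix_fit$assignment, scaled, fix_fit$map)
  expect_identical(tcm1$colors, tcm2$colors)
})

test_that("pseudo-zero units list partially missing patterns only", {
  expect_identical(nrow(pseudo_zero_neurons(fix_fit$assignment, fix_ds)), 0L)
  ds <- fix_ds
  i <- which(ds$entity_id == "MET002" & ds$sign == "original")
  ds$validity[i, 3] <- FALSE
  pz <- pseudo_zero_neurons(fix_fit$assignment, ds)
  expect_identical(unique(pz$entity_id), "MET002")
  expect_identical(unique(pz$missing_genotypes), "IL_3")
  expect_identical(sort(pz$unit), sort(fix_fit$assignment$bmu[i]))
})

test_that("chromosome subsetting follows the IL naming convention", {
  spec <- synth_spec(seed = 1)
  ds <- profile_dataset(genotypes = spec$genotype_names,
                        entity_id = "x", kind = "transcript",
                        sign = "original",
                        values = matrix(rnorm(21), 1))
  ch12 <- chromosome_subset(ds, 12)
  expect_identical(ch12$genotypes, c("12-1-1", "12-1", "12-2", "12-3"))
  expect_identical(ncol(ch12$values), 4L)
  # one-IL chromosomes restrict to P' = 1
  ds2 <- chromosome_subset(profile_dataset(
    genotypes = c("7-1", "9-1"), entity_id = "x", kind = "transcript",
    sign = "original", values = matrix(c(1, 2), 1)), "7")
  expect_identical(n_genotypes(ds2), 1L)
  # the case-study chromosome list covers all 21 genotype dimensions
  covered <- unlist(lapply(c(1, 2, 3, 5, 8, 10, 11, 12), function(ch)
    chromosome_subset(ds, ch)$genotypes))
  expect_setequal(covered, spec$genotype_names)
  expect_identical(length(covered), 21L)
  expect_error(chromosome_subset(ds, "4"), "available: .*12")
})

test_that("symmetry is reported against the 180-degree mirror", {
  sr <- symmetry_report(fix_fit$assignment, fix_ds, fix_fit$map)
  expect_true(sr$fraction >= 0 && sr$fraction <= 1)
  expect_identical(nrow(sr$pairs), n_patterns(fix_ds) %/% 2L)
  # displacement is 0 exactly for the matching pairs
  expect_identical(sr$pairs$displacement == 0L,
                   sr$pairs$unit_inverted == sr$pairs$mirror_of_original)
  # invariant under global negation of the dataset (twins swap roles)
  neg <- fix_ds
  neg$values <- -neg$values
  neg$sign <- ifelse(neg$sign == "original", "inverted", "original")
  asg_neg <- assign_patterns(neg, fix_fit$map)
  expect_equal(symmetry_report(asg_neg, neg, fix_fit$map)$fraction,
               sr$fraction)
  # a non-closed dataset is rejected
  expect_error(symmetry_report(fix_fit$assignment,
                               subset_orig <- ilsom:::subset_patterns(
                                 fix_ds, which(fix_ds$sign == "original")),
                               fix_fit$map),
               "inversion-closed")
})
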