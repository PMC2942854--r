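test_that("the Gaussian neighborhood kernel matches its closed form", {
  expect_equal(gaussian_neighborhood(0, 3), 1)
  expect_equal(gaussian_neighborhood(2, 2), exp(-1 / 2))
  # monotone decreasing in delta for fixed r
  g <- gaussian_neighborhood(seq(0, 10, by = 0.5), r = 2)
  expect_true(all(diff(g) < 0))
  # r = 0 degenerates to winner-takes-all
  expect_identical(gaussian_neighborhood(c(0, 1, 2), 0), c(1, 0, 0))
})

test_that("find_bmu agrees with exhaustive search, including masks", {
  set.seed(101)
  for (rep in 1:25) {
    P <- sample(3:8, 1)
    K <- sample(4:12, 1)
    cb <- matrix(rnorm(K * P), K, P)
    map <- ilsom:::new_som_map(som_config(rows = K, cols = 1L,
                                          n_epochs = 1L,
                                          radius_schedule = 1), cb)
    x <- rnorm(P)
    v <- runif(P) > 0.3
    if (!any(v)) v[1] <- TRUE
    expect_identical(find_bmu(x, map, v), bmu_bruteforce(x, v, cb))
  }
  # a pattern equal to a codebook vector maps to it with distance 0
  cb <- diag(4)
  map <- ilsom:::new_som_map(som_config(rows = 2L, cols = 2L, n_epochs = 1L,
                                        radius_schedule = 1), cb)
  expect_identical(find_bmu(cb[3, ], map), 3L)
  # masking a discriminating component can change the BMU
  cb <- rbind(c(0, 0), c(10, 0.5))
  map <- ilsom:::new_som_map(som_config(rows = 2L, cols = 1L, n_epochs = 1L,
                                        radius_schedule = 1), cb)
  x <- c(10, 0)
  expect_identical(find_bmu(x, map), 2L)
  expect_identical(find_bmu(x, map, c(FALSE, TRUE)), 1L)
})

test_that("PCA initialization is deterministic and symmetric for closed data", {
  ds <- random_closed_dataset(seed = 21)
  cfg <- som_config(rows = 5L, cols = 4L, n_epochs = 5L)
  m1 <- init_pca(ds, cfg)
  m2 <- init_pca(ds, cfg)
  expect_identical(m1$codebook, m2$codebook)
  # inversion-closed data: zero mean, codebook negation-symmetric under
  # 180-degree grid rotation
  expect_equal(max(abs(colMeans(ds$values))), 0)
  for (u in seq_len(nrow(m1$codebook))) {
    mu <- ilsom:::mirror_unit(u, m1)
    expect_equal(m1$codebook[u, ], -m1$codebook[mu, ], tolerance = 1e-12)
  }
})

test_that("a 2x1 map separates two orthogonal clusters along PC1", {
  vals <- rbind(c(1, 0), c(1.1, 0), c(-1, 0), c(-1.1, 0))
  ds <- profile_dataset(genotypes = c("IL_1", "IL_2"),
                        entity_id = paste0("T", 1:4),
                        kind = "transcript", sign = "original",
                        values = vals)
  cfg <- som_config(rows = 1L, cols = 2L, n_epochs = 1L,
                    radius_schedule = 0)
  map <- suppressWarnings(init_pca(ds, cfg))  # rank-1 configuration
  # PC1 of this configuration is the first axis; the two codebook
  # vectors sit at +/- sd1 along it
  expect_equal(map$codebook[, 2], c(0, 0), tolerance = 1e-12)
  expect_equal(sort(map$codebook[, 1]), c(-1, 1) * sd(vals[, 1]),
               tolerance = 1e-12)
})

test_that("rank-deficient data fall back to a PC1-only init with warning", {
  vals <- outer(c(1, 2, 3, -1), c(0.6, 0.8))
  ds <- profile_dataset(genotypes = c("IL_1", "IL_2"),
                        entity_id = paste0("T", 1:4),
                        kind = "transcript", sign = "original",
                        values = vals)
  expect_warning(map <- init_pca(ds, som_config(rows = 3L, cols = 3L,
                                                n_epochs = 2L)),
                 "single direction")
  expect_equal(qr(map$codebook)$rank, 1L)
})

test_that("training on one pattern collapses the map onto it", {
  ds <- profile_dataset(genotypes = paste0("IL_", 1:4),
                        entity_id = "solo", kind = "transcript",
                        sign = "original",
                        values = matrix(c(0.5, -0.5, 0.5, -0.5), 1))
  fit <- suppressWarnings(  # one pattern spans a single direction
    train_batch(ds, som_config(rows = 3L, cols = 3L, n_epochs = 30L,
                               radius_schedule = seq(2, 0.1,
                                                     length.out = 30))))
  expect_lt(quantization_error(ds, fit$map), 1e-6)
})

test_that("radius-0 batch epochs reproduce Lloyd k-means steps", {
  ds <- random_closed_dataset(n_transcripts = 15L, n_metabolites = 5L,
                              P = 6L, seed = 31, missing_frac = 0.15)
  cfg <- som_config(rows = 3L, cols = 3L, n_epochs = 10L,
                    radius_schedule = rep(0, 10))
  fit <- train_batch(ds, cfg)
  # oracle: same PCA start, ten independent Lloyd steps
  centers <- init_pca(ds, cfg)$codebook
  for (e in 1:10) centers <- lloyd_step(ds$values, ds$validity, centers)$centers
  expect_equal(fit$map$codebook, centers, tolerance = 1e-12)
  # k-means monotonicity of the squared quantization error
  expect_true(all(diff(fit$sse_trace) <= 1e-12))
})

test_that("training is deterministic and independent of pattern order", {
  ds <- random_closed_dataset(seed = 41)
  cfg <- som_config(rows = 4L, cols = 4L, n_epochs = 8L)
  fit1 <- train_batch(ds, cfg)
  fit2 <- train_batch(ds, cfg)
  expect_identical(fit1$map$codebook, fit2$map$codebook)
  # shuffle the original/inverted pairs: same final codebook
  set.seed(1)
  pair_order <- sample(n_patterns(ds) / 2)
  idx <- as.vector(rbind(2 * pair_order - 1, 2 * pair_order))
  fit3 <- train_batch(ilsom:::subset_patterns(ds, idx), cfg)
  expect_equal(fit3$map$codebook, fit1$map$codebook, tolerance = 1e-10)
})

test_that("assignment distances match recomputation from stored vectors", {
  ds <- random_closed_dataset(seed = 51, missing_frac = 0.1)
  fit <- train_tiny(ds)
  for (i in seq_len(n_patterns(ds))) {
    v <- ds$validity[i, ]
    d <- sqrt(sum(((ds$values[i, ] - fit$map$codebook[fit$assignment$bmu[i], ])[v])^2))
    expect_equal(fit$assignment$distance[i], d, tolerance = 1e-12)
  }
  # quantization error is the mean of those distances
  expect_equal(quantization_error(ds, fit$map), mean(fit$assignment$distance))
})

test_that("a trained map serializes and reloads losslessly", {
  ds <- random_closed_dataset(seed = 61)
  fit <- train_tiny(ds)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_som_map(fit$map, f)
  back <- read_som_map(f)
  expect_equal(back$codebook, fit$map$codebook, tolerance = 1e-15)
  expect_identical(back$config$rows, fit$map$config$rows)
  expect_identical(back$config$lattice, fit$map$config$lattice)
  expect_equal(back$config$radius_schedule, fit$map$config$radius_schedule)
  # reloaded map reproduces the assignment
  expect_identical(assign_patterns(ds, back)$bmu, fit$assignment$bmu)
})

test_that("hexagonal lattices use offset grid distances", {
  cfg <- som_config(rows = 2L, cols = 2L, lattice = "hexagonal",
                    n_epochs = 1L, radius_schedule = 1)
  d <- ilsom:::grid_distances(cfg)
  # neighbors in an offset row are exactly 1 apart
  expect_equal(d[1, 2], 1)           # unit 1 (1,1) to unit 2 (2,1)
  expect_equal(d[1, 3], 1)           # (1,1) to (1,2)
  cfg_rect <- som_config(rows = 2L, cols = 2L, n_epochs = 1L,
                         radius_schedule = 1)
  expect_equal(ilsom:::grid_distances(cfg_rect)[1, 4], sqrt(2))
})
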