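#' Configuration for a batch-trained self-organizing map
#'
#' @param rows,cols map topology (e.g. 40 x 40).
#' @param lattice `"rectangular"` (grid distances are Euclidean in grid
#'   coordinates) or `"hexagonal"` (odd rows offset by half a unit,
#'   row spacing sqrt(3)/2).
#' @param n_epochs number of batch epochs.
#' @param radius_schedule non-increasing vector of neighborhood radii,
#'   one per epoch; defaults to a linear decay from `max(rows, cols)/4`
#'   down to 1.
#' @param init `"pca"` (deterministic, order-independent) or `"random"`.
#' @param seed integer seed, used only by `init = "random"`.
#' @return An object of class `som_config`.
#' @export
som_config <- function(rows = 40L, cols = 40L,
                       lattice = c("rectangular", "hexagonal"),
                       n_epochs = 50L, radius_schedule = NULL,
                       init = c("pca", "random"), seed = 1L) {
  lattice <- match.arg(lattice)
  init <- match.arg(init)
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1L, cols >= 1L, rows * cols >= 2L, n_epochs >= 1L)
  if (is.null(radius_schedule))
    radius_schedule <- seq(max(1, max(rows, cols) / 4), 1,
                           length.out = n_epochs)
  if (length(radius_schedule) != n_epochs)
    stopf("radius_schedule must have one entry per epoch (%d)", n_epochs)
  if (any(diff(radius_schedule) > 0))
    stopf("radius_schedule must be non-increasing")
  if (any(radius_schedule < 0)) stopf("radii must be >= 0")
  structure(list(rows = rows, cols = cols, lattice = lattice,
                 n_epochs = as.integer(n_epochs),
                 radius_schedule = as.numeric(radius_schedule),
                 init = init, seed = as.integer(seed)),
            class = "som_config")
}

# 1-based, column-major unit numbering: unit = (row-1) + rows*(col-1) + 1
unit_coords <- function(rows, cols) {
  u <- seq_len(rows * cols)
  cbind(row = ((u - 1L) %% rows) + 1L,
        col = ((u - 1L) %/% rows) + 1L)
}

unit_index <- function(row, col, rows) (row - 1L) + rows * (col - 1L) + 1L

# planar positions used for grid distances delta_ij
lattice_positions <- function(config) {
  gc <- unit_coords(config$rows, config$cols)
  if (config$lattice == "hexagonal") {
    x <- gc[, "col"] + 0.5 * ((gc[, "row"] - 1L) %% 2L)
    y <- (gc[, "row"] - 1L) * sqrt(3) / 2 + 1
    cbind(x = x, y = y)
  } else {
    cbind(x = as.numeric(gc[, "col"]), y = as.numeric(gc[, "row"]))
  }
}

grid_distances <- function(config) {
  pos <- lattice_positions(config)
  as.matrix(stats::dist(pos))
}

#' Gaussian neighborhood kernel
#'
#' `g_ij = exp(-delta_ij^2 / (2 r^2))` for grid distance `delta` and
#' radius `r > 0`.  At `r = 0` the degenerate winner-takes-all limit is
#' returned: 1 at `delta = 0`, else 0.
#'
#' @param delta grid distance(s) between units.
#' @param r neighborhood radius.
#' @return Kernel value(s) in `[0, 1]`.
#' @export
gaussian_neighborhood <- function(delta, r) {
  if (r == 0) return(as.numeric(delta == 0))
  exp(-delta^2 / (2 * r^2))
}

#' Initialize a map codebook along the first two principal components
#'
#' Codebook vectors are laid out on the regular grid spanned by the
#' first two principal components of the data, scaled by the component
#' standard deviations and centered on the data mean (PC1 along the
#' column axis, PC2 along the row axis).  The initialization is
#' deterministic, so training is independent of pattern input order and
#' fully reproducible.  For inversion-closed data the mean is zero and
#' the initial codebook is negation-symmetric under 180-degree grid
#' rotation.  Invalid (pseudo-zero) entries enter the PCA as 0, their
#' placeholder value.
#'
#' @param dataset a [profile_dataset()].
#' @param config a [som_config()].
#' @return A `som_map` (see [train_batch()]).
#' @export
init_pca <- function(dataset, config) {
  X <- dataset$values
  X[!dataset$validity] <- 0
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0, nv = 2L)
  sdev <- sv$d / sqrt(max(1, nrow(X) - 1L))
  # canonical sign (largest-magnitude loading positive): the layout must
  # not depend on the row order fed to the SVD
  canon <- function(pc) if (pc[which.max(abs(pc))] < 0) -pc else pc
  pc1 <- canon(sv$v[, 1L])
  sd1 <- sdev[1L]
  if (length(sv$d) < 2L || sdev[2L] < 1e-12 * max(sdev[1L], 1)) {
    warnf("data span a single direction; PCA init falls back to PC1 only")
    pc2 <- rep(0, ncol(X)); sd2 <- 0
  } else {
    pc2 <- canon(sv$v[, 2L]); sd2 <- sdev[2L]
  }
  lin <- function(k, n) if (n == 1L) rep(0, length(k))
                        else 2 * (k - 1) / (n - 1) - 1
  gc <- unit_coords(config$rows, config$cols)
  a <- lin(gc[, "col"], config$cols)  # PC1 axis
  b <- lin(gc[, "row"], config$rows)  # PC2 axis
  codebook <- outer(a, sd1 * pc1) + outer(b, sd2 * pc2)
  codebook <- sweep(codebook, 2L, ctr, `+`)
  new_som_map(config, codebook)
}

init_random <- function(dataset, config) {
  X <- dataset$values
  X[!dataset$validity] <- 0
  K <- config$rows * config$cols
  codebook <- with_seed(config$seed, {
    lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
    matrix(stats::runif(K * ncol(X), rep(lo, each = K), rep(hi, each = K)),
           K, ncol(X))
  })
  new_som_map(config, codebook)
}

new_som_map <- function(config, codebook) {
  structure(list(config = config,
                 grid = unit_coords(config$rows, config$cols),
                 codebook = codebook),
            class = "som_map")
}

#' @export
print.som_map <- function(x, ...) {
  cat(sprintf("som_map: %d x %d %s lattice, codebook dimension P=%d\n",
              x$config$rows, x$config$cols, x$config$lattice,
              ncol(x$codebook)))
  invisible(x)
}

# masked squared Euclidean distances, patterns x units:
# sum over valid components of (x - w)^2
masked_sqdist <- function(values, validity, codebook) {
  V <- validity * 1
  XV <- values * V
  D2 <- matrix(rowSums(XV^2), nrow(values), nrow(codebook)) -
    2 * XV %*% t(codebook) + V %*% t(codebook^2)
  D2[D2 < 0] <- 0
  D2
}

#' Best-matching unit of a pattern
#'
#' Returns the unit whose codebook vector minimizes the Euclidean
#' distance to the pattern, summed over valid components only; ties are
#' broken towards the lowest unit index.
#'
#' @param x numeric pattern vector.
#' @param map a `som_map`.
#' @param validity logical mask over the components of `x`.
#' @return Integer unit index (1-based, column-major).
#' @export
find_bmu <- function(x, map, validity = NULL) {
  if (is.null(validity)) validity <- rep(TRUE, length(x))
  stopifnot(any(validity))
  d2 <- masked_sqdist(matrix(x, 1L), matrix(validity, 1L), map$codebook)
  which.min(d2[1L, ])
}

#' Assign every pattern of a dataset to its best-matching unit
#'
#' @param dataset a [profile_dataset()].
#' @param map a `som_map`.
#' @return An object of class `som_assignment`: list with integer `bmu`
#'   and numeric `distance` (masked Euclidean distance to the BMU), one
#'   entry per pattern.
#' @export
assign_patterns <- function(dataset, map) {
  D2 <- masked_sqdist(dataset$values, dataset$validity, map$codebook)
  bmu <- max.col(-D2, ties.method = "first")
  structure(list(bmu = bmu,
                 distance = sqrt(D2[cbind(seq_len(nrow(D2)), bmu)])),
            class = "som_assignment")
}

#' Batch-train a self-organizing map
#'
#' Each epoch passes the whole training set through the map at once:
#' every pattern is assigned to its best-matching unit, then every
#' codebook vector is replaced by the neighborhood-weighted mean of all
#' patterns, `w_j <- sum_i g(bmu_i, j) x_i / sum_i g(bmu_i, j)`,
#' computed per component over valid entries only.  The Gaussian
#' neighborhood radius follows `config$radius_schedule`.  A unit whose
#' total neighborhood weight is zero in some component keeps its
#' previous value there.  With `init = "pca"` the whole procedure is
#' deterministic and independent of pattern order.
#'
#' At radius 0 the update degenerates to one Lloyd step of k-means with
#' `rows * cols` centers.
#'
#' @param dataset a [profile_dataset()].
#' @param config a [som_config()].
#' @return list with `map` (the trained `som_map`), `assignment` (final
#'   [assign_patterns()] result) and `sse_trace` (mean masked squared
#'   quantization error measured at each epoch's assignment step).
#' @export
train_batch <- function(dataset, config) {
  stopifnot(n_patterns(dataset) >= 1L)
  map <- if (config$init == "pca") init_pca(dataset, config)
         else init_random(dataset, config)
  X <- dataset$values
  V <- dataset$validity * 1
  XV <- X * V
  delta <- grid_distances(config)
  sse <- numeric(config$n_epochs)
  frozen <- 0L
  for (e in seq_len(config$n_epochs)) {
    r <- config$radius_schedule[e]
    D2 <- masked_sqdist(X, dataset$validity, map$codebook)
    bmu <- max.col(-D2, ties.method = "first")
    sse[e] <- mean(D2[cbind(seq_along(bmu), bmu)])
    if (r == 0) {
      # winner-takes-all: plain per-cluster means (one Lloyd step)
      num <- rowsum(XV, bmu)
      den <- rowsum(V, bmu)
      units <- as.integer(rownames(num))
      new_cb <- map$codebook
      sub <- new_cb[units, , drop = FALSE]
      upd <- den > 0
      sub[upd] <- num[upd] / den[upd]
      new_cb[units, ] <- sub
      frozen <- frozen + sum(!upd)
      map$codebook <- new_cb
    } else {
      G <- gaussian_neighborhood(delta, r)
      A <- G[bmu, , drop = FALSE]          # n x K neighborhood weights
      num <- crossprod(A, XV)              # K x P
      den <- crossprod(A, V)
      upd <- den > 0
      new_cb <- map$codebook
      new_cb[upd] <- num[upd] / den[upd]
      frozen <- frozen + sum(!upd)
      map$codebook <- new_cb
    }
  }
  if (frozen > 0)
    message(sprintf("train_batch: %d codebook component update(s) had zero neighborhood weight and kept their previous value", frozen))
  list(map = map, assignment = assign_patterns(dataset, map),
       sse_trace = sse)
}

#' Mean quantization error of a dataset on a map
#'
#' Mean over patterns of the masked Euclidean distance to the
#' best-matching unit.
#'
#' @param dataset a [profile_dataset()].
#' @param map a `som_map`.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(dataset, map) {
  if (n_patterns(dataset) == 0L) stopf("empty dataset")
  mean(assign_patterns(dataset, map)$distance)
}

#' Serialize / load a trained map
#'
#' Tab-separated text: `#`-prefixed header lines carrying the
#' configuration, then one row per unit (`unit`, `row`, `col`, P
#' weights).  Round-trips through [read_som_map()].
#'
#' @param map a `som_map`.
#' @param path file path.
#' @return `path` (write) or a `som_map` (read).
#' @export
write_som_map <- function(map, path) {
  cfg <- map$config
  hdr <- c(
    sprintf("# rows=%d cols=%d lattice=%s n_epochs=%d init=%s seed=%d",
            cfg$rows, cfg$cols, cfg$lattice, cfg$n_epochs, cfg$init, cfg$seed),
    sprintf("# radius_schedule=%s",
            paste(format(cfg$radius_schedule, digits = 17), collapse = ","))
  )
  rows <- vapply(seq_len(nrow(map$codebook)), function(u) {
    paste(c(u, map$grid[u, "row"], map$grid[u, "col"],
            format(map$codebook[u, ], digits = 17, scientific = TRUE,
                   trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_som_map
#' @export
read_som_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  kv <- strsplit(sub("^#\\s*", "", hdr[1L]), "\\s+")[[1L]]
  get <- function(key) sub(paste0("^", key, "="), "",
                           kv[startsWith(kv, paste0(key, "="))])
  sched <- as.numeric(strsplit(sub("^#\\s*radius_schedule=", "", hdr[2L]),
                               ",")[[1L]])
  cfg <- som_config(rows = as.integer(get("rows")),
                    cols = as.integer(get("cols")),
                    lattice = get("lattice"),
                    n_epochs = as.integer(get("n_epochs")),
                    radius_schedule = sched,
                    init = get("init"),
                    seed = as.integer(get("seed")))
  toks <- lapply(strsplit(body, "\t"), as.numeric)
  codebook <- do.call(rbind, lapply(toks, function(t) t[-(1:3)]))
  ord <- order(vapply(toks, `[[`, numeric(1), 1L))
  new_som_map(cfg, codebook[ord, , drop = FALSE])
}
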