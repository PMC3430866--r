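## Self-organizing-map mosaic of expression dynamics: a small batch SOM on
## standardized four-point profiles, rendered as a per-population coloured
## grid in the style of expression-dynamics mosaic plots.

#' Train a SOM mosaic of expression profiles
#'
#' Each gene's four-point profile is standardized (z-scored across the
#' populations; zero-variance genes are centred only) and a batch
#' self-organizing map is trained on a `grid_rows` x `grid_cols` grid with
#' a Gaussian neighbourhood whose radius decays linearly from half the
#' larger grid dimension to 0.5 over the epochs. Codebooks are initialised
#' from randomly sampled gene profiles (seeded), and every gene is mapped
#' to exactly one tile (its best-matching unit, ties to the lowest tile
#' index). The batch update makes the fit independent of gene order.
#'
#' @param expr Genes x 4 linear expression matrix.
#' @param grid_rows,grid_cols Grid dimensions (each >= 2).
#' @param epochs Training epochs.
#' @param seed Integer seed for the codebook initialisation.
#' @return An object of class `som_mosaic`: list with `assignment` (named
#'   integer vector, gene -> tile index in row-major order), `grid`
#'   (c(rows, cols)), `codebook` (tiles x 4), `tile_profiles` (tiles x 4
#'   mean linear profile of assigned genes, `NA` for empty tiles) and
#'   `tile_counts`.
#' @export
som_mosaic <- function(expr, grid_rows = 10L, grid_cols = 10L,
                       epochs = 50L, seed = 1L) {
  stopifnot(is.matrix(expr), ncol(expr) == 4L)
  if (grid_rows < 2L || grid_cols < 2L) stop("grid must be at least 2x2")
  n <- nrow(expr)
  k <- grid_rows * grid_cols
  if (n < k)
    warning(sprintf("fewer genes (%d) than tiles (%d); training proceeds", n, k))
  lg <- log2(expr + 1)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1, stats::sd)
  x <- (lg - mu) / ifelse(sdv == 0, 1, sdv)
  set.seed(stage_seed(seed, "som"))
  code <- x[sample.int(n, k, replace = n < k), , drop = FALSE] +
    matrix(stats::rnorm(k * 4L, 0, 1e-3), k, 4L)
  rownames(code) <- NULL
  ## tile coordinates, row-major
  coords <- cbind(row = rep(seq_len(grid_rows), each = grid_cols),
                  col = rep(seq_len(grid_cols), times = grid_rows))
  gd2 <- as.matrix(stats::dist(coords))^2
  sigma0 <- max(grid_rows, grid_cols) / 2
  bmu <- integer(n)
  for (e in seq_len(epochs)) {
    sigma <- if (epochs == 1L) 0.5 else
      sigma0 + (0.5 - sigma0) * (e - 1) / (epochs - 1)
    ## best-matching unit per gene (ties -> lowest index)
    d <- outer(rowSums(x^2), rowSums(code^2), "+") - 2 * x %*% t(code)
    bmu <- max.col(-d, ties.method = "first")
    h <- exp(-gd2 / (2 * sigma^2))       # tiles x tiles neighbourhood
    wt <- h[, bmu, drop = FALSE]         # tiles x genes
    denom <- rowSums(wt)
    upd <- (wt %*% x) / denom
    keep <- denom > 0
    code[keep, ] <- upd[keep, ]
  }
  d <- outer(rowSums(x^2), rowSums(code^2), "+") - 2 * x %*% t(code)
  bmu <- max.col(-d, ties.method = "first")
  names(bmu) <- rownames(expr)
  counts <- tabulate(bmu, nbins = k)
  tile_prof <- matrix(NA_real_, k, 4L,
                      dimnames = list(NULL, colnames(expr)))
  for (t in which(counts > 0))
    tile_prof[t, ] <- colMeans(expr[bmu == t, , drop = FALSE])
  structure(list(assignment = bmu, grid = c(rows = grid_rows, cols = grid_cols),
                 codebook = code, tile_profiles = tile_prof,
                 tile_counts = counts),
            class = "som_mosaic")
}

#' @export
print.som_mosaic <- function(x, ...) {
  cat(sprintf("SOM mosaic: %d x %d grid, %d genes, %d occupied tiles\n",
              x$grid["rows"], x$grid["cols"], length(x$assignment),
              sum(x$tile_counts > 0)))
  invisible(x)
}

#' Tile grid coordinates of genes on a SOM mosaic
#' @param som A `som_mosaic` object.
#' @param genes Gene ids (default all).
#' @return Matrix with columns `row`, `col` (one row per gene).
#' @export
som_tile_coords <- function(som, genes = names(som$assignment)) {
  t <- som$assignment[genes]
  cols <- som$grid["cols"]
  cbind(row = (t - 1L) %/% cols + 1L, col = (t - 1L) %% cols + 1L)
}

#' Plot a SOM mosaic, one panel per population
#'
#' Renders the per-tile mean expression (log2) of each population as a
#' coloured grid, the mosaic view of expression dynamics across the
#' timecourse.
#'
#' @param x A `som_mosaic` object.
#' @param ... Ignored.
#' @method plot som_mosaic
#' @export
plot.som_mosaic <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 4), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  r <- x$grid["rows"]; cl <- x$grid["cols"]
  vals <- log2(x$tile_profiles + 1)
  zlim <- range(vals, na.rm = TRUE)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  for (j in 1:4) {
    m <- matrix(vals[, j], nrow = cl, ncol = r)  # row-major tiles
    graphics::image(seq_len(cl), seq_len(r), m, col = pal, zlim = zlim,
                    axes = FALSE, xlab = "", ylab = "",
                    main = colnames(vals)[j])
    graphics::box()
  }
  invisible(x)
}
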