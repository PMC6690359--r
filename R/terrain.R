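#' Deterministic force-directed layout of a subnetwork
#'
#' Places the subnetwork's genes in the unit square with a
#' Fruchterman-Reingold force-directed layout in which edge attraction
#' grows with interaction confidence, so high-confidence clusters gather
#' into spatial neighborhoods. Coordinates are rescaled into
#' [0.05, 0.95] x [0.05, 0.95]; the margin keeps rendered peaks off the
#' border. The layout is deterministic for a fixed seed and graph.
#'
#' @param sub A \code{subnetwork} (or \code{ppi_network}) with at least one
#'   node.
#' @param seed Integer layout seed.
#' @return A \code{layout_coords} data frame: gene, x, y, with the seed as
#'   attribute.
#' @export
layout_network <- function(sub, seed = 1L) {
  nodes <- sub$nodes
  if (length(nodes) == 0L) stop("cannot lay out an empty network")
  if (length(nodes) == 1L) {
    coords <- data.frame(gene = nodes, x = 0.5, y = 0.5,
                         stringsAsFactors = FALSE)
  } else {
    g <- as_igraph(sub)
    set.seed(seed)
    xy <- igraph::layout_with_fr(g, weights = igraph::E(g)$weight)
    rescale01 <- function(v) {
      rng <- range(v)
      if (diff(rng) == 0) return(rep(0.5, length(v)))
      pmin(pmax(0.05 + 0.9 * (v - rng[1]) / diff(rng), 0.05), 0.95)
    }
    coords <- data.frame(gene = igraph::V(g)$name,
                         x = rescale01(xy[, 1]), y = rescale01(xy[, 2]),
                         stringsAsFactors = FALSE)
  }
  rownames(coords) <- NULL
  attr(coords, "layout_seed") <- as.integer(seed)
  class(coords) <- c("layout_coords", "data.frame")
  coords
}

#' Rasterize a Gaussian-peak terrain over a network layout
#'
#' Evaluates, at the centers of a G x G grid over the unit square, the
#' superposition of one isotropic Gaussian kernel per gene:
#' surface(p) = sum_g z_g * exp(-||p - p_g||^2 / (2 sigma^2)).
#' Peak heights encode the chosen per-gene weight (typically the final
#' score); negative weights carve depressions. The result is the numeric
#' terrain matrix behind a terrain heat map of the scored network.
#'
#' @param coords A \code{layout_coords} covering every gene in
#'   \code{heights}.
#' @param heights Named numeric vector gene -> z.
#' @param grid_size Grid resolution G (default 256, minimum 16).
#' @param sigma Kernel width in unit coordinates (default 0.05), > 0.
#' @return A \code{terrain_surface}: list with \code{grid} (G x G matrix,
#'   rows indexing x, columns y), \code{sigma}, \code{grid_size},
#'   \code{heights_of} and \code{coords}.
#' @export
render_terrain <- function(coords, heights, grid_size = 256L, sigma = 0.05) {
  stopifnot(inherits(coords, "data.frame"))
  if (sigma <= 0) stop("sigma must be positive")
  grid_size <- as.integer(grid_size)
  if (grid_size < 16L) stop("grid_size must be at least 16")
  genes <- names(heights)
  if (is.null(genes) || any(!nzchar(genes)))
    stop("heights must be a named vector")
  miss <- setdiff(genes, coords$gene)
  if (length(miss))
    stop("no coordinates for gene(s): ", paste(utils::head(miss, 5), collapse = ", "))
  idx <- match(genes, coords$gene)
  gx <- coords$x[idx]
  gy <- coords$y[idx]
  centers <- (seq_len(grid_size) - 0.5) / grid_size
  z <- as.numeric(heights)
  # separable kernel: grid[i,j] = sum_g z_g ex[i,g] ey[j,g]
  ex <- exp(-outer(centers, gx, "-")^2 / (2 * sigma^2))
  ey <- exp(-outer(centers, gy, "-")^2 / (2 * sigma^2))
  grid <- ex %*% (t(ey) * z)
  structure(list(grid = grid, sigma = sigma, grid_size = grid_size,
                 heights_of = heights,
                 coords = coords[idx, , drop = FALSE]),
            class = "terrain_surface")
}

#' @export
print.terrain_surface <- function(x, ...) {
  cat("terrain_surface: ", x$grid_size, "x", x$grid_size,
      " grid, sigma = ", x$sigma, ", ", length(x$heights_of),
      " peaks, height range [", sprintf("%.3g", min(x$grid)), ", ",
      sprintf("%.3g", max(x$grid)), "]\n", sep = "")
  invisible(x)
}

#' Write a terrain matrix as plain TSV
#'
#' @param surface A \code{terrain_surface}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_terrain <- function(surface, path) {
  stopifnot(inherits(surface, "terrain_surface"))
  utils::write.table(surface$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plot a terrain surface as a heat map
#'
#' Renders the terrain matrix with [graphics::image()] (terrain palette)
#' and overlays gene positions and labels. Only the numeric matrix is
#' tested; the plot is a convenience view.
#'
#' @param x A \code{terrain_surface}.
#' @param labels Draw gene labels (default TRUE when 60 genes or fewer).
#' @param ... Passed to [graphics::image()].
#' @export
plot.terrain_surface <- function(x, labels = length(x$heights_of) <= 60, ...) {
  centers <- (seq_len(x$grid_size) - 0.5) / x$grid_size
  graphics::image(centers, centers, x$grid,
                  col = grDevices::hcl.colors(64, "Terrain", rev = TRUE),
                  xlab = "", ylab = "", useRaster = TRUE, ...)
  graphics::points(x$coords$x, x$coords$y, pch = 16, cex = 0.4)
  if (isTRUE(labels))
    graphics::text(x$coords$x, x$coords$y, x$coords$gene, cex = 0.5, pos = 3)
  invisible(x)
}
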