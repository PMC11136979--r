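#' Population-normalized histogram
#'
#' Bin counts divided by the population size (the total number of values,
#' including any falling outside the binned range), so histograms of
#' differently sized datasets are directly comparable.
#'
#' @param values numeric values (nm), non-empty.
#' @param edges strictly increasing bin edges; bins are left-closed,
#'   right-open, the last bin closed.
#' @return An object of class \code{"histogram_spec"}: \code{edges},
#'   \code{counts}, \code{heights} (counts / n) and \code{n}.
#' @export
population_histogram <- function(values, edges) {
  if (length(values) == 0L) stop("values must be non-empty")
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing")
  nb <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > nb] <- NA_integer_
  counts <- tabulate(idx, nbins = nb)
  structure(list(edges = edges, counts = counts,
                 heights = counts / length(values), n = length(values)),
            class = "histogram_spec")
}

#' Bivariate density scatter
#'
#' For each point (e.g. a pair of consecutive step sizes) the local density
#' is the number of points within a fixed Euclidean radius, itself
#' included; the densities serve as the color code of the scatter plot.
#'
#' @param pairs two-column matrix or data frame of points (nm).
#' @param radius neighborhood radius (nm), default 4, > 0.
#' @return A data frame \code{x}, \code{y}, \code{density} of class
#'   \code{"density_scatter"}.
#' @export
density_scatter <- function(pairs, radius = 4) {
  if (radius <= 0) stop("radius must be > 0")
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  n <- nrow(pairs)
  dens <- if (n == 0L) integer(0)
          else rowSums(as.matrix(stats::dist(pairs)) <= radius)
  structure(data.frame(x = pairs[, 1L], y = pairs[, 2L], density = dens),
            class = c("density_scatter", "data.frame"))
}

#' Common kernel bandwidth across datasets
#'
#' Silverman's rule-of-thumb bandwidth computed on the pooled values, so
#' densities of several datasets are estimated on the same scale and remain
#' comparable (identically scaled violins).
#'
#' @param ... numeric vectors (or a single list of them).
#' @return A single bandwidth.
#' @export
shared_bandwidth <- function(...) {
  vals <- list(...)
  if (length(vals) == 1L && is.list(vals[[1L]]) && !is.data.frame(vals[[1L]]))
    vals <- vals[[1L]]
  pooled <- unlist(vals, use.names = FALSE)
  if (length(pooled) < 2L) stop("need at least 2 values")
  stats::bw.nrd0(pooled)
}

#' Kernel probability density for violin plots
#'
#' Gaussian kernel density estimate evaluated on a user grid.  Pass a
#' \code{\link{shared_bandwidth}} to make densities of several datasets
#' comparable.
#'
#' @param values numeric sample, at least 2 values with non-zero spread.
#' @param grid evaluation grid.
#' @param bw kernel bandwidth; default Silverman's rule on \code{values}.
#' @return A list with \code{grid}, \code{density} and \code{bw}.
#' @export
violin_density <- function(values, grid, bw = NULL) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0)
    stop("zero-variance input: a kernel density is degenerate; ",
         "plot the single value directly instead")
  if (is.null(bw)) bw <- stats::bw.nrd0(values)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, values, bw)),
                 numeric(1L))
  list(grid = grid, density = dens, bw = bw)
}
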