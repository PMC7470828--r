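`%||%` <- function(a, b) if (is.null(a)) b else a

## population SD (divisor n, not n-1): the temporal CV map is a descriptive
## per-pixel statistic, not an estimate from a sample
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Otsu threshold of a numeric map
#'
#' Exhaustive between-class-variance maximisation over equal-width histogram
#' bins spanning the observed range. Ties are broken toward the lower
#' threshold. Used for the temporal-CV non-responsive mask and for seed
#' selection in the correlated-activity segmenter.
#'
#' @param x numeric vector or matrix; non-finite values are ignored.
#' @param n_bins number of equal-width histogram bins (default 256).
#' @return the threshold (a bin edge), or `NA` with a warning when the map is
#'   constant so no two classes exist.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no finite values to threshold")
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("constant map: no Otsu threshold exists")
    return(NA_real_)
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, edges, all.inside = TRUE), n_bins),
                nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[n_bins]
  mu_t <- mu[n_bins]
  ## between-class variance for threshold after bin k
  k <- seq_len(n_bins - 1L)
  w0 <- w[k]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  ## w0*w1*(mu0 - mu1)^2 up to a constant factor
  bcv[valid] <- (mu_t * w0[valid] - n * mu[k][valid])^2 /
    (w0[valid] * w1[valid])
  if (!any(is.finite(bcv))) {
    warning("degenerate histogram: no Otsu threshold exists")
    return(NA_real_)
  }
  k_star <- which.max(bcv)   # which.max returns the first (lowest) maximiser
  edges[k_star + 1L]
}

## integer-shift a matrix by (dy, dx), replicating edge values
shift_matrix <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  iy <- pmin(pmax(seq_len(ny) - dy, 1L), ny)
  ix <- pmin(pmax(seq_len(nx) - dx, 1L), nx)
  m[iy, ix, drop = FALSE]
}

## pixel coordinates of a filled disc centred at (cy, cx)
disc_pixels <- function(cy, cx, radius, ny, nx) {
  r <- ceiling(radius)
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  g <- expand.grid(y = ys, x = xs)
  keep <- (g$y - cy)^2 + (g$x - cx)^2 <= radius^2
  g[keep, , drop = FALSE]
}

## deterministic RNG scoping: run expr under set.seed(seed), restore state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## recycle a grouping to length n without dropping factor levels
as_group_factor <- function(group, n) {
  if (!is.factor(group)) group <- factor(group)
  rep(group, length.out = n)
}

## Jaccard index of two logical masks
jaccard <- function(a, b) {
  i <- sum(a & b); u <- sum(a | b)
  if (u == 0) return(NA_real_)
  i / u
}
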