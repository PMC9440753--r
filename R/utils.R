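# Internal geometry and numeric helpers.

# Round half away from zero to integer (the convention used for all reported
# integer percentages).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Normalize a 3-vector; zero vectors map to a fixed axis to stay deterministic.
unit3 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(c(1, 0, 0))
  v / nv
}

# Arclength of an n x 3 polyline in physical coordinates.
polyline_length <- function(p) {
  if (is.null(p) || nrow(p) < 2) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

# Resample a polyline at approximately `ds` spacing (keeps endpoints exactly).
resample_polyline <- function(p, ds) {
  if (nrow(p) < 2) return(p)
  seg <- sqrt(rowSums(diff(p)^2))
  dup <- c(FALSE, seg < 1e-12)   # drop zero-length segments
  if (any(dup)) {
    p <- p[!dup, , drop = FALSE]
    if (nrow(p) < 2) return(p[c(1, 1), , drop = FALSE])
    seg <- sqrt(rowSums(diff(p)^2))
  }
  L <- sum(seg)
  if (L <= ds) return(p[c(1, nrow(p)), , drop = FALSE])
  s <- c(0, cumsum(seg))
  n_out <- max(2, ceiling(L / ds) + 1)
  t_out <- seq(0, L, length.out = n_out)
  out <- matrix(0, n_out, 3)
  for (k in 1:3) out[, k] <- approx(s, p[, k], xout = t_out, ties = "ordered")$y
  out
}

# Point on a polyline at arclength `a` from its first vertex.
point_at_arclength <- function(p, a) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  a <- max(0, min(a, s[length(s)]))
  i <- findInterval(a, s, rightmost.closed = TRUE)
  i <- min(i, nrow(p) - 1)
  if (seg[i] < 1e-12) return(p[i, ])
  w <- (a - s[i]) / seg[i]
  (1 - w) * p[i, ] + w * p[i + 1, ]
}

# Truncate a polyline to its first `a` units of arclength.
clip_polyline <- function(p, a) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  a <- max(0, min(a, L))
  if (a <= 1e-12) return(p[1, , drop = FALSE])
  keep <- which(s <= a + 1e-12)
  q <- p[keep, , drop = FALSE]
  if (abs(s[length(keep)] - a) > 1e-9) {
    q <- rbind(q, point_at_arclength(p, a))
  }
  q
}

# Moving-average smoothing of interior polyline vertices (window must be odd).
# Endpoints are fixed; used to reduce voxel staircase bias in skeleton paths.
smooth_polyline <- function(p, window = 5L) {
  n <- nrow(p)
  if (n <= 2 || window < 3) return(p)
  h <- window %/% 2
  out <- p
  for (i in 2:(n - 1)) {
    a <- max(1, i - h)
    b <- min(n, i + h)
    out[i, ] <- colMeans(p[a:b, , drop = FALSE])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
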