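# Vectorised 3D geometry for cylindrical process segments.
# All coordinates in nanometres.

# Closest points between two 3D line segments P0->P1 and Q0->Q1 (row-wise
# over matrices). Returns list(dist, s, t) with s, t in [0, 1] the closest
# point parameters. Clamped projection algorithm; robust for degenerate
# (point-like) segments.
segment_segment_closest <- function(P0, P1, Q0, Q1) {
  d1 <- P1 - P0
  d2 <- Q1 - Q0
  r <- P0 - Q0
  a <- rowSums(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r)
  c_ <- rowSums(d1 * r)
  b <- rowSums(d1 * d2)
  denom <- a * e - b * b
  s <- ifelse(denom > 1e-12, pmin(pmax((b * f - c_ * e) / denom, 0), 1), 0)
  # handle degenerate first segment (a ~ 0)
  s <- ifelse(a <= 1e-12, 0, s)
  t <- ifelse(e > 1e-12, (b * s + f) / e, -1)  # -1 forces the clamp branch
  # clamp t and recompute s
  tc <- pmin(pmax(t, 0), 1)
  ns <- ifelse(a > 1e-12, pmin(pmax((tc * b - c_) / a, 0), 1), 0)
  s <- ifelse(t < 0 | t > 1, ns, s)
  t <- tc
  cp <- P0 + d1 * s
  cq <- Q0 + d2 * t
  list(dist = sqrt(rowSums((cp - cq)^2)), s = s, t = t,
       point = (cp + cq) / 2)
}

# Candidate segment pairs from two index sets within `max_dist` of each
# other (surface-to-surface: axis distance minus radii, clamped at 0).
# Uses a midpoint-distance prefilter so the exact segment-segment test only
# runs on plausible pairs. Pairs within one neuron are excluded.
#
# seg: segments data.frame; ia, ib: integer row indices of the two sets.
# Returns data.frame(i, j, dist, x, y, z) where (x, y, z) is the midpoint of
# closest approach; pairs are unordered across sets (i from ia, j from ib)
# and deduplicated when the sets overlap.
cross_neuron_segment_pairs <- function(seg, ia, ib, max_dist) {
  empty <- data.frame(i = integer(), j = integer(), dist = numeric(),
                      x = numeric(), y = numeric(), z = numeric())
  if (length(ia) == 0 || length(ib) == 0) return(empty)
  S0 <- as.matrix(seg[, c("x0", "y0", "z0")])
  S1 <- as.matrix(seg[, c("x1", "y1", "z1")])
  mid <- (S0 + S1) / 2
  reach <- sqrt(rowSums((S1 - S0)^2)) / 2 + seg$diameter / 2

  A <- mid[ia, , drop = FALSE]
  B <- mid[ib, , drop = FALSE]
  chunk <- max(1L, floor(4e6 / length(ib)))
  found <- list(); k <- 0L
  for (s in seq(1L, length(ia), by = chunk)) {
    e <- min(s + chunk - 1L, length(ia))
    blk <- A[s:e, , drop = FALSE]
    d2m <- outer(rowSums(blk^2), rowSums(B^2), "+") - 2 * tcrossprod(blk, B)
    lim <- outer(reach[ia[s:e]], reach[ib], "+") + max_dist
    hit <- which(d2m <= lim^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      k <- k + 1L
      found[[k]] <- cbind(ia[hit[, 1] + s - 1L], ib[hit[, 2]])
    }
  }
  if (k == 0L) return(empty)
  pr <- do.call(rbind, found)
  # drop same-neuron pairs and self pairs; dedupe unordered duplicates
  keep <- seg$neuron[pr[, 1]] != seg$neuron[pr[, 2]]
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) == 0) return(empty)
  key <- paste(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  pr <- pr[!duplicated(key), , drop = FALSE]
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]

  cl <- segment_segment_closest(S0[pr[, 1], , drop = FALSE],
                                S1[pr[, 1], , drop = FALSE],
                                S0[pr[, 2], , drop = FALSE],
                                S1[pr[, 2], , drop = FALSE])
  dist <- pmax(cl$dist - seg$diameter[pr[, 1]] / 2 - seg$diameter[pr[, 2]] / 2, 0)
  ok <- dist <= max_dist
  data.frame(i = pr[ok, 1], j = pr[ok, 2], dist = dist[ok],
             x = cl$point[ok, 1], y = cl$point[ok, 2], z = cl$point[ok, 3])
}

# Linear distance/diameter kernel shared by synapse placement and the
# insert/split/merge perturbation models: p_max below d1, linearly
# decreasing to 0 at d2, 0 beyond.
kernel_prob <- function(x, p_max, d1, d2) {
  stopifnot(p_max >= 0, p_max <= 1, d1 > 0, d2 > d1)
  ifelse(x < d1, p_max,
         ifelse(x > d2, 0, p_max * (d2 - x) / (d2 - d1)))
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
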