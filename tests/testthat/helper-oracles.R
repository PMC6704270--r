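# Independent brute-force oracles used to validate the implementations on
# small inputs, plus small fixture builders.

# Topographic prominence by explicit flood fill: for a strict local maximum at
# height h, descend through the observed levels until the level set containing
# it also contains strictly higher terrain; prominence = h - that level.
# Assumes fixtures without summit plateaus or tied peaks.
oracle_maxima_count <- function(m, tol) {
  nr <- nrow(m); nc <- ncol(m)
  neigh <- function(i, j) {
    d <- expand.grid(di = -1:1, dj = -1:1)
    d <- d[!(d$di == 0 & d$dj == 0), ]
    ii <- i + d$di; jj <- j + d$dj
    keep <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    cbind(ii[keep], jj[keep])
  }
  flood <- function(mask, start) {
    comp <- matrix(FALSE, nr, nc)
    stack <- list(start)
    comp[start[1], start[2]] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      nb <- neigh(p[1], p[2])
      for (r in seq_len(nrow(nb))) {
        q <- nb[r, ]
        if (mask[q[1], q[2]] && !comp[q[1], q[2]]) {
          comp[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    comp
  }
  count <- 0L
  levels_desc <- sort(unique(as.vector(m)), decreasing = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    h <- m[i, j]
    nb <- neigh(i, j)
    if (any(m[nb] >= h)) next               # not a strict local maximum
    prom <- h - min(m)
    for (v in levels_desc[levels_desc <= h]) {
      comp <- flood(m >= v, c(i, j))
      if (max(m[comp]) > h) { prom <- h - v; break }
    }
    if (prom > tol) count <- count + 1L
  }
  count
}

# Maximum one-to-one matching cardinality by exhaustive recursion.
oracle_matching <- function(d_ok) {
  na <- nrow(d_ok)
  if (na == 0L || ncol(d_ok) == 0L) return(0L)
  rec <- function(i, used) {
    if (i > na) return(0L)
    best <- rec(i + 1L, used)               # leave i unmatched
    for (j in which(d_ok[i, ] & !used)) {
      used[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  rec(1L, logical(ncol(d_ok)))
}

# Exact two-sided Mann-Whitney p by enumeration over all group assignments,
# with U computed from pairwise comparisons (not ranks), so the route is
# independent of the implementation.
oracle_mw <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); N <- length(pooled)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  U_obs <- u_of(a, b)
  combs <- combn(N, n1)
  Us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(Us <= U_obs + eps), mean(Us >= U_obs - eps)))
}

# Otsu by the definitional exhaustive search (explicit per-candidate loop).
oracle_otsu <- function(values) {
  u <- sort(unique(values))
  best_t <- NA_real_; best_v <- -Inf
  for (t in u[-1]) {
    fg <- values >= t
    v <- mean(fg) * mean(!fg) * (mean(values[fg]) - mean(values[!fg]))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# Minimal single-channel image fixture.
tiny_image <- function(m, role = "MBP", pixel_size = 0.1, unit = "um") {
  calibrated_image(setNames(list(m), role), pixel_size, unit = unit)
}

# Detection object with prescribed points, for matching tests.
fake_detection <- function(xy, marker = "OLIG2", dim = c(100L, 100L), px_um = 1) {
  pts <- as.data.frame(xy)
  if (ncol(pts) == 0) pts <- data.frame(x = numeric(), y = numeric())
  names(pts) <- c("x", "y")
  pts$value <- rep(1, nrow(pts))
  structure(list(points = pts, marker = marker, noise_tolerance = 0,
                 image_dim = dim, pixel_size_um = px_um),
            class = "cell_detection")
}

# Population SD, written out once more so the outlier rule is checked against
# an expression a reviewer can read off the definition.
pop_sd_oracle <- function(x) sqrt(mean((x - mean(x))^2))

# Truncated-normal draws shared by recovery tests.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}
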