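# Independent oracles, deliberately written as naive loops so they share
# no code path with the package implementations they check.

# Exhaustive between-class-variance scan over all 256 thresholds;
# classes are levels <= t vs > t, ties go to the smallest t.
bruteOtsu <- function(hist) {
  total <- sum(hist)
  best <- 0L
  bestVar <- -1
  for (t in 0:255) {
    n0 <- sum(hist[1:(t + 1)])
    n1 <- total - n0
    v <- 0
    if (n0 > 0 && n1 > 0) {
      mu0 <- sum((0:t) * hist[1:(t + 1)]) / n0
      mu1 <- sum(((t + 1):255) * hist[(t + 2):256]) / n1
      v <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    }
    if (v > bestVar + 1e-12) {
      bestVar <- v
      best <- t
    }
  }
  best
}

# Breadth-first flood fill count of connected foreground regions.
floodCount <- function(mask, connectivity = 8) {
  m <- mask > 0
  seen <- matrix(FALSE, nrow(m), ncol(m))
  offs <- if (connectivity == 8)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  n <- 0
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (!m[r, c] || seen[r, c]) next
    n <- n + 1
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r2 <- p[1] + offs[k, 1]; c2 <- p[2] + offs[k, 2]
        if (r2 >= 1 && r2 <= nrow(m) && c2 >= 1 && c2 <= ncol(m) &&
            m[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue <- c(queue, list(c(r2, c2)))
        }
      }
    }
  }
  n
}

# O(n^2) double loop over all pixel pairs.
bruteMinDist <- function(ea, eb) {
  best <- Inf
  for (i in seq_len(nrow(ea))) for (j in seq_len(nrow(eb))) {
    d <- sqrt((ea[i, 1] - eb[j, 1])^2 + (ea[i, 2] - eb[j, 2])^2)
    if (d < best) best <- d
  }
  unname(best)
}

# Independent rasterizers built on expand.grid rather than the package's
# matrix machinery.
rasterDisk <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  g <- expand.grid(y = 1:n, x = 1:n)
  m <- matrix(FALSE, n, n)
  inside <- (g$x - ctr)^2 + (g$y - ctr)^2 <= r^2
  m[cbind(g$y[inside], g$x[inside])] <- TRUE
  m
}

rasterEllipse <- function(a, b, pad = 3) {
  nx <- 2 * (a + pad) + 1; ny <- 2 * (b + pad) + 1
  cx <- a + pad + 1; cy <- b + pad + 1
  g <- expand.grid(y = 1:ny, x = 1:nx)
  m <- matrix(FALSE, ny, nx)
  inside <- ((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1
  m[cbind(g$y[inside], g$x[inside])] <- TRUE
  m
}

randomMask <- function(h, w, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w) * 1L
}

randomHistogram <- function() {
  h <- integer(256)
  nLevels <- sample(1:40, 1)
  lev <- sample(0:255, nLevels)
  h[lev + 1] <- sample(1:500, nLevels, replace = TRUE)
  h
}
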