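# Independent brute-force oracles for the texture matrices: naive exhaustive
# enumeration over voxels/pairs, written without reference to the package's
# compiled accumulators. `bins` is an integer array with 0 outside the region.

oracle_offsets13 <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  # unique direction pairs: keep lexicographically positive half
  keep <- apply(offs, 1, function(o) {
    o <- as.numeric(o)
    first <- o[which(o != 0)[1]]
    first > 0
  })
  offs[keep, ]
}

oracle_glcm <- function(bins) {
  d <- dim(bins)
  ng <- max(bins)
  P <- matrix(0, ng, ng)
  offs <- oracle_offsets13()
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    a <- bins[i, j, k]
    if (a == 0) next
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs$dx[r]; jj <- j + offs$dy[r]; kk <- k + offs$dz[r]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next
      b <- bins[ii, jj, kk]
      if (b == 0) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P
}

oracle_glrlm <- function(bins) {
  d <- dim(bins)
  ng <- max(bins)
  P <- matrix(0, ng, max(d))
  offs <- oracle_offsets13()
  inb <- function(i, j, k) i >= 1 && j >= 1 && k >= 1 &&
    i <= d[1] && j <= d[2] && k <= d[3]
  for (r in seq_len(nrow(offs))) {
    dx <- offs$dx[r]; dy <- offs$dy[r]; dz <- offs$dz[r]
    for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
      a <- bins[i, j, k]
      if (a == 0) next
      if (inb(i - dx, j - dy, k - dz) && bins[i - dx, j - dy, k - dz] == a)
        next
      len <- 1
      ci <- i + dx; cj <- j + dy; ck <- k + dz
      while (inb(ci, cj, ck) && bins[ci, cj, ck] == a) {
        len <- len + 1
        ci <- ci + dx; cj <- cj + dy; ck <- ck + dz
      }
      P[a, len] <- P[a, len] + 1
    }
  }
  P
}

oracle_glszm <- function(bins) {
  d <- dim(bins)
  seen <- array(FALSE, d)
  zones <- NULL
  nbr <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nbr <- nbr[!(nbr$dx == 0 & nbr$dy == 0 & nbr$dz == 0), ]
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (seen[i, j, k] || bins[i, j, k] == 0) next
    a <- bins[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(nbr))) {
        ii <- cur[1] + nbr$dx[r]; jj <- cur[2] + nbr$dy[r]
        kk <- cur[3] + nbr$dz[r]
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] ||
            kk > d[3]) next
        if (!seen[ii, jj, kk] && bins[ii, jj, kk] == a) {
          seen[ii, jj, kk] <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj, kk)
        }
      }
    }
    zones <- rbind(zones, c(a, size))
  }
  zones
}

oracle_gldm <- function(bins, alpha = 0) {
  d <- dim(bins)
  ng <- max(bins)
  P <- matrix(0, ng, 27)
  nbr <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nbr <- nbr[!(nbr$dx == 0 & nbr$dy == 0 & nbr$dz == 0), ]
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    a <- bins[i, j, k]
    if (a == 0) next
    dep <- 1
    for (r in seq_len(nrow(nbr))) {
      ii <- i + nbr$dx[r]; jj <- j + nbr$dy[r]; kk <- k + nbr$dz[r]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next
      b <- bins[ii, jj, kk]
      if (b != 0 && abs(b - a) <= alpha) dep <- dep + 1
    }
    P[a, dep] <- P[a, dep] + 1
  }
  P
}

oracle_ngtdm <- function(bins) {
  d <- dim(bins)
  ng <- max(bins)
  out <- matrix(0, ng, 2)
  nbr <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nbr <- nbr[!(nbr$dx == 0 & nbr$dy == 0 & nbr$dz == 0), ]
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    a <- bins[i, j, k]
    if (a == 0) next
    vals <- c()
    for (r in seq_len(nrow(nbr))) {
      ii <- i + nbr$dx[r]; jj <- j + nbr$dy[r]; kk <- k + nbr$dz[r]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next
      b <- bins[ii, jj, kk]
      if (b != 0) vals <- c(vals, b)
    }
    if (!length(vals)) next
    out[a, 1] <- out[a, 1] + 1
    out[a, 2] <- out[a, 2] + abs(a - mean(vals))
  }
  out
}

# Digital sphere mask of radius r (mm) on an isotropic grid.
sphere_mask <- function(r_mm, spacing = c(1, 1, 1), pad_mm = 6) {
  half <- r_mm + pad_mm
  dims <- as.integer(ceiling(2 * half / spacing)) + 1L
  centre <- (dims - 1) / 2 * spacing
  ax <- (seq_len(dims[1]) - 1) * spacing[1] - centre[1]
  ay <- (seq_len(dims[2]) - 1) * spacing[2] - centre[2]
  az <- (seq_len(dims[3]) - 1) * spacing[3] - centre[3]
  m <- outer(outer(ax^2, ay^2, `+`), az^2, `+`) <= r_mm^2
  attr(m, "spacing") <- spacing
  m
}

# One small heterogeneous phantom case, cached for reuse across test files.
cached_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(n_cases = 1, seed = 421, n_populations = 3,
                          population_separation = 200, noise_sd = 5,
                          lesion_radius_range_mm = c(9, 11))
      cache <<- generate_lesion(spec, 1)
    }
    cache
  }
})
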