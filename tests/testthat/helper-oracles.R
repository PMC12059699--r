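# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package.

# exhaustive 256-bin between-class variance scan
oracle_otsu_scan <- function(m, nbins = 256L) {
  v <- as.vector(m)
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  best <- -Inf; best_t <- NA_real_
  for (t in 1:(nbins - 1L)) {
    in0 <- idx <= t
    n0 <- sum(in0); n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(mids[idx[in0]]) / n0
    mu1 <- sum(mids[idx[!in0]]) / n1
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- edges[t + 1L] }
  }
  best_t
}

# stack-based 8-connected flood fill; returns number of components
oracle_flood_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[p]) next
      seen[p] <- TRUE
      r <- ((p - 1L) %% nr) + 1L; cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          q <- (c2 - 1L) * nr + r2
          if (mask[q] && !seen[q]) stack <- c(stack, q)
        }
      }
    }
  }
  count
}

# all-pairs half-open interval overlap
oracle_genes_with_peak <- function(windows, peaks) {
  hits <- character(0)
  for (i in seq_len(nrow(windows))) {
    for (j in seq_len(nrow(peaks))) {
      if (windows$chrom[i] == peaks$chrom[j] &&
          windows$start[i] < peaks$end[j] &&
          peaks$start[j] < windows$end[i]) {
        hits <- c(hits, windows$gene_id[i])
        break
      }
    }
  }
  unique(hits)
}

# KS D by scanning every pooled breakpoint
oracle_ks_d <- function(a, b) {
  brk <- sort(unique(c(a, b)))
  max(vapply(brk, function(t) abs(mean(a <= t) - mean(b <= t)), 0))
}

# Kolmogorov survival function via the Jacobi-theta (small-x) series,
# an algebraically different form from the package's alternating series
oracle_kolmogorov_sf <- function(x) {
  if (x <= 0) return(1)
  k <- seq_len(200L)
  1 - sqrt(2 * pi) / x * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * x^2)))
}

# direct 2-D Gaussian kernel, normalized over its truncated support
oracle_gaussian_kernel_2d <- function(sigma, radius) {
  x <- -radius:radius
  k <- outer(x, x, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  k / sum(k)
}

rotate90 <- function(m) t(m)[, nrow(m):1]

disk_mask <- function(n, r0, c0, r) {
  (row(matrix(0, n, n)) - r0)^2 + (col(matrix(0, n, n)) - c0)^2 <= r^2
}
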