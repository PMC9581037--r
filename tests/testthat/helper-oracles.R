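# Independent brute-force oracles used to validate the package's fast paths.
# All are O(n^2) (or worse) and operate on plain coordinate vectors.

toy_table <- function(x, y, sd = 10) {
  localization_table(x, y, rep_len(sd, length(x)))
}

bf_neighbor_counts <- function(x, y, r) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  as.integer(colSums(d <= r) - 1L)
}

# textbook DBSCAN on the full distance matrix
bf_dbscan <- function(x, y, eps, minPts) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # includes self
  core <- lengths(nbr) >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- i
    while (length(seeds)) {
      u <- seeds[1]
      seeds <- seeds[-1]
      if (!core[u]) next
      new <- nbr[[u]][labels[nbr[[u]]] == 0L]
      labels[new] <- cl
      seeds <- c(seeds, new)
    }
  }
  labels
}

# straight R transcription of the persistence merge trace on the same graph
bf_tomato <- function(x, y, r, tau) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nbr <- lapply(seq_len(n), function(i) setdiff(which(d[i, ] <= r), i))
  dens <- lengths(nbr)
  ord <- order(-dens, seq_len(n))
  rnk <- match(seq_len(n), ord)
  parent <- seq_len(n)
  peak <- rep(NA_real_, n)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  for (pos in seq_len(n)) {
    i <- ord[pos]
    proc <- nbr[[i]][rnk[nbr[[i]]] < pos]
    if (!length(proc)) {
      peak[i] <- dens[i]
      next
    }
    best <- proc[which.min(rnk[proc])]
    parent[i] <- find(best)
    for (j in proc) {
      r1 <- find(i)
      r2 <- find(j)
      if (r1 == r2) next
      hi <- r1
      lo <- r2
      if (peak[r2] > peak[r1] || (peak[r2] == peak[r1] && rnk[r2] < rnk[r1])) {
        hi <- r2
        lo <- r1
      }
      if (peak[lo] - dens[i] < tau) parent[lo] <- hi
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  labels <- integer(n)
  cl <- 0L
  relab <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    rt <- roots[i]
    if (peak[rt] < tau) next
    if (is.na(relab[rt])) {
      cl <- cl + 1L
      relab[rt] <- cl
    }
    labels[i] <- relab[rt]
  }
  labels
}

# do two labelings describe the same partition (bijection between labels,
# background 0 mapped to background 0)?
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  if (!any(a != 0L)) return(TRUE)
  t <- table(a[a != 0L], b[b != 0L])
  all(rowSums(t > 0) == 1) && all(colSums(t > 0) == 1)
}

# 2D Simpson quadrature of the single-sigma cluster marginal likelihood
# m = (1/A) * int prod_i N2(x_i; mu, v_i I) dmu over a window wide enough
# to hold essentially all posterior mass of mu
quad_marginal <- function(x, y, sd, sigma, A, m = 801, width = 12) {
  v <- sigma^2 + sd^2
  prec <- sum(1 / v)
  mu_x <- sum(x / v) / prec
  mu_y <- sum(y / v) / prec
  half <- width / sqrt(prec)
  gx <- seq(mu_x - half, mu_x + half, length.out = m)
  gy <- seq(mu_y - half, mu_y + half, length.out = m)
  # log product of 1D normal densities, evaluated on each axis grid
  lpx <- vapply(gx, function(mu) sum(dnorm(x, mu, sqrt(v), log = TRUE)), 0)
  lpy <- vapply(gy, function(mu) sum(dnorm(y, mu, sqrt(v), log = TRUE)), 0)
  # Simpson weights
  w <- rep(c(2, 4), length.out = m)
  w[1] <- w[m] <- 1
  hx <- (gx[2] - gx[1]) / 3
  hy <- (gy[2] - gy[1]) / 3
  mx <- max(lpx)
  my <- max(lpy)
  ix <- sum(w * exp(lpx - mx)) * hx
  iy <- sum(w * exp(lpy - my)) * hy
  # separable integrand: the 2D Simpson sum factorizes exactly
  log(ix) + mx + log(iy) + my - log(A)
}

# direct-ranking Kruskal-Wallis with tie correction
bf_kruskal <- function(groups) {
  xall <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(xall)
  o <- order(xall)
  rk <- numeric(N)
  i <- 1
  while (i <= N) {
    j <- i
    while (j < N && xall[o[j + 1]] == xall[o[i]]) j <- j + 1
    rk[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  Rj <- tapply(rk, g, sum)
  nj <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie <- table(xall)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  H / C
}
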