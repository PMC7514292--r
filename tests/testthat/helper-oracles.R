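# Independent brute-force oracles and small fixture builders.

# Plug-in transfer entropy by direct evaluation of the probability table
# (triplet counts over t = 1..T-1), independent of the compiled path.
te_oracle <- function(x, y) {
  n <- length(x) - 1
  trip <- data.frame(x1 = x[-1], x0 = x[-(n + 1)], y0 = y[-(n + 1)])
  counts <- aggregate(cnt ~ x1 + x0 + y0, cbind(trip, cnt = 1), sum)
  n_x0y0 <- aggregate(cnt ~ x0 + y0, cbind(trip, cnt = 1), sum)
  n_x1x0 <- aggregate(cnt ~ x1 + x0, cbind(trip, cnt = 1), sum)
  n_x0 <- aggregate(cnt ~ x0, cbind(trip, cnt = 1), sum)
  te <- 0
  for (r in seq_len(nrow(counts))) {
    p3 <- counts$cnt[r] / n
    p_joint <- counts$cnt[r] /
      n_x0y0$cnt[n_x0y0$x0 == counts$x0[r] & n_x0y0$y0 == counts$y0[r]]
    p_own <- n_x1x0$cnt[n_x1x0$x1 == counts$x1[r] & n_x1x0$x0 == counts$x0[r]] /
      n_x0$cnt[n_x0$x0 == counts$x0[r]]
    te <- te + p3 * log2(p_joint / p_own)
  }
  te
}

ce_oracle <- function(x) {
  n <- length(x) - 1
  pair <- data.frame(x1 = x[-1], x0 = x[-(n + 1)])
  counts <- aggregate(cnt ~ x1 + x0, cbind(pair, cnt = 1), sum)
  n_x0 <- aggregate(cnt ~ x0, cbind(pair, cnt = 1), sum)
  h <- 0
  for (r in seq_len(nrow(counts))) {
    p2 <- counts$cnt[r] / n
    p0 <- n_x0$cnt[n_x0$x0 == counts$x0[r]] / n
    h <- h - p2 * log2(p2 / p0)
  }
  h
}

# All simple paths from k to j in a directed distance matrix (Inf = no
# edge); returns list of total lengths and of intermediate-node sets.
enum_paths <- function(d, from, to) {
  n <- nrow(d)
  lengths <- numeric(0)
  through <- list()
  recurse <- function(node, visited, len) {
    if (node == to) {
      lengths[[length(lengths) + 1]] <<- len
      through[[length(through) + 1]] <<- setdiff(visited, c(from, to))
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (nxt %in% visited || !is.finite(d[node, nxt]) || nxt == node) next
      recurse(nxt, c(visited, nxt), len + d[node, nxt])
    }
  }
  recurse(from, from, 0)
  list(lengths = lengths, through = through)
}

# Betweenness (tied shortest paths counted) and characteristic path
# length by exhaustive simple-path enumeration.
bc_oracle <- function(d, tol = 1e-9) {
  n <- nrow(d)
  bc <- numeric(n)
  sp <- matrix(Inf, n, n)
  for (k in seq_len(n)) for (j in seq_len(n)) {
    if (k == j) { sp[k, j] <- 0; next }
    paths <- enum_paths(d, k, j)
    if (length(paths$lengths) == 0) next
    dmin <- min(paths$lengths)
    sp[k, j] <- dmin
    shortest <- which(paths$lengths <= dmin + tol)
    for (i in setdiff(seq_len(n), c(k, j))) {
      n_through <- sum(vapply(shortest, function(s)
        i %in% paths$through[[s]], TRUE))
      bc[i] <- bc[i] + n_through / length(shortest)
    }
  }
  off <- sp[row(sp) != col(sp)]
  list(bc = bc / ((n - 1) * (n - 2)),
       cpl = mean(off[is.finite(off)]))
}

# LZ76 production count by string search over the extended history.
lz76_oracle <- function(sym) {
  s <- paste(sym, collapse = "")
  n <- nchar(s)
  if (n == 0) return(0L)
  c <- 1L; l <- 2L
  while (l <= n) {
    k <- 0L
    while (l + k <= n &&
           grepl(substr(s, l, l + k), substr(s, 1, l + k - 1), fixed = TRUE))
      k <- k + 1L
    c <- c + 1L
    l <- l + k + 1L
  }
  c
}

# fixture builders ------------------------------------------------------

random_connectivity <- function(n, seed, density = 0.6) {
  set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  w[matrix(runif(n * n) > density, n, n)] <- 0
  diag(w) <- 0
  labels <- sprintf("N%02d", seq_len(n))
  dimnames(w) <- list(labels, labels)
  structure(list(weights = w, channel_labels = labels,
                 params = analysis_config(), condition = ""),
            class = "connectivity_matrix")
}

noise_recording <- function(n_ch = 3, n_samp = 1000, fs = 100, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n_ch * n_samp), n_ch, n_samp), fs)
}

# best template assignment over all permutations, with polarity freedom
match_templates <- function(fitted, planted) {
  k <- nrow(planted)
  pl <- t(planted)
  pl <- sweep(pl, 2, colMeans(pl))
  pl <- sweep(pl, 2, sqrt(colSums(pl^2)), "/")
  cmat <- abs(crossprod(fitted, pl))   # fitted k x planted k
  perms <- all_perms(k)
  scores <- vapply(perms, function(p) mean(cmat[cbind(seq_len(k), p)]), 0)
  best <- perms[[which.max(scores)]]
  list(perm = best, corrs = cmat[cbind(seq_len(k), best)])
}

all_perms <- function(k) {
  perm_of <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_of(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  perm_of(seq_len(k))
}
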