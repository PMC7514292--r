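#' Discretize a signal into equal-width bins
#'
#' Bins span `[min, max]` of the signal; the maximum value falls in the
#' top bin. A constant signal maps to all-zero symbols. Each channel is
#' discretized independently before transfer-entropy estimation.
#'
#' @param signal finite numeric vector, length >= 2.
#' @param n_bins alphabet size, >= 2.
#' @return Integer vector of symbols in `[0, n_bins)`.
#' @export
discretize <- function(signal, n_bins = 8L) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (length(signal) < 2) stop("signal must have at least 2 samples")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  rng <- range(signal)
  if (rng[2] - rng[1] < .Machine$double.eps)
    return(integer(length(signal)))
  sym <- floor((signal - rng[1]) / (rng[2] - rng[1]) * n_bins)
  as.integer(pmin(sym, n_bins - 1L))
}

#' Transfer entropy between symbol series
#'
#' Plug-in estimate, in bits, of the information flow from `y` to `x`
#' with single-lag embedding:
#' `TE = sum p(x1, x0, y0) log2[ p(x1 | x0, y0) / p(x1 | x0) ]`,
#' with joint probabilities from counts over `t = 1..T-1` and the
#' convention `0 log 0 = 0`. The measure is asymmetric and vanishes in
#' the large-sample limit when `y` carries no information about `x`'s
#' future beyond `x`'s own past.
#'
#' @param x,y integer symbol vectors of equal length (target `x`,
#'   source `y`), symbols in `[0, n_bins)`.
#' @param n_bins alphabet size; defaults to `max(symbols) + 1`.
#' @return Transfer entropy in bits (>= 0).
#' @export
transfer_entropy <- function(x, y, n_bins = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("series must have at least 2 samples")
  if (is.null(n_bins)) n_bins <- max(x, y) + 1L
  .te_symbols_cpp(as.integer(x), as.integer(y), as.integer(n_bins))
}

#' Conditional entropy of a symbol series
#'
#' `H(x_{t+1} | x_t) = -sum p(x1, x0) log2[ p(x1, x0) / p(x0) ]` in bits;
#' the normalizer of the normalized transfer entropy.
#'
#' @inheritParams transfer_entropy
#' @return Conditional entropy in bits (>= 0).
#' @export
conditional_entropy <- function(x, n_bins = NULL) {
  if (length(x) < 2) stop("series must have at least 2 samples")
  if (is.null(n_bins)) n_bins <- max(x) + 1L
  .ce_symbols_cpp(as.integer(x), as.integer(n_bins))
}

#' Normalized transfer entropy between two raw signals
#'
#' Discretizes both signals, estimates the transfer entropy from `y_raw`
#' to `x_raw`, subtracts the mean transfer entropy over
#' `cfg$n_surrogates` seeded random permutations of the source series
#' (which destroys all temporal structure and estimates the finite-sample
#' bias), and divides by the conditional entropy `H(x_{t+1} | x_t)` of
#' the target. Negative values after bias subtraction are floored at 0 so
#' the result is a valid graph weight; a deterministic target
#' (`H = 0`) yields 0 with a warning.
#'
#' @param x_raw,y_raw equal-length finite numeric vectors (target,
#'   source).
#' @param cfg an [analysis_config()]; uses `n_bins`, `n_surrogates`,
#'   `seed`.
#' @return Normalized transfer entropy (unitless, >= 0).
#' @export
nte <- function(x_raw, y_raw, cfg = analysis_config()) {
  if (length(x_raw) != length(y_raw)) stop("x and y must have equal length")
  xs <- discretize(x_raw, cfg$n_bins)
  ys <- discretize(y_raw, cfg$n_bins)
  with_seed(cfg$seed, nte_symbols(xs, ys, cfg))
}

# core NTE on pre-discretized series; caller owns RNG state.
# `perms` (samples x n_surrogates, 1-based) may be shared across pairs.
nte_symbols <- function(xs, ys, cfg, h = NULL, perms = NULL) {
  nb <- cfg$n_bins
  if (is.null(h)) h <- .ce_symbols_cpp(xs, nb)
  if (h <= 0) {
    warning("deterministic target series (H = 0); NTE defined as 0")
    return(0)
  }
  if (is.null(perms)) perms <- surrogate_perms(length(ys), cfg$n_surrogates)
  te <- .te_symbols_cpp(xs, ys, nb)
  surr <- .te_surrogate_mean_cpp(xs, ys, perms, nb)
  max(0, (te - surr) / h)
}

surrogate_perms <- function(n, n_surrogates) {
  vapply(seq_len(n_surrogates), function(i) sample.int(n), integer(n))
}

#' Directed effective-connectivity matrix
#'
#' Estimates the normalized transfer entropy for every ordered channel
#' pair. Orientation: `weights[i, j]` is the flow from channel `j`
#' (sender, columns) to channel `i` (receiver, rows); the diagonal is
#' exactly zero. The surrogate stream is seeded once from `cfg$seed`
#' (plus `seed_offset`), so the result is bit-reproducible.
#'
#' @param rec a [recording()].
#' @param cfg an [analysis_config()].
#' @param seed_offset integer added to `cfg$seed`, used by windowed
#'   analyses to decorrelate surrogate draws across windows.
#' @return An object of class `connectivity_matrix`: list with `weights`
#'   (N x N, receivers x senders), `channel_labels`, `params`.
#' @export
connectivity_matrix <- function(rec, cfg = analysis_config(), seed_offset = 0L) {
  n <- n_channels(rec)
  if (n < 3)
    warning("fewer than 3 channels: graph metrics will be degenerate")
  sym <- t(apply(rec$data, 1, discretize, n_bins = cfg$n_bins))
  hs <- vapply(seq_len(n), function(i) .ce_symbols_cpp(sym[i, ], cfg$n_bins), 0)
  w <- matrix(0, n, n)
  with_seed(cfg$seed + seed_offset, {
    # one seeded surrogate permutation set, shared by all ordered pairs:
    # each pair's bias estimate stays unbiased and the draw cost is O(1)
    perms <- surrogate_perms(ncol(sym), cfg$n_surrogates)
    for (i in seq_len(n)) {       # receiver
      for (j in seq_len(n)) {     # sender
        if (i == j) next
        w[i, j] <- suppressWarnings(
          nte_symbols(sym[i, ], sym[j, ], cfg, h = hs[i], perms = perms))
      }
    }
  })
  dimnames(w) <- list(rec$channel_labels, rec$channel_labels)
  structure(list(weights = w, channel_labels = rec$channel_labels,
                 params = cfg, condition = rec$condition),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d nodes (rows = receivers, cols = senders)\n",
              nrow(x$weights)))
  cat(sprintf("  mean off-diagonal NTE: %.4g\n",
              mean(x$weights[row(x$weights) != col(x$weights)])))
  invisible(x)
}

#' Write / read a connectivity matrix as delimited text
#'
#' The header records the orientation convention and the configuration
#' used to estimate the matrix.
#'
#' @param cm a `connectivity_matrix`.
#' @param path file path.
#' @return `read_connectivity` returns a `connectivity_matrix`.
#' @export
write_connectivity <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# NTE connectivity matrix; rows = receivers, columns = senders",
               sprintf("# n_bins=%d n_surrogates=%d seed=%d",
                       cm$params$n_bins, cm$params$n_surrogates,
                       cm$params$seed)), con)
  write.table(format(cm$weights, digits = 17, trim = TRUE),
              con, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  w <- as.matrix(read.table(path, sep = "\t", comment.char = "#",
                            header = TRUE, row.names = 1, check.names = FALSE))
  structure(list(weights = w, channel_labels = rownames(w),
                 params = analysis_config(), condition = ""),
            class = "connectivity_matrix")
}
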