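#' Global field power
#'
#' Per-sample spatial standard deviation across channels about the
#' instantaneous channel mean:
#' `GFP_t = sqrt( sum_i (x_{i,t} - mean_t)^2 / N_ch )`. Peaks of the GFP
#' index moments of strong, stable topography and are where microstate
#' templates are fitted.
#'
#' @param rec a [recording()] (>= 2 channels).
#' @return Nonnegative numeric vector, one value per sample.
#' @export
gfp <- function(rec) {
  x <- rec$data
  mu <- colMeans(x)
  sqrt(colMeans(sweep(x, 2, mu)^2))
}

# indices of strict-neighbor local maxima of a series
local_maxima <- function(x) {
  n <- length(x)
  which(x >= c(-Inf, x[-n]) & x > c(x[-1], -Inf))
}

# average-reference and unit-normalize a map (columns = maps)
norm_maps <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  nrm <- sqrt(colSums(m^2))
  nrm[nrm == 0] <- 1
  sweep(m, 2, nrm, "/")
}

#' Fit microstate templates by polarity-invariant k-means
#'
#' Extracts the scalp maps at local maxima of the global field power,
#' average-references and unit-normalizes them, and runs the modified
#' k-means of microstate analysis: maps are assigned to the template
#' with maximal squared spatial correlation (polarity-invariant), and
#' each template is updated to the first principal axis of its assigned
#' maps. Iterations stop when the relative change in global explained
#' variance (GEV) falls below `tol` or after `max_iter` iterations.
#' Deterministic given `seed` (which picks the initial template maps).
#'
#' @param rec a [recording()].
#' @param k number of microstate classes (default 4).
#' @param seed integer seed for the initialization.
#' @param n_init number of seeded restarts; the fit with the highest GEV
#'   is kept.
#' @param tol,max_iter convergence controls.
#' @return An object of class `microstate_model`: list with `templates`
#'   (channels x k, unit-norm, labeled `A`, `B`, ...), `gev`, `k`.
#' @export
fit_microstates <- function(rec, k = 4L, seed = 1L, n_init = 5L,
                            tol = 1e-6, max_iter = 100L) {
  g <- gfp(rec)
  pk <- local_maxima(g)
  if (length(pk) < 10 * k)
    stop("too few GFP peaks (", length(pk), ") to fit ", k,
         " templates; need at least ", 10 * k)
  maps <- norm_maps(rec$data[, pk, drop = FALSE])
  gpk <- g[pk]
  denom <- sum(gpk^2)
  fit_once <- function() {
    tpl <- maps[, sample.int(ncol(maps), k), drop = FALSE]
    gev_old <- -Inf
    for (iter in seq_len(max_iter)) {
      corr <- crossprod(tpl, maps)        # k x n_peaks
      assign <- max.col(t(corr^2), ties.method = "first")
      for (j in seq_len(k)) {
        sel <- assign == j
        if (!any(sel)) next               # empty class keeps its template
        m <- maps[, sel, drop = FALSE]
        s <- tcrossprod(sweep(m, 2, gpk[sel]^2, "*"), m)
        ev <- eigen(s, symmetric = TRUE)
        tpl[, j] <- ev$vectors[, 1]
      }
      tpl <- norm_maps(tpl)
      gev <- sum((gpk * corr[cbind(assign, seq_along(assign))])^2) / denom
      if (is.finite(gev_old) && abs(gev - gev_old) < tol * max(gev, 1e-12))
        break
      gev_old <- gev
    }
    list(templates = tpl, gev = gev)
  }
  best <- with_seed(seed, {
    fits <- lapply(seq_len(n_init), function(i) fit_once())
    fits[[which.max(vapply(fits, `[[`, 0, "gev"))]]
  })
  colnames(best$templates) <- LETTERS[seq_len(k)]
  rownames(best$templates) <- rec$channel_labels
  structure(list(templates = best$templates, gev = best$gev, k = k),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> %d templates over %d channels, GEV = %.3f\n",
              x$k, nrow(x$templates), x$gev))
  invisible(x)
}

#' Backfit a microstate model to every sample
#'
#' Labels each sample with the template of maximal squared spatial
#' correlation (polarity-invariant); ties break to the lowest label
#' index. Flat (zero-GFP) samples get label 1 by the tie rule and are
#' flagged in attribute `flat`.
#'
#' @param rec a [recording()].
#' @param model a `microstate_model` over the same channels.
#' @param smooth_min_samples optional minimum run length; shorter label
#'   runs are absorbed into the preceding run (off by default, matching
#'   the unsmoothed reference analysis).
#' @return An object of class `microstate_sequence`: list with `labels`
#'   (integer 1..k per sample), `label_chr` (letters), `gfp`, `k`.
#' @export
backfit <- function(rec, model, smooth_min_samples = 0L) {
  if (nrow(model$templates) != n_channels(rec))
    stop("model has ", nrow(model$templates), " channels but recording has ",
         n_channels(rec))
  maps <- norm_maps(rec$data)
  corr2 <- crossprod(model$templates, maps)^2   # k x T
  labels <- max.col(t(corr2), ties.method = "first")
  g <- gfp(rec)
  flat <- g == 0
  if (smooth_min_samples > 1) {
    r <- rle(labels)
    short <- which(r$lengths < smooth_min_samples)
    for (i in short) if (i > 1) r$values[i] <- r$values[i - 1]
    labels <- inverse.rle(r)
  }
  structure(list(labels = labels,
                 label_chr = LETTERS[labels],
                 gfp = g, k = model$k, flat = flat),
            class = "microstate_sequence")
}

#' @export
print.microstate_sequence <- function(x, ...) {
  cat(sprintf("<microstate_sequence> %d samples, %d classes; occupancy: %s\n",
              length(x$labels), x$k,
              paste(sprintf("%s %.0f%%", LETTERS[seq_len(x$k)],
                            100 * tabulate(x$labels, x$k) / length(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Lempel-Ziv (LZ76) complexity of a symbol sequence
#'
#' Counts the phrases of the exhaustive-history parse of the sequence
#' (each phrase is the longest substring reproducible from the extended
#' history plus one new symbol). Also reports the normalized form
#' `c(n) * log_alpha(n) / n` with the logarithm base equal to the
#' alphabet size, so quaternary microstate sequences of different window
#' lengths are comparable.
#'
#' @param seq integer vector (symbols `1..alphabet_size` or
#'   `0..alphabet_size-1`), a character vector of single letters, or a
#'   `microstate_sequence`.
#' @param alphabet_size alphabet size (default 4, quaternary).
#' @return List with `c` (integer parse count) and `normalized`.
#' @export
lz_complexity <- function(seq, alphabet_size = 4L) {
  if (inherits(seq, "microstate_sequence")) {
    alphabet_size <- seq$k
    seq <- seq$labels
  }
  if (is.character(seq)) seq <- match(seq, LETTERS)
  seq <- as.integer(seq)
  if (length(seq) == 0) stop("empty sequence")
  if (min(seq) >= 1) seq <- seq - 1L
  if (any(seq < 0 | seq >= alphabet_size))
    stop("symbols outside the stated alphabet of size ", alphabet_size)
  n <- length(seq)
  c_n <- .lz76_cpp(seq)
  list(c = c_n, normalized = c_n * log(n, base = alphabet_size) / n)
}

#' Per-window microstate complexity grouped by trigger type
#'
#' For every window carrying at least one hub-type peak, computes the
#' LZ76 complexity of the microstate label subsequence inside the
#' window, and groups windows into `HD`, `HC`, `HN` (exactly one type
#' peaking) or `common` (two or more types peaking simultaneously). The
#' groups partition the triggered windows.
#'
#' @param ms a `microstate_sequence` aligned with the recording the
#'   windows came from.
#' @param ws a `window_series` from [hub_count_series()] (needs
#'   `start_s`).
#' @param fs sampling rate of the label sequence, Hz.
#' @param window_length_s window length in seconds.
#' @param k_sd peak threshold, see [detect_peaks()].
#' @return Data frame with columns `window`, `group`, `c`, `normalized`;
#'   zero rows (with a warning) when no window is triggered.
#' @export
windowed_complexity <- function(ms, ws, fs, window_length_s = 5, k_sd = 1) {
  peaks <- cbind(HD = detect_peaks(ws$n_HD, k_sd),
                 HC = detect_peaks(ws$n_HC, k_sd),
                 HN = detect_peaks(ws$n_HN, k_sd))
  n_types <- rowSums(peaks)
  triggered <- which(n_types > 0)
  if (length(triggered) == 0) {
    warning("no triggered windows")
    return(data.frame(window = integer(), group = character(),
                      c = integer(), normalized = numeric()))
  }
  len <- floor(window_length_s * fs)
  out <- lapply(triggered, function(w) {
    s <- floor(ws$start_s[w] * fs) + 1L
    e <- min(s + len - 1L, length(ms$labels))
    lz <- lz_complexity(ms$labels[s:e], ms$k)
    grp <- if (n_types[w] >= 2) "common"
           else colnames(peaks)[which(peaks[w, ])]
    data.frame(window = w, group = grp, c = lz$c,
               normalized = lz$normalized)
  })
  do.call(rbind, out)
}

#' Write / read a microstate sequence as a single-column label file
#' @param ms a `microstate_sequence`.
#' @param path file path.
#' @param fs sampling rate recorded in the header.
#' @return `read_microstate_sequence` returns a `microstate_sequence`.
#' @export
write_microstate_sequence <- function(ms, path, fs) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g k=%d", fs, ms$k), con)
  writeLines(ms$label_chr, con)
  invisible(path)
}

#' @rdname write_microstate_sequence
#' @export
read_microstate_sequence <- function(path) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1], regexec("fs=([0-9.eE+-]+) k=([0-9]+)", lines[1]))[[1]]
  labels <- match(lines[-1], LETTERS)
  structure(list(labels = labels, label_chr = lines[-1],
                 gfp = rep(NA_real_, length(labels)),
                 k = as.integer(hdr[3]),
                 flat = rep(FALSE, length(labels))),
            class = "microstate_sequence")
}

#' Write a microstate model (channels x k template matrix)
#' @param model a `microstate_model`.
#' @param path file path.
#' @export
write_microstate_model <- function(model, path) {
  write.table(format(model$templates, digits = 17, trim = TRUE),
              path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
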