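#' Sliding windows over a recording
#'
#' Step = `length * (1 - overlap)` samples, rounded down (minimum 1);
#' the trailing partial window is dropped. A window longer than the
#' recording yields one full-recording window with a warning.
#'
#' @param rec a [recording()].
#' @param length_s window length in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return List of [recording()] views; each carries attributes
#'   `start_sample` (1-based) and `start_s`.
#' @export
sliding_windows <- function(rec, length_s = 5, overlap = 0.8) {
  stopifnot(overlap >= 0, overlap < 1)
  len <- floor(length_s * rec$fs)
  if (len < 2) stop("window must span at least 2 samples")
  total <- n_samples(rec)
  if (len > total) {
    warning("window longer than recording; returning a single full window")
    len <- total
  }
  step <- max(1L, floor(len * (1 - overlap) + 1e-9))
  starts <- seq(1L, total - len + 1L, by = step)
  lapply(starts, function(s) {
    w <- rec
    w$data <- rec$data[, s:(s + len - 1L), drop = FALSE]
    attr(w, "start_sample") <- s
    attr(w, "start_s") <- (s - 1) / rec$fs
    w
  })
}

#' Connectivity matrix per sliding window
#'
#' Runs [connectivity_matrix()] in every window. Each window's surrogate
#' stream is seeded with `cfg$seed` plus the window index, so results
#' are reproducible and windows are decorrelated.
#'
#' @param rec a [recording()].
#' @param cfg an [analysis_config()] (window geometry and NTE settings).
#' @return List of `connectivity_matrix`, with window start times in
#'   attribute `start_s`.
#' @export
windowed_connectivity <- function(rec, cfg = analysis_config()) {
  wins <- sliding_windows(rec, cfg$window_length_s, cfg$window_overlap)
  out <- lapply(seq_along(wins), function(k)
    connectivity_matrix(wins[[k]], cfg, seed_offset = k))
  attr(out, "start_s") <- vapply(wins, attr, 0, "start_s")
  out
}

#' Betweenness samples from windowed connectivity matrices
#'
#' @param wcm list of `connectivity_matrix` (see
#'   [windowed_connectivity()]).
#' @param mapping weight-to-distance mapping.
#' @return Matrix, windows x nodes, of betweenness centralities.
#' @export
bc_samples <- function(wcm, mapping = "reciprocal") {
  bc <- t(vapply(wcm, function(cm)
    betweenness_centrality(weight_to_distance(cm, mapping)),
    numeric(nrow(wcm[[1]]$weights))))
  colnames(bc) <- wcm[[1]]$channel_labels
  bc
}

#' Per-window hub-type count series
#'
#' For every window: the window's betweenness centralities identify
#' that window's hubs, each window-hub is typed from the window's
#' output/input degrees, and the counts of divergent, convergent and
#' neutral hubs form three parallel integer series.
#'
#' By default hubs are determined per window by a cross-sectional
#' outlier rule — a node is a window-hub when its betweenness exceeds
#' the across-node mean by more than `bc_k_sd` standard deviations
#' within that window (the single-window analog of "statistically
#' higher centrality than the remaining nodes"; a rank test needs
#' several samples per node and so only applies at the recording
#' level, see [identify_hubs()]). With this rule the total hub count
#' varies from window to window, so hubs of several types can surge
#' together, as they do during network transitions. Passing an explicit
#' `hubs` set switches to fixed-membership counting: the given hubs are
#' merely re-typed in every window.
#'
#' @param wcm list of `connectivity_matrix` from
#'   [windowed_connectivity()].
#' @param bc optional windows x nodes betweenness matrix (computed via
#'   [bc_samples()] when omitted).
#' @param hubs optional fixed hub set: character vector of labels or a
#'   data frame from [identify_hubs()].
#' @param threshold OD/ID imbalance fraction for typing.
#' @param bc_k_sd cross-sectional threshold of the per-window hub rule.
#' @param k_sd peak threshold (in SDs above the mean of each count
#'   series, population SD), recorded for [detect_peaks()].
#' @return An object of class `window_series`: data frame with columns
#'   `window`, `start_s`, `n_HD`, `n_HC`, `n_HN` and attributes
#'   `thresholds`, `k_sd`.
#' @export
hub_count_series <- function(wcm, bc = NULL, hubs = NULL, threshold = 0.10,
                             bc_k_sd = 1, k_sd = 1) {
  if (is.data.frame(hubs)) hubs <- hubs$node[hubs$is_hub]
  if (is.null(hubs) && is.null(bc)) bc <- bc_samples(wcm)
  counts <- t(vapply(seq_along(wcm), function(w) {
    cm <- wcm[[w]]
    members <- if (is.null(hubs)) {
      b <- bc[w, ]
      names(b)[b > mean(b) + bc_k_sd * pop_sd(b)]
    } else hubs
    if (length(members) == 0) return(integer(3))
    ht <- hub_table(cm, members, threshold)
    tab <- table(factor(ht$hub_type[ht$is_hub], levels = c("HD", "HC", "HN")))
    as.integer(tab)
  }, integer(3)))
  start_s <- attr(wcm, "start_s")
  if (is.null(start_s)) start_s <- rep(NA_real_, length(wcm))
  df <- data.frame(window = seq_along(wcm), start_s = start_s,
                   n_HD = counts[, 1], n_HC = counts[, 2], n_HN = counts[, 3])
  thr <- vapply(df[c("n_HD", "n_HC", "n_HN")], function(x)
    mean(x) + k_sd * pop_sd(x), 0)
  attr(df, "thresholds") <- stats::setNames(thr, c("HD", "HC", "HN"))
  attr(df, "k_sd") <- k_sd
  class(df) <- c("window_series", "data.frame")
  df
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Detect triggering peaks in a hub-count series
#'
#' A window is a peak when its count strictly exceeds `mean + k_sd * SD`
#' of the series (population SD) *and* is a local maximum (at least as
#' large as both neighbors; endpoints are compared to their single
#' neighbor). A constant series has no peaks.
#'
#' @param series numeric vector (a hub-count series).
#' @param k_sd threshold in standard deviations.
#' @return Logical vector of the same length.
#' @export
detect_peaks <- function(series, k_sd = 1) {
  n <- length(series)
  if (n < 2) stop("series must have at least 2 windows")
  thr <- mean(series) + k_sd * pop_sd(series)
  left <- c(-Inf, series[-n])
  right <- c(series[-1], -Inf)
  series > thr & series >= left & series >= right
}

#' Correlation between peak-occurrence indicators
#'
#' Product-moment correlation of two binary indicator series (the phi
#' coefficient). Used to quantify co-occurrence of peaks of different
#' hub types across windows. A constant indicator has no defined
#' correlation: `NA` is returned with a warning.
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @return Correlation in `[-1, 1]`, or `NA` for a constant input.
#' @export
peak_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("indicator series must have equal length")
  a <- as.numeric(a); b <- as.numeric(b)
  if (pop_sd(a) == 0 || pop_sd(b) == 0) {
    warning("constant indicator series: correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Windowed hub dynamics of a recording
#'
#' Convenience pipeline: sliding windows -> per-window NTE matrices ->
#' windowed betweenness -> hub identification -> per-window hub-type
#' counts -> peak detection -> pairwise peak correlations.
#'
#' @param rec a [recording()].
#' @param cfg an [analysis_config()].
#' @return List with `windowed` (connectivity matrices), `bc`
#'   (windows x nodes), `hubs` (from [identify_hubs()]), `counts`
#'   (a `window_series`), `peaks` (logical matrix windows x 3), and
#'   `peak_cor` (named correlations `HD_HC`, `HD_HN`, `HC_HN`).
#' @export
hub_dynamics <- function(rec, cfg = analysis_config()) {
  wcm <- windowed_connectivity(rec, cfg)
  bc <- bc_samples(wcm)
  hubs <- identify_hubs(bc, alpha = cfg$significance_level)
  counts <- hub_count_series(wcm, bc = bc,
                             threshold = cfg$imbalance_threshold)
  peaks <- cbind(HD = detect_peaks(counts$n_HD),
                 HC = detect_peaks(counts$n_HC),
                 HN = detect_peaks(counts$n_HN))
  pc <- c(HD_HC = suppressWarnings(peak_correlation(peaks[, "HD"], peaks[, "HC"])),
          HD_HN = suppressWarnings(peak_correlation(peaks[, "HD"], peaks[, "HN"])),
          HC_HN = suppressWarnings(peak_correlation(peaks[, "HC"], peaks[, "HN"])))
  list(windowed = wcm, bc = bc, hubs = hubs, counts = counts,
       peaks = peaks, peak_cor = pc)
}

#' Write a window series (counts and peak flags) as delimited text
#' @param ws a `window_series` from [hub_count_series()].
#' @param path file path.
#' @export
write_window_series <- function(ws, path) {
  out <- as.data.frame(ws)
  out$peak_HD <- detect_peaks(ws$n_HD, attr(ws, "k_sd"))
  out$peak_HC <- detect_peaks(ws$n_HC, attr(ws, "k_sd"))
  out$peak_HN <- detect_peaks(ws$n_HN, attr(ws, "k_sd"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
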