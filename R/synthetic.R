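#' Coupling specification for a simulated directed network
#'
#' Describes a first-order vector-autoregressive (VAR) system
#' `x_i(t+1) = ar_coeff * x_i(t) + sum_{j->i} c_ji * x_j(t) + noise`
#' with a planted directed edge list. The implied system matrix must be
#' stable (spectral radius < 1), which the constructor enforces.
#'
#' @param n_nodes number of nodes (channels).
#' @param edges data frame with columns `source`, `target` (1-based
#'   node indices) and `strength` in `(0, 1)`; no self-edges.
#' @param ar_coeff self-decay in `(0, 1)`.
#' @param noise_sd innovation standard deviation.
#' @param n_samples samples to generate (after burn-in).
#' @param fs nominal sampling rate attached to the output recording.
#' @param seed integer seed.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(n_nodes, edges = NULL, ar_coeff = 0.5,
                          noise_sd = 1, n_samples = 10000L, fs = 150,
                          seed = 1L) {
  if (is.null(edges))
    edges <- data.frame(source = integer(), target = integer(),
                        strength = numeric())
  stopifnot(n_nodes >= 2, ar_coeff > 0, ar_coeff < 1, noise_sd > 0,
            n_samples >= 2)
  if (nrow(edges) > 0 && any(edges$source == edges$target))
    stop("self-edges are not allowed")
  spec <- structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                         ar_coeff = ar_coeff, noise_sd = noise_sd,
                         n_samples = as.integer(n_samples), fs = fs,
                         seed = as.integer(seed)),
                    class = "coupling_spec")
  rho <- spectral_radius(system_matrix(spec))
  if (rho >= 1)
    stop(sprintf("unstable system matrix: spectral radius %.3f >= 1", rho))
  spec
}

system_matrix <- function(spec) {
  a <- diag(spec$ar_coeff, spec$n_nodes)
  e <- spec$edges
  for (r in seq_len(nrow(e)))
    a[e$target[r], e$source[r]] <- a[e$target[r], e$source[r]] + e$strength[r]
  a
}

spectral_radius <- function(a) max(Mod(eigen(a, only.values = TRUE)$values))

#' Simulate a coupled autoregressive recording
#'
#' Generates the VAR process of a [coupling_spec()], discarding a 500
#' sample burn-in. Deterministic given the spec's seed. Ground-truth
#' node roles (if the spec was built by [plant_hub_network()]) are
#' propagated in attribute `roles`.
#'
#' @param spec a [coupling_spec()].
#' @return A [recording()] with `n_nodes` channels labeled `N01..`.
#' @export
simulate_var <- function(spec) {
  a <- system_matrix(spec)
  rho <- spectral_radius(a)
  if (rho >= 1)
    stop(sprintf("unstable system matrix: spectral radius %.3f >= 1", rho))
  burn <- 500L
  total <- spec$n_samples + burn
  n <- spec$n_nodes
  x <- matrix(0, n, total)
  with_seed(spec$seed, {
    eps <- matrix(rnorm(n * total, sd = spec$noise_sd), n, total)
    x[, 1] <- eps[, 1]
    for (t in seq_len(total - 1))
      x[, t + 1] <- a %*% x[, t] + eps[, t + 1]
  })
  rec <- recording(x[, (burn + 1):total, drop = FALSE], spec$fs,
                   sprintf("N%02d", seq_len(n)))
  attr(rec, "roles") <- attr(spec, "roles")
  rec
}

#' Plant a hub network with known sources and sinks
#'
#' Builds a [coupling_spec()] with ground-truth directed hub structure
#' on top of a sparse random background (every node gets `bg_out` weak
#' outgoing edges):
#'
#' * each **source** (a planted divergent hub) broadcasts strongly to
#'   `ceiling((n-1)/2)` random targets and receives a few moderate
#'   incoming edges, making it a genuine relay on many shortest paths;
#' * each **sink** (a planted convergent hub) collects from
#'   `ceiling((n-1)/2)` random drivers and, by default, redistributes
#'   weakly to a couple of targets.
#'
#' Setting `snk_in_strength` low and `snk_out_deg = 0` yields a "light
#' collector" variant in which convergent hubs carry clearly less total
#' flow than divergent ones, the asymmetry reported for cortical
#' networks. If the implied system matrix comes too close to
#' instability, all coupling strengths are shrunk deterministically
#' until the spectral radius is below 0.97.
#'
#' @param n_nodes,n_sources,n_sinks network composition
#'   (`n_sources + n_sinks < n_nodes`).
#' @param seed integer seed (placement of planted and background edges).
#' @param src_out_strength source broadcast coupling.
#' @param src_in_strength,src_in_deg moderate incoming relay edges per
#'   source.
#' @param snk_in_strength sink collector coupling.
#' @param snk_out_strength,snk_out_deg weak redistribution edges per
#'   sink.
#' @param n_balanced planted balanced relay hubs: nodes with matched
#'   strong in- and out-flow whose divergent/convergent/neutral typing
#'   fluctuates window to window.
#' @param bal_strength,bal_deg coupling and in/out degree of balanced
#'   relays.
#' @param bg_strength,bg_out background coupling strength and
#'   out-degree.
#' @param ... further arguments passed to [coupling_spec()]
#'   (`n_samples`, `fs`, `ar_coeff`, `noise_sd`).
#' @return A [coupling_spec()] with attribute `roles` (character vector
#'   `"source"`, `"sink"`, `"balanced"` or `"background"` per node).
#' @export
plant_hub_network <- function(n_nodes = 15L, n_sources = 2L, n_sinks = 1L,
                              seed = 1L,
                              src_out_strength = 0.45,
                              src_in_strength = 0.28, src_in_deg = 3L,
                              snk_in_strength = 0.25,
                              snk_out_strength = 0.12, snk_out_deg = 2L,
                              n_balanced = 0L,
                              bal_strength = 0.20, bal_deg = 4L,
                              bg_strength = 0.07, bg_out = 2L,
                              ar_coeff = 0.55, ...) {
  if (n_sources + n_sinks + n_balanced >= n_nodes)
    stop("n_sources + n_sinks + n_balanced must be smaller than n_nodes")
  deg <- ceiling((n_nodes - 1) / 2)
  with_seed(seed, {
    roles <- rep("background", n_nodes)
    special <- sample.int(n_nodes, n_sources + n_sinks + n_balanced)
    sources <- head(special, n_sources)
    sinks <- special[n_sources + seq_len(n_sinks)]
    balanced <- utils::tail(special, n_balanced)
    roles[sources] <- "source"
    roles[sinks] <- "sink"
    roles[balanced] <- "balanced"
    plain <- function(v)
      setdiff(seq_len(n_nodes), c(v, sources, sinks, balanced))
    edges <- list()
    add <- function(src, tgt, s)
      edges[[length(edges) + 1]] <<- data.frame(source = src, target = tgt,
                                                strength = s)
    for (s in sources) {
      # broadcast into the periphery only: driving another planted hub
      # directly would blur the ground-truth roles
      add(s, sample(plain(s), deg), src_out_strength)
      add(sample(plain(s), src_in_deg), s, src_in_strength)
    }
    for (s in sinks) {
      add(sample(plain(s), deg), s, snk_in_strength)
      if (snk_out_deg > 0)
        add(s, sample(plain(s), snk_out_deg), snk_out_strength)
    }
    for (s in balanced) {
      add(s, sample(plain(s), bal_deg), bal_strength)
      add(sample(plain(s), bal_deg), s, bal_strength)
    }
    for (v in seq_len(n_nodes))
      add(v, sample(setdiff(seq_len(n_nodes), v), bg_out), bg_strength)
    e <- do.call(rbind, edges)
    e <- e[!duplicated(e[c("source", "target")]), ]
    # deterministic stability margin: shrink couplings until radius < 0.97
    scl <- 1
    repeat {
      a <- diag(ar_coeff, n_nodes)
      for (r in seq_len(nrow(e)))
        a[e$target[r], e$source[r]] <- a[e$target[r], e$source[r]] +
          e$strength[r] * scl
      if (spectral_radius(a) < 0.97) break
      scl <- scl * 0.9
    }
    e$strength <- e$strength * scl
    spec <- coupling_spec(n_nodes, e, ar_coeff = ar_coeff, seed = seed, ...)
    attr(spec, "roles") <- roles
    spec
  })
}

#' Simulate a recording that alternates between two coupling regimes
#'
#' The system matrix follows a schedule of segments, each governed by
#' regime `"A"` or `"B"`; the state carries over at every boundary so
#' the series is continuous. Useful fixtures include a single midpoint
#' switch (role reversal) and short `"A"` bursts embedded in a long
#' `"B"` background (transient episodes of hub-driven integration).
#'
#' @param specA,specB [coupling_spec()]s with equal `n_nodes` and `fs`;
#'   `specA` supplies `n_samples`, `noise_sd` and the channel count.
#' @param schedule data frame with columns `regime` (`"A"`/`"B"`) and
#'   `fraction` (positive, summing to 1).
#' @param seed seed for the innovation stream.
#' @return A [recording()]; attribute `boundaries` gives the first
#'   sample of every segment.
#' @export
simulate_regime_schedule <- function(specA, specB, schedule, seed = 1L) {
  if (specA$n_nodes != specB$n_nodes || specA$fs != specB$fs)
    stop("regime specs differ in dimension or sampling rate")
  stopifnot(is.data.frame(schedule), all(c("regime", "fraction") %in% names(schedule)),
            all(schedule$regime %in% c("A", "B")), all(schedule$fraction > 0),
            abs(sum(schedule$fraction) - 1) < 1e-8)
  aA <- system_matrix(specA)
  aB <- system_matrix(specB)
  n <- specA$n_nodes
  n_samp <- specA$n_samples
  burn <- 500L
  total <- n_samp + burn
  ends <- floor(cumsum(schedule$fraction) * n_samp)
  ends[length(ends)] <- n_samp
  regime_of <- schedule$regime[findInterval(seq_len(n_samp), c(0, ends),
                                            left.open = TRUE)]
  x <- matrix(0, n, total)
  with_seed(seed, {
    eps <- matrix(rnorm(n * total, sd = specA$noise_sd), n, total)
    x[, 1] <- eps[, 1]
    for (t in seq_len(total - 1)) {
      r <- if (t <= burn) schedule$regime[1] else regime_of[t - burn]
      a <- if (r == "A") aA else aB
      x[, t + 1] <- a %*% x[, t] + eps[, t + 1]
    }
  })
  rec <- recording(x[, (burn + 1):total, drop = FALSE], specA$fs,
                   sprintf("N%02d", seq_len(n)))
  attr(rec, "boundaries") <- as.integer(c(1, utils::head(ends, -1) + 1))
  attr(rec, "regimes") <- schedule$regime
  rec
}

#' Concatenate two coupling regimes with a single switch
#'
#' The first `switch_at` fraction of the samples follows `specA`, the
#' rest `specB`; a two-segment [simulate_regime_schedule()].
#'
#' @param specA,specB [coupling_spec()]s with equal `n_nodes` and `fs`.
#' @param switch_at fraction in `(0, 1)`.
#' @param seed seed for the innovation stream.
#' @return A [recording()]; attribute `switch_sample` gives the first
#'   sample governed by `specB`.
#' @export
simulate_regime_switch <- function(specA, specB, switch_at = 0.5, seed = 1L) {
  stopifnot(switch_at > 0, switch_at < 1)
  sched <- data.frame(regime = c("A", "B"),
                      fraction = c(switch_at, 1 - switch_at))
  rec <- simulate_regime_schedule(specA, specB, sched, seed)
  attr(rec, "switch_sample") <- attr(rec, "boundaries")[2]
  rec
}

#' Simulation spec for template-driven microstate EEG
#'
#' @param templates k x channels matrix of scalp topographies (rows are
#'   unit-normalized internally).
#' @param mean_dwell_ms mean microstate dwell time in milliseconds.
#' @param snr amplitude signal-to-noise ratio (RMS signal over RMS
#'   noise), > 0.
#' @param fs sampling rate, Hz.
#' @param duration_s recording length in seconds.
#' @param seed integer seed.
#' @return An object of class `microstate_sim_spec`.
#' @export
microstate_sim_spec <- function(templates, mean_dwell_ms = 100, snr = 5,
                                fs = 250, duration_s = 20, seed = 1L) {
  templates <- as.matrix(templates)
  if (nrow(templates) < 2) stop("need at least 2 templates")
  if (snr <= 0) stop("snr must be positive")
  if (mean_dwell_ms / 1000 * fs < 2) stop("mean dwell must span >= 2 samples")
  templates <- templates / sqrt(rowSums(templates^2))
  structure(list(templates = templates, mean_dwell_ms = mean_dwell_ms,
                 snr = snr, fs = fs, duration_s = duration_s,
                 seed = as.integer(seed)),
            class = "microstate_sim_spec")
}

#' Simulate microstate EEG from switching templates
#'
#' Draws geometric dwell times with the specified mean, activates one
#' template per dwell with a random positive amplitude (gamma with mean
#' 1), and adds white Gaussian channel noise scaled to the requested
#' amplitude SNR. Returns the recording together with the ground-truth
#' label sequence.
#'
#' @param spec a [microstate_sim_spec()].
#' @return List with `recording` (a [recording()]) and `labels`
#'   (integer ground-truth state per sample).
#' @export
simulate_microstate_eeg <- function(spec) {
  n_ch <- ncol(spec$templates)
  k <- nrow(spec$templates)
  n_samp <- round(spec$duration_s * spec$fs)
  dwell_mean <- spec$mean_dwell_ms / 1000 * spec$fs
  with_seed(spec$seed, {
    labels <- integer(0)
    state <- sample.int(k, 1)
    while (length(labels) < n_samp) {
      d <- 2L + stats::rgeom(1, 1 / (dwell_mean - 1))
      labels <- c(labels, rep(state, d))
      nxt <- sample.int(k - 1, 1)
      state <- setdiff(seq_len(k), state)[nxt]
    }
    labels <- labels[seq_len(n_samp)]
    amps <- rgamma(n_samp, shape = 4, rate = 4)  # mean 1, positive
    sig <- t(spec$templates[labels, , drop = FALSE]) * rep(amps, each = n_ch)
    rms_sig <- sqrt(mean(sig^2))
    noise_sd <- rms_sig / spec$snr
    dat <- sig + matrix(rnorm(n_ch * n_samp, sd = noise_sd), n_ch, n_samp)
    list(recording = recording(dat, spec$fs,
                               sprintf("E%02d", seq_len(n_ch))),
         labels = labels)
  })
}

#' Microstate label sequence with window-locked switching rate
#'
#' Generates a ground-truth label sequence whose switching rate is
#' elevated inside designated windows (e.g. windows triggered by peaks
#' of several hub types at once) and slow elsewhere. Used to test that
#' windowed sequence complexity recovers a planted switching-rate
#' difference.
#'
#' @param n_samples sequence length.
#' @param fs sampling rate, Hz.
#' @param ws a `window_series` (supplies window start times).
#' @param fast_windows indices into `ws` of the fast-switching windows.
#' @param window_length_s window length in seconds.
#' @param dwell_fast_ms,dwell_slow_ms mean dwell inside/outside fast
#'   windows.
#' @param k alphabet size.
#' @param seed integer seed.
#' @return Integer label vector in `1..k`.
#' @export
simulate_switching_labels <- function(n_samples, fs, ws, fast_windows,
                                      window_length_s = 5,
                                      dwell_fast_ms = 40,
                                      dwell_slow_ms = 120,
                                      k = 4L, seed = 1L) {
  fast <- rep(FALSE, n_samples)
  len <- floor(window_length_s * fs)
  for (w in fast_windows) {
    s0 <- floor(ws$start_s[w] * fs) + 1L
    fast[s0:min(s0 + len - 1L, n_samples)] <- TRUE
  }
  p <- ifelse(fast, 1000 / (dwell_fast_ms * fs), 1000 / (dwell_slow_ms * fs))
  with_seed(seed, {
    lab <- integer(n_samples)
    cur <- sample.int(k, 1)
    for (t in seq_len(n_samples)) {
      if (t > 1 && runif(1) < p[t])
        cur <- sample(setdiff(seq_len(k), cur), 1)
      lab[t] <- cur
    }
    lab
  })
}

#' Random orthonormal scalp templates
#'
#' Convenience generator (QR of a seeded Gaussian matrix) producing
#' `k` mutually orthogonal unit-norm topographies over `n_ch` channels,
#' used as planted ground truth in microstate recovery tests.
#'
#' @param k number of templates.
#' @param n_ch number of channels.
#' @param seed integer seed.
#' @return k x n_ch matrix with orthonormal rows.
#' @export
orthogonal_templates <- function(k = 4L, n_ch = 16L, seed = 1L) {
  with_seed(seed, {
    m <- matrix(rnorm(n_ch * k), n_ch, k)
    m <- sweep(m, 2, colMeans(m))   # zero-sum maps: average-reference safe
    q <- qr.Q(qr(m))
    t(q)
  })
}
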