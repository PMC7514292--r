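test_that("global field power matches its closed form", {
  rec <- recording(matrix(c(2, 2, 1, -1), 2, 2), fs = 100)
  g <- gfp(rec)
  expect_equal(g[1], 0)                       # equal channels
  expect_equal(g[2], 1)                       # (+1, -1): sqrt((1+1)/2)
  rec3 <- noise_recording(5, 50, seed = 91)
  expect_equal(gfp(recording(rec3$data * -2.5, rec3$fs)), 2.5 * gfp(rec3))
  # explicit formula on a random column
  x <- rec3$data[, 7]
  expect_equal(gfp(rec3)[7], sqrt(mean((x - mean(x))^2)))
})

test_that("template fitting recovers planted orthogonal topographies", {
  for (s in 1:3) {
    tpl <- orthogonal_templates(4, 16, seed = s)
    spec <- microstate_sim_spec(tpl, mean_dwell_ms = 100, snr = 5,
                                fs = 250, duration_s = 20, seed = s)
    sim <- simulate_microstate_eeg(spec)
    model <- fit_microstates(sim$recording, 4, seed = s)
    mt <- match_templates(model$templates, tpl)
    expect_gte(min(mt$corrs), 0.95)
    seq_ <- backfit(sim$recording, model)
    acc <- mean(mt$perm[seq_$labels] == sim$labels)
    expect_gte(acc, 0.90)
  }
})

test_that("fitting is polarity-invariant and deterministic", {
  tpl <- orthogonal_templates(4, 12, seed = 92)
  sim <- simulate_microstate_eeg(microstate_sim_spec(tpl, seed = 92))
  m1 <- fit_microstates(sim$recording, 4, seed = 5)
  m2 <- fit_microstates(sim$recording, 4, seed = 5)
  expect_identical(m1$templates, m2$templates)

  flipped <- recording(-sim$recording$data, sim$recording$fs)
  m3 <- fit_microstates(flipped, 4, seed = 5)
  for (j in 1:4) {
    d <- min(max(abs(m1$templates[, j] - m3$templates[, j])),
             max(abs(m1$templates[, j] + m3$templates[, j])))
    expect_lt(d, 1e-9)   # identical template up to polarity
  }

  expect_error(fit_microstates(noise_recording(4, 30, seed = 1), 4),
               "too few GFP peaks")
})

test_that("backfit labels by maximal squared correlation with tie rule", {
  tpl <- orthogonal_templates(3, 10, seed = 93)
  model <- structure(list(templates = t(tpl), gev = 1, k = 3),
                     class = "microstate_model")
  colnames(model$templates) <- LETTERS[1:3]
  # recording made of template 2 repeated (either polarity)
  dat <- cbind(tpl[2, ] %o% rep(1, 5), -tpl[2, ] %o% rep(1, 3))
  seq_ <- backfit(recording(dat, 100), model)
  expect_true(all(seq_$labels == 2))
  # flat sample: tie broken to the lowest label and flagged
  dat2 <- dat; dat2[, 4] <- 0
  seq2 <- backfit(recording(dat2, 100), model)
  expect_identical(seq2$labels[4], 1L)
  expect_true(seq2$flat[4])
  expect_error(backfit(noise_recording(5, 20), model), "channels")
})

test_that("LZ76 parse counts match hand parses and the string-search oracle", {
  expect_identical(lz_complexity(rep("A", 8))$c, 2L)     # A | AAAAAAA
  expect_identical(lz_complexity("A")$c, 1L)
  expect_identical(lz_complexity(c(0, 1, 0, 1, 0, 1), 2)$c, 3L)
  expect_error(lz_complexity(c(1, 5), 4), "outside")

  set.seed(94)
  for (r in 1:200) {
    n <- sample(2:40, 1)
    s <- sample(0:3, n, replace = TRUE)
    expect_identical(lz_complexity(s, 4)$c, lz76_oracle(s))
  }
  # exhaustive over short quaternary strings
  for (n in 1:5) {
    grid <- as.matrix(expand.grid(rep(list(0:3), n)))
    expect_identical(apply(grid, 1, function(s) lz_complexity(s, 4)$c),
                     apply(grid, 1, lz76_oracle))
  }
})

test_that("complexity is invariant under alphabet relabeling and normalized by length", {
  set.seed(95)
  for (r in 1:25) {
    s <- sample(0:3, 50, replace = TRUE)
    perm <- sample(0:3)
    expect_identical(lz_complexity(perm[s + 1], 4)$c, lz_complexity(s, 4)$c)
  }
  lz <- lz_complexity(sample(0:3, 100, replace = TRUE), 4)
  expect_equal(lz$normalized, lz$c * log(100, 4) / 100)
})

test_that("windowed complexity groups triggered windows into a partition", {
  ws <- data.frame(window = 1:8, start_s = 0:7,
                   n_HD = c(0, 3, 0, 0, 3, 0, 0, 0),
                   n_HC = c(0, 3, 0, 0, 0, 0, 3, 0),
                   n_HN = c(0, 0, 0, 3, 0, 0, 0, 0))
  class(ws) <- c("window_series", "data.frame")
  set.seed(96)
  ms <- structure(list(labels = sample(1:4, 1000, replace = TRUE), k = 4),
                  class = "microstate_sequence")
  wc <- windowed_complexity(ms, ws, fs = 100, window_length_s = 2)
  expect_setequal(wc$group[wc$window == 2], "common")
  expect_setequal(wc$group[wc$window == 4], "HN")
  expect_equal(anyDuplicated(wc$window), 0)      # a partition
  peaks <- cbind(detect_peaks(ws$n_HD), detect_peaks(ws$n_HC),
                 detect_peaks(ws$n_HN))
  expect_setequal(wc$window, which(rowSums(peaks) > 0))

  # constant subsequence attains the minimal parse count
  ms_const <- structure(list(labels = rep(1L, 1000), k = 4),
                        class = "microstate_sequence")
  wc2 <- windowed_complexity(ms_const, ws, fs = 100, window_length_s = 2)
  expect_true(all(wc2$c == 2))

  ws_none <- ws; ws_none[, c("n_HD", "n_HC", "n_HN")] <- 0
  expect_warning(empty <- windowed_complexity(ms, ws_none, 100, 2),
                 "no triggered windows")
  expect_identical(nrow(empty), 0L)
})

test_that("microstate artifacts round-trip through text formats", {
  tpl <- orthogonal_templates(4, 8, seed = 97)
  sim <- simulate_microstate_eeg(microstate_sim_spec(tpl, duration_s = 10, seed = 97))
  model <- fit_microstates(sim$recording, 4, seed = 97)
  seq_ <- backfit(sim$recording, model)
  dir <- withr::local_tempdir()
  write_microstate_sequence(seq_, file.path(dir, "seq.txt"), fs = 250)
  back <- read_microstate_sequence(file.path(dir, "seq.txt"))
  expect_identical(back$labels, seq_$labels)
  expect_identical(back$k, 4L)
  write_microstate_model(model, file.path(dir, "model.tsv"))
  m <- as.matrix(read.table(file.path(dir, "model.tsv"), header = TRUE,
                            row.names = 1, sep = "\t"))
  expect_equal(unname(m), unname(model$templates), tolerance = 1e-15)
})
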