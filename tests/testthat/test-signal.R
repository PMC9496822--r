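fs <- 512
tt <- (0:(10 * fs - 1)) / fs
steady <- (fs + 1):(9 * fs)  # transient-trimmed sample range

test_that("band-pass keeps the pass band and rejects the stop band", {
  ep <- signal_epoch(rbind(sin(2 * pi * 5.5 * tt),
                           cos(2 * pi * 5.5 * tt)), fs)
  out <- bandpass_filter(ep, 4, 7)
  expect_equal(dim(out$data), dim(ep$data))
  expect_gt(cor(ep$data[1, steady], out$data[1, steady]), 0.99)

  ep50 <- signal_epoch(rbind(sin(2 * pi * 50 * tt),
                             sin(2 * pi * 60 * tt)), fs)
  out50 <- bandpass_filter(ep50, 4, 7)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out50$data[1, steady]) / rms(ep50$data[1, steady]), 0.01)

  # mixture: the 5 Hz component survives, the 30 Hz one is removed
  mix <- signal_epoch(rbind(sin(2 * pi * 5 * tt) + sin(2 * pi * 30 * tt),
                            cos(2 * pi * 5 * tt)), fs)
  fmix <- bandpass_filter(mix, 4, 7)
  ref <- sin(2 * pi * 5 * tt)[steady]
  expect_lt(rms(fmix$data[1, steady] - ref) / rms(ref), 0.02)

  expect_error(bandpass_filter(ep, 4, 300), "fs/2")
  expect_error(bandpass_filter(ep, 0, 7), "fs/2")
})

test_that("middle-window extraction is sample-exact", {
  ep <- signal_epoch(matrix(seq_len(2 * 30720), nrow = 2, byrow = TRUE),
                     fs = 512)
  mid <- extract_middle_window(ep, 60)
  # samples [10240, 20480) 0-based = columns 10241..20480
  expect_equal(ncol(mid$data), 10240)
  expect_equal(unname(mid$data[1, 1]), 10241)
  expect_equal(unname(mid$data[1, 10240]), 20480)

  ep3 <- signal_epoch(matrix(1:6, nrow = 2, byrow = TRUE), fs = 1)
  expect_equal(unname(extract_middle_window(ep3, 3)$data[, 1]), c(2, 5))

  ep6 <- signal_epoch(matrix(1:12, nrow = 2, byrow = TRUE), fs = 1)
  expect_equal(unname(extract_middle_window(ep6, 6)$data[1, ]), c(3, 4))

  expect_error(extract_middle_window(ep3, 60), "not the declared")
})

test_that("analytic phase behaves like the Hilbert pair of a tone", {
  ep <- signal_epoch(rbind(cos(2 * pi * 5 * tt), sin(2 * pi * 5 * tt)), fs)
  ph <- instantaneous_phase(ep)
  step <- diff(ph$phases[1, steady]) %% (2 * pi)
  expect_equal(median(step), 2 * pi * 5 / fs, tolerance = 1e-6)
  # cos leads sin by pi/2
  off <- (ph$phases[1, steady] - ph$phases[2, steady]) %% (2 * pi)
  expect_equal(median(off), pi / 2, tolerance = 1e-3)
  # identical channels give identical phases
  ep2 <- signal_epoch(rbind(ep$data[1, ], ep$data[1, ]), fs,
                      channel_names = c("a", "b"))
  ph2 <- instantaneous_phase(ep2)
  expect_identical(ph2$phases[1, ], ph2$phases[2, ])

  ep0 <- signal_epoch(rbind(rep(0, 100), sin(1:100)), fs = 10)
  expect_error(instantaneous_phase(ep0), "all-zero")
})

test_that("PLV hits its synchrony and desynchrony limits", {
  mk <- function(ph) structure(
    list(phases = ph, fs = 1,
         channel_names = paste0("c", seq_len(nrow(ph)))),
    class = "phase_series")
  base <- seq(0, 20, length.out = 500)
  expect_equal(compute_plv_matrix(mk(rbind(base, base)))$values[1, 2], 1)
  expect_equal(compute_plv_matrix(mk(rbind(base, base + pi / 3)))$values[1, 2],
               1, tolerance = 1e-12)
  withr::with_seed(1, {
    ph <- rbind(stats::runif(10000, 0, 2 * pi),
                stats::runif(10000, 0, 2 * pi))
    expect_lt(compute_plv_matrix(mk(ph))$values[1, 2], 0.05)
  })
  expect_error(compute_plv_matrix(mk(rbind(c(1, NA), c(1, 2)))),
               "non-finite")
})

test_that("PLV matrices are symmetric, unit-diagonal, offset-invariant", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      ph <- matrix(stats::runif(5 * 200, -pi, pi), nrow = 5)
      ps <- structure(list(phases = ph, fs = 1,
                           channel_names = paste0("c", 1:5)),
                      class = "phase_series")
      v <- compute_plv_matrix(ps)$values
      expect_equal(v, t(v), tolerance = 1e-12)
      expect_equal(unname(diag(v)), rep(1, 5))
      expect_true(all(v >= 0 & v <= 1))
      # common additive phase constant leaves PLV unchanged
      ps2 <- ps; ps2$phases <- ph + 1.234
      expect_equal(compute_plv_matrix(ps2)$values, v, tolerance = 1e-12)
    }
  })
})

test_that("top-m binarization keeps exactly the strongest pairs", {
  v <- diag(4)
  v[1, 2] <- v[2, 1] <- 0.9; v[3, 4] <- v[4, 3] <- 0.8
  v[1, 3] <- v[3, 1] <- 0.3; v[2, 4] <- v[4, 2] <- 0.2
  v[1, 4] <- v[4, 1] <- 0.1; v[2, 3] <- v[3, 2] <- 0.05
  colnames(v) <- rownames(v) <- paste0("n", 1:4)
  net <- binarize_top_m(v, 2)
  expect_equal(net$edges, rbind(c(1L, 2L), c(3L, 4L)))

  expect_warning(e0 <- binarize_top_m(v, 0), "edgeless")
  expect_equal(nrow(e0$edges), 0L)
  expect_warning(full <- binarize_top_m(v, 6), "complete")
  expect_equal(nrow(full$edges), 6L)
  expect_error(binarize_top_m(v, 7), "between 0 and")

  # edge count is exact for every valid m on random matrices
  withr::with_seed(9, {
    for (rep in 1:5) {
      r <- matrix(stats::runif(36), 6, 6)
      r <- (r + t(r)) / 2; diag(r) <- 1
      colnames(r) <- rownames(r) <- paste0("x", 1:6)
      for (m in 0:15) {
        net_m <- suppressWarnings(binarize_top_m(r, m))
        expect_equal(nrow(net_m$edges), m)
      }
    }
  })
})

test_that("adaptive scan picks the edge count with the cleanest structure", {
  # two groups of 5 with a wide PLV gap: true intra count is 20
  v <- matrix(0.2, 10, 10); diag(v) <- 1
  for (i in 1:4) for (j in (i + 1):5) v[i, j] <- v[j, i] <- 0.9
  for (i in 6:9) for (j in (i + 1):10) v[i, j] <- v[j, i] <- 0.9
  colnames(v) <- rownames(v) <- paste0("n", 1:10)
  sc <- adaptive_threshold_scan(v, 16, 24, runs = 3, seed = 3,
                                pop_size = 30, max_gen_global = 15)
  expect_equal(sc$chosen_m, 20)
  expect_equal(nrow(sc$report), 9)

  one <- adaptive_threshold_scan(v, 20, 20, runs = 2, seed = 1,
                                 pop_size = 20, max_gen_global = 5)
  expect_equal(one$chosen_m, 20)
  expect_error(adaptive_threshold_scan(v, 5, 4), "must not exceed")
})
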