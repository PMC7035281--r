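test_that("bleed-through correction is the exact elementwise subtraction", {
  tr <- tibble::tibble(molecule_id = "m1", frame_index = 0:2,
                       donor = c(100, 200, 50),
                       acceptor_raw = c(16.5, 100, 10))
  out <- correct_bleed_through(tr, 0.165)
  expect_equal(out$acceptor, c(0, 100 - 0.165 * 200, 10 - 0.165 * 50))

  out0 <- correct_bleed_through(tr, 0)
  expect_equal(out0$acceptor, tr$acceptor_raw)

  set.seed(1)
  tr10 <- tibble::tibble(molecule_id = "m", frame_index = 0:9,
                         donor = runif(10, 0, 1000),
                         acceptor_raw = runif(10, 0, 1000))
  out10 <- correct_bleed_through(tr10, 0.165)
  for (i in 1:10)
    expect_equal(out10$acceptor[i],
                 tr10$acceptor_raw[i] - 0.165 * tr10$donor[i])
})

test_that("FRET efficiency follows I_A/(I_A+I_D) with dark frames zeroed", {
  tr <- tibble::tibble(molecule_id = "m1", frame_index = 0:3,
                       donor = c(500, 1, 100, 0),
                       acceptor = c(500, 3, 900, -5),
                       dark = c(FALSE, FALSE, TRUE, FALSE))
  out <- compute_fret(tr)
  expect_equal(out$efficiency[1], 0.5)
  expect_equal(out$efficiency[2], 0.75)
  expect_equal(out$efficiency[3], 0)   # dark despite bright acceptor
  expect_equal(out$efficiency[4], 0)   # non-positive total treated dark
  expect_true(out$dark[4])
})

test_that("bleach and blink detection handles canonical cases", {
  mk <- function(total) tibble::tibble(
    molecule_id = "m1", frame_index = seq_along(total) - 1L,
    donor = total / 2, acceptor = total / 2)
  # clean single-step bleach at frame 500
  det <- detect_bleach_and_blinks(mk(rep(c(1000, 0), each = 500)))
  expect_equal(det$bleach_index, 500)
  expect_true(det$single_step)
  expect_equal(det$n_blinks, 0)
  # two-step staircase fails the single-step test
  det2 <- detect_bleach_and_blinks(mk(rep(c(1000, 500, 0), each = 300)))
  expect_false(det2$single_step)
  # blink: transient dark interval with recovery before the bleach
  total3 <- rep(1000, 900); total3[301:320] <- 0; total3[601:900] <- 0
  det3 <- detect_bleach_and_blinks(mk(total3))
  expect_equal(det3$bleach_index, 600)
  expect_equal(det3$n_blinks, 1)
  expect_true(all(det3$blink_frames[[1]] == 300:319))
  # no bleach at all
  det4 <- detect_bleach_and_blinks(mk(rep(1000, 600)))
  expect_true(is.na(det4$bleach_index))
})

test_that("bleach frames are recovered within 2 frames on noisy traces", {
  cfg <- trace_sim_config(n_molecules = 150, n_frames = 1000,
                          noise_sd = 0.03, bleach_rate = 0.1,
                          blink_rate = 0, seed = 21)
  out <- simulate_traces(cfg)
  tr <- correct_bleed_through(out$traces)
  det <- detect_bleach_and_blinks(tr)
  true_frame <- floor(out$truth$bleach_time / cfg$frame_period)
  seen <- !is.na(det$bleach_index) & true_frame < 995
  err <- abs(det$bleach_index[seen] - true_frame[seen])
  expect_gt(mean(err <= 2), 0.95)
})

test_that("the five selection criteria match planted trace properties", {
  n <- 800
  base <- function(id, total, fret = 0.6, bleach_at = 600, blinks = 0,
                   steps = 1) {
    tot <- rep(total, n)
    if (steps == 2) tot[401:bleach_at] <- total / 2
    if (bleach_at < n) tot[(bleach_at + 1):n] <- 0
    if (blinks > 0)
      for (b in seq_len(blinks)) tot[(b * 50):(b * 50 + 5)] <- 0
    set.seed(id)
    tot_n <- tot + rnorm(n, 0, 8)
    tibble::tibble(molecule_id = sprintf("t%02d", id), frame_index = 0:(n - 1),
                   donor = tot_n * (1 - fret), acceptor = tot_n * fret)
  }
  traces <- dplyr::bind_rows(
    base(1, 1000),                       # passes everything
    base(2, 1000, bleach_at = n),        # no bleach -> fails (i)
    base(3, 1000, steps = 2),            # two-step -> fails (i)
    base(4, 1000, blinks = 4),           # four blinks -> fails (iv)
    base(5, 1000, fret = 0.10),          # low FRET -> fails (v)
    base(6, 1000, bleach_at = 200))      # only 200 bright frames -> fails (v)
  det <- detect_bleach_and_blinks(traces)
  fr <- compute_fret(traces, det)
  sel <- select_traces(fr, selection_criteria(), det)
  rep <- sel$report[order(sel$report$molecule_id), ]
  expect_equal(rep$accepted, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_false(rep$crit_single_step_bleach[2])
  expect_false(rep$crit_single_step_bleach[3])
  expect_false(rep$crit_blinks[4])
  expect_false(rep$crit_fret_frames[5])
  expect_false(rep$crit_fret_frames[6])
  expect_equal(sort(unique(sel$traces$molecule_id)), "t01")
})

test_that("selection agrees with an independently coded per-criterion check", {
  cfg <- trace_sim_config(n_molecules = 60, n_frames = 700, noise_sd = 0.05,
                          bleach_rate = 0.08, blink_rate = 0.05, seed = 33)
  tr <- correct_bleed_through(simulate_traces(cfg)$traces)
  det <- detect_bleach_and_blinks(tr)
  fr <- compute_fret(tr, det)
  crit <- selection_criteria()
  sel <- select_traces(fr, crit, det)
  # oracle: recompute each criterion directly from the detection table
  for (i in seq_len(nrow(det))) {
    mol <- det$molecule_id[i]
    e <- fr$efficiency[fr$molecule_id == mol]
    want <- (!is.na(det$bleach_index[i]) && det$single_step[i]) &&
      (!is.na(det$snr_background[i]) &&
         det$snr_background[i] >= crit$snr_background_min) &&
      (!is.na(det$snr_signal[i]) &&
         det$snr_signal[i] >= crit$snr_signal_min) &&
      det$n_blinks[i] <= crit$max_blink_events &&
      sum(e > crit$fret_floor) >= crit$min_frames
    expect_equal(sel$report$accepted[sel$report$molecule_id == mol], want)
  }
})
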