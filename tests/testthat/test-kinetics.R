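test_that("a single transition lands in the right TDP bin", {
  e <- c(rep(0.41, 50), rep(0.62, 50))
  tr <- tibble::tibble(molecule_id = "m1", frame_index = 0:99,
                       efficiency = e, dark = FALSE, frame_period = 0.025)
  sk <- idealize_skm(tr)
  td <- transition_density(sk, bin_width = 0.05)
  expect_equal(td$total_transitions, 1)
  i <- findInterval(0.41, td$edges, rightmost.closed = TRUE)
  j <- findInterval(0.62, td$edges, rightmost.closed = TRUE)
  expect_equal(td$counts[i, j], 1L)
  expect_equal(sum(td$counts), 1L)
  expect_equal(td$total_time, 100 * 0.025)
})

test_that("TDP counts are conserved for arbitrary inputs", {
  cfg <- trace_sim_config(n_molecules = 10, n_frames = 600, noise_sd = 0.04,
                          seed = 17)
  tr <- correct_bleed_through(simulate_traces(cfg)$traces)
  det <- detect_bleach_and_blinks(tr)
  sk <- idealize_skm(compute_fret(tr, det))
  td <- transition_density(sk)
  expect_equal(sum(td$counts), td$total_transitions)
  expect_equal(td$total_transitions, nrow(td$transitions))
  # per-path conservation
  per_path <- td$transitions |>
    dplyr::count(.data$molecule_id)
  expect_equal(sum(per_path$n), td$total_transitions)
})

test_that("a stationary reversible chain yields a symmetric TDP", {
  q <- matrix(0, 4, 4)
  q[2, 3] <- 1; q[3, 2] <- 1
  diag(q) <- -rowSums(q)
  cfg <- trace_sim_config(n_molecules = 20, n_frames = 2000,
                          noise_sd = 0.02, bleach_rate = 0, blink_rate = 0,
                          rate_matrix = q, seed = 19)
  tr <- correct_bleed_through(simulate_traces(cfg)$traces) |> compute_fret()
  sk <- idealize_skm(tr)
  td <- transition_density(sk, bin_width = 0.1)
  asym <- abs(td$counts - t(td$counts))
  # a two-state trace alternates, so per-trace imbalance is at most one
  expect_lte(max(asym), 20)
  expect_gt(td$total_transitions, 500)
})

test_that("alternating dwell paths give the exact dwell-time MLE rate", {
  # 2(10) [3(10) 2(10)] x 20: every state-3 dwell ends in a transition
  path <- c(rep(2L, 10), rep(rep(c(3L, 2L), each = 10), 20))
  sk <- idealize_skm(fret_from_path(path))
  re <- estimate_rates(sk, frame_period = 0.025)
  expect_equal(re$k[3, 2], 4)           # 20 events / 5 s
  # mirrored construction makes the 2 -> 3 rate exact instead
  path2 <- c(rep(3L, 10), rep(rep(c(2L, 3L), each = 10), 20))
  re2 <- estimate_rates(idealize_skm(fret_from_path(path2)),
                        frame_period = 0.025)
  expect_equal(re2$k[2, 3], 4)
})

test_that("paths without transitions are flagged as upper bounds", {
  sk <- idealize_skm(fret_from_path(rep(4L, 100)))
  re <- estimate_rates(sk, frame_period = 0.025)
  td <- tidy(re)
  out4 <- td[td$from == 4, ]
  expect_true(all(out4$rate == 0))
  expect_true(all(out4$flag == "upper bound (no events)"))
  unvisited <- td[td$from == 2, ]
  expect_true(all(is.na(unvisited$rate)))
  expect_true(all(unvisited$flag == "undefined (state unvisited)"))
})

test_that("rate estimates converge on the generating rates with more data", {
  q <- matrix(0, 4, 4)
  q[2, 3] <- 1; q[3, 2] <- 2
  diag(q) <- -rowSums(q)
  errs <- c()
  for (nf in c(2000, 8000, 32000)) {
    cfg <- trace_sim_config(n_molecules = 4, n_frames = nf,
                            frame_period = 0.005, noise_sd = 0.02,
                            bleach_rate = 0, blink_rate = 0,
                            rate_matrix = q, seed = 71)
    tr <- correct_bleed_through(simulate_traces(cfg)$traces) |> compute_fret()
    re <- estimate_rates(idealize_skm(tr))
    errs <- c(errs, abs(re$k[2, 3] - 1))
    if (nf == 32000)
      expect_lt(abs(re$k[2, 3] - 1), 3 * re$se[2, 3])
  }
  expect_lt(errs[3], errs[1] + 0.05)
})

test_that("occupancy reports per-state time fractions that sum to one", {
  sk <- idealize_skm(fret_from_path(rep(4L, 50)))
  occ <- occupancy(sk)
  expect_equal(occ$occupancy[order(occ$state)], c(0, 0, 1))
  cfg <- trace_sim_config(n_molecules = 8, n_frames = 500, noise_sd = 0.05,
                          seed = 23)
  tr <- correct_bleed_through(simulate_traces(cfg)$traces)
  det <- detect_bleach_and_blinks(tr)
  occ2 <- occupancy(idealize_skm(compute_fret(tr, det)))
  sums <- occ2 |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(s = sum(.data$occupancy))
  expect_equal(sums$s, 1)
})

test_that("stationary occupancy matches the analytic distribution", {
  q <- default_rate_matrix()
  cfg <- trace_sim_config(n_molecules = 40, n_frames = 4000,
                          noise_sd = 0.02, bleach_rate = 0, blink_rate = 0,
                          rate_matrix = q, seed = 29)
  tr <- correct_bleed_through(simulate_traces(cfg)$traces) |> compute_fret()
  occ <- occupancy(idealize_skm(tr))
  pi_ref <- stationary_distribution(q)
  for (s in 2:4) {
    row <- occ[occ$state == s, ]
    expect_lt(abs(row$occupancy - pi_ref[s]), 3 * row$se + 0.005)
  }
})

test_that("relative rates of identical estimates are one", {
  path <- rep(rep(c(2L, 3L), each = 20), 10)
  sk <- idealize_skm(fret_from_path(path))
  re <- estimate_rates(sk, frame_period = 0.025)
  rel <- relative_rates(re, re)
  expect_equal(rel$ratio[rel$from == 2 & rel$to == 3], 1)
})
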