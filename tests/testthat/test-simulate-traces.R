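test_that("identical config and seed give bitwise-identical output", {
  cfg <- trace_sim_config(n_molecules = 3, n_frames = 200, seed = 7)
  a <- simulate_traces(cfg)
  b <- simulate_traces(cfg)
  expect_identical(a, b)
})

test_that("a static noiseless chain reads back the pure state mean", {
  cfg <- trace_sim_config(n_molecules = 2, n_frames = 50, noise_sd = 0,
                          bleach_rate = 0, blink_rate = 0,
                          rate_matrix = matrix(0, 4, 4), start_state = 4,
                          seed = 1)
  tr <- simulate_traces(cfg)$traces |>
    correct_bleed_through() |>
    compute_fret()
  expect_equal(tr$efficiency, rep(0.79, 100), tolerance = 1e-12)
})

test_that("frame averaging matches the direct integral of the step function", {
  means <- c(0, 0.47, 0.63, 0.79)
  # path alternating between states 2 and 3 exactly every 10 frames
  jt <- seq(0, 0.975, by = 0.25)
  js <- rep(c(2L, 3L), 2)
  e <- frame_average_path(jt, js, means, 40, 0.025)
  expect_equal(e, rep(rep(c(0.47, 0.63), each = 10), 2))
  # a jump mid-frame gives the time-weighted mixture on that frame only
  e2 <- frame_average_path(c(0, 0.0175), c(2L, 4L), means, 2, 0.025)
  expect_equal(e2[1], (0.0175 * 0.47 + 0.0075 * 0.79) / 0.025)
  expect_equal(e2[2], 0.79)
})

test_that("simulated frame averages equal the reference integral of the sampled path", {
  cfg <- trace_sim_config(n_molecules = 5, n_frames = 200, noise_sd = 0,
                          bleach_rate = 0, blink_rate = 0, seed = 3)
  out <- simulate_traces(cfg)
  for (i in seq_len(5)) {
    ref <- frame_average_path(out$truth$jump_times[[i]],
                              out$truth$jump_states[[i]],
                              cfg$state_means, 200, 0.025)
    expect_equal(out$truth$frame_fret[[i]], ref, tolerance = 1e-9)
  }
})

test_that("every frame average lies in the convex hull of visited state means", {
  cfg <- trace_sim_config(n_molecules = 5, n_frames = 300, noise_sd = 0,
                          bleach_rate = 0, blink_rate = 0, seed = 11)
  out <- simulate_traces(cfg)
  for (i in seq_len(5)) {
    jt <- out$truth$jump_times[[i]]
    js <- out$truth$jump_states[[i]]
    e <- out$truth$frame_fret[[i]]
    for (f in seq_len(300)) {
      seg <- unique(js[findInterval(c((f - 1) * 0.025, f * 0.025 - 1e-9), jt)])
      visited <- unique(c(seg, js[jt > (f - 1) * 0.025 & jt < f * 0.025]))
      hull <- range(cfg$state_means[visited])
      expect_gte(e[f], hull[1] - 1e-9)
      expect_lte(e[f], hull[2] + 1e-9)
    }
  }
})

test_that("dwell times are exponential with the generating exit rate", {
  q <- matrix(0, 4, 4)
  q[2, 3] <- 2; q[3, 2] <- 2
  diag(q) <- -rowSums(q)
  cfg <- trace_sim_config(n_molecules = 1, n_frames = 220000, noise_sd = 0,
                          bleach_rate = 0, blink_rate = 0, rate_matrix = q,
                          start_state = 2, seed = 13)
  out <- simulate_traces(cfg)
  jt <- out$truth$jump_times[[1]]
  js <- out$truth$jump_states[[1]]
  dwell <- diff(jt)                      # completed dwells only
  states <- js[-length(js)]
  expect_gt(length(dwell), 1e4)
  ks <- stats::ks.test(dwell[states == 2], "pexp", rate = 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("ligand coupling saturates the coupled upper state", {
  cfg <- trace_sim_config(ligand_coupling = ligand_coupling())
  q <- cfg$rate_matrix
  cp <- cfg$ligand_coupling
  saturate <- function(conc) {
    qq <- q
    qq[cp$pair[1], cp$pair[2]] <- cp$k_on * conc
    qq[cp$pair[2], cp$pair[1]] <- cp$k_off
    diag(qq) <- 0; diag(qq) <- -rowSums(qq)
    stationary_distribution(qq)
  }
  pi_hi <- saturate(1e-2)   # ~2000-fold above k_off/k_on
  expect_lt(pi_hi[2], 0.01)
  expect_gt(pi_hi[3], 0.9)
  # at c = k_off/k_on the coupled pair sits at its midpoint
  pi_mid <- saturate(cp$k_off / cp$k_on)
  expect_equal(pi_mid[3] / (pi_mid[2] + pi_mid[3]), 0.5, tolerance = 1e-9)
  # at c = 0 the coupled forward rate is zero
  pi_0 <- saturate(0)
  expect_equal(pi_0[3], 0, tolerance = 1e-12)
})

test_that("titration occupancy matches the analytic stationary distribution", {
  cfg <- trace_sim_config(n_molecules = 10, n_frames = 20000, noise_sd = 0,
                          bleach_rate = 0, blink_rate = 0,
                          ligand_coupling = ligand_coupling(), seed = 5)
  concs <- c(2e-6, 10e-6)
  sim <- simulate_titration(cfg, concs)
  for (cc in concs) {
    q <- cfg$rate_matrix
    q[2, 3] <- cfg$ligand_coupling$k_on * cc
    q[3, 2] <- cfg$ligand_coupling$k_off
    diag(q) <- 0; diag(q) <- -rowSums(q)
    pi_ref <- stationary_distribution(q)
    tr <- sim$truth[sim$truth$concentration == cc, ]
    frac <- vapply(seq_len(nrow(tr)), function(i) {
      jt <- c(tr$jump_times[[i]], 20000 * 0.025)
      js <- tr$jump_states[[i]]
      sum(diff(jt)[js == 3]) / (20000 * 0.025)
    }, numeric(1))
    se <- sd(frac) / sqrt(length(frac))
    expect_lt(abs(mean(frac) - pi_ref[3]), 3 * se + 1e-3)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(trace_sim_config(state_means = c(0, 0.6, 0.5, 0.8)),
               class = "fretgate_config_error")
  expect_error(trace_sim_config(state_means = c(0.1, 0.5, 0.6, 0.8)),
               class = "fretgate_config_error")
  expect_error(trace_sim_config(bleed_through_fraction = 1),
               class = "fretgate_config_error")
  expect_error(trace_sim_config(total_intensity = 0),
               class = "fretgate_config_error")
  q <- matrix(1, 4, 4)  # rows do not sum to zero
  expect_error(trace_sim_config(rate_matrix = q),
               class = "fretgate_config_error")
  expect_error(simulate_titration(trace_sim_config(), 1e-6),
               class = "fretgate_config_error")
  expect_error(
    simulate_titration(
      trace_sim_config(ligand_coupling = ligand_coupling()), numeric(0)),
    class = "fretgate_config_error")
})
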