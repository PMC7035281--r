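atom_row <- function(elety, resno, x, y, z, resid = "XXX", chain = "A",
                     category = "protein") {
  tibble::tibble(elety = elety, resid = resid, chain = chain,
                 resno = as.integer(resno), x = x, y = y, z = z,
                 category = category, frame = 1L)
}

gate_frame <- function() {
  dplyr::bind_rows(
    atom_row("NE", 5, 0, 0, 0, "ARG"), atom_row("NH1", 5, 1, 0, 0, "ARG"),
    atom_row("NH2", 5, 0, 1, 0, "ARG"),
    atom_row("OD1", 369, 5, 0, 0, "ASP"), atom_row("OD2", 369, 9, 0, 0, "ASP"),
    atom_row("OH", 268, 0, 0, 10, "TYR"),
    atom_row("OE1", 361, 0, 6, 10, "GLN"), atom_row("NE2", 361, 0, 7, 10, "GLN"))
}

test_that("gate distances are the minimum over the configured atom sets", {
  d <- gate_distances(gate_frame())
  expect_equal(d$d_r5_d369, 4)       # NH1 (1,0,0) to OD1 (5,0,0)
  expect_equal(d$d_y268_q361, 6)     # OH to OE1
})

test_that("gate distances equal a brute-force all-pairs minimum", {
  gd <- gate_definition()
  for (seed in 1:20) {
    set.seed(seed)
    fr <- dplyr::bind_rows(
      purrr::map(gd$r5_atoms, ~atom_row(.x, 5, rnorm(1, 0, 5), rnorm(1), rnorm(1))),
      purrr::map(gd$d369_atoms, ~atom_row(.x, 369, rnorm(1, 5, 5), rnorm(1), rnorm(1))),
      atom_row("OH", 268, rnorm(1), rnorm(1), rnorm(1)),
      purrr::map(gd$q361_atoms, ~atom_row(.x, 361, rnorm(1), rnorm(1, 4), rnorm(1))))
    d <- gate_distances(fr)
    brute <- function(r1, a1, r2, a2) {
      s1 <- fr[fr$resno == r1 & fr$elety %in% a1, ]
      s2 <- fr[fr$resno == r2 & fr$elety %in% a2, ]
      best <- Inf
      for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2)))
        best <- min(best, sqrt((s1$x[i] - s2$x[j])^2 +
                                 (s1$y[i] - s2$y[j])^2 +
                                 (s1$z[i] - s2$z[j])^2))
      best
    }
    expect_equal(d$d_r5_d369, brute(5, gd$r5_atoms, 369, gd$d369_atoms))
    expect_equal(d$d_y268_q361, brute(268, gd$y268_atoms, 361, gd$q361_atoms))
  }
})

test_that("missing gate atoms raise a named-atom error", {
  fr <- gate_frame()[-1:-3, ]     # drop all R5 atoms
  expect_error(gate_distances(fr), regexp = "residue 5",
               class = "fretgate_atom_error")
})

chi_frame <- function(p4) {
  dplyr::bind_rows(
    atom_row("N", 268, 0, 1, 0, "TYR"), atom_row("CA", 268, 0, 0, 0, "TYR"),
    atom_row("CB", 268, 1, 0, 0, "TYR"),
    atom_row("CG", 268, p4[1], p4[2], p4[3], "TYR"))
}

test_that("chi1 reproduces planted trans and gauche(-) geometries", {
  trans <- chi1(chi_frame(c(1.5, -0.5, 0)))
  expect_equal(trans$chi1, 180)
  expect_equal(trans$rotamer, "out")
  gm <- chi1(chi_frame(c(1.5, 0.5, -sqrt(3) / 2)))
  expect_equal(gm$chi1, -60, tolerance = 1e-9)
  expect_equal(gm$rotamer, "in")
  # independent dihedral cross-check on random geometries
  for (seed in 1:10) {
    set.seed(seed)
    p <- matrix(rnorm(12), 4, 3)
    fr <- chi_frame(p[4, ])
    fr$x[1:3] <- p[1:3, 1]; fr$y[1:3] <- p[1:3, 2]; fr$z[1:3] <- p[1:3, 3]
    expect_equal(chi1(fr)$chi1,
                 as.numeric(bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4)),
                 tolerance = 1e-6)
  }
})

test_that("mirror imaging negates chi1", {
  fr <- chi_frame(c(1.5, 0.5, -sqrt(3) / 2))
  mir <- dplyr::mutate(fr, x = -x)
  expect_equal(chi1(mir)$chi1, -chi1(fr)$chi1, tolerance = 1e-9)
})

test_that("chi1 errors cleanly when dihedral atoms are absent", {
  fr <- chi_frame(c(1, 1, 1))[-4, ]   # no CG (glycine-like)
  expect_error(chi1(fr), class = "fretgate_atom_error")
})

test_that("substrate COM is the mass-weighted mean", {
  fr <- dplyr::bind_rows(
    atom_row("C1", 1, 0, 0, 0, "LIG", category = "substrate"),
    atom_row("C2", 1, 2, 0, 0, "LIG", category = "substrate"))
  expect_equal(as.numeric(substrate_com(fr)[, c("x", "y", "z")]), c(1, 0, 0))
  single <- atom_row("N", 1, 3, -2, 7, "LIG", category = "substrate")
  expect_equal(as.numeric(substrate_com(single)[, c("x", "y", "z")]),
               c(3, -2, 7))
  # 12-heavy-atom substrate against a direct weighted sum
  fx <- make_frame_fixture(frame_fixture_config(seed = 6))
  sub <- fx$atoms[fx$atoms$category == "substrate", ]
  masses <- c(N = 14.007, C = 12.011, O = 15.999)
  w <- masses[substr(sub$elety, 1, 1)]
  expect_equal(as.numeric(substrate_com(fx$atoms)[, c("x", "y", "z")]),
               c(sum(sub$x * w), sum(sub$y * w), sum(sub$z * w)) / sum(w),
               tolerance = 1e-9)
  expect_error(substrate_com(gate_frame()), class = "fretgate_atom_error")
})

test_that("water counting on large random fixtures equals the brute-force oracle", {
  fx <- make_frame_fixture(frame_fixture_config(seed = 44))
  ref <- fx$atoms[fx$atoms$category != "water", ]
  set.seed(45)
  n <- 1000
  waters <- tibble::tibble(
    elety = "O", resid = "HOH", chain = "W", resno = seq_len(n),
    x = runif(n, -18, 18), y = runif(n, -18, 18), z = runif(n, -18, 18),
    category = "water", frame = 1L)
  atoms <- dplyr::bind_rows(ref, waters)
  cw <- count_waters(atoms)
  orc <- oracle_water_labels(atoms)
  expect_identical(cw$vestibule, sum(orc$in_vestibule))
  expect_identical(cw$channel, sum(orc$in_channel))
  expect_lte(cw$channel, cw$vestibule)
  mem <- water_membership(atoms)
  expect_equal(as.data.frame(mem[, names(orc)[-1]]),
               orc[, -1], ignore_attr = TRUE)
})

test_that("waters outside the z window between F259 CB and G13 CA are excluded", {
  fx <- make_frame_fixture(frame_fixture_config(
    satisfy_channel = 0, satisfy_vestibule_only = 0, violate_com = 0,
    violate_lipid = 0, violate_z = 0, violate_l495 = 0, violate_l257 = 0,
    violate_ring = 0, seed = 1))
  w <- tibble::tibble(elety = "O", resid = "HOH", chain = "W", resno = 1L,
                      x = 0, y = 0, z = 13.5, category = "water", frame = 1L)
  mem <- water_membership(dplyr::bind_rows(fx$atoms, w))
  expect_false(mem$in_z_range)
  expect_false(mem$in_vestibule)
})

test_that("hydration histograms summarise counts, replicas and modes", {
  const <- tibble::tibble(frame = 1:50, channel = 6L)
  h <- hydration_histogram(const)
  expect_equal(h$mean, 6)
  expect_equal(h$modes, 6)
  two <- tibble::tibble(frame = 1:200, replica = rep(c("r1", "r2"), each = 100),
                        vestibule = rep(c(10L, 30L), each = 100))
  h2 <- hydration_histogram(two, value_col = "vestibule",
                            replica_col = "replica")
  expect_equal(sort(h2$replica_means$mean), c(10, 30))
  expect_setequal(h2$modes, c(10, 30))
  set.seed(7)
  pois <- tibble::tibble(frame = 1:2000, channel = rpois(2000, 6))
  h3 <- hydration_histogram(pois)
  expect_lt(abs(h3$mean - 6), 3 * sqrt(6 / 2000))
})

test_that("ion coordination counts and labels planted shells", {
  oct <- purrr::map_dfr(1:6, function(i) {
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    atom_row(paste0("O", i), 100 + i, 2.3 * dirs[i, 1], 2.3 * dirs[i, 2],
             2.3 * dirs[i, 3], "HOH", category = "water")
  })
  ion <- atom_row("NA", 500, 0, 0, 0, "NA", category = "ion")
  rep6 <- ion_coordination(dplyr::bind_rows(oct, ion), "NA")
  expect_equal(rep6$count, 6)
  expect_equal(rep6$geometry, "octahedral-like")
  rep5 <- ion_coordination(dplyr::bind_rows(oct[1:5, ], ion), "NA")
  expect_equal(rep5$geometry, "trigonal-bipyramidal-like")
  # brute-force within-cutoff scan on a random frame
  set.seed(9)
  rnd <- purrr::map_dfr(1:40, function(i)
    atom_row(sample(c("O", "N", "C"), 1), i, runif(1, -4, 4),
             runif(1, -4, 4), runif(1, -4, 4)))
  fr <- dplyr::bind_rows(rnd, ion)
  rep_r <- ion_coordination(fr, "NA", cutoff = 3)
  want <- rnd[substr(rnd$elety, 1, 1) %in% c("O", "N") &
                sqrt(rnd$x^2 + rnd$y^2 + rnd$z^2) <= 3, ]
  expect_setequal(rep_r$atoms$resno, want$resno)
  expect_error(ion_coordination(fr, "K"), class = "fretgate_atom_error")
})

test_that("all geometric operators are rigid-motion invariant", {
  fx <- make_frame_fixture(frame_fixture_config(seed = 55))
  gate_fr <- gate_frame()
  chi_fr <- chi_frame(c(1.5, 0.5, -sqrt(3) / 2))
  for (seed in 1:5) {
    set.seed(seed)
    rot <- random_rotation()
    shift <- runif(3, -20, 20)
    d0 <- gate_distances(gate_fr)
    d1 <- gate_distances(apply_rigid(gate_fr, rot, shift))
    expect_equal(d1$d_r5_d369, d0$d_r5_d369, tolerance = 1e-9)
    expect_equal(d1$d_y268_q361, d0$d_y268_q361, tolerance = 1e-9)
    expect_equal(abs(chi1(apply_rigid(chi_fr, rot, shift))$chi1),
                 abs(chi1(chi_fr)$chi1), tolerance = 1e-9)
  }
  # water counting is z-dependent: invariance holds for z-preserving motions
  set.seed(6)
  ang <- runif(1, 0, 2 * pi)
  rot_z <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
                 c(0, 0, 1))
  shift3 <- runif(3, -10, 10)  # z-translation moves the z bounds along too
  cw0 <- count_waters(fx$atoms)
  cw1 <- count_waters(apply_rigid(fx$atoms, rot_z, shift3))
  expect_identical(cw1$vestibule, cw0$vestibule)
  expect_identical(cw1$channel, cw0$channel)
})
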