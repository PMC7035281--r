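# Brute-force, loop-based oracles kept deliberately independent of the
# package's vectorized implementations.

# per-water hydration labels by direct distance checks
oracle_water_labels <- function(atoms, criteria = hydration_criteria()) {
  d <- function(p, q) sqrt(sum((p - q)^2))
  pt <- function(row) c(row$x, row$y, row$z)
  min_dist <- function(p, rows) {
    if (nrow(rows) == 0) return(Inf)
    best <- Inf
    for (i in seq_len(nrow(rows)))
      best <- min(best, d(p, c(rows$x[i], rows$y[i], rows$z[i])))
    best
  }
  sub <- atoms[atoms$category == "substrate", ]
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
              S = 32.06)
  w <- masses[substr(gsub("^[0-9]+", "", sub$elety), 1, 1)]
  com <- c(sum(sub$x * w), sum(sub$y * w), sum(sub$z * w)) / sum(w)
  bb <- function(res) atoms[atoms$resno %in% res &
                              atoms$category == "protein" &
                              atoms$elety %in% criteria$backbone_atoms, ]
  zb <- sort(c(atoms$z[atoms$resno == criteria$z_lower_res &
                         atoms$elety == criteria$z_lower_atom],
               atoms$z[atoms$resno == criteria$z_upper_res &
                         atoms$elety == criteria$z_upper_atom]))
  lipids <- atoms[atoms$category == "lipid", ]
  waters <- atoms[atoms$category == "water" & atoms$elety == "O", ]
  out <- vector("list", nrow(waters))
  for (i in seq_len(nrow(waters))) {
    p <- pt(waters[i, ])
    within_com <- d(p, com) <= criteria$substrate_com_radius
    clear_of_lipid <- min_dist(p, lipids) >= criteria$lipid_exclusion
    in_z_range <- p[3] >= zb[1] && p[3] <= zb[2]
    clear_l495 <- min_dist(p, bb(criteria$l495_res)) >= criteria$excl_l495
    clear_l257 <- min_dist(p, bb(criteria$l257_res)) >= criteria$excl_l257
    clear_ring <- min_dist(p, bb(criteria$ring_residues)) >= criteria$excl_ring
    near_a198 <- min_dist(p, bb(criteria$channel_res)) <= criteria$channel_radius
    vest <- within_com && clear_of_lipid && in_z_range && clear_l495 &&
      clear_l257 && clear_ring
    out[[i]] <- data.frame(
      resno = waters$resno[i], within_com = within_com,
      clear_of_lipid = clear_of_lipid, in_z_range = in_z_range,
      clear_l495 = clear_l495, clear_l257 = clear_l257,
      clear_ring = clear_ring, near_a198 = near_a198,
      in_vestibule = vest, in_channel = vest && near_a198)
  }
  do.call(rbind, out)
}

# random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qrd)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

apply_rigid <- function(atoms, rot, shift) {
  m <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- m[, 1] + shift[1]
  atoms$y <- m[, 2] + shift[2]
  atoms$z <- m[, 3] + shift[3]
  atoms
}

# fret-trace tibble from a per-frame state path (exact state means)
fret_from_path <- function(path, means = c(0, 0.47, 0.63, 0.79),
                           molecule_id = "m1", noise = 0) {
  e <- means[path]
  if (noise > 0) e <- e + rnorm(length(e), 0, noise)
  tibble::tibble(molecule_id = molecule_id,
                 frame_index = seq_along(path) - 1L,
                 efficiency = e, dark = FALSE, frame_period = 0.025)
}

# frame-level ground-truth states from a continuous path (frame midpoints)
truth_frame_states <- function(truth, n_frames, frame_period) {
  purrr::map2(truth$jump_times, truth$jump_states, function(jt, js) {
    mid <- (seq_len(n_frames) - 0.5) * frame_period
    js[findInterval(mid, jt)]
  })
}
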