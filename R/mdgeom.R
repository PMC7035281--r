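#' Intracellular gate definition
#'
#' Collective variables of the intracellular gate: the R5-D369 salt bridge
#' measured as the minimum distance between the arginine guanidinium
#' nitrogens and the aspartate carboxylate oxygens, and the Y268-Q361
#' hydrogen bond measured as the minimum distance between the tyrosine
#' hydroxyl oxygen and the glutamine amide oxygen/nitrogen. Minimum over the
#' chemically relevant polar-atom sets is robust to rotamer flips. The chi1
#' residue for rotamer classification is Y268.
#'
#' @param r5,d369,y268,q361 Residue numbers of the gate residues.
#' @param r5_atoms,d369_atoms,y268_atoms,q361_atoms Atom-name sets used for
#'   the minimum-distance computation.
#' @param chi1_residue Residue whose N-CA-CB-CG dihedral classifies the
#'   "in"/"out" rotamer.
#' @return A `gate_definition` list.
#' @export
gate_definition <- function(r5 = 5, d369 = 369, y268 = 268, q361 = 361,
                            r5_atoms = c("NE", "NH1", "NH2"),
                            d369_atoms = c("OD1", "OD2"),
                            y268_atoms = "OH",
                            q361_atoms = c("OE1", "NE2"),
                            chi1_residue = 268) {
  structure(list(r5 = r5, d369 = d369, y268 = y268, q361 = q361,
                 r5_atoms = r5_atoms, d369_atoms = d369_atoms,
                 y268_atoms = y268_atoms, q361_atoms = q361_atoms,
                 chi1_residue = chi1_residue),
            class = "gate_definition")
}

#' Hydration criteria for vestibule and channel water counting
#'
#' Numeric thresholds defining intracellular-vestibule membership of a water
#' oxygen: within `substrate_com_radius` of the substrate center of mass,
#' not within `lipid_exclusion` of any lipid atom, z-coordinate between the
#' z of F259 C-beta and G13 C-alpha (ordered per frame), and not within the
#' exclusion radii of the L495 / L257 / V276+L280+L420 backbones. The
#' channel is the part of the vestibule within `channel_radius` of the A198
#' backbone. "Backbone" means atoms named N, CA, C, O.
#'
#' @param substrate_com_radius Radius around the substrate COM (default 15).
#' @param lipid_exclusion Lipid exclusion distance (default 5).
#' @param z_lower_res,z_lower_atom Residue/atom giving one z bound
#'   (F259 C-beta).
#' @param z_upper_res,z_upper_atom Residue/atom giving the other z bound
#'   (G13 C-alpha).
#' @param excl_l495,l495_res Exclusion radius (8) around the L495 backbone.
#' @param excl_l257,l257_res Exclusion radius (5) around the L257 backbone.
#' @param excl_ring,ring_residues Exclusion radius (13) around the V276,
#'   L280 and L420 backbones.
#' @param channel_radius,channel_res Channel radius (12) around A198.
#' @param backbone_atoms Atom names constituting a backbone.
#' @return A `hydration_criteria` list. All distances in Angstrom.
#' @export
hydration_criteria <- function(substrate_com_radius = 15, lipid_exclusion = 5,
                               z_lower_res = 259, z_lower_atom = "CB",
                               z_upper_res = 13, z_upper_atom = "CA",
                               excl_l495 = 8, l495_res = 495,
                               excl_l257 = 5, l257_res = 257,
                               excl_ring = 13,
                               ring_residues = c(276, 280, 420),
                               channel_radius = 12, channel_res = 198,
                               backbone_atoms = c("N", "CA", "C", "O")) {
  radii <- c(substrate_com_radius, lipid_exclusion, excl_l495, excl_l257,
             excl_ring, channel_radius)
  if (any(radii <= 0))
    abort("all hydration radii must be positive", class = "fretgate_config_error")
  structure(list(substrate_com_radius = substrate_com_radius,
                 lipid_exclusion = lipid_exclusion,
                 z_lower_res = z_lower_res, z_lower_atom = z_lower_atom,
                 z_upper_res = z_upper_res, z_upper_atom = z_upper_atom,
                 excl_l495 = excl_l495, l495_res = l495_res,
                 excl_l257 = excl_l257, l257_res = l257_res,
                 excl_ring = excl_ring, ring_residues = ring_residues,
                 channel_radius = channel_radius, channel_res = channel_res,
                 backbone_atoms = backbone_atoms),
            class = "hydration_criteria")
}

# ---- internal selection helpers ----

split_frames <- function(atoms) {
  if (!"frame" %in% names(atoms)) atoms$frame <- 1L
  split(atoms, atoms$frame)
}

# rows of `atoms` for residue `resno` restricted to atom names `elety`;
# only protein atoms qualify (waters and ligands can reuse residue numbers);
# errors with a named-atom message when any requested atom is absent
residue_atoms <- function(atoms, resno, elety, chain = NULL,
                          require_all = FALSE) {
  sel <- atoms$resno == resno & atoms$elety %in% elety
  if ("category" %in% names(atoms)) sel <- sel & atoms$category == "protein"
  if (!is.null(chain)) sel <- sel & atoms$chain == chain
  out <- atoms[sel, , drop = FALSE]
  missing <- setdiff(elety, out$elety)
  if (nrow(out) == 0 || (require_all && length(missing) > 0))
    abort(sprintf("atom(s) %s of residue %s%s not found in frame",
                  paste(if (length(missing)) missing else elety,
                        collapse = ","),
                  resno, if (is.null(chain)) "" else paste0(" (chain ", chain, ")")),
          class = "fretgate_atom_error")
  out
}

coords_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# minimum Euclidean distance between two coordinate sets
min_set_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

# squared distances from one point set to another (n_a x n_b)
cross_dist2 <- function(a, b) {
  pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0)
}

# per-row minimum distance from points `a` to point set `b`
row_min_dist <- function(a, b) {
  if (nrow(b) == 0) return(rep(Inf, nrow(a)))
  sqrt(do.call(pmin, as.data.frame(cross_dist2(a, b))))
}

#' Gate collective-variable distances
#'
#' Per frame: the minimum distance between the R5 and D369 polar-atom sets
#' and between the Y268 and Q361 polar-atom sets.
#'
#' @param atoms Atom tibble (see [read_frames()]); multi-frame input uses
#'   the `frame` column.
#' @param gates A [gate_definition()].
#' @param chain Optional chain selector (the transporter crystallizes as a
#'   dimer; pick one monomer).
#' @return Tibble: `frame`, `d_r5_d369`, `d_y268_q361` (Angstrom).
#' @export
gate_distances <- function(atoms, gates = gate_definition(), chain = NULL) {
  purrr::map_dfr(split_frames(atoms), function(fr) {
    a1 <- coords_of(residue_atoms(fr, gates$r5, gates$r5_atoms, chain))
    a2 <- coords_of(residue_atoms(fr, gates$d369, gates$d369_atoms, chain))
    b1 <- coords_of(residue_atoms(fr, gates$y268, gates$y268_atoms, chain))
    b2 <- coords_of(residue_atoms(fr, gates$q361, gates$q361_atoms, chain))
    tibble::tibble(frame = fr$frame[1],
                   d_r5_d369 = min_set_distance(a1, a2),
                   d_y268_q361 = min_set_distance(b1, b2))
  })
}

# signed dihedral of four points (rows of m), degrees in (-180, 180]
dihedral_angle <- function(m) {
  b1 <- m[2, ] - m[1, ]
  b2 <- m[3, ] - m[2, ]
  b3 <- m[4, ] - m[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  # IUPAC sign convention (matches standard torsion tools)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Side-chain chi1 dihedral and rotamer class
#'
#' Signed N-CA-CB-CG dihedral in degrees, in (-180, 180]. The rotamer is
#' classified "out" when `|chi1| >= out_threshold` (trans-like, ~180
#' degrees) and "in" otherwise (gauche).
#'
#' @param atoms Atom tibble.
#' @param resno Residue number (default Y268).
#' @param chain Optional chain selector.
#' @param out_threshold Classification threshold in degrees (default 120).
#' @return Tibble: `frame`, `chi1`, `rotamer`.
#' @export
chi1 <- function(atoms, resno = 268, chain = NULL, out_threshold = 120) {
  needed <- c("N", "CA", "CB", "CG")
  purrr::map_dfr(split_frames(atoms), function(fr) {
    at <- residue_atoms(fr, resno, needed, chain, require_all = TRUE)
    m <- coords_of(at[match(needed, at$elety), ])
    ang <- dihedral_angle(m)
    tibble::tibble(frame = fr$frame[1], chi1 = ang,
                   rotamer = if (abs(ang) >= out_threshold) "out" else "in")
  })
}

# standard atomic masses for elements seen in protein/ligand/water atoms
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, NA. = 22.99, CL = 35.45,
                    K = 39.098, MG = 24.305, FE = 55.845, ZN = 65.38)

element_of <- function(elety) {
  up <- toupper(gsub("^[0-9']+", "", elety))
  two <- substr(up, 1, 2)
  one <- substr(up, 1, 1)
  ifelse(two %in% c("NA", "CL", "MG", "FE", "ZN"), two, one)
}

atom_masses <- function(elety) {
  el <- element_of(elety)
  el[el == "NA"] <- "NA."
  m <- .atomic_masses[el]
  if (any(is.na(m)))
    abort(sprintf("unknown element for atom name(s): %s",
                  paste(unique(elety[is.na(m)]), collapse = ", ")),
          class = "fretgate_atom_error")
  unname(m)
}

#' Center of mass of the bound substrate
#'
#' Mass-weighted mean of the substrate atoms (standard atomic masses;
#' hydrogens included when present).
#'
#' @param atoms Atom tibble with a `category` column.
#' @return Tibble: `frame`, `x`, `y`, `z`.
#' @export
substrate_com <- function(atoms) {
  purrr::map_dfr(split_frames(atoms), function(fr) {
    sub <- fr[fr$category == "substrate", , drop = FALSE]
    if (nrow(sub) == 0)
      abort("no substrate atoms in frame", class = "fretgate_atom_error")
    w <- atom_masses(sub$elety)
    com <- colSums(coords_of(sub) * w) / sum(w)
    tibble::tibble(frame = fr$frame[1], x = com[1], y = com[2], z = com[3])
  })
}

#' Per-water hydration-criterion membership
#'
#' Evaluates every individual vestibule criterion for each water oxygen:
#' proximity to the substrate center of mass, lipid exclusion, the z window
#' between the F259 C-beta and G13 C-alpha, the L495 / L257 / ring backbone
#' exclusions, and A198 backbone proximity (the channel criterion).
#'
#' @param atoms Atom tibble with `category` labels.
#' @param criteria A [hydration_criteria()].
#' @param chain Optional chain selector for the reference residues.
#' @return Tibble, one row per water per frame, with one logical column per
#'   criterion plus `in_vestibule` and `in_channel`.
#' @export
water_membership <- function(atoms, criteria = hydration_criteria(),
                             chain = NULL) {
  bb <- criteria$backbone_atoms
  purrr::map_dfr(split_frames(atoms), function(fr) {
    wat <- fr[fr$category == "water" & element_of(fr$elety) == "O", ,
              drop = FALSE]
    if (nrow(wat) == 0)
      return(tibble::tibble(frame = integer(0)))
    ox <- coords_of(wat)
    com <- as.numeric(substrate_com(fr)[, c("x", "y", "z")])
    zb <- sort(c(
      residue_atoms(fr, criteria$z_lower_res, criteria$z_lower_atom, chain,
                    require_all = TRUE)$z[1],
      residue_atoms(fr, criteria$z_upper_res, criteria$z_upper_atom, chain,
                    require_all = TRUE)$z[1]))
    lip <- fr[fr$category == "lipid", , drop = FALSE]
    bb_of <- function(res) coords_of(
      residue_atoms(fr, res, bb, chain, require_all = TRUE))
    l495 <- bb_of(criteria$l495_res)
    l257 <- bb_of(criteria$l257_res)
    ring <- do.call(rbind, lapply(criteria$ring_residues, bb_of))
    a198 <- bb_of(criteria$channel_res)

    d_com <- sqrt(rowSums(sweep(ox, 2, com)^2))
    min_to <- function(set) row_min_dist(ox, set)
    within_com <- d_com <= criteria$substrate_com_radius
    clear_of_lipid <- min_to(coords_of(lip)) >= criteria$lipid_exclusion
    in_z_range <- wat$z >= zb[1] & wat$z <= zb[2]
    clear_l495 <- min_to(l495) >= criteria$excl_l495
    clear_l257 <- min_to(l257) >= criteria$excl_l257
    clear_ring <- min_to(ring) >= criteria$excl_ring
    near_a198 <- min_to(a198) <= criteria$channel_radius
    vest <- within_com & clear_of_lipid & in_z_range & clear_l495 &
      clear_l257 & clear_ring
    tibble::tibble(
      frame = fr$frame[1], chain = wat$chain, resno = wat$resno,
      within_com = within_com, clear_of_lipid = clear_of_lipid,
      in_z_range = in_z_range, clear_l495 = clear_l495,
      clear_l257 = clear_l257, clear_ring = clear_ring,
      near_a198 = near_a198, in_vestibule = vest,
      in_channel = vest & near_a198)
  })
}

#' Count vestibule and channel waters
#'
#' Vestibule membership requires all exclusion criteria; the channel is the
#' vestibule restricted to within the A198 backbone radius, so the channel
#' count can never exceed the vestibule count.
#'
#' @inheritParams water_membership
#' @return Tibble per frame: `vestibule`, `channel` counts plus list
#'   columns `vestibule_ids` and `channel_ids` of water residue numbers.
#' @export
count_waters <- function(atoms, criteria = hydration_criteria(),
                         chain = NULL) {
  mem <- water_membership(atoms, criteria, chain)
  frames <- split_frames(atoms)
  out <- purrr::map_dfr(frames, function(fr) {
    m <- mem[mem$frame == fr$frame[1], , drop = FALSE]
    tibble::tibble(
      frame = fr$frame[1],
      vestibule = sum(m$in_vestibule), channel = sum(m$in_channel),
      vestibule_ids = list(m$resno[m$in_vestibule]),
      channel_ids = list(m$resno[m$in_channel]))
  })
  stopifnot(all(out$channel <= out$vestibule))
  out
}

#' Summarise hydration counts over frames and replicas
#'
#' Pooled histogram of per-frame water counts, per-replica means and the
#' modes (strict local maxima) of the pooled distribution.
#'
#' @param counts Tibble with a per-frame count column (e.g. from
#'   [count_waters()]).
#' @param value_col Name of the count column (default `"channel"`).
#' @param replica_col Optional column identifying replicas.
#' @return Object of class `hydration_summary` with `histogram`,
#'   `replica_means`, `modes` and the pooled `mean`.
#' @export
hydration_histogram <- function(counts, value_col = "channel",
                                replica_col = NULL) {
  if (nrow(counts) == 0)
    abort("need at least one frame", class = "fretgate_input_error")
  v <- counts[[value_col]]
  hist_tbl <- tibble::tibble(count = seq(min(v), max(v))) |>
    dplyr::left_join(
      tibble::tibble(count = v) |> dplyr::count(.data$count, name = "n"),
      by = "count") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  prob = .data$n / length(v))
  p <- c(-1, hist_tbl$prob, -1)
  modes <- hist_tbl$count[which(hist_tbl$prob > utils::head(p, -2) &
                                  hist_tbl$prob > utils::tail(p, -2))]
  replica_means <- if (!is.null(replica_col)) {
    counts |>
      dplyr::group_by(.data[[replica_col]]) |>
      dplyr::summarise(mean = mean(.data[[value_col]]),
                       n_frames = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(replica = "all", mean = mean(v), n_frames = length(v))
  }
  structure(list(histogram = hist_tbl, replica_means = replica_means,
                 modes = modes, mean = mean(v), value_col = value_col),
            class = "hydration_summary")
}

#' @export
print.hydration_summary <- function(x, ...) {
  cat(sprintf("Hydration summary (%s): mean %.2f waters, mode(s) %s\n",
              x$value_col, x$mean, paste(x$modes, collapse = ", ")))
  print(x$replica_means)
  invisible(x)
}

#' Ion coordination shell
#'
#' Polar protein/substrate/water atoms (O or N) within the cutoff of a named
#' ion, sorted by distance, with a count-based geometry label: 6 ligands is
#' octahedral-like, 5 trigonal-bipyramidal-like, anything else "other".
#'
#' @param atoms Atom tibble.
#' @param ion Either a residue number of an ion-category atom or a
#'   character matched against the ion atom name (`elety`); must identify
#'   exactly one atom.
#' @param cutoff Coordination cutoff in Angstrom (default 3.0).
#' @return Object of class `coordination_report`: `atoms` (coordinating
#'   atoms with distances), `count`, `geometry`.
#' @export
ion_coordination <- function(atoms, ion, cutoff = 3.0) {
  fr <- split_frames(atoms)[[1]]
  ions <- fr[fr$category == "ion", , drop = FALSE]
  sel <- if (is.numeric(ion)) ions$resno == ion else
    ions$elety == ion | ions$resid == ion
  ions <- ions[sel, , drop = FALSE]
  if (nrow(ions) == 0)
    abort(sprintf("ion '%s' not found", ion), class = "fretgate_atom_error")
  if (nrow(ions) > 1)
    abort(sprintf("ion '%s' matches %d atoms; disambiguate by residue number",
                  ion, nrow(ions)), class = "fretgate_atom_error")
  pos <- as.numeric(coords_of(ions))
  pool <- fr[fr$category %in% c("protein", "substrate", "water") &
               element_of(fr$elety) %in% c("O", "N"), , drop = FALSE]
  d <- sqrt(rowSums(sweep(coords_of(pool), 2, pos)^2))
  keep <- d <= cutoff
  shell <- pool[keep, , drop = FALSE]
  shell$distance <- d[keep]
  shell <- dplyr::arrange(shell, .data$distance)
  n <- nrow(shell)
  geometry <- if (n == 6) "octahedral-like" else
    if (n == 5) "trigonal-bipyramidal-like" else "other"
  structure(list(ion = ions, atoms = tibble::as_tibble(shell),
                 count = n, geometry = geometry, cutoff = cutoff),
            class = "coordination_report")
}

#' @export
print.coordination_report <- function(x, ...) {
  cat(sprintf("Ion %s (residue %s): %d coordinating atoms within %.1f A -> %s\n",
              x$ion$elety[1], x$ion$resno[1], x$count, x$cutoff, x$geometry))
  print(dplyr::select(x$atoms, "resno", "resid", "elety", "distance"))
  invisible(x)
}
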