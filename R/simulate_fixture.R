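#' Frame fixture configuration
#'
#' Counts of waters to plant per category: `satisfy_channel` waters meet
#' every vestibule criterion and lie within the channel radius of A198;
#' `satisfy_vestibule_only` meet every vestibule criterion but lie outside
#' the channel; each `violate_*` category fails exactly that one criterion
#' and passes all others. Lipids are single-atom placeholders; waters are
#' rigid 3-atom molecules of which only the oxygen is tested.
#'
#' @param satisfy_channel,satisfy_vestibule_only Counts of fully compliant
#'   waters (inside/outside the channel).
#' @param violate_com,violate_lipid,violate_z,violate_l495,violate_l257,violate_ring
#'   Counts of waters violating exactly the named criterion.
#' @param n_lipid Number of single-atom lipids ringing the vestibule.
#' @param box Cubic box edge length in Angstrom (must be at least twice the
#'   largest criterion radius).
#' @param seed Integer seed.
#' @return A `frame_fixture_config` list.
#' @export
frame_fixture_config <- function(satisfy_channel = 5,
                                 satisfy_vestibule_only = 3,
                                 violate_com = 2, violate_lipid = 2,
                                 violate_z = 2, violate_l495 = 2,
                                 violate_l257 = 2, violate_ring = 2,
                                 n_lipid = 6, box = 40, seed = 1L) {
  counts <- c(satisfy_channel, satisfy_vestibule_only, violate_com,
              violate_lipid, violate_z, violate_l495, violate_l257,
              violate_ring, n_lipid)
  if (any(counts < 0))
    abort("all counts must be non-negative", class = "fretgate_config_error")
  if (box < 30)
    abort("box must be at least twice the largest criterion radius (30 A)",
          class = "fretgate_config_error")
  structure(list(satisfy_channel = satisfy_channel,
                 satisfy_vestibule_only = satisfy_vestibule_only,
                 violate_com = violate_com, violate_lipid = violate_lipid,
                 violate_z = violate_z, violate_l495 = violate_l495,
                 violate_l257 = violate_l257, violate_ring = violate_ring,
                 n_lipid = n_lipid, box = box, seed = as.integer(seed)),
            class = "frame_fixture_config")
}

.fixture_cache <- new.env(parent = emptyenv())

# reference protein/substrate layout shared by all fixtures: substrate COM
# at the origin, z window (-12, 12), exclusion backbones inside or at the
# edge of the vestibule sphere so every violation category is reachable
fixture_reference_atoms <- function(n_lipid) {
  key <- as.character(n_lipid)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  at <- function(elety, resid, chain, resno, x, y, z, category)
    tibble::tibble(elety = elety, resid = resid, chain = chain,
                   resno = as.integer(resno), x = x, y = y, z = z,
                   category = category)
  bb_cluster <- function(resid, resno, cx, cy, cz) {
    dplyr::bind_rows(
      at("N", resid, "A", resno, cx - 0.7, cy, cz, "protein"),
      at("CA", resid, "A", resno, cx, cy, cz, "protein"),
      at("C", resid, "A", resno, cx + 0.7, cy + 0.4, cz, "protein"),
      at("O", resid, "A", resno, cx + 1.2, cy + 1.1, cz + 0.3, "protein"))
  }
  # 12 heavy atoms of an L-Phe-like substrate, centred so its COM ~ origin
  phe <- tibble::tribble(
    ~elety, ~x, ~y, ~z,
    "N", -1.9, 0.9, 0.1, "CA", -1.0, 0.0, -0.6, "C", -1.6, -1.4, -0.7,
    "O", -2.8, -1.6, -0.5, "OXT", -0.8, -2.3, -1.0, "CB", 0.4, 0.0, 0.1,
    "CG", 1.3, 0.9, 0.6, "CD1", 1.3, 2.3, 0.4, "CD2", 2.3, 0.4, 1.4,
    "CE1", 2.2, 3.1, 1.0, "CE2", 3.2, 1.2, 2.0, "CZ", 3.2, 2.6, 1.8) |>
    dplyr::mutate(resid = "LIG", chain = "S", resno = 1L,
                  category = "substrate")
  lipids <- if (n_lipid > 0) {
    ang <- 2 * pi * (seq_len(n_lipid) - 1) / max(n_lipid, 1)
    tibble::tibble(elety = "P", resid = "POPE", chain = "L",
                   resno = seq_len(n_lipid),
                   x = 16 * cos(ang), y = 16 * sin(ang),
                   z = rep_len(c(-6, 0, 6), n_lipid), category = "lipid")
  } else NULL
  out <- dplyr::bind_rows(
    phe,
    at("CA", "GLY", "A", 13, 0, 0.9, 12.0, "protein"),
    at("N", "GLY", "A", 13, -1.1, 1.3, 12.2, "protein"),
    at("CB", "PHE", "A", 259, 0, 0, -12.0, "protein"),
    at("CA", "PHE", "A", 259, 0, 1.0, -12.6, "protein"),
    bb_cluster("LEU", 495, 9, 9, 5),
    bb_cluster("LEU", 257, -9, 9, -5),
    bb_cluster("VAL", 276, 0, -24, 0),
    bb_cluster("LEU", 280, 2.5, -24, 1),
    bb_cluster("LEU", 420, -2.5, -24, -1),
    bb_cluster("ALA", 198, 0, 0, -7),
    lipids)
  .fixture_cache[[key]] <- out
  out
}

# precomputed reference geometry for fast candidate screening
fixture_ref_geometry <- function(ref, criteria) {
  sub <- ref[ref$category == "substrate", ]
  w <- atom_masses(sub$elety)
  bb <- function(resno) as.matrix(
    ref[ref$resno %in% resno & ref$category == "protein" &
          ref$elety %in% criteria$backbone_atoms, c("x", "y", "z")])
  list(com = c(sum(sub$x * w), sum(sub$y * w), sum(sub$z * w)) / sum(w),
       zb = sort(c(ref$z[ref$resno == criteria$z_lower_res &
                           ref$elety == criteria$z_lower_atom],
                   ref$z[ref$resno == criteria$z_upper_res &
                           ref$elety == criteria$z_upper_atom])),
       lipid = as.matrix(ref[ref$category == "lipid", c("x", "y", "z")]),
       l495 = bb(criteria$l495_res), l257 = bb(criteria$l257_res),
       ring = bb(criteria$ring_residues), a198 = bb(criteria$channel_res))
}

# criterion booleans for a batch of candidate points (n x 3 matrix);
# returns an n x 7 logical matrix in fixed column order
eval_criteria_batch <- function(pts, geom, criteria) {
  mind <- function(set) row_min_dist(pts, set)
  cbind(
    within_com = sqrt(rowSums(sweep(pts, 2, geom$com)^2)) <=
      criteria$substrate_com_radius,
    clear_of_lipid = mind(geom$lipid) >= criteria$lipid_exclusion,
    in_z_range = pts[, 3] >= geom$zb[1] & pts[, 3] <= geom$zb[2],
    clear_l495 = mind(geom$l495) >= criteria$excl_l495,
    clear_l257 = mind(geom$l257) >= criteria$excl_l257,
    clear_ring = mind(geom$ring) >= criteria$excl_ring,
    near_a198 = mind(geom$a198) <= criteria$channel_radius)
}

#' Build a coordinate-frame fixture with planted waters
#'
#' Emits a molecular frame containing the reference atoms required by the
#' hydration criteria (substrate heavy atoms, F259 C-beta, G13 C-alpha, the
#' L495/L257/V276/L280/L420/A198 backbones), single-atom lipids, and waters
#' planted by rejection sampling so that each water either satisfies every
#' criterion or violates exactly the one its category names. The returned
#' labels record the boolean outcome of every individual criterion per
#' water, for use as ground truth.
#'
#' @param config A [frame_fixture_config()].
#' @param criteria A [hydration_criteria()] (thresholds used for planting).
#' @return List with `atoms` (atom tibble, `frame = 1`) and `labels`
#'   (per-water criterion booleans plus `category_planted`, `in_vestibule`,
#'   `in_channel`).
#' @export
make_frame_fixture <- function(config = frame_fixture_config(),
                               criteria = hydration_criteria()) {
  stopifnot(inherits(config, "frame_fixture_config"))
  set.seed(config$seed)
  ref <- fixture_reference_atoms(config$n_lipid)
  half <- config$box / 2 - 2
  crit_names <- c("within_com", "clear_of_lipid", "in_z_range",
                  "clear_l495", "clear_l257", "clear_ring")
  # target pattern per category: TRUE pass for the six vestibule criteria,
  # NA = unconstrained for the channel criterion
  targets <- list(
    satisfy_channel = c(rep(TRUE, 6), TRUE),
    satisfy_vestibule_only = c(rep(TRUE, 6), FALSE),
    violate_com = c(FALSE, rep(TRUE, 5), NA),
    violate_lipid = c(TRUE, FALSE, rep(TRUE, 4), NA),
    violate_z = c(TRUE, TRUE, FALSE, rep(TRUE, 3), NA),
    violate_l495 = c(rep(TRUE, 3), FALSE, TRUE, TRUE, NA),
    violate_l257 = c(rep(TRUE, 4), FALSE, TRUE, NA),
    violate_ring = c(rep(TRUE, 5), FALSE, NA))
  geom <- fixture_ref_geometry(ref, criteria)
  pts_all <- matrix(numeric(0), 0, 3)
  got_all <- matrix(logical(0), 0, 7)
  cat_all <- character(0)
  for (cat in names(targets)) {
    n_want <- config[[cat]]
    if (n_want == 0) next
    tgt <- targets[[cat]]
    placed <- 0L
    for (batch in seq_len(150L)) {
      pts <- matrix(runif(3 * 1200L, -half, half), ncol = 3)
      got <- eval_criteria_batch(pts, geom, criteria)
      ok <- rowSums(got[, 1:6] == rep(tgt[1:6], each = nrow(got))) == 6L
      if (!is.na(tgt[7])) ok <- ok & got[, 7] == tgt[7]
      hits <- utils::head(which(ok), n_want - placed)
      if (length(hits) > 0) {
        pts_all <- rbind(pts_all, pts[hits, , drop = FALSE])
        got_all <- rbind(got_all, got[hits, , drop = FALSE])
        cat_all <- c(cat_all, rep(cat, length(hits)))
        placed <- placed + length(hits)
      }
      if (placed >= n_want) break
    }
    if (placed < n_want)
      abort(sprintf("could not place a '%s' water in the box (infeasible geometry)",
                    cat), class = "fretgate_config_error")
  }
  nw <- nrow(pts_all)
  waters <- if (nw > 0) tibble::tibble(
    elety = rep(c("O", "H1", "H2"), nw), resid = "HOH", chain = "W",
    resno = rep(seq_len(nw), each = 3),
    x = rep(pts_all[, 1], each = 3) + rep(c(0, 0.76, -0.76), nw),
    y = rep(pts_all[, 2], each = 3) + rep(c(0, 0.59, 0.59), nw),
    z = rep(pts_all[, 3], each = 3),
    category = "water") else NULL
  vest <- if (nw > 0) rowSums(got_all[, 1:6, drop = FALSE]) == 6L else logical(0)
  labels <- tibble::tibble(
    resno = seq_len(nw), category_planted = cat_all,
    !!!setNames(lapply(1:6, function(j) unname(got_all[, j])), crit_names),
    near_a198 = unname(got_all[, 7]),
    in_vestibule = vest, in_channel = vest & got_all[, 7])
  atoms <- dplyr::bind_rows(ref, waters)
  atoms$frame <- 1L
  atoms$eleno <- seq_len(nrow(atoms))
  list(atoms = atoms, labels = labels)
}
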