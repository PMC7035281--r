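.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Default residue-name category map
#'
#' Maps residue names to the atom categories used throughout the geometry
#' module. Assignment order: water, lipid, ion, substrate map, standard
#' amino acids as protein, then HETATM records not otherwise claimed as
#' substrate; anything left is "unknown" (with a warning on read).
#'
#' @return Named list of residue-name vectors.
#' @export
default_category_map <- function() {
  list(water = c("HOH", "TIP3", "TIP", "SOL", "WAT", "SPC"),
       lipid = c("POPE", "POPG", "POPC", "POPS", "DPPC", "DOPC", "DMPC"),
       ion = c("NA", "SOD", "CL", "CLA", "K", "POT", "MG", "ZN", "CAL"),
       substrate = c("LIG", "UNL"))
}

assign_categories <- function(resid, type, category_map) {
  out <- rep("unknown", length(resid))
  out[resid %in% category_map$water] <- "water"
  out[resid %in% category_map$lipid] <- "lipid"
  out[resid %in% category_map$ion] <- "ion"
  out[resid %in% category_map$substrate] <- "substrate"
  is_aa <- resid %in% .standard_aa & out == "unknown"
  out[is_aa & type == "ATOM"] <- "protein"
  # an amino-acid HETATM that is not part of a chain is a bound ligand
  out[is_aa & type == "HETATM"] <- "substrate"
  out[out == "unknown" & type == "HETATM"] <- "substrate"
  out
}

#' Read molecular coordinate frames from PDB
#'
#' Fixed-column PDB parsing via bio3d; MODEL/ENDMDL records delimit frames
#' in multi-model files. Categories are assigned from the residue-name map;
#' unmapped residue names go to an explicit "unknown" bucket with a
#' warning. Malformed ATOM/HETATM records raise an error naming the line.
#'
#' @param path PDB file path.
#' @param category_map See [default_category_map()].
#' @return Atom tibble: `frame`, `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z`, `category`. Coordinates in Angstrom; occupancy
#'   and B-factor columns are ignored.
#' @export
read_frames <- function(path, category_map = default_category_map()) {
  if (!file.exists(path))
    abort(paste("no such file:", path), class = "fretgate_io_error")
  lines <- readLines(path)
  rec <- grep("^(ATOM|HETATM)", lines)
  for (i in rec) {
    tokens <- strsplit(trimws(substr(lines[i], 31, 66)), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(utils::head(tokens, 3)))
    if (length(vals) < 3 || any(is.na(vals)))
      abort(sprintf("unparseable coordinate record at line %d", i),
            class = "fretgate_io_parse_error")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  base <- tibble::tibble(
    eleno = pdb$atom$eleno, elety = pdb$atom$elety, resid = pdb$atom$resid,
    chain = dplyr::coalesce(pdb$atom$chain, "A"),
    resno = pdb$atom$resno,
    category = assign_categories(pdb$atom$resid, pdb$atom$type,
                                 category_map))
  if (any(base$category == "unknown"))
    warn(paste("unknown residue name(s):",
               paste(unique(base$resid[base$category == "unknown"]),
                     collapse = ", ")))
  purrr::map_dfr(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    dplyr::mutate(base, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  frame = m, .before = 1)
  }) |>
    dplyr::relocate("frame", "eleno", "elety", "resid", "chain", "resno",
                    "x", "y", "z", "category")
}

#' Write coordinate frames as (multi-model) PDB
#'
#' Single frames are written as a plain PDB; multiple frames are wrapped in
#' MODEL/ENDMDL blocks in frame order. Records are emitted in fixed v3.3
#' columns (residue names up to 4 characters occupy columns 18-21, the
#' common convention for lipid residues); occupancy and B-factor are
#' written as 1.00 and 0.00.
#'
#' @param atoms Atom tibble (see [read_frames()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(atoms, path) {
  frames <- split_frames(atoms)
  record_lines <- function(fr) {
    het <- fr$category %in% c("substrate", "ion", "water", "lipid")
    eleno <- if ("eleno" %in% names(fr)) fr$eleno else seq_len(nrow(fr))
    name4 <- ifelse(nchar(fr$elety) >= 4, sprintf("%-4s", fr$elety),
                    sprintf(" %-3s", fr$elety))
    sprintf("%-6s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            ifelse(het, "HETATM", "ATOM"), eleno, name4, fr$resid,
            fr$chain, fr$resno, fr$x, fr$y, fr$z, 1, 0)
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (length(frames) == 1) {
    writeLines(record_lines(frames[[1]]), con)
  } else {
    for (i in seq_along(frames)) {
      writeLines(sprintf("MODEL %8d", i), con)
      writeLines(record_lines(frames[[i]]), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
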