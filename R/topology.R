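#' Construct and validate a topology
#'
#' A topology is the static description of the system: one row per atom with
#' position, partial charge, van der Waals radius, and fragment membership.
#' Fragment names follow the hole-hopping system this package models: the
#' two tryptophan indoles (`W124`, `W122`), the sensitizer pieces (`dmp`,
#' `ReCO3`, optional axial-ligand atoms, jointly `Re_minus`), the labeled
#' segment `SAL`, the glutamine `Q107`, `solvent`, and everything else as
#' `protein_rest`.
#'
#' @param atoms A data frame with columns `atom_id` (integer, unique),
#'   `element` (symbol), `x`, `y`, `z` (Angstrom), `charge` (e),
#'   `vdw_radius` (Angstrom, > 0), `residue_tag` (text), and `fragment`
#'   (one of the fragment names above).
#' @param re_axial_fragments Character vector of fragment names that, with
#'   `dmp` and `ReCO3`, make up the reduced sensitizer `Re_minus`
#'   (default none beyond the two).
#' @return A `topology` object: the validated atom tibble plus metadata.
#' @export
topology <- function(atoms, re_axial_fragments = character()) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("atom_id", "element", "x", "y", "z", "charge",
                "vdw_radius", "residue_tag", "fragment")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(atoms$atom_id)) {
    stop("duplicate atom_id in topology", call. = FALSE)
  }
  if (any(!nzchar(atoms$element)) || anyNA(atoms$element)) {
    stop("every atom needs a non-empty element symbol", call. = FALSE)
  }
  if (any(!is.finite(atoms$charge))) {
    stop("partial charges must be finite", call. = FALSE)
  }
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("atom positions must be finite", call. = FALSE)
  }
  if (any(atoms$vdw_radius <= 0)) {
    stop("van der Waals radii must be positive", call. = FALSE)
  }
  atoms$is_hydrogen <- atoms$element == "H"
  atoms$is_solvent <- atoms$fragment == "solvent"

  # solvent must come as whole waters: O,H,H per residue_tag
  solv <- atoms[atoms$is_solvent, ]
  if (nrow(solv)) {
    bad <- solv |>
      dplyr::summarise(
        n = dplyr::n(),
        n_o = sum(.data$element == "O"),
        n_h = sum(.data$element == "H"),
        .by = "residue_tag"
      ) |>
      dplyr::filter(.data$n != 3L | .data$n_o != 1L | .data$n_h != 2L)
    if (nrow(bad)) {
      stop("solvent must be whole 3-site waters (O,H,H); offending residue(s): ",
           paste(utils::head(bad$residue_tag, 5), collapse = ", "),
           call. = FALSE)
    }
  }

  known <- c("W124", "W122", "dmp", "ReCO3", re_axial_fragments,
             "SAL", "Q107", "solvent", "protein_rest")
  unknown <- setdiff(unique(atoms$fragment), known)
  if (length(unknown)) {
    stop("unknown fragment name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  structure(
    list(atoms = atoms,
         re_minus_fragments = c("dmp", "ReCO3", re_axial_fragments)),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  counts <- table(x$atoms$fragment)
  cat(sprintf("<topology> %d atoms in %d fragments\n",
              nrow(x$atoms), length(counts)))
  for (f in names(counts)) cat(sprintf("  %-12s %4d atoms\n", f, counts[[f]]))
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology A `topology`.
#' @return Integer count.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Atom indices of a fragment
#'
#' @param topology A `topology`.
#' @param fragment Fragment name; `"Re_minus"` expands to dmp + ReCO3 (+ any
#'   configured axial-ligand fragments), `"protein"` to everything that is
#'   not solvent and not an indole (the convention that the protein group
#'   includes the reduced sensitizer).
#' @param heavy_only Drop hydrogens (default FALSE).
#' @return Integer row indices into `topology$atoms`.
#' @export
fragment_atoms <- function(topology, fragment, heavy_only = FALSE) {
  a <- topology$atoms
  sel <- switch(
    fragment,
    Re_minus = a$fragment %in% topology$re_minus_fragments,
    protein = !(a$fragment %in% c("W124", "W122", "solvent")),
    a$fragment == fragment
  )
  if (heavy_only) sel <- sel & !a$is_hydrogen
  which(sel)
}

#' Read a topology from PDB plus a fragment-map config
#'
#' The PDB file supplies names and coordinates (first model only); the
#' config supplies fragment membership, a partial-charge sidecar, and
#' optional per-element van der Waals radius overrides (Bondi radii by
#' default, since PDB carries neither charges nor radii).
#'
#' @param pdb_path Path to a PDB file (parsed with \pkg{bio3d}).
#' @param fragment_config Either a path to a YAML file or a list with
#'   elements `fragments` (named list: fragment name -> integer atom serial
#'   numbers), optional `charges` (path to a CSV with columns
#'   `atom_id,charge_e`, or a named list/vector keyed by atom id; atoms
#'   absent from the table get charge 0), optional `radii` (named list of
#'   per-element overrides in Angstrom), and optional `re_axial_fragments`.
#' @return A `topology`.
#' @export
read_topology <- function(pdb_path, fragment_config) {
  cfg <- if (is.character(fragment_config) && length(fragment_config) == 1) {
    yaml::read_yaml(fragment_config)
  } else {
    fragment_config
  }
  if (is.null(cfg$fragments)) {
    stop("fragment config must contain a `fragments` map", call. = FALSE)
  }

  pdb <- bio3d::read.pdb(pdb_path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  ids <- as.integer(at$eleno)
  if (anyDuplicated(ids)) {
    stop("duplicate atom_id (serial) in PDB file", call. = FALSE)
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  elem <- trimws(elem)
  # normalise case: "RE" -> "Re"
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substring(elem, 2)))

  frag_lists <- lapply(cfg$fragments, as.integer)
  all_listed <- unlist(frag_lists, use.names = FALSE)
  if (anyDuplicated(all_listed)) {
    dup <- unique(all_listed[duplicated(all_listed)])
    owners <- names(frag_lists)[vapply(frag_lists, function(v) dup[1] %in% v,
                                       logical(1))]
    stop(sprintf("atom %d assigned to more than one fragment (%s)",
                 dup[1], paste(owners, collapse = ", ")), call. = FALSE)
  }
  unresolved <- setdiff(all_listed, ids)
  if (length(unresolved)) {
    bad_frag <- names(frag_lists)[vapply(
      frag_lists, function(v) any(v %in% unresolved), logical(1))]
    stop("fragment config names atom ids absent from the PDB (fragment ",
         paste(bad_frag, collapse = ", "), ")", call. = FALSE)
  }
  fragment <- rep("protein_rest", length(ids))
  for (f in names(frag_lists)) {
    fragment[match(frag_lists[[f]], ids)] <- f
  }

  charges <- rep(0, length(ids))
  if (!is.null(cfg$charges)) {
    if (is.character(cfg$charges) && length(cfg$charges) == 1) {
      tab <- readr::read_csv(cfg$charges, show_col_types = FALSE)
      if (!all(c("atom_id", "charge_e") %in% names(tab))) {
        stop("charge sidecar needs columns atom_id, charge_e", call. = FALSE)
      }
      idx <- match(tab$atom_id, ids)
      if (anyNA(idx)) stop("charge sidecar references unknown atom ids",
                           call. = FALSE)
      charges[idx] <- tab$charge_e
    } else {
      ch <- unlist(cfg$charges)
      idx <- match(as.integer(names(ch)), ids)
      if (anyNA(idx)) stop("charge table references unknown atom ids",
                           call. = FALSE)
      charges[idx] <- as.numeric(ch)
    }
  }

  overrides <- if (!is.null(cfg$radii)) unlist(cfg$radii) else NULL
  atoms <- tibble::tibble(
    atom_id = ids,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    charge = charges,
    vdw_radius = vdw_radius(elem, overrides),
    residue_tag = paste0(trimws(at$resid), at$resno),
    fragment = fragment
  )
  topology(atoms,
           re_axial_fragments = cfg$re_axial_fragments %||% character())
}

#' Write a topology to PDB plus sidecar files
#'
#' Inverse of [read_topology()]: emits a PDB (via \pkg{bio3d}), a charge
#' sidecar CSV, and a YAML fragment map whose `charges` entry points at the
#' sidecar, so the trio round-trips through [read_topology()].
#'
#' @param topology A `topology`.
#' @param pdb_path Output PDB path.
#' @param config_path Output YAML path (default: `pdb_path` with
#'   `.yaml` extension).
#' @return Invisibly, the config path.
#' @export
write_topology <- function(topology, pdb_path,
                           config_path = sub("\\.pdb$", ".yaml", pdb_path)) {
  a <- topology$atoms
  resno <- as.integer(factor(a$residue_tag, levels = unique(a$residue_tag)))
  pdb <- bio3d::write.pdb(
    file = pdb_path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = "ATOM",
    eleno = a$atom_id,
    elety = a$element,
    resid = substr(gsub("[0-9]+$", "", a$residue_tag), 1, 3),
    resno = resno,
    elesy = a$element
  )
  charge_path <- sub("\\.ya?ml$", "_charges.csv", config_path)
  readr::write_csv(tibble::tibble(atom_id = a$atom_id, charge_e = a$charge),
                   charge_path)
  frag <- split(a$atom_id, a$fragment)
  frag <- frag[setdiff(names(frag), "protein_rest")]
  axial <- setdiff(topology$re_minus_fragments, c("dmp", "ReCO3"))
  cfg <- list(fragments = lapply(frag, as.integer),
              charges = charge_path)
  if (length(axial)) cfg$re_axial_fragments <- axial
  yaml::write_yaml(cfg, config_path)
  invisible(config_path)
}
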