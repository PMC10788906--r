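# Shared fixture builders. Everything is generated in code; no data files.

# Minimal topology from parallel vectors; defaults give carbon atoms with
# zero charge in protein_rest.
toy_topology <- function(x, y, z,
                         element = rep("C", length(x)),
                         fragment = rep("protein_rest", length(x)),
                         charge = rep(0, length(x)),
                         residue_tag = NULL) {
  n <- length(x)
  if (is.null(residue_tag)) {
    residue_tag <- ifelse(fragment == "solvent", NA_character_,
                          paste0("RES", seq_len(n)))
    # group solvent atoms into consecutive O,H,H waters
    sol <- which(fragment == "solvent")
    if (length(sol)) {
      residue_tag[sol] <- paste0("WAT", rep(seq_len(length(sol) / 3),
                                            each = 3))
    }
  }
  topology(tibble::tibble(
    atom_id = seq_len(n), element = element,
    x = x, y = y, z = z, charge = charge,
    vdw_radius = vdw_radius(element),
    residue_tag = residue_tag, fragment = fragment
  ))
}

# One frame of coordinates straight from a topology
topo_coords <- function(topo) as.matrix(topo$atoms[, c("x", "y", "z")])

# A water (O,H,H rows) at a given oxygen position
water_rows <- function(ox, oy, oz, tag) {
  tibble::tibble(
    element = c("O", "H", "H"),
    x = ox + c(0, 0.9572, -0.24),
    y = oy + c(0, 0, 0.9266),
    z = oz,
    fragment = "solvent",
    residue_tag = tag,
    charge = c(-0.834, 0.417, 0.417)
  )
}

# Topology from a tibble of atom rows (element,x,y,z,fragment,...)
rows_topology <- function(rows) {
  rows$atom_id <- seq_len(nrow(rows))
  if (!"charge" %in% names(rows)) rows$charge <- 0
  rows$charge[is.na(rows$charge)] <- 0
  rows$vdw_radius <- vdw_radius(rows$element)
  if (!"residue_tag" %in% names(rows)) {
    rows$residue_tag <- paste0("R", rows$atom_id)
  }
  topology(rows[, c("atom_id", "element", "x", "y", "z", "charge",
                    "vdw_radius", "residue_tag", "fragment")])
}
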