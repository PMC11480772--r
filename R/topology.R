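## Topology, Trajectory and atom selections ------------------------------

# Standard atomic masses for the elements we expect in peptide/RNA systems
# and in the bead models (bead types map to carbon-like masses unless given).
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  NA. = 22.990, CL = 35.45, MG = 24.305, K = 39.098, X = 12.011
)

.guess_element <- function(name) {
  # PDB-style fallback: first alphabetic character; two-letter ions handled.
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", name)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "MG", "NA"), two, substr(nm, 1, 1))
}

#' Build a Topology
#'
#' A `Topology` is a data frame with one row per atom holding names, residue
#' assignment, chain, mass, charge and a hydrogen flag.  Atom ids are
#' zero-based and contiguous in file order.
#'
#' @param name character vector of atom names.
#' @param residue_index integer vector of residue numbers.
#' @param residue_name character vector of residue names.
#' @param chain_id character vector of chain identifiers.
#' @param mass atomic masses in amu; if `NULL`, deduced from the element.
#' @param charge per-atom charges in elementary charges (default 0).
#' @param element element symbols; if `NULL`, deduced from `name`.
#' @return An object of class `bindfe_topology` (a data frame).
#' @examples
#' topo <- topology(name = c("O", "H1", "H2"), residue_index = c(1, 1, 1),
#'                  residue_name = "HOH", chain_id = "A")
#' topo$is_hydrogen
#' @export
topology <- function(name, residue_index, residue_name, chain_id = "A",
                     mass = NULL, charge = 0, element = NULL) {
  n <- length(name)
  .assert(n >= 1L, "bindfe_input_error", "topology needs at least one atom")
  if (is.null(element)) element <- .guess_element(name)
  if (is.null(mass)) {
    mass <- unname(.element_masses[element])
    mass[is.na(mass)] <- .element_masses[["X"]]
  }
  df <- data.frame(
    atom_id = seq_len(n) - 1L,
    name = as.character(name),
    residue_index = rep_len(as.integer(residue_index), n),
    residue_name = rep_len(as.character(residue_name), n),
    chain_id = rep_len(as.character(chain_id), n),
    element = rep_len(as.character(element), n),
    mass = rep_len(as.numeric(mass), n),
    charge = rep_len(as.numeric(charge), n),
    stringsAsFactors = FALSE
  )
  df$is_hydrogen <- df$element == "H"
  .assert(all(df$mass > 0), "bindfe_input_error", "all masses must be > 0")
  class(df) <- c("bindfe_topology", "data.frame")
  df
}

#' Number of atoms in a topology
#' @param topology a [topology()] object.
#' @return Integer atom count.
#' @export
n_atoms <- function(topology) nrow(topology)

#' Build a Trajectory
#'
#' Frames are Nx3 coordinate matrices in Angstrom, one row per topology atom.
#'
#' @param topology a [topology()].
#' @param frames a list of Nx3 numeric matrices (a single matrix is wrapped).
#' @param frame_times optional frame time/index labels.
#' @return An object of class `bindfe_trajectory`.
#' @export
trajectory <- function(topology, frames, frame_times = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  .assert(length(frames) >= 1L, "bindfe_input_error", "trajectory needs >= 1 frame")
  na <- n_atoms(topology)
  for (f in frames) {
    .assert(is.matrix(f) && ncol(f) == 3L && nrow(f) == na,
            "bindfe_input_error",
            sprintf("every frame must be a %d x 3 coordinate matrix", na))
    .assert(all(is.finite(f)), "bindfe_input_error", "non-finite coordinates")
  }
  if (is.null(frame_times)) frame_times <- seq_along(frames)
  structure(list(topology = topology, frames = frames,
                 frame_times = frame_times),
            class = "bindfe_trajectory")
}

#' @export
print.bindfe_trajectory <- function(x, ...) {
  cat(sprintf("<bindfe_trajectory: %d atoms, %d frames>\n",
              n_atoms(x$topology), length(x$frames)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Define an atom selection
#'
#' Selections are declarative filters over topology columns; all supplied
#' criteria are combined with AND.  `atom_id` selects explicit ids directly.
#'
#' @param residue_index residues to keep (integer vector) or `NULL`.
#' @param residue_name residue names to keep or `NULL`.
#' @param name atom names to keep or `NULL`.
#' @param chain_id chains to keep or `NULL`.
#' @param hydrogens one of `"exclude"` (default), `"include"`, `"only"`.
#' @param atom_id explicit zero-based atom ids (overrides other criteria).
#' @return An object of class `bindfe_selection`.
#' @examples
#' sel <- atom_selection(residue_index = 1:3, hydrogens = "exclude")
#' @export
atom_selection <- function(residue_index = NULL, residue_name = NULL,
                           name = NULL, chain_id = NULL,
                           hydrogens = c("exclude", "include", "only"),
                           atom_id = NULL) {
  hydrogens <- match.arg(hydrogens)
  structure(list(residue_index = residue_index, residue_name = residue_name,
                 name = name, chain_id = chain_id, hydrogens = hydrogens,
                 atom_id = atom_id),
            class = "bindfe_selection")
}

#' Resolve a selection to atom ids
#'
#' @param sel an [atom_selection()] (or an integer vector of zero-based ids,
#'   taken verbatim).
#' @param topology the [topology()] to resolve against.
#' @param allow_empty if `FALSE` (default) an empty result is an error.
#' @return Zero-based integer atom ids.
#' @export
resolve_selection <- function(sel, topology, allow_empty = FALSE) {
  if (is.numeric(sel)) {
    ids <- as.integer(sel)
  } else {
    .assert(inherits(sel, "bindfe_selection"), "bindfe_input_error",
            "sel must be an atom_selection() or integer ids")
    if (!is.null(sel$atom_id)) {
      ids <- as.integer(sel$atom_id)
    } else {
      keep <- rep(TRUE, n_atoms(topology))
      if (!is.null(sel$residue_index))
        keep <- keep & topology$residue_index %in% sel$residue_index
      if (!is.null(sel$residue_name))
        keep <- keep & topology$residue_name %in% sel$residue_name
      if (!is.null(sel$name)) keep <- keep & topology$name %in% sel$name
      if (!is.null(sel$chain_id))
        keep <- keep & topology$chain_id %in% sel$chain_id
      keep <- switch(sel$hydrogens,
        exclude = keep & !topology$is_hydrogen,
        only    = keep & topology$is_hydrogen,
        include = keep)
      ids <- topology$atom_id[keep]
    }
  }
  if (!allow_empty)
    .assert(length(ids) >= 1L, "bindfe_selection_error",
            "selection resolves to no atoms")
  .assert(all(ids >= 0 & ids < n_atoms(topology)), "bindfe_selection_error",
          "selection contains out-of-range atom ids")
  ids
}
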