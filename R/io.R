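## File formats: PDB, XYZ, window series, profiles, printed tables --------

#' Read a PDB file into a topology and coordinate frame
#'
#' Parsing of the fixed-column PDB v3.3 ATOM/HETATM records is delegated to
#' bio3d; elements come from columns 77-78 with an atom-name fallback, masses
#' from the element, and charges from the optional `charges` vector (PDB
#' files carry none).
#'
#' @param path PDB file path.
#' @param charges optional per-atom charges in file order.
#' @return A list with `topology` ([topology()]) and `frame` (Nx3 matrix).
#' @export
read_pdb <- function(path, charges = NULL) {
  .assert(file.exists(path), "bindfe_io_error", paste("no such file:", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    .bindfe_stop("bindfe_parse_error",
                                 paste("PDB parse failure:", conditionMessage(e))))
  at <- pdb$atom
  .assert(nrow(at) >= 1L, "bindfe_parse_error", "PDB contains no atoms")
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- .guess_element(at$elety[is.na(elem) | elem == ""])
  topo <- topology(name = at$elety, residue_index = at$resno,
                   residue_name = at$resid,
                   chain_id = ifelse(is.na(at$chain), "A", at$chain),
                   charge = if (is.null(charges)) 0 else charges,
                   element = trimws(elem))
  frame <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  list(topology = topo, frame = frame)
}

#' Write a topology + frame as a PDB file
#'
#' @param topology a [topology()].
#' @param frame Nx3 coordinate matrix.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(topology, frame, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(frame)),
                   resno = topology$residue_index,
                   resid = topology$residue_name,
                   eleno = topology$atom_id + 1L,
                   elety = topology$name,
                   chain = topology$chain_id,
                   elesy = topology$element)
  invisible(path)
}

#' Write a trajectory as multi-frame XYZ text
#'
#' Standard XYZ layout per frame: atom count, comment line, then one
#' "element x y z" line per atom.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w"); on.exit(close(con))
  na <- n_atoms(traj$topology)
  for (i in seq_len(n_frames(traj))) {
    writeLines(c(as.character(na), sprintf("frame %d", i)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$topology$element,
                       traj$frames[[i]][, 1], traj$frames[[i]][, 2],
                       traj$frames[[i]][, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path XYZ file path.
#' @param topology optional [topology()] to attach; if `NULL` a minimal one
#'   is built from the element column.
#' @return A [trajectory()].
#' @export
read_xyz <- function(path, topology = NULL) {
  .assert(file.exists(path), "bindfe_io_error", paste("no such file:", path))
  lines <- readLines(path)
  .assert(length(lines) >= 3L, "bindfe_parse_error", "truncated XYZ file")
  frames <- list(); i <- 1L; elements <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    .assert(!is.na(na) && na >= 1L, "bindfe_parse_error",
            sprintf("bad atom count at line %d", i))
    .assert(i + 1L + na <= length(lines), "bindfe_parse_error",
            sprintf("truncated frame at line %d", i))
    block <- lines[(i + 2L):(i + 1L + na)]
    toks <- strsplit(trimws(block), "\\s+")
    el <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    .assert(all(is.finite(xyz)), "bindfe_parse_error",
            sprintf("non-numeric coordinates near line %d", i + 2L))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  if (is.null(topology))
    topology <- topology(name = elements, residue_index = seq_along(elements),
                         residue_name = "UNK", element = elements)
  trajectory(topology, frames)
}

#' Read a two-column (time, coordinate) window sample series
#' @param path whitespace-delimited text file.
#' @return Numeric coordinate vector with a `times` attribute.
#' @export
read_window_series <- function(path) {
  .assert(file.exists(path), "bindfe_io_error", paste("no such file:", path))
  d <- read.table(path, header = FALSE)
  .assert(ncol(d) >= 2L, "bindfe_parse_error", "expected two columns (time, coordinate)")
  x <- as.numeric(d[[2]])
  attr(x, "times") <- as.numeric(d[[1]])
  x
}

#' Write a window sample series as two-column text
#' @param x coordinate samples (optionally with a `times` attribute).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_window_series <- function(x, path) {
  times <- attr(x, "times")
  if (is.null(times)) times <- seq_along(x)
  write.table(data.frame(time = times, coordinate = as.numeric(x)), path,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a PMF profile as TSV (bin_center, free_energy, stderr)
#' @param pmf a [pmf_profile()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_pmf_tsv <- function(pmf, path) {
  write.table(data.frame(bin_center = pmf$bin_centers,
                         free_energy = pmf$free_energy,
                         stderr = pmf$stderr),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PMF profile from TSV
#' @param path file written by [write_pmf_tsv()].
#' @param temperature temperature label for the profile, K.
#' @return A [pmf_profile()].
#' @export
read_pmf_tsv <- function(path, temperature = 300) {
  d <- read.table(path, header = TRUE, sep = "\t")
  pmf_profile(d$bin_center, d$free_energy, d$stderr, temperature)
}

## Printed-table fixtures -------------------------------------------------

#' Load the packaged restraint-contribution table (printed values)
#'
#' Returns the shipped transcription of the published restraint-contribution
#' table: one row per (water model, salt, term), with the parenthetical
#' printed errors parsed into the `stderr` column.  Term labels: site
#' releases `minus_dG_{p,n,o,a}_S` (printed negative), `sep_term`
#' (-kT ln(I* S* C-std)), bulk releases `dG_{o,p,n}_B`, the printed total
#' `dG_b`, and the printed bulk-to-site rows `ddG_{p,n,o}`.
#'
#' @return A data frame with columns `water`, `salt_mM`, `term`, `value`,
#'   `stderr`.
#' @export
load_restraint_table <- function() {
  read.csv(system.file("extdata", "restraint_contributions.csv",
                       package = "bindfe"), stringsAsFactors = FALSE)
}

#' Load the packaged separation-only binding table (printed values)
#'
#' The companion table of binding free energies from conventional umbrella
#' sampling along the separation coordinate (one `sep_term` row per water
#' model and salt concentration).
#'
#' @return A data frame with columns `water`, `salt_mM`, `term`, `value`,
#'   `stderr`.
#' @export
load_separation_table <- function() {
  read.csv(system.file("extdata", "separation_contributions.csv",
                       package = "bindfe"), stringsAsFactors = FALSE)
}

#' Build a free-energy ledger from the printed restraint table
#'
#' @param water water-model label (`"TIP3P"` or `"TIP4P-D"`).
#' @param salt_mM salt concentration (81, 177 or 450).
#' @param table optionally a pre-loaded [load_restraint_table()] data frame.
#' @return A [free_energy_ledger()] (site terms converted to magnitudes).
#' @export
ledger_from_table <- function(water, salt_mM, table = NULL) {
  if (is.null(table)) table <- load_restraint_table()
  d <- table[table$water == water & table$salt_mM == salt_mM, ]
  .assert(nrow(d) > 0, "bindfe_input_error",
          sprintf("no table rows for %s / %s mM", water, salt_mM))
  get <- function(term) {
    row <- d[d$term == term, ]
    .assert(nrow(row) == 1L, "bindfe_ledger_error",
            paste("missing ledger term:", term))
    c(row$value, row$stderr)
  }
  vals <- c(sep_term = get("sep_term")[1],
            dG_p_B = get("dG_p_B")[1], dG_n_B = get("dG_n_B")[1],
            dG_o_B = get("dG_o_B")[1],
            dG_p_S = -get("minus_dG_p_S")[1], dG_n_S = -get("minus_dG_n_S")[1],
            dG_o_S = -get("minus_dG_o_S")[1], dG_a_S = -get("minus_dG_a_S")[1])
  errs <- c(sep_term = get("sep_term")[2],
            dG_p_B = get("dG_p_B")[2], dG_n_B = get("dG_n_B")[2],
            dG_o_B = get("dG_o_B")[2],
            dG_p_S = get("minus_dG_p_S")[2], dG_n_S = get("minus_dG_n_S")[2],
            dG_o_S = get("minus_dG_o_S")[2], dG_a_S = get("minus_dG_a_S")[2])
  free_energy_ledger(vals, errs, temperature = 300, salt_mM = salt_mM,
                     water_model = water)
}

#' Load the editable hydrogen-bond chemistry table
#'
#' Default donor (with attached hydrogen) and acceptor atom names for
#' protein and RNA polar atoms plus the toy bead types; users can pass an
#' edited copy to selection-building code.
#'
#' @param path optional path to an edited copy; default is the packaged
#'   table.
#' @return A data frame with `role`, `residue_class`, `atom_name`,
#'   `attached_hydrogen` columns.
#' @export
load_hbond_chemistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hbond_chemistry.csv", package = "bindfe")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write an order-parameter profile as TSV keyed by window center
#' @param profile an [order_parameter_profile()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  names(df)[names(df) == "value"] <- attr(profile, "statistic_id") %||% "value"
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a restraint scheme (without selections) to YAML
#'
#' Writes the scalar restraint definition -- equilibrium angles, force
#' constant, convention, anchor weighting -- in the pipeline config format.
#' Anchor selections are structural and must be re-supplied on read.
#'
#' @param scheme a [restraint_scheme()].
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
write_restraint_scheme_yaml <- function(scheme, path) {
  yaml::write_yaml(list(
    Theta0 = scheme$Theta0, Phi0 = scheme$Phi0, Psi0 = scheme$Psi0,
    theta0 = scheme$theta0, phi0 = scheme$phi0, k = scheme$k,
    convention = scheme$convention, weighting = scheme$weighting), path)
  invisible(path)
}

#' Read a restraint scheme serialized by [write_restraint_scheme_yaml()]
#' @param path YAML path.
#' @param P0,P1,P2,Q0,Q1,Q2 anchor selections to attach.
#' @return A [restraint_scheme()].
#' @export
read_restraint_scheme_yaml <- function(path, P0, P1, P2, Q0, Q1, Q2) {
  x <- yaml::read_yaml(path)
  restraint_scheme(P0, P1, P2, Q0, Q1, Q2,
                   Theta0 = x$Theta0, Phi0 = x$Phi0, Psi0 = x$Psi0,
                   theta0 = x$theta0, phi0 = x$phi0, k = x$k,
                   convention = x$convention, weighting = x$weighting)
}

#' Salt series of printed binding free energies
#'
#' @param water water-model label.
#' @param source `"restraint"` (ledger-route totals `dG_b`) or
#'   `"separation"` (separation-only route).
#' @return A [salt_series()].
#' @export
table_salt_series <- function(water, source = c("restraint", "separation")) {
  source <- match.arg(source)
  tab <- if (source == "restraint") load_restraint_table()
         else load_separation_table()
  term <- if (source == "restraint") "dG_b" else "sep_term"
  d <- tab[tab$water == water & tab$term == term, ]
  d <- d[order(d$salt_mM), ]
  .assert(nrow(d) >= 2L, "bindfe_input_error", "not enough table rows")
  salt_series(d$salt_mM, d$value, d$stderr)
}
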