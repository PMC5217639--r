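# PDB input/output. Structures are tidy atom tables: one row per atom with
# columns chain, resno, resname, atom, element, x, y, z, het, serial.
# Parsing and fixed-column formatting are delegated to bio3d.

#' Read a PDB file into a tidy atom table
#'
#' Reads ATOM/HETATM records (single model; altloc other than blank/'A'
#' dropped; insertion codes ignored) into one row per atom.
#'
#' @param path Path to a PDB file.
#' @return A tibble with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`, `het` (logical, HETATM record) and
#'   `serial`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("PDB file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop_format(sprintf("'%s' contains no ATOM/HETATM records", path))
  for (i in which(is_atom)) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46), substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop_format(sprintf("unparsable coordinates in '%s' at line %d: %s",
                          path, i, lines[i]))
    }
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop_format(sprintf("cannot parse PDB '%s': %s",
                                            path, conditionMessage(e)))
  )
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  out <- tibble::tibble(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    resname = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), at$elesy),
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    serial = as.integer(at$eleno)
  )
  dup <- duplicated(out[, c("chain", "resno", "atom")])
  if (any(dup)) {
    d <- out[dup, ][1, ]
    stop_validation(sprintf(
      "duplicate atom record: chain '%s' residue %d atom '%s'",
      d$chain, d$resno, d$atom
    ))
  }
  out
}

#' Write a tidy atom table as a PDB file
#'
#' Inverse of [read_pdb()]: coordinates are written at PDB precision
#' (0.001 Angstrom), so a read-write-read round trip preserves chains,
#' residues, atom names and coordinates.
#'
#' @param structure An atom tibble (see [read_pdb()] for columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  if (nrow(structure) == 0) stop_validation("cannot write an empty structure")
  xyz <- as.numeric(t(as.matrix(structure[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = ifelse(structure$het, "HETATM", "ATOM"),
    resno = structure$resno, resid = structure$resname,
    eleno = structure$serial %||% seq_len(nrow(structure)),
    elety = structure$atom, chain = structure$chain,
    o = rep(1, nrow(structure)), b = rep(0, nrow(structure)),
    elesy = structure$element
  )
  invisible(path)
}

#' Extract atoms by chain, residue, residue name or atom name
#'
#' @param structure An atom tibble.
#' @param chain,resno,resname,atom Optional filters; `NULL` keeps all.
#' @return The filtered atom tibble.
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL,
                         resname = NULL, atom = NULL) {
  out <- structure
  if (!is.null(chain)) out <- out[out$chain %in% chain, , drop = FALSE]
  if (!is.null(resno)) out <- out[out$resno %in% resno, , drop = FALSE]
  if (!is.null(resname)) out <- out[out$resname %in% resname, , drop = FALSE]
  if (!is.null(atom)) out <- out[out$atom %in% atom, , drop = FALSE]
  out
}

#' One-letter sequence of a chain
#'
#' @param structure An atom tibble.
#' @param chain Chain identifier.
#' @return A one-letter amino-acid string (phosphothreonine maps to T;
#'   other hetero groups are skipped).
#' @export
structure_sequence <- function(structure, chain) {
  res <- structure |>
    dplyr::filter(.data$chain == !!chain) |>
    dplyr::distinct(.data$resno, .data$resname) |>
    dplyr::arrange(.data$resno)
  letters1 <- AA3TO1[res$resname]
  paste(letters1[!is.na(letters1)], collapse = "")
}
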