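# Geometric interface analysis: hydrogen bonds, salt bridges, ambiguous
# distance-restraint verification and aggregated interface reports.
#
# H-bond criterion: donor-acceptor distance below 3.5 Angstrom and
# hydrogen-donor-acceptor angle below 30 degrees. X-ray-style inputs carry
# no hydrogens, so backbone amide hydrogens are inferred geometrically;
# sidechain donors without a hydrogen fall back to a distance-only check
# and are flagged.

SIDECHAIN_DONORS <- tibble::tribble(
  ~resname, ~atom,
  "LYS", "NZ",
  "ARG", "NE", "ARG", "NH1", "ARG", "NH2",
  "HIS", "ND1", "HIS", "NE2",
  "SER", "OG", "THR", "OG1", "TYR", "OH",
  "ASN", "ND2", "GLN", "NE2", "TRP", "NE1"
)

SIDECHAIN_ACCEPTORS <- tibble::tribble(
  ~resname, ~atom,
  "ASP", "OD1", "ASP", "OD2",
  "GLU", "OE1", "GLU", "OE2",
  "ASN", "OD1", "GLN", "OE1",
  "SER", "OG", "THR", "OG1", "TYR", "OH",
  "HIS", "ND1", "HIS", "NE2"
)

BASIC_ATOMS <- tibble::tribble(
  ~resname, ~atom,
  "LYS", "NZ",
  "ARG", "NE", "ARG", "NH1", "ARG", "NH2",
  "HIS", "ND1", "HIS", "NE2"
)

ACIDIC_ATOMS <- tibble::tribble(
  ~resname, ~atom,
  "ASP", "OD1", "ASP", "OD2",
  "GLU", "OE1", "GLU", "OE2"
)

PHOSPHATE_OXYGENS <- c(
  "O1A", "O2A", "O3A", "O1B", "O2B", "O3B", "O1G", "O2G", "O3G",
  "O1P", "O2P", "O3P"
)

in_pair_table <- function(structure, table) {
  paste(structure$resname, structure$atom) %in% paste(table$resname, table$atom)
}

atom_xyz <- function(row) c(row$x, row$y, row$z)

# Amide hydrogen inferred in the C(i-1)-N(i)-CA(i) plane, 1.0 Angstrom
# from N opposite the bisector of the two bonds.
infer_amide_hydrogen <- function(structure, chain, resno) {
  res <- select_atoms(structure, chain = chain, resno = resno)
  prev <- select_atoms(structure, chain = chain, resno = resno - 1, atom = "C")
  N <- backbone_coords(res, "N")
  CA <- backbone_coords(res, "CA")
  if (is.null(N) || is.null(CA) || nrow(prev) != 1) return(NULL)
  Cp <- atom_xyz(prev[1, ])
  dir <- -(vunit(Cp - N) + vunit(CA - N))
  if (anyNA(dir) || sqrt(sum(dir^2)) < 1e-9) return(NULL)
  N + vunit(dir) * 1.0
}

resolve_selection <- function(structure, sel) {
  do.call(select_atoms, c(list(structure = structure), sel))
}

donor_atoms <- function(atoms) {
  backbone_n <- atoms$atom == "N" & !atoms$het & atoms$resname != "PRO"
  sidechain <- in_pair_table(atoms, SIDECHAIN_DONORS)
  water <- atoms$resname == "HOH" & atoms$atom == "O"
  atoms[backbone_n | sidechain | water, , drop = FALSE]
}

acceptor_atoms <- function(atoms) {
  backbone_o <- atoms$atom == "O" & !atoms$het
  sidechain <- in_pair_table(atoms, SIDECHAIN_ACCEPTORS)
  hetero_o <- atoms$resname %in% c("ATP", "TPO", "HOH") &
    stringr::str_starts(atoms$atom, "O")
  atoms[backbone_o | sidechain | hetero_o, , drop = FALSE]
}

#' Detect hydrogen bonds between two selections
#'
#' Enumerates donor atoms in `donor_sel` against acceptor atoms in
#' `acceptor_sel` and keeps pairs with donor-acceptor distance below
#' `d_max` and hydrogen-donor-acceptor angle below `angle_max`. Backbone
#' amide hydrogens are inferred geometrically when absent; a backbone
#' donor whose hydrogen cannot be placed is skipped with a warning.
#' Sidechain donors without hydrogens are tested on distance only and
#' flagged (`angle = NA`, `h_inferred = FALSE`).
#'
#' @param structure An atom tibble.
#' @param donor_sel,acceptor_sel Selections: lists of [select_atoms()]
#'   arguments, e.g. `list(chain = "P")`.
#' @param d_max Donor-acceptor distance cutoff in Angstrom (default 3.5,
#'   strict `<`).
#' @param angle_max Angle cutoff in degrees (default 30, strict `<`).
#' @param angle_rule `"hda"` (default): the angle at the donor between the
#'   D-H and D-A directions. `"dha"`: deviation of the D-H...A angle at
#'   the hydrogen from linearity (180 degrees minus that angle).
#' @return A tibble of hydrogen bonds: donor and acceptor chain / resno /
#'   resname / atom, `distance`, `angle`, `h_inferred`.
#' @export
detect_hbonds <- function(structure, donor_sel, acceptor_sel,
                          d_max = 3.5, angle_max = 30,
                          angle_rule = c("hda", "dha")) {
  angle_rule <- match.arg(angle_rule)
  donors <- donor_atoms(resolve_selection(structure, donor_sel))
  acceptors <- acceptor_atoms(resolve_selection(structure, acceptor_sel))
  empty <- tibble::tibble(
    donor_chain = character(), donor_resno = integer(),
    donor_resname = character(), donor_atom = character(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_resname = character(), acceptor_atom = character(),
    distance = double(), angle = double(), h_inferred = logical()
  )
  if (nrow(donors) == 0 || nrow(acceptors) == 0) return(empty)
  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(donors))) {
    don <- donors[i, ]
    D <- atom_xyz(don)
    H <- NULL
    h_available <- TRUE
    if (don$atom == "N" && !don$het) {
      H <- infer_amide_hydrogen(structure, don$chain, don$resno)
      if (is.null(H)) {
        skipped <- c(skipped, sprintf("%s%d:%s", don$chain, don$resno, don$atom))
        next
      }
    } else {
      h_available <- FALSE
    }
    for (j in seq_len(nrow(acceptors))) {
      acc <- acceptors[j, ]
      if (acc$chain == don$chain && acc$resno == don$resno) next
      A <- atom_xyz(acc)
      dist <- sqrt(sum((A - D)^2))
      if (dist >= d_max) next
      ang <- NA_real_
      if (h_available) {
        if (angle_rule == "hda") {
          u <- vunit(H - D)
          v <- vunit(A - D)
          ang <- acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
        } else {
          u <- vunit(D - H)
          v <- vunit(A - H)
          ang <- 180 - acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
        }
        if (ang >= angle_max) next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        donor_chain = don$chain, donor_resno = don$resno,
        donor_resname = don$resname, donor_atom = don$atom,
        acceptor_chain = acc$chain, acceptor_resno = acc$resno,
        acceptor_resname = acc$resname, acceptor_atom = acc$atom,
        distance = dist, angle = ang, h_inferred = h_available
      )
    }
  }
  if (length(skipped) > 0) {
    warning(sprintf("skipped donor(s) with no placeable hydrogen: %s",
                    paste(unique(skipped), collapse = ", ")))
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$donor_chain, .data$donor_resno, .data$acceptor_chain,
                 .data$acceptor_resno)
}

#' Detect salt bridges between two selections
#'
#' Pairs positively charged nitrogens (Lys NZ; Arg NE/NH1/NH2; His
#' ND1/NE2) on either side with negatively charged oxygens on the other
#' (Asp/Glu carboxylates or phosphate oxygens of ATP/TPO) within `d_max`.
#'
#' @param structure An atom tibble.
#' @param sel_a,sel_b Selections (lists of [select_atoms()] arguments).
#' @param d_max Heavy-atom distance cutoff in Angstrom (default 4.0,
#'   inclusive).
#' @return A tibble with basic and acidic atom descriptors and `distance`.
#' @export
detect_salt_bridges <- function(structure, sel_a, sel_b, d_max = 4.0) {
  a <- resolve_selection(structure, sel_a)
  b <- resolve_selection(structure, sel_b)
  basic_of <- function(atoms) atoms[in_pair_table(atoms, BASIC_ATOMS), , drop = FALSE]
  acidic_of <- function(atoms) {
    atoms[in_pair_table(atoms, ACIDIC_ATOMS) |
            (atoms$resname %in% c("ATP", "TPO") & atoms$atom %in% PHOSPHATE_OXYGENS), ,
          drop = FALSE]
  }
  pair_up <- function(basic, acidic) {
    if (nrow(basic) == 0 || nrow(acidic) == 0) return(NULL)
    grid <- tidyr::expand_grid(i = seq_len(nrow(basic)), j = seq_len(nrow(acidic)))
    dist <- sqrt(
      (basic$x[grid$i] - acidic$x[grid$j])^2 +
        (basic$y[grid$i] - acidic$y[grid$j])^2 +
        (basic$z[grid$i] - acidic$z[grid$j])^2
    )
    keep <- dist <= d_max
    if (!any(keep)) return(NULL)
    tibble::tibble(
      basic_chain = basic$chain[grid$i[keep]],
      basic_resno = basic$resno[grid$i[keep]],
      basic_resname = basic$resname[grid$i[keep]],
      basic_atom = basic$atom[grid$i[keep]],
      acidic_chain = acidic$chain[grid$j[keep]],
      acidic_resno = acidic$resno[grid$j[keep]],
      acidic_resname = acidic$resname[grid$j[keep]],
      acidic_atom = acidic$atom[grid$j[keep]],
      distance = dist[keep]
    )
  }
  out <- dplyr::bind_rows(
    pair_up(basic_of(a), acidic_of(b)),
    pair_up(basic_of(b), acidic_of(a))
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(
      basic_chain = character(), basic_resno = integer(),
      basic_resname = character(), basic_atom = character(),
      acidic_chain = character(), acidic_resno = integer(),
      acidic_resname = character(), acidic_atom = character(),
      distance = double()
    ))
  }
  dplyr::arrange(dplyr::distinct(out), .data$basic_chain, .data$basic_resno,
                 .data$acidic_chain, .data$acidic_resno)
}

#' Build a restraint specification
#'
#' An ambiguous distance restraint is satisfied when the minimum
#' heavy-atom distance between two atom groups does not exceed
#' `max_distance`.
#'
#' @param name Restraint name.
#' @param group_a,group_b Selections (lists of [select_atoms()] arguments).
#' @param max_distance Maximum allowed minimum distance in Angstrom.
#' @return A one-row restraint tibble; rows can be combined with
#'   `dplyr::bind_rows()`.
#' @export
restraint <- function(name, group_a, group_b, max_distance) {
  if (!is.numeric(max_distance) || max_distance <= 0) {
    stop_usage("max_distance must be positive")
  }
  tibble::tibble(
    name = name, group_a = list(group_a), group_b = list(group_b),
    max_distance = max_distance
  )
}

#' Default docking restraints for the kinase/cyclin/substrate complex
#'
#' Encodes the three restraint families used to drive the docking of the
#' substrate peptide into the catalytic cleft: the phosphoacceptor
#' hydroxyl against the ATP gamma-phosphate; the basic P+3 residue against
#' phosphothreonine 160 of the kinase and I270 of the cyclin; and the
#' Mg2+ ion(s) against their coordinating ligands. Contact restraints
#' default to 3.5 Angstrom, Mg coordination to 3.0. Chain conventions
#' follow [make_complex_fixture()]: A = kinase, B = cyclin, P = substrate
#' peptide, X = hetero groups.
#'
#' @param include_atp,include_mg Include the ATP / Mg restraint rows
#'   (default `TRUE`).
#' @param contact_max,mg_max Distance ceilings in Angstrom.
#' @return A restraint tibble (see [restraint()]).
#' @export
default_restraints <- function(include_atp = TRUE, include_mg = TRUE,
                               contact_max = 3.5, mg_max = 3.0) {
  spec <- dplyr::bind_rows(
    restraint("p3_pt160",
              list(chain = "P", resno = 190),
              list(chain = "A", resno = 160), contact_max),
    restraint("p3_i270",
              list(chain = "P", resno = 190),
              list(chain = "B", resno = 270), contact_max)
  )
  if (include_atp) {
    spec <- dplyr::bind_rows(
      restraint("p0_atp",
                list(chain = "P", resno = 187),
                list(chain = "X", resname = "ATP"), contact_max),
      spec
    )
  }
  if (include_mg) {
    spec <- dplyr::bind_rows(
      spec,
      restraint("mg_coordination",
                list(chain = "X", resname = "MG"),
                list(chain = "X", resname = c("ATP", "HOH")), mg_max)
    )
  }
  spec
}

#' Read / write restraint specifications as JSON
#'
#' @param path JSON file: an array of objects with fields `name`,
#'   `group_a`, `group_b` (objects with optional `chain`, `resno`,
#'   `resname`, `atom`) and `max_distance`.
#' @return For `read_restraints()`, a restraint tibble.
#' @export
read_restraints <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map_dfr(raw, function(r) {
    clean <- function(g) purrr::map(g, function(v) unlist(v, use.names = FALSE))
    restraint(r$name, clean(r$group_a), clean(r$group_b), r$max_distance)
  })
}

#' @rdname read_restraints
#' @param spec A restraint tibble.
#' @export
write_restraints <- function(spec, path) {
  out <- purrr::pmap(spec, function(name, group_a, group_b, max_distance) {
    list(name = name, group_a = group_a, group_b = group_b,
         max_distance = max_distance)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Verify ambiguous distance restraints on a complex
#'
#' For each restraint, computes the minimum heavy-atom distance between
#' the two groups and flags it satisfied when that distance does not
#' exceed `max_distance`.
#'
#' @param structure An atom tibble.
#' @param spec A restraint tibble (default [default_restraints()]).
#' @return A tibble with one row per restraint: `name`, `min_distance`,
#'   `max_distance`, `satisfied`, `n_atoms_a`, `n_atoms_b`.
#' @export
check_restraints <- function(structure, spec = default_restraints()) {
  heavy <- structure[structure$element != "H", , drop = FALSE]
  purrr::pmap_dfr(spec, function(name, group_a, group_b, max_distance) {
    a <- resolve_selection(heavy, group_a)
    b <- resolve_selection(heavy, group_b)
    if (nrow(a) == 0) {
      stop_spec(sprintf("restraint '%s': selection group_a (%s) resolves to no atoms",
                        name, paste(names(group_a), unlist(group_a), sep = "=", collapse = ", ")))
    }
    if (nrow(b) == 0) {
      stop_spec(sprintf("restraint '%s': selection group_b (%s) resolves to no atoms",
                        name, paste(names(group_b), unlist(group_b), sep = "=", collapse = ", ")))
    }
    dmat <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
      sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
    })
    tibble::tibble(
      name = name, min_distance = min(dmat), max_distance = max_distance,
      satisfied = min(dmat) <= max_distance,
      n_atoms_a = nrow(a), n_atoms_b = nrow(b)
    )
  })
}

res_label <- function(resname, resno) {
  paste0(dplyr::coalesce(AA3TO1[resname], resname), resno)
}

#' Aggregated interface report for chain pairs
#'
#' Collects hydrogen bonds (both donor directions) and salt bridges for
#' each requested chain pair into one table with residue labels in
#' one-letter style (e.g. `R194-E42`), ordered deterministically.
#'
#' @param structure An atom tibble.
#' @param chain_pairs A list of length-2 character vectors, e.g.
#'   `list(c("P", "A"), c("P", "B"))`.
#' @param d_max,angle_max H-bond criteria (see [detect_hbonds()]).
#' @param salt_d_max Salt-bridge cutoff (see [detect_salt_bridges()]).
#' @return A tibble: `chain_a`, `chain_b`, `type`, `res_a`, `res_b`,
#'   `atom_a`, `atom_b`, `contact` (label pair), `distance`, `angle`.
#' @export
interface_report <- function(structure, chain_pairs,
                             d_max = 3.5, angle_max = 30, salt_d_max = 4.0) {
  known <- unique(structure$chain)
  for (pair in chain_pairs) {
    bad <- setdiff(pair, known)
    if (length(bad) > 0) {
      stop_validation(sprintf("unknown chain(s): %s", paste(bad, collapse = ", ")))
    }
  }
  rows <- purrr::map_dfr(chain_pairs, function(pair) {
    sa <- list(chain = pair[1])
    sb <- list(chain = pair[2])
    hb <- dplyr::bind_rows(
      detect_hbonds(structure, sa, sb, d_max, angle_max),
      detect_hbonds(structure, sb, sa, d_max, angle_max)
    )
    hb_rows <- NULL
    if (nrow(hb) > 0) {
      a_first <- hb$donor_chain == pair[1]
      hb_rows <- tibble::tibble(
        chain_a = pair[1], chain_b = pair[2], type = "hbond",
        res_a = ifelse(a_first, res_label(hb$donor_resname, hb$donor_resno),
                       res_label(hb$acceptor_resname, hb$acceptor_resno)),
        res_b = ifelse(a_first, res_label(hb$acceptor_resname, hb$acceptor_resno),
                       res_label(hb$donor_resname, hb$donor_resno)),
        atom_a = ifelse(a_first, hb$donor_atom, hb$acceptor_atom),
        atom_b = ifelse(a_first, hb$acceptor_atom, hb$donor_atom),
        resno_a = ifelse(a_first, hb$donor_resno, hb$acceptor_resno),
        distance = hb$distance, angle = hb$angle
      )
    }
    sb_tbl <- detect_salt_bridges(structure, sa, sb, salt_d_max)
    sb_rows <- NULL
    if (nrow(sb_tbl) > 0) {
      a_first <- sb_tbl$basic_chain == pair[1]
      sb_rows <- tibble::tibble(
        chain_a = pair[1], chain_b = pair[2], type = "salt_bridge",
        res_a = ifelse(a_first, res_label(sb_tbl$basic_resname, sb_tbl$basic_resno),
                       res_label(sb_tbl$acidic_resname, sb_tbl$acidic_resno)),
        res_b = ifelse(a_first, res_label(sb_tbl$acidic_resname, sb_tbl$acidic_resno),
                       res_label(sb_tbl$basic_resname, sb_tbl$basic_resno)),
        atom_a = ifelse(a_first, sb_tbl$basic_atom, sb_tbl$acidic_atom),
        atom_b = ifelse(a_first, sb_tbl$acidic_atom, sb_tbl$basic_atom),
        resno_a = ifelse(a_first, sb_tbl$basic_resno, sb_tbl$acidic_resno),
        distance = sb_tbl$distance, angle = NA_real_
      )
    }
    dplyr::bind_rows(hb_rows, sb_rows)
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      chain_a = character(), chain_b = character(), type = character(),
      res_a = character(), res_b = character(), atom_a = character(),
      atom_b = character(), contact = character(), distance = double(),
      angle = double()
    ))
  }
  rows |>
    dplyr::mutate(contact = paste(.data$res_a, .data$res_b, sep = "-")) |>
    dplyr::arrange(.data$chain_a, .data$chain_b, .data$resno_a, .data$type,
                   .data$atom_a, .data$atom_b) |>
    dplyr::select("chain_a", "chain_b", "type", "res_a", "res_b", "atom_a",
                  "atom_b", "contact", "distance", "angle")
}
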