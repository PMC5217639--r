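# Synthetic-data generators: peptide backbones from internal coordinates
# (NeRF chaining with ideal geometry), conformer ensembles with
# controllable phi/psi jitter, complex fixtures with planted interface
# contacts, simulated Michaelis-Menten velocities, and the packaged
# phosphosite table fixture. All generators are pure functions of their
# arguments (seed included).

# Ideal backbone geometry (Angstrom, degrees)
B_NCA <- 1.458
B_CAC <- 1.525
B_CN <- 1.329
B_CO <- 1.231
A_NCAC <- 111.0
A_CACN <- 116.2
A_CNCA <- 121.7
A_CACO <- 120.8

# Natural extension reference frame: place D given three chained atoms
# a-b-c, the c-d bond length, the b-c-d angle and the a-b-c-d torsion.
place_atom <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- -torsion_deg * pi / 180
  bc <- vunit(c_ - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c_ + d[1] * bc + d[2] * m + d[3] * n
}

#' Build a peptide backbone from phi/psi internal coordinates
#'
#' Chains N, CA, C, O atoms with ideal bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; omega fixed at 180
#' degrees), so that measured dihedrals reproduce the inputs.
#'
#' @param sequence One-letter amino-acid string.
#' @param phi_psi Either a length-2 numeric `c(phi, psi)` applied to every
#'   residue, or a data frame / tibble with `phi` and `psi` columns, one
#'   row per residue (the first phi and, except for carbonyl-oxygen
#'   placement, the last psi are unused).
#' @param chain Chain identifier (default `"A"`).
#' @param resno_start First residue number (default 1).
#' @return An atom tibble (see [read_pdb()]) with 4 atoms per residue.
#' @export
build_peptide <- function(sequence, phi_psi, chain = "A", resno_start = 1L) {
  assert_aa_string(sequence, "peptide sequence")
  n <- nchar(sequence)
  letters1 <- stringr::str_split_1(sequence, "")
  if (is.numeric(phi_psi) && length(phi_psi) == 2) {
    phi <- rep(phi_psi[1], n)
    psi <- rep(phi_psi[2], n)
  } else {
    phi_psi <- as.data.frame(phi_psi)
    if (nrow(phi_psi) != n) {
      stop_validation("phi_psi must have one row per residue")
    }
    phi <- phi_psi$phi
    psi <- phi_psi$psi
  }
  if (any(!is.finite(psi)) || any(!is.finite(phi[-1]))) {
    stop_validation("phi/psi angles must be finite")
  }
  Ns <- CAs <- Cs <- Os <- matrix(NA_real_, n, 3)
  Ns[1, ] <- c(0, 0, 0)
  CAs[1, ] <- c(B_NCA, 0, 0)
  ang <- pi - A_NCAC * pi / 180
  Cs[1, ] <- CAs[1, ] + B_CAC * c(cos(ang), sin(ang), 0)
  if (n > 1) {
    for (i in 2:n) {
      Ns[i, ] <- place_atom(Ns[i - 1, ], CAs[i - 1, ], Cs[i - 1, ],
                            B_CN, A_CACN, psi[i - 1])
      CAs[i, ] <- place_atom(CAs[i - 1, ], Cs[i - 1, ], Ns[i, ],
                             B_NCA, A_CNCA, 180)
      Cs[i, ] <- place_atom(Cs[i - 1, ], Ns[i, ], CAs[i, ],
                            B_CAC, A_NCAC, phi[i])
    }
  }
  for (i in seq_len(n)) {
    Os[i, ] <- place_atom(Ns[i, ], CAs[i, ], Cs[i, ],
                          B_CO, A_CACO, wrap_angle(psi[i] + 180))
  }
  resnos <- seq(resno_start, length.out = n)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      chain = chain,
      resno = as.integer(resnos[i]),
      resname = unname(AA3[letters1[i]]),
      atom = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = c(Ns[i, 1], CAs[i, 1], Cs[i, 1], Os[i, 1]),
      y = c(Ns[i, 2], CAs[i, 2], Cs[i, 2], Os[i, 2]),
      z = c(Ns[i, 3], CAs[i, 3], Cs[i, 3], Os[i, 3]),
      het = FALSE
    )
  })
  rows$serial <- seq_len(nrow(rows))
  rows
}

#' Sample a conformer ensemble around a base phi/psi profile
#'
#' Generates `n_models` backbones with per-residue phi/psi drawn as
#' `base + Normal(0, jitter_sd)`; `jitter_sd = 0` reproduces the base
#' conformer. Deterministic for a fixed seed.
#'
#' @param sequence One-letter amino-acid string (default the p27 C-terminal
#'   peptide, residues 180-194).
#' @param base_phi_psi Length-2 numeric or per-residue data frame (see
#'   [build_peptide()]); default extended (-120, 120).
#' @param jitter_sd Gaussian jitter standard deviation in degrees.
#' @param n_models Ensemble size.
#' @param seed RNG seed (mandatory).
#' @param chain Chain identifier for the models.
#' @param resno_start First residue number.
#' @return A named list of atom tibbles (`model_001`, ...).
#' @export
sample_ensemble <- function(sequence = "NAGSVEQTPKKPGLR",
                            base_phi_psi = c(-120, 120),
                            jitter_sd = 10, n_models = 200L, seed,
                            chain = "A", resno_start = 180L) {
  if (missing(seed)) stop_usage("sample_ensemble requires an explicit seed")
  if (n_models < 1) stop_validation("n_models must be at least 1")
  if (jitter_sd < 0) stop_validation("jitter_sd must be non-negative")
  n <- nchar(sequence)
  if (is.numeric(base_phi_psi) && length(base_phi_psi) == 2) {
    base <- tibble::tibble(phi = rep(base_phi_psi[1], n),
                           psi = rep(base_phi_psi[2], n))
  } else {
    base <- tibble::as_tibble(as.data.frame(base_phi_psi))
    if (nrow(base) != n) stop_validation("base_phi_psi must match sequence length")
  }
  withr::with_seed(seed, {
    models <- purrr::map(seq_len(n_models), function(k) {
      jit <- tibble::tibble(
        phi = wrap_angle(base$phi + stats::rnorm(n, 0, jitter_sd)),
        psi = wrap_angle(base$psi + stats::rnorm(n, 0, jitter_sd))
      )
      build_peptide(sequence, jit, chain = chain, resno_start = resno_start)
    })
    names(models) <- sprintf("model_%03d", seq_len(n_models))
    models
  })
}

add_atoms <- function(st, chain, resno, resname, atoms, elements, coords,
                      het = FALSE) {
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  dplyr::bind_rows(st, tibble::tibble(
    chain = chain, resno = as.integer(resno), resname = resname,
    atom = atoms, element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    het = het, serial = NA_integer_
  ))
}

res_coord <- function(st, chain, resno, atom) {
  row <- select_atoms(st, chain = chain, resno = resno, atom = atom)
  c(row$x[1], row$y[1], row$z[1])
}

# Geometric stub sidechain: CB off the backbone frame, then a terminal
# heavy atom extended along the CA->CB direction at the given reach.
place_stub <- function(st, chain, resno, tip_atom, tip_element, reach) {
  N <- res_coord(st, chain, resno, "N")
  CA <- res_coord(st, chain, resno, "CA")
  C <- res_coord(st, chain, resno, "C")
  CB <- place_atom(N, C, CA, 1.53, 110.5, 122.5)
  tip <- CA + vunit(CB - CA) * reach
  resname <- select_atoms(st, chain = chain, resno = resno)$resname[1]
  add_atoms(st, chain, resno, resname,
            c("CB", tip_atom), c("C", tip_element), c(CB, tip))
}

perpendicular_to <- function(u) {
  probe <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vunit(vcross(u, probe))
}

#' Build a kinase/cyclin/peptide complex fixture with planted contacts
#'
#' Constructs a synthetic three-chain complex around the p27 C-terminal
#' peptide (chain `P`, residues 180-194, NAGSVEQTPKKPGLR): a kinase
#' stand-in (chain `A`) carrying planted hydrogen-bond acceptors,
#' salt-bridge partners and phosphothreonine 160; a cyclin stand-in
#' (chain `B`) with I270; and optional ATP / Mg2+ / water hetero groups
#' (chain `X`). Planted hydrogen bonds sit at 2.9 Angstrom with a
#' hydrogen-donor-acceptor angle near 0; each decoy violates exactly one
#' criterion (distance 3.8 Angstrom, or angle 45 degrees). Salt bridges
#' are planted at 3.7 Angstrom (inside the 4.0 cutoff, outside the H-bond
#' one). Restraint geometries are planted satisfied or violated per
#' `restraint_satisfaction`. The chains are geometric stand-ins, not
#' homology models; the fixture exists to give the detectors known ground
#' truth.
#'
#' @param n_hbonds Number of planted peptide-to-kinase hydrogen bonds
#'   (0-4).
#' @param n_hbond_decoys Number of near-miss decoys (0-2).
#' @param n_salt_bridges Number of planted salt bridges (0-2).
#' @param include_atp Include the ATP phosphate group.
#' @param include_mg Number of Mg2+ ions (0-2).
#' @param restraint_satisfaction Named logical over the applicable
#'   restraints (`p0_atp`, `p3_pt160`, `p3_i270`, `mg_coordination`);
#'   default all satisfied.
#' @param peptide_offset Rigid x-translation of the peptide chain in
#'   Angstrom. Non-zero offsets are only allowed on a contact-free spec
#'   (no planted H-bonds/salt bridges, no satisfied restraint): anything
#'   else is contradictory and rejected.
#' @param seed RNG seed for the small backbone jitter (default 1).
#' @return An atom tibble with a `"manifest"` attribute: a list with the
#'   planted `hbonds`, `decoys`, `salt_bridges` tibbles, the restraint
#'   `spec`, and `restraint_expected` (named logical).
#' @export
make_complex_fixture <- function(n_hbonds = 3, n_hbond_decoys = 2,
                                 n_salt_bridges = 1, include_atp = TRUE,
                                 include_mg = 1,
                                 restraint_satisfaction = NULL,
                                 peptide_offset = 0, seed = 1) {
  if (n_hbonds < 0 || n_hbonds > 4 || n_hbond_decoys < 0 || n_hbond_decoys > 2) {
    stop_validation("n_hbonds must be 0-4 and n_hbond_decoys 0-2")
  }
  if (n_salt_bridges < 0 || n_salt_bridges > 2) {
    stop_validation("n_salt_bridges must be 0-2")
  }
  if (!include_mg %in% 0:2) stop_validation("include_mg must be 0, 1 or 2")
  if (include_mg > 0 && !include_atp) {
    stop_spec("contradictory fixture spec: Mg2+ ions require the ATP group")
  }
  spec <- default_restraints(include_atp = include_atp,
                             include_mg = include_mg > 0)
  expected <- stats::setNames(rep(TRUE, nrow(spec)), spec$name)
  if (!is.null(restraint_satisfaction)) {
    bad <- setdiff(names(restraint_satisfaction), spec$name)
    if (length(bad) > 0) {
      stop_spec(sprintf("restraint_satisfaction names not in the spec: %s",
                        paste(bad, collapse = ", ")))
    }
    expected[names(restraint_satisfaction)] <- restraint_satisfaction
  }
  if (peptide_offset != 0 &&
      (n_hbonds > 0 || n_salt_bridges > 0 || any(expected))) {
    stop_spec(paste(
      "contradictory fixture spec: a displaced peptide cannot carry planted",
      "contacts or satisfied restraints"
    ))
  }

  pep_seq <- "NAGSVEQTPKKPGLR"
  npep <- nchar(pep_seq)
  st <- withr::with_seed(seed, {
    jit <- tibble::tibble(
      phi = -120 + stats::rnorm(npep, 0, 2),
      psi = 120 + stats::rnorm(npep, 0, 2)
    )
    build_peptide(pep_seq, jit, chain = "P", resno_start = 180L)
  })

  # Planted hydrogen bonds: peptide backbone amides donate to Glu OE1
  # acceptors on the kinase stand-in.
  donor_pool <- c(182L, 184L, 186L, 192L, 189L, 194L)
  hb_resnos <- donor_pool[seq_len(n_hbonds)]
  decoy_resnos <- donor_pool[n_hbonds + seq_len(n_hbond_decoys)]
  plant_acceptor <- function(st, donor_resno, resno_a, dist, angle_off) {
    N <- res_coord(st, "P", donor_resno, "N")
    H <- infer_amide_hydrogen(st, "P", donor_resno)
    u <- vunit(H - N)
    if (angle_off != 0) {
      CA <- res_coord(st, "P", donor_resno, "CA")
      axis <- vunit(CA - N)
      w <- vunit(axis - sum(axis * u) * u)
      u <- cos(angle_off * pi / 180) * u + sin(angle_off * pi / 180) * w
    }
    target <- N + dist * u
    add_atoms(st, "A", resno_a, "GLU", c("CD", "OE1"), c("C", "O"),
              c(target + 1.25 * u, target))
  }
  hb_manifest <- NULL
  for (k in seq_along(hb_resnos)) {
    st <- plant_acceptor(st, hb_resnos[k], 10L + k, 2.9, 0)
    hb_manifest <- dplyr::bind_rows(hb_manifest, tibble::tibble(
      donor_chain = "P", donor_resno = hb_resnos[k], donor_atom = "N",
      acceptor_chain = "A", acceptor_resno = 10L + k, acceptor_atom = "OE1"
    ))
  }
  decoy_manifest <- NULL
  for (k in seq_along(decoy_resnos)) {
    violates <- if (k %% 2 == 1) "distance" else "angle"
    st <- plant_acceptor(st, decoy_resnos[k], 20L + k,
                         if (violates == "distance") 3.8 else 2.9,
                         if (violates == "angle") 45 else 0)
    decoy_manifest <- dplyr::bind_rows(decoy_manifest, tibble::tibble(
      donor_chain = "P", donor_resno = decoy_resnos[k], donor_atom = "N",
      acceptor_chain = "A", acceptor_resno = 20L + k, acceptor_atom = "OE1",
      violates = violates
    ))
  }

  # Planted salt bridges: basic peptide sidechain tips against Glu
  # carboxylates on the kinase stand-in, at 3.7 Angstrom.
  sb_manifest <- NULL
  sb_sources <- list(
    list(resno = 189L, tip = "NZ", reach = 4.9),
    list(resno = 194L, tip = "NH1", reach = 5.5)
  )
  for (k in seq_len(n_salt_bridges)) {
    src <- sb_sources[[k]]
    st <- place_stub(st, "P", src$resno, src$tip, "N", src$reach)
    CA <- res_coord(st, "P", src$resno, "CA")
    tip <- res_coord(st, "P", src$resno, src$tip)
    u <- vunit(tip - CA)
    target <- tip + 3.7 * u
    st <- add_atoms(st, "A", 30L + k, "GLU", c("CD", "OE1"), c("C", "O"),
                    c(target + 1.25 * u, target))
    sb_manifest <- dplyr::bind_rows(sb_manifest, tibble::tibble(
      basic_chain = "P", basic_resno = src$resno, basic_atom = src$tip,
      acidic_chain = "A", acidic_resno = 30L + k, acidic_atom = "OE1"
    ))
  }

  # Restraint geometry: P+3 (K190) against phosphothreonine 160 of the
  # kinase and I270 of the cyclin; P+0 (T187) hydroxyl against the ATP
  # gamma-phosphate; Mg2+ against its ligands.
  st <- place_stub(st, "P", 190L, "NZ", "N", 4.9)
  nz <- res_coord(st, "P", 190L, "NZ")
  ca190 <- res_coord(st, "P", 190L, "CA")
  u190 <- vunit(nz - ca190)
  w190 <- perpendicular_to(u190)
  d_pt160 <- if (expected[["p3_pt160"]]) 3.0 else 5.5
  o1p <- nz + d_pt160 * u190
  pph <- o1p + 1.6 * u190
  st <- add_atoms(st, "A", 160L, "TPO",
                  c("CA", "O1P", "P", "O2P", "O3P"),
                  c("C", "O", "P", "O", "O"),
                  c(nz + (d_pt160 + 3.2) * w190, o1p, pph,
                    pph + 1.5 * w190, pph - 1.5 * w190))
  d_i270 <- if (expected[["p3_i270"]]) 3.0 else 5.5
  cd1 <- nz + d_i270 * w190
  st <- add_atoms(st, "B", 270L, "ILE", c("CA", "CD1"), c("C", "C"),
                  c(cd1 + 2.0 * w190, cd1))

  if (include_atp) {
    st <- place_stub(st, "P", 187L, "OG1", "O", 2.4)
    og1 <- res_coord(st, "P", 187L, "OG1")
    ca187 <- res_coord(st, "P", 187L, "CA")
    u187 <- vunit(og1 - ca187)
    p1 <- perpendicular_to(u187)
    p2 <- vcross(u187, p1)
    d_atp <- if (expected[["p0_atp"]]) 3.0 else 5.5
    o3g <- og1 + d_atp * u187
    pg <- o3g + 1.6 * u187
    pb <- pg + 2.9 * u187
    pa <- pb + 2.9 * u187
    st <- add_atoms(st, "X", 500L, "ATP",
                    c("O3G", "PG", "O1G", "O2G", "PB", "O1B", "O2B", "O3B",
                      "PA", "O1A", "O2A", "O3A"),
                    c("O", "P", "O", "O", "P", "O", "O", "O", "P", "O", "O", "O"),
                    c(o3g, pg, pg + 1.5 * p1, pg - 1.5 * p1,
                      pb, pb + 1.5 * p1, pb - 1.5 * p1, pb + 1.5 * p2,
                      pa, pa + 1.5 * p1, pa - 1.5 * p1, pa + 1.5 * p2),
                    het = TRUE)
    if (include_mg > 0) {
      o1b <- pb + 1.5 * p1
      mg_ok <- isTRUE(expected["mg_coordination"] == TRUE)
      mg1 <- if (mg_ok) o1b + 2.0 * p1 else o1b + 8.0 * p1
      st <- add_atoms(st, "X", 600L, "MG", "MG", "MG", mg1, het = TRUE)
      st <- add_atoms(st, "X", 700L, "HOH", "O", "O",
                      if (mg_ok) mg1 + 2.0 * u187 else pa + 2.5 * p2,
                      het = TRUE)
      if (include_mg == 2) {
        o2b <- pb - 1.5 * p1
        mg2 <- if (mg_ok) o2b - 2.0 * p1 else o2b - 8.0 * p1
        st <- add_atoms(st, "X", 601L, "MG", "MG", "MG", mg2, het = TRUE)
      }
    }
  }

  if (peptide_offset != 0) {
    is_p <- st$chain == "P"
    st$x[is_p] <- st$x[is_p] + peptide_offset
  }
  st$serial <- seq_len(nrow(st))

  # contacts implied by satisfied restraint geometry are planted features
  if (isTRUE(expected["p3_pt160"] == TRUE)) {
    sb_manifest <- dplyr::bind_rows(sb_manifest, tibble::tibble(
      basic_chain = "P", basic_resno = 190L, basic_atom = "NZ",
      acidic_chain = "A", acidic_resno = 160L, acidic_atom = "O1P"
    ))
    hb_manifest <- dplyr::bind_rows(hb_manifest, tibble::tibble(
      donor_chain = "P", donor_resno = 190L, donor_atom = "NZ",
      acceptor_chain = "A", acceptor_resno = 160L, acceptor_atom = "O1P"
    ))
  }
  attr(st, "manifest") <- list(
    hbonds = hb_manifest %||% tibble::tibble(),
    decoys = decoy_manifest %||% tibble::tibble(),
    salt_bridges = sb_manifest %||% tibble::tibble(),
    spec = spec,
    restraint_expected = expected
  )
  st
}

#' Simulate Michaelis-Menten velocity data
#'
#' Draws `v = Vmax * S / (Km + S) * (1 + e)`, `e ~ Normal(0, cv)`,
#' truncated at zero, for each concentration and replicate. Seeded and
#' reproducible.
#'
#' @param Km,Vmax True kinetic constants (uM, pmol/min).
#' @param concentrations Substrate concentrations in uM (default a 2-fold
#'   dilution series, 12.5-400 uM).
#' @param replicates Measurements per concentration; the default 10
#'   mirrors the assay design of five independent experiments performed
#'   in duplicates.
#' @param cv Multiplicative noise coefficient of variation (default 0.05).
#' @param seed RNG seed (mandatory).
#' @param peptide Label carried into the output (default `"wt"`).
#' @return A tibble with columns `peptide`, `concentration_uM`,
#'   `velocity_pmol_min`, `replicate`.
#' @export
simulate_velocities <- function(Km, Vmax,
                                concentrations = c(12.5, 25, 50, 100, 200, 400),
                                replicates = 10L, cv = 0.05, seed,
                                peptide = "wt") {
  if (missing(seed)) stop_usage("simulate_velocities requires an explicit seed")
  if (cv < 0) stop_validation("cv must be non-negative")
  if (any(concentrations <= 0)) stop_validation("concentrations must be positive")
  grid <- tidyr::expand_grid(concentration_uM = concentrations,
                             replicate = seq_len(replicates))
  truth <- mm_velocity(grid$concentration_uM, Km, Vmax)
  withr::with_seed(seed, {
    eps <- stats::rnorm(nrow(grid), 0, cv)
    tibble::tibble(
      peptide = peptide,
      concentration_uM = grid$concentration_uM,
      velocity_pmol_min = pmax(0, truth * (1 + eps)),
      replicate = grid$replicate
    )
  })
}

#' Write the packaged phosphosite table as a TSV fixture
#'
#' Writes the 35-row curated CDK2 site table (see [cdk2_site_table()])
#' with columns `index`, `protein`, `uniprot`, `site`, `sequence`.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_site_table_fixture <- function(path) {
  readr::write_tsv(cdk2_site_table(), path)
  invisible(path)
}
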