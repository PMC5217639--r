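# Curated CDK2 phosphosite table and consensus-motif statistics.
#
# Sequence windows are anchored on the phosphoacceptor (P+0) and analysed
# at positions P-7..P+7. Positions a short window does not cover are gaps
# and are excluded from that column's denominator.

#' Curated table of in-vivo-confirmed human CDK2 phosphosites
#'
#' Returns the packaged curation of 35 CDK2 phosphorylation sites on 27
#' substrate proteins, each with an 11-15 residue sequence window around
#' the phosphoacceptor. This is the input of the consensus-motif analysis;
#' a TSV copy ships in `inst/extdata/cdk2_sites.tsv`.
#'
#' @return A tibble with columns `index`, `protein`, `uniprot`, `site`
#'   (e.g. `"T187"`) and `sequence`.
#' @export
#' @examples
#' cdk2_site_table()
cdk2_site_table <- function() {
  tibble::tribble(
    ~index, ~protein, ~uniprot, ~site, ~sequence,
    1L, "ATRIP", "Q8WXE1", "S224", "VSHVSPRKNPSV",
    2L, "BRCA1", "P38398", "S1497", "VERSSPSKCPSL",
    3L, "CDKN2D", "P55273", "S76", "SGTSPVHDAAR",
    4L, "CROCC iso2", "Q5TZA2-2", "S763", "PVPGSPARDAPA",
    5L, "Ctip", "Q99708", "T847", "IPPNTPENFWEV",
    6L, "DLG1", "Q12959", "S158", "HSHISPIKPTEA",
    7L, "DLG1", "Q12959", "S443", "QTPASPARYSPV",
    8L, "EZH2", "Q15910", "T345", "ERIKTPPKRPGG",
    9L, "FOXM1 iso2", "Q08050-2", "T596", "PISSTPSKSVLP",
    10L, "FOXO1A", "Q12778", "S249", "KSGKSPRRRAAS",
    11L, "HIRA", "P54198", "T555", "SVLTTPSKIEPM",
    12L, "HR6A", "P49459", "S120", "PNPNSPANSQAA",
    13L, "ID3", "Q02535", "S5", "MKALSPVRGCYE",
    14L, "ING5", "Q8WYH8", "T152", "EEEDTPKKKKHK",
    15L, "LIG3", "P49916", "S210", "GQVTSPVKGASF",
    16L, "ORC2", "Q13416", "T116", "ELAKTPQKSVSF",
    17L, "ORC2", "Q13416", "T226", "VGKETPSKRMKR",
    18L, "p27", "P46527", "T187", "SVEQTPKKPGLR",
    19L, "p63", "Q9H3D4", "T491", "RNALTPTTIPDG",
    20L, "p73", "O15350", "T86", "ASPYTPEHAASV",
    21L, "PELP1", "Q8IZL8", "S991", "PPPESPPKVQPE",
    22L, "PLZF", "Q05516", "S197", "LSAMSPTKAAVD",
    23L, "PLZF", "Q05516", "T282", "EGPGTPTRSSVI",
    24L, "PTPN2 iso2", "P17706-2", "S304", "AFDHSPNKIMTE",
    25L, "RbBP1", "P29374", "S864", "LGQSSPEKKIRI",
    26L, "RbBP1", "P29374", "S1007", "FSVASPLTLSQD",
    27L, "RPL12", "P30050", "S38", "PLGLSPKKVGDD",
    28L, "SIRT2", "Q8IXJ6", "S368", "STSASPKKSPPP",
    29L, "Smad3", "P84022", "T8", "ILPFTPPIVKRL",
    30L, "Smad3", "P84022", "T179", "NIPETPPPGYLS",
    31L, "Smad3", "P84022", "S213", "PNPMSPAHNNLD",
    32L, "SMRT", "Q9T618", "S1259", "IGEDSPSRLDRG",
    33L, "SMRT", "Q9T618", "T1463", "ITQGTPLKYDTG",
    34L, "SMRT", "Q9T618", "S1487", "SLIGSPGRTFPP",
    35L, "NBS1", "Q9NX02", "S432", "NYQLSPTKLPSI"
  )
}

#' Parse a phosphosite table from TSV
#'
#' Reads a tab-separated site table with columns `index`, `protein`,
#' `uniprot`, `site` (residue letter + protein position, e.g. `"T187"`)
#' and `sequence`, splits the site column into the phosphoacceptor residue
#' and its position, and validates every sequence window.
#'
#' @param path Path to a TSV file.
#' @return A tibble of phosphosites with columns `index`, `protein`,
#'   `uniprot`, `site_residue`, `site_position`, `window`. Pipe it through
#'   [anchor_sites()] before computing frequencies.
#' @export
parse_site_table <- function(path) {
  tbl <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character())),
    error = function(e) stop_format(sprintf("cannot read TSV '%s': %s", path, conditionMessage(e)))
  )
  required <- c("index", "protein", "uniprot", "site", "sequence")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop_format(sprintf("site table is missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(tbl) == 0) {
    stop_validation("site table contains no data rows")
  }
  ok <- stringr::str_detect(tbl$site, "^[A-Z][0-9]+$")
  if (any(!ok)) {
    stop_validation(sprintf("malformed site label(s): %s",
                            paste(tbl$site[!ok], collapse = ", ")))
  }
  residue <- stringr::str_sub(tbl$site, 1, 1)
  if (any(!residue %in% c("S", "T"))) {
    stop_validation(sprintf(
      "phosphoacceptor must be S or T; offending site(s): %s",
      paste(tbl$site[!residue %in% c("S", "T")], collapse = ", ")
    ))
  }
  assert_aa_string(tbl$sequence, "site sequence window")
  nlen <- nchar(tbl$sequence)
  if (any(nlen < 11 | nlen > 15)) {
    stop_validation("sequence windows must be 11-15 residues long")
  }
  tibble::tibble(
    index = as.integer(tbl$index),
    protein = tbl$protein,
    uniprot = tbl$uniprot,
    site_residue = residue,
    site_position = as.integer(stringr::str_sub(tbl$site, 2)),
    window = tbl$sequence
  )
}

#' Anchor sequence windows on their phosphoacceptor
#'
#' Sets `anchor_index` (1-based position of P+0 within each window) to the
#' S/T-followed-by-proline occurrence whose residue letter matches the
#' annotated phosphoacceptor. When several positions qualify, the one
#' nearest the window midpoint wins (then the leftmost). The S/T-P
#' requirement reflects the invariant proline at P+1 of the CDK2 consensus.
#'
#' @param sites A site tibble from [parse_site_table()].
#' @return The input tibble with an `anchor_index` integer column added.
#' @export
anchor_sites <- function(sites) {
  if (nrow(sites) == 0) stop_validation("cannot anchor an empty site table")
  sites$anchor_index <- purrr::pmap_int(
    list(sites$window, sites$site_residue, sites$site_position),
    function(window, residue, position) {
      chars <- stringr::str_split_1(window, "")
      n <- length(chars)
      cand <- which(chars == residue & c(chars[-1], "") == "P")
      if (length(cand) == 0) {
        stop_validation(sprintf(
          "no %s-P occurrence in window '%s' (site %s%d); cannot anchor",
          residue, window, residue, position
        ))
      }
      mid <- (1 + n) / 2
      cand[order(abs(cand - mid), cand)][1]
    }
  )
  sites
}

assert_anchored <- function(sites) {
  if (nrow(sites) == 0) stop_validation("site table is empty")
  if (!"anchor_index" %in% names(sites)) {
    stop_validation("site table is not anchored; call anchor_sites() first")
  }
  invisible(sites)
}

# Residue letter at relative position `rel` (P+0 = 0) for each site;
# NA where the window does not cover the position (gap).
residue_at <- function(sites, rel) {
  idx <- sites$anchor_index + rel
  out <- stringr::str_sub(sites$window, idx, idx)
  out[idx < 1 | idx > nchar(sites$window)] <- NA_character_
  out[out == ""] <- NA_character_
  out
}

#' Position-wise amino-acid frequencies around the phosphoacceptor
#'
#' Counts residues at each relative position P-flank..P+flank over all
#' anchored windows and normalizes by the number of windows covering that
#' position (gap-excluded normalization).
#'
#' @param sites An anchored site tibble (see [anchor_sites()]).
#' @param flank Number of positions either side of P+0 (default 7).
#' @return A long tibble with one row per (position, amino acid):
#'   columns `position` (-flank..flank), `aa`, `count`, `n_obs`, `freq`.
#'   Uncovered positions carry `n_obs = 0` and all-zero frequencies.
#' @export
position_frequencies <- function(sites, flank = 7L) {
  assert_anchored(sites)
  if (flank < 0) stop_usage("flank must be non-negative")
  grid <- tidyr::expand_grid(position = seq(-flank, flank), aa = AA1)
  obs <- purrr::map_dfr(seq(-flank, flank), function(rel) {
    tibble::tibble(position = rel, aa = residue_at(sites, rel))
  })
  obs <- dplyr::filter(obs, !is.na(.data$aa))
  counts <- dplyr::count(obs, .data$position, .data$aa, name = "count")
  totals <- dplyr::count(obs, .data$position, name = "n_obs")
  out <- grid |>
    dplyr::left_join(counts, by = c("position", "aa")) |>
    dplyr::left_join(totals, by = "position") |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      n_obs = dplyr::coalesce(.data$n_obs, 0L),
      freq = dplyr::if_else(.data$n_obs > 0, .data$count / .data$n_obs, 0)
    ) |>
    dplyr::arrange(.data$position, match(.data$aa, AA1))
  out
}

#' Sequence-logo column heights
#'
#' Converts a frequency matrix into logo letter heights. In `"frequency"`
#' mode heights are the frequencies themselves. In `"information"` mode the
#' column information content is `log2(20) - H` bits, where `H` is the
#' Shannon entropy of the observed column distribution, and each letter's
#' height is its frequency times the column information content. An
#' optional small-sample correction subtracts the bias term
#' `(20 - 1) / (2 ln(2) n)` from the column information content.
#'
#' @param fm A frequency tibble from [position_frequencies()].
#' @param mode `"frequency"` (default) or `"information"`.
#' @param small_sample_correction Apply the approximate small-n bias
#'   correction to the information content (default `FALSE`).
#' @return A long tibble with columns `position`, `aa`, `height`,
#'   `column_ic` (bits).
#' @export
logo_heights <- function(fm, mode = c("frequency", "information"),
                         small_sample_correction = FALSE) {
  if (length(mode) == 1 && !mode %in% c("frequency", "information")) {
    stop_usage(sprintf("unknown logo mode '%s'", mode))
  }
  mode <- match.arg(mode)
  ic <- fm |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      n_obs = max(.data$n_obs),
      entropy = -sum(ifelse(.data$freq > 0, .data$freq * log2(.data$freq), 0)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      column_ic = ifelse(.data$n_obs > 0, log2(20) - .data$entropy, 0)
    )
  if (small_sample_correction) {
    ic$column_ic <- pmax(
      0, ic$column_ic - ifelse(ic$n_obs > 0, (20 - 1) / (2 * log(2) * ic$n_obs), 0)
    )
  }
  out <- dplyr::left_join(
    fm, dplyr::select(ic, "position", "column_ic"), by = "position"
  )
  out$height <- if (mode == "information") out$freq * out$column_ic else out$freq
  dplyr::select(out, "position", "aa", "height", "column_ic")
}

#' Consensus-motif statistics of an anchored site table
#'
#' Summarises the S/T-P-X-R/K/H consensus over the table: the proline
#' fraction at P+1 and the fraction of sites (and of proteins with at
#' least one such site) carrying a basic residue (R, K or H) at P+3.
#'
#' @param sites An anchored site tibble.
#' @return A one-row tibble: `n_sites`, `n_proteins`, `frac_proline_p1`,
#'   `frac_basic_p3_sites`, `frac_basic_p3_proteins`.
#' @export
motif_statistics <- function(sites) {
  assert_anchored(sites)
  basic <- c("R", "K", "H")
  p1 <- residue_at(sites, 1L)
  p3 <- residue_at(sites, 3L)
  prot_basic <- sites |>
    dplyr::mutate(basic_p3 = !is.na(p3) & p3 %in% basic) |>
    dplyr::group_by(.data$uniprot) |>
    dplyr::summarise(any_basic = any(.data$basic_p3), .groups = "drop")
  tibble::tibble(
    n_sites = nrow(sites),
    n_proteins = dplyr::n_distinct(sites$uniprot),
    frac_proline_p1 = mean(p1 == "P", na.rm = TRUE),
    frac_basic_p3_sites = mean(!is.na(p3) & p3 %in% basic),
    frac_basic_p3_proteins = mean(prot_basic$any_basic)
  )
}

#' Write a frequency matrix as a wide TSV
#'
#' Rows are relative positions, columns the 20 amino acids.
#'
#' @param fm A frequency tibble from [position_frequencies()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(fm, path) {
  wide <- fm |>
    dplyr::select("position", "aa", "freq") |>
    tidyr::pivot_wider(names_from = "aa", values_from = "freq")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Plot a sequence logo
#'
#' Stacked-letter logo of a [logo_heights()] matrix: letters at each
#' relative position are stacked by height, tallest on top.
#'
#' @param logo A tibble from [logo_heights()].
#' @param min_height Letters shorter than this are drawn without a label
#'   (default 0.02).
#' @return A ggplot object.
#' @export
plot_logo <- function(logo, min_height = 0.02) {
  dat <- logo |>
    dplyr::filter(.data$height > 0) |>
    dplyr::group_by(.data$position) |>
    dplyr::arrange(.data$height, .by_group = TRUE) |>
    dplyr::mutate(
      ymax = cumsum(.data$height),
      ymin = .data$ymax - .data$height,
      ymid = (.data$ymin + .data$ymax) / 2
    ) |>
    dplyr::ungroup()
  ggplot2::ggplot(dat) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$position - 0.45, xmax = .data$position + 0.45,
        ymin = .data$ymin, ymax = .data$ymax, fill = .data$aa
      ),
      alpha = 0.25, show.legend = FALSE
    ) +
    ggplot2::geom_text(
      data = dplyr::filter(dat, .data$height >= min_height),
      ggplot2::aes(x = .data$position, y = .data$ymid, label = .data$aa,
                   size = .data$height),
      show.legend = FALSE
    ) +
    ggplot2::scale_size_continuous(range = c(2, 8)) +
    ggplot2::scale_x_continuous(breaks = unique(logo$position)) +
    ggplot2::labs(x = "position relative to P+0", y = "letter height") +
    ggplot2::theme_minimal()
}
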