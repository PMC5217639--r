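# Ramachandran classification and the model-selection protocol:
# filter a conformer ensemble on the fraction of residues in favored
# phi/psi regions, then pick the model with the lowest backbone RMSD to a
# reference.

#' Default Ramachandran region table
#'
#' A rectangle-based region set in (phi, psi) degree space covering the
#' beta, right-handed alpha and left-handed alpha cores as `favored`, each
#' surrounded by an `allowed` margin. Anything outside is an outlier. The
#' table ships as TSV (`inst/extdata/rama_regions.tsv`) so alternative
#' definitions can be swapped in via [read_rama_regions()].
#'
#' @return A tibble with columns `region`, `class` (`favored`/`allowed`),
#'   `phi_min`, `phi_max`, `psi_min`, `psi_max`.
#' @export
default_rama_regions <- function() {
  tibble::tribble(
    ~region,      ~class,    ~phi_min, ~phi_max, ~psi_min, ~psi_max,
    "beta",       "favored", -170,     -50,       90,       175,
    "alphaR",     "favored", -100,     -30,      -67,       -7,
    "alphaL",     "favored",  40,       80,       20,        80,
    "beta",       "allowed", -180,     -40,       70,       180,
    "beta_wrap",  "allowed", -180,     -40,      -180,      -165,
    "alphaR",     "allowed", -120,     -20,      -90,        10,
    "alphaL",     "allowed",  20,       100,      0,         100
  )
}

#' Read a Ramachandran region table from TSV
#'
#' @param path TSV with columns `region`, `class`, `phi_min`, `phi_max`,
#'   `psi_min`, `psi_max`.
#' @return A region tibble as in [default_rama_regions()].
#' @export
read_rama_regions <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(), class = readr::col_character(),
    .default = readr::col_double()
  ))
  need <- c("region", "class", "phi_min", "phi_max", "psi_min", "psi_max")
  if (!all(need %in% names(tbl))) {
    stop_format("region table must have columns region, class, phi_min, phi_max, psi_min, psi_max")
  }
  if (!all(tbl$class %in% c("favored", "allowed"))) {
    stop_format("region class must be 'favored' or 'allowed'")
  }
  tbl
}

wrap_angle <- function(x) {
  out <- (x + 180) %% 360 - 180
  ifelse(out == -180, 180, out)
}

#' Classify a phi/psi pair on the Ramachandran plot
#'
#' Angles are wrapped into (-180, 180]; rectangle boundaries are closed.
#' Favored regions take precedence over allowed; anything else is an
#' outlier. `NA` angles give `NA`.
#'
#' @param phi,psi Numeric vectors of dihedrals in degrees (recycled).
#' @param regions A region tibble (default [default_rama_regions()]).
#' @return Character vector: `"favored"`, `"allowed"` or `"outlier"`.
#' @export
rama_classify <- function(phi, psi, regions = default_rama_regions()) {
  n <- max(length(phi), length(psi))
  phi <- wrap_angle(rep_len(phi, n))
  psi <- wrap_angle(rep_len(psi, n))
  out <- rep(NA_character_, n)
  ok <- !is.na(phi) & !is.na(psi)
  inside <- function(cls) {
    hit <- rep(FALSE, n)
    rects <- regions[regions$class == cls, , drop = FALSE]
    for (j in seq_len(nrow(rects))) {
      hit <- hit | (phi >= rects$phi_min[j] & phi <= rects$phi_max[j] &
                      psi >= rects$psi_min[j] & psi <= rects$psi_max[j])
    }
    hit
  }
  out[ok] <- "outlier"
  out[ok & inside("allowed")] <- "allowed"
  out[ok & inside("favored")] <- "favored"
  out
}

#' Ramachandran filter over a conformer ensemble
#'
#' Scores each model by the fraction of classifiable residues (both phi
#' and psi defined) falling in favored regions, and flags models at or
#' above the threshold.
#'
#' @param ensemble A list of atom tibbles (all single-chain peptide
#'   models), e.g. from [sample_ensemble()].
#' @param threshold Passing fraction (default 0.90).
#' @param regions A region tibble.
#' @return A tibble with one row per model, in input order: `model_id`,
#'   `frac_favored`, `n_classified`, `passed_filter`.
#' @export
rama_filter <- function(ensemble, threshold = 0.90,
                        regions = default_rama_regions()) {
  if (length(ensemble) == 0) stop_validation("ensemble is empty")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop_usage("threshold must be a fraction in [0, 1]")
  }
  ids <- names(ensemble) %||% as.character(seq_along(ensemble))
  scores <- purrr::imap_dfr(ensemble, function(model, id) {
    chain <- model$chain[1]
    dih <- backbone_dihedrals(model, chain)
    cls <- rama_classify(dih$phi, dih$psi, regions)
    cls <- cls[!is.na(cls)]
    if (length(cls) < 3) {
      stop_validation(sprintf("model '%s' has fewer than 3 classifiable residues", id))
    }
    tibble::tibble(
      model_id = id,
      frac_favored = mean(cls == "favored"),
      n_classified = length(cls)
    )
  })
  scores$passed_filter <- scores$frac_favored >= threshold
  scores
}

#' Select the model with the lowest backbone RMSD to a reference
#'
#' @param models A (non-empty) named list of atom tibbles, typically the
#'   filter-passing subset of an ensemble.
#' @param reference An atom tibble.
#' @param mapping Optional residue mapping (see [backbone_rmsd()]).
#' @return A one-row tibble `model_id`, `rmsd`, with the full per-model
#'   RMSD table in attribute `"rmsds"`. Ties break to the earliest model.
#' @export
select_model <- function(models, reference, mapping = NULL) {
  if (length(models) == 0) stop_validation("no models to select from")
  ids <- names(models) %||% as.character(seq_along(models))
  rmsds <- purrr::map_dbl(models, backbone_rmsd, reference = reference,
                          mapping = mapping)
  best <- which.min(rmsds)
  out <- tibble::tibble(model_id = ids[best], rmsd = unname(rmsds[best]))
  attr(out, "rmsds") <- tibble::tibble(model_id = ids, rmsd = unname(rmsds))
  out
}

#' Plot dihedrals on the Ramachandran plane
#'
#' @param dihedrals A tibble from [backbone_dihedrals()].
#' @param regions A region tibble.
#' @return A ggplot object with region rectangles and phi/psi points.
#' @export
plot_ramachandran <- function(dihedrals, regions = default_rama_regions()) {
  pts <- dplyr::filter(dihedrals, !is.na(.data$phi), !is.na(.data$psi))
  pts$class <- rama_classify(pts$phi, pts$psi, regions)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$phi_min, xmax = .data$phi_max,
                   ymin = .data$psi_min, ymax = .data$psi_max,
                   alpha = .data$class),
      fill = "steelblue"
    ) +
    ggplot2::scale_alpha_manual(values = c(favored = 0.45, allowed = 0.2)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$phi, y = .data$psi,
                                     colour = .data$class)) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = "phi (degrees)", y = "psi (degrees)") +
    ggplot2::theme_minimal()
}
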