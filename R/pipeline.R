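# End-to-end orchestration: consensus statistics -> conformer model
# selection -> interface analysis -> kinetics, with a flat key=value
# configuration and a machine-readable summary.

pipeline_defaults <- function() {
  list(
    stages = "consensus,ensemble,interface,kinetics",
    table = system.file("extdata", "cdk2_sites.tsv", package = "cdk2substrate"),
    flank = 7,
    n_models = 50,
    jitter_sd = 15,
    rama_threshold = 0.90,
    hbond_dist = 3.5,
    hbond_angle = 30,
    salt_bridge_dist = 4.0,
    restraints = "",
    kinetics_data = "",
    km_wt = 93.6, vmax_wt = 2.21,
    km_mut = 81.4, vmax_mut = 1.11,
    cv = 0.05,
    seed = 1,
    out_dir = "",
    quiet = FALSE
  )
}

#' Read a flat key=value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' rejected. Values are coerced to the type of the documented default.
#'
#' @param path Path to the config file.
#' @return A validated config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  defaults <- pipeline_defaults()
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  lines <- lines[lines != ""]
  overrides <- list()
  for (ln in lines) {
    if (!stringr::str_detect(ln, "=")) {
      stop_usage(sprintf("malformed config line (expected key = value): '%s'", ln))
    }
    key <- stringr::str_trim(stringr::str_split_1(ln, "=")[1])
    value <- stringr::str_trim(stringr::str_remove(ln, "^[^=]*="))
    if (!key %in% names(defaults)) {
      stop_usage(sprintf("unknown config key '%s'", key))
    }
    proto <- defaults[[key]]
    overrides[[key]] <- if (is.numeric(proto)) as.numeric(value)
      else if (is.logical(proto)) as.logical(value) else value
  }
  utils::modifyList(defaults, overrides)
}

validate_config <- function(config) {
  config <- utils::modifyList(pipeline_defaults(), config)
  for (key in c("flank", "n_models", "rama_threshold", "hbond_dist",
                "hbond_angle", "salt_bridge_dist", "cv", "jitter_sd")) {
    if (!is.numeric(config[[key]]) || is.na(config[[key]]) || config[[key]] < 0) {
      stop_usage(sprintf("config parameter '%s' must be a non-negative number", key))
    }
  }
  if (config$rama_threshold > 1) stop_usage("rama_threshold must be in [0, 1]")
  if (config$hbond_dist == 0 || config$salt_bridge_dist == 0) {
    stop_usage("distance cutoffs must be positive")
  }
  config
}

#' Run the analysis pipeline
#'
#' Executes the requested stages on package-generated or user-supplied
#' inputs and writes per-stage outputs plus a `summary.json` into
#' `out_dir`:
#' \describe{
#'   \item{consensus}{parse + anchor the site table, write the frequency
#'     matrix TSV and motif statistics.}
#'   \item{ensemble}{sample a seeded conformer ensemble of the p27
#'     C-terminal peptide, Ramachandran-filter it and select the
#'     lowest-RMSD model against the extended reference.}
#'   \item{interface}{build the seeded complex fixture, report interface
#'     contacts and verify the docking restraints.}
#'   \item{kinetics}{fit wild-type and R194A velocity data (simulated at
#'     the packaged kinetic constants unless `kinetics_data` points to a
#'     CSV with a `peptide` column) and compare the fits.}
#' }
#'
#' @param config A config list (see [read_run_config()] for keys and
#'   defaults) or a path to a key=value config file.
#' @return The summary list, invisibly. Also written as JSON when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  stages <- stringr::str_split_1(config$stages, ",") |> stringr::str_trim()
  unknown <- setdiff(stages, c("consensus", "ensemble", "interface", "kinetics"))
  if (length(unknown) > 0) {
    stop_usage(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")))
  }
  say <- function(...) if (!isTRUE(config$quiet)) message(sprintf(...))
  out_dir <- config$out_dir
  save_file <- function(write_fn, name) {
    if (nzchar(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fn(file.path(out_dir, name))
    }
  }
  summary <- list(parameters = config[c("flank", "n_models", "jitter_sd",
                                        "rama_threshold", "hbond_dist",
                                        "hbond_angle", "salt_bridge_dist",
                                        "cv", "seed")])

  if ("consensus" %in% stages) {
    say("consensus: parsing %s", config$table)
    sites <- parse_site_table(config$table) |> anchor_sites()
    fm <- position_frequencies(sites, flank = as.integer(config$flank))
    stats_tbl <- motif_statistics(sites)
    save_file(function(p) write_frequency_matrix(fm, p), "frequency_matrix.tsv")
    save_file(function(p) jsonlite::write_json(as.list(stats_tbl), p,
                                               auto_unbox = TRUE, digits = NA),
              "motif_stats.json")
    summary$consensus <- as.list(stats_tbl)
    say("consensus: %d sites / %d proteins; basic P+3 fraction %.3f",
        stats_tbl$n_sites, stats_tbl$n_proteins, stats_tbl$frac_basic_p3_sites)
  }

  if ("ensemble" %in% stages) {
    say("ensemble: sampling %d models (jitter %.1f deg, seed %d)",
        config$n_models, config$jitter_sd, config$seed)
    reference <- build_peptide("NAGSVEQTPKKPGLR", c(-120, 120),
                               chain = "A", resno_start = 180L)
    ensemble <- sample_ensemble(n_models = as.integer(config$n_models),
                                jitter_sd = config$jitter_sd,
                                seed = as.integer(config$seed))
    scores <- rama_filter(ensemble, threshold = config$rama_threshold)
    passing <- ensemble[scores$passed_filter]
    selected <- if (length(passing) > 0) {
      select_model(passing, reference)
    } else {
      tibble::tibble(model_id = NA_character_, rmsd = NA_real_)
    }
    save_file(function(p) readr::write_tsv(scores, p), "model_scores.tsv")
    summary$ensemble <- list(
      n_models = length(ensemble),
      n_passing = sum(scores$passed_filter),
      selected_model = selected$model_id,
      selected_rmsd = selected$rmsd
    )
    say("ensemble: %d/%d models pass; selected %s (%.3f A)",
        sum(scores$passed_filter), length(ensemble),
        selected$model_id, selected$rmsd)
  }

  if ("interface" %in% stages) {
    say("interface: building seeded complex fixture")
    cplx <- make_complex_fixture(seed = as.integer(config$seed))
    spec <- if (nzchar(config$restraints)) read_restraints(config$restraints)
      else attr(cplx, "manifest")$spec
    report <- interface_report(cplx, list(c("P", "A"), c("P", "B")),
                               d_max = config$hbond_dist,
                               angle_max = config$hbond_angle,
                               salt_d_max = config$salt_bridge_dist)
    restr <- check_restraints(cplx, spec)
    save_file(function(p) readr::write_tsv(report, p), "interface_contacts.tsv")
    save_file(function(p) readr::write_tsv(restr, p), "restraint_report.tsv")
    summary$interface <- list(
      n_hbonds = sum(report$type == "hbond"),
      n_salt_bridges = sum(report$type == "salt_bridge"),
      n_restraints = nrow(restr),
      n_restraints_satisfied = sum(restr$satisfied)
    )
    say("interface: %d H-bonds, %d salt bridges, %d/%d restraints satisfied",
        summary$interface$n_hbonds, summary$interface$n_salt_bridges,
        summary$interface$n_restraints_satisfied, summary$interface$n_restraints)
  }

  if ("kinetics" %in% stages) {
    if (nzchar(config$kinetics_data)) {
      say("kinetics: reading %s", config$kinetics_data)
      data <- readr::read_csv(config$kinetics_data, show_col_types = FALSE)
      datasets <- split(data, data$peptide)
    } else {
      say("kinetics: simulating wt and R194A datasets (cv %.2f, seed %d)",
          config$cv, config$seed)
      datasets <- list(
        wt = simulate_velocities(config$km_wt, config$vmax_wt,
                                 cv = config$cv,
                                 seed = as.integer(config$seed),
                                 peptide = "wt"),
        R194A = simulate_velocities(config$km_mut, config$vmax_mut,
                                    cv = config$cv,
                                    seed = as.integer(config$seed) + 1L,
                                    peptide = "R194A")
      )
    }
    fits <- purrr::map(datasets, fit_michaelis_menten)
    fit_tbl <- purrr::map_dfr(fits, glance)
    save_file(function(p) readr::write_tsv(fit_tbl, p), "kinetic_fits.tsv")
    summary$kinetics <- purrr::map(fits, function(f) {
      list(Km = f$Km, Vmax = f$Vmax, efficiency = f$efficiency,
           converged = f$converged)
    })
    if (length(fits) == 2 && all(purrr::map_lgl(fits, "converged"))) {
      comp <- compare_kinetics(fits[[1]], fits[[2]])
      summary$kinetics$comparison <- as.list(comp)
      say("kinetics: Vmax ratio %.3f, Km ratio %.3f",
          comp$vmax_ratio, comp$km_ratio)
    }
  }

  if (nzchar(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
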