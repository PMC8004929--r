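#' Write a study dataset to CSV
#'
#' Columns: `matrix, time_h, replicate, conc_nM, conc_ng_mL, blq`.
#'
#' @param dataset a `study_dataset`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  cols <- c("matrix", "time_h", "replicate", "conc_nM", "conc_ng_mL", "blq")
  utils::write.csv(as.data.frame(dataset)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a study dataset from CSV
#'
#' Expects the columns written by [write_dataset()]; a dataset carrying only
#' one of the concentration columns (`conc_nM` or `conc_ng_mL`) is completed
#' using the molecular weight. Concentrations are normalized to nM
#' internally. Matrix names are validated (`"fat"` is accepted for adipose).
#'
#' @param path CSV file path.
#' @param MW molecular weight for unit completion, g/mol.
#' @return a `study_dataset` data frame.
#' @export
read_dataset <- function(path, MW = MMAE_MW) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("cannot parse ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  if (!nrow(tab)) stop("empty dataset: ", path, call. = FALSE)
  base <- c("matrix", "time_h", "replicate")
  if (!all(base %in% names(tab)))
    stop("dataset must have columns ", paste(base, collapse = ", "),
         " and a concentration column (conc_nM and/or conc_ng_mL)",
         call. = FALSE)
  has_nm <- "conc_nM" %in% names(tab)
  has_ng <- "conc_ng_mL" %in% names(tab)
  if (!has_nm && !has_ng)
    stop("no concentration column (conc_nM or conc_ng_mL) in ", path,
         call. = FALSE)
  bad_units <- grep("^conc_", names(tab), value = TRUE)
  bad_units <- setdiff(bad_units, c("conc_nM", "conc_ng_mL"))
  if (length(bad_units))
    stop("unknown concentration unit column(s): ",
         paste(bad_units, collapse = ", "), call. = FALSE)
  tab$matrix <- .canon_matrix(tab$matrix)
  num_cols <- intersect(c("time_h", "conc_nM", "conc_ng_mL"), names(tab))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (anyNA(v) && !anyNA(tab[[cc]]))
      stop("malformed value in column ", cc, " at data row ",
           which(is.na(v))[1], call. = FALSE)
    tab[[cc]] <- v
  }
  if (!has_nm) tab$conc_nM <- convert_units(tab$conc_ng_mL,
                                            "ng_per_mL_to_nM", MW)
  if (!has_ng) tab$conc_ng_mL <- convert_units(tab$conc_nM,
                                               "nM_to_ng_per_mL", MW)
  if (!"blq" %in% names(tab)) tab$blq <- FALSE
  tab$blq <- as.logical(tab$blq)
  out <- tab[, c("matrix", "time_h", "replicate", "conc_nM", "conc_ng_mL",
                 "blq")]
  class(out) <- c("study_dataset", "data.frame")
  out
}

#' Read a pipeline run configuration
#'
#' YAML file with any of: `physiology` (fixture name or path),
#' `drug_params`, `tumor_params` (key-value CSV paths), `dataset` (CSV path;
#' if absent, a synthetic study is generated), `design` (named list of
#' [study_design()] arguments), `estimate` (parameter names for the fit),
#' `seed`, `out_dir`, `solver` (`rtol`, `atol`), `fit_control` (`maxit`),
#' `hessian`.
#'
#' @param path YAML file path.
#' @return a `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(physiology = "mouse_28g", drug_params = NULL,
                   tumor_params = NULL, dataset = NULL, design = list(),
                   estimate = NULL, seed = 1, out_dir = "pipeline_out",
                   solver = list(rtol = 1e-6, atol = 1e-8),
                   fit_control = list(maxit = 300), hessian = TRUE)
  cfg <- utils::modifyList(defaults, cfg)
  for (f in c("drug_params", "tumor_params", "dataset")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config path for '", f, "' does not exist: ", cfg[[f]],
           call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load physiology and parameters; (2) load or synthesize the
#' study dataset; (3) maximum-likelihood fit; (4) NCA partition-coefficient
#' table; (5) percent-predictive-error table of model-predicted vs observed
#' AUCs; (6) write all artifacts and a run log. A failure in any stage
#' aborts with the stage name.
#'
#' @param config a [read_run_config()] object, a path to a YAML config, or
#'   a bare list of config entries.
#' @return named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, tmp)
    config <- read_run_config(tmp)
    unlink(tmp)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$out_dir, f)

  phys <- stage("physiology", load_physiology(config$physiology))
  drug <- stage("parameters", if (is.null(config$drug_params))
    drug_params() else read_drug_params(config$drug_params))
  tum <- stage("parameters", if (is.null(config$tumor_params))
    tumor_params() else read_tumor_params(config$tumor_params))

  design <- stage("design", do.call(study_design, utils::modifyList(
    list(seed = config$seed), config$design)))
  dataset <- stage("dataset", if (is.null(config$dataset)) {
    generate_study(design, phys, drug, tum)
  } else read_dataset(config$dataset, drug$MW))
  write_dataset(dataset, pth("dataset.csv"))

  dose <- dose_event(design$dose_per_bw, design$body_weight)
  spec <- if (is.null(config$estimate)) fit_spec() else
    fit_spec(estimate = config$estimate)
  fit <- stage("fit", fit_pbpk(dataset, spec, phys, drug, tum, dose,
                               seed = config$seed,
                               hessian = isTRUE(config$hessian),
                               control = config$fit_control,
                               rtol = config$solver$rtol,
                               atol = config$solver$atol))
  yaml::write_yaml(list(estimates = as.list(fit$estimates),
                        cv_percent = as.list(fit$cv_percent),
                        neg2ll = fit$neg2ll, AIC = fit$AIC,
                        converged = fit$converged, n_obs = fit$n_obs,
                        n_blq_excluded = fit$n_blq_excluded),
                   pth("fit.yaml"))
  utils::write.csv(fit$residuals, pth("residuals.csv"), row.names = FALSE)

  kptab <- stage("nca", kp_table(dataset, phys))
  utils::write.csv(kptab, pth("kp_table.csv"), row.names = FALSE)

  plasma <- .pooled_profile(dataset, "plasma")
  nca_sum <- stage("nca", moment_analysis(plasma$times, plasma$concs,
                                          dose_amount_pmol(dose, drug$MW)))
  utils::write.csv(data.frame(parameter = setdiff(names(nca_sum), "partial"),
                              value = unlist(nca_sum[setdiff(names(nca_sum),
                                                             "partial")])),
                   pth("nca_summary.csv"), row.names = FALSE)

  pe <- stage("predictive_error", {
    upd <- .apply_params(fit$estimates, drug, tum)
    mats <- intersect(.matrices, unique(dataset$matrix))
    rows <- lapply(mats, function(m) {
      p <- .pooled_profile(dataset, m)
      sim <- simulate_pbpk(dose, phys, upd$drug, upd$tum, times = p$times,
                           rtol = config$solver$rtol,
                           atol = config$solver$atol)
      pred <- sim$obs_nM[match(p$times, sim$times), m]
      data.frame(matrix = m,
                 AUC_obs = auc_linlog(p$times, p$concs),
                 AUC_pred = auc_linlog(p$times, pred))
    })
    pe <- do.call(rbind, rows)
    pe$percent_pe <- percent_pe(pe$AUC_pred, pe$AUC_obs)
    pe
  })
  utils::write.csv(pe, pth("pe_table.csv"), row.names = FALSE)

  log_lines <- c(
    paste("mmaepbpk", as.character(utils::packageVersion("mmaepbpk"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("seed", config$seed),
    paste("solver rtol", config$solver$rtol, "atol", config$solver$atol),
    paste("physiology", config$physiology),
    "krogh_geometry: R_cap/R_krogh in cm, defaults 8e-4/75e-4 (micron scale)",
    paste("records", nrow(dataset), "blq", sum(dataset$blq)),
    paste("fit converged", fit$converged))
  writeLines(log_lines, pth("run.log"))

  invisible(list(dataset = pth("dataset.csv"), fit = pth("fit.yaml"),
                 residuals = pth("residuals.csv"),
                 kp_table = pth("kp_table.csv"),
                 nca_summary = pth("nca_summary.csv"),
                 pe_table = pth("pe_table.csv"), log = pth("run.log")))
}
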