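# End-to-end pipeline: simulate -> assay -> annotate -> train -> sensitivity
# -> stats, with CSV interchange, a JSON run report and full seeding.

#' Build a pipeline configuration
#'
#' All stochastic stages derive their seeds from the single `seed`, so a
#' fixed configuration reproduces byte-identical numeric outputs. The
#' configuration round-trips losslessly through YAML/JSON.
#'
#' @param seed Master integer seed (required; every stochastic stage uses a
#'   seed derived from it).
#' @param n_sites Number of simulated sites (>= 2), default 9.
#' @param out_dir Output directory for CSV/JSON artifacts.
#' @param simulate Generate inputs with [simulate_study()] (`TRUE`, default)
#'   or read `climate.csv`, `od.csv`, `dose_response.csv`, `peaks.csv`,
#'   `responses.csv` from `out_dir`.
#' @param calibration List with `slope`, `intercept` (default the bundled
#'   rutin curve).
#' @param extraction Arguments for [extraction_spec()]; default dilution 10
#'   to match the generator.
#' @param annotation List with `tol_ppm` (default 5).
#' @param network Arguments for [network_config()] (topology, GA and BP
#'   budgets).
#' @param responses Character vector of response columns to model; default
#'   `"all"` = every compound plus TFC.
#' @param stats List with `thresholds` for correlation banding.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, n_sites = 9, out_dir = tempfile("run"),
                            simulate = TRUE,
                            calibration = list(slope = 10.655,
                                               intercept = -0.0076),
                            extraction = list(dilution_factor = 10),
                            annotation = list(tol_ppm = 5),
                            network = list(), responses = "all",
                            stats = list(thresholds = c(0.1, 0.4, 0.7))) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop("config error: an explicit integer `seed` is required",
         call. = FALSE)
  }
  if (!is.numeric(n_sites) || n_sites < 2) {
    stop("config error: n_sites must be >= 2", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 out_dir = out_dir, simulate = isTRUE(simulate),
                 calibration = calibration, extraction = extraction,
                 annotation = annotation, network = network,
                 responses = responses, stats = stats),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_config()].
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.write_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the six stages in order — simulate, assay, annotate, train,
#' sensitivity, stats — writing CSV artifacts and a JSON run report to
#' `config$out_dir`. A stage failure halts the run with a stage-named
#' error. Idempotent for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report` (also written as `report.json`):
#'   per-stage status, key output tables, config hash and package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  files <- character()
  status <- character()

  # --- simulate ----------------------------------------------------------
  study <- stage("simulate", {
    if (config$simulate) {
      s <- simulate_study(n_sites = config$n_sites, seed = config$seed)
      files <- c(files,
                 .write_csv(s$climate, config$out_dir, "climate.csv"),
                 .write_csv(data.frame(site_id = rownames(s$responses),
                                       s$responses), config$out_dir,
                            "responses.csv"),
                 .write_csv(data.frame(site_id = s$climate$site_id,
                                       od1 = s$od[, 1], od2 = s$od[, 2],
                                       od3 = s$od[, 3]),
                            config$out_dir, "od.csv"),
                 .write_csv(s$dose_response, config$out_dir,
                            "dose_response.csv"),
                 .write_csv(s$peaks, config$out_dir, "peaks.csv"))
      truth_path <- file.path(config$out_dir, "truth.json")
      jsonlite::write_json(
        list(seed = s$seed, tfc = as.list(s$truth$tfc),
             ic50 = as.data.frame(s$truth$ic50),
             sensitivities = as.data.frame(s$truth$sensitivities)),
        truth_path, auto_unbox = TRUE, digits = NA)
      files <- c(files, truth_path)
      s
    } else {
      need <- c("climate.csv", "od.csv", "dose_response.csv", "peaks.csv",
                "responses.csv")
      paths <- file.path(config$out_dir, need)
      missing <- need[!file.exists(paths)]
      if (length(missing) > 0L) {
        stop("missing input file(s): ", paste(missing, collapse = ", "))
      }
      cl <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
      odt <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
      rs <- utils::read.csv(paths[5], stringsAsFactors = FALSE)
      list(climate = cl, od = as.matrix(odt[, c("od1", "od2", "od3")]),
           dose_response = utils::read.csv(paths[3],
                                           stringsAsFactors = FALSE),
           peaks = utils::read.csv(paths[4], stringsAsFactors = FALSE),
           responses = as.matrix(rs[, -1, drop = FALSE]))
    }
  })
  status <- c(status, simulate = "ok")

  # --- assay -------------------------------------------------------------
  assay_tab <- stage("assay", {
    curve <- calibration_curve(config$calibration$slope,
                               config$calibration$intercept)
    spec <- do.call(extraction_spec, config$extraction)
    n <- nrow(study$climate)
    tfc <- vapply(seq_len(n), function(i) {
      compute_tfc(study$od[i, ], curve, spec)$tfc_mg_g
    }, numeric(1))
    dr <- study$dose_response
    assays <- unique(dr$assay)
    ic50 <- sapply(assays, function(a) {
      vapply(study$climate$site_id, function(sid) {
        sub <- dr[dr$assay == a & dr$site_id == sid, , drop = FALSE]
        tryCatch(estimate_ic50(list(
          concentrations = sub$concentration,
          sample_absorbances = sub$absorbance,
          control_absorbance = sub$control[1])),
          error = function(e) NA_real_)
      }, numeric(1))
    })
    tab <- data.frame(site_id = study$climate$site_id, tfc_mg_g = tfc,
                      ic50, stringsAsFactors = FALSE)
    names(tab)[-(1:2)] <- paste0("ic50_", assays)
    files <- c(files, .write_csv(tab, config$out_dir, "assay_results.csv"))
    tab
  })
  status <- c(status, assay = "ok")

  # --- annotate ----------------------------------------------------------
  annot <- stage("annotate", {
    pk <- study$peaks
    cand <- lapply(seq_len(nrow(pk)), function(i) {
      match_formula(pk$mz[i], pk$adduct[i],
                    tol_ppm = config$annotation$tol_ppm)
    })
    top <- vapply(cand, function(m) {
      if (nrow(m) == 0L) NA_character_ else m$formula[1]
    }, character(1))
    # recovery = the generating composition survives the ppm/RDBE filter
    # (rank-1 among all CHNOS isobars is not required at 5 ppm)
    hit <- vapply(seq_len(nrow(pk)), function(i) {
      pk$formula[i] %in% cand[[i]]$formula
    }, logical(1))
    out <- data.frame(pk, matched_formula = top, recovered = hit,
                      stringsAsFactors = FALSE)
    files <- c(files, .write_csv(out, config$out_dir, "annotations.csv"))
    out
  })
  status <- c(status, annotate = "ok")

  # --- train + sensitivity ----------------------------------------------
  resp_names <- if (identical(config$responses, "all")) {
    c(colnames(study$responses), "tfc_mg_g")
  } else config$responses
  Xc <- study$climate[, climate_factors(), drop = FALSE]
  nets <- list()
  sens_rows <- list()
  stage("train", {
    for (rn in resp_names) {
      y <- if (rn %in% colnames(study$responses)) {
        study$responses[, rn]
      } else if (rn %in% names(assay_tab)) {
        assay_tab[[rn]]
      } else stop("unknown response: ", rn)
      cfg <- do.call(network_config,
                     utils::modifyList(list(seed = config$seed +
                                              match(rn, resp_names)),
                                       config$network))
      nets[[rn]] <- suppressWarnings(train_gabp(as.matrix(Xc), y, cfg))
    }
    invisible(NULL)
  })
  status <- c(status, train = "ok")

  sens_tab <- stage("sensitivity", {
    rows <- lapply(resp_names, function(rn) {
      sx <- apply_scaling(as.matrix(Xc), nets[[rn]]$input_scaling)
      s <- sensitivity(nets[[rn]], sx, response = rn)
      data.frame(response = rn, t(as.numeric(s)),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    names(tab)[-1] <- climate_factors()
    files <- c(files, .write_csv(tab, config$out_dir, "sensitivity.csv"))
    model_path <- file.path(config$out_dir, "model.json")
    jsonlite::write_json(
      lapply(nets, function(nn) list(
        layer_sizes = nn$layer_sizes, sse = nn$sse, mae = nn$mae,
        converged = nn$converged, epochs = length(nn$error_trace) - 1L,
        seed = nn$config$seed)),
      model_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, model_path)
    tab
  })
  status <- c(status, sensitivity = "ok")

  # --- stats -------------------------------------------------------------
  stats_out <- stage("stats", {
    Ymat <- cbind(study$responses,
                  tfc_mg_g = assay_tab$tfc_mg_g,
                  as.matrix(assay_tab[, grep("^ic50_", names(assay_tab)),
                                      drop = FALSE]))
    rep <- pearson_matrix(Ymat, as.matrix(Xc),
                          thresholds = config$stats$thresholds)
    files <- c(files, .write_csv(correlation_table(rep), config$out_dir,
                                 "correlations.csv"))
    pca <- pca_scores(as.matrix(Xc))
    files <- c(files,
               .write_csv(data.frame(site_id = study$climate$site_id,
                                     pca$scores), config$out_dir,
                          "pca_scores.csv"),
               .write_csv(data.frame(factor = rownames(pca$loadings),
                                     pca$loadings, explained = pca$explained),
                          config$out_dir, "pca_loadings.csv"))
    hmat <- cbind(as.matrix(Xc), Ymat)
    rownames(hmat) <- study$climate$site_id
    hc <- hca(hmat)
    files <- c(files,
               .write_csv(data.frame(merge1 = hc$merge[, 1],
                                     merge2 = hc$merge[, 2],
                                     height = hc$height),
                          config$out_dir, "hca_merges.csv"),
               .write_csv(data.frame(site_id = rownames(hmat),
                                     hc$heatmap$matrix),
                          config$out_dir, "heatmap_matrix.csv"))
    list(correlations = rep, pca = pca, hca = hc)
  })
  status <- c(status, stats = "ok")

  report <- structure(list(
    status = status,
    files = basename(files),
    out_dir = config$out_dir,
    tfc = assay_tab$tfc_mg_g,
    ic50 = assay_tab[, grep("^ic50_", names(assay_tab)), drop = FALSE],
    annotation_recovery = mean(annot$recovered),
    sensitivity = sens_tab,
    config_hash = .config_hash(config),
    version = as.character(utils::packageVersion("flaviclim"))
  ), class = "run_report")
  jsonlite::write_json(
    unclass(report)[c("status", "files", "config_hash", "version",
                      "annotation_recovery")],
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE,
    digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run (", x$version, "), config ", x$config_hash, "\n",
      sep = "")
  for (s in names(x$status)) cat(sprintf("  %-12s %s\n", s, x$status[[s]]))
  cat("outputs in ", x$out_dir, ": ", paste(x$files, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
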