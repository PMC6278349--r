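# End-to-end analysis run: load a component table, check its internal
# arithmetic, attach surface areas, choose a non-electrostatic model, fit
# linear-response and ASA regressions, predict totals, and score.

#' Configuration for a full analysis run
#'
#' @param table_path component-table CSV (see [load_component_table()]);
#'   defaults to the packaged aromatic-hydrocarbon table.
#' @param geometry_dir optional directory of `<name>.xyz` / `<name>.pdb`
#'   files used to compute surface areas for records whose `asa` is missing
#'   (names matched case-insensitively to solute names).
#' @param model `"modified"` (frozen refit constants with offset-corrected
#'   intercept), `"original"` (stock continuum constants), or `"refit"`
#'   (coefficients re-estimated from the table itself).
#' @param es_mode,alpha_from,alpha_to electrostatic handling, see
#'   [predict_hydration()].
#' @param tol consistency tolerance, kcal/mol.
#' @param probe_radius,n_sphere_points surface-engine settings, see
#'   [shrake_rupley_asa()].
#' @param reference_path optional CSV with columns `name,exp_dA_hyd`
#'   supplying reference values when the table itself has none.
#' @param out_dir optional directory for artifacts (`consistency.csv`,
#'   `predictions.csv`, `report.json`); created if missing. `NULL` writes
#'   nothing.
#' @param seed integer recorded in the report (the run itself is
#'   deterministic; the seed matters only for `model = "refit"` on
#'   generated inputs upstream).
#' @return List of class `run_config`.
#' @export
run_config <- function(table_path = system.file("extdata",
                                                "aromatic_components.csv",
                                                package = "hydrodecomp"),
                       geometry_dir = NULL,
                       model = c("modified", "original", "refit"),
                       es_mode = c("as_given", "rescaled"),
                       alpha_from = 0.5, alpha_to = 0.41,
                       tol = 0.015, probe_radius = 1.4,
                       n_sphere_points = 960,
                       reference_path = NULL, out_dir = NULL, seed = 1L) {
  model <- match.arg(model)
  es_mode <- match.arg(es_mode)
  if (!file.exists(table_path)) {
    stop("table_path does not exist: ", table_path, call. = FALSE)
  }
  if (!is.null(geometry_dir) && !dir.exists(geometry_dir)) {
    stop("geometry_dir does not exist: ", geometry_dir, call. = FALSE)
  }
  if (!is.null(reference_path) && !file.exists(reference_path)) {
    stop("reference_path does not exist: ", reference_path, call. = FALSE)
  }
  structure(list(table_path = table_path, geometry_dir = geometry_dir,
                 model = model, es_mode = es_mode,
                 alpha_from = alpha_from, alpha_to = alpha_to, tol = tol,
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 reference_path = reference_path, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.log_stage <- function(name, ...) {
  message(sprintf("[%s] %s", name, sprintf(...)))
}

#' Run the full decomposition analysis pipeline
#'
#' Stages, each logged to stderr with row counts and aborting with a
#' stage-named error on failure: load the component table; consistency-check
#' printed totals; attach surface areas (from the table's `asa` column or by
#' running the Shrake-Rupley engine on `geometry_dir`); select or refit the
#' non-electrostatic model; fit the electrostatic linear response when the
#' table carries a `u_es` column; predict per-solute totals; score against
#' experimental references when available. Input files are never modified;
#' artifacts go to `out_dir`.
#'
#' @param config a [run_config()].
#' @return List of class `run_report`: `config`, `consistency`,
#'   `non_es_model`, `lrt_fit` (or `NULL`), `predictions`, `score` (or
#'   `NULL`), `asa_source`.
#' @examples
#' \donttest{
#' geom <- system.file("extdata", "geometries", package = "hydrodecomp")
#' rep <- run_pipeline(run_config(geometry_dir = geom))
#' rep$predictions
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  tab <- .stage("load", load_component_table(config$table_path))
  .log_stage("load", "%d record(s) from %s", nrow(tab), config$table_path)
  if (nrow(tab) == 0L) stop("[stage:load] empty component table",
                            call. = FALSE)

  cons <- NULL
  if (any(is.finite(tab$dA_hyd))) {
    cons <- .stage("consistency", check_consistency(tab, config$tol))
    .log_stage("consistency", "%d record(s), %d flagged (tol %.3g)",
               nrow(cons), sum(cons$flagged), config$tol)
  } else {
    .log_stage("consistency", "skipped: no printed totals")
  }

  asa_source <- "table"
  need_asa <- !is.finite(tab$asa)
  if (any(need_asa)) {
    if (is.null(config$geometry_dir)) {
      stop("[stage:asa] ", sum(need_asa), " record(s) lack asa and no ",
           "geometry_dir was given", call. = FALSE)
    }
    files <- list.files(config$geometry_dir, pattern = "\\.(xyz|pdb)$",
                        full.names = TRUE, ignore.case = TRUE)
    key <- tolower(tools::file_path_sans_ext(basename(files)))
    for (i in which(need_asa)) {
      hit <- which(key == tolower(tab$name[i]))
      if (length(hit) == 0L) {
        stop("[stage:asa] no geometry file for solute '", tab$name[i], "'",
             call. = FALSE)
      }
      mol <- .stage("asa", assign_radii(read_coordinates(files[hit[1L]])))
      res <- .stage("asa", shrake_rupley_asa(mol, config$probe_radius,
                                             config$n_sphere_points))
      tab$asa[i] <- res$total_asa
    }
    asa_source <- if (all(need_asa)) "geometry" else "mixed"
    .log_stage("asa", "computed %d surface area(s) from %s", sum(need_asa),
               config$geometry_dir)
  } else {
    .log_stage("asa", "all %d record(s) carry asa", nrow(tab))
  }

  model <- .stage("model", switch(config$model,
                                  original = pb_original_model(),
                                  modified = pb_modified_model(),
                                  refit = refit_non_es(tab)))
  .log_stage("model", "%s: slope %.5g, intercept %.4g", model$label,
             model$slope, model$intercept)

  lrt_fit <- NULL
  if ("u_es" %in% names(tab) && any(is.finite(tab$u_es))) {
    ok <- is.finite(tab$u_es) & is.finite(tab$dA_es)
    lrt_fit <- .stage("lrt",
                      fit_through_origin(energy_pairs(tab$dA_es[ok],
                                                      tab$u_es[ok],
                                                      tab$name[ok])))
    .log_stage("lrt", "origin-constrained slope %.4f (R^2 %.3f, n %d)",
               lrt_fit$slope, lrt_fit$r2, lrt_fit$n)
  } else {
    .log_stage("lrt", "skipped: no u_es column")
  }

  preds <- .stage("predict",
                  predict_hydration(tab, model, config$es_mode,
                                    config$alpha_from, config$alpha_to))
  .log_stage("predict", "%d prediction(s)", nrow(preds))

  refs <- tab$exp_dA_hyd
  if (!is.null(config$reference_path)) {
    ref_tab <- .stage("score", read.csv(config$reference_path,
                                        stringsAsFactors = FALSE))
    if (!all(c("name", "exp_dA_hyd") %in% names(ref_tab))) {
      stop("[stage:score] reference CSV needs columns name, exp_dA_hyd",
           call. = FALSE)
    }
    refs <- ref_tab$exp_dA_hyd[match(tab$name, ref_tab$name)]
  }
  score <- NULL
  if (any(is.finite(refs))) {
    ok <- is.finite(refs)
    score <- .stage("score", score_predictions(preds$dA_hyd_pred[ok],
                                               refs[ok]))
    .log_stage("score", "MAE %.4f, RMSE %.4f over %d record(s)", score$mae,
               score$rmse, score$n)
  } else {
    .log_stage("score", "skipped: no reference values")
  }

  report <- structure(list(config = config, consistency = cons,
                           non_es_model = model, lrt_fit = lrt_fit,
                           predictions = preds, score = score,
                           asa_source = asa_source),
                      class = "run_report")
  if (!is.null(config$out_dir)) .write_artifacts(report, config$out_dir)
  report
}

.write_artifacts <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- report$config
  if (!is.null(report$consistency)) {
    write.csv(as.data.frame(report$consistency),
              file.path(out_dir, "consistency.csv"), row.names = FALSE)
  }
  write.csv(as.data.frame(report$predictions),
            file.path(out_dir, "predictions.csv"), row.names = FALSE)
  json <- list(
    config = list(table_path = cfg$table_path, model = cfg$model,
                  es_mode = cfg$es_mode, alpha_from = cfg$alpha_from,
                  alpha_to = cfg$alpha_to, tol = cfg$tol,
                  probe_radius = cfg$probe_radius,
                  n_sphere_points = cfg$n_sphere_points, seed = cfg$seed),
    asa_source = report$asa_source,
    non_es_model = report$non_es_model[c("slope", "intercept", "label")],
    lrt_fit = if (!is.null(report$lrt_fit)) {
      report$lrt_fit[c("slope", "intercept", "r2", "n")]
    },
    n_flagged = if (!is.null(report$consistency)) {
      sum(report$consistency$flagged)
    },
    score = if (!is.null(report$score)) report$score[c("mae", "rmse", "n")])
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d prediction(s), model %s", nrow(x$predictions),
              x$non_es_model$label))
  if (!is.null(x$score)) {
    cat(sprintf("; MAE %.3f, RMSE %.3f kcal/mol", x$score$mae, x$score$rmse))
  }
  cat("\n")
  invisible(x)
}
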