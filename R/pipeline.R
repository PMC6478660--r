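#' Analyze one patient against a control cohort (in memory)
#'
#' The full parametric chain on already-loaded volumes.  Two modes:
#'
#' * `"petanalysis"` — the dedicated pipeline: gray-matter analysis mask from
#'   the atlas, quotient-parabola intensity normalization (controls against
#'   the template, patient against the cohort mean by default), Gaussian
#'   smoothing, hypometabolism t-map, multi-threshold sweep.
#' * `"spm-emulation"` — the generic pipeline: 0.3 background mask from the
#'   patient study, proportional-scaling normalization to a grand mean of 50,
#'   otherwise identical machinery (use `correction = "bonferroni"` for the
#'   family-wise-corrected regime).
#'
#' @param patient,template [volume()]s; `controls` a list of volumes.
#' @param atlas a [label_atlas()].
#' @param mode `"petanalysis"` or `"spm-emulation"`.
#' @param fwhm smoothing FWHM in mm (default 8).
#' @param p_grid,k_grid sweep grids (defaults as in [threshold_sweep()]).
#' @param correction threshold correction for the sweep and report call.
#' @param report_p,report_k the single (p, k) whose EZ call is reported as
#'   *the* call of the run (default p = 0.001, k = 100).
#' @param connectivity,midline_margin,mlt_share segmentation settings.
#' @param register if `TRUE`, affinely register the patient (and controls) to
#'   the template first; phantom data is generated aligned, so the default is
#'   `FALSE`.
#' @param deformation optional precomputed deformation field applied to the
#'   patient after affine alignment.
#' @param reference `"cohort-mean"` (default) or `"template"`: the image the
#'   patient's quotient distribution is taken against in parabola mode.
#' @return List of class `ez_analysis`: `tmap`, `sweep` (tibble), `ez`
#'   (call string at the report spec), `segmentation`, `mode`, `mask_size`,
#'   `normalization` (patient's factor diagnostics).
#' @export
analyze_patient <- function(patient, controls, template, atlas,
                            mode = c("petanalysis", "spm-emulation"),
                            fwhm = 8,
                            p_grid = c(0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4),
                            k_grid = c(50, 100, 150, 200),
                            correction = "none",
                            report_p = 0.001, report_k = 100,
                            connectivity = 26, midline_margin = 6,
                            mlt_share = 0.3,
                            register = FALSE, deformation = NULL,
                            reference = c("cohort-mean", "template")) {
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  if (register) {
    tr <- affine_register(patient, template)
    patient <- resample(patient, tr, template)
    controls <- lapply(controls, function(v)
      resample(v, affine_register(v, template), template))
  }
  if (!is.null(deformation)) patient <- apply_deformation(patient, deformation)

  if (mode == "petanalysis") {
    mask <- gray_matter_mask(atlas)
    norm_controls <- lapply(controls, function(v)
      apply_normalization(v, intensity_normalize_parabola(v, template, mask)))
    ref_img <- if (reference == "cohort-mean")
      with_data(template, Reduce(`+`, lapply(norm_controls, as.array)) /
                  length(norm_controls))
    else template
    pat_norm <- intensity_normalize_parabola(patient, ref_img, mask)
  } else {
    mask <- background_mask(patient, 0.3)
    norm_controls <- lapply(controls, function(v)
      apply_normalization(v, intensity_normalize_proportional(v, mask)))
    pat_norm <- intensity_normalize_proportional(patient, mask)
  }
  patient_n <- apply_normalization(patient, pat_norm)

  sm_controls <- lapply(norm_controls, smooth_gaussian, fwhm = fwhm)
  patient_s <- smooth_gaussian(patient_n, fwhm)
  cohort <- build_cohort(sm_controls)
  tm <- tmap(patient_s, cohort, mask)

  sweep <- threshold_sweep(tm, atlas, p_grid, k_grid, correction,
                           connectivity, midline_margin, mlt_share)
  seg <- segment_tmap(tm, threshold_spec(report_p, report_k, correction),
                      atlas, connectivity, midline_margin)
  structure(list(tmap = tm, sweep = sweep,
                 ez = ez_call(seg, atlas, mlt_share),
                 segmentation = seg, mode = mode,
                 mask_size = sum(mask$data != 0),
                 normalization = pat_norm),
            class = "ez_analysis")
}

#' @export
print.ez_analysis <- function(x, ...) {
  cat(sprintf("<ez_analysis> mode %s, %d in-mask voxels, EZ call: %s\n",
              x$mode, x$mask_size, x$ez))
  cat("Sweep:\n"); print(x$sweep, n = Inf)
  invisible(x)
}

default_run_config <- function() {
  list(mode = "petanalysis", fwhm = 8,
       p_grid = c(0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4),
       k_grid = c(50, 100, 150, 200),
       correction = "none", report_p = 0.001, report_k = 100,
       connectivity = 26, midline_margin = 6, mlt_share = 0.3,
       register = FALSE, reference = "cohort-mean", seed = 1)
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  if (cfg$mode == "petanalysis") {
    # dedicated mode pins its masks/normalization; emulation mode likewise
    cfg$normalization <- "parabola-quotient"
    cfg$mask <- "gray-matter"
  } else {
    cfg$normalization <- "proportional-scaling"
    cfg$mask <- "background-0.3"
  }
  cfg
}

log_jsonl <- function(path, record) {
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), con)
}

#' Run the analysis pipeline from a configuration
#'
#' Command-level entry point: loads the patient, control, template and atlas
#' files named in the configuration, runs [analyze_patient()], and writes a
#' JSON report, the sweep table (TSV), the t-map (NIfTI + JSON sidecar with
#' df and direction) and a JSON-lines run log into the output directory.
#'
#' @param config a list or path to a JSON file.  Required fields: `patient`,
#'   `controls` (vector of paths), `template`, `atlas_volume`, `atlas_table`,
#'   `out`.  Optional fields as in [analyze_patient()] plus `seed`.
#' @return The `ez_analysis`, invisibly; files under `config$out`.
#' @export
cmd_analyze <- function(config) {
  cfg <- read_run_config(config)
  for (f in c("patient", "template", "atlas_volume", "atlas_table", "out"))
    if (is.null(cfg[[f]])) stop("config field missing: ", f)
  if (is.null(cfg$controls) || length(cfg$controls) < 2)
    stop("config must name at least 2 control volumes")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  patient <- read_volume(cfg$patient)
  controls <- lapply(cfg$controls, read_volume)
  template <- read_volume(cfg$template)
  atlas <- load_atlas(cfg$atlas_volume, cfg$atlas_table)
  res <- analyze_patient(patient, controls, template, atlas,
                         mode = cfg$mode, fwhm = cfg$fwhm,
                         p_grid = cfg$p_grid, k_grid = cfg$k_grid,
                         correction = cfg$correction,
                         report_p = cfg$report_p, report_k = cfg$report_k,
                         connectivity = cfg$connectivity,
                         midline_margin = cfg$midline_margin,
                         mlt_share = cfg$mlt_share,
                         register = isTRUE(cfg$register),
                         reference = cfg$reference)
  utils::write.table(res$sweep, file.path(cfg$out, "sweep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_volume(res$tmap$t, file.path(cfg$out, "tmap.nii.gz"))
  jsonlite::write_json(list(df = res$tmap$df, direction = res$tmap$direction,
                            n_zero_variance = res$tmap$n_zero_variance,
                            mask_size = res$mask_size),
                       file.path(cfg$out, "tmap.json"), auto_unbox = TRUE)
  report <- list(mode = res$mode, ez = res$ez,
                 mask_size = res$mask_size,
                 normalization = list(method = res$normalization$method,
                                      factor = res$normalization$factor),
                 report_spec = list(p = cfg$report_p, k = cfg$report_k,
                                    correction = cfg$correction),
                 clusters = tidy_segmentation(res$segmentation),
                 n_excluded = length(res$segmentation$excluded),
                 sweep_rows = nrow(res$sweep))
  jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_jsonl(file.path(cfg$out, "run.log.jsonl"),
            list(command = "analyze",
                 package_version = as.character(utils::packageVersion("petez")),
                 config_hash = rlang::hash(cfg), seed = cfg$seed,
                 time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  invisible(res)
}

#' Evaluate a study-results table
#'
#' Command-level wrapper over [evaluate_study()]: parses the table, computes
#' the method summaries, kappas with verbal bands and pairwise exact McNemar
#' p values, and (optionally) writes a JSON report plus a summary TSV.
#'
#' @param table_path study TSV (defaults to the packaged fixture).
#' @param erratum use the corrected packaged fixture instead (single-cell
#'   variant; see [study_table_fixture()]).  Ignored when `table_path` is
#'   given explicitly.
#' @param out optional output directory.
#' @param rule a [match_rule()].
#' @param quiet suppress console output.
#' @return The `ez_evaluation`, invisibly.
#' @export
cmd_evaluate <- function(table_path = NULL, erratum = FALSE, out = NULL,
                         rule = match_rule(), quiet = FALSE) {
  if (is.null(table_path)) table_path <- study_table_fixture(erratum)
  tab <- load_study_table(table_path)
  ev <- evaluate_study(tab, rule)
  if (!quiet) print(ev)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(ev$summary, file.path(out, "method_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(summary = ev$summary, kappa = ev$kappa,
                              mcnemar = ev$mcnemar, n = ev$n),
                         file.path(out, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    log_jsonl(file.path(out, "run.log.jsonl"),
              list(command = "evaluate",
                   package_version = as.character(utils::packageVersion("petez")),
                   config_hash = rlang::hash(list(table_path, erratum)),
                   time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  }
  invisible(ev)
}

#' Simulate a phantom fixture directory
#'
#' Writes the template, label atlas (volume + TSV table), `n_controls`
#' control studies, one lesioned patient and a ground-truth JSON, all
#' deterministic per seed.  The directory is directly consumable by
#' [cmd_analyze()] (a ready-made `config.json` is also written).
#'
#' @param spec a [phantom_spec()].
#' @param out output directory.
#' @param seed base RNG seed; control i uses `seed + i`, the patient
#'   `seed`.
#' @return Paths list, invisibly.
#' @export
cmd_simulate <- function(spec = phantom_spec(), out, seed = 1) {
  if (missing(out)) stop("output directory required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ta <- make_template_and_atlas(spec)
  write_volume(ta$template, file.path(out, "template.nii.gz"))
  write_volume(ta$atlas$labels, file.path(out, "atlas.nii.gz"))
  write_atlas_table(ta$atlas, file.path(out, "atlas_table.tsv"))
  control_paths <- character(spec$n_controls)
  for (i in seq_len(spec$n_controls)) {
    v <- make_control(spec, seed + i, ta$template)
    control_paths[i] <- file.path(out, sprintf("control_%02d.nii.gz", i))
    write_volume(v, control_paths[i])
  }
  pat <- make_patient(spec, seed, ta$template, ta$atlas)
  write_volume(pat$volume, file.path(out, "patient.nii.gz"))
  jsonlite::write_json(list(truth = pat$truth, seed = seed,
                            lesion_region = spec$lesion_region,
                            lesion_contrast = spec$lesion_contrast,
                            lesion_radius = spec$lesion_radius,
                            clipped_fraction = pat$clipped_fraction),
                       file.path(out, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- list(patient = file.path(out, "patient.nii.gz"),
              controls = control_paths,
              template = file.path(out, "template.nii.gz"),
              atlas_volume = file.path(out, "atlas.nii.gz"),
              atlas_table = file.path(out, "atlas_table.tsv"),
              out = file.path(out, "analysis"), seed = seed)
  jsonlite::write_json(cfg, file.path(out, "config.json"), auto_unbox = TRUE)
  log_jsonl(file.path(out, "run.log.jsonl"),
            list(command = "simulate",
                 package_version = as.character(utils::packageVersion("petez")),
                 config_hash = rlang::hash(unclass(spec)), seed = seed,
                 time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  invisible(list(dir = out, config = file.path(out, "config.json"),
                 truth = pat$truth))
}
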