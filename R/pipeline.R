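# End-to-end orchestration: read -> harmonize -> lungs -> trachea ->
# airways -> vessels -> air reference -> parenchyma map -> classify ->
# score.  Every stage failure is re-raised with the stage name so QC can
# point at the module that broke.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the automated cyst-segmentation pipeline on a CT volume
#'
#' Pure in-memory version of [run_pipeline()]: takes a calibrated
#' [ct_volume] and returns every intermediate product.  The pipeline is
#' fully deterministic; no stage consumes random numbers.
#'
#' @param vol a [ct_volume].
#' @param config configuration list (see [default_config()]).
#' @return list with `volume` (harmonized), `lung`, `airway`, `vessel`,
#'   `cyst` masks, `ref` (air reference), `pmap` (parenchyma map),
#'   `result` (a `cyst_result`) and `qc` scalars.
#' @export
segment_volume <- function(vol, config = default_config()) {
  stopifnot(is_ct_volume(vol))
  hvol <- .stage("harmonize", harmonize_resolution(vol, config))
  lung <- .stage("lung segmentation", segment_lungs(hvol, config))
  seed <- .stage("trachea segmentation", segment_trachea(hvol, config))
  airway <- .stage("airway extension", extend_airways(hvol, seed, config))
  vessel <- .stage("vessel exclusion",
                   exclude_bright_structures(hvol, lung, config))
  bg <- .stage("air background", estimate_air_background(hvol, config))
  prof <- .stage("airway profile", airway_profile(hvol, airway, config))
  ref <- .stage("air reference", build_air_reference(bg, prof))
  pmap <- .stage("parenchyma map",
                 parenchyma_density_map(hvol, lung, airway, vessel, ref,
                                        config))
  cyst <- .stage("cyst classification",
                 classify_cysts(hvol, lung, airway, pmap, ref, config))
  result <- .stage("cyst score", cyst_score(cyst, lung, airway))
  lung_region <- lung$voxels & !airway$voxels
  qc <- list(I_background = ref$I_background,
             I_airway_superior = ref$I_airway[1],
             I_airway_inferior = ref$I_airway[length(ref$I_airway)],
             lung_volume_ml = result$lung_volume_ml,
             parenchyma_availability =
               sum(pmap$available) / max(sum(lung_region), 1))
  list(volume = hvol, lung = lung, airway = airway, vessel = vessel,
       cyst = cyst, ref = ref, pmap = pmap, result = result, qc = qc)
}

#' Run the pipeline on a DICOM series directory
#'
#' Reads the series, runs [segment_volume()], and (when `output` is given)
#' writes the cyst mask (NIfTI), a one-row report CSV and a JSON run
#' manifest recording the effective configuration and QC scalars.
#'
#' @param input DICOM series directory, or a [ct_volume].
#' @param config configuration list or YAML path (`NULL` = defaults).
#' @param output optional output directory.
#' @param save_intermediate also write lung/airway/vessel masks.
#' @param save_parenchyma_map also write the I_p map and availability mask.
#' @return invisibly, the [segment_volume()] result list plus `report`
#'   (one-row data frame) and `metadata`.
#' @export
run_pipeline <- function(input, config = NULL, output = NULL,
                         save_intermediate = FALSE,
                         save_parenchyma_map = FALSE) {
  cfg <- if (is.null(config)) default_config()
         else if (is.character(config)) load_config(config)
         else validate_config(utils::modifyList(default_config(), config))
  if (is_ct_volume(input)) {
    vol <- input
    meta <- list(patient_id = "UNKNOWN", exam_date = as.Date(NA),
                 kernel = input$kernel, contrast_flag = NA)
  } else {
    rd <- .stage("dicom ingestion",
                 read_dicom_series(input, sentinel_hu = cfg$sentinel_hu))
    vol <- rd$volume
    meta <- rd$metadata
  }
  res <- segment_volume(vol, cfg)
  report <- data.frame(
    patient_id = meta$patient_id,
    exam_date = as.character(meta$exam_date),
    kernel = meta$kernel,
    lung_volume_ml = res$result$lung_volume_ml,
    cyst_volume_ml = res$result$cyst_volume_ml,
    cyst_score = res$result$cyst_score,
    I_background = res$qc$I_background,
    I_airway_superior = res$qc$I_airway_superior,
    I_airway_inferior = res$qc$I_airway_inferior,
    stringsAsFactors = FALSE)
  if (!is.null(output)) {
    dir.create(output, recursive = TRUE, showWarnings = FALSE)
    write_mask(res$cyst, file.path(output, "cyst_mask.nii.gz"))
    if (save_intermediate) {
      write_mask(res$lung, file.path(output, "lung_mask.nii.gz"))
      write_mask(res$airway, file.path(output, "airway_mask.nii.gz"))
      write_mask(res$vessel, file.path(output, "vessel_mask.nii.gz"))
    }
    if (save_parenchyma_map) {
      pm <- res$pmap
      av <- mask_volume(pm$available, res$volume, "lung")
      write_mask(av, file.path(output, "parenchyma_available.nii.gz"))
      vals <- pm$values
      vals[!pm$available] <- -2048
      nii <- RNifti::asNifti(vals)
      RNifti::pixdim(nii) <- res$volume$spacing
      RNifti::writeNifti(nii, file.path(output, "parenchyma_map.nii.gz"))
    }
    utils::write.csv(report, file.path(output, "report.csv"),
                     row.names = FALSE)
    manifest <- list(tool = "lamcyst",
                     version = as.character(utils::packageVersion("lamcyst")),
                     generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     input = if (is.character(input)) input else "<in-memory>",
                     config = cfg, qc = res$qc)
    jsonlite::write_json(manifest, file.path(output, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(c(res, list(report = report, metadata = meta)))
}
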