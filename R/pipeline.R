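#' @title Pipeline configuration and orchestration
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Defaults equal the published protocol values (thresholds A = 3.8,
#' B = 12, C = 3, E = \[3, 4\]; voxel 0.00319 mm; subtraction order
#' 17.2 keV minus 16.5 keV; source-implied \eqn{\Delta(\mu/\rho)}).
#'
#' @param above_path,below_path input TIFF stacks (ignored in simulate
#'   mode).
#' @param output_dir directory for all intermediates and the report.
#' @param simulate generate a phantom instead of reading inputs.
#' @param phantom a [phantom_spec()] for simulate mode (`NULL` =
#'   default spec with `seed`).
#' @param truth_yttria_path optional ground-truth mask stack for Dice
#'   scoring when analysing files.
#' @param params a [segmentation_params()].
#' @param delta_mu_rho_source `"paper_implied"` or `"table"`.
#' @param registration align the below-edge volume before subtraction.
#' @param estimate_scale also search a global scale during
#'   registration.
#' @param bin_width,hist_range histogram binning (cm^-1).
#' @param voxel_size_mm voxel edge for physical volumes.
#' @param write_intermediates write all stage masks/volumes to
#'   `output_dir`.
#' @param seed master seed; all pipeline randomness flows from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(above_path = NULL, below_path = NULL,
                            output_dir = tempfile("kescan_run_"),
                            simulate = FALSE, phantom = NULL,
                            truth_yttria_path = NULL,
                            params = segmentation_params(),
                            delta_mu_rho_source = c("paper_implied", "table"),
                            registration = TRUE, estimate_scale = FALSE,
                            bin_width = 0.1, hist_range = c(-2, 20),
                            voxel_size_mm = 0.00319,
                            write_intermediates = TRUE, seed = 42) {
  delta_mu_rho_source <- match.arg(delta_mu_rho_source)
  if (!simulate) {
    for (p in c(above_path, below_path))
      if (is.null(p) || !file.exists(p))
        stop("input stack does not exist: ", p %||% "(missing)")
  }
  stopifnot(inherits(params, "segmentation_params"))
  structure(list(above_path = above_path, below_path = below_path,
                 output_dir = output_dir, simulate = simulate,
                 phantom = phantom, truth_yttria_path = truth_yttria_path,
                 params = params,
                 delta_mu_rho_source = delta_mu_rho_source,
                 registration = registration,
                 estimate_scale = estimate_scale,
                 bin_width = bin_width, hist_range = hist_range,
                 voxel_size_mm = voxel_size_mm,
                 write_intermediates = write_intermediates,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Threshold keys use the protocol's own letter names
#' (`threshold_A` ... `threshold_E`).
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pk <- intersect(names(y), c("threshold_A", "threshold_B", "threshold_C",
                              "threshold_D_cutoff", "threshold_E",
                              "dilation_iterations", "h_rule",
                              "use_threshold_E"))
  params <- do.call(segmentation_params, y[pk])
  y <- y[setdiff(names(y), pk)]
  y$params <- params
  if (!is.null(y$phantom)) {
    ph <- y$phantom
    if (!is.null(ph$shrinkage))
      ph$shrinkage <- rigid_scale_transform(ph$shrinkage$translation,
                                            ph$shrinkage$scale)
    y$phantom <- do.call(phantom_spec, ph)
  }
  do.call(pipeline_config, y)
}

stage_log <- function(report, stage, ...) {
  report$stages[[stage]] <- list(...)
  message(sprintf("[kescan] %-12s %s", stage,
                  paste(names(list(...)), unlist(list(...)),
                        sep = "=", collapse = " ")))
  report
}

#' Run the full KES analysis pipeline
#'
#' Executes register -> subtract -> histogram -> segment ->
#' concentration -> region stats, writing intermediates and a
#' machine-readable JSON report (`report.json`) to the output
#' directory.  Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (a named list, also serialized as
#'   JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  truth_mask <- NULL

  if (config$simulate) {
    spec <- config$phantom %||% phantom_spec(seed = config$seed)
    phantom <- build_root_phantom(spec)
    if (config$write_intermediates)
      write_phantom(phantom, file.path(out, "phantom"))
    above <- phantom$above; below <- phantom$below
    truth_mask <- phantom$truth$yttria
    report <- stage_log(report, "simulate",
                        shape = paste(dim(above), collapse = "x"),
                        yttria_voxels = sum(truth_mask))
  } else {
    above <- read_stack(config$above_path)
    below <- read_stack(config$below_path)
    if (!is.null(config$truth_yttria_path))
      truth_mask <- read_stack(config$truth_yttria_path) > 0
    report <- stage_log(report, "read",
                        shape = paste(dim(above), collapse = "x"))
  }

  if (config$registration) {
    tr <- estimate_transform(below, above,
                             estimate_scale = config$estimate_scale)
    below <- as_float32(resample_volume(below, tr))
    report$registration <- list(translation = tr$translation,
                                scale = tr$scale)
    report <- stage_log(report, "register",
                        t = paste(signif(tr$translation, 4),
                                  collapse = ","))
    yaml::write_yaml(list(translation = tr$translation, scale = tr$scale),
                     file.path(out, "transform.yaml"))
  }

  sub <- as_float32(kes_subtract(above, below))
  report <- stage_log(report, "subtract",
                      min = signif(min(sub), 5), max = signif(max(sub), 5))

  h_above <- pixel_histogram(above, config$bin_width, config$hist_range,
                             "17.2 keV")
  h_below <- pixel_histogram(below, config$bin_width, config$hist_range,
                             "16.5 keV")
  cross <- crossing_threshold(h_above, h_below)
  report$histogram <- list(
    bin_width = config$bin_width,
    crossing_candidate_A = if (is.na(cross)) NULL else cross,
    fallback_A = config$params$threshold_A)
  report <- stage_log(report, "histogram",
                      crossing = ifelse(is.na(cross), "none", cross))

  seg <- segment_yttria(above, below, sub, config$params,
                        return_stages = TRUE)
  counts <- lapply(seg$masks, function(m) sum(m))
  report$thresholds <- config$params[c("threshold_A", "threshold_B",
                                       "threshold_C", "threshold_D_cutoff",
                                       "threshold_E")]
  report$mask_voxels <- counts
  report <- stage_log(report, "segment",
                      final_voxels = counts$i)

  dmr <- kedge_delta_mu_rho(config$delta_mu_rho_source)
  regions <- label_regions(seg$final)
  cmap <- concentration_map(sub, seg$final, dmr)
  stats <- region_stats(cmap, regions, config$voxel_size_mm)
  report$delta_mu_rho <- dmr
  report$n_regions <- nrow(regions$summary)
  if (nrow(stats)) {
    report$concentration <- list(min_mg_cc = stats$min_mg_cc[1],
                                 max_mg_cc = stats$max_mg_cc[1],
                                 mean_mg_cc = stats$mean_mg_cc[1],
                                 labelled_voxels = stats$voxels[1])
  } else {
    report$concentration <- list(min_mg_cc = NA, max_mg_cc = NA,
                                 mean_mg_cc = NA, labelled_voxels = 0L)
  }
  report <- stage_log(report, "quantify", regions = report$n_regions)

  if (!is.null(truth_mask)) {
    report$dice <- dice_coefficient(seg$final, truth_mask)
    report <- stage_log(report, "score", dice = signif(report$dice, 4))
  }

  if (config$write_intermediates) {
    write_stack(sub, file.path(out, "subtraction.tif"))
    for (nm in names(seg$masks))
      write_stack(array(as.numeric(seg$masks[[nm]]), dim(above)),
                  file.path(out, paste0("mask_", nm, ".tif")), "uint8")
    write_stack(cmap, file.path(out, "concentration.tif"))
    write_concentration_preview(cmap,
                                file.path(out, "concentration_preview.tif"))
    write_histogram_csv(h_above, h_below, file.path(out, "histograms.csv"))
    write.csv(stats, file.path(out, "region_stats.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
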