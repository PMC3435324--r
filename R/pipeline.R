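#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its published default: hue cut
#' 0.7 rad, red cap 150, duct minimum area 2290 px^2, cribra minimum area 100
#' px^2, Otsu cap 242, duct morphology disc radii 1/3/9, cribra radii 4/3/4,
#' template 150 px, search image 500 px, translation bound 20% of the side,
#' 4 um target voxels, 10000 sampled voxels, architecture bounds 25/35
#' sections. The rotation search range/steps and the correlation failure
#' floor have no published values and are free parameters.
#'
#' @param hue_threshold hue cut (radians) for duct tissue.
#' @param red_cap red-intensity cap excluding near-white pixels from the duct.
#' @param min_duct_area,min_cribra_area object-area cut-offs (px^2).
#' @param otsu_cap maximum Otsu threshold on the equalized green channel.
#' @param duct_radii disc radii c(open, close, final close) for the duct chain.
#' @param cribra_radii disc radii c(erode, close, open) for the cribra chain.
#' @param clahe_tiles tiles per side for adaptive equalization.
#' @param clahe_limit clip limit of the adaptive equalization.
#' @param template_size,search_size,max_shift_frac,angle_range,angle_step,refine_step,failure_floor registration tunables (see [find_rigid_transform()]).
#' @param voxel_size_um target voxel edge (microns).
#' @param connectivity 3D connectivity for component labeling (6 or 26).
#' @param class_bounds architecture height thresholds in sections.
#' @param sample_n number of voxels sampled for the aspect-ratio plot.
#' @param seed random seed for the voxel sampling.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(hue_threshold = 0.7,
                            red_cap = 150,
                            min_duct_area = 2290,
                            min_cribra_area = 100,
                            otsu_cap = 242,
                            duct_radii = c(1, 3, 9),
                            cribra_radii = c(4, 3, 4),
                            clahe_tiles = 4L,
                            clahe_limit = 1.5,
                            template_size = 150L,
                            search_size = 500L,
                            max_shift_frac = 0.20,
                            angle_range = 20,
                            angle_step = 1,
                            refine_step = 0.1,
                            failure_floor = 0.2,
                            voxel_size_um = 4,
                            connectivity = 6L,
                            class_bounds = c(25, 35),
                            sample_n = 10000L,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$max_shift_frac > 0, cfg$max_shift_frac <= 0.5,
            length(cfg$duct_radii) == 3L, length(cfg$cribra_radii) == 3L,
            length(cfg$class_bounds) == 2L, cfg$class_bounds[1] < cfg$class_bounds[2])
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' The config round-trips losslessly through its file format.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config`: `path`, invisibly.
#'   `read_pipeline_config`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

pipeline_log <- function(report, stage, msg, verbose) {
  line <- sprintf("[%s] %s", stage, msg)
  if (verbose) message(line)
  c(report, line)
}

#' Run the full reconstruction pipeline on a section stack
#'
#' Executes alignment, per-slice duct and cribra segmentation, in-plane
#' downsampling to ~isotropic voxels, 3D connected-component labeling,
#' architecture classification, and the aspect-ratio analysis, collecting all
#' per-stage results into a specimen report. Stacks shorter than 40 sections
#' are processed but flagged against the inclusion criterion. A stage failure
#' is reported in the log rather than aborting the run. Given the same stack,
#' config and seed the report is identical.
#'
#' @param stack a [section_stack()] (or a directory readable by
#'   [read_section_stack()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, aligned slices,
#'   masks, the transforms JSON, the per-slice CSV, component CSV, aspect
#'   CSV, meshes (OBJ + PLY) and the specimen report JSON are written there.
#' @param verbose print progress messages.
#' @return a list of class `specimen_report`: `architecture`
#'   (an `architecture_call`), `components` (data.frame), `alignment`
#'   (transforms + failure flags), `per_slice` (data.frame), `aspect`
#'   (samples + `linear_fit`), `config`, and `log`.
#' @export
run_pipeline <- function(stack, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(stack)) stack <- read_section_stack(stack)
  stopifnot(inherits(stack, "section_stack"), inherits(config, "pipeline_config"))
  n <- length(stack$images)
  if (n < 2L) stop("pipeline needs at least 2 sections", call. = FALSE)
  log <- character()
  log <- pipeline_log(log, "start", sprintf("%d sections", n), verbose)
  if (n < 40L) {
    log <- pipeline_log(log, "start",
                        "stack shorter than 40 sections (inclusion criterion) - flagged",
                        verbose)
  }

  ali <- align_stack(stack,
                     search_size = config$search_size,
                     template_size = config$template_size,
                     max_shift_frac = config$max_shift_frac,
                     angle_range = config$angle_range,
                     angle_step = config$angle_step,
                     refine_step = config$refine_step,
                     failure_floor = config$failure_floor)
  log <- pipeline_log(log, "align",
                      sprintf("%d/%d pairs failed", sum(ali$failures), n - 1L),
                      verbose)

  seg <- segment_stack(ali$stack,
                       hue_threshold = config$hue_threshold,
                       red_cap = config$red_cap,
                       min_area = config$min_duct_area,
                       open_radius = config$duct_radii[1],
                       close_radius = config$duct_radii[2],
                       final_close_radius = config$duct_radii[3])
  # cribra pass with its own tunables (segment_stack splits args by formals;
  # min_area/close_radius collide between the two stages, so run it manually)
  for (i in seq_len(n)) {
    seg$cribra_masks[[i]] <- segment_cribra(
      ali$stack$images[[i]], seg$duct_masks[[i]],
      hue_threshold = config$hue_threshold,
      otsu_cap = config$otsu_cap, min_area = config$min_cribra_area,
      erode_radius = config$cribra_radii[1],
      close_radius = config$cribra_radii[2],
      open_radius = config$cribra_radii[3],
      tiles = config$clahe_tiles, clahe_limit = config$clahe_limit)
    seg$per_slice$cribra_count[i] <- max(label_mask_2d(seg$cribra_masks[[i]]))
    seg$per_slice$cribra_area_px[i] <- sum(seg$cribra_masks[[i]])
  }
  log <- pipeline_log(log, "segment",
                      sprintf("median duct area %.0f px^2, median cribra count %d",
                              stats::median(seg$per_slice$duct_area_px),
                              as.integer(stats::median(seg$per_slice$cribra_count))),
                      verbose)

  ds <- downsample_stack(seg$cribra_masks, stack$pixel_size_um,
                         stack$slice_thickness_um)
  comp <- label_components(ds, connectivity = config$connectivity)
  arch <- suppressWarnings(
    classify_architecture(comp, n, bounds = config$class_bounds))
  log <- pipeline_log(log, "classify",
                      sprintf("%s (largest cribrum %d sections)",
                              arch$label, arch$max_height_sections), verbose)

  aspect <- NULL
  if (any(ds$volume)) {
    samples <- sample_aspect_ratios(ds, n = config$sample_n, seed = config$seed)
    fit <- tryCatch(fit_line(samples$height, samples$aspect_ratio),
                    error = function(e) NULL)
    aspect <- list(samples = samples, fit = fit)
  }

  report <- structure(list(architecture = arch,
                           components = comp$components,
                           alignment = list(transforms = ali$transforms,
                                            failures = ali$failures),
                           per_slice = seg$per_slice,
                           aspect = aspect,
                           n_sections = n,
                           flagged_short = n < 40L,
                           config = config,
                           log = log),
                      class = "specimen_report")

  if (!is.null(out_dir)) write_specimen_report(report, ali, seg, ds, out_dir)
  report
}

#' @export
print.specimen_report <- function(x, ...) {
  cat(sprintf("specimen_report: %d sections, architecture '%s' (max height %d), %d components, %d alignment failures\n",
              x$n_sections, x$architecture$label,
              x$architecture$max_height_sections, nrow(x$components),
              sum(x$alignment$failures)))
  invisible(x)
}

# Write all pipeline artifacts for one specimen.
write_specimen_report <- function(report, ali, seg, ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_section_stack(ali$stack, file.path(out_dir, "aligned"))
  write_mask_stack(seg$duct_masks, file.path(out_dir, "masks"), prefix = "duct")
  write_mask_stack(seg$cribra_masks, file.path(out_dir, "masks"), prefix = "cribra")
  write_transforms_json(ali$transforms, file.path(out_dir, "transforms.json"))
  utils::write.csv(seg$per_slice, file.path(out_dir, "per_slice.csv"),
                   row.names = FALSE)
  utils::write.csv(report$components, file.path(out_dir, "components.csv"),
                   row.names = FALSE)
  if (!is.null(report$aspect)) {
    utils::write.csv(report$aspect$samples, file.path(out_dir, "aspect_ratios.csv"),
                     row.names = FALSE)
  }
  if (any(ds$volume)) {
    mesh <- extract_surface(ds)
    write_mesh_obj(mesh, file.path(out_dir, "lumen_surface.obj"))
    write_mesh_ply(mesh, file.path(out_dir, "lumen_surface.ply"))
  }
  payload <- list(
    architecture = report$architecture$label,
    max_height_sections = report$architecture$max_height_sections,
    class_bounds = report$architecture$bounds,
    n_sections = report$n_sections,
    flagged_short = report$flagged_short,
    alignment_failures = sum(report$alignment$failures),
    components = report$components,
    aspect_fit = if (!is.null(report$aspect) && !is.null(report$aspect$fit)) {
      unclass(report$aspect$fit)
    },
    config = unclass(report$config),
    log = report$log)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Score automatic cribra masks against manual masks
#'
#' Per-image precision/recall plus a dataset summary, the validation layout
#' used for the segmentation accuracy tables.
#'
#' @param auto_masks,manual_masks lists of logical matrices of equal length.
#' @param dataset label for the summary.
#' @return list with `per_image` (data.frame) and `summary`
#'   (a `score_summary`).
#' @export
validate_segmentation <- function(auto_masks, manual_masks, dataset = "dataset") {
  stopifnot(length(auto_masks) == length(manual_masks))
  scores <- Map(precision_recall, auto_masks, manual_masks)
  per_image <- data.frame(
    image = seq_along(scores),
    TP = vapply(scores, `[[`, numeric(1), "TP"),
    FP = vapply(scores, `[[`, numeric(1), "FP"),
    FN = vapply(scores, `[[`, numeric(1), "FN"),
    precision = vapply(scores, `[[`, numeric(1), "precision"),
    recall = vapply(scores, `[[`, numeric(1), "recall"),
    flagged = vapply(scores, `[[`, logical(1), "flagged"))
  list(per_image = per_image, summary = summarize_scores(scores, dataset))
}
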