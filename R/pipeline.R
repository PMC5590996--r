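# End-to-end orchestration: per-slice segmentation of the three channels,
# channel fusion, lattice assembly, cell extraction, viability
# classification, morphometry, fragmentation and group statistics, with a
# deterministic run manifest.

#' Pipeline configuration
#'
#' Builds the full configuration list with defaults; any entry can be
#' overridden by the matching argument of this function or by a YAML file
#' read with [read_pipeline_config()]. Every key has a default, so a config
#' round-trips through file.
#'
#' @param roi region of interest `c(x, y, w, h)` for the per-slice
#'   thresholds (`NULL` = whole frame).
#' @param threshold list: `min_contrast` (see [segment_slice()]).
#' @param cleanup list: `min_component_px`, `min_organelle_px`.
#' @param membrane list: `shell_px`.
#' @param refraction list: `factor` (see [correct_z()]).
#' @param viability list: `k_sd` (see [classify_viability()]).
#' @param frag list: `seed`, `density_gain` (see [split_clusters()]).
#' @param min_cell_voxels smallest connected component kept as a cell.
#' @param fluorescence_norm normalization for [fluorescence_stats()].
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(roi = NULL,
                            threshold = list(min_contrast = 50),
                            cleanup = list(min_component_px = 20L,
                                           min_organelle_px = 5L),
                            membrane = list(shell_px = 2L),
                            refraction = list(factor = 0.87),
                            viability = list(k_sd = 3),
                            frag = list(seed = 1L, density_gain = 1.5),
                            min_cell_voxels = 200L,
                            fluorescence_norm = 1) {
  defaults <- list(
    roi = NULL,
    threshold = list(min_contrast = 50),
    cleanup = list(min_component_px = 20L, min_organelle_px = 5L),
    membrane = list(shell_px = 2L),
    refraction = list(factor = 0.87),
    viability = list(k_sd = 3),
    frag = list(seed = 1L, density_gain = 1.5),
    min_cell_voxels = 200L,
    fluorescence_norm = 1
  )
  user <- list(roi = roi, threshold = threshold, cleanup = cleanup,
               membrane = membrane, refraction = refraction,
               viability = viability, frag = frag,
               min_cell_voxels = min_cell_voxels,
               fluorescence_norm = fluorescence_norm)
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline on one stack
#'
#' Segments every slice of the red and green channels (per-slice histogram
#' thresholds inside the ROI), fuses the two cell outlines, builds the
#' refraction-corrected interpolated voxel lattice with membrane shells,
#' extracts 26-connected cells, classifies their viability from the blue
#' channel, computes the per-cell morphometry table, runs the nuclear
#' fragmentation analysis for every cell with a nucleus, and compares the
#' viable and apoptotic groups when both are populated.
#'
#' @param stack an [image_stack()], or `NULL` to read from `stack_path`.
#' @param stack_path TIFF path readable by [read_stack()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, writes
#'   `morphometry.csv`, `fragmentation.json`, `stats.csv` (if computed),
#'   `lattice/` and a deterministic `manifest.json`.
#' @return List with `lattice`, `cells`, `morphometry`, `fragmentation`,
#'   `stats` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(stack = NULL, stack_path = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if (is.null(stack)) {
    if (is.null(stack_path)) stop("give `stack` or `stack_path`", call. = FALSE)
    stack <- read_stack(stack_path)
  }
  roi <- if (!is.null(config$roi)) config$roi else stack$roi
  nz <- n_slices(stack)
  seg_one <- function(z, channel, role) {
    sl <- get_slice(stack, z, channel)
    th <- slice_threshold(sl, roi)
    segment_slice(sl, role, th,
                  min_contrast = config$threshold$min_contrast,
                  min_component_px = config$cleanup$min_component_px,
                  min_organelle_px = config$cleanup$min_organelle_px)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  red_maps <- stage("segment", lapply(seq_len(nz), seg_one, "red", "red"))
  green_maps <- stage("segment", lapply(seq_len(nz), seg_one, "green", "green"))
  fused <- lapply(seq_len(nz), function(z)
    fuse_channels(red_maps[[z]], green_maps[[z]]))
  membranes <- lapply(seq_len(nz), function(z)
    membrane_mask(get_slice(stack, z, "blue"), fused[[z]],
                  shell_px = config$membrane$shell_px))
  lattice <- stage("reconstruct",
    build_lattice(stack, red_maps, green_maps, fused, membranes,
                  refraction_factor = config$refraction$factor))
  cells <- stage("extract",
                 extract_cells(lattice, min_voxels = config$min_cell_voxels))
  if (length(cells) > 0L) {
    bg <- background_blue_stats(lattice)
    cells <- lapply(cells, classify_viability, lattice = lattice,
                    background_stats = bg, k_sd = config$viability$k_sd)
  }
  morph <- stage("morph",
    morphometry_table(cells, lattice,
                      fluorescence_norm = config$fluorescence_norm))
  frag <- lapply(cells, function(cell) {
    if (length(cell$nucleus) == 0L)
      return(list(cell_id = cell$cell_id, n_cl = NA_integer_,
                  note = "no nucleus"))
    res <- tryCatch(
      analyze_fragmentation(cell, lattice, seed = config$frag$seed,
                            density_gain = config$frag$density_gain),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(res))
      return(list(cell_id = cell$cell_id, n_cl = NA_integer_,
                  note = "fragmentation undefined"))
    list(cell_id = cell$cell_id, n_cl = res$n_cl, I_th = res$I_th,
         I_m = res$I_m, I_5pct = res$I_5pct, saturated = res$saturated,
         n_valid = res$n_valid,
         leaves = lapply(res$clusters$leaves, function(l)
           list(size = l$size, centroid = as.numeric(l$centroid),
                rho = l$rho)))
  })
  viable <- morph[!is.na(morph$viability) & morph$viability == "viable", ]
  apop <- morph[!is.na(morph$viability) & morph$viability == "apoptotic", ]
  stats_tab <- if (nrow(viable) >= 2L && nrow(apop) >= 2L)
    stage("stats", compare_groups(viable, apop,
                                  labels = c("viable", "apoptotic")))
  else NULL

  manifest <- list(
    package = "voxmorph",
    version = as.character(utils::packageVersion("voxmorph")),
    config = unclass(config),
    n_slices = nz,
    n_cells = length(cells),
    n_viable = sum(morph$viability == "viable", na.rm = TRUE),
    n_apoptotic = sum(morph$viability == "apoptotic", na.rm = TRUE)
  )
  result <- list(lattice = lattice, cells = cells, morphometry = morph,
                 fragmentation = frag, stats = stats_tab, manifest = manifest)
  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    if (!ok) stop("cannot create ", out_dir, call. = FALSE)
    write_cell_table(morph, file.path(out_dir, "morphometry.csv"))
    jsonlite::write_json(frag, file.path(out_dir, "fragmentation.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    if (!is.null(stats_tab))
      utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                       row.names = FALSE)
    write_lattice(lattice, file.path(out_dir, "lattice"))
    outputs <- c("morphometry.csv", "fragmentation.json",
                 if (!is.null(stats_tab)) "stats.csv")
    manifest$output_md5 <- as.list(tools::md5sum(file.path(out_dir, outputs)))
    names(manifest$output_md5) <- outputs
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    result$manifest <- manifest
  }
  result
}
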