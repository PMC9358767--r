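## Pipeline orchestration: configured, logged, reproducible runs of
## generate -> segment -> measure -> scale, plus a human-readable report.

#' Read a run configuration
#'
#' Configurations are JSON (canonical; YAML is also accepted when the yaml
#' package is installed). Recognized fields, all optional unless noted:
#' `seed` (integer), `tau` (threshold, default 100), `propagation_mode`
#' (`"distance_modified"`/`"plain"`), `min_contact_faces` (default 1),
#' `curvature_radius_mult` (default 0.75), `exclude_labels`, `sa_unit_glm`
#' (`"cm2"`/`"mm2"`), `voxel_spacing_mm`, `valley_depth`, `series` (fields
#' of [series_spec()]), `shell` (fields of [shell_spec()]), and — for the
#' real-data path — `specimens`: a list of `{volume, seeds}` file paths.
#'
#' @param path config file path (.json or .yaml/.yml).
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  for (sp in cfg$specimens) {
    for (p in unlist(sp))
      if (!file.exists(p)) stop("referenced path does not exist: ", p)
  }
  cfg$.source <- path
  class(cfg) <- c("run_config", "list")
  cfg
}

config_default <- function(cfg, field, default) {
  if (is.null(cfg[[field]])) default else cfg[[field]]
}

#' Run the full pipeline
#'
#' Executes generate (synthetic mode) or load (real-data mode), then
#' segment, measure and scale for every specimen, writing all artifacts and
#' a machine-readable manifest into `out_dir`. Deterministic for a fixed
#' config + seed. On failure the stage name and specimen id are reported
#' and a `FAILED` marker is left next to the partial outputs.
#'
#' @param config a `run_config` (or path to one).
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly; artifacts on disk: per specimen
#'   `labels_<i>.nrrd`, `surface_<i>.ply`, `rag_<i>.graphml` /
#'   `rag_edges_<i>.csv`, `stats_<i>.csv`; series-level `series_table.csv`,
#'   `fits.json`, `manifest.json`, `run.log`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = logfile, append = TRUE)
  }
  stage <- "init"; specimen_id <- NA
  on_fail <- function(e) {
    writeLines(sprintf("stage=%s specimen=%s error=%s", stage, specimen_id,
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s' (specimen %s): %s", stage,
                 specimen_id, conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    seed <- as.integer(config_default(config, "seed", 1L))
    tau <- config_default(config, "tau", 100)
    mode <- config_default(config, "propagation_mode", "distance_modified")
    mcf <- config_default(config, "min_contact_faces", 1L)
    crm <- config_default(config, "curvature_radius_mult", 0.75)
    excl <- config_default(config, "exclude_labels", integer(0))
    sa_unit <- config_default(config, "sa_unit_glm", "cm2")

    # serialize the config verbatim into the run directory
    if (!is.null(config$.source)) {
      file.copy(config$.source, file.path(out_dir, basename(config$.source)),
                overwrite = TRUE)
    } else {
      cfg_out <- config
      cfg_out$.source <- NULL
      jsonlite::write_json(unclass(cfg_out), file.path(out_dir, "config.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }

    specimens <- list()
    if (!is.null(config$specimens) && length(config$specimens) > 0) {
      stage <- "load"
      sp_cfg <- config$specimens
      if (is.data.frame(sp_cfg)) sp_cfg <- split(sp_cfg, seq_len(nrow(sp_cfg)))
      for (i in seq_along(sp_cfg)) {
        specimen_id <- i
        vol <- read_volume(as.character(sp_cfg[[i]]$volume))
        seeds <- read_seeds(as.character(sp_cfg[[i]]$seeds))
        specimens[[i]] <- list(intensity = vol, seeds = seeds)
        log_line("loaded specimen ", i)
      }
    } else {
      stage <- "generate"
      specimen_id <- NA
      shell_args <- config_default(config, "shell", list())
      base <- do.call(shell_spec, c(shell_args, list(rng_seed = seed)))
      series_args <- config_default(config, "series", list())
      series_args$rng_seed <- seed
      ser <- do.call(series_spec, series_args)
      gen <- generate_series(
        ser, base,
        voxel_spacing_mm = config_default(config, "voxel_spacing_mm",
                                          base$shell_thickness_mm / 3),
        valley_depth = config_default(config, "valley_depth", 0.5))
      if (ser$mode == "table_only")
        stop("table_only series have no geometry to run the pipeline on; ",
             "use fit_series_table() directly")
      specimens <- lapply(gen$specimens, function(s)
        list(intensity = s$intensity, seeds = s$seeds, truth = s$truth))
      log_line("generated ", length(specimens), " specimens (seed ", seed, ")")
    }

    stats_list <- list()
    sa <- numeric(length(specimens))
    for (i in seq_along(specimens)) {
      specimen_id <- i
      sp <- specimens[[i]]
      stage <- "segment"
      mask <- threshold_segment(sp$intensity, tau)
      labels <- propagate_contours(sp$intensity, mask, sp$seeds, mode = mode)
      rag <- build_rag(labels, min_contact_faces = mcf)
      mesh <- extract_surface(labels)
      write_nrrd(labels, file.path(out_dir, sprintf("labels_%02d.nrrd", i)))
      write_ply(mesh, file.path(out_dir, sprintf("surface_%02d.ply", i)))
      write_rag(rag, file.path(out_dir, sprintf("rag_%02d.graphml", i)),
                file.path(out_dir, sprintf("rag_edges_%02d.csv", i)))
      log_line("segmented specimen ", i, ": ", nrow(rag$nodes), " scutes")
      stage <- "measure"
      stats <- compute_scute_stats(labels, rag, mesh, exclude_labels = excl,
                                   curvature_radius_mult = crm)
      sa[i] <- carapace_surface_area(mesh, exclude_labels = excl)
      write.csv(stats, file.path(out_dir, sprintf("stats_%02d.csv", i)),
                row.names = FALSE)
      stats_list[[i]] <- stats
      log_line("measured specimen ", i, ": SA ", signif(sa[i], 6), " mm^2")
    }

    stage <- "scale"
    specimen_id <- NA
    summ <- summarize_series(stats_list, sa, sa_unit_glm = sa_unit)
    write.csv(summ$table, file.path(out_dir, "series_table.csv"),
              row.names = FALSE)
    write.csv(summ$box_summaries, file.path(out_dir, "box_summaries.csv"),
              row.names = FALSE)
    write_fits(summ$fits, file.path(out_dir, "fits.json"))
    log_line("fitted ", length(summ$fits), " scaling models")

    stage <- "manifest"
    arts <- setdiff(list.files(out_dir), c("manifest.json", "run.log"))
    manifest <- list(
      package = "scutegrow",
      version = as.character(utils::packageVersion("scutegrow")),
      seed = seed,
      n_specimens = length(specimens),
      config = {
        x <- unclass(config); x$.source <- NULL; x
      },
      artifacts = as.list(setNames(
        unname(tools::md5sum(file.path(out_dir, arts))), arts)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    log_line("run complete")
    invisible(out_dir)
  }, error = on_fail)
}

#' Summarize a completed run as Markdown
#'
#' Produces a human-readable summary of a [run_pipeline()] output
#' directory: the per-specimen table, every fitted slope against its
#' isometry reference (flagged as isometric / positive / negative
#' allometry by whether the 95% CI contains the reference), and the
#' neighbor-count relative-frequency table per specimen.
#'
#' @param run_dir a completed run directory.
#' @param path optional output file; default `report.md` inside `run_dir`.
#' @return the report path, invisibly.
#' @export
pipeline_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("not a completed run directory (no manifest.json): ", run_dir)
  manifest <- jsonlite::fromJSON(manifest_path)
  tab <- read.csv(file.path(run_dir, "series_table.csv"))
  fits_raw <- jsonlite::fromJSON(file.path(run_dir, "fits.json"))
  lines <- c(sprintf("# scutegrow run report"),
             sprintf("- package version: %s, seed: %s", manifest$version,
                     manifest$seed),
             sprintf("- specimens: %d", manifest$n_specimens),
             "", "## Per-specimen series table", "",
             md_table(tab), "", "## Scaling fits vs surface area", "",
             md_table(do.call(rbind, lapply(names(fits_raw), function(nm) {
               f <- fits_raw[[nm]]
               fit <- new_allometry_fit(f$slope, f$intercept,
                                        unlist(f$ci), f$model,
                                        f$isometry_reference, f$n)
               data.frame(variable = nm, model = f$model,
                          slope = signif(f$slope, 4),
                          ci = sprintf("[%.4g; %.4g]", f$ci[1], f$ci[2]),
                          isometry_ref = f$isometry_reference,
                          classification = allometry_class(fit))
             }))))
  stats_files <- sort(list.files(run_dir, "^stats_.*\\.csv$",
                                 full.names = TRUE))
  if (length(stats_files) > 0) {
    freq <- do.call(rbind, lapply(seq_along(stats_files), function(i) {
      st <- read.csv(stats_files[i])
      t <- table(st$n_neighbors)
      data.frame(specimen = i, n_neighbors = as.integer(names(t)),
                 rel_freq = round(as.numeric(t) / nrow(st), 3))
    }))
    wide <- stats::reshape(freq, idvar = "n_neighbors", timevar = "specimen",
                           direction = "wide")
    wide[is.na(wide)] <- 0
    lines <- c(lines, "", "## Neighbor-count relative frequencies", "",
               md_table(wide[order(wide$n_neighbors), ]))
  }
  writeLines(lines, path)
  invisible(path)
}

md_table <- function(df) {
  df <- as.data.frame(lapply(df, function(x)
    if (is.numeric(x)) signif(x, 5) else x))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}
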