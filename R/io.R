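#' Read a form-factor table
#'
#' TSV with header columns `qz`, `F`, and optionally `delta`. qz must be
#' strictly ascending and amplitudes non-negative; violations are reported
#' with the offending line number.
#'
#' @param path File path (gzip transparent).
#' @param scale_status Scale status to record on the result.
#' @return A [form_factor()].
#' @export
read_formfactor_table <- function(path, scale_status = "arbitrary") {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  if (!all(c("qz", "F") %in% names(d))) {
    stop("form-factor table must have columns 'qz' and 'F'")
  }
  bad <- which(diff(d$qz) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("qz not strictly ascending at line %d of %s",
                 bad[1] + 2L, path))   # +1 header, +1 for the second point
  }
  neg <- which(d$F < 0)
  if (length(neg) > 0L) {
    stop(sprintf("negative amplitude at line %d of %s", neg[1] + 1L, path))
  }
  form_factor(d$qz, d$F,
              delta = if ("delta" %in% names(d)) d$delta else NULL,
              scale_status = scale_status)
}

#' Write a form-factor table
#'
#' @param ff A [form_factor()].
#' @param path Output path (gzip transparent via a `.gz` suffix).
#' @return `path`, invisibly.
#' @export
write_formfactor_table <- function(ff, path) {
  stopifnot(inherits(ff, "form_factor"))
  d <- as.data.frame(ff)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(d, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write density profiles to a TSV table
#'
#' One `z` column plus one column per component; a leading comment line
#' records the weighting and frame count.
#'
#' @param profiles Named list of [density_profile()]s on a shared grid.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  stopifnot(length(profiles) > 0L)
  z <- profiles[[1]]$bin_centers
  for (p in profiles) stopifnot(all(p$bin_centers == z))
  d <- data.frame(z = z)
  for (nm in names(profiles)) d[[nm]] <- profiles[[nm]]$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# weighting=%s n_frames=%d",
                     profiles[[1]]$weighting, profiles[[1]]$n_frames), con)
  utils::write.table(format(d, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read density profiles from a TSV table
#'
#' @param path File written by [write_profile_table()].
#' @return Named list of [density_profile()]s.
#' @export
read_profile_table <- function(path) {
  first <- readLines(path, n = 1L)
  weighting <- sub(".*weighting=(\\S+).*", "\\1", first)
  n_frames <- as.integer(sub(".*n_frames=(\\d+).*", "\\1", first))
  d <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE)
  comps <- setdiff(names(d), "z")
  out <- lapply(comps, function(nm) {
    density_profile(d$z, d[[nm]], weighting = weighting, component = nm,
                    n_frames = n_frames)
  })
  names(out) <- comps
  out
}

#' Write a toy trajectory as JSON lines
#'
#' First line holds the box and metadata; each subsequent line is one frame
#' (column-oriented bead arrays). Gzip transparent via a `.gz` suffix.
#'
#' @param traj A [toy_trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_jsonl <- function(traj, path) {
  stopifnot(inherits(traj, "toy_trajectory"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  header <- list(box = as.list(traj$box), metadata = traj$metadata)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (fr in traj$frames) {
    writeLines(jsonlite::toJSON(as.list(fr), auto_unbox = FALSE,
                                digits = NA), con)
  }
  invisible(path)
}

#' Read a toy trajectory from JSON lines
#'
#' @param path File written by [write_trajectory_jsonl()].
#' @return A [toy_trajectory].
#' @export
read_trajectory_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("trajectory file has no frames")
  header <- jsonlite::fromJSON(lines[1])
  frames <- lapply(lines[-1], function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  structure(list(frames = frames,
                 box = unlist(header$box),
                 metadata = header$metadata),
            class = "toy_trajectory")
}

#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the pipeline with their standard
#' defaults: qz grid 0-0.8 by 0.005 1/Angstrom, bin width 0.25 Angstrom,
#' Delta error model 0.05/0.1 split at 0.6 1/Angstrom, chi-square cutoff
#' 3.4, analysis fraction 0.5.
#'
#' @param ... Overrides of the default fields.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- utils::modifyList(
    list(qz_min = 0, qz_max = 0.8, qz_step = 0.005,
         bin_width = 0.25,
         delta_qz_break = 0.6, delta_low = 0.05, delta_high = 0.1,
         cutoff = 3.4, equilibration_fraction = 0.5,
         water_density = 0.333, seed = 1L),
    list(...))
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a bilayer model specification as YAML
#'
#' Serializes the Gaussian components and slab parameters of a
#' [bilayer_model()] so model families can be defined in configuration
#' files.
#'
#' @param model A [bilayer_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "bilayer_model"))
  spec <- list(
    components = lapply(model$gaussians, function(g) {
      list(label = g$label, center = g$center, width = g$width,
           areal_excess = g$areal_excess)
    }),
    hydrocarbon = list(plateau = model$hc_plateau,
                       halfwidth = model$hc_halfwidth,
                       smoothing = model$hc_smoothing),
    water_density = model$water_density,
    box_halfheight = model$box_halfheight)
  yaml::write_yaml(spec, path, precision = 15)
  invisible(path)
}

#' Read a bilayer model specification from YAML
#' @param path File written by [write_model_yaml()].
#' @return A [bilayer_model()].
#' @export
read_model_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  gaussians <- lapply(spec$components, function(g) {
    component_gaussian(g$label, g$center, g$width, g$areal_excess)
  })
  bilayer_model(gaussians,
                hc_plateau = spec$hydrocarbon$plateau,
                hc_halfwidth = spec$hydrocarbon$halfwidth,
                hc_smoothing = spec$hydrocarbon$smoothing,
                water_density = spec$water_density,
                box_halfheight = spec$box_halfheight)
}

#' Log the reproducibility context of a run
#'
#' Writes the configuration hash, seed, and package version to standard
#' error, so every pipeline stage records what produced its outputs.
#'
#' @param cfg A [run_config()].
#' @return The config hash, invisibly.
#' @export
log_run <- function(cfg) {
  h <- rlang::hash(unclass(cfg))
  message(sprintf("bilayerff %s | config %s | seed %s",
                  as.character(utils::packageVersion("bilayerff")),
                  substr(h, 1, 12), cfg$seed))
  invisible(h)
}

#' Write a scan table to TSV (cells) and JSON (summary)
#'
#' @param scan A `scan_table` from [scan_grid()].
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_scan_table <- function(scan, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(scan, "scan_table"))
  if (!is.null(tsv_path)) {
    utils::write.table(scan$cells, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(best_cell = scan$best_cell, cutoff = scan$cutoff,
           summary = scan$summary),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
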