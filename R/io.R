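# File formats and the pipeline driver. Multi-page TIFF for images (16-bit
# integer holograms; paired float32 amplitude/phase pages for complex
# fields), JSON sidecars for metadata, CSV for tables.

sidecar_path <- function(path) paste0(path, ".json")

# stable short hash of an R object (via its serialized YAML text)
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass_deep(x)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}

#' Write / read a hologram stack as multi-page 16-bit TIFF
#'
#' Digital numbers are stored losslessly as 16-bit unsigned pages; the
#' camera model, frame count and a configuration hash go into a JSON
#' sidecar (`<path>.json`). Reading without the sidecar falls back to the
#' default camera with a warning.
#'
#' @param frames List of [hologram_frame()]s.
#' @param path Output TIFF path.
#' @param config Optional [optical_config()] recorded (as a hash) in the
#'   sidecar.
#' @return `write_stack()`: the path, invisibly. `read_stack()`: a list
#'   of [hologram_frame()]s.
#' @export
write_stack <- function(frames, path, config = NULL) {
  stopifnot(length(frames) > 0,
            all(vapply(frames, inherits, TRUE, "hologram_frame")))
  camera <- frames[[1]]$camera
  pages <- lapply(frames, function(f) {
    dn <- round(f$dn)
    if (any(dn < 0 | dn > 65535)) stop("DN outside the 16-bit range")
    dn / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(kind = "hologram_stack",
               n_frames = length(frames),
               timestamp_index = vapply(frames, `[[`, 1L, "timestamp_index"),
               camera = unclass(camera),
               config_hash = if (is.null(config)) NA else config_hash(config))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    camera <- camera_model(meta$camera$full_well, meta$camera$bit_depth,
                           meta$camera$read_noise)
    ts <- meta$timestamp_index
  } else {
    warning("missing sidecar ", sc, "; applying default camera model")
    camera <- camera_model()
    ts <- seq_along(pages)
  }
  lapply(seq_along(pages), function(i) {
    hologram_frame(round(pages[[i]] * 65535), timestamp_index = ts[i],
                   camera = camera)
  })
}

#' Write / read a complex-field stack as paired float32 TIFF pages
#'
#' Each field contributes two 32-bit float pages: amplitude divided by
#' the stack-wide maximum, and phase mapped to `[0, 1]` as
#' `(phase + pi) / (2 * pi)`. The scale factor, grid metadata and channel
#' go into the JSON sidecar. The round trip is exact to float32
#' precision.
#'
#' @param fields List of [complex_field()]s (same channel and grid).
#' @param path Output TIFF path.
#' @return `write_field_stack()`: the path, invisibly.
#'   `read_field_stack()`: a list of [complex_field()]s.
#' @export
write_field_stack <- function(fields, path) {
  stopifnot(length(fields) > 0,
            all(vapply(fields, inherits, TRUE, "complex_field")))
  amp_max <- max(vapply(fields, function(f) max(Mod(f$values)), numeric(1)))
  if (amp_max == 0) amp_max <- 1
  pages <- list()
  for (f in fields) {
    pages[[length(pages) + 1]] <- Mod(f$values) / amp_max
    pages[[length(pages) + 1]] <- (Arg(f$values) + pi) / (2 * pi)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  f1 <- fields[[1]]
  meta <- list(kind = "field_stack", n_fields = length(fields),
               page_order = "amplitude,phase per field",
               amp_scale = amp_max, channel = f1$channel,
               sample_plane_pixel = f1$sample_plane_pixel,
               wavelength = f1$wavelength, medium_index = f1$medium_index,
               z_offset = vapply(fields, `[[`, numeric(1), "z_offset"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_field_stack
#' @export
read_field_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("field stacks require their JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stopifnot(length(pages) == 2 * meta$n_fields)
  lapply(seq_len(meta$n_fields), function(i) {
    amp <- pages[[2 * i - 1]] * meta$amp_scale
    phs <- pages[[2 * i]] * 2 * pi - pi
    complex_field(amp * exp(1i * phs), meta$channel,
                  meta$sample_plane_pixel, meta$wavelength,
                  meta$medium_index, z_offset = meta$z_offset[i])
  })
}

#' Run one pipeline stage from a configuration list
#'
#' Thin driver tying the analysis stages together for scripted and
#' command-line use. Every stage writes its artifacts plus a provenance
#' JSON (`<out>/provenance.json`) naming the configuration hash, seed and
#' package version.
#'
#' Stages and their main `params` entries:
#' \describe{
#'   \item{simulate}{`n_frames`, `diameter` (nm), `index`, optional
#'     `motion`; writes `holograms.tif` + `truth.csv`.}
#'   \item{reconstruct}{`holograms`, `background` (paths), `channel`,
#'     `refocus`; writes `sa_<channel>.tif`.}
#'   \item{noise}{`holograms` path, `channel`; writes
#'     `noise_report.json` + `std_map.tif`.}
#'   \item{particles}{`holograms` path, `channel`, `min_sa`; writes
#'     `particles.csv`.}
#'   \item{dynamics}{`holograms` path, `channel`, `bands` (list of
#'     `c(lo, hi)`); writes one map TIFF per band.}
#'   \item{drymass}{`holograms`, `background` paths, `gamma`; writes
#'     `drymass.tif` and `drymass.json`.}
#' }
#'
#' @param config List with elements `optical` ([optical_config()]),
#'   `camera` ([camera_model()]), `seed`, `out_dir`, and `params` (stage
#'   parameters).
#' @param stage Stage name.
#' @return List of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, stage = c("simulate", "reconstruct",
                                           "noise", "particles",
                                           "dynamics", "drymass")) {
  stage <- match.arg(stage)
  opt <- config$optical %||% optical_config()
  cam <- config$camera %||% camera_model()
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "."
  p <- config$params %||% list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()

  read_holo <- function(key) {
    path <- p[[key]]
    if (is.null(path)) stop(stage, " stage needs params$", key)
    read_stack(path)
  }

  if (stage == "simulate") {
    bead <- bead_spec(p$diameter %||% 203, p$index %||% 1.43,
                      row = p$row %||% (opt$sensor_shape[1] / 2),
                      col = p$col %||% (opt$sensor_shape[2] / 2))
    scene <- sim_scene(list(bead), seed = seed,
                       background_roughness_rms = p$roughness %||% 0)
    motion <- p$motion %||% motion_none()
    ts <- simulate_timeseries(scene, opt, cam, p$n_frames %||% 10, motion)
    artifacts$holograms <- file.path(out_dir, "holograms.tif")
    write_stack(ts$frames, artifacts$holograms, config = opt)
    artifacts$truth <- file.path(out_dir, "truth.csv")
    utils::write.csv(ts$truth, artifacts$truth, row.names = FALSE)
  } else if (stage == "reconstruct") {
    frames <- read_holo("holograms")
    bg <- read_holo("background")
    ch <- p$channel %||% "fs"
    sa <- reconstruct_sa(frames[[p$frame %||% 1]], bg[[1]], opt, ch,
                         refocus = p$refocus %||% "none")
    artifacts$sa <- file.path(out_dir, paste0("sa_", ch, ".tif"))
    vals <- sa$values; vals[is.na(vals)] <- 0
    tiff::writeTIFF(vals / 2, artifacts$sa, bits.per.sample = 32)
  } else if (stage == "noise") {
    frames <- read_holo("holograms")
    ch <- p$channel %||% "fs"
    rep <- temporal_noise(frames, opt, ch,
                          window = p$window %||% c(200, 200))
    artifacts$report <- file.path(out_dir, "noise_report.json")
    jsonlite::write_json(rep[c("scalar_noise", "nu", "n_electron",
                               "theory_floor", "n_differentials")],
                         artifacts$report, auto_unbox = TRUE, digits = NA)
    artifacts$std_map <- file.path(out_dir, "std_map.tif")
    tiff::writeTIFF(rep$std_map / max(rep$std_map), artifacts$std_map,
                    bits.per.sample = 32)
  } else if (stage == "particles") {
    frames <- read_holo("holograms")
    ch <- p$channel %||% "bs"
    t <- p$frame %||% ceiling(length(frames) / 2)
    fields <- lapply(frames, function(f) demultiplex(f, opt, ch))
    e_np <- static_background(fields)
    sa <- differential_sa(fields[[t]], e_np, e_np,
                          channel_alpha(opt, ch), channel = ch)
    det <- detect_particles(sa, min_sa = p$min_sa %||% 0.01)
    det$sigma <- vapply(seq_len(nrow(det)), function(i) {
      as.numeric(cross_section(sa, c(det$row[i], det$col[i]),
                               mode = p$mode %||% "gauss"))
    }, numeric(1))
    artifacts$particles <- file.path(out_dir, "particles.csv")
    utils::write.csv(det, artifacts$particles, row.names = FALSE)
  } else if (stage == "dynamics") {
    frames <- read_holo("holograms")
    ch <- p$channel %||% "fs"
    fields <- lapply(frames, function(f) demultiplex(f, opt, ch)$values)
    bg <- static_background(fields)
    ratios <- lapply(fields, function(f) f / bg)
    ratios <- subtract_local_mean(normalize_frames(ratios),
                                  kernel = p$kernel %||% 11)
    bands <- p$bands %||% list(c(1, 10), c(100, 250))
    for (b in bands) {
      mp <- bandpass_std_map(ratios, b[1], b[2], opt$frame_rate,
                             alpha = channel_alpha(opt, ch), channel = ch)
      f <- file.path(out_dir, sprintf("dynamic_%s_%g-%gHz.tif", ch,
                                      b[1], b[2]))
      tiff::writeTIFF(mp$values / max(mp$values, 1e-12), f,
                      bits.per.sample = 32)
      artifacts[[sprintf("band_%g_%g", b[1], b[2])]] <- f
    }
  } else if (stage == "drymass") {
    frames <- read_holo("holograms")
    bg <- read_holo("background")
    field <- demultiplex(frames[[1]], opt, "fs")
    field_bg <- demultiplex(bg[[1]], opt, "fs")
    phase <- Arg(field$values / field_bg$values)
    px <- sample_pixel(opt)
    dm <- dry_mass_map(phase, opt$wavelength, p$gamma %||% 0.18,
                       pixel_area = px^2)
    artifacts$map <- file.path(out_dir, "drymass.tif")
    rng <- range(dm$surface_density, na.rm = TRUE)
    tiff::writeTIFF((dm$surface_density - rng[1]) / max(diff(rng), 1e-12),
                    artifacts$map, bits.per.sample = 32)
    artifacts$total <- file.path(out_dir, "drymass.json")
    jsonlite::write_json(list(total_pg = dm$total), artifacts$total,
                         auto_unbox = TRUE, digits = NA)
  }

  prov <- list(stage = stage, seed = seed,
               config_hash = config_hash(list(opt, cam, p)),
               package_version = as.character(utils::packageVersion("holoscat")),
               artifacts = lapply(artifacts, normalizePath, mustWork = FALSE),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
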