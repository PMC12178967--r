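# Plain-text persistence: VPTS-style CSV for profiles, CSV matrices with a
# JSON sidecar for gridded fields, CSVs for local weather, JSON for planted
# truth and manifests.

#' Read and write VPTS-style profile CSVs
#'
#' The community VPTS-style layout: one row per (radar, timestamp, altitude
#' bin), columns `radar`, `datetime` (ISO-8601 UTC), `height` (m, bin lower
#' edge), `dens` (ind km^-3), and optionally `eta` (cm^2 km^-3) and
#' `airspeed` (m s^-1).
#'
#' @param x data.frame of profile rows.
#' @param path CSV file path.
#' @return `read_vpts_csv` returns the data.frame with `datetime` parsed as
#'   POSIXct UTC.
#' @export
write_vpts_csv <- function(x, path) {
  x <- as.data.frame(x)
  x$datetime <- format(as.POSIXct(x$datetime, tz = "UTC"),
                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.table::fwrite(x, path)
  invisible(path)
}

#' @rdname write_vpts_csv
#' @export
read_vpts_csv <- function(path) {
  x <- as.data.frame(data.table::fread(path))
  x$datetime <- as.POSIXct(x$datetime, tz = "UTC",
                           format = "%Y-%m-%dT%H:%M:%OSZ")
  x
}

#' Read and write gridded synoptic field panels
#'
#' Fields are stored as one CSV matrix per variable (rows = nights, columns =
#' grid cells, longitude-fastest cell order) next to a `grid.json` sidecar
#' holding the grid lines, the night dates and the variable names.
#'
#' @param synoptic Synoptic panel: list with `nights`, `grid` (see
#'   [make_grid()]) and `fields` (named list of nights x cells matrices).
#' @param dir Directory for the files (created if needed).
#' @return `read_field_panel` returns a synoptic panel list.
#' @export
write_field_panel <- function(synoptic, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(lon = synoptic$grid$lon, lat = synoptic$grid$lat,
               nights = format(synoptic$nights),
               variables = names(synoptic$fields))
  jsonlite::write_json(meta, file.path(dir, "grid.json"), digits = NA)
  for (v in names(synoptic$fields)) {
    data.table::fwrite(data.table::as.data.table(synoptic$fields[[v]]),
                       file.path(dir, paste0(v, ".csv")), col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_field_panel
#' @export
read_field_panel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  grid <- make_grid(lon = meta$lon, lat = meta$lat)
  fields <- lapply(meta$variables, function(v) {
    as.matrix(data.table::fread(file.path(dir, paste0(v, ".csv")),
                                header = FALSE))
  })
  names(fields) <- meta$variables
  for (v in meta$variables) dimnames(fields[[v]]) <- NULL
  list(nights = as.Date(meta$nights), grid = grid, fields = fields)
}

#' Read and write local weather panels
#'
#' Two CSVs: `local_profiles.csv` in long layout (radar, night, slot, height,
#' one column per profile variable) and `local_scalars.csv` (radar, night,
#' slot, cloud, precip).
#'
#' @param local Local panel: list with `meta`, `profiles`, `cloud`, `precip`.
#' @param dir Directory for the files.
#' @return `read_local_panel` returns a local panel list.
#' @export
write_local_panel <- function(local, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alt <- local$altitudes
  n <- nrow(local$meta)
  long <- data.table::data.table(
    radar = rep(local$meta$radar, each = length(alt)),
    night = rep(format(local$meta$night), each = length(alt)),
    slot = rep(local$meta$slot, each = length(alt)),
    height = rep(alt, times = n)
  )
  for (v in names(local$profiles)) {
    long[[v]] <- as.vector(t(local$profiles[[v]]))
  }
  data.table::fwrite(long, file.path(dir, "local_profiles.csv"))
  data.table::fwrite(
    data.table::data.table(radar = local$meta$radar,
                           night = format(local$meta$night),
                           slot = local$meta$slot,
                           cloud = local$cloud, precip = local$precip),
    file.path(dir, "local_scalars.csv")
  )
  invisible(dir)
}

#' @rdname write_local_panel
#' @export
read_local_panel <- function(dir) {
  long <- data.table::fread(file.path(dir, "local_profiles.csv"))
  scal <- data.table::fread(file.path(dir, "local_scalars.csv"))
  alt <- sort(unique(long$height))
  vars <- setdiff(names(long), c("radar", "night", "slot", "height"))
  key_long <- paste(long$radar, long$night, long$slot)
  key_meta <- paste(scal$radar, scal$night, scal$slot)
  row_of <- match(key_long, key_meta)
  col_of <- match(long$height, alt)
  profiles <- lapply(vars, function(v) {
    m <- matrix(NA_real_, nrow(scal), length(alt))
    m[cbind(row_of, col_of)] <- long[[v]]
    m
  })
  names(profiles) <- vars
  list(meta = data.frame(radar = scal$radar, night = as.Date(scal$night),
                         slot = scal$slot),
       profiles = profiles, cloud = scal$cloud, precip = scal$precip,
       altitudes = alt)
}

#' Write a full synthetic dataset to disk
#'
#' Writes `vpts.csv`, `local/`, `fields/`, `truth.json` (planted phenology,
#' effect sizes, per-row anomalies; the large mode matrices are summarized by
#' shape and fingerprints) and `manifest.json` (seed, config fingerprint,
#' row counts).
#'
#' @param ds A `mig_dataset` from [generate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vpts_csv(ds$raw, file.path(dir, "vpts.csv"))
  write_local_panel(ds$local, file.path(dir, "local"))
  write_field_panel(ds$synoptic, file.path(dir, "fields"))
  truth <- list(
    effect_sizes = ds$truth$effect_sizes,
    noise_sd = ds$truth$noise_sd,
    ar_coef = ds$truth$ar_coef,
    phenology = ds$truth$phenology,
    bird_modes = ds$truth$bird_modes,
    vertical_modes = ds$truth$vertical_modes,
    truth_rows = ds$truth_rows
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  cfg <- unclass(ds$config)
  cfg$grid <- NULL
  manifest <- list(
    seed = cfg$seed,
    config_hash = fnv1a(jsonlite::toJSON(cfg, digits = NA, auto_unbox = TRUE)),
    n_raw_rows = nrow(ds$raw),
    n_nights = length(ds$synoptic$nights),
    radars = ds$radars$id
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
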