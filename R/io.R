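#' Plain-text recording container
#'
#' Writes a recording to a directory as delimited text plus a JSON
#' sidecar: `data.csv` (measurement matrix), `events.csv`,
#' `channels.csv` / `optodes.csv` (montage tables), `meta.json`
#' (kind, sampling rate, wavelengths, pairing) and, when present, one
#' `truth_<component>.csv` per ground-truth component.
#'
#' @param rec A [new_recording()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(rec$data), file.path(path, "data.csv"),
            row.names = FALSE)
  write.csv(rec$events, file.path(path, "events.csv"), row.names = FALSE)
  write.csv(rec$montage$channels, file.path(path, "channels.csv"),
            row.names = FALSE)
  write.csv(rec$montage$optodes, file.path(path, "optodes.csv"),
            row.names = FALSE)
  meta <- list(kind = rec$kind, fs_hz = rec$fs_hz,
               wavelengths = rec$montage$wavelengths,
               pairing = as.list(rec$montage$pairing))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(rec$truth)) {
    for (nm in names(rec$truth)) {
      write.csv(as.data.frame(rec$truth[[nm]]),
                file.path(path, paste0("truth_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  channels <- read.csv(file.path(path, "channels.csv"))
  optodes <- read.csv(file.path(path, "optodes.csv"))
  pairing <- unlist(meta$pairing)
  montage <- nirs_montage(channels, optodes, meta$wavelengths, pairing)
  dat <- as.matrix(read.csv(file.path(path, "data.csv"), check.names = FALSE))
  events <- read.csv(file.path(path, "events.csv"))
  if (!nrow(events)) events <- empty_events()
  truth_files <- list.files(path, pattern = "^truth_.*\\.csv$")
  truth <- NULL
  if (length(truth_files)) {
    truth <- lapply(truth_files, function(f) {
      as.matrix(read.csv(file.path(path, f), check.names = FALSE))
    })
    names(truth) <- sub("^truth_(.*)\\.csv$", "\\1", truth_files)
  }
  new_recording(dat, kind = meta$kind, fs_hz = meta$fs_hz, montage = montage,
                events = tibble::as_tibble(events), truth = truth)
}

#' Save / load a trained model as JSON
#'
#' Serialises configuration, weights, normalisation stats and seeds into
#' one text archive, reloadable with [read_model()].
#'
#' @param model A `nirs_model`.
#' @param path File path (`.json`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "vshortr-model-1",
    cfg = unclass(model$cfg),
    seed = model$seed,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), x = as.numeric(p)) else
        list(dim = NULL, x = as.numeric(p))
    }),
    norm_stats = if (!is.null(model$norm_stats))
      lapply(model$norm_stats, as.list) else NULL,
    history = if (!is.null(model$history)) as.list(model$history) else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vshortr-model-1")) {
    stop("unrecognised model archive version")
  }
  cfg <- do.call(transformer_config, obj$cfg[names(obj$cfg) != "window_len"])
  cfg$window_len <- as.integer(obj$cfg$window_len)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim)) matrix(p$x, p$dim[1], p$dim[2]) else as.numeric(p$x)
  })
  m <- structure(list(params = params, cfg = cfg,
                      seed = as.integer(obj$seed),
                      history = if (!is.null(obj$history))
                        tibble::as_tibble(obj$history) else NULL,
                      norm_stats = if (!is.null(obj$norm_stats))
                        lapply(obj$norm_stats, tibble::as_tibble) else NULL),
                 class = "nirs_model")
  m
}
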