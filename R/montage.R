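#' fNIRS montage objects
#'
#' A montage records the optode geometry and the source-detector channels of
#' an fNIRS probe: channel ids, their source and detector optodes, the
#' source-detector separation, the channel role (`"long"` ~30 mm probing
#' cortex + scalp, `"short"` ~8 mm probing scalp only), the 2-D scalp
#' coordinates of every optode (arbitrary planar units, here mm) and the
#' wavelengths measured.  The long-to-short pairing used for model targets,
#' quality control and short-channel regression is derived from geometry by
#' [pair_channels()] unless supplied explicitly.
#'
#' @param channels Data frame with columns `channel_id`, `source`,
#'   `detector`, `separation_mm`, `role` (`"long"` or `"short"`).
#' @param optodes Data frame with columns `optode_id`, `x`, `y`.
#' @param wavelengths Numeric vector of wavelengths in nm.
#' @param pairing Optional named character vector mapping each long channel
#'   id to a short channel id; computed from geometry when `NULL`.
#' @return An object of class `nirs_montage`.
#' @seealso [montage_default()], [montage_frontal20()]
#' @export
nirs_montage <- function(channels, optodes, wavelengths = c(760, 850),
                         pairing = NULL) {
  channels <- tibble::as_tibble(channels)
  optodes <- tibble::as_tibble(optodes)
  stopifnot(
    all(c("channel_id", "source", "detector", "separation_mm", "role") %in%
          names(channels)),
    all(c("optode_id", "x", "y") %in% names(optodes)),
    all(channels$role %in% c("long", "short")),
    all(channels$source %in% optodes$optode_id),
    all(channels$detector %in% optodes$optode_id),
    !anyDuplicated(channels$channel_id),
    length(wavelengths) >= 1
  )
  long_sep <- channels$separation_mm[channels$role == "long"]
  short_sep <- channels$separation_mm[channels$role == "short"]
  if (length(long_sep) && length(short_sep) &&
      min(long_sep) <= max(short_sep)) {
    stop("long-channel separations must exceed short-channel separations")
  }
  # order: long channels first, then short, stable within role
  channels <- channels[order(channels$role == "short", channels$channel_id), ]
  m <- structure(
    list(channels = channels, optodes = optodes,
         wavelengths = as.numeric(wavelengths), pairing = pairing),
    class = "nirs_montage"
  )
  if (is.null(pairing)) m$pairing <- pair_channels(m)
  validate_pairing(m)
  m
}

validate_pairing <- function(montage) {
  long_ids <- long_channels(montage)
  p <- montage$pairing
  if (!all(long_ids %in% names(p))) {
    stop("every long channel needs a paired short channel")
  }
  if (!all(p[long_ids] %in% short_channels(montage))) {
    stop("pairing maps to unknown short channels")
  }
  invisible(montage)
}

#' @export
print.nirs_montage <- function(x, ...) {
  cat(sprintf(
    "<nirs_montage> %d long + %d short channels, %d optodes, wavelengths: %s nm\n",
    length(long_channels(x)), length(short_channels(x)),
    nrow(x$optodes), paste(x$wavelengths, collapse = "/")
  ))
  invisible(x)
}

#' @rdname nirs_montage
#' @param montage A `nirs_montage`.
#' @export
long_channels <- function(montage) {
  montage$channels$channel_id[montage$channels$role == "long"]
}

#' @rdname nirs_montage
#' @export
short_channels <- function(montage) {
  montage$channels$channel_id[montage$channels$role == "short"]
}

channel_midpoints <- function(montage) {
  ch <- montage$channels
  op <- montage$optodes
  xs <- op$x[match(ch$source, op$optode_id)]
  ys <- op$y[match(ch$source, op$optode_id)]
  xd <- op$x[match(ch$detector, op$optode_id)]
  yd <- op$y[match(ch$detector, op$optode_id)]
  tibble::tibble(channel_id = ch$channel_id,
                 x = (xs + xd) / 2, y = (ys + yd) / 2)
}

#' Pair each long channel with its nearest short channel
#'
#' Assignment is by smallest Euclidean distance between channel midpoints,
#' the geometric reading of "nearest short channel".  Several long channels
#' may share one short channel.
#'
#' @param montage A [nirs_montage()].
#' @return Named character vector: `long_channel_id -> short_channel_id`.
#' @export
pair_channels <- function(montage) {
  mid <- channel_midpoints(montage)
  long_ids <- long_channels(montage)
  short_ids <- short_channels(montage)
  if (!length(short_ids)) stop("montage has no short channels to pair with")
  sm <- mid[match(short_ids, mid$channel_id), ]
  p <- vapply(long_ids, function(l) {
    lm_ <- mid[mid$channel_id == l, ]
    d <- sqrt((sm$x - lm_$x)^2 + (sm$y - lm_$y)^2)
    short_ids[which.min(d)]
  }, character(1))
  p
}

#' Default resting-state montage: 14 long + 8 short channels
#'
#' Eight dual-tip sources and eight detectors giving six prefrontal and
#' 2 x 4 temporo-parietal long channels at 30 mm, plus one 8 mm short
#' channel bundled next to every source.  Coordinates are planar scalp
#' millimetres.  Dual wavelengths 760 and 850 nm.
#'
#' @return A [nirs_montage()].
#' @export
montage_default <- function() {
  sq2 <- 8 / sqrt(2)
  src <- tibble::tibble(
    optode_id = paste0("S", 1:8),
    x = c(-45, 15, -15, 45, -115, -85, 85, 115),
    y = c(90, 90, 120, 120, 15, -15, 15, -15)
  )
  det <- tibble::tibble(
    optode_id = paste0("D", 1:8),
    x = c(-15, 45, -45, 15, -85, -115, 115, 85),
    y = c(90, 90, 120, 120, 15, -15, 15, -15)
  )
  sdet <- tibble::tibble(
    optode_id = paste0("SD", 1:8),
    x = src$x + sq2, y = src$y + sq2
  )
  long <- tibble::tibble(
    channel_id = sprintf("L%02d", 1:14),
    source = c("S1", "S2", "S2", "S3", "S3", "S4",
               "S5", "S5", "S6", "S6", "S7", "S7", "S8", "S8"),
    detector = c("D1", "D1", "D2", "D3", "D4", "D4",
                 "D5", "D6", "D5", "D6", "D7", "D8", "D7", "D8"),
    separation_mm = 30, role = "long"
  )
  short <- tibble::tibble(
    channel_id = sprintf("S%02d", 1:8),
    source = paste0("S", 1:8), detector = paste0("SD", 1:8),
    separation_mm = 8, role = "short"
  )
  nirs_montage(rbind(long, short), rbind(src, det, sdet))
}

#' Frontal montage with 20 long + 8 short channels (40 model features)
#'
#' A 4 x 4 checkerboard of sources and detectors at 30 mm spacing over the
#' frontal cortex, keeping 20 of the 24 nearest-neighbour source-detector
#' edges, plus an 8 mm short channel at every source.  This is the expanded
#' layout used to exercise montage adaptation (20 long channels x 2
#' wavelengths = 40 features).
#'
#' @return A [nirs_montage()].
#' @export
montage_frontal20 <- function() {
  grid <- expand.grid(i = 0:3, j = 0:3)
  grid$x <- (grid$i - 1.5) * 30
  grid$y <- 40 + grid$j * 30
  grid$is_source <- (grid$i + grid$j) %% 2 == 0
  grid$optode_id <- ifelse(grid$is_source,
                           paste0("S", cumsum(grid$is_source)),
                           paste0("D", cumsum(!grid$is_source)))
  edges <- list()
  for (r in seq_len(nrow(grid))) {
    for (s in seq_len(nrow(grid))) {
      if (grid$is_source[r] && !grid$is_source[s]) {
        d <- sqrt((grid$x[r] - grid$x[s])^2 + (grid$y[r] - grid$y[s])^2)
        if (abs(d - 30) < 1e-9) {
          edges[[length(edges) + 1]] <-
            data.frame(source = grid$optode_id[r], detector = grid$optode_id[s],
                       y = min(grid$y[r], grid$y[s]),
                       x = min(grid$x[r], grid$x[s]))
        }
      }
    }
  }
  edges <- do.call(rbind, edges)
  edges <- edges[order(edges$y, edges$x, edges$source, edges$detector), ]
  edges <- utils::head(edges, 20)
  long <- tibble::tibble(
    channel_id = sprintf("L%02d", seq_len(nrow(edges))),
    source = edges$source, detector = edges$detector,
    separation_mm = 30, role = "long"
  )
  srcs <- grid[grid$is_source, ]
  sq2 <- 8 / sqrt(2)
  sdet <- tibble::tibble(optode_id = paste0("SD", seq_len(nrow(srcs))),
                         x = srcs$x + sq2, y = srcs$y + sq2)
  short <- tibble::tibble(
    channel_id = sprintf("S%02d", seq_len(nrow(srcs))),
    source = srcs$optode_id, detector = sdet$optode_id,
    separation_mm = 8, role = "short"
  )
  optodes <- rbind(
    tibble::tibble(optode_id = grid$optode_id, x = grid$x, y = grid$y),
    sdet
  )
  nirs_montage(rbind(long, short), optodes)
}

#' Measurement (feature) layout of a montage
#'
#' Measurement columns are indexed by (channel, wavelength) in a fixed,
#' documented order: channels in montage order (long channels first), and
#' within each channel the wavelengths in montage order.  Column names are
#' `"<channel_id>@<wavelength>"`.
#'
#' @param montage A [nirs_montage()].
#' @param channels Optional subset of channel ids (kept in montage order).
#' @return Tibble with columns `column`, `channel_id`, `wavelength`, `role`.
#' @export
measurement_index <- function(montage, channels = NULL) {
  ch <- montage$channels
  if (!is.null(channels)) ch <- ch[ch$channel_id %in% channels, ]
  out <- tidyr::expand_grid(
    channel_id = ch$channel_id,
    wavelength = montage$wavelengths
  )
  out$role <- ch$role[match(out$channel_id, ch$channel_id)]
  out$column <- paste0(out$channel_id, "@", out$wavelength)
  out[, c("column", "channel_id", "wavelength", "role")]
}
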