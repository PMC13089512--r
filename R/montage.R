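#' Idealized 10-20 scalp montage
#'
#' Returns an idealized spherical montage following the extended 10-20 layout:
#' electrode positions are placed on the unit sphere from their nominal
#' inclination (angle from the vertex Cz) and azimuth (angle from the anterior
#' midline, positive to the right). This synthetic layout is geometrically
#' faithful enough for neighbourhood construction and topographic plotting; it
#' is not a digitized head model.
#'
#' @param channels Optional character vector selecting a subset of channels.
#' @return A tibble with columns `channel`, `x`, `y`, `z` (unit sphere,
#'   x right, y anterior, z up) and 2-D projection columns `px`, `py`.
#' @export
#' @examples
#' montage_1020(c("Oz", "Pz", "Cz"))
montage_1020 <- function(channels = NULL) {
  def <- tibble::tribble(
    ~channel, ~incl, ~azim,
    "Fp1", 72, -18,  "Fpz", 72,   0,  "Fp2", 72,  18,
    "F7",  72, -54,  "F3",  54, -27,  "Fz",  36,   0,  "F4", 54,  27,  "F8", 72, 54,
    "FC5", 57, -66,  "FC1", 27, -45,  "FC2", 27,  45,  "FC6", 57, 66,
    "T7",  72, -90,  "C3",  36, -90,  "Cz",   0,   0,  "C4", 36,  90,  "T8", 72, 90,
    "CP5", 57, -114, "CP1", 27, -135, "CP2", 27, 135,  "CP6", 57, 114,
    "P7",  72, -126, "P3",  54, -153, "Pz",  36, 180,  "P4", 54, 153,  "P8", 72, 126,
    "PO7", 72, -144, "PO3", 63, -160, "POz", 54, 180,  "PO4", 63, 160, "PO8", 72, 144,
    "O1",  72, -162, "Oz",  72, 180,  "O2",  72, 162
  )
  if (!is.null(channels)) {
    missing <- setdiff(channels, def$channel)
    abort_if(length(missing) > 0,
             paste0("unknown channel(s): ", paste(missing, collapse = ", ")))
    def <- def[match(channels, def$channel), ]
  }
  ir <- def$incl * pi / 180
  ar <- def$azim * pi / 180
  tibble::tibble(
    channel = def$channel,
    x = sin(ir) * sin(ar),
    y = sin(ir) * cos(ar),
    z = cos(ir),
    px = def$incl / 90 * sin(ar),
    py = def$incl / 90 * cos(ar)
  )
}

#' Posterior (parieto-occipital) channel subset of a montage
#'
#' Channels whose label starts with P, PO or O; the scalp region where
#' stimulus-induced alpha activity is read out.
#'
#' @param montage A montage tibble from [montage_1020()].
#' @return Character vector of channel names.
#' @export
posterior_channels <- function(montage) {
  montage$channel[grepl("^(P|PO|O)", montage$channel)]
}

#' Write / read a montage as a plain-text channel location file
#'
#' Tab-separated columns `channel`, `x`, `y`, `z` (unit-sphere Cartesian).
#'
#' @param montage A montage tibble.
#' @param path File path.
#' @return `read_montage()` returns a montage tibble (with 2-D projections
#'   recomputed); `write_montage()` returns `path` invisibly.
#' @export
write_montage <- function(montage, path) {
  readr::write_tsv(montage[, c("channel", "x", "y", "z")], path)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  abort_if(!all(c("channel", "x", "y", "z") %in% names(m)),
           "montage file must have columns channel, x, y, z")
  r_xy <- sqrt(m$x^2 + m$y^2)
  incl <- atan2(r_xy, m$z)
  az <- atan2(m$x, m$y)
  tibble::tibble(
    channel = m$channel, x = m$x, y = m$y, z = m$z,
    px = incl / (pi / 2) * sin(az),
    py = incl / (pi / 2) * cos(az)
  )
}
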