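#' Read and write contour CSV files
#'
#' Contours are stored as two-column CSV (`x_mm,y_mm`) with one header line,
#' vertices in order and no repeated closing vertex.
#'
#' @param path file path
#' @param label contour label (defaults to the file name)
#' @export
read_contour <- function(path, label = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("x_mm", "y_mm") %in% names(d)))
    stop("contour CSV needs columns x_mm, y_mm", call. = FALSE)
  if (is.null(label)) label <- sub("\\.csv$", "", basename(path))
  contour(cbind(d$x_mm, d$y_mm), label = label)
}

#' @rdname read_contour
#' @param c an `eit_contour`
#' @export
write_contour <- function(c, path) {
  v <- unclass(c)
  utils::write.csv(data.frame(x_mm = v[, 1L], y_mm = v[, 2L]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a geometry bundle directory
#'
#' A bundle holds `thorax.csv`, optional `lung_left.csv` / `lung_right.csv` /
#' `heart.csv`, and a `geometry.yaml` sidecar recording the geometry kind,
#' electrode count and belt orientation.
#'
#' @param dir bundle directory
#' @export
read_geometry <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "geometry.yaml"))
  lungs <- list()
  for (f in c("lung_left.csv", "lung_right.csv")) {
    p <- file.path(dir, f)
    if (file.exists(p)) lungs <- c(lungs, list(read_contour(p)))
  }
  hp <- file.path(dir, "heart.csv")
  thorax_geometry(read_contour(file.path(dir, "thorax.csv"), "thorax"),
                  lungs = lungs,
                  heart = if (file.exists(hp)) read_contour(hp, "heart"),
                  kind = meta$kind)
}

#' @rdname read_geometry
#' @param g a `thorax_geometry`
#' @param n_electrodes,direction belt metadata stored in the sidecar
#' @export
write_geometry <- function(g, dir, n_electrodes = 32L,
                           direction = "left-first") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_contour(g$thorax, file.path(dir, "thorax.csv"))
  for (l in g$lungs)
    write_contour(l, file.path(dir, paste0(attr(l, "label"), ".csv")))
  if (!is.null(g$heart)) write_contour(g$heart, file.path(dir, "heart.csv"))
  yaml::write_yaml(list(kind = g$kind, n_electrodes = n_electrodes,
                        direction = direction),
                   file.path(dir, "geometry.yaml"))
  invisible(dir)
}

#' Read and write voltage series CSV
#'
#' One row per frame: a `t_s` column followed by 1024 channel columns
#' (`ch0001`..), invalid channels written as `NaN`; a `scheme.yaml` sidecar
#' records electrode count, skip and amplitude.
#'
#' @param s a [voltage_series()]
#' @param path CSV path (the sidecar is written next to it)
#' @param scheme the generating [skip4_scheme()]
#' @export
write_voltage_series <- function(s, path, scheme = skip4_scheme()) {
  d <- as.data.frame(s$V)
  names(d) <- sprintf("ch%04d", seq_len(ncol(s$V)))
  d <- cbind(t_s = s$t, d)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "NaN")
  yaml::write_yaml(list(n_electrodes = scheme$n_electrodes,
                        skip = scheme$skip,
                        amplitude_mA = scheme$amplitude),
                   sub("\\.csv$", ".yaml", path))
  invisible(path)
}

#' @rdname write_voltage_series
#' @export
read_voltage_series <- function(path) {
  d <- utils::read.csv(path)
  t <- d$t_s
  V <- as.matrix(d[, -1L, drop = FALSE])
  fs <- 1 / stats::median(diff(t))
  voltage_series(V, fs = fs, t0 = t[1L])
}

#' Write and read plain-text image matrices
#'
#' Images and masks are stored as whitespace-separated numeric matrices, one
#' image row per line, row 1 = anterior.
#'
#' @param img numeric or logical matrix (or `tidal_image`)
#' @param path file path
#' @export
write_image_matrix <- function(img, path) {
  if (inherits(img, "tidal_image")) img <- img$pixels
  utils::write.table(img * 1, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_matrix
#' @export
read_image_matrix <- function(path) {
  as.matrix(utils::read.table(path))
}

#' Write a ventilation profile CSV (`band_index, vd_percent`)
#' @param p a `vent_profile`
#' @param path file path
#' @export
write_profile <- function(p, path) {
  utils::write.csv(data.frame(band_index = p$band, vd_percent = p$vd),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- utils::read.csv(path)
  structure(tibble::tibble(band = d$band_index, vd = d$vd_percent),
            class = c("vent_profile", "tbl_df", "tbl", "data.frame"))
}
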