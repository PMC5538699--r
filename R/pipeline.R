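#' Voltage series container
#'
#' Frame-by-channel EIT voltage recording. Channels follow the drive-major
#' ordering of [skip4_scheme()]; invalid channels are `NA` in every frame.
#'
#' @param V frames x channels numeric matrix
#' @param fs sampling rate in Hz
#' @param valid logical channel-validity mask
#' @param t0 time of the first frame (s)
#' @return a `voltage_series`
#' @export
voltage_series <- function(V, fs = 48, valid = NULL, t0 = 0) {
  V <- as.matrix(V)
  if (is.null(valid)) valid <- !is.na(V[1L, ])
  structure(list(V = V, t = t0 + (seq_len(nrow(V)) - 1L) / fs,
                 fs = fs, valid = valid),
            class = "voltage_series")
}

#' @export
print.voltage_series <- function(x, ...) {
  cat(sprintf("<voltage_series> %d frames x %d channels (%d valid) @ %g Hz, %.1f s\n",
              nrow(x$V), ncol(x$V), sum(x$valid), x$fs,
              nrow(x$V) / x$fs))
  invisible(x)
}

#' Difference-reference a voltage series (TD / NTD)
#'
#' Time difference: `v_diff = v - v(t_r)`; normalized time difference:
#' `v_diff = v / v(t_r) - 1`, channel-wise against the frames at reference
#' index `t_r`.
#'
#' @param s a [voltage_series()]
#' @param t_r reference frame index
#' @param method `"TD"` or `"NTD"`
#' @return the differenced `voltage_series` (attribute `reference` records
#'   `t_r` and the method)
#' @export
difference_voltages <- function(s, t_r, method = c("TD", "NTD")) {
  method <- match.arg(method)
  stopifnot(inherits(s, "voltage_series"))
  if (t_r < 1L || t_r > nrow(s$V)) stop("invalid reference frame", call. = FALSE)
  ref <- s$V[t_r, ]
  if (method == "TD") {
    D <- sweep(s$V, 2L, ref, "-")
  } else {
    bad <- which(s$valid & (is.na(ref) | ref == 0))
    if (length(bad))
      stop("division-guard error: zero reference voltage in channel(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    D <- sweep(s$V, 2L, ref, "/") - 1
  }
  out <- voltage_series(D, fs = s$fs, valid = s$valid, t0 = s$t[1L])
  attr(out, "reference") <- list(t_r = t_r, method = method)
  out
}

#' Reconstruct an image series from a differenced voltage series
#'
#' Applies the reconstruction matrix frame by frame.
#'
#' @param rm a `recon_matrix` (from [train_model()])
#' @param d a differenced [voltage_series()]
#' @return an `image_series`: list with `P` (frames x 1024 pixel matrix,
#'   row-major pixels), `t`, `grid`
#' @export
reconstruct_series <- function(rm, d) {
  stopifnot(inherits(rm, "recon_matrix"), inherits(d, "voltage_series"))
  if (sum(d$valid) != ncol(rm$R))
    stop("interface error: series has ", sum(d$valid),
         " valid channels, matrix expects ", ncol(rm$R), call. = FALSE)
  P <- d$V[, d$valid, drop = FALSE] %*% t(rm$R)
  structure(list(P = P, t = d$t, grid = rm$grid), class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %d frames of %dx%d\n", nrow(x$P),
              x$grid$n, x$grid$n))
  invisible(x)
}

#' Mean in-body pixel signal of an image series
#' @param z an `image_series`
#' @export
global_signal <- function(z) {
  body <- as.vector(t(z$grid$body_mask))
  rowMeans(z$P[, body, drop = FALSE])
}

#' Detect end-inspiration and end-expiration instants
#'
#' Smooths the global signal with a moving average and takes local maxima as
#' end-inspiration (`t_in`) and local minima as end-expiration (`t_ex`),
#' enforcing a minimum separation between same-kind extrema.
#'
#' @param signal per-frame scalar series (e.g. [global_signal()] of an image
#'   series, where inspiration increases the signal)
#' @param fs sampling rate (Hz)
#' @param nominal_period expected breath period (s); peaks closer than
#'   `min_sep_frac` of it are merged
#' @param smooth_window moving-average window (s)
#' @param min_sep_frac minimum extremum separation as a fraction of
#'   `nominal_period`
#' @return a `breath_markers` list with integer frame indices `t_in`, `t_ex`
#' @export
detect_breath_phases <- function(signal, fs = 48, nominal_period = 10,
                                 smooth_window = 0.5, min_sep_frac = 0.6) {
  if (diff(range(signal)) < 1e-12)
    stop("detection error: flat signal", call. = FALSE)
  w <- max(1L, round(smooth_window * fs))
  if (w %% 2L == 0L) w <- w + 1L
  pad <- (w - 1L) %/% 2L
  xs <- stats::filter(c(rep(signal[1L], pad), signal, rep(signal[length(signal)], pad)),
                      rep(1 / w, w), sides = 2L)
  xs <- as.numeric(xs)[pad + seq_along(signal)]
  min_sep <- round(min_sep_frac * nominal_period * fs)
  t_in <- find_extrema(xs, min_sep, maxima = TRUE)
  t_ex <- find_extrema(xs, min_sep, maxima = FALSE)
  if (!length(t_in) || !length(t_ex))
    stop("detection error: no breath extrema found", call. = FALSE)
  structure(list(t_in = t_in, t_ex = t_ex), class = "breath_markers")
}

# interior local extrema with minimum separation; the stronger extremum wins
# a conflict (boundary frames are never extrema: a series ending mid-slope
# must not contribute a phase marker)
find_extrema <- function(x, min_sep, maxima = TRUE) {
  if (!maxima) x <- -x
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer()
  for (c_ in cand) {
    if (all(abs(c_ - keep) >= min_sep)) keep <- c(keep, c_)
  }
  sort(keep)
}

#' Tidal image from an image series and breath markers
#'
#' Pairs each end-inspiration with the nearest following end-expiration,
#' forms the breath-wise differences `Z(t_in) - Z(t_ex)` and averages them
#' into a robust tidal image.
#'
#' @param z an `image_series`
#' @param b a [detect_breath_phases()] result
#' @return a `tidal_image`: list with `pixels` (n x n matrix), `grid`,
#'   `masks_applied`, `n_breaths`
#' @export
tidal_image <- function(z, b) {
  pairs <- pair_breaths(b)
  if (!nrow(pairs)) stop("pairing error: no complete breath", call. = FALSE)
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    z$P[pairs[k, 1L], ] - z$P[pairs[k, 2L], ]
  }, numeric(ncol(z$P)))
  structure(list(pixels = pixvec_to_image(rowMeans(d), z$grid$n),
                 grid = z$grid, masks_applied = "none",
                 n_breaths = nrow(pairs)),
            class = "tidal_image")
}

pair_breaths <- function(b) {
  out <- NULL
  for (ti in b$t_in) {
    te <- b$t_ex[b$t_ex > ti]
    if (length(te)) out <- rbind(out, c(ti, te[1L]))
  }
  if (is.null(out)) out <- matrix(integer(), 0L, 2L)
  out
}

#' @export
print.tidal_image <- function(x, ...) {
  cat(sprintf("<tidal_image> %dx%d, masks: %s, %d breath(s), max %.3g\n",
              nrow(x$pixels), ncol(x$pixels), x$masks_applied, x$n_breaths,
              max(x$pixels)))
  invisible(x)
}

#' Zero pixels below a fraction of the tidal-image maximum
#'
#' Excludes pixels below `frac` of the image maximum (default 10%) to remove
#' non-ventilation artifacts; negative pixels fall below any positive
#' threshold and are zeroed.
#'
#' @param t a `tidal_image`
#' @param frac threshold fraction of the maximum
#' @export
threshold_mask <- function(t, frac = 0.10) {
  stopifnot(inherits(t, "tidal_image"))
  if (all(t$pixels == 0)) stop("invalid argument: all-zero image", call. = FALSE)
  thr <- frac * max(t$pixels)
  px <- t$pixels
  px[px < thr] <- 0
  t$pixels <- px
  t$masks_applied <- "threshold"
  t
}

#' Restrict a tidal image to pulmonary pixels
#'
#' Zeroes all pixels outside the grid's lung mask.
#'
#' @param t a `tidal_image`
#' @param grid a `pixel_grid` carrying the lung mask (defaults to the image's
#'   own grid)
#' @export
lung_select <- function(t, grid = t$grid) {
  stopifnot(inherits(t, "tidal_image"))
  if (!any(grid$lung_mask)) stop("invalid argument: empty lung mask", call. = FALSE)
  px <- t$pixels
  px[!grid$lung_mask] <- 0
  t$pixels <- px
  t$masks_applied <- "lung"
  t
}

#' Voltage recording to tidal ventilation image
#'
#' The full post-processing chain: provisional time-difference referencing
#' against the first frame, frame-wise reconstruction, breath-phase detection
#' on the mean in-body signal, re-referencing against the first detected
#' end-expiration frame with the requested method, final reconstruction and
#' breath-averaged tidal image.
#'
#' @param s a [voltage_series()]
#' @param rm a `recon_matrix`
#' @param method voltage referencing, `"TD"` or `"NTD"` (should match the
#'   referencing the matrix was trained for)
#' @param nominal_period expected breath period (s)
#' @return list with `tidal` (the `tidal_image`), `markers`, `t_r`, `images`
#'   (the final `image_series`)
#' @export
ventilation_pipeline <- function(s, rm, method = rm$config$reference,
                                 nominal_period = 10) {
  z0 <- reconstruct_series(rm, difference_voltages(s, 1L, "TD"))
  mk0 <- detect_breath_phases(global_signal(z0), fs = s$fs,
                              nominal_period = nominal_period)
  t_r <- mk0$t_ex[1L]
  z <- reconstruct_series(rm, difference_voltages(s, t_r, method))
  mk <- detect_breath_phases(global_signal(z), fs = s$fs,
                             nominal_period = nominal_period)
  list(tidal = tidal_image(z, mk), markers = mk, t_r = t_r, images = z)
}
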