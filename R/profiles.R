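#' Anteroposterior ventilation profile
#'
#' Partitions the image rows into `n_regions` equal horizontal bands
#' (anterior first), sums the masked pixel values per band and normalizes the
#' result to 100%. Works for the native 32x32 EIT images and for
#' high-resolution reference aeration images alike.
#'
#' @param img image matrix (rows anterior to posterior) or a `tidal_image`
#' @param region_mask logical matrix of pixels to include (defaults to all)
#' @param n_regions number of horizontal bands (default 32)
#' @return a `vent_profile` tibble with columns `band` and `vd` (percent)
#' @export
ap_profile <- function(img, region_mask = NULL, n_regions = 32L) {
  if (inherits(img, "tidal_image")) img <- img$pixels
  nr <- nrow(img)
  if (nr < n_regions) stop("image has fewer rows than regions", call. = FALSE)
  if (nr %% n_regions != 0L)
    stop("image rows must be divisible by n_regions", call. = FALSE)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nr, ncol(img))
  stopifnot(all(dim(region_mask) == dim(img)))
  vals <- img
  vals[!region_mask] <- 0
  rows_per_band <- nr %/% n_regions
  band <- rep(seq_len(n_regions), each = rows_per_band)
  sums <- as.vector(rowsum(rowSums(vals), band))
  tot <- sum(sums)
  if (tot <= 0) stop("invalid argument: masked image sum is not positive", call. = FALSE)
  structure(tibble::tibble(band = seq_len(n_regions), vd = 100 * sums / tot),
            class = c("vent_profile", "tbl_df", "tbl", "data.frame"))
}

#' Root-mean-square error between two ventilation profiles (percent points)
#'
#' @param a,b `vent_profile`s (or plain numeric vectors of band percentages)
#' @export
profile_rmse <- function(a, b) {
  va <- profile_values(a); vb <- profile_values(b)
  if (length(va) != length(vb))
    stop("interface error: profile lengths differ", call. = FALSE)
  sqrt(mean((va - vb)^2))
}

profile_values <- function(p) {
  if (inherits(p, "data.frame")) p$vd else as.numeric(p)
}

#' Pooled Pearson correlation of reference vs EIT band values
#'
#' Pools (subject, band) pairs and computes the product-moment correlation.
#' By default the agreement filter is applied first: only pairs where at
#' least one of the two values is greater than zero are retained.
#'
#' @param pairs data frame with columns `ref` and `eit` (band percentages)
#' @param filter_zero drop pairs where both values are zero (or negative)
#' @export
pooled_pearson <- function(pairs, filter_zero = TRUE) {
  stopifnot(all(c("ref", "eit") %in% names(pairs)))
  d <- pairs
  if (filter_zero) d <- d[d$ref > 0 | d$eit > 0, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(d$ref) == 0 || stats::sd(d$eit) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(d$ref, d$eit)
}

#' Bland-Altman agreement with median bias and 95% quantile limits
#'
#' Differences `eit - ref` are computed over the retained pairs (at least one
#' of the two values positive), the bias is their median and the limits of
#' agreement are the 2.5th and 97.5th percentiles, using linear interpolation
#' between order statistics (quantile type 6).
#'
#' @param pairs data frame with columns `ref` and `eit`
#' @return one-row tibble: `bias`, `loa_lower`, `loa_upper`, `n`
#' @export
bland_altman <- function(pairs) {
  stopifnot(all(c("ref", "eit") %in% names(pairs)))
  d <- pairs[pairs$ref > 0 | pairs$eit > 0, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("invalid argument: fewer than 3 retained pairs", call. = FALSE)
  diffs <- d$eit - d$ref
  q <- stats::quantile(diffs, c(0.025, 0.975), type = 6, names = FALSE)
  tibble::tibble(bias = stats::median(diffs),
                 loa_lower = q[1L], loa_upper = q[2L], n = length(diffs))
}

#' 2D correlation between an EIT tidal image and a reference aeration image
#'
#' The reference image (any resolution over the same bounding box) is
#' downsampled to the EIT grid by block averaging; the Pearson correlation is
#' computed over in-body pixels.
#'
#' @param eit a `tidal_image` (or 32x32 matrix)
#' @param ref reference image matrix (rows anterior to posterior), resolution
#'   an integer multiple of the EIT grid
#' @param grid `pixel_grid` providing the body mask (defaults to the tidal
#'   image's grid)
#' @export
image_correlation_2d <- function(eit, ref, grid = NULL) {
  if (inherits(eit, "tidal_image")) {
    if (is.null(grid)) grid <- eit$grid
    eit <- eit$pixels
  }
  if (is.null(grid)) stop("grid required", call. = FALSE)
  ref32 <- block_mean(ref, nrow(eit))
  a <- eit[grid$body_mask]
  b <- ref32[grid$body_mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant image inside mask", call. = FALSE)
  stats::cor(a, b)
}

#' Block-average an image down to n x n
#' @param img matrix whose dimensions are multiples of `n`
#' @param n output resolution
#' @export
block_mean <- function(img, n) {
  f <- nrow(img) / n
  if (f != round(f) || ncol(img) %% n != 0L)
    stop("image resolution must be a multiple of the target", call. = FALSE)
  rows <- rep(seq_len(n), each = f)
  cols <- rep(seq_len(n), each = ncol(img) / n)
  t(rowsum(t(rowsum(img, rows)), cols)) / (f * (ncol(img) / n))
}
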