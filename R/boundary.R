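#' Project a pose-normalized cloud to a binary occupancy image
#'
#' Half-open binning: pixel `(i, j)` (0-based) collects points with
#' `i = floor((x - x_min) / dx_img)`, and is black when at least one projected
#' point falls in it. The image covers the full x/y range of the cloud.
#'
#' @param cloud a pose-normalized `point_cloud` (stage `P3`).
#' @param dx_img,dy_img pixel resolution in mm (default 3; distinct from the
#'   Stage-8 resampling grid spacing, which happens to share the value).
#' @return an object of class `binary_projection_image` with fields `pixels`
#'   (logical matrix, rows = x bins, cols = y bins), `dx_img`, `dy_img`,
#'   `x_min`, `y_min`, `i_max`, `j_max`.
#' @export
project_to_binary <- function(cloud, dx_img = 3, dy_img = 3) {
  pts <- cloud$points
  if (length(unique(pts[, 1])) < 2L || length(unique(pts[, 2])) < 2L)
    stop("need at least 2 distinct x and y values to project")
  x_min <- min(pts[, 1]); y_min <- min(pts[, 2])
  i <- floor((pts[, 1] - x_min) / dx_img)
  j <- floor((pts[, 2] - y_min) / dy_img)
  i_max <- max(i); j_max <- max(j)
  pix <- matrix(FALSE, i_max + 1L, j_max + 1L)
  pix[cbind(i + 1L, j + 1L)] <- TRUE
  structure(list(pixels = pix, dx_img = dx_img, dy_img = dy_img,
                 x_min = x_min, y_min = y_min, i_max = i_max, j_max = j_max),
            class = "binary_projection_image")
}

#' @export
print.binary_projection_image <- function(x, ...) {
  cat(sprintf("<binary_projection_image: %d x %d px (%.3g x %.3g mm), %d black>\n",
              nrow(x$pixels), ncol(x$pixels), x$dx_img, x$dy_img,
              sum(x$pixels)))
  invisible(x)
}

#' Discrete width function of a binary projection image
#'
#' The width of the black region along y at each discrete x position:
#' the black-pixel count of column `i` times the y pixel resolution.
#'
#' @param img a `binary_projection_image`.
#' @return an object of class `width_profile` with fields `x` (bin centres,
#'   mm), `w_d` (widths, mm), and empty fit slots.
#' @export
width_function <- function(img) {
  w_d <- rowSums(img$pixels) * img$dy_img
  x <- img$x_min + (seq_len(nrow(img$pixels)) - 0.5) * img$dx_img
  structure(list(x = x, w_d = w_d, coefficients = NULL,
                 domain = range(x), order = NULL),
            class = "width_profile")
}

#' Fit a polynomial width model
#'
#' Least-squares polynomial fit of the discrete width function, performed on
#' an abscissa normalized to `[-1, 1]` for conditioning (a raw 10th-order fit
#' on mm abscissas is numerically hostile). Coefficients are stored on the
#' normalized abscissa.
#'
#' @param profile a `width_profile`.
#' @param order polynomial order (default 10).
#' @return the profile with `coefficients`, `order` and `domain` filled in.
#' @export
fit_width_polynomial <- function(profile, order = 10) {
  x <- profile$x
  if (length(x) < order + 1L)
    stop("insufficient columns for a polynomial fit of order ", order)
  s <- normalize_abscissa(x, profile$domain)
  V <- outer(s, 0:order, "^")
  fit <- qr(V, LAPACK = TRUE)
  profile$coefficients <- qr.coef(fit, profile$w_d)
  profile$coefficients[is.na(profile$coefficients)] <- 0
  profile$order <- order
  profile
}

normalize_abscissa <- function(x, domain) {
  mid <- mean(domain)
  half <- diff(domain) / 2
  (x - mid) / half
}

#' Evaluate the fitted width polynomial
#'
#' @param profile a fitted `width_profile`.
#' @param x positions in mm.
#' @return fitted widths in mm.
#' @export
eval_width_polynomial <- function(profile, x) {
  if (is.null(profile$coefficients)) stop("profile has no fitted polynomial")
  s <- normalize_abscissa(x, profile$domain)
  # Horner evaluation
  cf <- rev(profile$coefficients)
  out <- rep(0, length(s))
  for (c_i in cf) out <- out * s + c_i
  out
}

#' Locate the back boundaries from the width profile
#'
#' The neck boundary is the interior local minimum of the fitted width
#' polynomial with the smallest width value inside the cranial fraction of
#' the x-range (upper x), and the breech boundary the corresponding minimum
#' inside the caudal fraction (lower x). When a window contains no interior
#' minimum the corresponding domain end is returned with a warning.
#'
#' @param profile a fitted `width_profile`.
#' @param cranial_frac fraction of the x-range, from the cranial end, searched
#'   for the neck minimum (default 0.4).
#' @param caudal_frac fraction searched for the breech minimum (default 0.3).
#' @return named numeric `c(x_neck, x_breech)` in mm, with `x_breech < x_neck`.
#' @export
find_back_boundaries <- function(profile, cranial_frac = 0.4,
                                 caudal_frac = 0.3) {
  dom <- profile$domain
  xs <- seq(dom[1], dom[2], length.out = max(512L, 4L * length(profile$x)))
  w <- eval_width_polynomial(profile, xs)
  dw <- diff(w)
  # interior local minima: derivative sign change - to +
  min_ix <- which(dw[-1] > 0 & dw[-length(dw)] < 0) + 1L
  x_min_loc <- xs[min_ix]
  w_min_loc <- w[min_ix]
  rng <- diff(dom)

  pick <- function(lo, hi, fallback, side) {
    inwin <- x_min_loc >= lo & x_min_loc <= hi
    if (!any(inwin)) {
      warning(sprintf("no interior width minimum in the %s window; falling back to the domain end", side))
      return(fallback)
    }
    cand_x <- x_min_loc[inwin]
    cand_w <- w_min_loc[inwin]
    cand_x[which.min(cand_w)]
  }
  x_neck <- pick(dom[2] - cranial_frac * rng, dom[2], dom[2], "cranial")
  x_breech <- pick(dom[1], dom[1] + caudal_frac * rng, dom[1], "caudal")
  c(x_neck = x_neck, x_breech = x_breech)
}

#' Crop the back-only point cloud
#'
#' Keeps the points with `x_breech <= x <= x_neck` over the full y range,
#' excluding breech, neck and occipital surfaces.
#'
#' @param cloud a pose-normalized `point_cloud` (stage `P3`).
#' @param x_neck,x_breech boundaries in mm (`x_breech < x_neck`).
#' @return an object of class `back_crop` with fields `x_neck`, `x_breech`
#'   and `cropped` (a `point_cloud`, stage tag `P4`).
#' @export
crop_back <- function(cloud, x_neck, x_breech) {
  if (!(x_breech < x_neck)) stop("x_breech must be below x_neck")
  keep <- cloud$points[, 1] >= x_breech & cloud$points[, 1] <= x_neck
  if (!any(keep)) stop("degenerate crop")
  structure(list(x_neck = x_neck, x_breech = x_breech,
                 cropped = subset_cloud(cloud, keep, stage_tag = "P4")),
            class = "back_crop")
}

#' Dump a width profile as CSV (debug aid)
#'
#' @param profile a `width_profile` (fitted or not).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_width_profile_csv <- function(profile, path) {
  d <- data.frame(x = profile$x, w_d = profile$w_d)
  if (!is.null(profile$coefficients))
    d$w_y <- eval_width_polynomial(profile, profile$x)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
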