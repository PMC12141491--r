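#' Analytic circularity of an ellipse
#'
#' `4 * pi * Area / Perimeter^2` with area `pi * a * b` and the perimeter
#' given by Ramanujan's second approximation,
#' `P = pi (a + b) (1 + 3h / (10 + sqrt(4 - 3h)))`, `h = ((a-b)/(a+b))^2`.
#' Equals 1 for a circle and decreases monotonically toward 0 as the axis
#' ratio grows.
#'
#' @param a Semi-major axis, > 0.
#' @param b Semi-minor axis, `0 < b <= a`.
#' @return Circularity in `(0, 1]` (vectorized).
#' @export
ellipse_circularity <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("axes must be positive")
  if (any(b > a)) stop("require a >= b")
  p <- ellipse_perimeter(a, b)
  4 * pi * (pi * a * b) / p^2
}

#' Ramanujan-II ellipse perimeter
#' @param a,b Semi-axes, > 0.
#' @return Perimeter (vectorized).
#' @export
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Configuration for the synthetic chloroplast scene generator
#'
#' Scenes are fields of ovoid-to-spherical objects (filled ellipses) with
#' known analytic shape, rendered as a grayscale fluorescence image plus a
#' true label mask.
#'
#' @param image_shape_px `c(rows, cols)` of the image.
#' @param pixel_size_um Isotropic pixel size in micrometers.
#' @param n_objects Number of objects, >= 0.
#' @param axis_ratio Either a single number >= 1 (fixed major/minor ratio) or
#'   a function `n -> n ratios >= 1`.
#' @param mean_radius_um Mean equivalent radius `sqrt(a*b)` in micrometers,
#'   > 0.
#' @param radius_cv Coefficient of variation of the (lognormal) equivalent
#'   radius (default 0.15).
#' @param intensity Object fluorescence on a 0-1 scale (default 0.8).
#' @param blur_sigma_px Gaussian optical blur applied to the rendered image
#'   (default 1).
#' @param noise_model `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise SD on the 0-1 scale (ignored for Poisson).
#' @param poisson_peak Expected photon count at intensity 1 for the Poisson
#'   model (default 200).
#' @param min_separation_px Minimum gap between object boundaries (via
#'   bounding circles); set negative/`allow_touching = TRUE` to permit
#'   overlap.
#' @param allow_touching If TRUE, objects are placed without separation
#'   checks.
#' @param seed RNG seed.
#' @return A list of class `image_gen_config`.
#' @export
image_gen_config <- function(image_shape_px = c(512, 512),
                             pixel_size_um = 0.2,
                             n_objects = 30,
                             axis_ratio = 1.3,
                             mean_radius_um = 3,
                             radius_cv = 0.15,
                             intensity = 0.8,
                             blur_sigma_px = 1,
                             noise_model = c("gaussian", "poisson"),
                             noise_sd = 0.01,
                             poisson_peak = 200,
                             min_separation_px = 3,
                             allow_touching = FALSE,
                             seed = NULL) {
  if (n_objects < 0) stop("n_objects must be >= 0")
  if (mean_radius_um <= 0) stop("mean_radius_um must be > 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (is.numeric(axis_ratio) && any(axis_ratio < 1))
    stop("axis ratios must be >= 1")
  structure(list(image_shape_px = image_shape_px,
                 pixel_size_um = pixel_size_um, n_objects = n_objects,
                 axis_ratio = axis_ratio, mean_radius_um = mean_radius_um,
                 radius_cv = radius_cv, intensity = intensity,
                 blur_sigma_px = blur_sigma_px,
                 noise_model = match.arg(noise_model),
                 noise_sd = noise_sd, poisson_peak = poisson_peak,
                 min_separation_px = min_separation_px,
                 allow_touching = allow_touching, seed = seed),
            class = "image_gen_config")
}

#' Generate a synthetic chloroplast scene with analytic ground truth
#'
#' Places `n_objects` ellipses (sampled radius, axis ratio and orientation)
#' by rejection sampling under the minimum-separation constraint, rasterizes
#' them into an intensity image (optical blur + noise) and a clean label
#' mask, and attaches per-object analytic truth: center, axes, orientation,
#' area `pi*a*b`, Ramanujan perimeter, and circularity.
#'
#' @param cfg An [image_gen_config()].
#' @return A list of class `labeled_scene`: `image` (numeric matrix on a 0-1
#'   scale), `mask` (integer label matrix, background 0), `truth` (data
#'   frame: `label`, `cx_px`, `cy_px`, `a_px`, `b_px`, `theta`, `area_px2`,
#'   `perimeter_px`, `circularity`, `area_um2`), `pixel_size_um`.
#' @export
gen_chloroplast_image <- function(cfg) {
  stopifnot(inherits(cfg, "image_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nr <- cfg$image_shape_px[1L]
  nc <- cfg$image_shape_px[2L]
  n <- cfg$n_objects
  mask <- matrix(0L, nr, nc)
  img <- matrix(0, nr, nc)
  truth <- data.frame()
  if (n > 0) {
    r_px <- cfg$mean_radius_um / cfg$pixel_size_um
    sdlog <- sqrt(log(1 + cfg$radius_cv^2))
    radii <- stats::rlnorm(n, meanlog = log(r_px) - sdlog^2 / 2, sdlog = sdlog)
    q <- if (is.function(cfg$axis_ratio)) cfg$axis_ratio(n)
         else rep(cfg$axis_ratio, length.out = n)
    if (any(q < 1)) stop("axis ratios must be >= 1")
    a <- radii * sqrt(q)
    b <- radii / sqrt(q)
    theta <- runif(n, 0, pi)
    cx <- numeric(n); cy <- numeric(n)
    placed <- 0L
    tries <- 0L
    max_tries <- 400L * n
    while (placed < n && tries < max_tries) {
      tries <- tries + 1L
      i <- placed + 1L
      x <- runif(1, 1 + a[i], nr - a[i])
      y <- runif(1, 1 + a[i], nc - a[i])
      ok <- TRUE
      if (!cfg$allow_touching && placed > 0L) {
        j <- seq_len(placed)
        d2 <- (cx[j] - x)^2 + (cy[j] - y)^2
        ok <- all(d2 >= (a[j] + a[i] + cfg$min_separation_px)^2)
      }
      if (ok) {
        cx[i] <- x; cy[i] <- y
        placed <- i
      }
    }
    if (placed < n)
      stop(sprintf("could only place %d of %d objects at the requested separation",
                   placed, n))
    for (i in seq_len(n)) {
      ir <- max(1L, floor(cx[i] - a[i] - 1)):min(nr, ceiling(cx[i] + a[i] + 1))
      ic <- max(1L, floor(cy[i] - a[i] - 1)):min(nc, ceiling(cy[i] + a[i] + 1))
      dx <- outer(ir - cx[i], rep(1, length(ic)))
      dy <- outer(rep(1, length(ir)), ic - cy[i])
      u <- dx * cos(theta[i]) + dy * sin(theta[i])
      v <- -dx * sin(theta[i]) + dy * cos(theta[i])
      inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
      mask[ir, ic][inside] <- i
      img[ir, ic][inside] <- cfg$intensity
    }
    truth <- data.frame(
      label = seq_len(n), cx_px = cx, cy_px = cy, a_px = a, b_px = b,
      theta = theta, area_px2 = pi * a * b,
      perimeter_px = ellipse_perimeter(a, b),
      circularity = ellipse_circularity(a, b),
      area_um2 = pi * a * b * cfg$pixel_size_um^2)
  }
  if (cfg$blur_sigma_px > 0)
    img <- gaussian_blur(img, cfg$blur_sigma_px)
  if (cfg$noise_model == "gaussian") {
    if (cfg$noise_sd > 0)
      img <- img + rnorm(length(img), sd = cfg$noise_sd)
  } else {
    img <- rpois(length(img), lambda = pmax(img, 0) * cfg$poisson_peak) /
      cfg$poisson_peak
    img <- matrix(img, nr, nc)
  }
  structure(list(image = img, mask = mask, truth = truth,
                 pixel_size_um = cfg$pixel_size_um),
            class = "labeled_scene")
}

# separable Gaussian blur with zero padding
gaussian_blur <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    out <- stats::filter(c(rep(0, r), v, rep(0, r)), k, sides = 2)
    as.numeric(out[(r + 1):(length(v) + r)])
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(m2, 1L, conv1))
}
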