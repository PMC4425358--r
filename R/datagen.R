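#' Container for a patch dataset
#'
#' @param Y `N x D` matrix of observed patches (rows are vectorized patches).
#' @param S_true optional `N x H` generating latents.
#' @param W_true optional `D x H` generating dictionary.
#' @param k_true optional integer vector: ground-truth component count per patch.
#' @param Y_clean optional noise-free patches.
#' @param meta named list of provenance (generator, seed, parameters).
#' @return object of class `ssmca_databatch`.
#' @export
databatch <- function(Y, S_true = NULL, W_true = NULL, k_true = NULL,
                      Y_clean = NULL, meta = list()) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 1 || ncol(Y) < 1 || any(!is.finite(Y)))
    stop("Y must be a finite matrix with N >= 1, D >= 1")
  if (!is.null(k_true)) {
    if (length(k_true) != nrow(Y) || any(k_true < 0))
      stop("k_true must be nonnegative, one entry per patch")
  }
  structure(list(Y = Y, S_true = S_true, W_true = W_true,
                 k_true = k_true, Y_clean = Y_clean, meta = meta),
            class = "ssmca_databatch")
}

#' @export
print.ssmca_databatch <- function(x, ...) {
  cat(sprintf("ssmca data batch: N = %d patches, D = %d pixels (%s)\n",
              nrow(x$Y), ncol(x$Y),
              if (is.null(x$meta$generator)) "unknown origin" else x$meta$generator))
  if (!is.null(x$k_true))
    cat("  ground-truth component counts: ",
        paste(names(table(x$k_true)), table(x$k_true), sep = ":", collapse = " "),
        "\n")
  invisible(x)
}

#' Model-generated overlapping-bars benchmark data
#'
#' The classic bars test: the generating dictionary holds `H/2` horizontal and
#' `H/2` vertical single-pixel-wide bars on a `grid x grid` patch, each column
#' normalized to sum `D = grid^2` so the slab values carry all intensity
#' variation. Latents are drawn from the spike-and-slab prior and rendered
#' through the max; iid Gaussian noise is added. With the defaults each patch
#' contains two bars on average.
#'
#' @param H number of latents (even, `H/2 <= grid`).
#' @param grid patch side length; `D = grid^2`.
#' @param pi spike probability (default `2/H`: two active bars on average).
#' @param mu_pr,sigma_pr slab mean and sd of the generating prior.
#' @param sigma observation noise sd.
#' @param N number of patches.
#' @param seed integer seed; the batch is byte-identical for equal seeds.
#' @return [databatch()] with `S_true`, `W_true`, `k_true` attached.
#' @export
generate_bars <- function(H = 10, grid = 5, pi = 2 / H, mu_pr = 2,
                          sigma_pr = 0.5, sigma = 2, N = 2000, seed = NULL) {
  if (H %% 2 != 0) stop("H must be even (half horizontal, half vertical bars)")
  if (H / 2 > grid) stop("H/2 bars per orientation cannot exceed grid size")
  D <- grid * grid
  W <- matrix(0, D, H)
  px <- matrix(seq_len(D), grid, grid)  # pixel index by (row, col)
  for (i in seq_len(H / 2)) {
    W[px[i, ], i] <- 1                  # horizontal bar in row i
    W[px[, i], H / 2 + i] <- 1          # vertical bar in column i
  }
  W <- normalize_dictionary(W)
  with_seed(seed, {
    pr <- sample_prior(model_params(W, sigma, pi, mu_pr, sigma_pr,
                                    normalize = FALSE), n = N)
    Yc <- render(pr$s, W)
    Y <- Yc + matrix(rnorm(N * D, 0, sigma), N, D)
    databatch(Y, S_true = pr$s, W_true = W,
              k_true = rowSums(pr$s != 0), Y_clean = Yc,
              meta = list(generator = "bars", seed = seed, H = H, grid = grid,
                          pi = pi, mu_pr = mu_pr, sigma_pr = sigma_pr,
                          sigma = sigma, N = N))
  })
}

# distance from pixel centers to a segment; used by the stroke rasterizer
.seg_dist <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx * vx + vy * vy
  if (L2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / L2))
  sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
}

# TRUE for every patch-window containing at least one TRUE pixel of M
.window_any <- function(M, patch) {
  n1 <- nrow(M) - patch + 1
  n2 <- ncol(M) - patch + 1
  I <- matrix(0, nrow(M) + 1, ncol(M) + 1)
  I[-1, -1] <- t(apply(apply(M, 2, cumsum), 1, cumsum))
  r <- seq_len(n1); cc <- seq_len(n2)
  (I[r + patch, cc + patch, drop = FALSE] - I[r, cc + patch, drop = FALSE] -
     I[r + patch, cc, drop = FALSE] + I[r, cc, drop = FALSE]) > 0
}

#' Occluding-strokes image dataset with ground-truth complexity labels
#'
#' Draws `n_strokes` opaque strokes on a square canvas in painter's order
#' (later strokes overwrite earlier ones -- true occlusion, not the max rule
#' of the model), cuts out every overlapping `patch x patch` window (stride
#' 1), adds iid Gaussian noise independently per patch, and labels each
#' window with the number of distinct strokes *visible* in its clean pixels.
#' Windows with more than `max_k` visible strokes are discarded.
#'
#' Each stroke has an integer intensity in `intensity_range`, an integer
#' width in `width_range`, a uniform start point and orientation, and an
#' integer length uniform in `len_range`; a pixel belongs to a stroke when
#' its center lies within width/2 of the stroke's center segment.
#'
#' @param canvas canvas side length in pixels.
#' @param n_strokes number of strokes drawn.
#' @param patch window side length.
#' @param noise_sigma sd of the additive per-patch noise.
#' @param seed integer seed.
#' @param len_range,width_range,intensity_range stroke geometry/intensity.
#' @param max_k windows with more visible strokes than this are dropped.
#' @return [databatch()] with `k_true` and `Y_clean`; `meta$n_discarded`
#'   records how many windows were removed.
#' @export
generate_strokes <- function(canvas = 256, n_strokes = 300, patch = 9,
                             noise_sigma = 25, seed = NULL,
                             len_range = c(5, 30), width_range = c(2, 4),
                             intensity_range = c(1, 255), max_k = 5) {
  if (patch > canvas) stop("patch must not exceed canvas")
  with_seed(seed, {
    img <- matrix(0, canvas, canvas)
    ids <- matrix(0L, canvas, canvas)
    if (n_strokes > 0) {
      x0 <- runif(n_strokes, 1, canvas)
      y0 <- runif(n_strokes, 1, canvas)
      ang <- runif(n_strokes, 0, 2 * pi)
      len <- sample(len_range[1]:len_range[2], n_strokes, replace = TRUE)
      wid <- sample(width_range[1]:width_range[2], n_strokes, replace = TRUE)
      inten <- sample(intensity_range[1]:intensity_range[2], n_strokes,
                      replace = TRUE)
      for (i in seq_len(n_strokes)) {
        x1 <- min(canvas, max(1, x0[i] + len[i] * cos(ang[i])))
        y1 <- min(canvas, max(1, y0[i] + len[i] * sin(ang[i])))
        half <- wid[i] / 2
        rr <- max(1, floor(min(x0[i], x1) - half - 1)):
              min(canvas, ceiling(max(x0[i], x1) + half + 1))
        cc <- max(1, floor(min(y0[i], y1) - half - 1)):
              min(canvas, ceiling(max(y0[i], y1) + half + 1))
        pg <- expand.grid(r = rr, c = cc)
        d <- .seg_dist(pg$r, pg$c, x0[i], y0[i], x1, y1)
        hit <- d <= half
        if (any(hit)) {
          lin <- pg$r[hit] + (pg$c[hit] - 1) * canvas
          img[lin] <- inten[i]   # opaque overwrite: painter's rule
          ids[lin] <- i
        }
      }
    }
    nw <- canvas - patch + 1
    kw <- matrix(0L, nw, nw)
    for (i in unique(ids[ids > 0L]))
      kw <- kw + .window_any(ids == i, patch)
    Yc <- .extract_patches(img, patch)
    k <- as.vector(kw)
    keep <- k <= max_k
    Yc <- Yc[keep, , drop = FALSE]
    k <- k[keep]
    Y <- Yc + matrix(rnorm(length(Yc), 0, noise_sigma), nrow(Yc), ncol(Yc))
    databatch(Y, k_true = k, Y_clean = Yc,
              meta = list(generator = "strokes", seed = seed, canvas = canvas,
                          n_strokes = n_strokes, patch = patch,
                          noise_sigma = noise_sigma, len_range = len_range,
                          width_range = width_range,
                          intensity_range = intensity_range, max_k = max_k,
                          n_discarded = sum(!keep),
                          stroke_intensities = if (n_strokes > 0) inten else integer(0)))
  })
}

# all overlapping patch x patch windows of img as rows (row index varies
# fastest, matching column-major window order)
.extract_patches <- function(img, patch) {
  n1 <- nrow(img) - patch + 1
  n2 <- ncol(img) - patch + 1
  Y <- matrix(0, n1 * n2, patch * patch)
  for (dc in seq_len(patch))
    for (dr in seq_len(patch))
      Y[, (dc - 1) * patch + dr] <-
        as.vector(img[dr:(dr + n1 - 1), dc:(dc + n2 - 1)])
  Y
}

#' Cut a grayscale image into overlapping noisy patches
#'
#' @param image 2-D numeric intensity matrix, at least `patch x patch`.
#' @param patch window side length.
#' @param noise_sigma sd of the additive per-patch Gaussian noise.
#' @param seed integer seed.
#' @return [databatch()] without ground-truth labels.
#' @export
generate_patch_dataset <- function(image, patch = 9, noise_sigma = 5,
                                   seed = NULL) {
  image <- as.matrix(image)
  if (nrow(image) < patch || ncol(image) < patch)
    stop("image smaller than the requested patch size")
  with_seed(seed, {
    Yc <- .extract_patches(image, patch)
    Y <- Yc + matrix(rnorm(length(Yc), 0, noise_sigma), nrow(Yc), ncol(Yc))
    databatch(Y, Y_clean = Yc,
              meta = list(generator = "patches", seed = seed, patch = patch,
                          noise_sigma = noise_sigma))
  })
}

#' Split a signed patch into nonnegative ON/OFF channels
#'
#' Mirrors the transfer of visual information by center-on and center-off
#' LGN pathways: `y_d = max(x_d, 0)` and `y_{D+d} = max(-x_d, 0)`. The
#' original patch is `out[1:D] - out[D + (1:D)]`.
#'
#' @param patch numeric vector of length `D`.
#' @return nonnegative vector of length `2 D`.
#' @export
split_channels <- function(patch) {
  c(pmax(patch, 0), pmax(-patch, 0))
}

#' Local contrast normalization to the range 0..10
#'
#' @param patch nonnegative numeric vector.
#' @return patch rescaled so its maximum is 10; all-zero patches unchanged.
#' @export
normalize_contrast <- function(patch) {
  if (any(patch < 0)) stop("normalize_contrast expects nonnegative input")
  m <- max(patch)
  if (m == 0) return(patch)
  pmin(patch * (10 / m), 10)  # guard float round-up past the stated range
}

#' Pseudo-whitening of square grayscale images
#'
#' Frequency-domain flattening of the 1/f natural-image amplitude spectrum
#' with a low-pass roll-off: the filter is `f * exp(-(f/f0)^4)` on the radial
#' frequency `f` in cycles per image. The zero-frequency gain is zero, so the
#' output is zero-mean. Note the filter is not a projection: applying it
#' twice is not the same as applying it once.
#'
#' @param images a square matrix or list of square matrices.
#' @param f0 roll-off frequency in cycles/image; the default scales the
#'   conventional 200 cycles/image at 512 pixels to the image size.
#' @return filtered image(s), same shape as the input.
#' @export
pseudo_whiten <- function(images, f0 = NULL) {
  one <- function(img) {
    img <- as.matrix(img)
    n <- nrow(img)
    if (ncol(img) != n) stop("pseudo_whiten expects square images")
    cut <- if (is.null(f0)) 200 * n / 512 else f0
    fr <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
    rho <- sqrt(outer(fr^2, fr^2, "+"))
    filt <- rho * exp(-(rho / cut)^4)
    Re(fft(fft(img) * filt, inverse = TRUE)) / (n * n)
  }
  if (is.list(images)) lapply(images, one) else one(images)
}
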