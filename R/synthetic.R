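#' Run code with a fixed RNG seed, restoring prior state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(seed)
  }
  force(code)
}

#' Symmetric random walk
#'
#' Cumulative sum of i.i.d. steps drawn uniformly from {-1, +1}. A random
#' walk is the canonical H(q) = 0.5 reference signal: its increments are
#' uncorrelated, so the structure-function estimate of the classic Hurst
#' exponent H(2) should recover 0.5.
#'
#' @param n signal length, >= 2.
#' @param seed RNG seed for reproducibility (optional).
#' @return numeric vector of length `n`.
#' @export
generate_random_walk <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  with_seed(seed, cumsum(sample(c(-1, 1), n, replace = TRUE)))
}

#' Fractional Gaussian noise by exact circulant embedding
#'
#' Davies-Harte synthesis: the length-n autocovariance of fGn with Hurst
#' parameter H is embedded in a circulant matrix of order 2n whose
#' eigenvalues (obtained by FFT) are nonnegative for H in (0, 1), so an
#' exact Gaussian sample with the target covariance can be drawn in the
#' spectral domain.
#'
#' @param n number of increments.
#' @param hurst Hurst parameter in (0, 1).
#' @param seed RNG seed (optional).
#' @return numeric vector of `n` unit-variance fGn samples.
#' @export
generate_fgn <- function(n, hurst, seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1) {
    stop("hurst must lie strictly between 0 and 1", call. = FALSE)
  }
  h2 <- 2 * hurst
  k <- 0:n
  acov <- 0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
  m <- 2L * n
  lambda <- Re(stats::fft(c(acov, acov[n:2])))
  if (min(lambda) < -1e-8 * max(lambda)) {
    stop("circulant embedding not nonnegative definite", call. = FALSE)
  }
  lambda[lambda < 0] <- 0
  with_seed(seed, {
    w <- complex(m)
    w[1] <- sqrt(lambda[1]) * stats::rnorm(1)
    w[n + 1] <- sqrt(lambda[n + 1]) * stats::rnorm(1)
    re <- stats::rnorm(n - 1)
    im <- stats::rnorm(n - 1)
    mid <- sqrt(lambda[2:n] / 2) * complex(real = re, imaginary = im)
    w[2:n] <- mid
    w[m:(n + 2)] <- Conj(mid)
    Re(stats::fft(w))[1:n] / sqrt(m)
  })
}

#' Fractional Brownian motion
#'
#' Cumulative sum of exact fractional Gaussian noise ([generate_fgn()]).
#' The increments of the result at lag d have variance proportional to
#' d^(2 hurst), making fBm the ground-truth test signal for Hurst-exponent
#' estimators: the spectrum H(q) of an fBm path is flat (monofractal) and
#' equal to the generating Hurst parameter.
#'
#' @param n path length; powers of two keep the embedding FFT fast.
#' @param hurst Hurst parameter in (0, 1).
#' @param seed RNG seed (optional).
#' @return numeric vector of length `n`.
#' @export
generate_fbm <- function(n, hurst, seed = NULL) {
  cumsum(generate_fgn(n, hurst, seed))
}

#' Fractal texture by 2D spectral synthesis
#'
#' Draws a complex Gaussian random field on the frequency grid, shapes its
#' amplitude with the power law `|f|^-(roughness + 1)` (the spectral density
#' of a self-affine surface with Hurst-like roughness parameter), inverts
#' the FFT and min-max rescales the real part to `[0, 1]`. Larger roughness
#' gives smoother, more persistent textures whose row-concatenated signals
#' carry a higher Hurst exponent.
#'
#' @param height,width image dimensions, each >= 32.
#' @param roughness roughness parameter in (0, 1).
#' @param seed RNG seed (optional).
#' @return a `"grayscale_image"` with values in `[0, 1]`.
#' @export
generate_texture <- function(height = 256L, width = 256L, roughness = 0.5,
                             seed = NULL) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 32L || width < 32L) {
    stop("texture dimensions must be >= 32", call. = FALSE)
  }
  if (!is.numeric(roughness) || roughness <= 0 || roughness >= 1) {
    stop("roughness must lie strictly between 0 and 1", call. = FALSE)
  }
  fy <- fft_freq(height)
  fx <- fft_freq(width)
  rad <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- rad^(-(roughness + 1))
  amp[1, 1] <- 0  # zero the DC component
  field <- with_seed(seed, {
    matrix(complex(real = stats::rnorm(height * width),
                   imaginary = stats::rnorm(height * width)),
           nrow = height)
  })
  surf <- Re(stats::fft(field * amp, inverse = TRUE)) / (height * width)
  rng <- range(surf)
  grayscale_image((surf - rng[1]) / (rng[2] - rng[1]), source_depth = NA)
}

fft_freq <- function(n) {
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / n
  f[seq_len(n)]
}

#' Synthetic two-class fractal-texture dataset
#'
#' Generates `n_per_class` textures per class with class-specific roughness
#' and extracts the default generalized-Hurst feature vector from each. The
#' rougher low-`roughness` class plays the role of normal tissue texture
#' (label -1) and the smoother high-`roughness` class the role of the
#' disease class (label +1), mirroring the persistence contrast seen between
#' healthy and Alzheimer brain MR images. Fully determined by `seed`.
#'
#' @param n_per_class images per class.
#' @param class_roughness length-2 vector: roughness of the negative (-1)
#'   class then the positive (+1) class.
#' @param seed integer RNG seed.
#' @param height,width texture dimensions.
#' @param q_values,d_max feature-extraction parameters.
#' @param dir optional directory; when given, each texture is also written
#'   as a PNG named after its `image_id`.
#' @return data frame with columns `image_id`, `H1..Hk`, `label`.
#' @export
generate_dataset <- function(n_per_class = 20L,
                             class_roughness = c(0.3, 0.7),
                             seed = 1L,
                             height = 256L, width = 256L,
                             q_values = 1:6, d_max = 19L,
                             dir = NULL) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (length(class_roughness) != 2L) {
    stop("class_roughness must have two elements", call. = FALSE)
  }
  labels <- c(rep(-1L, n_per_class), rep(1L, n_per_class))
  rough <- c(rep(class_roughness[1], n_per_class),
             rep(class_roughness[2], n_per_class))
  ids <- sprintf("%s_%02d", ifelse(labels == 1L, "pos", "neg"),
                 c(seq_len(n_per_class), seq_len(n_per_class)))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    img <- generate_texture(height, width, rough[i],
                            seed = seed * 10000L + i)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      png::writePNG(img$pixels, file.path(dir, paste0(ids[i], ".png")))
    }
    h <- extract_features(img, q_values, d_max)$H
    row <- as.data.frame(as.list(h))
    names(row) <- paste0("H", seq_along(q_values))
    rows[[i]] <- cbind(data.frame(image_id = ids[i],
                                  stringsAsFactors = FALSE),
                       row, data.frame(label = labels[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
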