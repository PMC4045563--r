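# Brute-force reference for the structure function: explicit double loop,
# independent of the vectorized implementation.
naive_structure_function <- function(s, q, d) {
  n <- length(s)
  num <- 0
  for (t in seq_len(n - d)) {
    num <- num + abs(s[t + d] - s[t])^q
  }
  num <- num / (n - d)
  den <- sum(abs(s)^q) / n
  num / den
}

# Two tight, linearly separable 1D clusters.
make_separable_data <- function() {
  list(x = matrix(c(-2, -1.9, -2.1, -2.05, 2, 2.1, 1.9, 2.05), ncol = 1),
       y = c(-1, -1, -1, -1, 1, 1, 1, 1))
}

# Noisy XOR corners: not linearly separable, quadratic-kernel separable.
make_xor_data <- function(n_per_corner = 10, noise = 0.1, seed = 42) {
  corners <- list(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  x <- with_test_seed(seed, do.call(rbind, lapply(corners, function(cn) {
    sweep(matrix(rnorm(2 * n_per_corner, 0, noise), n_per_corner, 2),
          2, cn, "+")
  })))
  list(x = x, y = c(rep(-1, 2 * n_per_corner), rep(1, 2 * n_per_corner)))
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Small gradient test image written as an 8-bit PNG; returns the path.
write_test_png <- function(path, pixels = NULL, nrow = 64, ncol = 64) {
  if (is.null(pixels)) {
    pixels <- matrix(seq(0, 1, length.out = nrow * ncol),
                     nrow = nrow, byrow = TRUE)
  }
  png::writePNG(pixels, path)
  path
}
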