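#' Configure the non-subsampled shearlet transform
#'
#' The transform is built in the frequency domain from a Meyer-windowed
#' radial partition (a non-subsampled pyramid with one smooth annulus per
#' level) and, within each annulus, Meyer-type angular wedge windows that
#' tile orientation space. All windows are real, antipodally symmetric, and
#' satisfy a sum-of-squares (Parseval) identity, so applying each window once
#' for analysis and once for synthesis reconstructs the input exactly up to
#' floating-point error. Every band keeps the input's size (no subsampling),
#' which makes the transform fully shift-covariant under circular shifts.
#'
#' `directions` is ordered finest to coarsest: `directions[1]` is the number
#' of orientation wedges on the outermost (highest-frequency) annulus.
#' Boundary handling is periodic (FFT-native).
#'
#' @param levels number of pyramid levels (L >= 1).
#' @param directions integer vector of length `levels`; each entry a power of
#'   two >= 2 giving the number of shear orientations at that level,
#'   finest level first.
#' @param pyramid pyramid filter family; only `"meyer"` (smooth Meyer-window
#'   radial tiling) is implemented.
#' @param boundary boundary mode; only `"periodic"` is implemented.
#' @return an object of class `nsst_config`.
#' @seealso [nsst_decompose()], [nsst_reconstruct()]
#' @export
#' @examples
#' cfg <- nsst_config(levels = 2, directions = c(4, 4))
nsst_config <- function(levels = 4L, directions = c(16L, 16L, 8L, 8L),
                        pyramid = "meyer", boundary = "periodic") {
  levels <- as.integer(levels)
  if (length(levels) != 1L || is.na(levels) || levels < 1L)
    stop_validation("levels must be a positive integer")
  directions <- as.integer(directions)
  if (length(directions) != levels)
    stop_validation("directions must have one entry per level (", levels, ")")
  if (any(is.na(directions)) || any(directions < 2L) ||
      any(bitwAnd(directions, directions - 1L) != 0L))
    stop_validation("every directions entry must be a power of two >= 2")
  pyramid <- match.arg(pyramid, "meyer")
  boundary <- match.arg(boundary, "periodic")
  structure(list(levels = levels, directions = directions,
                 pyramid = pyramid, boundary = boundary),
            class = "nsst_config")
}

#' @export
print.nsst_config <- function(x, ...) {
  cat("NSST configuration\n")
  cat("  levels:    ", x$levels, "\n")
  cat("  directions:", paste(x$directions, collapse = ", "),
      "(finest -> coarsest)\n")
  cat("  pyramid:   ", x$pyramid, " / boundary: ", x$boundary, "\n", sep = "")
  invisible(x)
}

# Meyer auxiliary polynomial: smooth 0 -> 1 on [0,1], v(t) + v(1-t) = 1
.meyer_v <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# smooth step rising 0 -> 1 across [a, b] with the sin(pi/2 v) profile, so
# that step^2 + costep^2 = 1 for the matching falling window
.meyer_step <- function(r, a, b) {
  s <- sin(pi / 2 * .meyer_v((r - a) / (b - a)))
  s[r <= a] <- 0
  s[r >= b] <- 1
  s
}

# Build the full window stack for one image size: list(low = matrix,
# high = list over levels of lists over directions). Windows satisfy
# low^2 + sum high^2 = 1 at every frequency bin.
.nsst_windows <- function(nr, nc, cfg) {
  key <- paste(nr, nc, cfg$levels, paste(cfg$directions, collapse = "_"),
               sep = "x")
  cached <- .nsst_cache[[key]]
  if (!is.null(cached)) return(cached)

  w1 <- .fft_freqs(nr)
  w2 <- .fft_freqs(nc)
  r <- sqrt(outer(w1^2, rep(1, nc)) + outer(rep(1, nr), w2^2))
  theta <- atan2(outer(rep(1, nr), w2), outer(w1, rep(1, nc))) %% pi

  L <- cfg$levels
  cut <- pi / 2^(1:L)            # radial cutoffs, finest first
  steps <- lapply(seq_len(L), function(l)
    .meyer_step(r, 0.75 * cut[l], cut[l]))

  radial <- vector("list", L)
  radial[[1L]] <- steps[[1L]]
  if (L >= 2L) for (l in 2:L)
    radial[[l]] <- steps[[l]] * sqrt(pmax(1 - steps[[l - 1L]]^2, 0))
  low <- sqrt(pmax(1 - steps[[L]]^2, 0))

  high <- vector("list", L)
  for (l in seq_len(L)) {
    K <- cfg$directions[l]
    # angular coordinate in wedge units; period K, centres at 0..K-1
    xw <- K * theta / pi
    high[[l]] <- lapply(seq_len(K), function(k) {
      d <- (xw - (k - 1)) %% K
      d <- pmin(d, K - d)                      # wrapped distance to centre
      ang <- cos(pi / 2 * .meyer_v(d))
      ang[d >= 1] <- 0
      radial[[l]] * ang
    })
  }

  # Enforce exact Hermitian symmetry (so every band is real): average each
  # window with its index-negated mirror, then renormalise the whole stack
  # by its sum of squares to restore the exact Parseval tiling. Away from
  # the Nyquist rows/columns the windows are already symmetric and the
  # normaliser is 1.
  mirror <- function(w) w[c(1L, nr:2L), c(1L, nc:2L), drop = FALSE]
  low <- (low + mirror(low)) / 2
  for (l in seq_len(L))
    high[[l]] <- lapply(high[[l]], function(w) (w + mirror(w)) / 2)
  total <- low^2
  for (l in seq_len(L)) for (w in high[[l]]) total <- total + w^2
  scale <- 1 / sqrt(total)
  low <- low * scale
  for (l in seq_len(L))
    high[[l]] <- lapply(high[[l]], function(w) w * scale)

  out <- list(low = low, high = high)
  .nsst_cache[[key]] <- out
  out
}

#' Decompose an image with the non-subsampled shearlet transform
#'
#' Splits `img` into one low-frequency approximation band and
#' `sum(directions)` directional high-frequency bands, all with the same
#' size as the input. The transform is linear and, together with
#' [nsst_reconstruct()], reconstructs the input to floating-point accuracy.
#'
#' @param img numeric matrix with finite entries; both dimensions must be at
#'   least `2^(levels + 2)` so the coarsest annulus is resolved on the
#'   frequency grid.
#' @param cfg an [nsst_config()] object.
#' @return an object of class `nsst_coefficients`: a list with `low` (matrix),
#'   `high` (list over levels, each a list over directions of matrices), and
#'   `config`.
#' @export
#' @examples
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' co <- nsst_decompose(img, nsst_config(2, c(4, 4)))
#' max(abs(nsst_reconstruct(co) - img)) < 1e-6
nsst_decompose <- function(img, cfg = nsst_config()) {
  assert_gray_image(img, "img")
  if (!inherits(cfg, "nsst_config")) stop_validation("cfg must be an nsst_config")
  min_dim <- 2^(cfg$levels + 2L)
  if (min(dim(img)) < min_dim)
    stop_validation("image too small for ", cfg$levels,
                    " decomposition levels: both dimensions must be at least ",
                    min_dim)
  win <- .nsst_windows(nrow(img), ncol(img), cfg)
  Fh <- .fft2(img)
  high <- lapply(seq_len(cfg$levels), function(l)
    lapply(win$high[[l]], function(w) .ifft2_real(Fh * w)))
  low <- .ifft2_real(Fh * win$low)
  structure(list(low = low, high = high, config = cfg),
            class = "nsst_coefficients")
}

#' @export
print.nsst_coefficients <- function(x, ...) {
  cat("NSST coefficients:", nrow(x$low), "x", ncol(x$low), "\n")
  cat("  levels:", x$config$levels,
      "| high bands:", sum(x$config$directions), "\n")
  invisible(x)
}

#' Reconstruct an image from NSST coefficients
#'
#' Exact (numerical-precision) inverse of [nsst_decompose()] for untouched
#' coefficients; linear in the coefficients, so it is equally valid for
#' fused band sets.
#'
#' @param coeffs an `nsst_coefficients` object (bands may have been modified
#'   but must keep consistent shapes).
#' @return a numeric matrix of the bands' common size.
#' @export
nsst_reconstruct <- function(coeffs) {
  if (!inherits(coeffs, "nsst_coefficients"))
    stop_validation("coeffs must be an nsst_coefficients object")
  cfg <- coeffs$config
  d <- dim(coeffs$low)
  for (l in seq_len(cfg$levels)) {
    if (length(coeffs$high[[l]]) != cfg$directions[l])
      stop_validation("level ", l, " must hold ", cfg$directions[l], " bands")
    for (k in seq_len(cfg$directions[l]))
      if (!identical(dim(coeffs$high[[l]][[k]]), d))
        stop_validation("band (", l, ",", k, ") shape differs from the low band")
  }
  win <- .nsst_windows(d[1L], d[2L], cfg)
  acc <- .fft2(coeffs$low) * win$low
  for (l in seq_len(cfg$levels))
    for (k in seq_len(cfg$directions[l]))
      acc <- acc + .fft2(coeffs$high[[l]][[k]]) * win$high[[l]][[k]]
  .ifft2_real(acc)
}
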