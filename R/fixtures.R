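# Synthetic multimodal brain phantoms. The pairs emulate the complementary
# structure of clinical CT/MR and MR/PET-SPECT slices: one modality carries a
# bright high-contrast skull-like ring, the other a textured soft-tissue
# interior with a focal lesion absent from the first. Ground-truth masks ship
# with each pair so structure retention can be measured after fusion.

#' Generate a complementary gray-scale phantom pair
#'
#' Modality A is CT-like: a bright skull-like ring on a dark interior with
#' additive Gaussian noise (sd 0.02). Modality B is MR-like: the ring is
#' strongly attenuated, the interior carries band-limited texture (smoothed
#' white noise) plus a gentle gradient, and a focal bright lesion appears
#' that is absent from A. By construction the ring contrast lives almost
#' entirely in A and the lesion contrast entirely in B. Regeneration with
#' the same seed is bit-identical.
#'
#' @param seed integer seed.
#' @param size image side length in pixels (>= 64); default 256.
#' @return an object of class `phantom_pair`: `modality_a`, `modality_b`
#'   (matrices in `[0, 1]`), `masks` (disjoint logical matrices `ring`,
#'   `lesion`, `texture`, plus reference surrounds `ring_bg`, `lesion_bg`),
#'   `seed`, `size`, `kind`.
#' @seealso [phantom_contrast()], [make_color_pair()]
#' @export
#' @examples
#' p <- make_gray_pair(seed = 7, size = 64)
#' range(p$modality_a)
make_gray_pair <- function(seed, size = 256L) {
  size <- as.integer(size)
  if (is.na(size) || size < 64L)
    stop_validation("size must be at least 64")
  seed <- as.integer(seed)

  u <- seq(-1, 1, length.out = size)
  X <- outer(rep(1, size), u)
  Y <- outer(u, rep(1, size))
  R <- sqrt(X^2 + Y^2)

  ring_profile <- exp(-((R - 0.72) / 0.045)^2)
  ring_mask <- abs(R - 0.72) <= 0.05
  ring_bg <- (abs(R - 0.72) > 0.10) & (abs(R - 0.72) <= 0.18)

  les_r <- sqrt((X - 0.30)^2 + (Y + 0.22)^2)
  lesion_profile <- exp(-(les_r / 0.07)^2)
  lesion_mask <- les_r <= 0.08
  lesion_bg <- les_r > 0.12 & les_r <= 0.20 & R < 0.6

  interior <- R < 0.62
  texture_mask <- interior & les_r > 0.14

  withr::with_seed(seed, {
    noise_a <- matrix(rnorm(size^2, sd = 0.02), size, size)
    tex_raw <- matrix(rnorm(size^2), size, size)
  })
  tex <- .gauss_smooth(tex_raw, sigma = 2.5)
  tex <- tex / max(sd(as.vector(tex)), 1e-9) * 0.06

  A <- 0.08 + 0.85 * ring_profile + 0.06 * interior + noise_a
  B <- 0.10 + 0.22 * ring_profile +
    interior * (0.35 + 0.10 * Y + tex) +
    0.45 * lesion_profile

  masks <- list(ring = ring_mask, lesion = lesion_mask,
                texture = texture_mask & !ring_mask,
                ring_bg = ring_bg, lesion_bg = lesion_bg)
  structure(list(modality_a = clip01(A), modality_b = clip01(B),
                 masks = masks, seed = seed, size = size, kind = "gray"),
            class = "phantom_pair")
}

#' Generate a gray/pseudo-colour phantom pair
#'
#' Modality A is an MR-like gray image (textured interior, attenuated ring).
#' Modality B emulates a PET/SPECT map: its luminance carries a smooth
#' metabolic hotspot blob and its chrominance encodes a colour map, so the
#' chroma planes are nonconstant and the gray content of B is only weakly
#' correlated with A.
#'
#' @inheritParams make_gray_pair
#' @return a `phantom_pair` whose `modality_b` is an RGB array
#'   (`size x size x 3`); masks include `hotspot` and `hotspot_bg`.
#' @export
make_color_pair <- function(seed, size = 256L) {
  size <- as.integer(size)
  if (is.na(size) || size < 64L)
    stop_validation("size must be at least 64")
  seed <- as.integer(seed)

  u <- seq(-1, 1, length.out = size)
  X <- outer(rep(1, size), u)
  Y <- outer(u, rep(1, size))
  R <- sqrt(X^2 + Y^2)
  ring_profile <- exp(-((R - 0.72) / 0.045)^2)
  interior <- R < 0.62

  withr::with_seed(seed, {
    tex_raw <- matrix(rnorm(size^2), size, size)
    noise_a <- matrix(rnorm(size^2, sd = 0.02), size, size)
  })
  tex <- .gauss_smooth(tex_raw, sigma = 2.5)
  tex <- tex / max(sd(as.vector(tex)), 1e-9) * 0.08

  A <- clip01(0.10 + 0.25 * ring_profile +
                interior * (0.40 + 0.12 * X + tex) + noise_a)

  hot_r <- sqrt((X + 0.18)^2 + (Y - 0.12)^2)
  hot <- exp(-(hot_r / 0.16)^2)
  hotspot_mask <- hot_r <= 0.16
  hotspot_bg <- hot_r > 0.24 & hot_r <= 0.38 & R < 0.62
  lum <- clip01(0.12 + 0.78 * hot)

  # pseudo-colour map (hot-metal style): dark -> red -> yellow -> white
  rgb_b <- array(0, c(size, size, 3L))
  rgb_b[, , 1L] <- clip01(3 * lum)
  rgb_b[, , 2L] <- clip01(3 * lum - 1)
  rgb_b[, , 3L] <- clip01(3 * lum - 2)

  masks <- list(hotspot = hotspot_mask, hotspot_bg = hotspot_bg,
                interior = interior)
  structure(list(modality_a = A, modality_b = rgb_b, masks = masks,
                 seed = seed, size = size, kind = "color"),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat("Synthetic phantom pair (", x$kind, "), ", x$size, "x", x$size,
      ", seed ", x$seed, "\n", sep = "")
  cat("  masks:", paste(names(x$masks), collapse = ", "), "\n")
  invisible(x)
}

#' Structure contrast on a phantom mask
#'
#' Mean intensity over a structure's mask minus the mean over its matched
#' background surround — the quantity whose retention through fusion the
#' phantom pairs are designed to measure.
#'
#' @param img gray image (matrix) to measure; RGB arrays are reduced to
#'   luminance.
#' @param pair the [make_gray_pair()] / [make_color_pair()] object that owns
#'   the masks.
#' @param structure `"ring"`, `"lesion"` or `"hotspot"`.
#' @return scalar contrast (can be negative if the structure is darker than
#'   its surround).
#' @export
phantom_contrast <- function(img, pair, structure = c("ring", "lesion",
                                                      "hotspot")) {
  structure <- match.arg(structure)
  img <- .to_luma(img)
  if (!inherits(pair, "phantom_pair"))
    stop_validation("pair must be a phantom_pair")
  m <- pair$masks[[structure]]
  bg <- pair$masks[[paste0(structure, "_bg")]]
  if (is.null(m) || is.null(bg))
    stop_validation("pair has no masks for structure '", structure, "'")
  mean(img[m]) - mean(img[bg])
}
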