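# Six objective fusion-quality indices. Inputs to compute_metrics() are
# [0,1]-scaled images; they are clipped and rescaled to the 8-bit range
# internally. The metric_* workers operate directly on 0-255-scale matrices
# without clipping, which lets invariances (e.g. shift of the mean before
# clipping) be examined directly.

#' Fusion quality metrics
#'
#' Scores a fused image `F` against its two sources with six standard
#' indices:
#' * `EN` — Shannon entropy of the 256-bin grey-level histogram (bits).
#' * `Q_ABF` — Xydeas-Petrovic edge-information retention: Sobel edge
#'   strength and orientation of each source compared with the fused image
#'   through sigmoid preservation curves, weighted by source edge strength.
#'   Scored in `[0, 1]`; identical images score 1.
#' * `MI` — mutual information `I(F;A) + I(F;B)` from 256x256 joint
#'   histograms (bits, unnormalized sum).
#' * `AG` — average gradient: mean over interior pixels of
#'   `sqrt((dx^2 + dy^2)/2)` with forward differences.
#' * `SF` — spatial frequency `sqrt(RF^2 + CF^2)`, RF/CF the RMS of
#'   horizontal / vertical first differences (normalised by the pixel count).
#' * `SD` — population standard deviation of `F`.
#'
#' Colour fused images are evaluated on the luminance channel only.
#'
#' @param F fused image: `[0, 1]` matrix (or RGB array, reduced to
#'   luminance).
#' @param A,B source images on the same scale and shape.
#' @return an object of class `fusion_metrics` (named list with fields `EN`,
#'   `Q_ABF`, `MI`, `AG`, `SF`, `SD`); `as.data.frame()` gives a one-row
#'   table.
#' @export
#' @examples
#' A <- matrix(runif(64 * 64), 64, 64)
#' compute_metrics(A, A, A)
compute_metrics <- function(F, A, B) {
  F <- .to_luma(F); A <- .to_luma(A); B <- .to_luma(B)
  assert_gray_image(F, "F"); assert_gray_image(A, "A"); assert_gray_image(B, "B")
  assert_same_shape(F, A, B, names = c("F", "A", "B"))
  F8 <- clip01(F) * 255; A8 <- clip01(A) * 255; B8 <- clip01(B) * 255
  structure(list(EN = metric_en(F8),
                 Q_ABF = metric_qabf(F8, A8, B8),
                 MI = metric_mi(F8, A8) + metric_mi(F8, B8),
                 AG = metric_ag(F8),
                 SF = metric_sf(F8),
                 SD = metric_sd(F8)),
            class = "fusion_metrics")
}

#' @export
print.fusion_metrics <- function(x, ...) {
  cat("Fusion quality metrics\n")
  cat(sprintf("  EN    %8.4f bits\n", x$EN))
  cat(sprintf("  Q_ABF %8.4f\n", x$Q_ABF))
  cat(sprintf("  MI    %8.4f bits\n", x$MI))
  cat(sprintf("  AG    %8.4f\n", x$AG))
  cat(sprintf("  SF    %8.4f\n", x$SF))
  cat(sprintf("  SD    %8.4f\n", x$SD))
  invisible(x)
}

#' @export
as.data.frame.fusion_metrics <- function(x, ...) {
  data.frame(EN = x$EN, Q_ABF = x$Q_ABF, MI = x$MI, AG = x$AG, SF = x$SF,
             SD = x$SD)
}

.to_luma <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L)
    return(0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L])
  x
}

# 256-bin histogram of a 0-255-scale matrix (values rounded to grey levels)
.hist256 <- function(x) {
  idx <- pmin(pmax(round(x), 0), 255) + 1L
  tabulate(idx, nbins = 256L)
}

#' @rdname compute_metrics
#' @param x numeric matrix on the 0-255 scale (not clipped).
#' @export
metric_en <- function(x) {
  p <- .hist256(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @rdname compute_metrics
#' @param y second image for the joint histogram.
#' @export
metric_mi <- function(x, y) {
  ix <- pmin(pmax(round(x), 0), 255)
  iy <- pmin(pmax(round(y), 0), 255)
  joint <- tabulate(ix * 256L + iy + 1L, nbins = 256L * 256L) / length(x)
  px <- .hist256(x) / length(x)
  py <- .hist256(y) / length(y)
  keep <- joint > 0
  pxy <- joint[keep]
  kx <- (which(keep) - 1L) %/% 256L + 1L
  ky <- (which(keep) - 1L) %% 256L + 1L
  sum(pxy * log2(pxy / (px[kx] * py[ky])))
}

#' @rdname compute_metrics
#' @export
metric_ag <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  dx <- x[-nr, -1L] - x[-nr, -nc]
  dy <- x[-1L, -nc] - x[-nr, -nc]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' @rdname compute_metrics
#' @export
metric_sf <- function(x) {
  n <- length(x)
  rf2 <- sum((x[, -1L] - x[, -ncol(x)])^2) / n
  cf2 <- sum((x[-1L, ] - x[-nrow(x), ])^2) / n
  sqrt(rf2 + cf2)
}

#' @rdname compute_metrics
#' @export
metric_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Sobel edge strength and orientation (edge-replicated boundary)
.sobel <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  up <- c(1L, 1:(nr - 1L)); dn <- c(2:nr, nr)
  lf <- c(1L, 1:(nc - 1L)); rt <- c(2:nc, nc)
  gx <- (x[up, rt] + 2 * x[, rt] + x[dn, rt]) -
    (x[up, lf] + 2 * x[, lf] + x[dn, lf])
  gy <- (x[dn, lf] + 2 * x[dn, ] + x[dn, rt]) -
    (x[up, lf] + 2 * x[up, ] + x[up, rt])
  g <- sqrt(gx^2 + gy^2)
  a <- atan2(gy, gx)
  a[a >= pi / 2] <- a[a >= pi / 2] - pi   # fold to [-pi/2, pi/2)
  a[a < -pi / 2] <- a[a < -pi / 2] + pi
  list(g = g, a = a)
}

#' @rdname compute_metrics
#' @param a,b source images on the 0-255 scale for the edge-retention index.
#' @export
metric_qabf <- function(x, a, b) {
  sF <- .sobel(x); sA <- .sobel(a); sB <- .sobel(b)
  # sigmoid preservation curves, normalised so perfect transfer scores 1
  Gg <- 0.9994; kg <- -15; sg <- 0.5
  Ga <- 0.9879; ka <- -22; sa <- 0.8
  qg <- function(G) (Gg / (1 + exp(kg * (G - sg)))) /
    (Gg / (1 + exp(kg * (1 - sg))))
  qa <- function(Aa) (Ga / (1 + exp(ka * (Aa - sa)))) /
    (Ga / (1 + exp(ka * (1 - sa))))
  q_one <- function(sS) {
    G <- ifelse(sS$g == sF$g, 1,
                ifelse(pmax(sS$g, sF$g) == 0, 1,
                       pmin(sS$g, sF$g) / pmax(sS$g, sF$g)))
    Aa <- 1 - abs(sS$a - sF$a) / (pi / 2)
    qg(G) * qa(Aa)
  }
  wA <- sA$g; wB <- sB$g
  denom <- sum(wA + wB)
  if (denom == 0) return(1)  # no edges anywhere: vacuously perfect transfer
  sum(q_one(sA) * wA + q_one(sB) * wB) / denom
}

#' Peak signal-to-noise ratio
#'
#' PSNR in decibels between two `[0, 1]`-scale images (peak = 1). Identical
#' images give `Inf`.
#'
#' @param x,ref same-shape numeric matrices.
#' @return scalar PSNR in dB.
#' @export
psnr <- function(x, ref) {
  assert_gray_image(x, "x"); assert_gray_image(ref, "ref")
  assert_same_shape(x, ref, names = c("x", "ref"))
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}
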