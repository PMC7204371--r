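#' Configure the full fusion pipeline
#'
#' Collects the sub-configurations of the three fusion stages. The CSR
#' dictionary may be given as a `conv_dictionary`, a path to a plain-text
#' dictionary file, or `NULL` for the dictionary shipped with the package.
#'
#' @param nsst an [nsst_config()].
#' @param papcnn list of PAPCNN settings: `iterations` (default 110),
#'   `delta_beta` (grid step of the link-strength search, default 0.01),
#'   `weight_unfired`, `weight_fired` (objective class weights, default 1),
#'   `optimize_beta` (logical, default `TRUE`).
#' @param csr list of CSR settings: `dictionary` (see above), `lambda`
#'   (sparsity weight, default 0.01), `max_iter`, `abs_tol`, `rel_tol`.
#' @param color_mode `"gray"` to require gray inputs, `"luminance-chroma"`
#'   (default) to fuse the luminance of a colour second input and pass its
#'   chrominance through unchanged.
#' @return an object of class `fusion_config`.
#' @export
fusion_config <- function(nsst = nsst_config(),
                          papcnn = list(),
                          csr = list(),
                          color_mode = c("luminance-chroma", "gray")) {
  if (!inherits(nsst, "nsst_config"))
    stop_validation("nsst must be an nsst_config")
  papcnn <- modifyList(list(iterations = 110L, delta_beta = 0.01,
                            weight_unfired = 1, weight_fired = 1,
                            optimize_beta = TRUE), papcnn)
  csr <- modifyList(list(dictionary = NULL, lambda = 0.01,
                         max_iter = 200L, abs_tol = 1e-4, rel_tol = 1e-4),
                    csr)
  color_mode <- match.arg(color_mode)
  structure(list(nsst = nsst, papcnn = papcnn, csr = csr,
                 color_mode = color_mode),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("Fusion pipeline configuration\n")
  print(x$nsst)
  cat("  papcnn: iterations=", x$papcnn$iterations,
      " delta_beta=", x$papcnn$delta_beta,
      " optimize_beta=", x$papcnn$optimize_beta, "\n", sep = "")
  cat("  csr: lambda=", x$csr$lambda, " max_iter=", x$csr$max_iter,
      "\n", sep = "")
  cat("  color_mode:", x$color_mode, "\n")
  invisible(x)
}

.resolve_dictionary <- function(spec) {
  if (is.null(spec)) return(default_dictionary())
  if (inherits(spec, "conv_dictionary")) return(spec)
  if (is.character(spec) && length(spec) == 1L) {
    if (!file.exists(spec))
      stop_validation("dictionary file not found: ", spec)
    return(read_dictionary(spec))
  }
  stop_validation("csr$dictionary must be NULL, a conv_dictionary, or a path")
}

# BT.601 full-range luminance/chrominance transform
.rgb_to_ycbcr <- function(rgb) {
  y <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  cb <- (rgb[, , 3L] - y) * 0.564 + 0.5
  cr <- (rgb[, , 1L] - y) * 0.713 + 0.5
  list(y = y, cb = cb, cr = cr)
}

.ycbcr_to_rgb <- function(y, cb, cr) {
  r <- y + 1.402 * (cr - 0.5)
  b <- y + 1.772 * (cb - 0.5)
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(dim(y), 3L))
  out[, , 1L] <- r; out[, , 2L] <- g; out[, , 3L] <- b
  out
}

# PAPCNN fusion of one high-band pair: the pair's absolute values are
# normalised by their common maximum so the two firing counts are comparable
.fuse_high_pair <- function(HA, HB, pcfg) {
  SA <- abs(HA); SB <- abs(HB)
  m <- max(SA, SB)
  if (m <= 0) return(HA)
  SA <- SA / m; SB <- SB / m
  bs <- if (isTRUE(pcfg$optimize_beta))
    beta_search_config(delta_beta = pcfg$delta_beta,
                       weight_unfired = pcfg$weight_unfired,
                       weight_fired = pcfg$weight_fired)
  else NULL
  TA <- papcnn_iterate(SA, compute_adaptive_params(SA, pcfg$iterations),
                       beta_search = bs)
  TB <- papcnn_iterate(SB, compute_adaptive_params(SB, pcfg$iterations),
                       beta_search = bs)
  fuse_high(HA, HB, TA, TB)
}

#' Fuse two co-registered images
#'
#' Runs the four-stage pipeline: (1) decompose both inputs with the
#' non-subsampled shearlet transform; (2) fuse every directional
#' high-frequency band pair with the parameter-adaptive PCNN firing-count
#' rule; (3) fuse the low-frequency pair by convolutional sparse coding
#' with the choose-max activity rule; (4) invert the transform. If `B` is an
#' RGB array (PET/SPECT-style pseudo-colour) its luminance is fused with `A`
#' and its chrominance planes pass through unchanged.
#'
#' Inputs are expected on the `[0, 1]` scale (rescale by the format's
#' nominal maximum, not per-image, so the modalities keep their relative
#' brightness). The fused result is kept unclipped; clipping to the output
#' range happens only when writing to disk.
#'
#' @param A gray image (matrix, `[0, 1]` scale).
#' @param B gray image or RGB array of the same spatial size.
#' @param cfg a [fusion_config()].
#' @param metrics if `TRUE`, attach [compute_metrics()] of the fused image
#'   against the sources.
#' @return an object of class `fusion_result`: `fused` (matrix, or RGB array
#'   for colour input), `fused_gray` (the fused luminance), `chroma`
#'   (chrominance planes passed through, colour input only), `metrics`
#'   (optional), `provenance` (config snapshot and package version).
#' @export
#' @examples
#' \donttest{
#' p <- make_gray_pair(seed = 1, size = 64)
#' cfg <- fusion_config(nsst = nsst_config(2, c(4, 4)),
#'                      papcnn = list(iterations = 30))
#' r <- fuse_images(p$modality_a, p$modality_b, cfg)
#' }
fuse_images <- function(A, B, cfg = fusion_config(), metrics = FALSE) {
  if (!inherits(cfg, "fusion_config"))
    stop_validation("cfg must be a fusion_config")
  assert_gray_image(A, "A")

  is_color <- is.array(B) && length(dim(B)) == 3L && dim(B)[3L] == 3L
  if (is_color && cfg$color_mode == "gray")
    stop_validation("B is colour but color_mode is 'gray'")
  if (!is_color) assert_gray_image(B, "B")
  dB <- if (is_color) dim(B)[1:2] else dim(B)
  if (!identical(dim(A), as.integer(dB)) && !identical(dim(A), dB))
    stop_validation("A and B must have the same spatial size (got ",
                    paste(dim(A), collapse = "x"), " vs ",
                    paste(dB, collapse = "x"), ")")

  chroma <- NULL
  B_gray <- B
  if (is_color) {
    ycc <- .rgb_to_ycbcr(B)
    B_gray <- ycc$y
    chroma <- list(cb = ycc$cb, cr = ycc$cr)
  }

  dict <- .resolve_dictionary(cfg$csr$dictionary)
  opts <- admm_options(max_iter = cfg$csr$max_iter,
                       abs_tol = cfg$csr$abs_tol, rel_tol = cfg$csr$rel_tol,
                       lambda = cfg$csr$lambda)

  ca <- nsst_decompose(A, cfg$nsst)
  cb <- nsst_decompose(B_gray, cfg$nsst)

  fused <- ca
  for (l in seq_len(cfg$nsst$levels))
    for (k in seq_len(cfg$nsst$directions[l]))
      fused$high[[l]][[k]] <- .fuse_high_pair(ca$high[[l]][[k]],
                                              cb$high[[l]][[k]], cfg$papcnn)
  fused$low <- fuse_low(ca$low, cb$low, dict, cfg$csr$lambda, opts)

  F_gray <- nsst_reconstruct(fused)
  out <- if (is_color) .ycbcr_to_rgb(F_gray, chroma$cb, chroma$cr) else F_gray

  met <- if (metrics) compute_metrics(F_gray, A, B_gray) else NULL
  structure(list(fused = out, fused_gray = F_gray, chroma = chroma,
                 metrics = met,
                 provenance = list(
                   config = cfg,
                   package = "shearfuse",
                   version = as.character(packageVersion("shearfuse")))),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  d <- dim(x$fused_gray)
  cat("Fusion result:", d[1L], "x", d[2L],
      if (!is.null(x$chroma)) "(colour)" else "(gray)", "\n")
  cat("  gray range before clipping: [",
      sprintf("%.4f", min(x$fused_gray)), ", ",
      sprintf("%.4f", max(x$fused_gray)), "]\n", sep = "")
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Read and write raster images
#'
#' Thin wrappers over EBImage raster I/O. `read_image()` returns a `[0, 1]`
#' matrix for gray inputs or an RGB array for colour inputs (pixel (1,1) is
#' the top-left corner, row-major). `write_image()` clips to `[0, 1]` and
#' writes PNG/TIFF/JPEG according to the file extension.
#'
#' @param path file path.
#' @return `read_image()`: matrix or `h x w x 3` array; `write_image()`:
#'   `path`, invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_validation("cannot read image: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  # EBImage stores x (columns) in dim 1; transpose to row-major matrices
  if (length(dim(dat)) == 2L) return(t(dat))
  if (length(dim(dat)) == 3L && dim(dat)[3L] >= 3L) {
    out <- array(0, c(dim(dat)[2L], dim(dat)[1L], 3L))
    for (ch in 1:3) out[, , ch] <- t(dat[, , ch])
    return(out)
  }
  stop_validation("unsupported image layout in ", path)
}

#' @param img matrix or RGB array on the `[0, 1]` scale.
#' @rdname read_image
#' @export
write_image <- function(img, path) {
  img <- if (length(dim(img)) == 3L) {
    a <- array(0, c(dim(img)[2L], dim(img)[1L], 3L))
    for (ch in 1:3) a[, , ch] <- t(clip01(img[, , ch]))
    EBImage::Image(a, colormode = "Color")
  } else {
    EBImage::Image(t(clip01(img)))
  }
  EBImage::writeImage(img, path)
  invisible(path)
}
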