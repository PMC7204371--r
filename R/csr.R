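#' Construct a convolutional dictionary
#'
#' A set of `M` small square filters, each constrained to unit Euclidean
#' norm, used as the synthesis dictionary of the convolutional sparse model
#' `s ~ sum_m d_m * x_m` (circular convolution).
#'
#' @param filters numeric array `filter_size x filter_size x M`.
#' @param normalize if `TRUE` each filter is rescaled to unit norm; if
#'   `FALSE`, filters violating the constraint raise an error.
#' @return an object of class `conv_dictionary` with fields `filters`, `M`,
#'   `filter_size`.
#' @export
conv_dictionary <- function(filters, normalize = FALSE) {
  if (!is.array(filters) || length(dim(filters)) != 3L)
    stop_validation("filters must be a 3-D array (size x size x M)")
  d <- dim(filters)
  if (d[1L] != d[2L]) stop_validation("filters must be square")
  if (!all(is.finite(filters))) stop_validation("filters must be finite")
  M <- d[3L]
  for (m in seq_len(M)) {
    nrm <- sqrt(sum(filters[, , m]^2))
    if (normalize) {
      if (nrm < 1e-12) stop_validation("filter ", m, " is numerically zero")
      filters[, , m] <- filters[, , m] / nrm
    } else if (abs(nrm - 1) > 1e-6) {
      stop_validation("filter ", m, " has norm ", signif(nrm, 6),
                      "; dictionary filters must be unit-norm")
    }
  }
  structure(list(filters = filters, M = M, filter_size = d[1L]),
            class = "conv_dictionary")
}

#' @export
print.conv_dictionary <- function(x, ...) {
  cat("Convolutional dictionary:", x$M, "filters of size",
      x$filter_size, "x", x$filter_size, "\n")
  invisible(x)
}

#' ADMM solver options for convolutional sparse coding
#'
#' @param rho augmented-Lagrangian penalty; default couples to the sparsity
#'   weight as `10 * lambda + 0.1`.
#' @param max_iter iteration cap.
#' @param abs_tol,rel_tol absolute / relative stopping tolerances on the
#'   primal and dual residuals (standard ADMM criterion).
#' @param lambda sparsity weight used only to derive the default `rho`.
#' @return an object of class `admm_options`.
#' @export
admm_options <- function(rho = NULL, max_iter = 200L, abs_tol = 1e-4,
                         rel_tol = 1e-4, lambda = 0.01) {
  if (is.null(rho)) rho <- 10 * lambda + 0.1
  assert_scalar(rho, "rho", lower = 0, strict_lower = TRUE)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop_validation("max_iter must be >= 1")
  assert_scalar(abs_tol, "abs_tol", lower = 0, strict_lower = TRUE)
  assert_scalar(rel_tol, "rel_tol", lower = 0, strict_lower = TRUE)
  structure(list(rho = rho, max_iter = max_iter, abs_tol = abs_tol,
                 rel_tol = rel_tol), class = "admm_options")
}

#' Sparse-code a signal over a convolutional dictionary
#'
#' Solves the convolutional basis-pursuit denoising problem
#' \deqn{\arg\min_{\{x_m\}} \tfrac12\|\textstyle\sum_m d_m \otimes x_m -
#'   s\|_2^2 + \lambda \sum_m \|x_m\|_1}
#' by Fourier-domain ADMM: the quadratic subproblem is solved exactly per
#' frequency bin through the rank-one Sherman-Morrison identity, the l1
#' subproblem by elementwise soft thresholding. Convolution is circular.
#' The signal should be mean-centred (the model has no DC atom guarantee);
#' [fuse_low()] handles the DC component of lowpass bands separately.
#'
#' If the residual criterion is not met within `max_iter` iterations a
#' warning is emitted and the best iterate (lowest objective seen, including
#' the starting point) is returned.
#'
#' @param s numeric matrix (mean-centred signal).
#' @param dict a [conv_dictionary()].
#' @param lambda_csr sparsity weight (>= 0).
#' @param opts an [admm_options()] object.
#' @param warm optional array of maps to warm-start from.
#' @return an object of class `csr_coefficients`: list with `maps` (array
#'   `nrow x ncol x M`), `lambda`, `objective` (per-iteration trace,
#'   including the initial point), `converged`, `iterations`,
#'   `primal_residual`, `dual_residual`.
#' @export
#' @examples
#' dict <- conv_dictionary(array(rnorm(8 * 8 * 4), c(8, 8, 4)), normalize = TRUE)
#' s <- matrix(rnorm(32 * 32), 32, 32); s <- s - mean(s)
#' co <- csr_encode(s, dict, lambda_csr = 0.05)
#' co$final_objective <= 0.5 * sum(s^2)
csr_encode <- function(s, dict, lambda_csr = 0.01,
                       opts = admm_options(lambda = lambda_csr),
                       warm = NULL) {
  assert_gray_image(s, "s")
  if (!inherits(dict, "conv_dictionary"))
    stop_validation("dict must be a conv_dictionary")
  assert_scalar(lambda_csr, "lambda_csr", lower = 0)
  if (!inherits(opts, "admm_options"))
    stop_validation("opts must be an admm_options object")
  if (min(dim(s)) < dict$filter_size)
    stop_validation("signal smaller than the dictionary filters")
  y0 <- NULL
  if (!is.null(warm)) {
    if (!identical(dim(warm)[1:2], dim(s)) || dim(warm)[3L] != dict$M)
      stop_validation("warm-start maps have the wrong shape")
    y0 <- as.numeric(warm)
  }
  res <- .csr_encode_cpp(s, dict$filters, lambda_csr, opts$rho, opts$max_iter,
                         opts$abs_tol, opts$rel_tol, y0)
  if (!isTRUE(res$converged))
    warning("csr_encode: ADMM residual criterion not met within ",
            opts$max_iter, " iterations; returning the best iterate",
            call. = FALSE)
  structure(list(maps = res$maps, lambda = lambda_csr,
                 objective = res$objective,
                 final_objective = res$final_objective,
                 iterations = res$iterations, converged = res$converged,
                 primal_residual = res$primal_residual,
                 dual_residual = res$dual_residual),
            class = "csr_coefficients")
}

#' @export
print.csr_coefficients <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf(
    "CSR coefficients: %d maps of %dx%d | objective %.5g | %s in %d iter\n",
    d[3L], d[1L], d[2L], x$final_objective,
    if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Synthesize a signal from coefficient maps
#'
#' Computes `sum_m d_m * x_m` (circular convolution).
#'
#' @param coeffs a `csr_coefficients` object or a bare maps array.
#' @param dict the [conv_dictionary()] used for coding.
#' @return numeric matrix.
#' @export
csr_reconstruct <- function(coeffs, dict) {
  maps <- if (inherits(coeffs, "csr_coefficients")) coeffs$maps else coeffs
  if (!is.array(maps) || length(dim(maps)) != 3L)
    stop_validation("coeffs must be csr_coefficients or a 3-D array")
  if (dim(maps)[3L] != dict$M)
    stop_validation("map count does not match the dictionary")
  .csr_reconstruct_cpp(maps, dict$filters)
}

# objective of the convolutional sparse model for given dict and maps
.csr_objective <- function(s, maps, dict, lambda_csr) {
  r <- .csr_reconstruct_cpp(maps, dict$filters) - s
  0.5 * sum(r^2) + lambda_csr * sum(abs(maps))
}

#' Learn a convolutional dictionary
#'
#' Block-coordinate descent on the convolutional dictionary-learning
#' problem: alternate sparse coding of every (mean-centred) training image
#' over the current dictionary with a constrained dictionary update (ADMM
#' with a conjugate-gradient frequency-domain solve, followed by projection
#' onto zero-padded support and the unit sphere). The recorded objective is
#' the full model cost evaluated after each coding step; a monotonicity
#' safeguard rejects any dictionary update that would increase the data-fit
#' term for the current coefficients, so the objective sequence is
#' non-increasing.
#'
#' @param training list of numeric matrices (or a single matrix); each is
#'   mean-centred internally.
#' @param M number of filters (>= 1).
#' @param filter_size filter side length; must not exceed any training image.
#' @param lambda_csr sparsity weight.
#' @param opts [admm_options()] for the coding steps.
#' @param alternations number of code/update alternations.
#' @param seed integer seed for the random initial dictionary.
#' @param sigma penalty parameter of the dictionary-update ADMM.
#' @param verbose print the objective each alternation.
#' @return a [conv_dictionary()] with attributes `objective` (trace over
#'   alternations) and `seed`.
#' @export
csr_learn_dictionary <- function(training, M = 32L, filter_size = 8L,
                                 lambda_csr = 0.01,
                                 opts = admm_options(lambda = lambda_csr),
                                 alternations = 20L, seed = 1L,
                                 sigma = 10, verbose = FALSE) {
  if (is.matrix(training)) training <- list(training)
  if (!is.list(training) || length(training) < 1L)
    stop_validation("training must be a non-empty list of matrices")
  M <- as.integer(M); filter_size <- as.integer(filter_size)
  if (is.na(M) || M < 1L) stop_validation("M must be >= 1")
  for (im in training) {
    assert_gray_image(im, "training image")
    if (min(dim(im)) <= filter_size)
      stop_validation("every training image must be larger than filter_size")
  }
  training <- lapply(training, function(im) im - mean(im))

  filters <- withr::with_seed(seed, {
    f <- array(rnorm(filter_size^2 * M), c(filter_size, filter_size, M))
    f
  })
  dict <- conv_dictionary(filters, normalize = TRUE)

  obj_trace <- numeric(alternations)
  codes <- vector("list", length(training))
  for (t in seq_len(alternations)) {
    # sparse coding step (warm-started after the first pass)
    obj_t <- 0
    for (k in seq_along(training)) {
      codes[[k]] <- suppressWarnings(
        csr_encode(training[[k]], dict, lambda_csr, opts,
                   warm = if (t > 1L) codes[[k]]$maps else NULL))
      obj_t <- obj_t + codes[[k]]$final_objective
    }
    obj_trace[t] <- obj_t
    if (verbose) message(sprintf("alternation %d: objective %.6g", t, obj_t))

    # dictionary update with monotone safeguard on the fit term
    new_filters <- .csr_dict_update_cpp(training,
                                        lapply(codes, `[[`, "maps"),
                                        dict$filters, sigma, 8L, 20L, 1e-5)
    cand <- conv_dictionary(new_filters, normalize = TRUE)
    fit <- function(d) sum(vapply(seq_along(training), function(k) {
      r <- .csr_reconstruct_cpp(codes[[k]]$maps, d$filters) - training[[k]]
      0.5 * sum(r^2)
    }, numeric(1)))
    if (fit(cand) <= fit(dict)) dict <- cand
  }
  attr(dict, "objective") <- obj_trace
  attr(dict, "seed") <- seed
  attr(dict, "lambda") <- lambda_csr
  dict
}

#' Fuse two low-frequency bands by convolutional sparse coding
#'
#' Each band's mean (DC) is removed and the residual is sparse-coded over
#' the dictionary. Per pixel, an activity measure — the l1 norm across
#' coefficient maps, smoothed by a 3x3 box filter — decides which band's
#' entire coefficient vector is kept (ties favour band A). The fused band is
#' the average of the two source means plus the synthesis of the selected
#' maps.
#'
#' @param LA,LB low-frequency bands (same shape).
#' @param dict a [conv_dictionary()]; defaults to the dictionary shipped
#'   with the package.
#' @param lambda_csr sparsity weight.
#' @param opts [admm_options()] for the two coding problems.
#' @return fused low-frequency band (matrix) with attribute `selection`
#'   (logical matrix, `TRUE` where band A was selected).
#' @export
fuse_low <- function(LA, LB, dict = default_dictionary(),
                     lambda_csr = 0.01,
                     opts = admm_options(lambda = lambda_csr)) {
  assert_gray_image(LA, "LA"); assert_gray_image(LB, "LB")
  assert_same_shape(LA, LB, names = c("LA", "LB"))
  mu_a <- mean(LA); mu_b <- mean(LB)
  ca <- suppressWarnings(csr_encode(LA - mu_a, dict, lambda_csr, opts))
  cb <- suppressWarnings(csr_encode(LB - mu_b, dict, lambda_csr, opts))
  act_a <- .box3(apply(abs(ca$maps), c(1, 2), sum))
  act_b <- .box3(apply(abs(cb$maps), c(1, 2), sum))
  take_a <- act_a >= act_b
  # per-pixel selection of the whole coefficient vector
  fused_maps <- cb$maps
  for (m in seq_len(dict$M)) {
    slab_a <- ca$maps[, , m]; slab_b <- cb$maps[, , m]
    slab_b[take_a] <- slab_a[take_a]
    fused_maps[, , m] <- slab_b
  }
  fused <- (mu_a + mu_b) / 2 + .csr_reconstruct_cpp(fused_maps, dict$filters)
  attr(fused, "selection") <- take_a
  fused
}

# 3x3 box filter with edge replication
.box3 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  up <- c(1L, 1:(nr - 1L)); dn <- c(2:nr, nr)
  lf <- c(1L, 1:(nc - 1L)); rt <- c(2:nc, nc)
  (x[up, lf] + x[up, ] + x[up, rt] +
     x[, lf] + x + x[, rt] +
     x[dn, lf] + x[dn, ] + x[dn, rt]) / 9
}

#' The dictionary shipped with the package
#'
#' 32 unit-norm 8x8 filters learned once, with a fixed seed, from
#' low-frequency bands of the synthetic phantom images (see
#' [make_gray_pair()]), so coding and fusion are reproducible without any
#' download. Stored as a plain-text file under `inst/extdata/`;
#' [csr_learn_dictionary()] (or the CLI `learn-dict` subcommand) rebuilds it.
#'
#' @return a [conv_dictionary()].
#' @export
default_dictionary <- function() {
  path <- system.file("extdata", "dict_synthetic_m32.txt",
                      package = "shearfuse", mustWork = TRUE)
  read_dictionary(path)
}

#' Read / write a dictionary as plain text
#'
#' The format is a comment header (`# key: value` lines recording the filter
#' count, filter size and learning provenance) followed by one filter
#' coefficient per line in column-major order.
#'
#' @param path file path.
#' @return `read_dictionary()` returns a [conv_dictionary()];
#'   `write_dictionary()` returns `path` invisibly.
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) != 1L) stop_validation("dictionary header missing ", key)
    sub(paste0("^# ", key, ":\\s*"), "", ln)
  }
  M <- as.integer(get_field("filters"))
  fs <- as.integer(get_field("filter_size"))
  vals <- as.numeric(lines[!grepl("^#", lines) & nzchar(lines)])
  if (length(vals) != M * fs * fs)
    stop_validation("dictionary file holds ", length(vals),
                    " values; expected ", M * fs * fs)
  conv_dictionary(array(vals, c(fs, fs, M)))
}

#' @param dict a [conv_dictionary()].
#' @param meta named list of extra header fields (seed, lambda, ...).
#' @rdname read_dictionary
#' @export
write_dictionary <- function(dict, path, meta = list()) {
  if (!inherits(dict, "conv_dictionary"))
    stop_validation("dict must be a conv_dictionary")
  hdr <- c(paste0("# filters: ", dict$M),
           paste0("# filter_size: ", dict$filter_size),
           vapply(names(meta), function(k)
             paste0("# ", k, ": ", format(meta[[k]], digits = 17)),
             character(1)))
  writeLines(c(hdr, format(as.numeric(dict$filters), digits = 17,
                           scientific = TRUE, trim = TRUE)), path)
  invisible(path)
}
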