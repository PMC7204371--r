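#' Compute adaptive PAPCNN parameters from a stimulus band
#'
#' Derives all free parameters of the simplified pulse-coupled neural
#' network from statistics of the normalized stimulus `S` (values expected
#' in `(0, 1]`), so nothing has to be hand-tuned per image:
#' \deqn{\alpha_f = \ln(1/\sigma(S))}
#' \deqn{\lambda = (S_{max}/S' - 1)/6}
#' \deqn{V_E = e^{-\alpha_f} + 1 + 6\lambda}
#' \deqn{\alpha_e = \ln\!\left(\frac{V_E}{S'\frac{1 - e^{-3\alpha_f}}
#'   {1 - e^{-\alpha_f}} + 6\lambda e^{-\alpha_f}}\right)}
#' where \eqn{\sigma(S)} is the standard deviation, \eqn{S_{max}} the
#' maximum, and \eqn{S'} the Otsu threshold of the band. \eqn{\sigma} is
#' clipped below at `1e-4` so a near-constant band still yields finite
#' decays, and \eqn{\alpha_e} is floored at `1e-3` to stay strictly
#' positive on degenerate bands.
#'
#' The link amplitude is fixed at \eqn{V_L = 1}, so the adaptive weighted
#' link strength \eqn{\lambda = \beta V_L} doubles as the initial / fallback
#' link strength \eqn{\beta} (clamped to `[0, 1]`); the final \eqn{\beta}
#' used during iteration is normally refined by [optimize_beta()].
#'
#' @param band numeric matrix, the stimulus, normalized to `[0, 1]`.
#' @param iterations total iteration count `N` stored in the parameter set.
#' @param W 3x3 synaptic weight kernel (centre must be 0); default
#'   inverse-distance weights.
#' @return an object of class `papcnn_params` with fields `alpha_f`,
#'   `alpha_e`, `V_E`, `V_L`, `beta`, `lambda_link`, `W`, `N`.
#' @export
#' @examples
#' b <- matrix(runif(64 * 64), 64, 64)
#' compute_adaptive_params(b)
compute_adaptive_params <- function(band, iterations = 110L,
                                    W = papcnn_kernel()) {
  assert_gray_image(band, "band")
  if (length(band) < 2L) stop_validation("band must hold at least 2 pixels")
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop_validation("iterations must be >= 1")

  st <- .adaptive_from_stats(sigma = sd(as.vector(band)),
                             s_max = max(band),
                             s_otsu = .otsu_threshold(band))
  papcnn_params(alpha_f = st$alpha_f, alpha_e = st$alpha_e, V_E = st$V_E,
                beta = min(max(st$lambda, 0), 1), lambda_link = st$lambda,
                W = W, N = iterations)
}

# parameter formulas on the band statistics (sd, max, Otsu threshold)
.adaptive_from_stats <- function(sigma, s_max, s_otsu) {
  sigma <- max(sigma, 1e-4)
  alpha_f <- log(1 / sigma)
  lambda <- max((s_max / s_otsu - 1) / 6, 0)
  V_E <- exp(-alpha_f) + 1 + 6 * lambda
  denom <- s_otsu * (1 - exp(-3 * alpha_f)) / (1 - exp(-alpha_f)) +
    6 * lambda * exp(-alpha_f)
  alpha_e <- max(log(V_E / denom), 1e-3)
  list(alpha_f = alpha_f, alpha_e = alpha_e, V_E = V_E, lambda = lambda)
}

#' Construct a PAPCNN parameter set
#'
#' Low-level constructor; most users will call [compute_adaptive_params()].
#' The link amplitude `V_L` is fixed at 1, so `beta` is the effective
#' weighted link strength applied to the neighbour sum.
#'
#' @param alpha_f decay of the internal activity `U` (> 0).
#' @param alpha_e decay of the dynamic threshold `E` (> 0).
#' @param V_E threshold amplitude (> 0).
#' @param beta link strength in `[0, 1]`.
#' @param lambda_link unclamped adaptive weighted link strength (recorded for
#'   reference; defaults to `beta` since `V_L = 1`).
#' @param W 3x3 weight kernel with zero centre.
#' @param N total number of iterations (>= 1).
#' @return an object of class `papcnn_params`.
#' @export
papcnn_params <- function(alpha_f, alpha_e, V_E, beta, lambda_link = beta,
                          W = papcnn_kernel(), N = 110L) {
  assert_scalar(alpha_f, "alpha_f", lower = 0, strict_lower = TRUE)
  assert_scalar(alpha_e, "alpha_e", lower = 0, strict_lower = TRUE)
  assert_scalar(V_E, "V_E", lower = 0, strict_lower = TRUE)
  assert_scalar(beta, "beta", lower = 0, upper = 1)
  assert_scalar(lambda_link, "lambda_link", lower = 0)
  if (!is.matrix(W) || !identical(dim(W), c(3L, 3L)) || W[2L, 2L] != 0)
    stop_validation("W must be a 3x3 kernel with zero centre")
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop_validation("N must be >= 1")
  structure(list(alpha_f = alpha_f, alpha_e = alpha_e, V_E = V_E, V_L = 1,
                 beta = beta, lambda_link = lambda_link, W = W, N = N),
            class = "papcnn_params")
}

#' @export
print.papcnn_params <- function(x, ...) {
  cat(sprintf(
    "PAPCNN parameters: alpha_f=%.4f alpha_e=%.4f V_E=%.4f beta=%.4f N=%d\n",
    x$alpha_f, x$alpha_e, x$V_E, x$beta, x$N))
  invisible(x)
}

#' Default synaptic weight kernel
#'
#' Inverse-distance weights over the 8-neighbourhood with a zero centre.
#' @return a 3x3 numeric matrix.
#' @export
papcnn_kernel <- function() {
  matrix(c(0.5, 1, 0.5, 1, 0, 1, 0.5, 1, 0.5), 3L, 3L)
}

# Otsu threshold of a [0,1] band (256 grey levels), via EBImage
.otsu_threshold <- function(band) {
  rng <- range(band)
  if (rng[2L] <= rng[1L]) return(max(rng[1L], 1e-4))  # flat band: lambda -> 0
  th <- EBImage::otsu(EBImage::Image(clip01(band)), range = c(0, 1),
                      levels = 256L)
  max(as.numeric(th), 1e-4)
}

# weighted 8-neighbour link sum with edge replication; matches the
# accumulation order of the compiled kernel
.link_field <- function(Y, W, V_L = 1) {
  nr <- nrow(Y); nc <- ncol(Y)
  up <- c(1L, 1:(nr - 1L)); dn <- c(2:nr, nr)
  lf <- c(1L, 1:(nc - 1L)); rt <- c(2:nc, nc)
  acc <- W[1L, 1L] * Y[up, lf]
  acc <- acc + W[1L, 2L] * Y[up, ]
  acc <- acc + W[1L, 3L] * Y[up, rt]
  acc <- acc + W[2L, 1L] * Y[, lf]
  acc <- acc + W[2L, 3L] * Y[, rt]
  acc <- acc + W[3L, 1L] * Y[dn, lf]
  acc <- acc + W[3L, 2L] * Y[dn, ]
  acc <- acc + W[3L, 3L] * Y[dn, rt]
  V_L * acc
}

#' Configure the link-strength grid search
#'
#' @param delta_beta grid step in `(0, 1]`; candidates are
#'   `seq(0, 1, by = delta_beta)`.
#' @param weight_unfired,weight_fired class weights of the objective for the
#'   stays-unfired and fires classes (both default 1).
#' @param fallback_beta value returned when the candidate neighbour set is
#'   empty; `NA` means "use the adaptive parameter set's beta".
#' @return an object of class `beta_search_config`.
#' @export
beta_search_config <- function(delta_beta = 0.01, weight_unfired = 1,
                               weight_fired = 1, fallback_beta = NA_real_) {
  assert_scalar(delta_beta, "delta_beta", lower = 0, upper = 1,
                strict_lower = TRUE)
  assert_scalar(weight_unfired, "weight_unfired", lower = 0)
  assert_scalar(weight_fired, "weight_fired", lower = 0)
  if (!is.na(fallback_beta))
    assert_scalar(fallback_beta, "fallback_beta", lower = 0, upper = 1)
  structure(list(delta_beta = delta_beta, weight_unfired = weight_unfired,
                 weight_fired = weight_fired, fallback_beta = fallback_beta),
            class = "beta_search_config")
}

#' Optimize the PAPCNN link strength on a mid-iteration snapshot
#'
#' Grid search for the link strength \eqn{\beta \in [0, 1]} minimising the
#' two-class dispersion objective
#' \deqn{\sum_{c=1}^{2} \lambda_c \sum_{x \in X_c} (I_x - m_c)^2}
#' where the candidate set `X` holds neurons that receive link input but have
#' not fired (`L > 0`, `Y = 0`), a trial \eqn{\beta} splits `X` into the
#' stays-unfired class `X1` (trial activity \eqn{U \le E}) and the fires
#' class `X2`, and \eqn{m_1, m_2} are the stimulus means over the currently
#' unfired / fired regions. Ties are broken toward the smaller \eqn{\beta}.
#'
#' @param band the stimulus `I` (matrix), typically the normalized absolute
#'   high-frequency band.
#' @param state a list snapshot with elements `U`, `Y`, `E` (fields after the
#'   previous iteration) and `L` (link field of the current iteration).
#' @param cfg a [beta_search_config()].
#' @param params a [papcnn_params()] set (supplies the `U` decay and the
#'   fallback `beta`).
#' @return the optimal `beta` (scalar in `[0, 1]`).
#' @export
optimize_beta <- function(band, state, cfg = beta_search_config(),
                          params) {
  assert_gray_image(band, "band")
  if (!inherits(cfg, "beta_search_config"))
    stop_validation("cfg must be a beta_search_config")
  if (!all(c("U", "Y", "E", "L") %in% names(state)))
    stop_validation("state must carry fields U, Y, E and L")
  fallback <- if (is.na(cfg$fallback_beta)) params$beta else cfg$fallback_beta

  X <- state$L > 0 & state$Y == 0
  if (!any(X)) return(fallback)

  unfired <- state$Y == 0
  if (!any(unfired) || all(unfired)) return(fallback)
  m1 <- mean(band[unfired])
  m2 <- mean(band[!unfired])

  I_X <- band[X]
  L_X <- state$L[X]
  U_X <- state$U[X]
  E_X <- state$E[X]
  S_X <- band[X]
  ef <- exp(-params$alpha_f)
  d1 <- (I_X - m1)^2
  d2 <- (I_X - m2)^2

  betas <- seq(0, 1, by = cfg$delta_beta)
  if (betas[length(betas)] < 1) betas <- c(betas, 1)
  best_beta <- betas[1L]
  best_obj <- Inf
  for (b in betas) {
    U_trial <- ef * U_X + S_X * (1 + b * L_X)
    stays <- U_trial <= E_X
    obj <- cfg$weight_unfired * sum(d1[stays]) +
      cfg$weight_fired * sum(d2[!stays])
    if (obj < best_obj) { best_obj <- obj; best_beta <- b }
  }
  best_beta
}

#' Run the PAPCNN and accumulate firing counts
#'
#' Iterates the simplified pulse-coupled network on a non-negative stimulus
#' band (callers pass the absolute value of a high-frequency band) with all
#' fields initialised to zero, so every neuron of a strictly positive band
#' fires at the first step. Per iteration, each neuron's internal activity
#' decays and is driven by its stimulus modulated by the weighted firing of
#' its 8-neighbourhood; it fires when the activity exceeds its dynamic
#' threshold, which then recharges. The returned map counts each neuron's
#' total number of firings over all `N` iterations — the activity measure
#' used by [fuse_high()].
#'
#' When `beta_search` is supplied, the link strength is refined once per
#' band: at the first iteration where fired and unfired neurons coexist the
#' dynamics pause, [optimize_beta()] is run on the snapshot, and iteration
#' resumes with the optimised value held fixed.
#'
#' @param band non-negative numeric matrix (stimulus).
#' @param params a [papcnn_params()] set; default adapts to the band.
#' @param beta_search optional [beta_search_config()] enabling the one-shot
#'   link-strength refinement.
#' @return integer-valued firing-count matrix `T` (same shape as `band`,
#'   entries in `[0, N]`), with attributes `beta` (link strength actually
#'   used) and `params`.
#' @export
#' @examples
#' b <- matrix(runif(32 * 32), 32, 32)
#' T1 <- papcnn_iterate(b, compute_adaptive_params(b))
#' range(T1)
papcnn_iterate <- function(band, params = compute_adaptive_params(band),
                           beta_search = NULL) {
  assert_gray_image(band, "band")
  if (any(band < 0)) stop_validation("band must be non-negative (pass |H|)")
  if (!inherits(params, "papcnn_params"))
    stop_validation("params must be a papcnn_params object")
  if (params$N < 1L) stop_validation("N must be >= 1")

  zero <- matrix(0, nrow(band), ncol(band))
  ef <- exp(-params$alpha_f)
  ee <- exp(-params$alpha_e)
  beta <- params$beta
  st <- .papcnn_cpp(band, params$W, ef, ee, params$V_E, params$V_L, beta,
                    params$N, zero, zero, zero, zero, 0L,
                    !is.null(beta_search))
  if (!is.null(beta_search) && isTRUE(st$stopped)) {
    snap <- list(U = st$U, Y = st$Y, E = st$E,
                 L = .link_field(st$Y, params$W, params$V_L))
    beta <- optimize_beta(band, snap, beta_search, params)
    st <- .papcnn_cpp(band, params$W, ef, ee, params$V_E, params$V_L, beta,
                      params$N, st$U, st$Y, st$E, st$T, st$n_done, FALSE)
  }
  structure(st$T, beta = beta, params = params)
}

#' Fuse two high-frequency bands by firing counts
#'
#' Per-pixel choose-max rule on the accumulated firing counts: the fused
#' coefficient is taken (with its sign) from source A wherever A's neuron
#' fired at least as often as B's, and from source B otherwise.
#'
#' @param HA,HB signed high-frequency coefficient bands.
#' @param TA,TB firing-count maps from [papcnn_iterate()] run on `|HA|`,
#'   `|HB|`.
#' @return fused coefficient matrix.
#' @export
fuse_high <- function(HA, HB, TA, TB) {
  assert_gray_image(HA, "HA"); assert_gray_image(HB, "HB")
  assert_same_shape(HA, HB, TA, TB, names = c("HA", "HB", "TA", "TB"))
  out <- HB
  take_a <- TA >= TB
  out[take_a] <- HA[take_a]
  out
}
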