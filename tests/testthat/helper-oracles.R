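# Independent oracles used across the suite: literal scalar transcriptions
# of the model dynamics and metric definitions, kept deliberately naive
# (explicit loops) so they share no code path with the package internals.

# circular shift of a matrix by (dy, dx)
shift_mat <- function(m, dy, dx) {
  m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
    ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
}

# --- PAPCNN: literal scalar transcription of the five update equations plus
# firing-count accumulation, with the same neighbour order and
# edge-replicated padding as the package kernel.
papcnn_oracle <- function(S, params, beta = params$beta) {
  nr <- nrow(S); nc <- ncol(S)
  ef <- exp(-params$alpha_f); ee <- exp(-params$alpha_e)
  VE <- params$V_E; VL <- params$V_L; W <- params$W
  U <- matrix(0, nr, nc); Y <- matrix(0, nr, nc)
  E <- matrix(0, nr, nc); Tm <- matrix(0, nr, nc)
  di <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  for (n in seq_len(params$N)) {
    L <- matrix(0, nr, nc)
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      acc <- 0
      for (o in 1:8) {
        ii <- min(max(i + di[o], 1L), nr)
        jj <- min(max(j + dj[o], 1L), nc)
        acc <- acc + W[di[o] + 2L, dj[o] + 2L] * Y[ii, jj]
      }
      L[i, j] <- VL * acc
    }
    Ynew <- matrix(0, nr, nc)
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      u <- ef * U[i, j] + S[i, j] * (1 + beta * L[i, j])
      y <- if (u > E[i, j]) 1 else 0
      E[i, j] <- ee * E[i, j] + VE * y
      U[i, j] <- u
      Ynew[i, j] <- y
      Tm[i, j] <- Tm[i, j] + y
    }
    Y <- Ynew
  }
  Tm
}

# --- exhaustive grid evaluation of the link-strength objective
beta_grid_oracle <- function(I, state, cfg, params) {
  betas <- seq(0, 1, by = cfg$delta_beta)
  if (betas[length(betas)] < 1) betas <- c(betas, 1)
  X_idx <- which(state$L > 0 & state$Y == 0)
  if (length(X_idx) == 0) return(params$beta)
  m1 <- mean(I[state$Y == 0])
  m2 <- mean(I[state$Y == 1])
  ef <- exp(-params$alpha_f)
  best_obj <- Inf; best_b <- betas[1]
  for (b in betas) {
    obj <- 0
    for (x in X_idx) {
      u <- ef * state$U[x] + I[x] * (1 + b * state$L[x])
      obj <- obj + if (u <= state$E[x])
        cfg$weight_unfired * (I[x] - m1)^2
      else
        cfg$weight_fired * (I[x] - m2)^2
    }
    if (obj < best_obj) { best_obj <- obj; best_b <- b }
  }
  best_b
}

# random mid-iteration snapshot with mixed firing state, for beta-search tests
random_beta_context <- function(n = 6) {
  I <- matrix(runif(n * n, 0.05, 1), n, n)
  Y <- matrix(rbinom(n * n, 1, 0.4), n, n)
  if (all(Y == 0)) Y[1, 1] <- 1
  if (all(Y == 1)) Y[1, 1] <- 0
  W <- papcnn_kernel()
  L <- matrix(0, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- min(max(i + di, 1L), n); jj <- min(max(j + dj, 1L), n)
      acc <- acc + W[di + 2L, dj + 2L] * Y[ii, jj]
    }
    L[i, j] <- acc
  }
  list(I = I, state = list(U = matrix(runif(n * n), n, n), Y = Y,
                           E = matrix(runif(n * n, 0.2, 1.5), n, n), L = L))
}

# --- metric oracles (explicit loops, 0-255-scale inputs)
grey_levels <- function(x) pmin(pmax(round(x), 0), 255)

en_oracle <- function(x) {
  v <- grey_levels(x)
  counts <- numeric(256)
  for (g in 0:255) counts[g + 1] <- sum(v == g)
  p <- counts / length(v); p <- p[p > 0]
  -sum(p * log2(p))
}

mi_oracle <- function(x, y) {
  vx <- grey_levels(x); vy <- grey_levels(y)
  joint <- matrix(0, 256, 256)
  for (k in seq_along(vx))
    joint[vx[k] + 1, vy[k] + 1] <- joint[vx[k] + 1, vy[k] + 1] + 1
  joint <- joint / length(vx)
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (a in 1:256) for (b in 1:256)
    if (joint[a, b] > 0)
      s <- s + joint[a, b] * log2(joint[a, b] / (px[a] * py[b]))
  s
}

sd_oracle <- function(x) {
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / length(x))
}

sf_oracle <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  rf <- 0; cf <- 0
  for (i in 1:nr) for (j in 2:nc) rf <- rf + (x[i, j] - x[i, j - 1])^2
  for (j in 1:nc) for (i in 2:nr) cf <- cf + (x[i, j] - x[i - 1, j])^2
  sqrt(rf / length(x) + cf / length(x))
}

ag_oracle <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  s <- 0; cnt <- 0
  for (i in 1:(nr - 1)) for (j in 1:(nc - 1)) {
    dx <- x[i, j + 1] - x[i, j]
    dy <- x[i + 1, j] - x[i, j]
    s <- s + sqrt((dx^2 + dy^2) / 2); cnt <- cnt + 1
  }
  s / cnt
}

sobel_oracle <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  g <- matrix(0, nr, nc); a <- matrix(0, nr, nc)
  cl <- function(v, lo, hi) min(max(v, lo), hi)
  for (i in 1:nr) for (j in 1:nc) {
    p <- function(di, dj) x[cl(i + di, 1, nr), cl(j + dj, 1, nc)]
    gx <- (p(-1, 1) + 2 * p(0, 1) + p(1, 1)) -
      (p(-1, -1) + 2 * p(0, -1) + p(1, -1))
    gy <- (p(1, -1) + 2 * p(1, 0) + p(1, 1)) -
      (p(-1, -1) + 2 * p(-1, 0) + p(-1, 1))
    g[i, j] <- sqrt(gx^2 + gy^2)
    aa <- atan2(gy, gx)
    if (aa >= pi / 2) aa <- aa - pi
    if (aa < -pi / 2) aa <- aa + pi
    a[i, j] <- aa
  }
  list(g = g, a = a)
}

qabf_oracle <- function(f, a, b) {
  sF <- sobel_oracle(f); sA <- sobel_oracle(a); sB <- sobel_oracle(b)
  Gg <- 0.9994; kg <- -15; sg <- 0.5
  Ga <- 0.9879; ka <- -22; sa <- 0.8
  qg <- function(G) (Gg / (1 + exp(kg * (G - sg)))) /
    (Gg / (1 + exp(kg * (1 - sg))))
  qa <- function(Aa) (Ga / (1 + exp(ka * (Aa - sa)))) /
    (Ga / (1 + exp(ka * (1 - sa))))
  num <- 0; den <- 0
  for (k in seq_along(sF$g)) {
    for (src in list(sA, sB)) {
      gs <- src$g[k]; gf <- sF$g[k]
      G <- if (gs == gf) 1 else if (max(gs, gf) == 0) 1
      else min(gs, gf) / max(gs, gf)
      Aa <- 1 - abs(src$a[k] - sF$a[k]) / (pi / 2)
      num <- num + qg(G) * qa(Aa) * gs
      den <- den + gs
    }
  }
  if (den == 0) 1 else num / den
}

# --- CSR helpers
# low-coherence unit-norm dictionary (orthonormalised random filters)
ortho_dictionary <- function(fs = 8, M = 6) {
  q <- qr.Q(qr(matrix(rnorm(fs * fs * M), fs * fs, M)))
  conv_dictionary(array(q, c(fs, fs, M)))
}

# one ADMM iteration from zero initialisation, replicated with R's fft
admm_first_step_oracle <- function(s, dict, lambda, rho) {
  nr <- nrow(s); nc <- ncol(s); M <- dict$M; fs <- dict$filter_size
  Dhat <- array(0i, c(nr, nc, M))
  for (m in seq_len(M)) {
    dp <- matrix(0, nr, nc)
    dp[1:fs, 1:fs] <- dict$filters[, , m]
    Dhat[, , m] <- fft(dp)
  }
  shat <- fft(s)
  DtD <- matrix(0, nr, nc)
  for (m in seq_len(M)) DtD <- DtD + Mod(Dhat[, , m])^2
  bhat <- array(0i, c(nr, nc, M))
  cc <- matrix(0i, nr, nc)
  for (m in seq_len(M)) {
    bhat[, , m] <- Conj(Dhat[, , m]) * shat
    cc <- cc + Dhat[, , m] * bhat[, , m]
  }
  cc <- cc / (DtD + rho)
  y <- array(0, c(nr, nc, M))
  for (m in seq_len(M)) {
    xh <- (bhat[, , m] - Conj(Dhat[, , m]) * cc) / rho
    xm <- Re(fft(xh, inverse = TRUE)) / (nr * nc)
    y[, , m] <- sign(xm) * pmax(abs(xm) - lambda / rho, 0)
  }
  y
}

csr_objective_oracle <- function(s, maps, dict, lambda) {
  r <- csr_reconstruct(maps, dict) - s
  0.5 * sum(r^2) + lambda * sum(abs(maps))
}
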