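// Compiled kernels: 2-D FFT helpers, PAPCNN dynamics, and the Fourier-domain
// ADMM solvers for convolutional sparse coding and dictionary update.
// All convolutions are circular (FFT-native, periodic boundary) except the
// PCNN link sum, which uses edge replication to match the documented
// symmetric-padding convention.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// ---------------------------------------------------------------------------
// FFT helpers

// [[Rcpp::export(name = ".fft2_real_cpp")]]
arma::cx_mat fft2_real_cpp(const arma::mat& x) {
  return fft2(x);
}

// [[Rcpp::export(name = ".fft2_cpx_cpp")]]
arma::cx_mat fft2_cpx_cpp(const arma::cx_mat& x, bool inverse) {
  return inverse ? ifft2(x) : fft2(x);
}

// ---------------------------------------------------------------------------
// PAPCNN dynamics
//
// Per iteration n (literal transcription of the simplified model):
//   L  = VL * sum_kl W_kl Y_kl[n-1]        (8-neighbour weighted sum,
//                                           edge-replicated padding)
//   U  = exp(-alpha_f) U[n-1] + S (1 + beta L)
//   Y  = U > E[n-1]
//   E  = exp(-alpha_e) E[n-1] + VE Y
//   T += Y
// The neighbour accumulation order is fixed (row-major offsets) so that a
// scalar transcription using the same order reproduces the result bit for
// bit; decay factors exp(-alpha) are passed in precomputed for the same
// reason.

// [[Rcpp::export(name = ".papcnn_cpp")]]
Rcpp::List papcnn_cpp(const arma::mat& S, const arma::mat& W,
                      double ef, double ee, double VE, double VL,
                      double beta, int n_iter,
                      arma::mat U, arma::mat Y, arma::mat E, arma::mat T,
                      int n_done, bool stop_when_mixed) {
  const int nr = S.n_rows, nc = S.n_cols;
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  double w[8];
  for (int o = 0; o < 8; o++) w[o] = W(di[o] + 1, dj[o] + 1);

  mat L(nr, nc);
  bool stopped = false;
  int n = n_done;
  while (n < n_iter) {
    if (stop_when_mixed) {
      double ymin = Y.min(), ymax = Y.max();
      if (ymin == 0.0 && ymax == 1.0) { stopped = true; break; }
    }
    n++;
    for (int j = 0; j < nc; j++) {
      for (int i = 0; i < nr; i++) {
        double acc = 0.0;
        for (int o = 0; o < 8; o++) {
          int ii = i + di[o]; if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          int jj = j + dj[o]; if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
          acc += w[o] * Y(ii, jj);
        }
        L(i, j) = VL * acc;
      }
    }
    for (int j = 0; j < nc; j++) {
      for (int i = 0; i < nr; i++) {
        double u = ef * U(i, j) + S(i, j) * (1.0 + beta * L(i, j));
        double y = (u > E(i, j)) ? 1.0 : 0.0;
        E(i, j) = ee * E(i, j) + VE * y;
        U(i, j) = u;
        Y(i, j) = y;
        T(i, j) += y;
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("U") = U, Rcpp::Named("Y") = Y, Rcpp::Named("E") = E,
    Rcpp::Named("T") = T, Rcpp::Named("n_done") = n,
    Rcpp::Named("stopped") = stopped);
}

// ---------------------------------------------------------------------------
// Convolutional sparse coding (CBPDN) by Fourier-domain ADMM.
//
//   argmin_x 1/2 || sum_m d_m * x_m - s ||_2^2 + lambda sum_m || x_m ||_1
//
// x-update solved per frequency bin by the rank-one Sherman-Morrison
// identity; y-update is elementwise soft thresholding; the returned maps are
// the split (exactly sparse) variable at the iterate with the lowest
// objective seen, including the initial point.

static cx_cube pad_dict_fft(const cube& D, int nr, int nc) {
  const int M = D.n_slices, fs = D.n_rows;
  cx_cube Dhat(nr, nc, M);
  for (int m = 0; m < M; m++) {
    mat dp(nr, nc, fill::zeros);
    dp.submat(0, 0, fs - 1, fs - 1) = D.slice(m);
    Dhat.slice(m) = fft2(dp);
  }
  return Dhat;
}

// [[Rcpp::export(name = ".csr_encode_cpp")]]
Rcpp::List csr_encode_cpp(const arma::mat& s, const arma::cube& D,
                          double lambda, double rho, int max_iter,
                          double abs_tol, double rel_tol,
                          Rcpp::Nullable<Rcpp::NumericVector> y_init) {
  const int nr = s.n_rows, nc = s.n_cols, M = D.n_slices;
  const double N = double(nr) * double(nc);
  const double sqnm = std::sqrt(N * M);

  cx_mat shat = fft2(s);
  cx_cube Dhat = pad_dict_fft(D, nr, nc);
  mat DtD(nr, nc, fill::zeros);
  for (int m = 0; m < M; m++) DtD += square(abs(Dhat.slice(m)));
  cx_mat denom = conv_to<cx_mat>::from(DtD + rho);

  cube y(nr, nc, M, fill::zeros), u(nr, nc, M, fill::zeros),
       x(nr, nc, M, fill::zeros);
  if (y_init.isNotNull()) {
    Rcpp::NumericVector yv(y_init);
    y = cube(yv.begin(), nr, nc, M);
  }
  cx_cube yhat(nr, nc, M), uhat(nr, nc, M, fill::zeros),
          xhat(nr, nc, M);
  cx_mat Dy(nr, nc, fill::zeros);
  for (int m = 0; m < M; m++) {
    yhat.slice(m) = fft2(y.slice(m));
    Dy += Dhat.slice(m) % yhat.slice(m);
  }

  auto objective = [&](const cx_mat& Dyh, const cube& yy) {
    double fit = 0.5 / N * accu(square(abs(Dyh - shat)));
    return fit + lambda * accu(abs(yy));
  };

  std::vector<double> trace;
  double obj = objective(Dy, y);
  trace.push_back(obj);
  cube best_y = y;
  double best_obj = obj;

  bool converged = false;
  int it = 0;
  double r_norm = 0.0, s_norm = 0.0;
  const double thr = lambda / rho;

  for (it = 1; it <= max_iter; it++) {
    // x-update (Sherman-Morrison per frequency bin)
    cx_mat c(nr, nc, fill::zeros);
    for (int m = 0; m < M; m++) {
      xhat.slice(m) = conj(Dhat.slice(m)) % shat +
                      rho * (yhat.slice(m) - uhat.slice(m));
      c += Dhat.slice(m) % xhat.slice(m);
    }
    c /= denom;
    for (int m = 0; m < M; m++) {
      xhat.slice(m) = (xhat.slice(m) - conj(Dhat.slice(m)) % c) / rho;
      x.slice(m) = real(ifft2(xhat.slice(m)));
    }
    // y-update: soft threshold; u-update in both domains
    cube y_prev = y;
    Dy.zeros();
    for (int m = 0; m < M; m++) {
      mat v = x.slice(m) + u.slice(m);
      y.slice(m) = sign(v) % max(abs(v) - thr, mat(nr, nc, fill::zeros));
      u.slice(m) = v - y.slice(m);
      yhat.slice(m) = fft2(y.slice(m));
      uhat.slice(m) += xhat.slice(m) - yhat.slice(m);
      Dy += Dhat.slice(m) % yhat.slice(m);
    }
    obj = objective(Dy, y);
    trace.push_back(obj);
    if (obj < best_obj) { best_obj = obj; best_y = y; }

    r_norm = std::sqrt(accu(square(x - y)));
    s_norm = rho * std::sqrt(accu(square(y - y_prev)));
    double eps_pri = sqnm * abs_tol +
      rel_tol * std::max(std::sqrt(accu(square(x))), std::sqrt(accu(square(y))));
    double eps_dua = sqnm * abs_tol + rel_tol * rho * std::sqrt(accu(square(u)));
    if (r_norm <= eps_pri && s_norm <= eps_dua) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("maps") = best_y,
    Rcpp::Named("objective") = trace,
    Rcpp::Named("final_objective") = best_obj,
    Rcpp::Named("iterations") = std::min(it, max_iter),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("primal_residual") = r_norm,
    Rcpp::Named("dual_residual") = s_norm);
}

// [[Rcpp::export(name = ".csr_reconstruct_cpp")]]
arma::mat csr_reconstruct_cpp(const arma::cube& X, const arma::cube& D) {
  const int nr = X.n_rows, nc = X.n_cols, M = X.n_slices;
  cx_cube Dhat = pad_dict_fft(D, nr, nc);
  cx_mat acc(nr, nc, fill::zeros);
  for (int m = 0; m < M; m++) acc += Dhat.slice(m) % fft2(X.slice(m));
  return real(ifft2(acc));
}

// ---------------------------------------------------------------------------
// Dictionary update (convolutional constrained MOD): ADMM with a
// conjugate-gradient x-space solve in the Fourier domain and projection of
// the split variable onto {zero outside the filter support, unit l2 norm}.

// [[Rcpp::export(name = ".csr_dict_update_cpp")]]
arma::cube csr_dict_update_cpp(const Rcpp::List& images, const Rcpp::List& coefs,
                               const arma::cube& D0, double sigma,
                               int outer_iter, int cg_iter, double cg_tol) {
  const int K = images.size();
  const int fs = D0.n_rows, M = D0.n_slices;
  mat s0 = Rcpp::as<mat>(images[0]);
  const int nr = s0.n_rows, nc = s0.n_cols;

  std::vector<cx_mat> shat(K);
  std::vector<cx_cube> Xhat(K);
  for (int k = 0; k < K; k++) {
    shat[k] = fft2(Rcpp::as<mat>(images[k]));
    cube xk = Rcpp::as<cube>(coefs[k]);
    Xhat[k].set_size(nr, nc, M);
    for (int m = 0; m < M; m++) Xhat[k].slice(m) = fft2(xk.slice(m));
  }

  // normal-equation operator A(v) = sum_k X_k^H X_k v + sigma v
  auto apply_A = [&](const cx_cube& v) {
    cx_cube out = sigma * v;
    for (int k = 0; k < K; k++) {
      cx_mat acc(nr, nc, fill::zeros);
      for (int m = 0; m < M; m++) acc += Xhat[k].slice(m) % v.slice(m);
      for (int m = 0; m < M; m++) out.slice(m) += conj(Xhat[k].slice(m)) % acc;
    }
    return out;
  };
  auto cdot = [&](const cx_cube& a, const cx_cube& b) {
    double s = 0.0;
    for (int m = 0; m < M; m++) s += accu(real(conj(a.slice(m)) % b.slice(m)));
    return s;
  };

  cube g(nr, nc, M, fill::zeros), h(nr, nc, M, fill::zeros), dsp(nr, nc, M);
  for (int m = 0; m < M; m++)
    g.slice(m).submat(0, 0, fs - 1, fs - 1) = D0.slice(m);
  cx_cube dhat(nr, nc, M);
  for (int m = 0; m < M; m++) dhat.slice(m) = fft2(g.slice(m));

  for (int ot = 0; ot < outer_iter; ot++) {
    // rhs = sum_k X_k^H s_k + sigma * fft(g - h)
    cx_cube rhs(nr, nc, M);
    for (int m = 0; m < M; m++)
      rhs.slice(m) = sigma * fft2(mat(g.slice(m) - h.slice(m)));
    for (int k = 0; k < K; k++)
      for (int m = 0; m < M; m++)
        rhs.slice(m) += conj(Xhat[k].slice(m)) % shat[k];

    // CG from the current dhat
    cx_cube r = rhs - apply_A(dhat);
    cx_cube p = r;
    double rs = cdot(r, r), rs0 = rs;
    for (int ci = 0; ci < cg_iter && rs > cg_tol * cg_tol * (rs0 + 1e-30); ci++) {
      cx_cube Ap = apply_A(p);
      double alpha = rs / std::max(cdot(p, Ap), 1e-300);
      dhat += alpha * p;
      r -= alpha * Ap;
      double rs_new = cdot(r, r);
      p = r + (rs_new / rs) * p;
      rs = rs_new;
    }

    for (int m = 0; m < M; m++) dsp.slice(m) = real(ifft2(dhat.slice(m)));
    // projection: restrict to support, unit-normalise
    for (int m = 0; m < M; m++) {
      mat v = dsp.slice(m) + h.slice(m);
      mat gm(nr, nc, fill::zeros);
      mat blk = v.submat(0, 0, fs - 1, fs - 1);
      double nrm = norm(vectorise(blk), 2);
      if (nrm > 1e-12) gm.submat(0, 0, fs - 1, fs - 1) = blk / nrm;
      else gm.submat(0, 0, fs - 1, fs - 1) =
             g.slice(m).submat(0, 0, fs - 1, fs - 1);
      g.slice(m) = gm;
    }
    h += dsp - g;
  }

  cube out(fs, fs, M);
  for (int m = 0; m < M; m++)
    out.slice(m) = g.slice(m).submat(0, 0, fs - 1, fs - 1);
  return out;
}
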