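// Spectral kernels for the coupled Swift-Hohenberg gradient flow.
//
// State layout ("packed" vector, all real): [Re z, Im z, o_1, ..., o_m],
// each block a column-major ny x nx field.  Operator tables (growth spectra
// on the wavenumber lattice, time-unit multipliers, coupling list) are
// prepared once per model on the R side (model_tables()).
//
// Sign conventions: the dynamics is the gradient descent
//   dz/dt = mu_z [ L_z z - |z|^2 z - dU/dconj(z) ]
//   do/dt = mu_i [ L_i o - o^3 + gamma_i - dU/do ]
// with mu_f = 1/(r_z c_f) folding the intrinsic time unit tau = 1/r_z.
// Coupling forces are in divergence form for the gradient-type energies,
// evaluated spectrally so that energy and force are exactly consistent on
// the discrete torus (finite-difference functional-derivative contract).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;

namespace {

struct Tables {
  int ny, nx, m;
  std::vector<mat> lam;      // growth spectrum per field (m + 1 entries)
  vec mu, gamma_, cstr;
  ivec ckind, ca, cb;        // coupling kind (1..4) and field pair (0 = z)
  cx_mat ikx, iky;           // spectral derivative multipliers

  explicit Tables(const List& tab) {
    List lamL = tab["lam"];
    for (R_xlen_t i = 0; i < lamL.size(); ++i)
      lam.push_back(Rcpp::as<mat>(lamL[i]));
    mu = Rcpp::as<vec>(tab["mu"]);
    gamma_ = Rcpp::as<vec>(tab["gamma"]);
    cstr = Rcpp::as<vec>(tab["cstr"]);
    ckind = Rcpp::as<ivec>(tab["ckind"]);
    ca = Rcpp::as<ivec>(tab["ca"]);
    cb = Rcpp::as<ivec>(tab["cb"]);
    mat kx = Rcpp::as<mat>(tab["kx"]), ky = Rcpp::as<mat>(tab["ky"]);
    ikx = cx_mat(zeros<mat>(kx.n_rows, kx.n_cols), kx);
    iky = cx_mat(zeros<mat>(ky.n_rows, ky.n_cols), ky);
    ny = kx.n_rows; nx = kx.n_cols;
    m = static_cast<int>(lam.size()) - 1;
  }
};

inline cx_mat unpack_z(const vec& u, int ny, int nx) {
  int n = ny * nx;
  return cx_mat(reshape(mat(u.memptr(), n, 1), ny, nx),
                reshape(mat(u.memptr() + n, n, 1), ny, nx));
}

inline mat unpack_o(const vec& u, int ny, int nx, int i) {
  int n = ny * nx;
  return reshape(mat(u.memptr() + (2 + i) * n, n, 1), ny, nx);
}

// spectral divergence of a (complex) vector field
inline cx_mat div_spec(const cx_mat& gx, const cx_mat& gy, const Tables& T) {
  return ifft2(T.ikx % fft2(gx) + T.iky % fft2(gy));
}

struct FieldDeriv {            // cached transforms per field
  cx_mat val, Lu, ux, uy;      // value, L u, gradients (real fields: Im ~ 0)
};

void spectral_pieces(const cx_mat& f, const mat& lam, const Tables& T,
                     FieldDeriv& d, bool need_grad) {
  cx_mat fh = fft2(f);
  d.val = f;
  d.Lu = ifft2(lam % fh);
  if (need_grad) {
    d.ux = ifft2(T.ikx % fh);
    d.uy = ifft2(T.iky % fh);
  }
}

bool grad_needed(const Tables& T, int field) {
  for (uword c = 0; c < T.ckind.n_elem; ++c)
    if ((T.ckind[c] >= 3) && (T.ca[c] == field || T.cb[c] == field))
      return true;
  return false;
}

} // namespace

// [[Rcpp::export]]
arma::vec cpp_rhs(const arma::vec& u, const Rcpp::List& tab) {
  Tables T(tab);
  int n = T.ny * T.nx;
  std::vector<FieldDeriv> d(T.m + 1);
  spectral_pieces(unpack_z(u, T.ny, T.nx), T.lam[0], T, d[0], grad_needed(T, 0));
  for (int i = 1; i <= T.m; ++i)
    spectral_pieces(cx_mat(unpack_o(u, T.ny, T.nx, i - 1),
                           zeros<mat>(T.ny, T.nx)),
                    T.lam[i], T, d[i], grad_needed(T, i));

  // single-field part of the bracket
  cx_mat Fz = d[0].Lu - square(abs(d[0].val)) % d[0].val;
  std::vector<mat> Fo(T.m);
  for (int i = 1; i <= T.m; ++i) {
    mat o = real(d[i].val);
    Fo[i - 1] = real(d[i].Lu) - pow(o, 3) + T.gamma_[i - 1];
  }

  // coupling forces: subtract dU/dconj(z) resp. dU/do
  for (uword c = 0; c < T.ckind.n_elem; ++c) {
    int a = T.ca[c], b = T.cb[c], kind = T.ckind[c];
    double s = T.cstr[c];
    if (s == 0.0) continue;
    const FieldDeriv& A = d[a];
    const FieldDeriv& B = d[b];
    bool a_complex = (a == 0);
    if (kind == 1 || kind == 2) {          // product-type
      mat ob = real(B.val);
      if (a_complex) {
        mat az2 = square(abs(A.val));
        if (kind == 1) {                   // alpha o^2 |z|^2
          Fz -= s * square(ob) % A.val;
          Fo[b - 1] -= 2.0 * s * ob % az2;
        } else {                           // tau o^4 |z|^4
          Fz -= 2.0 * s * pow(ob, 4) % az2 % A.val;
          Fo[b - 1] -= 4.0 * s * pow(ob, 3) % square(az2);
        }
      } else {
        mat oa = real(A.val);
        if (kind == 1) {                   // alpha oa^2 ob^2
          Fo[a - 1] -= 2.0 * s * oa % square(ob);
          Fo[b - 1] -= 2.0 * s * ob % square(oa);
        } else {                           // tau oa^4 ob^4
          Fo[a - 1] -= 4.0 * s * pow(oa, 3) % pow(ob, 4);
          Fo[b - 1] -= 4.0 * s * pow(ob, 3) % pow(oa, 4);
        }
      }
    } else {                               // gradient-type
      cx_mat S = A.ux % B.ux + A.uy % B.uy;   // grad a . grad b
      mat S2 = square(abs(S));
      if (a_complex) {
        // dU/dconj(z) = -div(coef_z S grad o); dU/do = -div(coef_o Re(conj(S) grad z))
        mat coef_z = (kind == 3) ? mat(ones<mat>(T.ny, T.nx) * s) : mat(2.0 * s * S2);
        mat coef_o = (kind == 3) ? mat(ones<mat>(T.ny, T.nx) * 2.0 * s) : mat(4.0 * s * S2);
        Fz += div_spec(cx_mat(coef_z, zeros<mat>(T.ny, T.nx)) % S % B.ux,
                       cx_mat(coef_z, zeros<mat>(T.ny, T.nx)) % S % B.uy, T);
        mat gx = coef_o % real(conj(S) % A.ux);
        mat gy = coef_o % real(conj(S) % A.uy);
        Fo[b - 1] += real(div_spec(cx_mat(gx, zeros<mat>(T.ny, T.nx)),
                                   cx_mat(gy, zeros<mat>(T.ny, T.nx)), T));
      } else {
        mat Sr = real(S);
        mat coef = (kind == 3) ? mat(2.0 * s * Sr) : mat(4.0 * s * pow(Sr, 3));
        mat gax = coef % real(B.ux), gay = coef % real(B.uy);
        mat gbx = coef % real(A.ux), gby = coef % real(A.uy);
        Fo[a - 1] += real(div_spec(cx_mat(gax, zeros<mat>(T.ny, T.nx)),
                                   cx_mat(gay, zeros<mat>(T.ny, T.nx)), T));
        Fo[b - 1] += real(div_spec(cx_mat(gbx, zeros<mat>(T.ny, T.nx)),
                                   cx_mat(gby, zeros<mat>(T.ny, T.nx)), T));
      }
    }
  }

  vec out(u.n_elem);
  cx_mat dz = T.mu[0] * Fz;
  std::memcpy(out.memptr(), mat(real(dz)).memptr(), n * sizeof(double));
  std::memcpy(out.memptr() + n, mat(imag(dz)).memptr(), n * sizeof(double));
  for (int i = 1; i <= T.m; ++i) {
    mat doi = T.mu[i] * Fo[i - 1];
    std::memcpy(out.memptr() + (1 + i) * n, doi.memptr(), n * sizeof(double));
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_energy(const arma::vec& u, const Rcpp::List& tab) {
  Tables T(tab);
  std::vector<FieldDeriv> d(T.m + 1);
  spectral_pieces(unpack_z(u, T.ny, T.nx), T.lam[0], T, d[0], grad_needed(T, 0));
  for (int i = 1; i <= T.m; ++i)
    spectral_pieces(cx_mat(unpack_o(u, T.ny, T.nx, i - 1),
                           zeros<mat>(T.ny, T.nx)),
                    T.lam[i], T, d[i], grad_needed(T, i));

  vec single(T.m + 1);
  single[0] = mean(mean(-real(conj(d[0].val) % d[0].Lu)
                        + 0.5 * square(square(abs(d[0].val)))));
  for (int i = 1; i <= T.m; ++i) {
    mat o = real(d[i].val), Lo = real(d[i].Lu);
    single[i] = mean(mean(-0.5 * o % Lo + 0.25 * pow(o, 4) - T.gamma_[i - 1] * o));
  }

  vec coup(T.ckind.n_elem, fill::zeros);
  for (uword c = 0; c < T.ckind.n_elem; ++c) {
    int a = T.ca[c], b = T.cb[c], kind = T.ckind[c];
    double s = T.cstr[c];
    if (kind == 1 || kind == 2) {
      mat fa = (a == 0) ? mat(square(abs(d[a].val))) : mat(square(real(d[a].val)));
      mat fb = square(real(d[b].val));
      coup[c] = (kind == 1) ? s * mean(mean(fb % fa))
                            : s * mean(mean(square(fb) % square(fa)));
    } else {
      cx_mat S = d[a].ux % d[b].ux + d[a].uy % d[b].uy;
      mat S2 = square(abs(S));
      coup[c] = (kind == 3) ? s * mean(mean(S2)) : s * mean(mean(square(S2)));
    }
  }
  return List::create(Rcpp::Named("single") = single,
                      Rcpp::Named("coupling") = coup,
                      Rcpp::Named("total") = accu(single) + accu(coup));
}

// Apply a per-field diagonal Fourier multiplier (preconditioner workhorse).
// mults: list of m + 1 real ny x nx matrices in FFT layout.
// [[Rcpp::export]]
arma::vec cpp_fourier_diag(const arma::vec& u, const Rcpp::List& mults,
                           int ny, int nx) {
  int n = ny * nx, m = mults.size() - 1;
  vec out(u.n_elem);
  cx_mat z = unpack_z(u, ny, nx);
  mat m0 = Rcpp::as<mat>(mults[0]);
  cx_mat w = ifft2(cx_mat(m0, zeros<mat>(ny, nx)) % fft2(z));
  std::memcpy(out.memptr(), mat(real(w)).memptr(), n * sizeof(double));
  std::memcpy(out.memptr() + n, mat(imag(w)).memptr(), n * sizeof(double));
  for (int i = 1; i <= m; ++i) {
    mat mi = Rcpp::as<mat>(mults[i]);
    mat o = unpack_o(u, ny, nx, i - 1);
    mat wo = real(ifft2(cx_mat(mi, zeros<mat>(ny, nx)) %
                        fft2(cx_mat(o, zeros<mat>(ny, nx)))));
    std::memcpy(out.memptr() + (1 + i) * n, wo.memptr(), n * sizeof(double));
  }
  return out;
}
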