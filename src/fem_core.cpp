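// Total-Lagrangian hex8 kernels for the LV mechanics solver.
//
// Element technology: 8-node hexahedra, 2x2x2 Gauss for the anisotropic
// exponential (Guccione-type) strain energy and the fiber active stress,
// single-point (mean-dilatation) quadrature for the volumetric penalty
// kappa/2 (J-1)^2 so the near-incompressible limit does not lock.
// Pressure loads are follower loads on bilinear quad facets with the
// (nonsymmetric) consistent load stiffness.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

typedef mat::fixed<3, 3> mat33;
typedef mat::fixed<8, 3> mat83;
typedef vec::fixed<3> vec3;

namespace {

const double GP1 = 1.0 / std::sqrt(3.0);

// local node coordinates of the hex8 master element
const double XI[8]  = {-1,  1,  1, -1, -1,  1, 1, -1};
const double ETA[8] = {-1, -1,  1,  1, -1, -1, 1,  1};
const double ZTA[8] = {-1, -1, -1, -1,  1,  1, 1,  1};

void hex_dshape(double xi, double eta, double zta, mat83 &dN) {
  for (int a = 0; a < 8; ++a) {
    dN(a, 0) = 0.125 * XI[a] * (1 + ETA[a] * eta) * (1 + ZTA[a] * zta);
    dN(a, 1) = 0.125 * (1 + XI[a] * xi) * ETA[a] * (1 + ZTA[a] * zta);
    dN(a, 2) = 0.125 * (1 + XI[a] * xi) * (1 + ETA[a] * eta) * ZTA[a];
  }
}

// shape gradients at the 8 Gauss points and the centroid, computed once
struct ShapeTables {
  mat83 dN[9];
  ShapeTables() {
    for (int gp = 0; gp < 8; ++gp)
      hex_dshape(GP1 * XI[gp], GP1 * ETA[gp], GP1 * ZTA[gp], dN[gp]);
    hex_dshape(0, 0, 0, dN[8]);
  }
};
const ShapeTables SHP;

struct ActiveConsts {
  double lR, l0, B, Ca0, Ca0max;
};

// Active fiber tension (kPa) and its derivative w.r.t. fiber Green strain.
void active_tension(double E11, double Tmax, double act, const ActiveConsts &ac,
                    double &T0, double &dT0_dE11) {
  T0 = 0.0;
  dT0_dE11 = 0.0;
  if (Tmax <= 0.0 || act <= 0.0) return;
  double lsq = 2.0 * E11 + 1.0;
  if (lsq <= 0.0) return;
  double l = ac.lR * std::sqrt(lsq);
  if (l <= ac.l0) return; // below zero-tension length: clamped
  double ex = std::exp(ac.B * (l - ac.l0));
  double g = ex - 1.0; // ECa50^2 = Ca0max^2 / g
  double A = ac.Ca0 * ac.Ca0;
  double Bm = ac.Ca0max * ac.Ca0max;
  double den = A * g + Bm;
  double frac = A * g / den;
  T0 = Tmax * act * frac;
  double dfrac_dg = A * Bm / (den * den);
  double dg_dl = ac.B * ex;
  double dl_dE11 = ac.lR * ac.lR / l;
  dT0_dE11 = Tmax * act * dfrac_dg * dg_dl * dl_dE11;
}

} // namespace

// Pointwise second Piola-Kirchhoff stress of the passive law, in the fiber
// frame. Used by the R-level material API and as the cross-check for the
// assembled element kernels.
// [[Rcpp::export(name = ".pk2_point_cpp")]]
arma::mat pk2_point_cpp(const arma::mat &E, double Cc, double bf, double bt,
                        double bfs, double kappa, bool include_vol) {
  mat D = {{bf, bfs, bfs}, {bfs, bt, bt}, {bfs, bt, bt}};
  double Q = accu(D % (E % E));
  mat S = Cc * std::exp(Q) * (D % E);
  if (include_vol) {
    mat C = 2.0 * E + eye(3, 3);
    double detC = det(C);
    if (detC <= 0) Rcpp::stop("non-invertible deformation: det(2E+I) <= 0");
    double J = std::sqrt(detC);
    S += kappa * (J - 1.0) * J * inv_sympd(C);
  }
  return S;
}

// [[Rcpp::export(name = ".active_point_cpp")]]
double active_point_cpp(double E11, double Tmax, double act, double lR,
                        double l0, double B, double Ca0, double Ca0max) {
  ActiveConsts ac{lR, l0, B, Ca0, Ca0max};
  double T0, d;
  active_tension(E11, Tmax, act, ac, T0, d);
  return T0;
}

// Assemble residual R = f_int - f_ext, tangent K (triplets) and the passive
// strain energy. elems/faces are 1-based index matrices from R.
// [[Rcpp::export(name = ".fem_assemble_cpp")]]
Rcpp::List fem_assemble_cpp(const arma::mat &X, const arma::vec &u,
                            const arma::imat &elems, const arma::mat &ec,
                            const arma::mat &el, const arma::mat &er,
                            const arma::vec &t0_el, const arma::vec &t1_el,
                            double th_endo, double th_epi,
                            const arma::vec &Cn, double kappa, double bf,
                            double bt, double bfs, const arma::vec &Tmax_el,
                            double act, double lR, double l0, double B,
                            double Ca0, double Ca0max, double act_crossfiber,
                            double kappa_stab_frac, const arma::imat &faces,
                            const arma::vec &face_p, bool want_K) {
  const int nnode = X.n_rows;
  const int nel = elems.n_rows;
  const int nface = faces.n_rows;
  ActiveConsts ac{lR, l0, B, Ca0, Ca0max};

  vec R(3 * nnode, fill::zeros);
  vec Rabs(3 * nnode, fill::zeros); // |contribution| sums: roundoff floor
  double energy = 0.0;
  std::vector<int> Ki, Kj;
  std::vector<double> Kv;
  if (want_K) {
    Ki.reserve((size_t)nel * 576 + (size_t)nface * 144);
    Kj.reserve((size_t)nel * 576 + (size_t)nface * 144);
    Kv.reserve((size_t)nel * 576 + (size_t)nface * 144);
  }

  mat33 D;
  D(0, 0) = bf;  D(0, 1) = bfs; D(0, 2) = bfs;
  D(1, 0) = bfs; D(1, 1) = bt;  D(1, 2) = bt;
  D(2, 0) = bfs; D(2, 1) = bt;  D(2, 2) = bt;
  mat83 dNdX, Xe, ue;
  mat::fixed<24, 24> Ke;
  mat83 fe;
  const mat33 I3(fill::eye);

  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xe(a, i) = X(n, i);
        ue(a, i) = u(3 * n + i);
      }
    }
    vec3 vec_c, vec_l, vec_r;
    for (int i = 0; i < 3; ++i) {
      vec_c(i) = ec(e, i);
      vec_l(i) = el(e, i);
      vec_r(i) = er(e, i);
    }
    double Cc = Cn(e);
    double Tm = Tmax_el(e);
    if (want_K) Ke.zeros();
    fe.zeros();

    // 9 quadrature passes: 8 full points (anisotropic + active),
    // final centroid point (volumetric penalty, weight 8)
    for (int gp = 0; gp < 9; ++gp) {
      const bool vol_pt = (gp == 8);
      const double w = vol_pt ? 8.0 : 1.0;
      const mat83 &dN = SHP.dN[gp];
      mat33 J = Xe.t() * dN;
      double detJ = det(J);
      if (detJ <= 0.0)
        Rcpp::stop("element %d has non-positive Jacobian", e + 1);
      dNdX = dN * inv(J);
      mat33 F = I3 + ue.t() * dNdX;
      mat33 E = 0.5 * (F.t() * F - I3);
      double wj = w * detJ;

      // fiber frame at this integration point: the helix angle is sampled
      // at the point's transmural coordinate (zeta is the transmural axis
      // of the master element by construction)
      double zeta = vol_pt ? 0.0 : GP1 * ZTA[gp];
      double tq = t0_el(e) + 0.5 * (1.0 + zeta) * (t1_el(e) - t0_el(e));
      double th = th_endo + tq * (th_epi - th_endo);
      mat33 Rloc;
      Rloc.col(0) = std::cos(th) * vec_c + std::sin(th) * vec_l; // fiber
      Rloc.col(1) = cross(vec_r, Rloc.col(0));                   // sheet
      Rloc.col(2) = vec_r;                                       // normal
      const vec3 f0 = Rloc.col(0);

      // volumetric penalty: mean-dilatation share at the centroid point,
      // small fully integrated share as hourglass-type stabilization (the
      // deviatoric exponential law is orders of magnitude softer than kappa
      // and cannot control the non-constant-J element modes on its own)
      double keff = vol_pt ? (1.0 - kappa_stab_frac) * kappa
                           : kappa_stab_frac * kappa;
      mat33 S(fill::zeros);
      mat33 DEf, Aact;
      double eQ = 0.0, T0 = 0.0, dT0 = 0.0, Jdef = 0.0;
      mat33 Cinv;
      bool have_act = false, have_vol = false;
      if (keff > 0.0) {
        mat33 C = F.t() * F;
        double detC = det(C);
        if (detC <= 0.0)
          Rcpp::stop("element %d lost invertibility", e + 1);
        Jdef = std::sqrt(detC);
        Cinv = inv_sympd(C);
        S = keff * (Jdef - 1.0) * Jdef * Cinv;
        energy += wj * 0.5 * keff * (Jdef - 1.0) * (Jdef - 1.0);
        have_vol = true;
      }
      if (!vol_pt) {
        mat33 Ef = Rloc.t() * E * Rloc;
        double Q = accu(D % (Ef % Ef));
        eQ = std::exp(Q);
        DEf = D % Ef;
        S += Cc * eQ * (Rloc * DEf * Rloc.t());
        energy += wj * 0.5 * Cc * (eQ - 1.0);
        active_tension(Ef(0, 0), Tm, act, ac, T0, dT0);
        if (T0 != 0.0 || dT0 != 0.0) {
          have_act = true;
          Aact = f0 * f0.t();
          if (act_crossfiber > 0.0)
            Aact += act_crossfiber * (Rloc.col(1) * Rloc.col(1).t() +
                                      Rloc.col(2) * Rloc.col(2).t());
          if (T0 != 0.0) S += T0 * Aact;
        }
      }

      mat33 P = F * S;
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          fe(a, i) += wj * (P(i, 0) * dNdX(a, 0) + P(i, 1) * dNdX(a, 1) +
                            P(i, 2) * dNdX(a, 2));

      if (!want_K) continue;

      // geometric part: common to all stress contributions at this point
      mat::fixed<8, 8> W8 = dNdX * S * dNdX.t();
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b) {
          double g = wj * W8(a, b);
          Ke(3 * a + 0, 3 * b + 0) += g;
          Ke(3 * a + 1, 3 * b + 1) += g;
          Ke(3 * a + 2, 3 * b + 2) += g;
        }

      // material part: loop over column variations (b, j)
      for (int b = 0; b < 8; ++b) {
        const double gb0 = dNdX(b, 0), gb1 = dNdX(b, 1), gb2 = dNdX(b, 2);
        for (int j = 0; j < 3; ++j) {
          mat33 dE;
          const double Fj0 = F(j, 0), Fj1 = F(j, 1), Fj2 = F(j, 2);
          dE(0, 0) = Fj0 * gb0;
          dE(1, 1) = Fj1 * gb1;
          dE(2, 2) = Fj2 * gb2;
          dE(0, 1) = dE(1, 0) = 0.5 * (Fj0 * gb1 + Fj1 * gb0);
          dE(0, 2) = dE(2, 0) = 0.5 * (Fj0 * gb2 + Fj2 * gb0);
          dE(1, 2) = dE(2, 1) = 0.5 * (Fj1 * gb2 + Fj2 * gb1);
          mat33 dS(fill::zeros);
          if (have_vol) {
            double dJ = Jdef * accu(Cinv % dE);
            dS = keff * ((2.0 * Jdef - 1.0) * dJ * Cinv -
                         2.0 * (Jdef - 1.0) * Jdef * (Cinv * dE * Cinv));
          }
          if (!vol_pt) {
            mat33 dEf = Rloc.t() * dE * Rloc;
            mat33 dSf = Cc * eQ * ((D % dEf) + 2.0 * DEf * accu(DEf % dEf));
            dS += Rloc * dSf * Rloc.t();
            if (have_act && dT0 != 0.0) {
              double dE11 = as_scalar(f0.t() * dE * f0);
              dS += dT0 * dE11 * Aact;
            }
          }
          mat33 dP = F * dS;
          for (int a = 0; a < 8; ++a)
            for (int i = 0; i < 3; ++i)
              Ke(3 * a + i, 3 * b + j) +=
                  wj * (dP(i, 0) * dNdX(a, 0) + dP(i, 1) * dNdX(a, 1) +
                        dP(i, 2) * dNdX(a, 2));
        }
      }
    }

    for (int a = 0; a < 8; ++a) {
      int na = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        R(3 * na + i) += fe(a, i);
        Rabs(3 * na + i) += std::fabs(fe(a, i));
      }
    }
    if (want_K) {
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          int gi = 3 * (elems(e, a) - 1) + i + 1;
          for (int b = 0; b < 8; ++b)
            for (int j = 0; j < 3; ++j) {
              Ki.push_back(gi);
              Kj.push_back(3 * (elems(e, b) - 1) + j + 1);
              Kv.push_back(Ke(3 * a + i, 3 * b + j));
            }
        }
    }
  }

  // follower pressure on quad facets: residual += p * w * N_a * (x_xi x x_eta)
  const double QXI[4] = {-1, 1, 1, -1};
  const double QETA[4] = {-1, -1, 1, 1};
  mat::fixed<4, 3> xq;
  for (int fidx = 0; fidx < nface; ++fidx) {
    double p = face_p(fidx);
    if (p == 0.0) continue;
    for (int a = 0; a < 4; ++a) {
      int n = faces(fidx, a) - 1;
      for (int i = 0; i < 3; ++i) xq(a, i) = X(n, i) + u(3 * n + i);
    }
    mat::fixed<12, 12> Kf;
    if (want_K) Kf.zeros();
    for (int gp = 0; gp < 4; ++gp) {
      double xi = GP1 * QXI[gp], eta = GP1 * QETA[gp];
      vec::fixed<4> Nq, dxi, deta;
      for (int a = 0; a < 4; ++a) {
        Nq(a) = 0.25 * (1 + QXI[a] * xi) * (1 + QETA[a] * eta);
        dxi(a) = 0.25 * QXI[a] * (1 + QETA[a] * eta);
        deta(a) = 0.25 * (1 + QXI[a] * xi) * QETA[a];
      }
      vec3 xxi = xq.t() * dxi, xeta = xq.t() * deta;
      vec3 cv = cross(xxi, xeta);
      for (int a = 0; a < 4; ++a) {
        int n = faces(fidx, a) - 1;
        for (int i = 0; i < 3; ++i) {
          R(3 * n + i) += p * Nq(a) * cv(i);
          Rabs(3 * n + i) += std::fabs(p * Nq(a) * cv(i));
        }
      }
      if (!want_K) continue;
      for (int j = 0; j < 3; ++j) {
        vec3 ej(fill::zeros);
        ej(j) = 1.0;
        vec3 A1 = cross(ej, xeta), A2 = cross(xxi, ej);
        for (int b = 0; b < 4; ++b) {
          vec3 dcv = dxi(b) * A1 + deta(b) * A2;
          for (int a = 0; a < 4; ++a)
            for (int i = 0; i < 3; ++i)
              Kf(3 * a + i, 3 * b + j) += p * Nq(a) * dcv(i);
        }
      }
    }
    if (want_K) {
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) {
          int gi = 3 * (faces(fidx, a) - 1) + i + 1;
          for (int b = 0; b < 4; ++b)
            for (int j = 0; j < 3; ++j) {
              Ki.push_back(gi);
              Kj.push_back(3 * (faces(fidx, b) - 1) + j + 1);
              Kv.push_back(Kf(3 * a + i, 3 * b + j));
            }
        }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("R") = R, Rcpp::Named("Rabs") = Rabs,
      Rcpp::Named("energy") = energy);
  if (want_K) {
    out["Ki"] = Rcpp::IntegerVector(Ki.begin(), Ki.end());
    out["Kj"] = Rcpp::IntegerVector(Kj.begin(), Kj.end());
    out["Kv"] = Rcpp::NumericVector(Kv.begin(), Kv.end());
  }
  return out;
}

// Per-element centroid Green-Lagrange strain of the ED -> ES deformation,
// rotated into the local cardiac frame (columns of the output: Ecc, Ell, Err).
// [[Rcpp::export(name = ".fem_rel_strains_cpp")]]
arma::mat fem_rel_strains_cpp(const arma::mat &X, const arma::imat &elems,
                              const arma::vec &u_ref, const arma::vec &u_def,
                              const arma::mat &ec, const arma::mat &el,
                              const arma::mat &er) {
  const int nel = elems.n_rows;
  mat out(nel, 3);
  mat83 Xe, ua, ub;
  const mat33 I3(fill::eye);
  const mat83 &dN = SHP.dN[8];
  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xe(a, i) = X(n, i);
        ua(a, i) = u_ref(3 * n + i);
        ub(a, i) = u_def(3 * n + i);
      }
    }
    mat33 J = Xe.t() * dN;
    mat83 dNdX = dN * inv(J);
    mat33 Fref = I3 + ua.t() * dNdX;
    mat33 Fdef = I3 + ub.t() * dNdX;
    mat33 Frel = Fdef * inv(Fref);
    mat33 E = 0.5 * (Frel.t() * Frel - I3);
    mat33 Q;
    for (int i = 0; i < 3; ++i) {
      Q(i, 0) = ec(e, i);
      Q(i, 1) = el(e, i);
      Q(i, 2) = er(e, i);
    }
    mat33 Ecl = Q.t() * E * Q;
    out(e, 0) = Ecl(0, 0);
    out(e, 1) = Ecl(1, 1);
    out(e, 2) = Ecl(2, 2);
  }
  return out;
}

// Deformed element volumes (2x2x2 Gauss) and the minimum Gauss-point
// Jacobian determinant; with u = 0 these are the reference quantities.
// [[Rcpp::export(name = ".fem_elem_quality_cpp")]]
Rcpp::List fem_elem_quality_cpp(const arma::mat &X, const arma::imat &elems,
                                const arma::vec &u) {
  const int nel = elems.n_rows;
  vec vols(nel, fill::zeros), minj(nel);
  minj.fill(datum::inf);
  mat83 xe;
  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) xe(a, i) = X(n, i) + u(3 * n + i);
    }
    for (int gp = 0; gp < 8; ++gp) {
      double dj = det(mat33(xe.t() * SHP.dN[gp]));
      vols(e) += dj;
      if (dj < minj(e)) minj(e) = dj;
    }
  }
  return Rcpp::List::create(Rcpp::Named("volume") = vols,
                            Rcpp::Named("min_detJ") = minj);
}
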