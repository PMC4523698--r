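// Tensor-voting accumulation core and batched symmetric 3x3 eigensolvers.
//
// Vote kernel (tangent-orientation arc connection):
//   a voter with unit tangent e casts, at displacement v (mm), a rank-1 vote
//   DF * t' t'^T where t' is e rotated by 2*theta in the (e, v) plane,
//   theta = angle(v, +/-e) in [0, pi/2], and
//   DF = exp(-(s_arc^2 + c * kappa_arc^2) / sigma_d^2)
//   with s_arc = l*theta/sin(theta), kappa_arc = 2*sin(theta)/l, l = |v|.
//   Votes are zero beyond the angular cutoff. Plate votes integrate unit
//   stick votes over the plate plane's orientation circle (period pi);
//   ball votes use the azimuthal symmetry reduction to a 1-D theta integral.
//   Quadrature nodes are supplied from R so the R reference implementation
//   and this accumulator share the exact same kernel definition.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Sym3 {
  double xx = 0, xy = 0, xz = 0, yy = 0, yz = 0, zz = 0;
  void add_outer(double w, const double t[3]) {
    xx += w * t[0] * t[0];
    xy += w * t[0] * t[1];
    xz += w * t[0] * t[2];
    yy += w * t[1] * t[1];
    yz += w * t[1] * t[2];
    zz += w * t[2] * t[2];
  }
  void add_iso(double w) { xx += w; yy += w; zz += w; }
};

// Unit-saliency stick vote; accumulates weight * vote into acc.
void stick_vote_into(Sym3& acc, const double v[3], const double e[3],
                     double sigma_d, double curv_c, double cutoff,
                     double weight) {
  const double l2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  if (l2 == 0.0) {
    acc.add_outer(weight, e);
    return;
  }
  const double l = std::sqrt(l2);
  double ct = (v[0] * e[0] + v[1] * e[1] + v[2] * e[2]) / l;
  double es[3] = {e[0], e[1], e[2]};
  if (ct < 0) { es[0] = -es[0]; es[1] = -es[1]; es[2] = -es[2]; ct = -ct; }
  if (ct > 1.0) ct = 1.0;
  const double theta = std::acos(ct);
  if (theta > cutoff + 1e-12) return;
  const double st = std::sin(theta);
  double tp[3];
  double s_arc, kappa;
  if (st < 1e-12) {
    tp[0] = es[0]; tp[1] = es[1]; tp[2] = es[2];
    s_arc = l;
    kappa = 0.0;
  } else {
    double b[3] = {v[0] / l - ct * es[0], v[1] / l - ct * es[1],
                   v[2] / l - ct * es[2]};
    const double nb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
    b[0] /= nb; b[1] /= nb; b[2] /= nb;
    const double c2 = std::cos(2 * theta), s2 = std::sin(2 * theta);
    tp[0] = c2 * es[0] + s2 * b[0];
    tp[1] = c2 * es[1] + s2 * b[1];
    tp[2] = c2 * es[2] + s2 * b[2];
    s_arc = l * theta / st;
    kappa = 2 * st / l;
  }
  const double df =
      std::exp(-(s_arc * s_arc + curv_c * kappa * kappa) / (sigma_d * sigma_d));
  acc.add_outer(weight * df, tp);
}

// Ball vote radial factors alpha (along v) and beta (transverse) at distance
// l, via Gauss-Legendre nodes over theta in [0, cutoff].
void ball_factors(double l, double sigma_d, double curv_c,
                  const arma::vec& th, const arma::vec& tw,
                  double& alpha, double& beta) {
  alpha = 0.0;
  beta = 0.0;
  for (arma::uword i = 0; i < th.n_elem; ++i) {
    const double theta = th[i];
    const double st = std::sin(theta), ct = std::cos(theta);
    double s_arc, kappa;
    if (st < 1e-12) {
      s_arc = l;
      kappa = 0.0;
    } else {
      s_arc = l * theta / st;
      kappa = 2 * st / l;
    }
    const double df = std::exp(-(s_arc * s_arc + curv_c * kappa * kappa) /
                               (sigma_d * sigma_d));
    alpha += tw[i] * df * ct * ct * st;
    beta += tw[i] * df * st * st * st / 2.0;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cast_votes_cpp(IntegerVector dim, NumericVector spacing,
                             IntegerMatrix sites, IntegerVector scale_idx,
                             IntegerMatrix halfwidth, NumericVector sigma_d,
                             NumericVector curv_c, double cutoff,
                             NumericVector s_stick, NumericMatrix e1,
                             NumericVector s_plate, NumericMatrix e2,
                             NumericVector s_ball, NumericVector phi_nodes,
                             NumericVector theta_nodes,
                             NumericVector theta_weights) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int ntok = sites.nrow();
  const int nsc = sigma_d.size();
  NumericMatrix field(nvox, 6);
  arma::vec th(theta_nodes.begin(), theta_nodes.size());
  arma::vec tw(theta_weights.begin(), theta_weights.size());
  const int nphi = phi_nodes.size();

  // Per-scale ball stencils: unit ball vote (alpha, beta) per radial distance
  // is cheap, but cache per-scale since windows repeat across tokens.
  std::vector<std::vector<double>> ball_alpha(nsc), ball_beta(nsc);
  std::vector<bool> ball_ready(nsc, false);

  for (int t = 0; t < ntok; ++t) {
    const double ss = s_stick[t], sp = s_plate[t], sb = s_ball[t];
    if (ss == 0.0 && sp == 0.0 && sb == 0.0) continue;
    const int sc = scale_idx[t] - 1;
    const int hx = halfwidth(sc, 0), hy = halfwidth(sc, 1),
              hz = halfwidth(sc, 2);
    const double sd = sigma_d[sc], cc = curv_c[sc];
    const int ci = sites(t, 0) - 1, cj = sites(t, 1) - 1, ck = sites(t, 2) - 1;
    double ev1[3] = {e1(t, 0), e1(t, 1), e1(t, 2)};
    double ev2[3] = {e2(t, 0), e2(t, 1), e2(t, 2)};

    // Lazily build this scale's ball radial table over the window offsets.
    const int wx = 2 * hx + 1, wy = 2 * hy + 1, wz = 2 * hz + 1;
    const size_t wlen = (size_t)wx * wy * wz;
    if (sb != 0.0 && !ball_ready[sc]) {
      ball_alpha[sc].assign(wlen, 0.0);
      ball_beta[sc].assign(wlen, 0.0);
      size_t w = 0;
      for (int dk = -hz; dk <= hz; ++dk)
        for (int dj = -hy; dj <= hy; ++dj)
          for (int di = -hx; di <= hx; ++di, ++w) {
            const double vx = di * spacing[0], vy = dj * spacing[1],
                         vz = dk * spacing[2];
            const double l = std::sqrt(vx * vx + vy * vy + vz * vz);
            if (l == 0.0) continue;  // self-vote handled directly
            ball_factors(l, sd, cc, th, tw, ball_alpha[sc][w],
                         ball_beta[sc][w]);
          }
      ball_ready[sc] = true;
    }

    size_t w = 0;
    for (int dk = -hz; dk <= hz; ++dk) {
      const int k = ck + dk;
      for (int dj = -hy; dj <= hy; ++dj) {
        const int j = cj + dj;
        for (int di = -hx; di <= hx; ++di, ++w) {
          const int i = ci + di;
          if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
            continue;
          const double v[3] = {di * spacing[0], dj * spacing[1],
                               dk * spacing[2]};
          Sym3 acc;
          if (ss != 0.0) stick_vote_into(acc, v, ev1, sd, cc, cutoff, ss);
          if (sp != 0.0) {
            const double l2v = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
            if (l2v == 0.0) {
              // self-vote: the plate component itself
              acc.add_outer(sp, ev1);
              acc.add_outer(sp, ev2);
            } else {
              const double wgt = sp * 2.0 / nphi;
              for (int q = 0; q < nphi; ++q) {
                const double cp = std::cos(phi_nodes[q]),
                             spn = std::sin(phi_nodes[q]);
                const double eq[3] = {cp * ev1[0] + spn * ev2[0],
                                      cp * ev1[1] + spn * ev2[1],
                                      cp * ev1[2] + spn * ev2[2]};
                stick_vote_into(acc, v, eq, sd, cc, cutoff, wgt);
              }
            }
          }
          if (sb != 0.0) {
            const double l2v = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
            if (l2v == 0.0) {
              acc.add_iso(sb);
            } else {
              const double a = ball_alpha[sc][w], b = ball_beta[sc][w];
              const double l = std::sqrt(l2v);
              const double vh[3] = {v[0] / l, v[1] / l, v[2] / l};
              acc.add_iso(3.0 * sb * b);
              acc.add_outer(3.0 * sb * (a - b), vh);
            }
          }
          const R_xlen_t vox = (R_xlen_t)i + (R_xlen_t)nx * j +
                               (R_xlen_t)nx * ny * k;
          field(vox, 0) += acc.xx;
          field(vox, 1) += acc.xy;
          field(vox, 2) += acc.xz;
          field(vox, 3) += acc.yy;
          field(vox, 4) += acc.yz;
          field(vox, 5) += acc.zz;
        }
      }
    }
  }
  return field;
}

// Deterministic eigenvector sign: largest-|component| positive, first on tie.
static void fix_sign3(arma::vec& v) {
  int imax = 0;
  double amax = std::abs(v[0]);
  for (int i = 1; i < 3; ++i)
    if (std::abs(v[i]) > amax) { amax = std::abs(v[i]); imax = i; }
  if (v[imax] < 0) v = -v;
}

// Batched eigendecomposition of symmetric 3x3 matrices (rows of H as
// h11,h12,h13,h22,h23,h33). abs_order = TRUE returns |.|-ascending kappas
// (vessel convention); FALSE returns algebraically descending lambdas
// (PSD saliency decomposition: vec1 = e1, vec3 = e3).
// [[Rcpp::export]]
List eig_sym_field_cpp(NumericMatrix H, bool abs_order) {
  const int n = H.nrow();
  NumericMatrix values(n, 3), vec1(n, 3), vec2(n, 3), vec3(n, 3);
  arma::mat33 A;
  arma::vec eval;
  arma::mat evec;
  for (int r = 0; r < n; ++r) {
    A(0, 0) = H(r, 0); A(0, 1) = H(r, 1); A(0, 2) = H(r, 2);
    A(1, 0) = H(r, 1); A(1, 1) = H(r, 3); A(1, 2) = H(r, 4);
    A(2, 0) = H(r, 2); A(2, 1) = H(r, 4); A(2, 2) = H(r, 5);
    if (!arma::eig_sym(eval, evec, A))
      stop("eigendecomposition failed at row %d", r + 1);
    // arma: ascending eigenvalues
    arma::uvec ord(3);
    if (abs_order) {
      ord = arma::stable_sort_index(arma::abs(eval), "ascend");
    } else {
      ord = {2, 1, 0};  // descending
    }
    for (int c = 0; c < 3; ++c) {
      arma::vec v = evec.col(ord[c]);
      fix_sign3(v);
      values(r, c) = eval[ord[c]];
      NumericMatrix& out = (c == 0) ? vec1 : (c == 1 ? vec2 : vec3);
      out(r, 0) = v[0]; out(r, 1) = v[1]; out(r, 2) = v[2];
    }
  }
  return List::create(Named("values") = values, Named("vec1") = vec1,
                      Named("vec2") = vec2, Named("vec3") = vec3);
}
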