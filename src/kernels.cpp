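// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Optimal least-squares rigid superposition (Kabsch, SVD form).
// X, Y: m x 3 row-per-point matrices. Returns rotation R and translation t
// such that X %*% R + t best fits Y (rotation applied on the right because
// coordinates are stored as rows), plus the residual RMSD.
// [[Rcpp::export(name = ".kabsch_cpp")]]
List kabsch_cpp(const arma::mat& X, const arma::mat& Y) {
  const arma::uword m = X.n_rows;
  arma::rowvec cx = arma::mean(X, 0);
  arma::rowvec cy = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - cx;
  arma::mat Yc = Y.each_row() - cy;

  arma::mat H = Xc.t() * Yc;  // 3 x 3 cross-covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat R = U * D * V.t();  // maximizes tr(R' H) over proper rotations

  arma::rowvec t = cy - cx * R;
  arma::mat fit = X * R + arma::repmat(t, m, 1);
  double rmsd = std::sqrt(arma::accu(arma::square(fit - Y)) / double(m));

  return List::create(_["rotation"] = R, _["translation"] = t.t(),
                      _["rmsd"] = rmsd);
}

// All pairwise Cbeta-distance derived quantities needed by the scoring
// function, in one pass over the placed residues:
//   - neighbor counts per residue (cosine-switched between nc_lo and nc_hi)
//   - residue-residue clash penalty (linear overlap below clash_r, pairs
//     from different SSEs only)
//   - generic residue-pairing energy (binned distance potential evaluated
//     on inter-SSE pairs within its last bin edge)
// cb: m x 3; sse_id: integer id of the SSE owning each residue.
// pair_edges (length nb+1, ascending) and pair_energy (length nb) describe
// the pairing potential; pass numeric(0) edges to disable the term.
// [[Rcpp::export(name = ".pair_terms_cpp")]]
List pair_terms_cpp(const arma::mat& cb, const arma::ivec& sse_id,
                    double nc_lo, double nc_hi, double clash_r,
                    const arma::vec& pair_edges,
                    const arma::vec& pair_energy) {
  const arma::uword m = cb.n_rows;
  arma::vec nc(m, arma::fill::zeros);
  double clash = 0.0, pairing = 0.0;
  const double span = nc_hi - nc_lo;
  const bool has_pair = pair_edges.n_elem >= 2;
  const double pair_max = has_pair ? pair_edges(pair_edges.n_elem - 1) : 0.0;

  for (arma::uword i = 0; i + 1 < m; ++i) {
    for (arma::uword j = i + 1; j < m; ++j) {
      double dx = cb(i, 0) - cb(j, 0);
      double dy = cb(i, 1) - cb(j, 1);
      double dz = cb(i, 2) - cb(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);

      double w;
      if (d <= nc_lo) w = 1.0;
      else if (d >= nc_hi) w = 0.0;
      else w = 0.5 * (std::cos(M_PI * (d - nc_lo) / span) + 1.0);
      nc(i) += w;
      nc(j) += w;

      if (sse_id(i) != sse_id(j)) {
        if (d < clash_r) clash += clash_r - d;
        if (has_pair && d <= pair_max && d >= pair_edges(0)) {
          // locate bin: edges are few (tens), linear scan is fine
          for (arma::uword b = 0; b + 1 < pair_edges.n_elem; ++b) {
            if (d >= pair_edges(b) && d < pair_edges(b + 1)) {
              pairing += pair_energy(b);
              break;
            }
          }
        }
      }
    }
  }
  return List::create(_["neighbor_counts"] = nc, _["clash"] = clash,
                      _["pairing"] = pairing);
}

// Shortest distance between two 3-D segments (a0-a1, b0-b1).
// [[Rcpp::export(name = ".segment_distance_cpp")]]
double segment_distance_cpp(const arma::vec& a0, const arma::vec& a1,
                            const arma::vec& b0, const arma::vec& b1) {
  arma::vec u = a1 - a0, v = b1 - b0, w = a0 - b0;
  double a = arma::dot(u, u), b = arma::dot(u, v), c = arma::dot(v, v);
  double d = arma::dot(u, w), e = arma::dot(v, w);
  double D = a * c - b * b;
  double sc, sN, sD = D, tc, tN, tD = D;
  const double eps = 1e-12;

  if (D < eps) { sN = 0.0; sD = 1.0; tN = e; tD = c; }
  else {
    sN = b * e - c * d;
    tN = a * e - b * d;
    if (sN < 0) { sN = 0; tN = e; tD = c; }
    else if (sN > sD) { sN = sD; tN = e + b; tD = c; }
  }
  if (tN < 0) {
    tN = 0;
    if (-d < 0) sN = 0;
    else if (-d > a) sN = sD;
    else { sN = -d; sD = a; }
  } else if (tN > tD) {
    tN = tD;
    if (-d + b < 0) sN = 0;
    else if (-d + b > a) sN = sD;
    else { sN = -d + b; sD = a; }
  }
  sc = std::abs(sD) < eps ? 0.0 : sN / sD;
  tc = std::abs(tD) < eps ? 0.0 : tN / tD;
  arma::vec dp = w + sc * u - tc * v;
  return std::sqrt(arma::dot(dp, dp));
}

// --- GDT search -----------------------------------------------------------

static inline void kabsch_fit(const arma::mat& X, const arma::mat& Y,
                              const arma::uvec& S, const arma::mat& Xall,
                              arma::vec& d_out) {
  arma::mat Xs = X.rows(S), Ys = Y.rows(S);
  arma::rowvec cx = arma::mean(Xs, 0), cy = arma::mean(Ys, 0);
  arma::mat H = (Xs.each_row() - cx).t() * (Ys.each_row() - cy);
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, H);
  double det = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = det;
  arma::mat R = U * D * V.t();
  arma::rowvec t = cy - cx * R;
  arma::mat fit = Xall * R;
  fit.each_row() += t;
  d_out = arma::sqrt(arma::sum(arma::square(fit - Y), 1));
}

// Best number of residues superposable within each threshold.
// m <= exhaustive_limit: enumerate every subset of size >= 3 (exact).
// Larger m: LGA-style window seeds (lengths 3..8 plus the full set),
// iteratively extended over the residues currently inside the threshold.
// [[Rcpp::export(name = ".gdt_counts_cpp")]]
Rcpp::IntegerVector gdt_counts_cpp(const arma::mat& X, const arma::mat& Y,
                                   const arma::vec& thresholds,
                                   int exhaustive_limit = 12,
                                   int max_iter = 20) {
  const arma::uword m = X.n_rows;
  const arma::uword nt = thresholds.n_elem;
  std::vector<int> best(nt, 0);
  arma::vec d;

  if ((int)m <= exhaustive_limit) {
    const unsigned long nmask = 1UL << m;
    for (unsigned long mask = 0; mask < nmask; ++mask) {
      int sz = __builtin_popcountl(mask);
      if (sz < 3) continue;
      arma::uvec S(sz);
      int k = 0;
      for (arma::uword i = 0; i < m; ++i)
        if (mask & (1UL << i)) S(k++) = i;
      kabsch_fit(X, Y, S, X, d);
      for (arma::uword t = 0; t < nt; ++t) {
        int cnt = (int)arma::accu(d <= thresholds(t));
        if (cnt > best[t]) best[t] = cnt;
      }
    }
  } else {
    std::vector<arma::uvec> seeds;
    for (arma::uword w = 3; w <= std::min<arma::uword>(8, m); ++w)
      for (arma::uword s0 = 0; s0 + w <= m; ++s0) {
        arma::uvec S(w);
        for (arma::uword i = 0; i < w; ++i) S(i) = s0 + i;
        seeds.push_back(S);
      }
    seeds.push_back(arma::regspace<arma::uvec>(0, m - 1));

    for (arma::uword t = 0; t < nt; ++t) {
      const double thr = thresholds(t);
      for (const arma::uvec& seed : seeds) {
        arma::uvec S = seed;
        for (int iter = 0; iter < max_iter; ++iter) {
          kabsch_fit(X, Y, S, X, d);
          arma::uvec inside = arma::find(d <= thr);
          if ((int)inside.n_elem > best[t]) best[t] = inside.n_elem;
          if (inside.n_elem < 3 ||
              (inside.n_elem == S.n_elem &&
               arma::all(inside == S))) break;
          S = inside;
        }
      }
    }
  }
  return Rcpp::IntegerVector(best.begin(), best.end());
}
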