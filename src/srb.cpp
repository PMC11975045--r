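#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// SplitMix64 finalizer: bijective avalanche mix of a 64-bit word.
static inline uint64_t sm64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t hash_seed(int seed) {
  return sm64(sm64((uint64_t)(int64_t)seed));
}

// Standard-normal deviate attached to the unordered motif pair (a, b) of one
// coupling stream.  Counter-based and stateless: identical on every call, so
// the full coupling table never needs to be stored.
static inline double pair_normal(uint64_t sh, int a, int b) {
  if (a > b) std::swap(a, b);
  uint64_t z = sm64(sh ^ (((uint64_t)(uint32_t)a << 32) | (uint64_t)(uint32_t)b));
  // 53-bit mantissa, offset by half a ulp so u is strictly inside (0, 1)
  double u = ((double)(z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  return R::qnorm(u, 0.0, 1.0, 1, 0);
}

// [[Rcpp::export]]
NumericVector cpp_coupling(IntegerVector seed, IntegerVector m1, IntegerVector m2,
                           double sigma) {
  R_xlen_t n = std::max(seed.size(), std::max(m1.size(), m2.size()));
  NumericVector out(n);
  bool one_seed = seed.size() == 1;
  uint64_t sh0 = one_seed ? hash_seed(seed[0]) : 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t sh = one_seed ? sh0 : hash_seed(seed[i % seed.size()]);
    out[i] = sigma * pair_normal(sh, m1[i % m1.size()], m2[i % m2.size()]);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_coupling_matrix(int M, int seed, double sigma) {
  NumericMatrix out(M, M);
  uint64_t sh = hash_seed(seed);
  for (int a = 0; a < M; ++a)
    for (int b = a; b < M; ++b) {
      double v = sigma * pair_normal(sh, a, b);
      out(a, b) = v;
      out(b, a) = v;
    }
  return out;
}

// Derive child stream seeds from (seed, label, index); result in [0, 2^31 - 2].
// [[Rcpp::export]]
IntegerVector cpp_derive_seed(int seed, std::string stream, IntegerVector index) {
  uint64_t z = hash_seed(seed);
  for (size_t i = 0; i < stream.size(); ++i)
    z = sm64(z ^ (uint64_t)(unsigned char)stream[i]);
  IntegerVector out(index.size());
  for (R_xlen_t i = 0; i < index.size(); ++i)
    out[i] = (int)(sm64(z ^ (uint64_t)(uint32_t)index[i]) % 2147483647ULL);
  return out;
}

// All oriented epitope-epitope energies between two proteins already encoded
// as motif matrices (rows = epitopes, columns = motif positions, 0-based
// motif codes).  parallel[a, b] = sum_i J(MP[a, i], MB[b, i]);
// antiparallel[a, b] = sum_i J(MP[a, lp - 1 - i], MB[b, i]).
// [[Rcpp::export]]
List cpp_pair_energies(IntegerMatrix MP, IntegerMatrix MB, int seed, double sigma) {
  int nP = MP.nrow(), nB = MB.nrow(), lp = MP.ncol();
  if (MB.ncol() != lp) stop("motif matrices must have the same number of columns");
  uint64_t sh = hash_seed(seed);
  std::unordered_map<uint64_t, double> cache;
  cache.reserve(256);
  NumericMatrix par(nP, nB), anti(nP, nB);
  for (int a = 0; a < nP; ++a) {
    for (int b = 0; b < nB; ++b) {
      double sp = 0.0, sa = 0.0;
      for (int i = 0; i < lp; ++i) {
        int x = MP(a, i), y = MB(b, i);
        if (x > y) std::swap(x, y);
        uint64_t k = ((uint64_t)(uint32_t)x << 32) | (uint64_t)(uint32_t)y;
        std::unordered_map<uint64_t, double>::iterator it = cache.find(k);
        double v;
        if (it == cache.end()) {
          v = sigma * pair_normal(sh, x, y);
          cache.emplace(k, v);
        } else v = it->second;
        sp += v;
        int xr = MP(a, lp - 1 - i), yr = MB(b, i);
        if (xr > yr) std::swap(xr, yr);
        uint64_t kr = ((uint64_t)(uint32_t)xr << 32) | (uint64_t)(uint32_t)yr;
        it = cache.find(kr);
        if (it == cache.end()) {
          v = sigma * pair_normal(sh, xr, yr);
          cache.emplace(kr, v);
        } else v = it->second;
        sa += v;
      }
      par(a, b) = sp;
      anti(a, b) = sa;
    }
  }
  return List::create(_["parallel"] = par, _["antiparallel"] = anti);
}

// Quenched coupling source: dense table for small motif alphabets, stateless
// hash otherwise (xi = 7 at ||A|| = 4 gives ||M|| = 16384, a 2 GB table).
struct CouplingSource {
  int M;
  bool dense;
  double sigma;
  uint64_t sh;
  std::vector<double> table;
  void init(int M_, int seed, double sigma_) {
    M = M_;
    sigma = sigma_;
    sh = hash_seed(seed);
    dense = M <= 4096;
    if (dense) {
      table.assign((size_t)M * M, 0.0);
      for (int a = 0; a < M; ++a)
        for (int b = a; b < M; ++b) {
          double v = sigma * pair_normal(sh, a, b);
          table[(size_t)a * M + b] = v;
          table[(size_t)b * M + a] = v;
        }
    }
  }
  inline double get(int a, int b) const {
    if (dense) return table[(size_t)a * M + b];
    return sigma * pair_normal(sh, a, b);
  }
};

// Mutation-selection dynamics of an ensemble of N binary complexes under the
// Fermi survival rule with a threshold tracking the current ensemble mean.
// In homodimer mode founderB is ignored and U is the minimum over the
// homodimer level set (unordered distinct epitope pairs x 2 orientations plus
// the two isologous levels per epitope); in heterodimer mode both proteins
// mutate and U is the minimum over all nP x nB pairs x 2 orientations.
// Uses R's RNG for mutation/selection/resampling draws.
// [[Rcpp::export]]
List cpp_evolve(IntegerMatrix founderP, IntegerMatrix founderB, IntegerVector perm,
                int A, int xi, int N, double eps, int generations,
                int coupling_seed, double sigma, double sel_width, bool homodimer) {
  int nP = founderP.nrow(), l = founderP.ncol();
  int lp = l - xi + 1;
  int nB = homodimer ? 0 : founderB.nrow();
  int M = perm.size();
  if (A < 2 || A > 255) stop("alphabet size out of range for the kernel");
  if (lp < 1) stop("xi exceeds the peptide length");
  if (N < 1) stop("ensemble size must be at least 1");

  CouplingSource J;
  J.init(M, coupling_seed, sigma);

  int nResP = nP * l, nResB = nB * l;
  int nRes = nResP + nResB;
  int nEpTot = homodimer ? nP : nP + nB;

  // first residue of a window is the most significant digit
  std::vector<int> pw(xi);
  pw[xi - 1] = 1;
  for (int k = xi - 2; k >= 0; --k) pw[k] = pw[k + 1] * A;

  std::vector<uint8_t> founder(nRes);
  for (int e = 0; e < nP; ++e)
    for (int j = 0; j < l; ++j) founder[e * l + j] = (uint8_t)founderP(e, j);
  if (!homodimer)
    for (int e = 0; e < nB; ++e)
      for (int j = 0; j < l; ++j) founder[nResP + e * l + j] = (uint8_t)founderB(e, j);

  std::vector<uint8_t> cur((size_t)N * nRes), nxt((size_t)N * nRes);
  for (int i = 0; i < N; ++i)
    std::copy(founder.begin(), founder.end(), cur.begin() + (size_t)i * nRes);

  std::vector<int> mot((size_t)nEpTot * lp);
  const int* permp = INTEGER(perm);

  // lowest level of the member's spectrum (complex binding energy, Eq. 4 role)
  auto member_min_energy = [&](const uint8_t* res) -> double {
    for (int e = 0; e < nEpTot; ++e) {
      const uint8_t* r = res + e * l;
      for (int i = 0; i < lp; ++i) {
        int t = 0;
        for (int k = 0; k < xi; ++k) t += r[i + k] * pw[k];
        mot[e * lp + i] = permp[t];
      }
    }
    double best = R_PosInf;
    if (homodimer) {
      for (int a = 0; a < nP; ++a) {
        const int* ma = &mot[(size_t)a * lp];
        for (int b = a; b < nP; ++b) {
          const int* mb = &mot[(size_t)b * lp];
          double sp = 0.0, sa = 0.0;
          for (int i = 0; i < lp; ++i) {
            sp += J.get(ma[i], mb[i]);
            sa += J.get(ma[lp - 1 - i], mb[i]);
          }
          if (sp < best) best = sp;
          if (sa < best) best = sa;
        }
      }
    } else {
      for (int a = 0; a < nP; ++a) {
        const int* ma = &mot[(size_t)a * lp];
        for (int b = 0; b < nB; ++b) {
          const int* mb = &mot[(size_t)(nP + b) * lp];
          double sp = 0.0, sa = 0.0;
          for (int i = 0; i < lp; ++i) {
            sp += J.get(ma[i], mb[i]);
            sa += J.get(ma[lp - 1 - i], mb[i]);
          }
          if (sp < best) best = sp;
          if (sa < best) best = sa;
        }
      }
    }
    return best;
  };

  std::vector<double> U(N), Unxt(N);
  double Uf = member_min_energy(founder.data());
  std::fill(U.begin(), U.end(), Uf);

  NumericVector trU0(generations), trMin(generations), trPost(generations);
  IntegerVector trSurv(generations);

  std::vector<int> idx(nRes);
  for (int j = 0; j < nRes; ++j) idx[j] = j;
  std::vector<int> survivors;
  survivors.reserve(N);

  for (int t = 0; t < generations; ++t) {
    // mutate every member; members with no substitution keep their cached U
    for (int i = 0; i < N; ++i) {
      uint8_t* res = &cur[(size_t)i * nRes];
      int k = (eps > 0.0) ? (int)R::rbinom((double)nRes, eps) : 0;
      if (k > 0) {
        // partial Fisher-Yates: k distinct positions, uniform over subsets
        for (int j = 0; j < k; ++j) {
          int r = j + (int)(R::unif_rand() * (double)(nRes - j));
          if (r >= nRes) r = nRes - 1;
          std::swap(idx[j], idx[r]);
        }
        for (int j = 0; j < k; ++j) {
          int pos = idx[j];
          int step = 1 + (int)(R::unif_rand() * (double)(A - 1));
          if (step > A - 1) step = A - 1;
          res[pos] = (uint8_t)((res[pos] + step) % A);
        }
        U[i] = member_min_energy(res);
      }
    }
    // threshold U0 = post-mutation, pre-selection ensemble mean
    double mean = 0.0, mn = R_PosInf;
    for (int i = 0; i < N; ++i) {
      mean += U[i];
      if (U[i] < mn) mn = U[i];
    }
    mean /= (double)N;
    trU0[t] = mean;
    trMin[t] = mn;

    survivors.clear();
    for (int i = 0; i < N; ++i) {
      double p = 1.0 / (std::exp((U[i] - mean) / sel_width) + 1.0);
      if (R::unif_rand() < p) survivors.push_back(i);
    }
    trSurv[t] = (int)survivors.size();

    if (!survivors.empty()) {
      int ns = (int)survivors.size();
      for (int i = 0; i < N; ++i) {
        int s = survivors[(int)(R::unif_rand() * (double)ns) % ns];
        std::copy(cur.begin() + (size_t)s * nRes,
                  cur.begin() + (size_t)(s + 1) * nRes,
                  nxt.begin() + (size_t)i * nRes);
        Unxt[i] = U[s];
      }
      std::swap(cur, nxt);
      std::swap(U, Unxt);
    } // zero survivors: keep the pre-selection ensemble

    double post = 0.0;
    for (int i = 0; i < N; ++i) post += U[i];
    trPost[t] = post / (double)N;

    if ((t & 31) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix fin(N, nRes);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < nRes; ++j) fin(i, j) = (int)cur[(size_t)i * nRes + j];
  NumericVector Uout(U.begin(), U.end());

  return List::create(_["U0"] = trU0, _["min_U"] = trMin,
                      _["survivors"] = trSurv, _["mean_U_selected"] = trPost,
                      _["final"] = fin, _["final_U"] = Uout);
}
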