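// Reduced nearest-neighbor RNA folding engine.
//
// Energy model (shared with the R-level score_structure / test oracle):
//   E(S) = sum of stack free energies over adjacent pairs
//        + sum of hairpin-loop terms + sum of internal/bulge-loop terms;
//   multibranch loops and exterior unpaired bases contribute 0.
// Stacks:  dG(T) = dH - T*dS.   Loops are purely entropic:
//   dG(T) = (T/310.15) * dG37, with Jacobson-Stockmayer log extrapolation
//   beyond the tabulated sizes.
//
// V(i,j) (best energy of a structure closed by pair i.j) and M(i,j)
// (best energy on [i..j] containing at least one pair, non-loop unpaired
// bases free) depend only on the subsequence [i..j], so a scan fills them
// once per temperature for all spans up to the largest window and reuses
// them for every window; only the exterior W array and the traceback are
// per-window work.  The same holds for the partition-function inside
// arrays Qb / Qm / Qmb.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double GASCONST = 1.98717e-3; // kcal/(mol*K)
static const double T37 = 310.15;
static const int MINHP = 3;     // minimum hairpin loop (unpaired)
static const int MAXLOOP = 30;  // internal/bulge loop total-unpaired cap
static const double EINF = 1e9;

// base codes: A=0, C=1, G=2, U=3; pair types AU,UA,CG,GC,GU,UG = 0..5
static inline int ptype(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Model {
  double dH[36], dS[36];          // [outer + 6*inner]
  std::vector<double> hp, lp;     // dG37 by size (1-based index)
  int hmax, lmax;
  double tK, RT;

  double stackE(int po, int pi) const {
    return dH[po + 6 * pi] - tK * dS[po + 6 * pi];
  }
  double hairpinE(int size) const {
    double g37 = (size <= hmax)
      ? hp[size]
      : hp[hmax] + 1.75 * GASCONST * T37 * std::log((double)size / hmax);
    return (tK / T37) * g37;
  }
  double loopE(int size) const {
    double g37 = (size <= lmax)
      ? lp[size]
      : lp[lmax] + 1.75 * GASCONST * T37 * std::log((double)size / lmax);
    return (tK / T37) * g37;
  }
};

static Model make_model(List par, double tK) {
  Model m;
  NumericMatrix dH = par["dH"], dS = par["dS"];
  for (int o = 0; o < 6; ++o)
    for (int i = 0; i < 6; ++i) {
      m.dH[o + 6 * i] = dH(o, i);
      m.dS[o + 6 * i] = dS(o, i);
    }
  NumericVector hp = par["hp"], lp = par["lp"];
  m.hmax = hp.size();
  m.lmax = lp.size();
  m.hp.assign(m.hmax + 1, 0.0);
  m.lp.assign(m.lmax + 1, 0.0);
  for (int s = 1; s <= m.hmax; ++s) m.hp[s] = hp[s - 1];
  for (int s = 1; s <= m.lmax; ++s) m.lp[s] = lp[s - 1];
  m.tK = tK;
  m.RT = GASCONST * tK;
  return m;
}

// ---------------------------------------------------------------- MFE ----

struct MfeTables {
  int n;
  std::vector<double> V, M; // flattened (i-1)*n + (j-1), 1-based i<j
  std::vector<int> seq;     // 0-based codes, seq[0] is position 1
  double at(const std::vector<double>& A, int i, int j) const {
    return A[(size_t)(i - 1) * n + (j - 1)];
  }
};

static void fill_mfe(const std::vector<int>& seq, const Model& m, int maxspan,
                     MfeTables& T) {
  int n = (int)seq.size();
  T.n = n;
  T.seq = seq;
  T.V.assign((size_t)n * n, EINF);
  T.M.assign((size_t)n * n, EINF);
  std::vector<double>& V = T.V;
  std::vector<double>& M = T.M;
  if (maxspan > n) maxspan = n;
  for (int len = MINHP + 2; len <= maxspan; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      size_t ij = (size_t)(i - 1) * n + (j - 1);
      int pij = ptype(seq[i - 1], seq[j - 1]);
      if (pij >= 0) {
        double best = m.hairpinE(j - i - 1);
        // stack / internal / bulge (two-loop)
        for (int k = i + 1; k <= j - 1 - (MINHP + 1) && k - i - 1 <= MAXLOOP; ++k) {
          int rem = MAXLOOP - (k - i - 1);
          int lmin = std::max(k + MINHP + 1, j - 1 - rem);
          for (int l = j - 1; l >= lmin; --l) {
            double vkl = V[(size_t)(k - 1) * n + (l - 1)];
            if (vkl >= EINF / 2) continue;
            int pkl = ptype(seq[k - 1], seq[l - 1]);
            double cost = (k == i + 1 && l == j - 1)
              ? m.stackE(pij, pkl)
              : m.loopE((k - i - 1) + (j - l - 1));
            double cand = cost + vkl;
            if (cand < best) best = cand;
          }
        }
        // multibranch: >= 2 branches inside, zero loop penalty
        for (int k = i + 1; k <= j - 2; ++k) {
          double a = M[(size_t)i * n + (k - 1)];         // M(i+1, k)
          double b = M[(size_t)k * n + (j - 2)];         // M(k+1, j-1)
          if (a >= EINF / 2 || b >= EINF / 2) continue;
          double cand = a + b;
          if (cand < best) best = cand;
        }
        V[ij] = best;
      }
      // M(i,j): >= 1 pair somewhere in [i..j], unpaired free
      double best = V[ij];
      double c = M[(size_t)i * n + (j - 1)];             // M(i+1, j)
      if (c < best) best = c;
      c = M[(size_t)(i - 1) * n + (j - 2)];              // M(i, j-1)
      if (c < best) best = c;
      for (int k = i + 1; k <= j - 2; ++k) {
        double a = M[(size_t)(i - 1) * n + (k - 1)];
        double b = M[(size_t)k * n + (j - 1)];
        if (a >= EINF / 2 || b >= EINF / 2) continue;
        double cand = a + b;
        if (cand < best) best = cand;
      }
      M[ij] = best;
    }
  }
}

// deterministic traceback; tie order: hairpin, stack, smallest interior
// loop, bifurcation at the smallest split point
static void traceV(const MfeTables& T, const Model& m, int i, int j,
                   std::vector<int>& mate);

static void traceM(const MfeTables& T, const Model& m, int i, int j,
                   std::vector<int>& mate) {
  int n = T.n;
  while (true) {
    double mm = T.M[(size_t)(i - 1) * n + (j - 1)];
    if (mm >= EINF / 2) stop("internal traceback error (M undefined)");
    if (T.V[(size_t)(i - 1) * n + (j - 1)] == mm) {
      traceV(T, m, i, j, mate);
      return;
    }
    if (i + 1 <= j && T.M[(size_t)i * n + (j - 1)] == mm) { ++i; continue; }
    if (i <= j - 1 && T.M[(size_t)(i - 1) * n + (j - 2)] == mm) { --j; continue; }
    for (int k = i + 1; k <= j - 2; ++k) {
      double a = T.M[(size_t)(i - 1) * n + (k - 1)];
      double b = T.M[(size_t)k * n + (j - 1)];
      if (a >= EINF / 2 || b >= EINF / 2) continue;
      if (a + b == mm) {
        traceM(T, m, i, k, mate);
        i = k + 1;
        goto next;
      }
    }
    stop("internal traceback error (M)");
    next:;
  }
}

static void traceV(const MfeTables& T, const Model& m, int i, int j,
                   std::vector<int>& mate) {
  int n = T.n;
  const std::vector<int>& seq = T.seq;
  while (true) {
    double v = T.V[(size_t)(i - 1) * n + (j - 1)];
    if (v >= EINF / 2) stop("internal traceback error (V undefined)");
    mate[i - 1] = j;
    mate[j - 1] = i;
    int pij = ptype(seq[i - 1], seq[j - 1]);
    if (m.hairpinE(j - i - 1) == v) return;
    // stack
    {
      int k = i + 1, l = j - 1;
      if (l - k - 1 >= MINHP) {
        double vkl = T.V[(size_t)(k - 1) * n + (l - 1)];
        if (vkl < EINF / 2) {
          int pkl = ptype(seq[k - 1], seq[l - 1]);
          if (m.stackE(pij, pkl) + vkl == v) { i = k; j = l; continue; }
        }
      }
    }
    // interior loops, smallest total unpaired first, then smallest k
    {
      bool found = false;
      for (int size = 1; size <= MAXLOOP && !found; ++size) {
        double cost = m.loopE(size);
        for (int u1 = 0; u1 <= size; ++u1) {
          int k = i + 1 + u1, l = j - 1 - (size - u1);
          if (k == i + 1 && l == j - 1) continue; // that's a stack
          if (l - k - 1 < MINHP || l > j - 1 || k < i + 1) continue;
          double vkl = T.V[(size_t)(k - 1) * n + (l - 1)];
          if (vkl >= EINF / 2) continue;
          if (cost + vkl == v) { i = k; j = l; found = true; break; }
        }
      }
      if (found) continue;
    }
    // multibranch, smallest split point
    for (int k = i + 1; k <= j - 2; ++k) {
      double a = T.M[(size_t)i * n + (k - 1)];
      double b = T.M[(size_t)k * n + (j - 2)];
      if (a >= EINF / 2 || b >= EINF / 2) continue;
      if (a + b == v) {
        traceM(T, m, i + 1, k, mate);
        traceM(T, m, k + 1, j - 1, mate);
        return;
      }
    }
    stop("internal traceback error (V)");
  }
}

// exterior prefix W over [s..j]; W[0] corresponds to j = s-1
static void fill_W(const MfeTables& T, int s, int emax, std::vector<double>& W) {
  int n = T.n;
  W.assign(emax - s + 2, 0.0);
  for (int j = s; j <= emax; ++j) {
    double best = W[j - s]; // j unpaired
    for (int k = s; k <= j - (MINHP + 1); ++k) {
      double v = T.V[(size_t)(k - 1) * n + (j - 1)];
      if (v >= EINF / 2) continue;
      double cand = W[k - s] + v;
      if (cand < best) best = cand;
    }
    W[j - s + 1] = best;
  }
}

// traceback of window [s..e] given prefix array W (from fill_W with the
// same s); fills mate (full-length, 1-based partners) for window positions
static void trace_exterior(const MfeTables& T, const Model& m, int s, int e,
                           const std::vector<double>& W, std::vector<int>& mate) {
  int n = T.n;
  int j = e;
  while (j >= s) {
    if (W[j - s + 1] == W[j - s]) { --j; continue; }
    bool found = false;
    for (int k = s; k <= j - (MINHP + 1); ++k) {
      double v = T.V[(size_t)(k - 1) * n + (j - 1)];
      if (v >= EINF / 2) continue;
      if (W[k - s] + v == W[j - s + 1]) {
        traceV(T, m, k, j, mate);
        j = k - 1;
        found = true;
        break;
      }
    }
    if (!found) stop("internal traceback error (W)");
  }
}

// ------------------------------------------------- partition function ----

struct PfTables {
  int n;
  std::vector<double> Qb, Qm, Qmb; // flattened as in MfeTables
  std::vector<int> seq;
};

static void fill_pf(const std::vector<int>& seq, const Model& m, int maxspan,
                    PfTables& T) {
  int n = (int)seq.size();
  T.n = n;
  T.seq = seq;
  T.Qb.assign((size_t)n * n, 0.0);
  T.Qm.assign((size_t)n * n, 0.0);
  T.Qmb.assign((size_t)n * n, 0.0);
  std::vector<double>& Qb = T.Qb;
  std::vector<double>& Qm = T.Qm;
  std::vector<double>& Qmb = T.Qmb;
  if (maxspan > n) maxspan = n;
  for (int len = 2; len <= maxspan; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      size_t ij = (size_t)(i - 1) * n + (j - 1);
      int pij = (len >= MINHP + 2) ? ptype(seq[i - 1], seq[j - 1]) : -1;
      if (pij >= 0) {
        double qb = std::exp(-m.hairpinE(j - i - 1) / m.RT);
        for (int k = i + 1; k <= j - 1 - (MINHP + 1) && k - i - 1 <= MAXLOOP; ++k) {
          int rem = MAXLOOP - (k - i - 1);
          int lmin = std::max(k + MINHP + 1, j - 1 - rem);
          for (int l = j - 1; l >= lmin; --l) {
            double q = Qb[(size_t)(k - 1) * n + (l - 1)];
            if (q <= 0) continue;
            int pkl = ptype(seq[k - 1], seq[l - 1]);
            double cost = (k == i + 1 && l == j - 1)
              ? m.stackE(pij, pkl)
              : m.loopE((k - i - 1) + (j - l - 1));
            qb += std::exp(-cost / m.RT) * q;
          }
        }
        qb += Qmb[(size_t)i * n + (j - 2)]; // multibranch inside (i+1, j-1)
        Qb[ij] = qb;
      }
      // Qm: >= 1 branch on [i..j]; first branch starts at i or later
      double qm = (i + 1 <= j) ? Qm[(size_t)i * n + (j - 1)] : 0.0;
      double qmb = (i + 1 <= j) ? Qmb[(size_t)i * n + (j - 1)] : 0.0;
      for (int l = i + MINHP + 1; l <= j; ++l) {
        double q = Qb[(size_t)(i - 1) * n + (l - 1)];
        if (q <= 0) continue;
        double tail = (l + 1 <= j) ? Qm[(size_t)l * n + (j - 1)] : 0.0;
        qm += q * (1.0 + tail);
        qmb += q * tail;
      }
      Qm[ij] = qm;
      Qmb[ij] = qmb;
    }
  }
}

// exterior partition over [s..j], Q[0] ~ j = s-1
static void fill_Q(const PfTables& T, const Model& m, int s, int emax,
                   std::vector<double>& Q) {
  int n = T.n;
  Q.assign(emax - s + 2, 1.0);
  for (int j = s; j <= emax; ++j) {
    double q = Q[j - s]; // j unpaired
    for (int k = s; k <= j - (MINHP + 1); ++k) {
      double qb = T.Qb[(size_t)(k - 1) * n + (j - 1)];
      if (qb > 0) q += Q[k - s] * qb;
    }
    Q[j - s + 1] = q;
  }
}

// pair probabilities inside window [s..e] by an outside recursion;
// returns flattened window-local (w x w) upper-triangular matrix
static void window_probs(const PfTables& T, const Model& m, int s, int e,
                         std::vector<double>& P, double& Z) {
  int n = T.n;
  int w = e - s + 1;
  const std::vector<int>& seq = T.seq;
  std::vector<double> Q, Qr(w + 2, 1.0);
  fill_Q(T, m, s, e, Q);
  Z = Q[w];
  // right exterior: Qr[j-s] = partition over [j..e]; Qr[w] ~ empty
  for (int j = e; j >= s; --j) {
    double q = Qr[j - s + 1];
    for (int l = j + MINHP + 1; l <= e; ++l) {
      double qb = T.Qb[(size_t)(j - 1) * n + (l - 1)];
      if (qb > 0) q += qb * Qr[l - s + 1];
    }
    Qr[j - s] = q;
  }
  std::vector<double> Qbout((size_t)w * w, 0.0);
  P.assign((size_t)w * w, 0.0);
  for (int len = w; len >= MINHP + 2; --len) {
    for (int i = s; i + len - 1 <= e; ++i) {
      int j = i + len - 1;
      if (T.Qb[(size_t)(i - 1) * n + (j - 1)] <= 0) continue;
      int pij = ptype(seq[i - 1], seq[j - 1]);
      // exterior context
      double t = Q[i - s] * Qr[j - s + 1];
      // two-loop context closed by (p,q)
      for (int p = i - 1; p >= s && i - p - 1 <= MAXLOOP; --p) {
        int rem = MAXLOOP - (i - p - 1);
        for (int q = j + 1; q <= e && q - j - 1 <= rem; ++q) {
          double qo = Qbout[(size_t)(p - s) * w + (q - s)];
          if (qo <= 0) continue;
          int ppq = ptype(seq[p - 1], seq[q - 1]);
          if (ppq < 0) continue;
          double cost = (p == i - 1 && q == j + 1)
            ? m.stackE(ppq, pij)
            : m.loopE((i - p - 1) + (q - j - 1));
          t += std::exp(-cost / m.RT) * qo;
        }
      }
      // multibranch context: (i,j) a branch of a loop closed by (p,q),
      // with at least one other branch
      for (int p = s; p <= i - 1; ++p) {
        for (int q = j + 1; q <= e; ++q) {
          double qo = Qbout[(size_t)(p - s) * w + (q - s)];
          if (qo <= 0) continue;
          double left = (p + 1 <= i - 1) ? T.Qm[(size_t)p * n + (i - 2)] : 0.0;
          double right = (j + 1 <= q - 1) ? T.Qm[(size_t)j * n + (q - 2)] : 0.0;
          double ways = (1.0 + left) * (1.0 + right) - 1.0;
          if (ways > 0) t += qo * ways;
        }
      }
      Qbout[(size_t)(i - s) * w + (j - s)] = t;
      P[(size_t)(i - s) * w + (j - s)] =
        T.Qb[(size_t)(i - 1) * n + (j - 1)] * t / Z;
    }
  }
}

// --------------------------------------------------------- R interface ----

static std::vector<int> as_codes(IntegerVector seq) {
  std::vector<int> s(seq.size());
  for (int i = 0; i < seq.size(); ++i) {
    s[i] = seq[i];
    if (s[i] < 0 || s[i] > 3) stop("invalid base code at position %d", i + 1);
  }
  return s;
}

// [[Rcpp::export]]
List mfe_fold_cpp(IntegerVector seq, double tK, List par) {
  std::vector<int> s = as_codes(seq);
  int n = (int)s.size();
  Model m = make_model(par, tK);
  MfeTables T;
  fill_mfe(s, m, n, T);
  std::vector<double> W;
  fill_W(T, 1, n, W);
  std::vector<int> mate(n, 0);
  trace_exterior(T, m, 1, n, W, mate);
  return List::create(_["energy"] = W[n], _["mate"] = IntegerVector(mate.begin(), mate.end()));
}

// [[Rcpp::export]]
List partition_cpp(IntegerVector seq, double tK, List par) {
  std::vector<int> s = as_codes(seq);
  int n = (int)s.size();
  Model m = make_model(par, tK);
  PfTables T;
  fill_pf(s, m, n, T);
  std::vector<double> P;
  double Z;
  window_probs(T, m, 1, n, P, Z);
  NumericMatrix Pm(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      Pm(i, j) = P[(size_t)i * n + j];
  return List::create(_["Z"] = Z, _["p"] = Pm);
}

// centroid mates within a window from window-local probabilities
static void centroid_mates(const std::vector<double>& P, int s, int w,
                           std::vector<int>& mate) {
  for (int a = 0; a < w; ++a)
    for (int b = a + 1; b < w; ++b)
      if (P[(size_t)a * w + b] > 0.5) {
        mate[s - 1 + a] = s + b;
        mate[s - 1 + b] = s + a;
      }
}

static int mate_distance(const std::vector<int>& m1, const std::vector<int>& m2,
                         int s, int e) {
  int d = 0;
  for (int i = s; i <= e; ++i) {
    if (m1[i - 1] > i && m1[i - 1] != m2[i - 1]) ++d;
    if (m2[i - 1] > i && m2[i - 1] != m1[i - 1]) ++d;
  }
  return d;
}

// mode: 0 = mfe, 1 = centroid.  Returns dot records ordered by
// (window size ascending, start ascending).
// [[Rcpp::export]]
List scan_cpp(IntegerVector seq, int wmin, int wmax, double t1K, double t2K,
              int mode, List par) {
  std::vector<int> s = as_codes(seq);
  int n = (int)s.size();
  if (wmin < 1 || wmax < wmin) stop("invalid window range");
  int maxspan = std::min(wmax, n);
  Model m1 = make_model(par, t1K);
  Model m2 = make_model(par, t2K);

  // output slots: ascending w, then ascending start
  std::vector<int> offset(wmax + 2, 0);
  int total = 0;
  for (int w = wmin; w <= wmax; ++w) {
    offset[w] = total;
    total += std::max(0, n - w + 1);
  }
  IntegerVector ox(total), ow(total), od(total);

  if (mode == 0) {
    MfeTables A, B;
    fill_mfe(s, m1, maxspan, A);
    fill_mfe(s, m2, maxspan, B);
    std::vector<double> WA, WB;
    std::vector<int> mateA(n), mateB(n);
    for (int st = 1; st <= n - wmin + 1; ++st) {
      int emax = std::min(n, st + wmax - 1);
      fill_W(A, st, emax, WA);
      fill_W(B, st, emax, WB);
      for (int w = wmin; w <= wmax; ++w) {
        int e = st + w - 1;
        if (e > n) break;
        std::fill(mateA.begin(), mateA.end(), 0);
        std::fill(mateB.begin(), mateB.end(), 0);
        trace_exterior(A, m1, st, e, WA, mateA);
        trace_exterior(B, m2, st, e, WB, mateB);
        int idx = offset[w] + (st - 1);
        ox[idx] = st;
        ow[idx] = w;
        od[idx] = mate_distance(mateA, mateB, st, e);
      }
    }
  } else {
    PfTables A, B;
    fill_pf(s, m1, maxspan, A);
    fill_pf(s, m2, maxspan, B);
    std::vector<double> PA, PB;
    std::vector<int> mateA(n), mateB(n);
    double Z;
    for (int st = 1; st <= n - wmin + 1; ++st) {
      for (int w = wmin; w <= wmax; ++w) {
        int e = st + w - 1;
        if (e > n) break;
        std::fill(mateA.begin(), mateA.end(), 0);
        std::fill(mateB.begin(), mateB.end(), 0);
        window_probs(A, m1, st, e, PA, Z);
        window_probs(B, m2, st, e, PB, Z);
        centroid_mates(PA, st, w, mateA);
        centroid_mates(PB, st, w, mateB);
        int idx = offset[w] + (st - 1);
        ox[idx] = st;
        ow[idx] = w;
        od[idx] = mate_distance(mateA, mateB, st, e);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["x"] = ox, _["w"] = ow, _["distance"] = od);
}
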