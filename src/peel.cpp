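#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact pedigree likelihood over a 3-state latent type by variable
// elimination.  Factors are the founder prior, one transmission factor per
// non-founder (child, father, mother) and per-individual penetrances
// (pre-multiplied into the unary/ternary factors).  Elimination order is
// greedy smallest-resulting-scope; per-step rescaling keeps values in range
// even when penetrances are ~exp(-700).

struct Factor {
  std::vector<int> vars;        // member indices, first var has stride 1
  std::vector<double> val;      // length 3^vars.size()
  bool alive;
};

static double peel_one(int n,
                       const int *father,  // 1-based within pedigree, 0 = founder
                       const int *mother,
                       const int *elim,    // 1-based elimination order
                       const double *pen,  // 3 x n, type fastest
                       const double *prior,   // length 3 (AA, AB, BB)
                       const double *trans) { // 27: child + 3*father + 9*mother
  std::vector<Factor> fs;
  fs.reserve(n);
  for (int i = 0; i < n; ++i) {
    Factor f;
    f.alive = true;
    if (father[i] == 0) {           // founder: prior * penetrance
      f.vars = { i };
      f.val.resize(3);
      for (int u = 0; u < 3; ++u) f.val[u] = prior[u] * pen[3 * i + u];
    } else {                        // transmission * child's penetrance
      int fa = father[i] - 1, mo = mother[i] - 1;
      f.vars = { i, fa, mo };
      f.val.resize(27);
      for (int um = 0; um < 3; ++um)
        for (int uf = 0; uf < 3; ++uf)
          for (int uc = 0; uc < 3; ++uc)
            f.val[uc + 3 * uf + 9 * um] =
              trans[uc + 3 * uf + 9 * um] * pen[3 * i + uc];
    }
    fs.push_back(std::move(f));
  }

  double logscale = 0.0;
  std::vector<double> joint;      // scratch, reused across steps

  for (int step = 0; step < n; ++step) {
    int best_v = elim[step] - 1;

    // union scope with the eliminated variable first
    int U[13];
    int ku = 1;
    U[0] = best_v;
    int used[32];
    int nused = 0;
    for (size_t j = 0; j < fs.size(); ++j) {
      Factor &f = fs[j];
      if (!f.alive) continue;
      bool has = false;
      for (int w : f.vars) if (w == best_v) { has = true; break; }
      if (!has) continue;
      if (nused == 32) stop("pedigree too entangled for exact peeling");
      used[nused++] = (int) j;
      for (int w : f.vars) {
        bool seen = false;
        for (int u = 0; u < ku; ++u) if (U[u] == w) { seen = true; break; }
        if (!seen) {
          if (ku == 13) stop("pedigree too entangled for exact peeling");
          U[ku++] = w;
        }
      }
    }
    if (nused == 0) continue;       // variable no longer in any factor
    int k = ku;
    if (k > 12) stop("pedigree too entangled for exact peeling");
    size_t m = 1; for (int j = 0; j < k; ++j) m *= 3;

    // per-factor strides along the joint index over U
    size_t stride[32][13];
    const double *vals[32];
    for (int fi = 0; fi < nused; ++fi) {
      const Factor &f = fs[used[fi]];
      vals[fi] = f.val.data();
      for (int j = 0; j < k; ++j) stride[fi][j] = 0;
      size_t s = 1;
      for (size_t a = 0; a < f.vars.size(); ++a, s *= 3)
        for (int j = 0; j < k; ++j)
          if (U[j] == f.vars[a]) stride[fi][j] = s;
    }

    if (joint.size() < m) joint.resize(m);
    int digit[13];
    size_t fidx[32];
    for (int j = 0; j < k; ++j) digit[j] = 0;
    for (int fi = 0; fi < nused; ++fi) fidx[fi] = 0;
    for (size_t idx = 0; idx < m; ++idx) {
      double p = vals[0][fidx[0]];
      for (int fi = 1; fi < nused; ++fi) p *= vals[fi][fidx[fi]];
      joint[idx] = p;
      // increment mixed-radix counter and factor indices
      for (int j = 0; j < k; ++j) {
        if (++digit[j] < 3) {
          for (int fi = 0; fi < nused; ++fi) fidx[fi] += stride[fi][j];
          break;
        }
        digit[j] = 0;
        for (int fi = 0; fi < nused; ++fi) fidx[fi] -= 2 * stride[fi][j];
      }
    }

    // sum out best_v (stride 1), rescale
    Factor nf;
    nf.alive = true;
    nf.vars.assign(U + 1, U + k);
    nf.val.resize(m / 3);
    double mx = 0.0;
    for (size_t r = 0; r < m / 3; ++r) {
      double s = joint[3 * r] + joint[3 * r + 1] + joint[3 * r + 2];
      nf.val[r] = s;
      if (s > mx) mx = s;
    }
    if (!(mx > 0.0)) return R_NegInf;
    for (size_t r = 0; r < m / 3; ++r) nf.val[r] /= mx;
    logscale += std::log(mx);

    for (int fi = 0; fi < nused; ++fi) fs[used[fi]].alive = false;
    if (!nf.vars.empty()) fs.push_back(std::move(nf));
    else logscale += std::log(nf.val[0]);   // scalar remnant (==1 after rescale)
  }
  return logscale;
}

// Full regressive-model likelihood for a set of pedigrees: builds the
// penetrance tables from the parameters and the precomputed regressive
// indicators, then peels each family. With ascertain = true the log
// marginal probability of the proband's affection (all other phenotypes
// unknown, regressive terms vanishing) is subtracted per family.
// [[Rcpp::export]]
NumericVector peel_model_cpp(IntegerVector n_members,
                             IntegerVector father,
                             IntegerVector mother,
                             IntegerVector elim,
                             IntegerVector trait,      // 1 aff, 0 unaff, -1 unknown
                             NumericVector assoc,      // delta/covariate sum per member
                             NumericVector xb,         // covariate term per member
                             IntegerVector proband_global, // 1-based, NA if none
                             NumericVector beta,       // length 3
                             double q_A,
                             NumericVector tau,        // length 3
                             bool ascertain) {
  int nped = n_members.size();
  int total = father.size();
  double prior[3] = { q_A * q_A, 2 * q_A * (1 - q_A),
                      (1 - q_A) * (1 - q_A) };
  double trans[27];
  for (int m = 0; m < 3; ++m)
    for (int f = 0; f < 3; ++f) {
      double a = tau[f], b = tau[m];
      trans[0 + 3 * f + 9 * m] = a * b;
      trans[1 + 3 * f + 9 * m] = a * (1 - b) + (1 - a) * b;
      trans[2 + 3 * f + 9 * m] = (1 - a) * (1 - b);
    }
  std::vector<double> pen(3 * total);
  for (int i = 0; i < total; ++i) {
    if (trait[i] < 0) {
      pen[3 * i] = pen[3 * i + 1] = pen[3 * i + 2] = 1.0;
    } else {
      for (int u = 0; u < 3; ++u) {
        double th = beta[u] + assoc[i] + xb[i];
        // log P(t | theta) = t*th - log1p(exp(th)), stable in both tails
        double lp;
        if (th > 0) lp = (trait[i] ? 0.0 : -th) - std::log1p(std::exp(-th));
        else lp = (trait[i] ? th : 0.0) - std::log1p(std::exp(th));
        pen[3 * i + u] = std::exp(lp);
      }
    }
  }
  NumericVector out(nped);
  int off = 0;
  for (int p = 0; p < nped; ++p) {
    int n = n_members[p];
    out[p] = peel_one(n, &father[off], &mother[off], &elim[off],
                      &pen[3 * off], prior, trans);
    if (ascertain) {
      int pb = proband_global[p];   // 1-based global index
      std::vector<double> pen0(3 * n, 1.0);
      int local = pb - 1 - off;
      for (int u = 0; u < 3; ++u) {
        double th = beta[u] + xb[pb - 1];
        double g = (th > 0) ? 1.0 / (1.0 + std::exp(-th))
                            : std::exp(th) / (1.0 + std::exp(th));
        pen0[3 * local + u] = g;
      }
      out[p] -= peel_one(n, &father[off], &mother[off], &elim[off],
                         &pen0[0], prior, trans);
    }
    off += n;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector peel_loglik_cpp(IntegerVector n_members,
                              IntegerVector father,
                              IntegerVector mother,
                              IntegerVector elim,
                              NumericVector pen,
                              NumericVector prior,
                              NumericVector trans) {
  int nped = n_members.size();
  NumericVector out(nped);
  int off = 0;
  for (int p = 0; p < nped; ++p) {
    int n = n_members[p];
    out[p] = peel_one(n, &father[off], &mother[off], &elim[off],
                      &pen[3 * off], &prior[0], &trans[0]);
    off += n;
  }
  return out;
}
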