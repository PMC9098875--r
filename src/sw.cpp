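#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// A gap of length L costs gap_open + L * gap_ext (opening charged once,
// extension charged for every gapped position, including the first).
// N (code 4) scores as a mismatch against everything, including N itself.

static inline int encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 4;
    default: return -1;
  }
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int b = encode_base(s[i]);
    if (b < 0) stop("invalid character '%s' in sequence (alphabet is A,C,G,T,N)",
                    std::string(1, s[i]).c_str());
    v[i] = b;
  }
  return v;
}

static inline double subst(int a, int b, double match, double mismatch) {
  return (a == b && a < 4) ? match : mismatch;
}

// [[Rcpp::export]]
double sw_score_cpp(std::string a, std::string b, double match, double mismatch,
                    double gap_open, double gap_ext) {
  std::vector<int> x = encode_seq(a), y = encode_seq(b);
  const int n = (int)x.size(), m = (int)y.size();
  if (n == 0 || m == 0) return 0.0;
  const double gopen = gap_open + gap_ext;  // cost of a length-1 gap
  const double NEG = -1e300;

  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fcol(m + 1, NEG);  // gap in b (vertical), per column
  double best = 0.0;

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    double E = NEG;  // gap in a (horizontal), within this row
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hcur[j - 1] - gopen, E - gap_ext);
      Fcol[j] = std::max(Hprev[j] - gopen, Fcol[j] - gap_ext);
      double h = Hprev[j - 1] + subst(x[i - 1], y[j - 1], match, mismatch);
      h = std::max(h, E);
      h = std::max(h, Fcol[j]);
      if (h < 0.0) h = 0.0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// Full-matrix variant returning the optimal score plus the aligned spans
// (0-based half-open on each sequence). Traceback ties are broken
// diagonal > up (gap in b) > left (gap in a). Quadratic memory; intended
// for on-request span extraction, not bulk scoring.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_ext) {
  std::vector<int> x = encode_seq(a), y = encode_seq(b);
  const int n = (int)x.size(), m = (int)y.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  const double gopen = gap_open + gap_ext;
  const double NEG = -1e300;
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[at(i, j)] = std::max(H[at(i, j - 1)] - gopen, E[at(i, j - 1)] - gap_ext);
      F[at(i, j)] = std::max(H[at(i - 1, j)] - gopen, F[at(i - 1, j)] - gap_ext);
      double diag = H[at(i - 1, j - 1)] + subst(x[i - 1], y[j - 1], match, mismatch);
      double h = std::max(0.0, std::max(diag, std::max(E[at(i, j)], F[at(i, j)])));
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);

  // traceback from (bi, bj) until H hits 0
  const double eps = 1e-9;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = F (up, gap in b), 2 = E (left, gap in a)
  while (i > 0 && j > 0) {
    if (state == 0) {
      double h = H[at(i, j)];
      if (h <= eps) break;
      double diag = H[at(i - 1, j - 1)] + subst(x[i - 1], y[j - 1], match, mismatch);
      if (std::abs(h - diag) < eps) { --i; --j; }
      else if (std::abs(h - F[at(i, j)]) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      bool opened = std::abs(F[at(i, j)] - (H[at(i - 1, j)] - gopen)) < eps;
      --i;
      if (opened) state = 0;
    } else {
      bool opened = std::abs(E[at(i, j)] - (H[at(i, j - 1)] - gopen)) < eps;
      --j;
      if (opened) state = 0;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj);
}
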