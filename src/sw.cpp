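#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman with Gotoh's three-state
// recursion) on integer-encoded residues.
//
// a, b : 0-based indices into rows/columns of the scoring matrix `mat`.
// A gap of length L costs gap_open + gap_extend * L (BLAST convention:
// the first gapped residue pays both the opening and one extension).
//
// Returns the optimal score, the 0-based half-open spans of the aligned
// region in each sequence, and the aligned position vectors (NA = gap).
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix mat,
                  double gap_open, double gap_extend) {
    const int n = a.size(), m = b.size();
    const double NEG = -1e18;

    std::vector<std::vector<double> > H(n + 1, std::vector<double>(m + 1, 0.0));
    std::vector<std::vector<double> > E(n + 1, std::vector<double>(m + 1, NEG));
    std::vector<std::vector<double> > F(n + 1, std::vector<double>(m + 1, NEG));
    // tbH: 0 stop, 1 diagonal, 2 came from E (gap in a), 3 came from F (gap in b)
    // tbE/tbF: 1 = gap opened from H, 0 = gap extended
    std::vector<std::vector<char> > tbH(n + 1, std::vector<char>(m + 1, 0));
    std::vector<std::vector<char> > tbE(n + 1, std::vector<char>(m + 1, 0));
    std::vector<std::vector<char> > tbF(n + 1, std::vector<char>(m + 1, 0));

    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double eo = H[i][j - 1] - (gap_open + gap_extend);
            double ee = E[i][j - 1] - gap_extend;
            if (eo >= ee) { E[i][j] = eo; tbE[i][j] = 1; }
            else          { E[i][j] = ee; tbE[i][j] = 0; }

            double fo = H[i - 1][j] - (gap_open + gap_extend);
            double fe = F[i - 1][j] - gap_extend;
            if (fo >= fe) { F[i][j] = fo; tbF[i][j] = 1; }
            else          { F[i][j] = fe; tbF[i][j] = 0; }

            double diag = H[i - 1][j - 1] + mat(a[i - 1], b[j - 1]);
            double h = 0.0; char t = 0;
            if (diag > h)    { h = diag;    t = 1; }
            if (E[i][j] > h) { h = E[i][j]; t = 2; }
            if (F[i][j] > h) { h = F[i][j]; t = 3; }
            H[i][j] = h; tbH[i][j] = t;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }

    std::vector<int> qa, sa;   // -1 encodes a gap
    int i = bi, j = bj, state = 0;
    while (i > 0 && j > 0) {
        if (state == 0) {
            char t = tbH[i][j];
            if (t == 0) break;
            if (t == 1)      { qa.push_back(i - 1); sa.push_back(j - 1); --i; --j; }
            else if (t == 2) { state = 2; }
            else             { state = 3; }
        } else if (state == 2) {        // gap in a, consume b[j-1]
            qa.push_back(-1); sa.push_back(j - 1);
            char t = tbE[i][j];
            --j;
            if (t == 1) state = 0;
        } else {                        // gap in b, consume a[i-1]
            qa.push_back(i - 1); sa.push_back(-1);
            char t = tbF[i][j];
            --i;
            if (t == 1) state = 0;
        }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(sa.begin(), sa.end());

    int qs = 0, qe = 0, ss = 0, se = 0;
    bool any = false;
    for (size_t k = 0; k < qa.size(); ++k) {
        if (qa[k] >= 0) {
            if (!any || qa[k] < qs) qs = qa[k];
            if (!any || qa[k] + 1 > qe) qe = qa[k] + 1;
        }
        if (sa[k] >= 0) {
            if (!any || sa[k] < ss) ss = sa[k];
            if (!any || sa[k] + 1 > se) se = sa[k] + 1;
        }
        any = true;
    }
    // recompute spans independently per sequence (the !any shortcut above
    // mixes them when the first column is a gap)
    qs = qe = ss = se = 0; bool anyq = false, anys = false;
    for (size_t k = 0; k < qa.size(); ++k) {
        if (qa[k] >= 0) {
            if (!anyq) { qs = qa[k]; anyq = true; }
            qe = qa[k] + 1;
        }
        if (sa[k] >= 0) {
            if (!anys) { ss = sa[k]; anys = true; }
            se = sa[k] + 1;
        }
    }

    IntegerVector qv(qa.size()), sv(sa.size());
    for (size_t k = 0; k < qa.size(); ++k) {
        qv[k] = (qa[k] < 0) ? NA_INTEGER : qa[k];
        sv[k] = (sa[k] < 0) ? NA_INTEGER : sa[k];
    }
    return List::create(_["score"] = best,
                        _["q_start"] = qs, _["q_end"] = qe,
                        _["s_start"] = ss, _["s_end"] = se,
                        _["q_aln"] = qv, _["s_aln"] = sv);
}
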