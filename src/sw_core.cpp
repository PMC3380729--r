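#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cstdint>
using namespace Rcpp;

// Flattened sequence store: one contiguous int buffer plus offsets, so the
// all-vs-all loops touch no R objects.
struct SeqStore {
    std::vector<int> buf;
    std::vector<int> off;
    std::vector<int> len;
    explicit SeqStore(const List& seqs) {
        int n = seqs.size();
        off.resize(n);
        len.resize(n);
        size_t total = 0;
        for (int i = 0; i < n; ++i) total += Rf_length(seqs[i]);
        buf.reserve(total);
        for (int i = 0; i < n; ++i) {
            IntegerVector s = seqs[i];
            off[i] = (int)buf.size();
            len[i] = s.size();
            for (int k = 0; k < s.size(); ++k) buf.push_back(s[k]);
        }
    }
    const int* seq(int i) const { return buf.data() + off[i]; }
};

// Linear-gap local alignment score, rolling single row.
static inline int sw_score(const int* a, int la, const int* b, int lb,
                           const int* S, int ns, int gap, int* H) {
    int best = 0;
    for (int j = 0; j <= lb; ++j) H[j] = 0;
    for (int i = 1; i <= la; ++i) {
        const int* Srow = S + (size_t)a[i - 1]; // column-major, symmetric
        int diagOld = H[0];
        int left = 0;
        for (int j = 1; j <= lb; ++j) {
            int old = H[j];
            int val = diagOld + Srow[(size_t)b[j - 1] * ns];
            int up = old - gap;
            if (up > val) val = up;
            int lf = left - gap;
            if (lf > val) val = lf;
            if (val < 0) val = 0;
            H[j] = val;
            left = val;
            diagOld = old;
            if (val > best) best = val;
        }
    }
    return best;
}

// [[Rcpp::export]]
List cpp_sw_pair(IntegerVector a, IntegerVector b, IntegerMatrix S, int gap) {
    int la = a.size(), lb = b.size(), ns = S.nrow();
    const int* Sp = S.begin();
    std::vector<int> H((size_t)(la + 1) * (lb + 1), 0);
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= la; ++i) {
        for (int j = 1; j <= lb; ++j) {
            int val = H[(size_t)(i - 1) * (lb + 1) + (j - 1)] +
                      Sp[a[i - 1] + (size_t)b[j - 1] * ns];
            int up = H[(size_t)(i - 1) * (lb + 1) + j] - gap;
            if (up > val) val = up;
            int lf = H[(size_t)i * (lb + 1) + (j - 1)] - gap;
            if (lf > val) val = lf;
            if (val < 0) val = 0;
            H[(size_t)i * (lb + 1) + j] = val;
            // strict '>' keeps the first optimum in (i, j) scan order, i.e.
            // the smallest (query_end, subject_end) lexicographically
            if (val > best) { best = val; bi = i; bj = j; }
        }
    }
    int qs = 0, qe = 0, ss = 0, se = 0;
    if (best > 0) {
        qe = bi; se = bj;
        int i = bi, j = bj;
        while (i > 0 && j > 0) {
            int h = H[(size_t)i * (lb + 1) + j];
            if (h == 0) break;
            int diag = H[(size_t)(i - 1) * (lb + 1) + (j - 1)] +
                       Sp[a[i - 1] + (size_t)b[j - 1] * ns];
            if (h == diag) { --i; --j; continue; }
            if (h == H[(size_t)(i - 1) * (lb + 1) + j] - gap) { --i; continue; }
            --j;
        }
        qs = i; ss = j;
    }
    return List::create(_["score"] = best,
                        _["query_start"] = qs, _["query_end"] = qe,
                        _["subject_start"] = ss, _["subject_end"] = se);
}

// [[Rcpp::export]]
IntegerVector cpp_sw_one_vs_many(IntegerVector q, List subjects,
                                 IntegerMatrix S, int gap) {
    SeqStore st(subjects);
    int n = st.len.size(), ns = S.nrow();
    const int* Sp = S.begin();
    std::vector<int> qv(q.begin(), q.end());
    int maxlen = 0;
    for (int i = 0; i < n; ++i) if (st.len[i] > maxlen) maxlen = st.len[i];
    std::vector<int> H(maxlen + 1);
    IntegerVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = sw_score(qv.data(), (int)qv.size(), st.seq(i), st.len[i],
                          Sp, ns, gap, H.data());
    return out;
}

// Pass 1 of the significance scan: per-window count / sum / sum of squares of
// scores against all windows from other proteins.
// [[Rcpp::export]]
List cpp_sw_allpairs_stats(List seqs, IntegerVector prot, IntegerMatrix S,
                           int gap) {
    SeqStore st(seqs);
    int n = st.len.size(), ns = S.nrow();
    const int* Sp = S.begin();
    int maxlen = 0;
    for (int i = 0; i < n; ++i) if (st.len[i] > maxlen) maxlen = st.len[i];
    std::vector<int> H(maxlen + 1);
    std::vector<double> cnt(n, 0.0), sum(n, 0.0), sumsq(n, 0.0);
    for (int i = 0; i < n; ++i) {
        if (i % 64 == 0) Rcpp::checkUserInterrupt();
        for (int j = i + 1; j < n; ++j) {
            if (prot[i] == prot[j]) continue;
            int s = sw_score(st.seq(i), st.len[i], st.seq(j), st.len[j],
                             Sp, ns, gap, H.data());
            double d = (double)s;
            cnt[i] += 1; sum[i] += d; sumsq[i] += d * d;
            cnt[j] += 1; sum[j] += d; sumsq[j] += d * d;
        }
    }
    return List::create(_["n"] = wrap(cnt), _["sum"] = wrap(sum),
                        _["sumsq"] = wrap(sumsq));
}

// Pass 2: emit window pairs whose score reaches both windows' thresholds.
// thr is per-window; NA (NaN) disables a window.
// [[Rcpp::export]]
DataFrame cpp_sw_allpairs_sig(List seqs, IntegerVector prot, IntegerMatrix S,
                              int gap, NumericVector thr) {
    SeqStore st(seqs);
    int n = st.len.size(), ns = S.nrow();
    const int* Sp = S.begin();
    int maxlen = 0;
    for (int i = 0; i < n; ++i) if (st.len[i] > maxlen) maxlen = st.len[i];
    std::vector<int> H(maxlen + 1);
    std::vector<int> ia, jb, sc;
    for (int i = 0; i < n; ++i) {
        if (i % 64 == 0) Rcpp::checkUserInterrupt();
        if (NumericVector::is_na(thr[i])) continue;
        double ti = thr[i];
        for (int j = i + 1; j < n; ++j) {
            if (prot[i] == prot[j]) continue;
            if (NumericVector::is_na(thr[j])) continue;
            int s = sw_score(st.seq(i), st.len[i], st.seq(j), st.len[j],
                             Sp, ns, gap, H.data());
            if ((double)s >= ti && (double)s >= thr[j]) {
                ia.push_back(i + 1); jb.push_back(j + 1); sc.push_back(s);
            }
        }
    }
    return DataFrame::create(_["window_a"] = wrap(ia), _["window_b"] = wrap(jb),
                             _["score"] = wrap(sc));
}

// Best ungapped placement of a position-specific score profile along each
// window. Offsets may hang over either end; only overlapping columns score,
// and placements with fewer than minOverlap overlapping columns (capped at
// the shorter of the two lengths) are not considered.
// [[Rcpp::export]]
NumericVector cpp_profile_best_scores(NumericMatrix prof, List windows,
                                      int minOverlap) {
    SeqStore st(windows);
    int n = st.len.size();
    int Lp = prof.nrow();
    const double* P = prof.begin();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        int Lw = st.len[i];
        const int* wseq = st.seq(i);
        int mo = minOverlap;
        if (mo > Lp) mo = Lp;
        if (mo > Lw) mo = Lw;
        if (mo < 1) mo = 1;
        double best = -std::numeric_limits<double>::infinity();
        for (int o = -(Lp - mo); o <= Lw - mo; ++o) {
            int k0 = o < 0 ? -o : 0;
            int k1 = (Lw - o < Lp) ? (Lw - o) : Lp;
            double s = 0.0;
            for (int k = k0; k < k1; ++k)
                s += P[k + (size_t)wseq[o + k] * Lp];
            if (s > best) best = s;
        }
        out[i] = best;
    }
    return out;
}

// Pairwise distance (1 - identity) used for the MSA guide tree: identity is
// the best count of matching residues over all ungapped offsets, divided by
// the shorter sequence length.
// [[Rcpp::export]]
NumericMatrix cpp_pid_dist(List seqs) {
    SeqStore st(seqs);
    int n = st.len.size();
    NumericMatrix D(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            int li = st.len[i], lj = st.len[j];
            const int* a = st.seq(i);
            const int* b = st.seq(j);
            int bestm = 0;
            for (int o = -(lj - 1); o <= li - 1; ++o) {
                int k0 = o < 0 ? -o : 0;
                int k1 = (li - o < lj) ? (li - o) : lj;
                int m = 0;
                for (int k = k0; k < k1; ++k)
                    if (a[o + k] == b[k]) ++m;
                if (m > bestm) bestm = m;
            }
            double pid = (double)bestm / (double)(li < lj ? li : lj);
            D(i, j) = 1.0 - pid;
            D(j, i) = 1.0 - pid;
        }
    }
    return D;
}

// Needleman-Wunsch over a profile-column score matrix with free terminal
// gaps (used to merge two alignments during progressive MSA). Returns the
// alignment path as two integer vectors of 1-based column indices, 0 = gap.
// [[Rcpp::export]]
List cpp_nw_profile_path(NumericMatrix cs, double gap) {
    int ca = cs.nrow(), cb = cs.ncol();
    std::vector<double> H((size_t)(ca + 1) * (cb + 1), 0.0);
    for (int i = 1; i <= ca; ++i) {
        for (int j = 1; j <= cb; ++j) {
            double d = H[(size_t)(i - 1) * (cb + 1) + j - 1] + cs(i - 1, j - 1);
            double u = H[(size_t)(i - 1) * (cb + 1) + j] - gap;
            double l = H[(size_t)i * (cb + 1) + j - 1] - gap;
            double v = d;
            if (u > v) v = u;
            if (l > v) v = l;
            H[(size_t)i * (cb + 1) + j] = v;
        }
    }
    int bi = ca, bj = cb;
    double best = H[(size_t)ca * (cb + 1) + cb];
    for (int j = 0; j <= cb; ++j) {
        double v = H[(size_t)ca * (cb + 1) + j];
        if (v > best) { best = v; bi = ca; bj = j; }
    }
    for (int i = 0; i <= ca; ++i) {
        double v = H[(size_t)i * (cb + 1) + cb];
        if (v > best) { best = v; bi = i; bj = cb; }
    }
    std::vector<int> ai, bv;
    int i = bi, j = bj;
    while (i > 0 && j > 0) {
        double h = H[(size_t)i * (cb + 1) + j];
        if (h == H[(size_t)(i - 1) * (cb + 1) + j - 1] + cs(i - 1, j - 1)) {
            ai.push_back(i); bv.push_back(j); --i; --j;
        } else if (h == H[(size_t)(i - 1) * (cb + 1) + j] - gap) {
            ai.push_back(i); bv.push_back(0); --i;
        } else {
            ai.push_back(0); bv.push_back(j); --j;
        }
    }
    while (i > 0) { ai.push_back(i); bv.push_back(0); --i; }
    while (j > 0) { ai.push_back(0); bv.push_back(j); --j; }
    std::reverse(ai.begin(), ai.end());
    std::reverse(bv.begin(), bv.end());
    for (int k = bi + 1; k <= ca; ++k) { ai.push_back(k); bv.push_back(0); }
    for (int k = bj + 1; k <= cb; ++k) { ai.push_back(0); bv.push_back(k); }
    return List::create(_["a"] = wrap(ai), _["b"] = wrap(bv));
}
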