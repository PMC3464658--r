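#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const int NEG = -1000000000;

struct ExtResult { int qlen; int slen; int score; };

// Gapped X-drop extension of q[0..qmax) vs s[0..smax), elements accessed with
// stride so the same routine runs forwards and backwards. Affine gaps: the
// first gap character costs `go`, each further one `ge` (both negative).
// Returns the best-scoring prefix pair and its score (>= 0; empty allowed).
static ExtResult xdrop_extend(const int* q, int qstep, int qmax,
                              const int* s, int sstep, int smax,
                              const std::vector<int>& sm, int alpha,
                              int go, int ge, int xdrop) {
    ExtResult res = {0, 0, 0};
    if (qmax <= 0 || smax <= 0) return res;
    int best = 0, bq = 0, bs = 0;
    std::vector<int> Hp, Fp, Hc, Fc;
    int plo = 0, phi = 0;
    Hp.push_back(0); Fp.push_back(NEG);
    int v = go;
    for (int j = 1; j <= smax && v >= best - xdrop; j++, v += ge) {
        Hp.push_back(v); Fp.push_back(NEG);
        phi = j;
    }
    for (int i = 1; i <= qmax; i++) {
        int qc = q[(i - 1) * qstep];
        Hc.clear(); Fc.clear();
        int lo = -1, hi = -1;
        int E = NEG;
        int jend = phi + 1;
        if (jend > smax) jend = smax;
        for (int j = plo; j <= smax; j++) {
            if (j > jend && E < best - xdrop) break;
            int diag = NEG, up = NEG;
            if (j >= 1 && j - 1 >= plo && j - 1 <= phi && Hp[j - 1 - plo] > NEG) {
                int sc = s[(j - 1) * sstep];
                diag = Hp[j - 1 - plo] + sm[qc * alpha + sc];
            }
            if (j >= plo && j <= phi) {
                int a = (Hp[j - plo] > NEG) ? Hp[j - plo] + go : NEG;
                int b = (Fp[j - plo] > NEG) ? Fp[j - plo] + ge : NEG;
                up = a > b ? a : b;
            }
            int h = diag;
            if (E > h) h = E;
            if (up > h) h = up;
            if (h < best - xdrop) h = NEG;
            if (h > NEG) {
                if (lo < 0) lo = j;
                hi = j;
                if (h > best) { best = h; bq = i; bs = j; }
            }
            if (lo >= 0) {
                Hc.push_back(h);
                Fc.push_back(up >= best - xdrop ? up : NEG);
            }
            // E for cell (i, j+1)
            int e1 = (h > NEG) ? h + go : NEG;
            int e2 = (E > NEG) ? E + ge : NEG;
            E = e1 > e2 ? e1 : e2;
            if (E < best - xdrop) E = NEG;
        }
        if (lo < 0) break;
        // first stored cell corresponds to the first j at which lo was set;
        // that j is lo itself only if nothing was stored before. We started
        // storing at the iteration where lo got set, i.e. at column lo.
        Hc.resize(hi - lo + 1);
        Fc.resize(hi - lo + 1);
        std::swap(Hp, Hc); std::swap(Fp, Fc);
        plo = lo; phi = hi;
    }
    res.qlen = bq; res.slen = bs; res.score = best;
    return res;
}

struct HitBox { int qb, qe, sb, se, score, dmin, dmax; };

static bool in_box(const std::vector<HitBox>& boxes, int i, int j, int k, int tol) {
    int d = j - i;
    for (size_t b = 0; b < boxes.size(); b++) {
        const HitBox& h = boxes[b];
        if (i >= h.qb && i + k <= h.qe && j >= h.sb && j + k <= h.se &&
            d >= h.dmin - tol && d <= h.dmax + tol)
            return true;
    }
    return false;
}

// Seeded gapped X-drop local alignment between integer-coded sequences.
// q_seed_ok / s_seed_ok mark positions usable for exact-match seeding
// (unmasked, code < seed_alpha). In self_mode q and s are the same sequence:
// only seed pairs with j >= i + seed_k are used (upper half-plane) and
// extensions are capped so the two aligned intervals never overlap.
// [[Rcpp::export]]
DataFrame cpp_seed_extend(IntegerVector q, IntegerVector s,
                          LogicalVector q_seed_ok, LogicalVector s_seed_ok,
                          IntegerMatrix score_matrix, int seed_alpha,
                          int gap_open, int gap_extend,
                          int seed_k, int xdrop, int min_score,
                          bool self_mode, int diag_tol, int max_hits) {
    int qlen = q.size(), slen = s.size();
    int alpha = score_matrix.nrow();
    std::vector<int> sm(alpha * alpha);
    for (int a = 0; a < alpha; a++)
        for (int b = 0; b < alpha; b++)
            sm[a * alpha + b] = score_matrix(a, b);
    std::vector<int> qv(q.begin(), q.end()), sv(s.begin(), s.end());

    // index subject k-mers
    std::unordered_map<uint64_t, std::vector<int> > index;
    {
        uint64_t h = 0;
        int run = 0;
        uint64_t top = 1;
        for (int t = 0; t < seed_k - 1; t++) top *= (uint64_t)seed_alpha;
        for (int j = 0; j < slen; j++) {
            int c = sv[j];
            if (c >= 0 && c < seed_alpha && s_seed_ok[j]) {
                h = (run >= seed_k ? h - (uint64_t)sv[j - seed_k] * top : h);
                h = h * (uint64_t)seed_alpha + (uint64_t)c;
                run++;
            } else { run = 0; h = 0; continue; }
            if (run >= seed_k) index[h].push_back(j - seed_k + 1);
        }
    }

    std::vector<HitBox> boxes;
    bool truncated = false;
    uint64_t h = 0; int run = 0;
    uint64_t top = 1;
    for (int t = 0; t < seed_k - 1; t++) top *= (uint64_t)seed_alpha;
    for (int i = 0; i < qlen && !truncated; i++) {
        int c = qv[i];
        if (c >= 0 && c < seed_alpha && q_seed_ok[i]) {
            h = (run >= seed_k ? h - (uint64_t)qv[i - seed_k] * top : h);
            h = h * (uint64_t)seed_alpha + (uint64_t)c;
            run++;
        } else { run = 0; h = 0; continue; }
        if (run < seed_k) continue;
        int qs = i - seed_k + 1; // seed start in q
        std::unordered_map<uint64_t, std::vector<int> >::iterator it = index.find(h);
        if (it == index.end()) continue;
        const std::vector<int>& bucket = it->second;
        size_t b0 = 0;
        if (self_mode) {
            // first j >= qs + seed_k
            b0 = std::lower_bound(bucket.begin(), bucket.end(), qs + seed_k)
                 - bucket.begin();
        }
        for (size_t bi = b0; bi < bucket.size(); bi++) {
            int j = bucket[bi];
            if (in_box(boxes, qs, j, seed_k, diag_tol)) continue;
            // right extension from (qs, j)
            int qmax_r = qlen - qs;
            if (self_mode && qmax_r > j - qs) qmax_r = j - qs; // q end <= j
            int smax_r = slen - j;
            ExtResult r = xdrop_extend(&qv[qs], 1, qmax_r, &sv[j], 1, smax_r,
                                       sm, alpha, gap_open, gap_extend, xdrop);
            // left extension (reversed), s capped so s begin >= q end
            int qmax_l = qs;
            int smax_l = j;
            if (self_mode && smax_l > j - (qs + r.qlen))
                smax_l = j - (qs + r.qlen);
            ExtResult l = {0, 0, 0};
            if (qmax_l > 0 && smax_l > 0)
                l = xdrop_extend(&qv[qs - 1], -1, qmax_l, &sv[j - 1], -1, smax_l,
                                 sm, alpha, gap_open, gap_extend, xdrop);
            int total = l.score + r.score;
            if (total >= min_score && r.qlen + l.qlen > 0) {
                HitBox hb;
                hb.qb = qs - l.qlen; hb.qe = qs + r.qlen;
                hb.sb = j - l.slen;  hb.se = j + r.slen;
                hb.score = total;
                int d1 = hb.sb - hb.qb, d2 = hb.se - hb.qe;
                hb.dmin = d1 < d2 ? d1 : d2;
                hb.dmax = d1 < d2 ? d2 : d1;
                boxes.push_back(hb);
                if ((int)boxes.size() >= max_hits) { truncated = true; break; }
            }
        }
    }

    int n = boxes.size();
    IntegerVector qb(n), qe(n), sb(n), se(n), sc(n);
    for (int x = 0; x < n; x++) {
        qb[x] = boxes[x].qb; qe[x] = boxes[x].qe;
        sb[x] = boxes[x].sb; se[x] = boxes[x].se;
        sc[x] = boxes[x].score;
    }
    DataFrame out = DataFrame::create(_["qs"] = qb, _["qe"] = qe,
                                      _["ss"] = sb, _["se"] = se,
                                      _["score"] = sc);
    out.attr("truncated") = truncated;
    return out;
}

// DUST-style low-complexity scoring. codes: 0..3 = ACGT, 4 = other.
// For every full window of `window` bases the triplet counts c_t give
// score = 10 * sum c_t (c_t - 1) / 2 / (L - 1), L = number of triplet slots;
// windows with score > threshold are masked entirely.
// [[Rcpp::export]]
LogicalVector cpp_dust_mask(IntegerVector codes, int window, int threshold) {
    int n = codes.size();
    LogicalVector mask(n, false);
    if (n < 5) return mask;
    int w = window < n ? window : n;
    int L = w - 2;                 // triplet slots per window
    if (L < 2) return mask;
    std::vector<int> trip(n - 2, -1);
    for (int i = 0; i + 2 < n; i++) {
        int a = codes[i], b = codes[i + 1], c = codes[i + 2];
        if (a < 4 && b < 4 && c < 4) trip[i] = a * 16 + b * 4 + c;
    }
    std::vector<int> cnt(64, 0);
    long cur = 0; // sum c (c-1) / 2
    for (int i = 0; i < L; i++) {
        int t = trip[i];
        if (t >= 0) { cur += cnt[t]; cnt[t]++; }
    }
    for (int w0 = 0; w0 + w <= n; w0++) {
        if (w0 > 0) {
            int tout = trip[w0 - 1];
            if (tout >= 0) { cnt[tout]--; cur -= cnt[tout]; }
            int tin = trip[w0 + w - 3];
            if (tin >= 0) { cur += cnt[tin]; cnt[tin]++; }
        }
        if (10 * cur > (long)threshold * (L - 1)) {
            for (int p = w0; p < w0 + w; p++) mask[p] = true;
        }
    }
    return mask;
}
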