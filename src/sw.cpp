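#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length L costs
// gapOpen + L * gapExtend. Traceback is deterministic: at every cell the
// diagonal move is preferred over a gap in the subject ("up", consuming the
// query) which is preferred over a gap in the query ("left"); the best cell
// is the one with maximal score and, among ties, smallest query index then
// smallest subject index. Characters absent from the alphabet are scored
// like 'X' when present, otherwise as the matrix minimum.

namespace {

struct AlnResult {
    int score;
    int qstart, qend, sstart, send;
    std::vector<int> qpos, spos;
};

inline int char_index(const std::vector<int> &lut, char c) {
    unsigned char u = static_cast<unsigned char>(c);
    return lut[u];
}

AlnResult sw_one(const std::string &a, const std::string &b,
                 const IntegerMatrix &smat, const std::vector<int> &lut,
                 int gapOpen, int gapExtend) {
    const int n = a.size(), m = b.size();
    const int NEG = INT_MIN / 4;
    const int go = gapOpen + gapExtend;  // cost of opening a length-1 gap
    const int ge = gapExtend;

    // full matrices: sequences here are short (peptide windows) or single
    // proteins, so O(nm) ints is fine and makes traceback exact.
    std::vector<int> H((n + 1) * (m + 1), 0);
    std::vector<int> E((n + 1) * (m + 1), NEG);  // gap in query (left)
    std::vector<int> F((n + 1) * (m + 1), NEG);  // gap in subject (up)
    auto at = [m](int i, int j) { return i * (m + 1) + j; };

    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        const int ai = char_index(lut, a[i - 1]);
        for (int j = 1; j <= m; ++j) {
            const int bj_ = char_index(lut, b[j - 1]);
            const int s = smat(ai, bj_);
            int e = std::max(H[at(i, j - 1)] - go, E[at(i, j - 1)] - ge);
            int f = std::max(H[at(i - 1, j)] - go, F[at(i - 1, j)] - ge);
            int d = H[at(i - 1, j - 1)] + s;
            int h = d;
            if (f > h) h = f;
            if (e > h) h = e;
            if (h < 0) h = 0;
            E[at(i, j)] = e;
            F[at(i, j)] = f;
            H[at(i, j)] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }

    AlnResult res;
    res.score = best;
    if (best <= 0) {
        res.qstart = res.qend = res.sstart = res.send = 0;
        return res;
    }

    // traceback from (bi, bj); state 0 = H, 1 = F (up), 2 = E (left)
    std::vector<int> qp, sp;
    int i = bi, j = bj, state = 0;
    while (i > 0 && j > 0) {
        if (state == 0) {
            int h = H[at(i, j)];
            if (h == 0) break;
            int s = smat(char_index(lut, a[i - 1]), char_index(lut, b[j - 1]));
            if (h == H[at(i - 1, j - 1)] + s) {
                qp.push_back(i); sp.push_back(j);
                --i; --j;
            } else if (h == F[at(i, j)]) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {
            // gap in subject, consume query row
            int f = F[at(i, j)];
            if (f == F[at(i - 1, j)] - ge) { --i; }
            else { --i; state = 0; }  // came from H[i-1][j] - go
        } else {
            int e = E[at(i, j)];
            if (e == E[at(i, j - 1)] - ge) { --j; }
            else { --j; state = 0; }
        }
    }
    std::reverse(qp.begin(), qp.end());
    std::reverse(sp.begin(), sp.end());
    res.qpos = qp;
    res.spos = sp;
    res.qstart = qp.front(); res.qend = qp.back();
    res.sstart = sp.front(); res.send = sp.back();
    return res;
}

std::vector<int> make_lut(const CharacterVector &alphabet) {
    std::vector<int> lut(256, -1);
    for (int k = 0; k < alphabet.size(); ++k) {
        std::string s = as<std::string>(alphabet[k]);
        if (s.size() == 1) lut[static_cast<unsigned char>(s[0])] = k;
    }
    int xk = -1;
    for (int k = 0; k < alphabet.size(); ++k)
        if (as<std::string>(alphabet[k]) == "X") xk = k;
    for (int c = 0; c < 256; ++c)
        if (lut[c] < 0) lut[c] = xk;  // unknowns score like X
    return lut;
}

}  // namespace

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b, IntegerMatrix smat,
              CharacterVector alphabet, int gapOpen, int gapExtend) {
    std::vector<int> lut = make_lut(alphabet);
    AlnResult r = sw_one(a, b, smat, lut, gapOpen, gapExtend);
    return List::create(
        _["score"] = r.score,
        _["qstart"] = r.qstart, _["qend"] = r.qend,
        _["sstart"] = r.sstart, _["send"] = r.send,
        _["qpos"] = IntegerVector(r.qpos.begin(), r.qpos.end()),
        _["spos"] = IntegerVector(r.spos.begin(), r.spos.end()));
}

// [[Rcpp::export(name = ".sw_align_batch")]]
List sw_align_batch(std::string query, CharacterVector subjects,
                    IntegerMatrix smat, CharacterVector alphabet,
                    int gapOpen, int gapExtend) {
    std::vector<int> lut = make_lut(alphabet);
    const int ns = subjects.size();
    IntegerVector score(ns), qstart(ns), qend(ns), sstart(ns), send(ns);
    List qpos(ns), spos(ns);
    for (int k = 0; k < ns; ++k) {
        AlnResult r = sw_one(query, as<std::string>(subjects[k]), smat, lut,
                             gapOpen, gapExtend);
        score[k] = r.score;
        qstart[k] = r.qstart; qend[k] = r.qend;
        sstart[k] = r.sstart; send[k] = r.send;
        qpos[k] = IntegerVector(r.qpos.begin(), r.qpos.end());
        spos[k] = IntegerVector(r.spos.begin(), r.spos.end());
    }
    return List::create(
        _["score"] = score,
        _["qstart"] = qstart, _["qend"] = qend,
        _["sstart"] = sstart, _["send"] = send,
        _["qpos"] = qpos, _["spos"] = spos);
}
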