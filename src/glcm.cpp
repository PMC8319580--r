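#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One direction's co-occurrence features inside one window. `pairs` holds the
// symmetric accumulation (both orders of every pixel pair) and must be sorted
// lexicographically so runs of identical (i,j) cells can be counted for
// ENT / ENE / MAX. Levels are 1-based gray levels.
// Feature order (accumulated into feat[0..7]): ENT CON COR MAX MEA HOM STD ENE.
static void dir_features(std::vector<std::pair<int, int> > &pairs, double *feat)
{
    const int n = (int)pairs.size();
    const double N = (double)n;
    double mu = 0.0, con = 0.0, hom = 0.0;
    for (int k = 0; k < n; ++k) {
        const double d = (double)(pairs[k].first - pairs[k].second);
        mu += pairs[k].first;
        con += d * d;
        hom += 1.0 / (1.0 + d * d);
    }
    mu /= N; con /= N; hom /= N;

    double var = 0.0, cov = 0.0;
    for (int k = 0; k < n; ++k) {
        const double da = pairs[k].first - mu, db = pairs[k].second - mu;
        var += da * da;
        cov += da * db;
    }
    var /= N; cov /= N;
    // constant window: perfect self-correlation convention
    const double cor = (var > 1e-12) ? (cov / var) : 1.0;

    std::sort(pairs.begin(), pairs.end());
    double ent = 0.0, ene = 0.0, mx = 0.0;
    int k = 0;
    while (k < n) {
        int j = k;
        while (j < n && pairs[j] == pairs[k]) ++j;
        const double p = (double)(j - k) / N;
        ent -= p * std::log2(p);
        ene += p * p;
        if (p > mx) mx = p;
        k = j;
    }
    feat[0] += ent; feat[1] += con; feat[2] += cor; feat[3] += mx;
    feat[4] += mu;  feat[5] += hom; feat[6] += std::sqrt(var); feat[7] += ene;
}

// Sliding-window GLCM parametric maps. For every window of side `win`
// (odd) whose pixels are all mask-true and inside the image, computes one
// symmetric GLCM per angle at offset `dist` and assigns the per-feature
// average over angles to the window's center pixel.
// Angles use the usual GLCM convention: 0 -> (0,+d), 45 -> (-d,+d),
// 90 -> (-d,0), 135 -> (-d,-d) in (row, col) offsets.
// [[Rcpp::export(name = ".glcm_maps_cpp")]]
List glcm_maps_cpp(IntegerMatrix levels, LogicalMatrix mask,
                   int win, int step, int dist, IntegerVector angles)
{
    const int nr = levels.nrow(), nc = levels.ncol();
    const int half = win / 2;
    const int na = angles.size();

    std::vector<int> dr(na), dc(na);
    for (int a = 0; a < na; ++a) {
        switch (angles[a]) {
        case 0:   dr[a] = 0;     dc[a] = dist;  break;
        case 45:  dr[a] = -dist; dc[a] = dist;  break;
        case 90:  dr[a] = -dist; dc[a] = 0;     break;
        case 135: dr[a] = -dist; dc[a] = -dist; break;
        default: stop("unsupported angle (use 0, 45, 90, 135)");
        }
    }

    List maps(8);
    std::vector<NumericMatrix> M;
    for (int f = 0; f < 8; ++f) {
        NumericMatrix m(nr, nc);
        std::fill(m.begin(), m.end(), NA_REAL);
        M.push_back(m);
        maps[f] = m;
    }
    LogicalMatrix valid(nr, nc);

    std::vector<std::pair<int, int> > pairs;
    pairs.reserve(2 * win * win);
    int n_assigned = 0;

    for (int r0 = half; r0 + half < nr; r0 += step) {
        for (int c0 = half; c0 + half < nc; c0 += step) {
            bool ok = true;
            for (int r = r0 - half; ok && r <= r0 + half; ++r)
                for (int c = c0 - half; c <= c0 + half; ++c)
                    if (!mask(r, c)) { ok = false; break; }
            if (!ok) continue;

            double feat[8] = {0, 0, 0, 0, 0, 0, 0, 0};
            int n_dir = 0;
            for (int a = 0; a < na; ++a) {
                pairs.clear();
                for (int r = r0 - half; r <= r0 + half; ++r) {
                    for (int c = c0 - half; c <= c0 + half; ++c) {
                        const int r2 = r + dr[a], c2 = c + dc[a];
                        if (r2 < r0 - half || r2 > r0 + half ||
                            c2 < c0 - half || c2 > c0 + half) continue;
                        const int v1 = levels(r, c), v2 = levels(r2, c2);
                        pairs.push_back(std::make_pair(v1, v2));
                        pairs.push_back(std::make_pair(v2, v1));
                    }
                }
                if (pairs.empty()) continue;
                dir_features(pairs, feat);
                ++n_dir;
            }
            if (n_dir == 0) continue;
            for (int f = 0; f < 8; ++f) M[f](r0, c0) = feat[f] / n_dir;
            valid(r0, c0) = true;
            ++n_assigned;
        }
    }

    return List::create(_["maps"] = maps, _["validity"] = valid,
                        _["n_valid"] = n_assigned);
}
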