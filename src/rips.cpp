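#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Vietoris-Rips persistent homology of a planar point cloud in dimensions 0
// and 1, with filtration capped at `cap`.
//
// Dimension 0: single-linkage union-find over edges sorted by length; every
// merging edge contributes a (0, length) interval, components alive at the
// cap are reported separately so the caller can apply its infinite-interval
// convention.
//
// Dimension 1: standard boundary-matrix reduction of the triangle boundary
// over GF(2), columns processed in filtration order. The lowest row of each
// nonzero reduced column pairs a loop-creating edge (interval start) with
// the triangle that fills it (interval end). Loop-creating edges never
// paired within the cap are reported as capped intervals.

struct DisjointSet {
    std::vector<int> parent;
    DisjointSet(int n) : parent(n) {
        for (int i = 0; i < n; i++) parent[i] = i;
    }
    int find(int a) {
        while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
        return a;
    }
    bool unite(int a, int b) {
        a = find(a); b = find(b);
        if (a == b) return false;
        parent[b] = a;
        return true;
    }
};

struct Edge { double w; int i, j; };

// [[Rcpp::export(name = ".ripsPairsCpp")]]
List ripsPairsCpp(NumericMatrix pts, double cap, bool do_h1) {
    int n = pts.nrow();
    std::vector<Edge> edges;
    for (int i = 0; i < n; i++) {
        for (int j = i + 1; j < n; j++) {
            double dx = pts(i, 0) - pts(j, 0);
            double dy = pts(i, 1) - pts(j, 1);
            double d = std::sqrt(dx * dx + dy * dy);
            if (d <= cap) edges.push_back({d, i, j});
        }
    }
    std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
        if (a.w != b.w) return a.w < b.w;
        if (a.i != b.i) return a.i < b.i;
        return a.j < b.j;
    });
    int m = (int)edges.size();

    DisjointSet ds(n);
    std::vector<double> h0;
    std::vector<char> positive(m, 0);
    for (int e = 0; e < m; e++) {
        if (ds.unite(edges[e].i, edges[e].j)) h0.push_back(edges[e].w);
        else positive[e] = 1;
    }
    int n_inf0 = n - (int)h0.size();

    NumericMatrix h1fin(0, 2);
    NumericVector h1capped(0);
    if (do_h1 && m > 0) {
        // adjacency (sorted neighbour ids) and edge-id lookup
        std::vector<std::vector<std::pair<int, int>>> adj(n);  // (nbr, edge id)
        for (int e = 0; e < m; e++) {
            adj[edges[e].i].push_back({edges[e].j, e});
            adj[edges[e].j].push_back({edges[e].i, e});
        }
        for (int v = 0; v < n; v++) std::sort(adj[v].begin(), adj[v].end());

        struct Tri { double w; int e1, e2, e3; };  // edge ids, e1<e2<e3
        std::vector<Tri> tris;
        // enumerate triangles i<j<k via sorted adjacency intersection
        std::vector<int> eid(n, -1);
        for (int i = 0; i < n; i++) {
            for (auto& pj : adj[i]) eid[pj.first] = pj.second;
            for (auto& pj : adj[i]) {
                int j = pj.first;
                if (j < i) continue;
                for (auto& pk : adj[j]) {
                    int k = pk.first;
                    if (k <= j) continue;
                    if (eid[k] >= 0) {
                        int a = pj.second, b = pk.second, c = eid[k];
                        int lo = std::min({a, b, c}), hi = std::max({a, b, c});
                        int mid = a + b + c - lo - hi;
                        double w = std::max({edges[a].w, edges[b].w,
                                             edges[c].w});
                        tris.push_back({w, lo, mid, hi});
                    }
                }
            }
            for (auto& pj : adj[i]) eid[pj.first] = -1;
        }
        std::sort(tris.begin(), tris.end(), [](const Tri& a, const Tri& b) {
            if (a.w != b.w) return a.w < b.w;
            if (a.e3 != b.e3) return a.e3 < b.e3;
            if (a.e2 != b.e2) return a.e2 < b.e2;
            return a.e1 < b.e1;
        });

        std::vector<int> pivot(m, -1);            // edge row -> stored column
        std::vector<std::vector<int>> cols;       // stored reduced columns
        std::vector<double> colw;                 // death value per column
        std::vector<int> collow;
        std::vector<std::pair<double, double>> pairs;
        std::vector<int> work, tmp;
        for (auto& tr : tris) {
            work.clear();
            work.push_back(tr.e1); work.push_back(tr.e2); work.push_back(tr.e3);
            int low = work.back();
            while (!work.empty() && pivot[low] != -1) {
                const std::vector<int>& other = cols[pivot[low]];
                tmp.clear();
                std::set_symmetric_difference(work.begin(), work.end(),
                                              other.begin(), other.end(),
                                              std::back_inserter(tmp));
                work.swap(tmp);
                if (work.empty()) break;
                low = work.back();
            }
            if (!work.empty()) {
                pivot[low] = (int)cols.size();
                cols.push_back(work);
                colw.push_back(tr.w);
                collow.push_back(low);
                if (tr.w > edges[low].w)
                    pairs.push_back({edges[low].w, tr.w});
            }
        }
        std::vector<double> capped;
        for (int e = 0; e < m; e++)
            if (positive[e] && pivot[e] == -1) capped.push_back(edges[e].w);

        NumericMatrix hf((int)pairs.size(), 2);
        for (int p = 0; p < (int)pairs.size(); p++) {
            hf(p, 0) = pairs[p].first;
            hf(p, 1) = pairs[p].second;
        }
        h1fin = hf;
        h1capped = wrap(capped);
    }

    return List::create(_["h0_end"] = wrap(h0), _["n_inf0"] = n_inf0,
                        _["h1"] = h1fin, _["h1_capped"] = h1capped);
}
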