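#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-image displacement component on a periodic axis of length L.
static inline double minImage(double d, double L) {
    return d - L * std::round(d / L);
}

// dU/dr for the Morse potential U(r) = -J [exp(-r/lA) - ratio * exp(-r/lR)].
static inline double morseDUdr(double r, double J, double lA, double lR,
                               double ratio) {
    return J * (std::exp(-r / lA) / lA - ratio * std::exp(-r / lR) / lR);
}

struct CellGrid {
    int nb;
    double L, hw, width;
    std::vector<int> head, nxt;
    CellGrid(double hw_, double rmax, int ncap) : hw(hw_) {
        L = 2.0 * hw_;
        nb = std::max(1, (int)std::floor(L / rmax));
        width = L / nb;
        head.assign(nb * nb, -1);
        nxt.assign(ncap, -1);
    }
    inline int binOf(double x, double y) const {
        int bx = (int)std::floor((x + hw) / width);
        int by = (int)std::floor((y + hw) / width);
        if (bx < 0) bx = 0; if (bx >= nb) bx = nb - 1;
        if (by < 0) by = 0; if (by >= nb) by = nb - 1;
        return by * nb + bx;
    }
    void build(const std::vector<double>& x, const std::vector<double>& y,
               int n) {
        std::fill(head.begin(), head.end(), -1);
        if ((int)nxt.size() < n) nxt.resize(n, -1);
        for (int i = 0; i < n; i++) {
            int b = binOf(x[i], y[i]);
            nxt[i] = head[b];
            head[b] = i;
        }
    }
};

// Count neighbours of cell i within rmax (periodic), excluding itself.
static int countNeighbors(const CellGrid& g, const std::vector<double>& x,
                          const std::vector<double>& y, int i, double rmax) {
    int cnt = 0;
    double r2 = rmax * rmax;
    int bx = (int)std::floor((x[i] + g.hw) / g.width);
    int by = (int)std::floor((y[i] + g.hw) / g.width);
    for (int dy = -1; dy <= 1; dy++) {
        for (int dx = -1; dx <= 1; dx++) {
            int cx = ((bx + dx) % g.nb + g.nb) % g.nb;
            int cy = ((by + dy) % g.nb + g.nb) % g.nb;
            for (int j = g.head[cy * g.nb + cx]; j != -1; j = g.nxt[j]) {
                if (j == i) continue;
                double ddx = minImage(x[j] - x[i], g.L);
                double ddy = minImage(y[j] - y[i], g.L);
                if (ddx * ddx + ddy * ddy <= r2) cnt++;
            }
        }
    }
    return cnt;
}

// Overdamped self-propelled particle dynamics with Morse adhesion, periodic
// boundaries, periodic repolarization and (optionally) contact-inhibited
// division. All randomness comes from R's RNG so runs are seed-reproducible.
// [[Rcpp::export(name = ".runSimCpp")]]
List runSimCpp(NumericMatrix pos0, IntegerVector types0, NumericMatrix pol0,
               NumericVector clocks0, IntegerVector offsets0, NumericMatrix J,
               double hw, double dt, double eta, double pmag,
               int repol_period, double rmax, double lA, double lR,
               double ratio, double nsteps, double step0, bool prolif,
               double cycle_steps, int max_neighbors, double daughter_offset,
               double snapshot_every) {
    int n = pos0.nrow();
    std::vector<double> x(n), y(n), px(n), py(n), clk(n);
    std::vector<int> type(n), off(n);
    for (int i = 0; i < n; i++) {
        x[i] = pos0(i, 0); y[i] = pos0(i, 1);
        px[i] = pol0(i, 0); py[i] = pol0(i, 1);
        clk[i] = clocks0[i]; type[i] = types0[i]; off[i] = offsets0[i];
    }
    double L = 2.0 * hw, r2max = rmax * rmax;
    // Verlet neighbour list with a displacement-tracked skin: the list
    // holds all pairs within rmax + skin and is rebuilt only once the
    // accumulated maximum per-step displacement could have let a new pair
    // enter the interaction radius, so the trajectory is identical to a
    // per-step neighbour search.
    const double skin = 0.4;
    const double rlist = rmax + skin, r2list = rlist * rlist;
    CellGrid grid(hw, rlist, n + 64);
    std::vector<int> nbrOff, nbrLst;
    std::vector<double> fx, fy;
    std::vector<int> ncnt;
    bool rebuild = true;
    double accum = 0.0;
    List snaps;
    double two_pi = 2.0 * M_PI;

    for (double t = 0; t < nsteps; t += 1.0) {
        long long s = (long long)(step0 + t);  // absolute step index
        // repolarization (before displacement), ascending cell order
        for (int i = 0; i < n; i++) {
            if ((s + off[i]) % (long long)repol_period == 0) {
                double th = two_pi * unif_rand();
                px[i] = pmag * std::cos(th);
                py[i] = pmag * std::sin(th);
            }
        }
        if (rebuild) {
            nbrOff.assign(n + 1, 0);
            nbrLst.clear();
            if (grid.nb < 3) {
                // box too small for distinct 3x3 bin neighbourhoods
                for (int i = 0; i < n; i++) {
                    nbrOff[i] = (int)nbrLst.size();
                    for (int j = i + 1; j < n; j++) {
                        double ddx = minImage(x[j] - x[i], L);
                        double ddy = minImage(y[j] - y[i], L);
                        if (ddx * ddx + ddy * ddy <= r2list)
                            nbrLst.push_back(j);
                    }
                }
            } else {
                grid.build(x, y, n);
                for (int i = 0; i < n; i++) {
                    nbrOff[i] = (int)nbrLst.size();
                    int bx = (int)std::floor((x[i] + hw) / grid.width);
                    int by = (int)std::floor((y[i] + hw) / grid.width);
                    for (int dy = -1; dy <= 1; dy++) {
                        for (int dx = -1; dx <= 1; dx++) {
                            int cx = ((bx + dx) % grid.nb + grid.nb) %
                                grid.nb;
                            int cy = ((by + dy) % grid.nb + grid.nb) %
                                grid.nb;
                            for (int j = grid.head[cy * grid.nb + cx];
                                 j != -1; j = grid.nxt[j]) {
                                if (j <= i) continue;
                                double ddx = minImage(x[j] - x[i], L);
                                double ddy = minImage(y[j] - y[i], L);
                                if (ddx * ddx + ddy * ddy <= r2list)
                                    nbrLst.push_back(j);
                            }
                        }
                    }
                    std::sort(nbrLst.begin() + nbrOff[i], nbrLst.end());
                }
            }
            nbrOff[n] = (int)nbrLst.size();
            rebuild = false;
            accum = 0.0;
        }
        fx.assign(n, 0.0); fy.assign(n, 0.0);
        ncnt.assign(n, 0);
        // each unordered pair visited once (j > i); forces antisymmetric
        for (int i = 0; i < n; i++) {
            for (int idx = nbrOff[i]; idx < nbrOff[i + 1]; idx++) {
                int j = nbrLst[idx];
                double ddx = minImage(x[j] - x[i], L);
                double ddy = minImage(y[j] - y[i], L);
                double r2 = ddx * ddx + ddy * ddy;
                if (r2 > r2max) continue;
                ncnt[i]++; ncnt[j]++;
                if (r2 == 0.0) continue;
                double r = std::sqrt(r2);
                double f = morseDUdr(r, J(type[i], type[j]), lA, lR,
                                     ratio) / r;
                fx[i] += f * ddx;
                fy[i] += f * ddy;
                fx[j] -= f * ddx;
                fy[j] -= f * ddy;
            }
        }
        double c = dt / eta;
        double maxd2 = 0.0;
        for (int i = 0; i < n; i++) {
            double ux = c * (px[i] + fx[i]);
            double uy = c * (py[i] + fy[i]);
            double d2 = ux * ux + uy * uy;
            if (d2 > maxd2) maxd2 = d2;
            x[i] += ux;
            y[i] += uy;
            // wrap into [-hw, hw)
            x[i] -= L * std::floor((x[i] + hw) / L);
            y[i] -= L * std::floor((y[i] + hw) / L);
        }
        accum += std::sqrt(maxd2);
        if (2.0 * accum >= skin) rebuild = true;
        if (prolif) {
            bool any = false;
            for (int i = 0; i < n; i++) {
                clk[i] += 1.0;
                if (clk[i] >= cycle_steps) any = true;
            }
            if (any) {
                // neighbour counts from the force pass (pre-displacement
                // positions of this step; displacements are ~1e-4 per step)
                int n0 = n;
                for (int i = 0; i < n0; i++) {
                    if (clk[i] < cycle_steps) continue;
                    if (ncnt[i] > max_neighbors)
                        continue;
                    double th = two_pi * unif_rand();
                    double nx = x[i] + daughter_offset * std::cos(th);
                    double ny = y[i] + daughter_offset * std::sin(th);
                    nx -= L * std::floor((nx + hw) / L);
                    ny -= L * std::floor((ny + hw) / L);
                    x.push_back(nx); y.push_back(ny);
                    px.push_back(-px[i]); py.push_back(-py[i]);
                    type.push_back(type[i]); off.push_back(off[i]);
                    clk.push_back(0.0);
                    clk[i] = 0.0;
                    n++;
                }
                if (n > n0) rebuild = true;  // list must include daughters
            }
        }
        if (snapshot_every > 0 &&
            ((long long)(t + 1.0)) % (long long)snapshot_every == 0) {
            NumericMatrix sp(n, 2);
            IntegerVector st(n);
            for (int i = 0; i < n; i++) {
                sp(i, 0) = x[i]; sp(i, 1) = y[i]; st[i] = type[i];
            }
            snaps.push_back(List::create(_["step"] = s + 1.0,
                                         _["positions"] = sp,
                                         _["types"] = st));
        }
    }

    NumericMatrix pos(n, 2), pol(n, 2);
    NumericVector clko(n);
    IntegerVector typeo(n), offo(n);
    for (int i = 0; i < n; i++) {
        pos(i, 0) = x[i]; pos(i, 1) = y[i];
        pol(i, 0) = px[i]; pol(i, 1) = py[i];
        clko[i] = clk[i]; typeo[i] = type[i]; offo[i] = off[i];
    }
    return List::create(_["positions"] = pos, _["polarizations"] = pol,
                        _["types"] = typeo, _["clocks"] = clko,
                        _["offsets"] = offo, _["step_index"] = step0 + nsteps,
                        _["snapshots"] = snaps);
}

// Neighbour counts (cells within rmax, periodic) for a static configuration.
// [[Rcpp::export(name = ".neighborCountsCpp")]]
IntegerVector neighborCountsCpp(NumericMatrix pos, double hw, double rmax) {
    int n = pos.nrow();
    std::vector<double> x(n), y(n);
    for (int i = 0; i < n; i++) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
    CellGrid grid(hw, rmax, n);
    grid.build(x, y, n);
    IntegerVector out(n);
    for (int i = 0; i < n; i++)
        out[i] = countNeighbors(grid, x, y, i, rmax);
    return out;
}
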