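#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Neighbor offsets in fixed tie-break order N, NE, E, SE, S, SW, W, NW
// (grid-native coordinates, y axis pointing up). The von Neumann
// neighborhood takes every second entry: N, E, S, W.
static const int NB_DX[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int NB_DY[8] = {1, 1, 0, -1, -1, -1, 0, 1};
static const int VN_IDX[4] = {0, 2, 4, 6};

// Incremental cost change of moving node i to (nx, ny): only the n-1
// terms involving i change, so the delta is O(n) instead of O(n^2).
static long long delta_move(const IntegerMatrix &coords, const IntegerMatrix &W,
                            int i, int nx, int ny) {
    const int n = coords.nrow();
    const int xi = coords(i, 0), yi = coords(i, 1);
    long long d = 0;
    for (int k = 0; k < n; ++k) {
        if (k == i) continue;
        const int w = W(i, k);
        if (w == 0) continue;
        const int xk = coords(k, 0), yk = coords(k, 1);
        const int dold = std::abs(xi - xk) + std::abs(yi - yk);
        const int dnew = std::abs(nx - xk) + std::abs(ny - yk);
        d += (long long)w * (dnew - dold);
    }
    return d;
}

static std::vector<int> build_occ(const IntegerMatrix &coords, int width, int height) {
    std::vector<int> occ((size_t)width * height, -1);
    for (int i = 0; i < coords.nrow(); ++i) {
        occ[(size_t)coords(i, 1) * width + coords(i, 0)] = i;
    }
    return occ;
}

// Total layout cost: sum over unordered pairs of w_ij times the
// Manhattan distance between the occupied cells. Accumulated in 64-bit
// integers; coordinates and weights are integral so the result is exact.
// [[Rcpp::export]]
double cpp_cost(IntegerMatrix coords, IntegerMatrix W) {
    const int n = coords.nrow();
    long long total = 0;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            const int d = std::abs(coords(i, 0) - coords(j, 0)) +
                          std::abs(coords(i, 1) - coords(j, 1));
            total += (long long)W(i, j) * d;
        }
    }
    return (double)total;
}

// [[Rcpp::export]]
double cpp_delta_cost(IntegerMatrix coords, IntegerMatrix W, int i, int nx, int ny) {
    return (double)delta_move(coords, W, i, nx, ny);
}

// Neighborhood test: sweep nodes in index order, moving each to the best
// strictly-improving vacant neighbor cell (ties broken by the fixed
// N..NW order); repeat full sweeps until none moves. The result is a
// single-move local minimum of the cost.
// [[Rcpp::export]]
List cpp_neighborhood_test(IntegerMatrix coords_in, IntegerMatrix W,
                           int width, int height, bool moore) {
    IntegerMatrix coords = clone(coords_in);
    const int n = coords.nrow();
    std::vector<int> occ = build_occ(coords, width, height);
    const int nnb = moore ? 8 : 4;
    long long evals = 0;
    int sweeps = 0;
    bool moved = true;
    while (moved) {
        moved = false;
        ++sweeps;
        for (int i = 0; i < n; ++i) {
            const int x = coords(i, 0), y = coords(i, 1);
            long long best = 0;
            int bx = -1, by = -1;
            for (int t = 0; t < nnb; ++t) {
                const int k = moore ? t : VN_IDX[t];
                const int nx = x + NB_DX[k], ny = y + NB_DY[k];
                if (nx < 0 || nx >= width || ny < 0 || ny >= height) continue;
                if (occ[(size_t)ny * width + nx] >= 0) continue;
                const long long d = delta_move(coords, W, i, nx, ny);
                ++evals;
                if (d < best) { best = d; bx = nx; by = ny; }
            }
            if (best < 0) {
                occ[(size_t)y * width + x] = -1;
                occ[(size_t)by * width + bx] = i;
                coords(i, 0) = bx;
                coords(i, 1) = by;
                moved = true;
            }
        }
        if (sweeps % 16 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["coords"] = coords,
                        _["evaluations"] = (double)evals,
                        _["sweeps"] = sweeps);
}

// Perturbation: visit nodes in index order; with probability p move the
// node to a uniformly chosen vacant neighbor cell (vacancy evaluated at
// move time, so earlier moves in the same pass free and block cells).
// Nodes with no vacant neighbor stay put. Uses R's RNG stream.
// [[Rcpp::export]]
IntegerMatrix cpp_perturb(IntegerMatrix coords_in, int width, int height,
                          double p, bool moore) {
    IntegerMatrix coords = clone(coords_in);
    const int n = coords.nrow();
    std::vector<int> occ = build_occ(coords, width, height);
    const int nnb = moore ? 8 : 4;
    int cx[8], cy[8];
    for (int i = 0; i < n; ++i) {
        if (unif_rand() >= p) continue;
        const int x = coords(i, 0), y = coords(i, 1);
        int m = 0;
        for (int t = 0; t < nnb; ++t) {
            const int k = moore ? t : VN_IDX[t];
            const int nx = x + NB_DX[k], ny = y + NB_DY[k];
            if (nx < 0 || nx >= width || ny < 0 || ny >= height) continue;
            if (occ[(size_t)ny * width + nx] >= 0) continue;
            cx[m] = nx;
            cy[m] = ny;
            ++m;
        }
        if (m == 0) continue;
        int pick = (int)std::floor(unif_rand() * m);
        if (pick >= m) pick = m - 1;
        occ[(size_t)y * width + x] = -1;
        occ[(size_t)cy[pick] * width + cx[pick]] = i;
        coords(i, 0) = cx[pick];
        coords(i, 1) = cy[pick];
    }
    return coords;
}

// Main loop: locally optimize the initial layout, then niter times
// perturb + re-optimize and accept the candidate only on a strict cost
// improvement. Returns the final layout, the accepted-cost trace
// (initial value plus one entry per iteration) and the total number of
// delta-cost evaluations performed.
// [[Rcpp::export]]
List cpp_optimize(IntegerMatrix coords_in, IntegerMatrix W, int width, int height,
                  double p, int niter, bool moore) {
    List nt = cpp_neighborhood_test(coords_in, W, width, height, moore);
    IntegerMatrix coords = nt["coords"];
    double evals = as<double>(nt["evaluations"]);
    long long cur = (long long)cpp_cost(coords, W);
    NumericVector trace(niter + 1);
    trace[0] = (double)cur;
    for (int it = 1; it <= niter; ++it) {
        IntegerMatrix cand = cpp_perturb(coords, width, height, p, moore);
        List nt2 = cpp_neighborhood_test(cand, W, width, height, moore);
        IntegerMatrix cand_opt = nt2["coords"];
        evals += as<double>(nt2["evaluations"]);
        const long long cc = (long long)cpp_cost(cand_opt, W);
        if (cc < cur) {
            coords = cand_opt;
            cur = cc;
        }
        trace[it] = (double)cur;
        if (it % 8 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["coords"] = coords,
                        _["cost"] = (double)cur,
                        _["trace"] = trace,
                        _["evaluations"] = evals);
}
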