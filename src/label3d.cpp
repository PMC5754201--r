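#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// 26-connected component labelling of a 3D logical mask stored in R array
// order with dims (nz, ny, nx): linear index = z + nz*(y + ny*x), 0-based.
// Returns an integer vector of the same length with labels 1..k (0 =
// background), numbered in order of first occurrence.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim) {
    if (dim.size() != 3) stop("dim must have length 3");
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (mask.size() != n) stop("mask length does not match dim");

    std::vector<int> parent(n);
    for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

    // Backward half of the 26-neighbourhood: offsets lexicographically
    // smaller than (0,0,0) in (dx, dy, dz) scan order.
    for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) {
            for (int z = 0; z < nz; ++z) {
                R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
                if (!mask[i]) continue;
                for (int dx = -1; dx <= 0; ++dx) {
                    int xx = x + dx;
                    if (xx < 0) continue;
                    for (int dy = -1; dy <= 1; ++dy) {
                        if (dx == 0 && dy > 0) break;
                        int yy = y + dy;
                        if (yy < 0 || yy >= ny) continue;
                        for (int dz = -1; dz <= 1; ++dz) {
                            if (dx == 0 && dy == 0 && dz >= 0) break;
                            int zz = z + dz;
                            if (zz < 0 || zz >= nz) continue;
                            R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
                            if (mask[j]) uf_union(parent, (int)i, (int)j);
                        }
                    }
                }
            }
        }
    }

    IntegerVector out(n, 0);
    std::vector<int> relabel(n, 0);
    int next = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i]) continue;
        int r = uf_find(parent, (int)i);
        if (relabel[r] == 0) relabel[r] = ++next;
        out[i] = relabel[r];
    }
    return out;
}
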