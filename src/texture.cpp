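#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 13 unique direction vectors: one representative per opposite pair of the
// 26-neighbourhood. Texture matrices built over them (plus mirrors where
// symmetry is required) aggregate all 26 angles.
static const int DIR13[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + ny * z);
}

// img: 0 outside the region, 1..ng inside (discretised gray levels)
// Returns the symmetric gray-level co-occurrence matrix summed over the 26
// angles (each ordered voxel pair counted once per direction and mirrored).
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector img, IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int ng = 0;
    for (int i = 0; i < img.size(); ++i) if (img[i] > ng) ng = img[i];
    if (ng < 1) ng = 1;
    NumericMatrix P(ng, ng);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int g1 = img[idx3(x, y, z, nx, ny)];
                if (g1 <= 0) continue;
                for (int d = 0; d < 13; ++d) {
                    int xx = x + DIR13[d][0], yy = y + DIR13[d][1], zz = z + DIR13[d][2];
                    if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
                    int g2 = img[idx3(xx, yy, zz, nx, ny)];
                    if (g2 <= 0) continue;
                    P(g1 - 1, g2 - 1) += 1.0;
                    P(g2 - 1, g1 - 1) += 1.0;
                }
            }
    return P;
}

// Gray-level run-length matrix summed over the 13 unique directions.
// Runs are maximal sequences of equal gray level along a direction; voxels
// outside the region terminate runs.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector img, IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int n = nx * ny * nz;
    int ng = 0;
    for (int i = 0; i < n; ++i) if (img[i] > ng) ng = img[i];
    if (ng < 1) ng = 1;
    int maxrun = std::max(std::max(nx, ny), nz);
    NumericMatrix R(ng, maxrun);
    for (int d = 0; d < 13; ++d) {
        int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    // line start: predecessor along -d is outside the grid
                    int px = x - dx, py = y - dy, pz = z - dz;
                    if (px >= 0 && py >= 0 && pz >= 0 && px < nx && py < ny && pz < nz)
                        continue;
                    int cx = x, cy = y, cz = z;
                    int cur = 0, len = 0;
                    while (cx >= 0 && cy >= 0 && cz >= 0 && cx < nx && cy < ny && cz < nz) {
                        int g = img[idx3(cx, cy, cz, nx, ny)];
                        if (g == cur && g > 0) {
                            ++len;
                        } else {
                            if (cur > 0 && len > 0) R(cur - 1, len - 1) += 1.0;
                            cur = g;
                            len = (g > 0) ? 1 : 0;
                        }
                        cx += dx; cy += dy; cz += dz;
                    }
                    if (cur > 0 && len > 0) R(cur - 1, len - 1) += 1.0;
                }
    }
    return R;
}

// Gray-level size-zone matrix: zones are 26-connected components of equal
// gray level; entry (g, s) counts zones of level g and size s.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector img, IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int n = nx * ny * nz;
    int ng = 0, nin = 0;
    for (int i = 0; i < n; ++i) {
        if (img[i] > ng) ng = img[i];
        if (img[i] > 0) ++nin;
    }
    if (ng < 1) ng = 1;
    if (nin < 1) nin = 1;
    std::vector<char> seen(n, 0);
    std::vector<std::pair<int, int> > zones; // (gray, size)
    std::vector<int> stack;
    int maxsize = 1;
    for (int start = 0; start < n; ++start) {
        if (seen[start] || img[start] <= 0) continue;
        int g = img[start];
        int size = 0;
        stack.clear();
        stack.push_back(start);
        seen[start] = 1;
        while (!stack.empty()) {
            int cur = stack.back();
            stack.pop_back();
            ++size;
            int cz = cur / (nx * ny);
            int rem = cur - cz * nx * ny;
            int cy = rem / nx;
            int cx = rem - cy * nx;
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (!dx && !dy && !dz) continue;
                        int xx = cx + dx, yy = cy + dy, zz = cz + dz;
                        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
                        int j = idx3(xx, yy, zz, nx, ny);
                        if (!seen[j] && img[j] == g) {
                            seen[j] = 1;
                            stack.push_back(j);
                        }
                    }
        }
        zones.push_back(std::make_pair(g, size));
        if (size > maxsize) maxsize = size;
    }
    NumericMatrix S(ng, maxsize);
    for (size_t i = 0; i < zones.size(); ++i)
        S(zones[i].first - 1, zones[i].second - 1) += 1.0;
    return S;
}

// Gray-level dependence matrix: dependence of a voxel = number of 26
// neighbours inside the region whose |gray difference| <= alpha.
// Columns index dependence 0..26 (so ncol = 27).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector img, IntegerVector dims, int alpha) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int ng = 0;
    for (int i = 0; i < img.size(); ++i) if (img[i] > ng) ng = img[i];
    if (ng < 1) ng = 1;
    NumericMatrix D(ng, 27);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int g = img[idx3(x, y, z, nx, ny)];
                if (g <= 0) continue;
                int dep = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int xx = x + dx, yy = y + dy, zz = z + dz;
                            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
                            int gn = img[idx3(xx, yy, zz, nx, ny)];
                            if (gn > 0 && std::abs(gn - g) <= alpha) ++dep;
                        }
                D(g - 1, dep) += 1.0;
            }
    return D;
}

// Neighbouring gray-tone difference matrix pieces: for each level g,
// column 1 = voxel count n_g, column 2 = s_g = sum |g - mean(neighbours)|
// over voxels of level g that have at least one in-region neighbour.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector img, IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int ng = 0;
    for (int i = 0; i < img.size(); ++i) if (img[i] > ng) ng = img[i];
    if (ng < 1) ng = 1;
    NumericMatrix M(ng, 2);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int g = img[idx3(x, y, z, nx, ny)];
                if (g <= 0) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int xx = x + dx, yy = y + dy, zz = z + dz;
                            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
                            int gn = img[idx3(xx, yy, zz, nx, ny)];
                            if (gn > 0) { sum += gn; ++cnt; }
                        }
                if (cnt > 0) {
                    M(g - 1, 0) += 1.0;
                    M(g - 1, 1) += std::fabs((double)g - sum / cnt);
                }
            }
    return M;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void edt1d(std::vector<double> &f, std::vector<double> &d, int n, double w2) {
    std::vector<int> v(n);
    std::vector<double> zbound(n + 1);
    int k = 0;
    v[0] = 0;
    zbound[0] = -std::numeric_limits<double>::infinity();
    zbound[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            int p = v[k];
            s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
            if (s <= zbound[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        zbound[k] = s;
        zbound[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (zbound[k + 1] < q) ++k;
        int p = v[k];
        d[q] = w2 * (q - p) * (q - p) + f[p];
    }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel of `mask`, honouring anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    int n = nx * ny * nz;
    // large finite sentinel: infinity breaks the parabola intersection
    // arithmetic (inf - inf) in edt1d
    const double BIG = 1e20;
    NumericVector D(n);
    for (int i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : BIG;
    std::vector<double> f(std::max(std::max(nx, ny), nz)), d(std::max(std::max(nx, ny), nz));
    // x pass
    double w2 = spacing[0] * spacing[0];
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x) f[x] = D[idx3(x, y, z, nx, ny)];
            edt1d(f, d, nx, w2);
            for (int x = 0; x < nx; ++x) D[idx3(x, y, z, nx, ny)] = d[x];
        }
    // y pass
    w2 = spacing[1] * spacing[1];
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            for (int y = 0; y < ny; ++y) f[y] = D[idx3(x, y, z, nx, ny)];
            edt1d(f, d, ny, w2);
            for (int y = 0; y < ny; ++y) D[idx3(x, y, z, nx, ny)] = d[y];
        }
    // z pass
    w2 = spacing[2] * spacing[2];
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            for (int z = 0; z < nz; ++z) f[z] = D[idx3(x, y, z, nx, ny)];
            edt1d(f, d, nz, w2);
            for (int z = 0; z < nz; ++z) D[idx3(x, y, z, nx, ny)] = d[z];
        }
    return D;
}

// Maximum pairwise Euclidean distance between rows of a point matrix (mm).
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
    int n = pts.nrow(), m = pts.ncol();
    double best = 0.0;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            double s = 0.0;
            for (int k = 0; k < m; ++k) {
                double dd = pts(i, k) - pts(j, k);
                s += dd * dd;
            }
            if (s > best) best = s;
        }
    return std::sqrt(best);
}
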