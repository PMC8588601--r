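// Hot-path pixel kernels for the synthetic-recording pipeline:
// frame rendering with per-pixel Gaussian noise, and per-label
// feature/crop extraction from a connected-component labelling.
#include <Rcpp.h>
using namespace Rcpp;

// Fast deterministic Gaussian pixel noise: xorshift128+ uniforms fed
// through the Marsaglia polar transform. The two 64-bit state words
// are seeded from R's RNG, so set.seed() still governs every frame.
struct GaussStream {
    uint64_t s0, s1;
    double spare;
    bool hasSpare;
    GaussStream(uint64_t a, uint64_t b)
        : s0(a ? a : 0x9E3779B97F4A7C15ULL),
          s1(b ? b : 0xBF58476D1CE4E5B9ULL),
          spare(0), hasSpare(false) {}
    inline double unif() {
        uint64_t x = s0, y = s1;
        s0 = y;
        x ^= x << 23;
        s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
        return ((s1 + y) >> 11) * (1.0 / 9007199254740992.0);
    }
    inline double norm() {
        if (hasSpare) { hasSpare = false; return spare; }
        double u, v, s;
        do {
            u = 2.0 * unif() - 1.0;
            v = 2.0 * unif() - 1.0;
            s = u * u + v * v;
        } while (s >= 1.0 || s == 0.0);
        double f = std::sqrt(-2.0 * std::log(s) / s);
        spare = v * f;
        hasSpare = true;
        return u * f;
    }
};

// Render one frame: background bg everywhere, foreground fg at the
// supplied (1-based) pixel coordinates, optional N(0, noiseSd) pixel
// noise, clipped to [0, 1].
// [[Rcpp::export(name = ".renderFrameCpp")]]
NumericMatrix renderFrameCpp(int h, int w, double bg, double fg,
        double noiseSd, IntegerVector px, IntegerVector py) {
    NumericMatrix img(h, w);
    double *p = img.begin();
    R_xlen_t n = (R_xlen_t)h * w;
    RNGScope scope;
    if (noiseSd > 0) {
        GaussStream g(
            (uint64_t)(unif_rand() * 9007199254740992.0),
            (uint64_t)(unif_rand() * 9007199254740992.0));
        for (R_xlen_t i = 0; i < n; i++)
            p[i] = bg + g.norm() * noiseSd;
        for (R_xlen_t k = 0; k < px.size(); k++) {
            int x = px[k] - 1, y = py[k] - 1;
            if (x >= 0 && x < w && y >= 0 && y < h)
                p[(R_xlen_t)x * h + y] = fg + g.norm() * noiseSd;
        }
        for (R_xlen_t i = 0; i < n; i++) {
            if (p[i] < 0) p[i] = 0;
            else if (p[i] > 1) p[i] = 1;
        }
    } else {
        std::fill(p, p + n, bg);
        for (R_xlen_t k = 0; k < px.size(); k++) {
            int x = px[k] - 1, y = py[k] - 1;
            if (x >= 0 && x < w && y >= 0 && y < h)
                p[(R_xlen_t)x * h + y] = fg;
        }
    }
    return img;
}

// Per-label area, centroid sums and bounding box from a label matrix
// (labels 1..nObj, 0 = background). Coordinates are 0-based,
// x = column, y = row.
// [[Rcpp::export(name = ".labelFeaturesCpp")]]
List labelFeaturesCpp(NumericMatrix lab, int nObj) {
    int h = lab.nrow(), w = lab.ncol();
    IntegerVector area(nObj);
    NumericVector sumx(nObj), sumy(nObj);
    IntegerVector rmin(nObj, h), rmax(nObj, -1), cmin(nObj, w),
        cmax(nObj, -1);
    const double *p = lab.begin();
    for (int c = 0; c < w; c++) {
        for (int r = 0; r < h; r++) {
            int v = (int)p[(R_xlen_t)c * h + r];
            if (v > 0) {
                int i = v - 1;
                area[i]++;
                sumx[i] += c;
                sumy[i] += r;
                if (r < rmin[i]) rmin[i] = r;
                if (r > rmax[i]) rmax[i] = r;
                if (c < cmin[i]) cmin[i] = c;
                if (c > cmax[i]) cmax[i] = c;
            }
        }
    }
    return List::create(_["area"] = area, _["sumx"] = sumx,
        _["sumy"] = sumy, _["rmin"] = rmin, _["rmax"] = rmax,
        _["cmin"] = cmin, _["cmax"] = cmax);
}

// Binary crops of the selected labels (1-based label ids), using the
// precomputed bounding boxes.
// [[Rcpp::export(name = ".labelCropsCpp")]]
List labelCropsCpp(NumericMatrix lab, IntegerVector keep,
        IntegerVector rmin, IntegerVector rmax, IntegerVector cmin,
        IntegerVector cmax) {
    int h = lab.nrow();
    List out(keep.size());
    const double *p = lab.begin();
    for (int k = 0; k < keep.size(); k++) {
        int id = keep[k], i = id - 1;
        int nr = rmax[i] - rmin[i] + 1, nc = cmax[i] - cmin[i] + 1;
        IntegerMatrix crop(nr, nc);
        for (int c = 0; c < nc; c++)
            for (int r = 0; r < nr; r++)
                if ((int)p[(R_xlen_t)(c + cmin[i]) * h + r + rmin[i]]
                        == id)
                    crop[(R_xlen_t)c * nr + r] = 1;
        out[k] = crop;
    }
    return out;
}

// Per-object 2x2 configuration-count Crofton perimeter and Euler
// number, computed directly from the label matrix over each object's
// (1-padded) bounding box. Pixels of other labels count as background.
// euler (8-connected foreground) = (n1corner - n3corner - 2*ndiag)/4;
// objects with holes (euler < 1) need outer-contour handling upstream.
// [[Rcpp::export(name = ".croftonLabelCpp")]]
List croftonLabelCpp(NumericMatrix lab, IntegerVector keep,
        IntegerVector rmin, IntegerVector rmax, IntegerVector cmin,
        IntegerVector cmax, NumericVector coefs) {
    int h = lab.nrow();
    const double *p = lab.begin();
    NumericVector perim(keep.size());
    IntegerVector euler4(keep.size());
    std::vector<unsigned char> buf;
    for (int k = 0; k < keep.size(); k++) {
        int id = keep[k], i = id - 1;
        int nr = rmax[i] - rmin[i] + 3;  // 1-pixel zero pad each side
        int nc = cmax[i] - cmin[i] + 3;
        buf.assign((size_t)nr * nc, 0);
        for (int c = cmin[i]; c <= cmax[i]; c++) {
            const double *col = p + (R_xlen_t)c * h;
            unsigned char *b =
                &buf[(size_t)(c - cmin[i] + 1) * nr + 1];
            for (int r = rmin[i]; r <= rmax[i]; r++)
                b[r - rmin[i]] = (int)col[r] == id;
        }
        double per = 0.0;
        int n1 = 0, n3 = 0, nd = 0;
        for (int c = 0; c < nc - 1; c++) {
            const unsigned char *b0 = &buf[(size_t)c * nr];
            const unsigned char *b1 = &buf[(size_t)(c + 1) * nr];
            for (int r = 0; r < nr - 1; r++) {
                int tl = b0[r], bl = b0[r + 1];
                int tr = b1[r], br = b1[r + 1];
                int s = tl + tr + bl + br;
                if (!s) continue;
                per += coefs[tl + 2 * tr + 4 * bl + 8 * br];
                if (s == 1) n1++;
                else if (s == 3) n3++;
                else if (s == 2 && ((tl && br) || (tr && bl))) nd++;
            }
        }
        perim[k] = per;
        euler4[k] = n1 - n3 - 2 * nd;  // 4 * Euler (8-connected fg)
    }
    return List::create(_["perimeter"] = perim,
        _["euler4"] = euler4);
}

// 256-bin histogram of [0, 1] intensities (values outside are ignored).
// [[Rcpp::export(name = ".hist256Cpp")]]
IntegerVector hist256Cpp(NumericMatrix img) {
    IntegerVector h(256);
    const double *p = img.begin();
    R_xlen_t n = img.size();
    for (R_xlen_t i = 0; i < n; i++) {
        double v = p[i];
        if (v >= 0 && v <= 1) h[(int)(v * 255.999)]++;
    }
    return h;
}
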