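#include <Rcpp.h>
using namespace Rcpp;

// Sequential raster-order iterated-conditional-modes sweep.
//
// labels: current label array (0 = background / out of mask, 1..K classes),
//         column-major with dims = c(nx, ny, nz).
// nll:    nvox x K matrix of per-class emission negative log-likelihoods.
// beta:   Potts coupling; the local energy of class k at voxel i is
//         nll(i, k) + beta * #(in-mask neighbours with label != k).
// neigh3d: 0 -> 8-neighbourhood within the axial slice, 1 -> 6-neighbourhood
//          in 3-D. Out-of-mask neighbours never contribute.
// Ties break toward the smaller class code (CSF > GM > WM priority).
// [[Rcpp::export]]
IntegerVector icm_sweep_cpp(IntegerVector labels, NumericMatrix nll,
                            IntegerVector dims, double beta, int neigh3d) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = nll.ncol();
  IntegerVector lab = clone(labels);

  const int off8x[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int off8y[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (lab[i] == 0) continue;
        int nbr_n = 0;          // in-mask neighbours
        int cnt[16] = {0};      // per-class neighbour counts (K <= 16)
        if (neigh3d == 0) {
          for (int t = 0; t < 8; ++t) {
            const int xx = x + off8x[t], yy = y + off8y[t];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny) continue;
            const int l = lab[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * z)];
            if (l > 0) { ++nbr_n; ++cnt[l - 1]; }
          }
        } else {
          const int ox[6] = {-1, 1, 0, 0, 0, 0};
          const int oy[6] = {0, 0, -1, 1, 0, 0};
          const int oz[6] = {0, 0, 0, 0, -1, 1};
          for (int t = 0; t < 6; ++t) {
            const int xx = x + ox[t], yy = y + oy[t], zz = z + oz[t];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const int l = lab[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
            if (l > 0) { ++nbr_n; ++cnt[l - 1]; }
          }
        }
        int best = lab[i] - 1;
        double ebest = R_PosInf;
        for (int k = 0; k < K; ++k) {
          const double e = nll(i, k) + beta * (nbr_n - cnt[k]);
          if (e < ebest - 1e-12) { ebest = e; best = k; }
        }
        lab[i] = best + 1;
      }
    }
  }
  return lab;
}
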