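// Low-level numerical kernels for the multi-stream 3D CNN and mask utilities.
//
// Feature maps are passed as arma::mat of shape (channels x voxels), voxels
// enumerated column-major over a (d1, d2, d3) grid: v = x + d1*(y + d2*z).
// Convolutions are 3x3x3, stride 1, zero padding 1 ("same"), the geometry the
// network architecture fixes; pooling is max-pooling with ceil-mode output
// dims and windows clipped at the border.
//
// The im2col row convention is row = cin*27 + ko with ko = (dz+1)*9 +
// (dy+1)*3 + (dx+1); weight matrices on the R side use the same ordering.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col3(const arma::mat& X, int d1, int d2, int d3) {
  const int cin = X.n_rows;
  const int V = d1 * d2 * d3;
  arma::mat Xc(cin * 27, V, arma::fill::zeros);
  for (int z = 0; z < d3; ++z) {
    for (int y = 0; y < d2; ++y) {
      for (int x = 0; x < d1; ++x) {
        const int v = x + d1 * (y + d2 * z);
        double* col = Xc.colptr(v);
        for (int dz = -1; dz <= 1; ++dz) {
          const int zz = z + dz;
          if (zz < 0 || zz >= d3) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= d2) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              const int xx = x + dx;
              if (xx < 0 || xx >= d1) continue;
              const int ko = (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
              const double* src = X.colptr(xx + d1 * (yy + d2 * zz));
              for (int c = 0; c < cin; ++c) col[c * 27 + ko] = src[c];
            }
          }
        }
      }
    }
  }
  return Xc;
}

// [[Rcpp::export(name = ".conv3_forward")]]
arma::mat conv3_forward(const arma::mat& X, int d1, int d2, int d3,
                        const arma::mat& W, const arma::vec& b) {
  arma::mat Y = W * im2col3(X, d1, d2, d3);
  Y.each_col() += b;
  return Y;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(const arma::mat& X, int d1, int d2, int d3,
                    const arma::mat& W, const arma::mat& dY) {
  arma::mat Xc = im2col3(X, d1, d2, d3);
  arma::mat dW = dY * Xc.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dXc = W.t() * dY;
  const int cin = X.n_rows;
  arma::mat dX(cin, X.n_cols, arma::fill::zeros);
  for (int z = 0; z < d3; ++z) {
    for (int y = 0; y < d2; ++y) {
      for (int x = 0; x < d1; ++x) {
        const int v = x + d1 * (y + d2 * z);
        const double* col = dXc.colptr(v);
        for (int dz = -1; dz <= 1; ++dz) {
          const int zz = z + dz;
          if (zz < 0 || zz >= d3) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= d2) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              const int xx = x + dx;
              if (xx < 0 || xx >= d1) continue;
              const int ko = (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
              double* dst = dX.colptr(xx + d1 * (yy + d2 * zz));
              for (int c = 0; c < cin; ++c) dst[c] += col[c * 27 + ko];
            }
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".pool3_forward")]]
List pool3_forward(const arma::mat& X, int d1, int d2, int d3,
                   int k1, int k2, int k3, int s1, int s2, int s3) {
  const int C = X.n_rows;
  const int o1 = (d1 + s1 - 1) / s1;
  const int o2 = (d2 + s2 - 1) / s2;
  const int o3 = (d3 + s3 - 1) / s3;
  arma::mat Y(C, o1 * o2 * o3);
  arma::umat amax(C, o1 * o2 * o3);
  for (int z = 0; z < o3; ++z) {
    const int z0 = z * s3, z1 = std::min(z0 + k3, d3);
    for (int y = 0; y < o2; ++y) {
      const int y0 = y * s2, y1 = std::min(y0 + k2, d2);
      for (int x = 0; x < o1; ++x) {
        const int x0 = x * s1, x1 = std::min(x0 + k1, d1);
        const int vo = x + o1 * (y + o2 * z);
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bi = 0;
          for (int zz = z0; zz < z1; ++zz)
            for (int yy = y0; yy < y1; ++yy)
              for (int xx = x0; xx < x1; ++xx) {
                const arma::uword vi = xx + d1 * (yy + d2 * zz);
                const double val = X(c, vi);
                if (val > best) { best = val; bi = vi; }
              }
          Y(c, vo) = best;
          amax(c, vo) = bi;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = amax,
                      _["dims"] = IntegerVector::create(o1, o2, o3));
}

// [[Rcpp::export(name = ".pool3_backward")]]
arma::mat pool3_backward(const arma::mat& dY, const arma::umat& amax,
                         int Vin) {
  const int C = dY.n_rows;
  arma::mat dX(C, Vin, arma::fill::zeros);
  for (arma::uword j = 0; j < dY.n_cols; ++j)
    for (int c = 0; c < C; ++c)
      dX(c, amax(c, j)) += dY(c, j);
  return dX;
}

// 6-connected component labelling of a 3D binary array (BFS flood fill).
// [[Rcpp::export(name = ".label_components3")]]
IntegerVector label_components3(const LogicalVector& mask,
                                const IntegerVector& dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int V = d1 * d2 * d3;
  IntegerVector lab(V, 0);
  std::vector<int> queue;
  queue.reserve(1024);
  int next = 0;
  const int off1[6] = {-1, 1, 0, 0, 0, 0};
  const int off2[6] = {0, 0, -1, 1, 0, 0};
  const int off3[6] = {0, 0, 0, 0, -1, 1};
  for (int v0 = 0; v0 < V; ++v0) {
    if (mask[v0] != TRUE || lab[v0] != 0) continue;
    ++next;
    lab[v0] = next;
    queue.clear();
    queue.push_back(v0);
    while (!queue.empty()) {
      const int v = queue.back();
      queue.pop_back();
      const int x = v % d1, y = (v / d1) % d2, z = v / (d1 * d2);
      for (int k = 0; k < 6; ++k) {
        const int xx = x + off1[k], yy = y + off2[k], zz = z + off3[k];
        if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3)
          continue;
        const int w = xx + d1 * (yy + d2 * zz);
        if (mask[w] == TRUE && lab[w] == 0) {
          lab[w] = next;
          queue.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
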