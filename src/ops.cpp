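#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 3D convolution kernels for (x, y, z, channel) arrays stored column-major
// (x fastest). Weights are (k, k, k, c_in, c_out) with odd k and "same"
// zero padding of (k-1)/2. Stride is always 1; downsampling is done by
// pooling outside these kernels.

static inline void get_dims4(const NumericVector& a, int* d) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 4) stop("expected a 4D array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// [[Rcpp::export]]
NumericVector conv3_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4]; get_dims4(x, dx);
  IntegerVector dw = w.attr("dim");
  if (dw.size() != 5) stop("weights must be 5D (k,k,k,cin,cout)");
  const int k = dw[0], cin = dw[3], cout = dw[4];
  if (dw[1] != k || dw[2] != k) stop("kernel must be cubic");
  if (cin != dx[3]) stop("input channel mismatch");
  const int nx = dx[0], ny = dx[1], nz = dx[2], p = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox * cout);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();

  for (int co = 0; co < cout; ++co) {
    double* ob = op + nvox * co;
    const double bc = b[co];
    for (R_xlen_t i = 0; i < nvox; ++i) ob[i] = bc;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xb = xp + nvox * ci;
      for (int kz = -p; kz <= p; ++kz)
        for (int ky = -p; ky <= p; ++ky)
          for (int kx = -p; kx <= p; ++kx) {
            const double wv = wp[(kx + p) + k * ((ky + p) + k * ((kz + p) + k * (ci + cin * co)))];
            if (wv == 0.0) continue;
            const int z0 = std::max(0, -kz), z1 = nz - 1 - std::max(0, kz);
            const int y0 = std::max(0, -ky), y1 = ny - 1 - std::max(0, ky);
            const int x0 = std::max(0, -kx), x1 = nx - 1 - std::max(0, kx);
            for (int z = z0; z <= z1; ++z) {
              const R_xlen_t zo = (R_xlen_t)z * nx * ny;
              const R_xlen_t zi = (R_xlen_t)(z + kz) * nx * ny;
              for (int y = y0; y <= y1; ++y) {
                double* orow = ob + zo + (R_xlen_t)y * nx;
                const double* irow = xb + zi + (R_xlen_t)(y + ky) * nx + kx;
                for (int xx = x0; xx <= x1; ++xx) orow[xx] += wv * irow[xx];
              }
            }
          }
    }
  }
  return out;
}

// gradient wrt input: correlate the output gradient with the flipped kernel
// [[Rcpp::export]]
NumericVector conv3_bwd_input(NumericVector gy, NumericVector w) {
  int dg[4]; get_dims4(gy, dg);
  IntegerVector dw = w.attr("dim");
  const int k = dw[0], cin = dw[3], cout = dw[4];
  if (cout != dg[3]) stop("output channel mismatch");
  const int nx = dg[0], ny = dg[1], nz = dg[2], p = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gx(nvox * cin);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  const double* gp = gy.begin();
  const double* wp = w.begin();
  double* xp = gx.begin();

  for (int ci = 0; ci < cin; ++ci) {
    double* xb = xp + nvox * ci;
    for (int co = 0; co < cout; ++co) {
      const double* gb = gp + nvox * co;
      for (int kz = -p; kz <= p; ++kz)
        for (int ky = -p; ky <= p; ++ky)
          for (int kx = -p; kx <= p; ++kx) {
            const double wv = wp[(kx + p) + k * ((ky + p) + k * ((kz + p) + k * (ci + cin * co)))];
            if (wv == 0.0) continue;
            // out[v] += w * in[v + off]  =>  gin[u] += w * gout[u - off]
            const int qz = -kz, qy = -ky, qx = -kx;
            const int z0 = std::max(0, -qz), z1 = nz - 1 - std::max(0, qz);
            const int y0 = std::max(0, -qy), y1 = ny - 1 - std::max(0, qy);
            const int x0 = std::max(0, -qx), x1 = nx - 1 - std::max(0, qx);
            for (int z = z0; z <= z1; ++z) {
              const R_xlen_t zo = (R_xlen_t)z * nx * ny;
              const R_xlen_t zi = (R_xlen_t)(z + qz) * nx * ny;
              for (int y = y0; y <= y1; ++y) {
                double* orow = xb + zo + (R_xlen_t)y * nx;
                const double* irow = gb + zi + (R_xlen_t)(y + qy) * nx + qx;
                for (int xx = x0; xx <= x1; ++xx) orow[xx] += wv * irow[xx];
              }
            }
          }
    }
  }
  return gx;
}

// gradients wrt weights and bias
// [[Rcpp::export]]
List conv3_bwd_weight(NumericVector x, NumericVector gy, int k) {
  int dx[4]; get_dims4(x, dx);
  int dg[4]; get_dims4(gy, dg);
  const int nx = dx[0], ny = dx[1], nz = dx[2], cin = dx[3], cout = dg[3];
  const int p = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gw((R_xlen_t)k * k * k * cin * cout);
  gw.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
  NumericVector gb(cout);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* wp = gw.begin();

  for (int co = 0; co < cout; ++co) {
    const double* gbch = gp + nvox * co;
    double s = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) s += gbch[i];
    gb[co] = s;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xb = xp + nvox * ci;
      for (int kz = -p; kz <= p; ++kz)
        for (int ky = -p; ky <= p; ++ky)
          for (int kx = -p; kx <= p; ++kx) {
            const int z0 = std::max(0, -kz), z1 = nz - 1 - std::max(0, kz);
            const int y0 = std::max(0, -ky), y1 = ny - 1 - std::max(0, ky);
            const int x0 = std::max(0, -kx), x1 = nx - 1 - std::max(0, kx);
            double acc = 0.0;
            for (int z = z0; z <= z1; ++z) {
              const R_xlen_t zo = (R_xlen_t)z * nx * ny;
              const R_xlen_t zi = (R_xlen_t)(z + kz) * nx * ny;
              for (int y = y0; y <= y1; ++y) {
                const double* orow = gbch + zo + (R_xlen_t)y * nx;
                const double* irow = xb + zi + (R_xlen_t)(y + ky) * nx + kx;
                for (int xx = x0; xx <= x1; ++xx) acc += orow[xx] * irow[xx];
              }
            }
            wp[(kx + p) + k * ((ky + p) + k * ((kz + p) + k * (ci + cin * co)))] = acc;
          }
    }
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// ---- connected components (6/18/26) on a 3D logical/numeric mask ----

static void neighbour_offsets(int conn, std::vector<int>& ox,
                              std::vector<int>& oy, std::vector<int>& oz) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (conn == 6 && m > 1) continue;
        if (conn == 18 && m > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
}

// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, int nx, int ny, int nz, int conn) {
  if (conn != 6 && conn != 18 && conn != 26) stop("connectivity must be 6, 18 or 26");
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if ((R_xlen_t)mask.size() != n) stop("mask size mismatch");
  IntegerVector lab(n, 0);
  std::vector<int> ox, oy, oz;
  neighbour_offsets(conn, ox, oy, oz);
  const int nb = (int)ox.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int vx = (int)(v % nx);
      int vy = (int)((v / nx) % ny);
      int vz = (int)(v / ((R_xlen_t)nx * ny));
      for (int t = 0; t < nb; ++t) {
        int ux = vx + ox[t], uy = vy + oy[t], uz = vz + oz[t];
        if (ux < 0 || uy < 0 || uz < 0 || ux >= nx || uy >= ny || uz >= nz) continue;
        R_xlen_t u = ux + (R_xlen_t)nx * (uy + (R_xlen_t)ny * uz);
        if (mask[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}

// binary dilation/erosion with a Euclidean ball of integer radius r
// [[Rcpp::export]]
LogicalVector morph3d(LogicalVector mask, int nx, int ny, int nz, int r, bool dilate) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if ((R_xlen_t)mask.size() != n) stop("mask size mismatch");
  std::vector<int> ox, oy, oz;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r * r) {
          ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
        }
  const int nb = (int)ox.size();
  LogicalVector out(n);
  for (int vz = 0; vz < nz; ++vz)
    for (int vy = 0; vy < ny; ++vy)
      for (int vx = 0; vx < nx; ++vx) {
        R_xlen_t v = vx + (R_xlen_t)nx * (vy + (R_xlen_t)ny * vz);
        bool hit = dilate ? false : true;
        for (int t = 0; t < nb; ++t) {
          int ux = vx + ox[t], uy = vy + oy[t], uz = vz + oz[t];
          bool inside = !(ux < 0 || uy < 0 || uz < 0 || ux >= nx || uy >= ny || uz >= nz);
          bool val = inside ? (bool)mask[ux + (R_xlen_t)nx * (uy + (R_xlen_t)ny * uz)] : false;
          if (dilate) { if (val) { hit = true; break; } }
          else       { if (!val) { hit = false; break; } }
        }
        out[v] = hit;
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// ---- im2col / col2im so convolutions run through BLAS ----------------------

// rows = voxels (x fastest), cols = (kx, ky, kz, ci) taps with zero padding
// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, int k) {
  int dx[4]; get_dims4(x, dx);
  const int nx = dx[0], ny = dx[1], nz = dx[2], cin = dx[3], p = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(nvox, (R_xlen_t)k * k * k * cin);
  const double* xp = x.begin();
  R_xlen_t col = 0;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xb = xp + nvox * ci;
    for (int kz = -p; kz <= p; ++kz)
      for (int ky = -p; ky <= p; ++ky)
        for (int kx = -p; kx <= p; ++kx) {
          double* ob = &out(0, col++);
          for (int z = 0; z < nz; ++z) {
            const int zi = z + kz;
            const bool zok = zi >= 0 && zi < nz;
            for (int y = 0; y < ny; ++y) {
              const int yi = y + ky;
              const bool yok = zok && yi >= 0 && yi < ny;
              double* orow = ob + (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
              if (!yok) { std::memset(orow, 0, nx * sizeof(double)); continue; }
              const double* irow = xb + (R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx + kx;
              const int x0 = std::max(0, -kx), x1 = nx - 1 - std::max(0, kx);
              for (int xx = 0; xx < x0; ++xx) orow[xx] = 0.0;
              for (int xx = x0; xx <= x1; ++xx) orow[xx] = irow[xx];
              for (int xx = x1 + 1; xx < nx; ++xx) orow[xx] = 0.0;
            }
          }
        }
  }
  return out;
}

// scatter-add the im2col-shaped gradient back onto the input grid
// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix g, int nx, int ny, int nz, int cin, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox * cin);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  double* op = out.begin();
  R_xlen_t col = 0;
  for (int ci = 0; ci < cin; ++ci) {
    double* ob = op + nvox * ci;
    for (int kz = -p; kz <= p; ++kz)
      for (int ky = -p; ky <= p; ++ky)
        for (int kx = -p; kx <= p; ++kx) {
          const double* gb = &g(0, col++);
          for (int z = 0; z < nz; ++z) {
            const int zi = z + kz;
            if (zi < 0 || zi >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int yi = y + ky;
              if (yi < 0 || yi >= ny) continue;
              const double* grow = gb + (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
              double* orow = ob + (R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx + kx;
              const int x0 = std::max(0, -kx), x1 = nx - 1 - std::max(0, kx);
              for (int xx = x0; xx <= x1; ++xx) orow[xx] += grow[xx];
            }
          }
        }
  }
  return out;
}
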