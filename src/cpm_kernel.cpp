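// Cellular Potts kernel: modified-Metropolis pixel-copy dynamics with
// incremental volume/surface/contact/chemotaxis energy evaluation, plus the
// forward-Euler reaction-diffusion stepper and whole-lattice bookkeeping
// passes (recount, contact census).
//
// Conventions shared with the R side:
//   - grid is an integer W x H matrix; entry 0 is medium, k > 0 is cell id k.
//   - per-cell vectors are indexed by id (element id-1); retired cells keep
//     their slot with volume 0 and never reappear on the grid.
//   - contact energy and copy-source neighbourhoods are 2nd order
//     (8-neighbour); surface and medium-surface counts use 4-neighbour faces.
//   - the lattice boundary is fixed: out-of-bounds neighbours are never
//     proposed and faces on the domain edge are not counted.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const int DX8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX4[4] = {-1, 1, 0, 0};
static const int DY4[4] = {0, 0, -1, 1};

// xorshift64* generator, seeded through splitmix64 so that small seeds from
// R's RNG give well-mixed states. All kernel randomness flows through this;
// the R wrapper draws the seed from R's RNG, so set.seed() governs runs.
struct Xorshift {
  uint64_t s;
  explicit Xorshift(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x853C49E6748FEA9BULL;
  }
  inline double unif() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return ((s * 0x2545F4914F6CDD1DULL) >> 11) * (1.0 / 9007199254740992.0);
  }
  inline int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// Energy change for copying occupant `os` into pixel (tx,ty) currently
// holding `ot`. Coordinates are 0-based. If sx >= 0 the chemotaxis term is
// evaluated using the concentration difference target - source pixel for the
// extending (source) cell. Returns the dH and, through the pointers, the
// 4-neighbour surface deltas needed for bookkeeping on acceptance.
static double delta_H(const IntegerMatrix& grid, int tx, int ty, int os, int ot,
                      const IntegerVector& type,
                      const NumericVector& volume, const NumericVector& surface,
                      const NumericVector& tvol, const NumericVector& lamv,
                      const NumericVector& tsurf, const NumericVector& lams,
                      const NumericMatrix& J, const NumericMatrix& chem_lam,
                      const std::vector<const double*>& fields,
                      int sx, int sy, int W, int H,
                      int* ds_os_out, int* ds_ot_out) {
  double dH = 0.0;
  // volume terms
  if (os > 0) {
    double v = volume[os - 1], vt = tvol[os - 1];
    dH += lamv[os - 1] * ((v + 1 - vt) * (v + 1 - vt) - (v - vt) * (v - vt));
  }
  if (ot > 0) {
    double v = volume[ot - 1], vt = tvol[ot - 1];
    dH += lamv[ot - 1] * ((v - 1 - vt) * (v - 1 - vt) - (v - vt) * (v - vt));
  }
  // surface deltas over the 4-neighbour faces of the flipped pixel
  int eq_os = 0, ne_os = 0, eq_ot = 0, ne_ot = 0;
  for (int k = 0; k < 4; ++k) {
    int nx = tx + DX4[k], ny = ty + DY4[k];
    if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
    int id = grid(nx, ny);
    if (id == os) ++eq_os; else ++ne_os;
    if (id == ot) ++eq_ot; else ++ne_ot;
  }
  int ds_os = ne_os - eq_os;   // source cell gains faces to unlike pixels
  int ds_ot = eq_ot - ne_ot;   // target cell loses its faces, gains exposure
  if (os > 0) {
    double s = surface[os - 1], st = tsurf[os - 1];
    dH += lams[os - 1] * ((s + ds_os - st) * (s + ds_os - st) - (s - st) * (s - st));
  }
  if (ot > 0) {
    double s = surface[ot - 1], st = tsurf[ot - 1];
    dH += lams[ot - 1] * ((s + ds_ot - st) * (s + ds_ot - st) - (s - st) * (s - st));
  }
  // contact energy over the 8-neighbourhood
  int tau_os = (os > 0) ? type[os - 1] : 0;
  int tau_ot = (ot > 0) ? type[ot - 1] : 0;
  for (int k = 0; k < 8; ++k) {
    int nx = tx + DX8[k], ny = ty + DY8[k];
    if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
    int id = grid(nx, ny);
    int tau_n = (id > 0) ? type[id - 1] : 0;
    if (id != os) dH += J(tau_os, tau_n);
    if (id != ot) dH -= J(tau_ot, tau_n);
  }
  // chemotaxis bias for the extending cell: moves up-gradient are favoured
  if (os > 0 && sx >= 0 && chem_lam.nrow() >= os) {
    int nf = (int)fields.size();
    for (int f = 0; f < nf; ++f) {
      double lam = chem_lam(os - 1, f);
      if (lam != 0.0) {
        const double* c = fields[f];
        dH -= lam * (c[tx + (size_t)W * ty] - c[sx + (size_t)W * sy]);
      }
    }
  }
  *ds_os_out = ds_os;
  *ds_ot_out = ds_ot;
  return dH;
}

static void apply_flip(IntegerMatrix& grid, int tx, int ty, int os, int ot,
                       NumericVector& volume, NumericVector& surface,
                       NumericVector& msurface, NumericVector& sumx,
                       NumericVector& sumy, int ds_os, int ds_ot,
                       int W, int H) {
  grid(tx, ty) = os;
  if (os > 0) {
    volume[os - 1] += 1;
    surface[os - 1] += ds_os;
    sumx[os - 1] += tx + 1;
    sumy[os - 1] += ty + 1;
  }
  if (ot > 0) {
    volume[ot - 1] -= 1;
    surface[ot - 1] += ds_ot;
    sumx[ot - 1] -= tx + 1;
    sumy[ot - 1] -= ty + 1;
  }
  // medium-contact faces
  int med_faces = 0;
  for (int k = 0; k < 4; ++k) {
    int nx = tx + DX4[k], ny = ty + DY4[k];
    if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
    int id = grid(nx, ny);
    if (id == 0) ++med_faces;
    if (id > 0) {
      if (ot == 0) msurface[id - 1] -= 1;
      if (os == 0) msurface[id - 1] += 1;
    }
  }
  if (ot > 0) msurface[ot - 1] -= med_faces;
  if (os > 0) msurface[os - 1] += med_faces;
}

static void diffuse_inplace(NumericMatrix c, double D, double dec,
                            const NumericMatrix& S, int nsub,
                            std::vector<double>& buf) {
  int W = c.nrow(), H = c.ncol();
  double dt = 1.0 / nsub;
  double* cc = REAL(c);
  const double* ss = REAL(S);
  if ((int)buf.size() < W * H) buf.resize((size_t)W * H);
  for (int sub = 0; sub < nsub; ++sub) {
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        size_t i = x + (size_t)W * y;
        double ci = cc[i];
        double lap = 0.0;
        if (x > 0)     lap += cc[i - 1] - ci;
        if (x < W - 1) lap += cc[i + 1] - ci;
        if (y > 0)     lap += cc[i - W] - ci;
        if (y < H - 1) lap += cc[i + W] - ci;
        double v = ci + dt * (D * lap - dec * ci + ss[i]);
        buf[i] = (v < 0.0) ? 0.0 : v;
      }
    }
    std::copy(buf.begin(), buf.begin() + (size_t)W * H, cc);
  }
}

//' @noRd
// [[Rcpp::export(name = ".cpm_delta_energy_cpp")]]
double cpm_delta_energy_cpp(IntegerMatrix grid, int tx, int ty, int src_id,
                            IntegerVector type, NumericVector volume,
                            NumericVector surface, NumericVector tvol,
                            NumericVector lamv, NumericVector tsurf,
                            NumericVector lams, NumericMatrix J,
                            NumericMatrix chem_lam, List field_list,
                            int src_x, int src_y) {
  int W = grid.nrow(), H = grid.ncol();
  if (tx < 1 || tx > W || ty < 1 || ty > H)
    stop("target pixel out of bounds");
  int ot = grid(tx - 1, ty - 1);
  if (src_id == ot)
    stop("null attempt: source id equals current occupant");
  std::vector<const double*> fptr;
  for (int f = 0; f < field_list.size(); ++f)
    fptr.push_back(REAL((SEXP)field_list[f]));
  int ds_os, ds_ot;
  return delta_H(grid, tx - 1, ty - 1, src_id, ot, type, volume, surface,
                 tvol, lamv, tsurf, lams, J, chem_lam, fptr,
                 src_x - 1, src_y - 1, W, H, &ds_os, &ds_ot);
}

//' @noRd
// [[Rcpp::export(name = ".cpm_advance_cpp")]]
void cpm_advance_cpp(IntegerMatrix grid, IntegerVector type,
                     NumericVector volume, NumericVector surface,
                     NumericVector msurface, NumericVector sumx,
                     NumericVector sumy, NumericVector tvol,
                     NumericVector lamv, NumericVector tsurf,
                     NumericVector lams, NumericMatrix J,
                     NumericMatrix chem_lam, List field_list,
                     NumericVector D, NumericVector decay, List source_list,
                     int nsub, double Tm, int n_mcs, double seed) {
  if (Tm <= 0) stop("membrane fluctuation amplitude T_m must be > 0");
  int W = grid.nrow(), H = grid.ncol();
  int nf = field_list.size();
  std::vector<NumericMatrix> fmat, smat;
  std::vector<const double*> fptr;
  for (int f = 0; f < nf; ++f) {
    fmat.push_back(as<NumericMatrix>(field_list[f]));
    smat.push_back(as<NumericMatrix>(source_list[f]));
    fptr.push_back(REAL((SEXP)fmat[f]));
  }
  Xorshift rng((uint64_t)seed);
  std::vector<double> buf;
  long attempts = (long)W * H;
  for (int step = 0; step < n_mcs; ++step) {
    for (long a = 0; a < attempts; ++a) {
      int tx = rng.below(W), ty = rng.below(H);
      int k = rng.below(8);
      int sx = tx + DX8[k], sy = ty + DY8[k];
      if (sx < 0 || sx >= W || sy < 0 || sy >= H) continue;
      int os = grid(sx, sy);
      int ot = grid(tx, ty);
      if (os == ot) continue;
      int ds_os, ds_ot;
      double dH = delta_H(grid, tx, ty, os, ot, type, volume, surface, tvol,
                          lamv, tsurf, lams, J, chem_lam, fptr, sx, sy,
                          W, H, &ds_os, &ds_ot);
      if (dH <= 0.0 || rng.unif() < std::exp(-dH / Tm))
        apply_flip(grid, tx, ty, os, ot, volume, surface, msurface,
                   sumx, sumy, ds_os, ds_ot, W, H);
    }
    for (int f = 0; f < nf; ++f)
      diffuse_inplace(fmat[f], D[f], decay[f], smat[f], nsub, buf);
  }
}

//' @noRd
// [[Rcpp::export(name = ".diffuse_field_cpp")]]
void diffuse_field_cpp(NumericMatrix field, double D, double decay,
                       NumericMatrix source, int nsub, int n_steps) {
  std::vector<double> buf;
  for (int s = 0; s < n_steps; ++s)
    diffuse_inplace(field, D, decay, source, nsub, buf);
}

//' @noRd
// [[Rcpp::export(name = ".cpm_recount_cpp")]]
List cpm_recount_cpp(IntegerMatrix grid, int n_ids) {
  int W = grid.nrow(), H = grid.ncol();
  NumericVector volume(n_ids), surface(n_ids), msurface(n_ids);
  NumericVector sumx(n_ids), sumy(n_ids);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int id = grid(x, y);
      if (id <= 0) continue;
      volume[id - 1] += 1;
      sumx[id - 1] += x + 1;
      sumy[id - 1] += y + 1;
      for (int k = 0; k < 4; ++k) {
        int nx = x + DX4[k], ny = y + DY4[k];
        if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
        int nid = grid(nx, ny);
        if (nid != id) {
          surface[id - 1] += 1;
          if (nid == 0) msurface[id - 1] += 1;
        }
      }
    }
  }
  return List::create(_["volume"] = volume, _["surface"] = surface,
                      _["msurface"] = msurface, _["sumx"] = sumx,
                      _["sumy"] = sumy);
}

// Contact census over 4-neighbour faces: for every live cell, the number of
// faces shared with each neighbour category (categories are assigned per id
// by the caller; medium has its own category med_cat). Also records, per id,
// one adjacent medium pixel (1-based linear index) usable for ECM deposition.
//' @noRd
// [[Rcpp::export(name = ".cpm_census_cpp")]]
List cpm_census_cpp(IntegerMatrix grid, IntegerVector cat, int ncat,
                    int med_cat) {
  int W = grid.nrow(), H = grid.ncol();
  int n_ids = cat.size();
  NumericMatrix contact(n_ids, ncat);
  IntegerVector medium_adj(n_ids);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int id = grid(x, y);
      if (id <= 0) continue;
      for (int k = 0; k < 4; ++k) {
        int nx = x + DX4[k], ny = y + DY4[k];
        if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
        int nid = grid(nx, ny);
        if (nid == id) continue;
        int c = (nid == 0) ? med_cat : cat[nid - 1];
        if (c >= 1 && c <= ncat) contact(id - 1, c - 1) += 1;
        if (nid == 0 && medium_adj[id - 1] == 0)
          medium_adj[id - 1] = (nx + 1) + W * ny;  // 1-based linear index
      }
    }
  }
  return List::create(_["contact"] = contact, _["medium_adj"] = medium_adj);
}
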