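#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labeling of a logical 2D/3D grid.
// full = true: 8-connectivity (2D) / 26-connectivity (3D); else 4 / 6.
// Labels are assigned in raster-scan order of each component's first voxel,
// so the output is independent of any RNG state and reproducible.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, bool full) {
  int nd = dims.size();
  int nz = (nd == 3) ? dims[0] : 1;
  int ny = (nd == 3) ? dims[1] : dims[0];
  int nx = (nd == 3) ? dims[2] : dims[1];
  // R arrays are column-major over (z, y, x): index = z + nz*(y + ny*x)
  long n = (long)nz * ny * nx;
  IntegerVector lab(n, 0);

  // neighbor offsets
  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; az++)
    for (int ay = -1; ay <= 1; ay++)
      for (int ax = -1; ax <= 1; ax++) {
        if (az == 0 && ay == 0 && ax == 0) continue;
        if (nd == 2 && az != 0) continue;
        int nn = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (!full && nn != 1) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  int nb = dz.size();

  int next = 0;
  std::queue<long> q;
  for (long i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      long cur = q.front(); q.pop();
      int z = cur % nz;
      int y = (cur / nz) % ny;
      int x = cur / ((long)nz * ny);
      for (int k = 0; k < nb; k++) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        long j = zz + (long)nz * (yy + (long)ny * xx);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_objects") = next;
  return lab;
}
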