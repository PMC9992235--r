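#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic FOD-peak streamline propagation (Euler, nearest-voxel peak
// lookup). Records, for every visited point, the containing voxel, how many
// peaks were available there and which one was consumed — the bookkeeping
// the multi-level branching logic relies on.
//
// dirs:   flat (nx, ny, nz, K, 3) array of unit peak directions
// amps:   flat (nx, ny, nz, K) array of peak amplitudes
// counts: flat (nx, ny, nz) per-voxel peak counts
// invAffine: 4x4 world-to-voxel matrix (0-based voxel centres at integers)
// target: flat (nx, ny, nz) 0/1 target membership (may be length 0)
//
// Termination codes: 1 angle, 2 amplitude, 3 exited_volume,
// 4 entered_target, 5 max_length.
// [[Rcpp::export(name = ".propagateCore")]]
List propagateCore(NumericVector dirs, NumericVector amps,
                   IntegerVector counts, IntegerVector dim,
                   NumericMatrix invAffine, NumericVector seed,
                   NumericVector initDir, double step, double cosAngle,
                   double ampThreshold, int maxSteps, IntegerVector target,
                   bool stopAtTarget) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nVox = nx * ny * nz;
  const int K = (counts.size() > 0 && dirs.size() > 0)
                  ? (int)(dirs.size() / (3 * (size_t)nVox)) : 0;
  const bool haveTarget = target.size() == nVox;

  std::vector<double> px, py, pz;
  std::vector<int> uvx, uvy, uvz, uAvail, uUsed;
  px.reserve(maxSteps + 1);

  double p[3] = {seed[0], seed[1], seed[2]};
  double prev[3] = {initDir[0], initDir[1], initDir[2]};
  int reason = 5;  // max_length unless something else stops us
  bool reached = false;

  for (int s = 0; s <= maxSteps; ++s) {
    px.push_back(p[0]); py.push_back(p[1]); pz.push_back(p[2]);
    // containing voxel
    double vx = invAffine(0,0)*p[0] + invAffine(0,1)*p[1] + invAffine(0,2)*p[2] + invAffine(0,3);
    double vy = invAffine(1,0)*p[0] + invAffine(1,1)*p[1] + invAffine(1,2)*p[2] + invAffine(1,3);
    double vz = invAffine(2,0)*p[0] + invAffine(2,1)*p[1] + invAffine(2,2)*p[2] + invAffine(2,3);
    int i = (int)std::floor(vx + 0.5), j = (int)std::floor(vy + 0.5), k = (int)std::floor(vz + 0.5);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
      uvx.push_back(-1); uvy.push_back(-1); uvz.push_back(-1);
      uAvail.push_back(0); uUsed.push_back(0);
      reason = 3; break;
    }
    const int vlin = i + nx * (j + ny * k);
    const int navail = counts[vlin];
    uvx.push_back(i); uvy.push_back(j); uvz.push_back(k);
    uAvail.push_back(navail);

    if (haveTarget && target[vlin]) {
      reached = true;
      if (stopAtTarget) { uUsed.push_back(0); reason = 4; break; }
    }
    if (navail == 0) { uUsed.push_back(0); reason = 2; break; }

    // least-deviating peak (antipodal sign resolved); ties by amplitude
    int best = -1; double bestAdot = -1.0, bestAmp = -1.0, bestSign = 1.0;
    for (int q = 0; q < navail; ++q) {
      const double amp = amps[vlin + (size_t)nVox * q];
      if (amp < ampThreshold) continue;   // below the propagation threshold
      const size_t base = vlin + (size_t)nVox * q;
      const double dx = dirs[base];
      const double dy = dirs[base + (size_t)nVox * K];
      const double dz = dirs[base + 2 * (size_t)nVox * K];
      const double dot = dx * prev[0] + dy * prev[1] + dz * prev[2];
      const double adot = std::fabs(dot);
      if (adot > bestAdot + 1e-12 ||
          (adot > bestAdot - 1e-12 && amp > bestAmp)) {
        best = q; bestAdot = adot; bestAmp = amp;
        bestSign = (dot >= 0) ? 1.0 : -1.0;
      }
    }
    if (best < 0) { uUsed.push_back(0); reason = 2; break; }
    if (bestAdot < cosAngle) { uUsed.push_back(0); reason = 1; break; }
    uUsed.push_back(best + 1);
    if (s == maxSteps) { reason = 5; break; }

    const size_t base = vlin + (size_t)nVox * best;
    prev[0] = bestSign * dirs[base];
    prev[1] = bestSign * dirs[base + (size_t)nVox * K];
    prev[2] = bestSign * dirs[base + 2 * (size_t)nVox * K];
    p[0] += step * prev[0]; p[1] += step * prev[1]; p[2] += step * prev[2];
  }

  const int n = px.size();
  NumericMatrix pts(n, 3);
  IntegerMatrix voxm(n, 3);
  IntegerVector avail(n), used(n);
  for (int r = 0; r < n; ++r) {
    pts(r,0) = px[r]; pts(r,1) = py[r]; pts(r,2) = pz[r];
    voxm(r,0) = uvx[r]; voxm(r,1) = uvy[r]; voxm(r,2) = uvz[r];
    avail[r] = uAvail[r]; used[r] = uUsed[r];
  }
  return List::create(_["points"] = pts, _["voxel"] = voxm,
                      _["nAvailable"] = avail, _["used"] = used,
                      _["reason"] = reason, _["reached"] = reached);
}
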