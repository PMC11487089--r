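#include <Rcpp.h>
using namespace Rcpp;

// Cellular Potts kinetics: Metropolis-accepted spin-copy attempts on an
// integer lattice. Spin 0 is the ECM/medium compartment; positive spins are
// cell ids whose type (1 = core C1, 2 = cortical C2) comes from cell_types.
// Contact energy J is indexed by type (row/col 0 = medium); the volume
// constraint lambda * (v - V_T)^2 applies to cells only.

static inline int spin_type(int s, const IntegerVector& cell_types) {
  return s == 0 ? 0 : cell_types[s - 1];
}

struct Lattice {
  int H, W;
  IntegerMatrix spins;
  const IntegerVector& cell_types;
  const NumericMatrix& J;
  double lambda, vt, temp;
  std::vector<double> vol;
  int ndir;
  bool connectivity;
  int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  // 8-neighborhood in cyclic (ring) order for the connectivity test
  int ring_r[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int ring_c[8] = {0, 1, 1, 1, 0, -1, -1, -1};

  Lattice(IntegerMatrix s, const IntegerVector& ct, const NumericMatrix& Jm,
          double lam, double vtarget, double temperature, int neighborhood,
          bool connect)
      : H(s.nrow()), W(s.ncol()), spins(s), cell_types(ct), J(Jm),
        lambda(lam), vt(vtarget), temp(temperature), connectivity(connect) {
    ndir = neighborhood == 1 ? 4 : 8;
    vol.assign(ct.size(), 0.0);
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        if (spins(r, c) > 0) vol[spins(r, c) - 1] += 1.0;
  }

  // contact-energy change at site (r, c) if its spin flips old_s -> new_s
  double contact_delta(int r, int c, int old_s, int new_s) const {
    double de = 0.0;
    int t_old = spin_type(old_s, cell_types);
    int t_new = spin_type(new_s, cell_types);
    for (int d = 0; d < ndir; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int sn = spins(rr, cc);
      int tn = spin_type(sn, cell_types);
      if (sn != new_s) de += J(t_new, tn);
      if (sn != old_s) de -= J(t_old, tn);
    }
    return de;
  }

  double volume_delta(int old_s, int new_s) const {
    double de = 0.0;
    if (old_s > 0) {
      double v = vol[old_s - 1];
      de += lambda * ((v - 1 - vt) * (v - 1 - vt) - (v - vt) * (v - vt));
    }
    if (new_s > 0) {
      double v = vol[new_s - 1];
      de += lambda * ((v + 1 - vt) * (v + 1 - vt) - (v - vt) * (v - vt));
    }
    return de;
  }

  // one copy attempt at a random boundary pair: (site, neighbor) draws are
  // rejected until the two spins differ, so every attempt proposes a real
  // copy. Returns 1 accepted, 0 rejected, and fills de.
  int attempt(double* de_out) {
    int r = 0, c = 0, rr = 0, cc = 0, old_s = 0, new_s = 0;
    bool found = false;
    *de_out = NA_REAL;
    for (int tries = 0; tries < 4096; ++tries) {
      int site = (int)(unif_rand() * (double)(H * W));
      if (site >= H * W) site = H * W - 1;
      r = site % H; c = site / H;
      int d = (int)(unif_rand() * ndir);
      if (d >= ndir) d = ndir - 1;
      rr = r + dr[d]; cc = c + dc[d];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      old_s = spins(r, c);
      new_s = spins(rr, cc);
      if (old_s != new_s) { found = true; break; }
    }
    if (!found) return 0;
    // local-connectivity guard: refuse to remove a site whose same-cell
    // neighbors do not form a single contiguous arc of the 8-ring (the
    // removal could split the cell locally)
    if (connectivity && old_s > 0 && !ring_connected(r, c, old_s)) return 0;
    // the model has no cell death: a cell may not lose its last site
    if (old_s > 0 && vol[old_s - 1] <= 1.0) return 0;
    double de = contact_delta(r, c, old_s, new_s) +
                volume_delta(old_s, new_s);
    *de_out = de;
    bool accept = de <= 0.0 ||
      (temp > 0.0 && unif_rand() < std::exp(-de / temp));
    if (!accept) return 0;
    spins(r, c) = new_s;
    if (old_s > 0) vol[old_s - 1] -= 1.0;
    if (new_s > 0) vol[new_s - 1] += 1.0;
    return 1;
  }

  // true when the neighbors of (r, c) belonging to cell `s` form one
  // contiguous arc of the cyclic 8-ring (off-lattice ring positions count
  // as not-belonging)
  bool ring_connected(int r, int c, int s) const {
    int belong[8];
    int count = 0;
    for (int k = 0; k < 8; ++k) {
      int rr = r + ring_r[k], cc = c + ring_c[k];
      belong[k] = (rr >= 0 && rr < H && cc >= 0 && cc < W &&
                   spins(rr, cc) == s) ? 1 : 0;
      count += belong[k];
    }
    if (count == 0) return true;  // lone site: removal deletes a fragment
    int transitions = 0;
    for (int k = 0; k < 8; ++k)
      if (belong[k] != belong[(k + 1) % 8]) ++transitions;
    return transitions <= 2;
  }
};

// [[Rcpp::export]]
List cpm_evolve_cpp(IntegerMatrix spins, IntegerVector cell_types,
                    NumericMatrix J, double lambda, double vtarget,
                    double temperature, double n_attempts,
                    double record_every, int neighborhood,
                    bool connectivity) {
  Lattice lat(clone(spins), cell_types, J, lambda, vtarget, temperature,
              neighborhood, connectivity);
  long long n = (long long)n_attempts;
  long long rec = (long long)record_every;
  if (rec <= 0) rec = n > 0 ? n : 1;
  int n_snap = (int)(n / rec) + 1;
  List snapshots(n_snap);
  NumericVector snap_attempts(n_snap);
  snapshots[0] = clone(lat.spins);
  snap_attempts[0] = 0;
  long long accepted = 0;
  double de;
  int si = 1;
  for (long long i = 1; i <= n; ++i) {
    accepted += lat.attempt(&de);
    if (i % rec == 0 && si < n_snap) {
      snapshots[si] = clone(lat.spins);
      snap_attempts[si] = (double)i;
      ++si;
    }
  }
  return List::create(_["spins"] = lat.spins,
                      _["volumes"] = NumericVector(lat.vol.begin(),
                                                   lat.vol.end()),
                      _["snapshots"] = snapshots,
                      _["snapshot_attempts"] = snap_attempts,
                      _["accepted"] = (double)accepted);
}

// audit variant: runs n_moves attempts, recording per-attempt delta-E and
// acceptance, plus the spin field after every attempt (for oracle checks of
// local-vs-global energy consistency on small lattices)
// [[Rcpp::export]]
List cpm_audit_cpp(IntegerMatrix spins, IntegerVector cell_types,
                   NumericMatrix J, double lambda, double vtarget,
                   double temperature, int n_moves, int neighborhood,
                   bool connectivity, bool keep_snapshots) {
  Lattice lat(clone(spins), cell_types, J, lambda, vtarget, temperature,
              neighborhood, connectivity);
  NumericVector de(n_moves);
  IntegerVector acc(n_moves);
  List snaps(keep_snapshots ? n_moves : 0);
  for (int i = 0; i < n_moves; ++i) {
    double d;
    acc[i] = lat.attempt(&d);
    de[i] = d;
    if (keep_snapshots) snaps[i] = clone(lat.spins);
  }
  return List::create(_["spins"] = lat.spins,
                      _["volumes"] = NumericVector(lat.vol.begin(),
                                                   lat.vol.end()),
                      _["delta_e"] = de, _["accepted"] = acc,
                      _["snapshots"] = snaps);
}
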