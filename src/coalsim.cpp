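// Structured-coalescent engine.
//
// Conventions shared by all entry points:
//  * populations are 0-based integer indices into a size vector; the pairwise
//    coalescence rate inside population p is 1/size[p] per pair per unit time,
//    so size = nu (relative N) in N_ref-scaled models and size = theta/2 in
//    mutation-scaled (per-site) models;
//  * `mig(i,j)` is the backward-in-time rate at which a single lineage currently
//    in i moves to j, per unit time;
//  * `events` is a matrix with columns (time, code, i, j, x), sorted by time;
//    events sharing a time stamp are applied in row order.  Codes:
//      0 size:   size[i] <- x
//      1 join:   every lineage in i moves to j (population merger, backward)
//      2 pulse:  every lineage in i moves to j independently with probability x
//      3 mig:    mig(i,j) <- x
//      4 clear:  all migration rates <- 0
//  * all randomness comes from R's RNG, so set.seed() on the R side makes every
//    routine here fully reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static void simulate_tree(const std::vector<int>& sample_pop, int n_pops,
                          std::vector<double> size, std::vector<double> mig,
                          const NumericMatrix& events,
                          std::vector<int>& parent, std::vector<double>& ntime)
{
  const int n = (int) sample_pop.size();
  const int n_nodes = 2 * n - 1;
  parent.assign(n_nodes, -1);
  ntime.assign(n_nodes, 0.0);

  std::vector<int> lin_node(n), lin_pop(sample_pop);
  for (int i = 0; i < n; ++i) lin_node[i] = i;

  int next_node = n;
  double t = 0.0;
  int ev = 0;
  const int nE = events.nrow();

  std::vector<double> coal_rate(n_pops), mig_out(n_pops);
  std::vector<int> k(n_pops);

  while ((int) lin_node.size() > 1) {
    std::fill(k.begin(), k.end(), 0);
    for (size_t i = 0; i < lin_pop.size(); ++i) k[lin_pop[i]]++;

    double R = 0.0;
    for (int p = 0; p < n_pops; ++p) {
      double cr = 0.0;
      if (k[p] > 1 && size[p] > 0.0)
        cr = (k[p] * (k[p] - 1) / 2.0) / size[p];
      coal_rate[p] = cr;
      R += cr;
      double mo = 0.0;
      if (k[p] > 0)
        for (int q = 0; q < n_pops; ++q)
          if (q != p) mo += mig[p + q * n_pops];
      mig_out[p] = k[p] * mo;
      R += mig_out[p];
    }

    double t_ev = (ev < nE) ? events(ev, 0) : R_PosInf;
    double dt = (R > 0.0) ? exp_rand() / R : R_PosInf;

    if (!(t + dt < t_ev)) {            // demographic event fires first
      if (!R_finite(t_ev))
        stop("coalescent cannot complete: zero total rate and no events remain");
      t = t_ev;
      while (ev < nE && events(ev, 0) <= t_ev) {
        const int code = (int) events(ev, 1);
        const int ei = (int) events(ev, 2), ej = (int) events(ev, 3);
        const double x = events(ev, 4);
        if (code == 0) size[ei] = x;
        else if (code == 1) { for (auto& pp : lin_pop) if (pp == ei) pp = ej; }
        else if (code == 2) { for (auto& pp : lin_pop) if (pp == ei && unif_rand() < x) pp = ej; }
        else if (code == 3) mig[ei + ej * n_pops] = x;
        else if (code == 4) std::fill(mig.begin(), mig.end(), 0.0);
        else stop("unknown event code");
        ++ev;
      }
      continue;
    }

    t += dt;
    double u = unif_rand() * R;
    int chosen = -1; bool is_coal = true;
    for (int p = 0; p < n_pops; ++p) {
      if (u < coal_rate[p]) { chosen = p; is_coal = true; break; }
      u -= coal_rate[p];
      if (u < mig_out[p]) { chosen = p; is_coal = false; break; }
      u -= mig_out[p];
    }
    if (chosen < 0) continue;          // rare floating-point edge: redraw

    if (is_coal) {
      const int kp = k[chosen];
      int a = (int)(unif_rand() * kp); if (a >= kp) a = kp - 1;
      int b = (int)(unif_rand() * (kp - 1)); if (b >= kp - 1) b = kp - 2;
      if (b >= a) ++b;
      int ia = -1, ib = -1, cnt = 0;
      for (size_t i = 0; i < lin_pop.size(); ++i)
        if (lin_pop[i] == chosen) {
          if (cnt == a) ia = (int) i;
          if (cnt == b) ib = (int) i;
          ++cnt;
        }
      const int node = next_node++;
      parent[lin_node[ia]] = node;
      parent[lin_node[ib]] = node;
      ntime[node] = t;
      lin_node[ia] = node;             // merged lineage stays in `chosen`
      lin_node[ib] = lin_node.back();
      lin_pop[ib] = lin_pop.back();
      lin_node.pop_back();
      lin_pop.pop_back();
    } else {
      // migration: uniform lineage within `chosen`, destination by rate
      double mo = 0.0;
      for (int q = 0; q < n_pops; ++q)
        if (q != chosen) mo += mig[chosen + q * n_pops];
      double u2 = unif_rand() * mo;
      int dest = -1;
      for (int q = 0; q < n_pops; ++q) {
        if (q == chosen) continue;
        const double r = mig[chosen + q * n_pops];
        if (u2 < r) { dest = q; break; }
        u2 -= r;
      }
      if (dest < 0) continue;
      const int kp = k[chosen];
      int a = (int)(unif_rand() * kp); if (a >= kp) a = kp - 1;
      int cnt = 0;
      for (size_t i = 0; i < lin_pop.size(); ++i)
        if (lin_pop[i] == chosen) {
          if (cnt == a) { lin_pop[i] = dest; break; }
          ++cnt;
        }
    }
  }
}

// [[Rcpp::export]]
List sim_genealogy_cpp(IntegerVector sample_pop, int n_pops,
                       NumericVector sizes, NumericMatrix mig,
                       NumericMatrix events)
{
  std::vector<int> sp(sample_pop.begin(), sample_pop.end());
  std::vector<double> sz(sizes.begin(), sizes.end());
  std::vector<double> mg(mig.begin(), mig.end());
  std::vector<int> parent;
  std::vector<double> ntime;
  simulate_tree(sp, n_pops, sz, mg, events, parent, ntime);
  return List::create(_["parent"] = wrap(parent), _["time"] = wrap(ntime));
}

// Expected joint SFS from branch lengths: for each genealogy, the length of a
// branch is credited to the cell indexed by the per-axis counts of tips it
// subtends.  `sample_axis` maps each tip to axis 0..2, or -1 to be ignored
// (e.g. an outgroup).  Returns the accumulated (unnormalised) length array of
// dim (n1+1, n2+1, n3+1) in R's column-major order.
// [[Rcpp::export]]
NumericVector branch_spectrum_cpp(IntegerVector sample_pop, int n_pops,
                                  NumericVector sizes, NumericMatrix mig,
                                  NumericMatrix events,
                                  IntegerVector sample_axis,
                                  IntegerVector axis_n, int n_reps)
{
  const int n = sample_pop.size();
  const int n_nodes = 2 * n - 1;
  const int d1 = axis_n[0] + 1, d2 = axis_n[1] + 1, d3 = axis_n[2] + 1;
  NumericVector out(d1 * d2 * d3);
  std::vector<int> sp(sample_pop.begin(), sample_pop.end());
  std::vector<double> sz(sizes.begin(), sizes.end());
  std::vector<double> mg(mig.begin(), mig.end());
  std::vector<int> parent;
  std::vector<double> ntime;
  std::vector<int> c1(n_nodes), c2(n_nodes), c3(n_nodes);

  for (int rep = 0; rep < n_reps; ++rep) {
    simulate_tree(sp, n_pops, sz, mg, events, parent, ntime);
    std::fill(c1.begin(), c1.end(), 0);
    std::fill(c2.begin(), c2.end(), 0);
    std::fill(c3.begin(), c3.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int ax = sample_axis[i];
      if (ax == 0) c1[i] = 1; else if (ax == 1) c2[i] = 1; else if (ax == 2) c3[i] = 1;
    }
    // children always have smaller ids than parents
    for (int i = 0; i < n_nodes - 1; ++i) {
      const int pa = parent[i];
      c1[pa] += c1[i]; c2[pa] += c2[i]; c3[pa] += c3[i];
      const int tot = c1[i] + c2[i] + c3[i];
      if (tot == 0) continue;
      const double len = ntime[pa] - ntime[i];
      out[c1[i] + d1 * (c2[i] + d2 * c3[i])] += len;
    }
  }
  return out;
}

// One locus under the infinite-sites model: simulate a genealogy, drop
// Poisson(mu * L * total length) mutations on branches proportional to length,
// and return the 0/1 genotype matrix (sites x samples) plus 0-based positions.
// [[Rcpp::export]]
List sim_locus_cpp(IntegerVector sample_pop, int n_pops,
                   NumericVector sizes, NumericMatrix mig,
                   NumericMatrix events, double mu, int locus_len)
{
  const int n = sample_pop.size();
  if (n > 64) stop("genotype simulation supports at most 64 samples per locus");
  const int n_nodes = 2 * n - 1;
  std::vector<int> sp(sample_pop.begin(), sample_pop.end());
  std::vector<double> sz(sizes.begin(), sizes.end());
  std::vector<double> mg(mig.begin(), mig.end());
  std::vector<int> parent;
  std::vector<double> ntime;
  simulate_tree(sp, n_pops, sz, mg, events, parent, ntime);

  std::vector<uint64_t> below(n_nodes, 0);
  for (int i = 0; i < n; ++i) below[i] = ((uint64_t)1) << i;
  std::vector<double> cumlen(n_nodes - 1);
  double tot = 0.0;
  for (int i = 0; i < n_nodes - 1; ++i) {
    below[parent[i]] |= below[i];
    tot += ntime[parent[i]] - ntime[i];
    cumlen[i] = tot;
  }

  int S = (int) R::rpois(mu * (double) locus_len * tot);
  if (S > locus_len)
    stop("more mutations than sites; increase locus_len or lower the mutation scale");

  // distinct positions (S << L in practice)
  std::set<int> posset;
  while ((int) posset.size() < S) {
    int p = (int)(unif_rand() * locus_len);
    if (p >= locus_len) p = locus_len - 1;
    posset.insert(p);
  }
  IntegerVector positions(posset.begin(), posset.end());

  IntegerMatrix geno(S, n);
  for (int s = 0; s < S; ++s) {
    const double u = unif_rand() * tot;
    int lo = 0, hi = n_nodes - 2;
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      if (cumlen[mid] < u) lo = mid + 1; else hi = mid;
    }
    const uint64_t mask = below[lo];
    for (int i = 0; i < n; ++i)
      geno(s, i) = (mask >> i) & 1;
  }
  return List::create(_["genotypes"] = geno,
                      _["positions"] = positions,
                      _["tree_length"] = tot,
                      _["tmrca"] = ntime[n_nodes - 1]);
}

// Pairwise raw distances (and coalescence times) for one locus without
// materialising sites: mutation counts are Poisson per branch and summed along
// root paths, d(a,b) = (c[a] + c[b] - 2 c[mrca]) / L.
// [[Rcpp::export]]
List sim_distances_cpp(IntegerVector sample_pop, int n_pops,
                       NumericVector sizes, NumericMatrix mig,
                       NumericMatrix events, double mu, double locus_len)
{
  const int n = sample_pop.size();
  const int n_nodes = 2 * n - 1;
  std::vector<int> sp(sample_pop.begin(), sample_pop.end());
  std::vector<double> sz(sizes.begin(), sizes.end());
  std::vector<double> mg(mig.begin(), mig.end());
  std::vector<int> parent;
  std::vector<double> ntime;
  simulate_tree(sp, n_pops, sz, mg, events, parent, ntime);

  std::vector<double> croot(n_nodes, 0.0);   // mutations on the path node -> root
  for (int i = n_nodes - 2; i >= 0; --i) {
    const double len = ntime[parent[i]] - ntime[i];
    croot[i] = croot[parent[i]] + R::rpois(mu * locus_len * len);
  }

  NumericMatrix D(n, n), T(n, n);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      int pa = a, pb = b;
      while (pa != pb) { if (pa < pb) pa = parent[pa]; else pb = parent[pb]; }
      const double d = (croot[a] + croot[b] - 2.0 * croot[pa]) / locus_len;
      D(a, b) = D(b, a) = d;
      T(a, b) = T(b, a) = ntime[pa];
    }
  return List::create(_["d"] = D, _["t"] = T);
}
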