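#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of one piecewise-
// constant-rate segment of a mass-action reaction network.
//
// Every channel has propensity rate[j] * x[r1] * x[r2] where r1, r2 are
// 0-based species indices (-1 = absent factor), so at most bimolecular with
// distinct reactant species; promoter configurations are encoded as species
// counts, which makes this exact for the networks built in R.
//
// Optional stopping rule on a linear functional w.x: the walk stops as soon
// as w.x <= stopLow (exit 1) or w.x >= stopHigh (exit 2).  NA disables a
// bound.  Exit 0 = reached tEnd, 3 = absorbing state (all propensities 0),
// 4 = event budget exhausted.
//
// States are recorded on the caller-supplied sample grid (state held since
// the previous jump, i.e. the exact cadlag value at each grid time).
// Uses R's RNG so set.seed() in R makes runs bit-reproducible.

// [[Rcpp::export]]
List ssa_segment_cpp(IntegerVector x0,
                     IntegerMatrix stoich,     // nch x nsp
                     IntegerMatrix reactants,  // nch x 2, 0-based, -1 = none
                     NumericVector rates,      // per channel, constant in segment
                     double t0,
                     double tEnd,
                     NumericVector sampleTimes, // increasing, in (t0, tEnd]
                     NumericVector stopW,       // length nsp, or length 0 = no rule
                     double stopLow,
                     double stopHigh,
                     double maxEvents) {
  const int nch = stoich.nrow();
  const int nsp = stoich.ncol();
  const int nsamp = sampleTimes.size();
  const bool hasStop = stopW.size() == nsp;
  const bool hasLow = hasStop && !NumericVector::is_na(stopLow);
  const bool hasHigh = hasStop && !NumericVector::is_na(stopHigh);

  std::vector<double> x(nsp);
  for (int i = 0; i < nsp; ++i) x[i] = x0[i];

  // flatten channel data for the hot loop: sparse stoichiometry and
  // reactant indices
  std::vector<int> r1(nch), r2(nch);
  std::vector<double> k(nch);
  std::vector<int> sIdx;   // concatenated nonzero-species indices
  std::vector<double> sVal;
  std::vector<int> sOff(nch + 1, 0);
  for (int j = 0; j < nch; ++j) {
    r1[j] = reactants(j, 0);
    r2[j] = reactants(j, 1);
    k[j] = rates[j];
    for (int i = 0; i < nsp; ++i)
      if (stoich(j, i) != 0) { sIdx.push_back(i); sVal.push_back(stoich(j, i)); }
    sOff[j + 1] = (int) sIdx.size();
  }

  // per-channel increment of w.x, to track the stop functional incrementally
  std::vector<double> dW(nch, 0.0);
  double wx = 0.0;
  if (hasStop) {
    for (int i = 0; i < nsp; ++i) wx += stopW[i] * x[i];
    for (int j = 0; j < nch; ++j) {
      double s = 0.0;
      for (int i = 0; i < nsp; ++i) s += stopW[i] * stoich(j, i);
      dW[j] = s;
    }
  }

  NumericMatrix samples(nsamp, nsp);
  int nsFilled = 0;
  double t = t0;
  double nEvents = 0.0;
  int exitCode = 0;

  std::vector<double> a(nch);

  RNGScope scope;

  // the initial state may already satisfy the stopping rule
  if (hasLow && wx <= stopLow) exitCode = 1;
  if (exitCode == 0 && hasHigh && wx >= stopHigh) exitCode = 2;

  while (exitCode == 0) {
    double A = 0.0;
    for (int j = 0; j < nch; ++j) {
      double aj = k[j];
      if (r1[j] >= 0) aj *= x[r1[j]];
      if (r2[j] >= 0) aj *= x[r2[j]];
      a[j] = aj;
      A += aj;
    }
    if (A <= 0.0) { // absorbing: state constant until tEnd
      while (nsFilled < nsamp) {
        for (int i = 0; i < nsp; ++i) samples(nsFilled, i) = x[i];
        ++nsFilled;
      }
      t = tEnd;
      exitCode = 3;
      break;
    }
    double tNew = t + R::exp_rand() / A;
    // record grid states strictly before the jump takes effect
    while (nsFilled < nsamp && sampleTimes[nsFilled] < tNew) {
      for (int i = 0; i < nsp; ++i) samples(nsFilled, i) = x[i];
      ++nsFilled;
    }
    if (tNew > tEnd) { t = tEnd; break; }
    t = tNew;
    double u = unif_rand() * A;
    int j = 0;
    double cum = a[0];
    while (cum < u && j < nch - 1) { ++j; cum += a[j]; }
    for (int s = sOff[j]; s < sOff[j + 1]; ++s) x[sIdx[s]] += sVal[s];
    nEvents += 1.0;
    if (hasStop) {
      wx += dW[j];
      if (hasLow && wx <= stopLow) { exitCode = 1; break; }
      if (hasHigh && wx >= stopHigh) { exitCode = 2; break; }
    }
    if (nEvents >= maxEvents) { exitCode = 4; break; }
  }

  // grid points at/after the stop time stay unfilled; caller truncates
  if (exitCode == 0) { // reached tEnd: fill any grid point at exactly tEnd
    while (nsFilled < nsamp && sampleTimes[nsFilled] <= tEnd) {
      for (int i = 0; i < nsp; ++i) samples(nsFilled, i) = x[i];
      ++nsFilled;
    }
  }

  IntegerVector xf(nsp);
  for (int i = 0; i < nsp; ++i) xf[i] = (int) x[i];
  return List::create(_["state"] = xf,
                      _["t"] = t,
                      _["nEvents"] = nEvents,
                      _["exit"] = exitCode,
                      _["samples"] = samples,
                      _["nSamples"] = nsFilled);
}

// Flood-fill labelling of the TRUE voxels of a 3D mask, 26-connectivity.
// Returns an integer array of labels (0 = background).
// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int cur = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int z = v / (nx * ny), r = v % (nx * ny);
      int y = r / nx, xx = r % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int X = xx + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
            int w = X + nx * (Y + ny * Z);
            if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
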