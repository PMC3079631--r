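// Kedem-Katchalsky two-compartment oocyte model: state (V, Ns), adaptive
// Dormand-Prince 5(4) integration with output clipped to requested sample
// times. Canonical units: cm, cm3, min, mol, atm; concentrations mol/cm3.
#include <Rcpp.h>
using namespace Rcpp;

struct KKPars {
  double Lp;      // cm/(min atm)
  double Ps;      // cm/min
  double sigma;   // dimensionless, [0, 1]
  double S;       // membrane area, cm2
  double Vb;      // osmotically inactive volume, cm3
  double Nimp;    // internal impermeant osmoles, osmol (conserved)
  double vs;      // partial molar volume of the permeant, cm3/mol
  double RT;      // cm3 atm / mol
  double osm_out; // external impermeant osmolarity, osmol/cm3
  double Cs_out;  // external permeant concentration, mol/cm3
  bool   drag;    // include (1 - sigma) * Cbar * Jv solvent-drag term
};

// returns false when the free-water volume is exhausted (model breakdown)
static bool kk_rhs(double V, double Ns, const KKPars& p,
                   double& dV, double& dNs) {
  if (Ns < 0.0) Ns = 0.0;
  double Vfree = V - p.Vb - Ns * p.vs;
  if (Vfree <= 0.0) return false;
  double Cs_in   = Ns / Vfree;
  double Cimp_in = p.Nimp / Vfree;
  double Jv = p.Lp * (p.RT * (Cimp_in - p.osm_out) +
                      p.sigma * p.RT * (Cs_in - p.Cs_out));
  dV  = Jv * p.S;
  dNs = p.Ps * p.S * (p.Cs_out - Cs_in);
  if (p.drag) dNs += (1.0 - p.sigma) * 0.5 * (Cs_in + p.Cs_out) * Jv * p.S;
  return true;
}

static KKPars as_pars(const List& pars) {
  KKPars p;
  p.Lp      = as<double>(pars["Lp"]);
  p.Ps      = as<double>(pars["Ps"]);
  p.sigma   = as<double>(pars["sigma"]);
  p.S       = as<double>(pars["S"]);
  p.Vb      = as<double>(pars["Vb"]);
  p.Nimp    = as<double>(pars["Nimp"]);
  p.vs      = as<double>(pars["vs"]);
  p.RT      = as<double>(pars["RT"]);
  p.osm_out = as<double>(pars["osm_out"]);
  p.Cs_out  = as<double>(pars["Cs_out"]);
  p.drag    = as<bool>(pars["drag"]);
  return p;
}

// [[Rcpp::export]]
NumericVector kk_rhs_cpp(double V, double Ns, List pars) {
  KKPars p = as_pars(pars);
  double dV, dNs;
  if (!kk_rhs(V, Ns, p, dV, dNs))
    stop("free water volume exhausted: V - Vb - Ns*vs <= 0");
  return NumericVector::create(_["dV"] = dV, _["dNs"] = dNs);
}

// Dormand-Prince RK5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                    c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Integrate from times[0] landing exactly on every requested time.
// Returns a (length(times) x 2) matrix of (V, Ns).
// [[Rcpp::export]]
NumericMatrix kk_integrate_cpp(NumericVector times, double V0, double Ns0,
                               List pars, double rtol = 1e-8,
                               double atol = 1e-12) {
  KKPars p = as_pars(pars);
  int n = times.size();
  NumericMatrix out(n, 2);
  double t = times[0], V = V0, Ns = Ns0;
  out(0, 0) = V; out(0, 1) = Ns;

  double k1V, k1N;
  if (!kk_rhs(V, Ns, p, k1V, k1N))
    stop("free water volume exhausted at t = %f", t);
  double h = 1e-4;  // min; adapted immediately
  bool have_k1 = true;
  long nsteps = 0;
  const long max_steps = 5000000;

  for (int i = 1; i < n; ++i) {
    double t_end = times[i];
    while (t < t_end) {
      if (++nsteps > max_steps) stop("kk_integrate: step limit exceeded");
      if (h > t_end - t) h = t_end - t;
      if (!have_k1) {
        if (!kk_rhs(V, Ns, p, k1V, k1N))
          stop("free water volume exhausted at t = %f", t);
        have_k1 = true;
      }
      double k2V, k2N, k3V, k3N, k4V, k4N, k5V, k5N, k6V, k6N, k7V, k7N;
      bool ok =
        kk_rhs(V + h * a21 * k1V, Ns + h * a21 * k1N, p, k2V, k2N) &&
        kk_rhs(V + h * (a31 * k1V + a32 * k2V),
               Ns + h * (a31 * k1N + a32 * k2N), p, k3V, k3N) &&
        kk_rhs(V + h * (a41 * k1V + a42 * k2V + a43 * k3V),
               Ns + h * (a41 * k1N + a42 * k2N + a43 * k3N), p, k4V, k4N) &&
        kk_rhs(V + h * (a51 * k1V + a52 * k2V + a53 * k3V + a54 * k4V),
               Ns + h * (a51 * k1N + a52 * k2N + a53 * k3N + a54 * k4N),
               p, k5V, k5N) &&
        kk_rhs(V + h * (a61 * k1V + a62 * k2V + a63 * k3V + a64 * k4V +
                        a65 * k5V),
               Ns + h * (a61 * k1N + a62 * k2N + a63 * k3N + a64 * k4N +
                         a65 * k5N), p, k6V, k6N);
      double Vn = 0, Nn = 0;
      if (ok) {
        Vn = V + h * (b1 * k1V + b3 * k3V + b4 * k4V + b5 * k5V + b6 * k6V);
        Nn = Ns + h * (b1 * k1N + b3 * k3N + b4 * k4N + b5 * k5N + b6 * k6N);
        ok = kk_rhs(Vn, Nn, p, k7V, k7N);
      }
      if (!ok) {  // stage left the feasible region: shrink and retry
        h *= 0.5;
        if (h < 1e-14) stop("free water volume exhausted near t = %f", t);
        continue;
      }
      double errV = h * (e1 * k1V + e3 * k3V + e4 * k4V + e5 * k5V +
                         e6 * k6V + e7 * k7V);
      double errN = h * (e1 * k1N + e3 * k3N + e4 * k4N + e5 * k5N +
                         e6 * k6N + e7 * k7N);
      double sV = atol + rtol * std::max(std::fabs(V), std::fabs(Vn));
      double sN = atol + rtol * std::max(std::fabs(Ns), std::fabs(Nn));
      double err = std::sqrt(0.5 * ((errV / sV) * (errV / sV) +
                                    (errN / sN) * (errN / sN)));
      if (err <= 1.0) {  // accept (FSAL: k7 becomes next k1)
        t += h; V = Vn; Ns = Nn;
        k1V = k7V; k1N = k7N;
      } else {
        have_k1 = true;  // k1 still valid at unchanged (t, V, Ns)
      }
      double fac = 0.9 * std::pow(err > 1e-10 ? err : 1e-10, -0.2);
      fac = std::min(5.0, std::max(0.2, fac));
      h *= fac;
      if (h < 1e-14) stop("kk_integrate: step size underflow at t = %f", t);
    }
    out(i, 0) = V; out(i, 1) = Ns;
  }
  return out;
}
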