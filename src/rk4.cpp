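// Fixed-step RK4 integration of conductance-based point-neuron models.
// Mirrors the R-level membrane_rhs()/rate-form registry exactly; the R side
// cross-checks a single step against this code in the test suite.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// rate-form codes shared with R/rate_functions.R
enum RateForm {
  LINOID = 1, EXPO = 2, LOGISTIC = 3, CONSTANT = 4,
  BIEXP_INV = 5, SIGTAU = 6, PRODSIGTAU = 7
};

struct RateFun {
  int form;
  double p[8];
  double eval(double V) const {
    switch (form) {
      case LINOID: {
        double x = V - p[1];
        if (std::fabs(x) < 1e-7) return p[0] * (p[2] + x / 2.0);
        return p[0] * x / (1.0 - std::exp(-x / p[2]));
      }
      case EXPO: return p[0] * std::exp((V - p[1]) / p[2]);
      case LOGISTIC: return p[0] / (1.0 + std::exp(-(V - p[1]) / p[2]));
      case CONSTANT: return p[0];
      case BIEXP_INV:
        return p[0] / (p[1] * std::exp((V - p[2]) / p[3]) +
                       p[4] * std::exp(-(V - p[2]) / p[5]));
      case SIGTAU: return p[0] + p[1] / (1.0 + std::exp((V - p[2]) / p[3]));
      case PRODSIGTAU:
        return (p[0] + p[1] / (1.0 + std::exp((V - p[2]) / p[3]))) *
               (p[4] + p[5] / (1.0 + std::exp(-(V - p[6]) / p[7])));
      default: stop("unknown rate form code");
    }
    return NA_REAL;
  }
};

struct Gate {
  bool rate_based;
  bool instantaneous;
  double phi;
  RateFun f1, f2;  // alpha/beta or inf/tau

  double inf(double V) const {
    if (!rate_based) return f1.eval(V);
    double a = f1.eval(V), b = f2.eval(V);
    return a / (a + b);
  }
  double deriv(double V, double x) const {
    if (instantaneous) return 0.0;
    if (rate_based) {
      double a = f1.eval(V), b = f2.eval(V);
      return phi * (a * (1.0 - x) - b * x);
    }
    return phi * (f1.eval(V) - x) / f2.eval(V);
  }
};

struct Channel {
  double g_max, E;
  std::vector<int> gate_idx;  // indices into the gate state vector
  std::vector<int> expo;
};

struct Model {
  double C_m, g_leak, E_leak;
  std::vector<Gate> gates;
  std::vector<Channel> channels;
  std::vector<std::string> gate_names;
};

static RateFun parse_rate(const List& rf) {
  RateFun f;
  f.form = as<int>(rf["form"]);
  NumericVector pars = rf["params"];
  for (int i = 0; i < pars.size() && i < 8; ++i) f.p[i] = pars[i];
  return f;
}

// compiled model layout produced by R's compile_model(): see R/integrator.R
static Model parse_model(const List& cm) {
  Model m;
  m.C_m = as<double>(cm["C_m"]);
  m.g_leak = as<double>(cm["g_leak"]);
  m.E_leak = as<double>(cm["E_leak"]);
  List gates = cm["gates"];
  for (int i = 0; i < gates.size(); ++i) {
    List g = gates[i];
    Gate gg;
    gg.rate_based = as<bool>(g["rate_based"]);
    gg.instantaneous = as<bool>(g["instantaneous"]);
    gg.phi = as<double>(g["phi"]);
    gg.f1 = parse_rate(g["f1"]);
    gg.f2 = parse_rate(g["f2"]);
    m.gates.push_back(gg);
    m.gate_names.push_back(as<std::string>(g["name"]));
  }
  List channels = cm["channels"];
  for (int i = 0; i < channels.size(); ++i) {
    List ch = channels[i];
    Channel cc;
    cc.g_max = as<double>(ch["g_max"]);
    cc.E = as<double>(ch["E"]);
    IntegerVector gi = ch["gate_idx"], ex = ch["exponent"];
    for (int j = 0; j < gi.size(); ++j) {
      cc.gate_idx.push_back(gi[j] - 1);  // R 1-based -> C 0-based
      cc.expo.push_back(ex[j]);
    }
    m.channels.push_back(cc);
  }
  return m;
}

static inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

// dy/dt for state y = (V, gates...); instantaneous gates read x_inf(V)
static void rhs(const Model& m, const std::vector<double>& y, double I,
                std::vector<double>& dy) {
  double V = y[0];
  size_t ng = m.gates.size();
  double I_ion = 0.0;
  for (size_t c = 0; c < m.channels.size(); ++c) {
    const Channel& ch = m.channels[c];
    double open = 1.0;
    for (size_t j = 0; j < ch.gate_idx.size(); ++j) {
      int gi = ch.gate_idx[j];
      double x = m.gates[gi].instantaneous ? m.gates[gi].inf(V) : y[gi + 1];
      open *= ipow(x, ch.expo[j]);
    }
    I_ion += ch.g_max * open * (V - ch.E);
  }
  dy[0] = (-m.g_leak * (V - m.E_leak) + I - I_ion) / m.C_m;
  for (size_t g = 0; g < ng; ++g) dy[g + 1] = m.gates[g].deriv(V, y[g + 1]);
}

// [[Rcpp::export(name = ".rk4_integrate")]]
List rk4_integrate(List compiled_model, NumericVector y0,
                   NumericVector I_start, NumericVector I_mid,
                   NumericVector I_end, double dt,
                   bool record_gates, double clamp_tol) {
  Model m = parse_model(compiled_model);
  size_t ng = m.gates.size();
  size_t nv = ng + 1;
  if ((size_t)y0.size() != nv) stop("state length mismatch");
  int n_steps = I_start.size();
  if (I_mid.size() != n_steps || I_end.size() != n_steps)
    stop("stimulus stage vectors must have equal length");

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(nv), k2(nv), k3(nv), k4(nv), tmp(nv);

  NumericVector V_out(n_steps + 1);
  NumericMatrix G_out = record_gates ? NumericMatrix(n_steps + 1, ng)
                                     : NumericMatrix(0, 0);
  V_out[0] = y[0];
  if (record_gates)
    for (size_t g = 0; g < ng; ++g) G_out(0, g) = y[g + 1];

  for (int s = 0; s < n_steps; ++s) {
    rhs(m, y, I_start[s], k1);
    for (size_t i = 0; i < nv; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    rhs(m, tmp, I_mid[s], k2);
    for (size_t i = 0; i < nv; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    rhs(m, tmp, I_mid[s], k3);
    for (size_t i = 0; i < nv; ++i) tmp[i] = y[i] + dt * k3[i];
    rhs(m, tmp, I_end[s], k4);
    for (size_t i = 0; i < nv; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // pin instantaneous gates to steady state at the new voltage
    for (size_t g = 0; g < ng; ++g)
      if (m.gates[g].instantaneous) y[g + 1] = m.gates[g].inf(y[0]);

    if (!std::isfinite(y[0]))
      stop("integration blow-up at t = %g ms", (s + 1) * dt);

    // floating-point guard: clamp tiny overshoots, error on real violations
    for (size_t g = 0; g < ng; ++g) {
      double x = y[g + 1];
      if (x < 0.0) {
        if (x < -clamp_tol)
          stop("gate '%s' left [0,1] (value %g) at t = %g ms",
               m.gate_names[g].c_str(), x, (s + 1) * dt);
        y[g + 1] = 0.0;
      } else if (x > 1.0) {
        if (x > 1.0 + clamp_tol)
          stop("gate '%s' left [0,1] (value %g) at t = %g ms",
               m.gate_names[g].c_str(), x, (s + 1) * dt);
        y[g + 1] = 1.0;
      }
    }

    V_out[s + 1] = y[0];
    if (record_gates)
      for (size_t g = 0; g < ng; ++g) G_out(s + 1, g) = y[g + 1];
  }

  NumericVector y_final(y.begin(), y.end());
  return List::create(_["V"] = V_out, _["gates"] = G_out,
                      _["final_state"] = y_final);
}
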