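// Discrete-time stepper for semantic-pointer networks.
//
// Rate-mode buffers are evaluated through per-ensemble static response tables
// (decoded output as a function of input, exact at the table nodes);
// associative memories through per-detector activation tables plus optional
// winner-take-all inhibition settled via a fast synapse. Connections are
// first-order low-pass filters carrying linear transforms or circular
// convolution (binding / unbinding) of the decoded source states.
//
// All model matrices are copied once into flat row-major arrays so the inner
// loop touches plain doubles.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Flat {
  std::vector<double> v;
  int nrow, ncol;
  void from(const NumericMatrix& m) {        // row-major copy
    nrow = m.nrow(); ncol = m.ncol();
    v.resize((size_t)nrow * ncol);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < ncol; ++j) v[(size_t)i * ncol + j] = m(i, j);
  }
  inline const double* row(int i) const { return v.data() + (size_t)i * ncol; }
};

inline double interp(const double* row, double g0, double inv_dg, int G, double x) {
  double pos = (x - g0) * inv_dg;
  if (pos <= 0.0) return row[0];
  if (pos >= G - 1) return row[G - 1];
  int i = (int)pos;
  double f = pos - i;
  return row[i] + (row[i + 1] - row[i]) * f;
}

void circ_conv(const std::vector<double>& a, const std::vector<double>& b,
               std::vector<double>& out, bool invert_b) {
  int D = (int)a.size();
  std::fill(out.begin(), out.end(), 0.0);
  for (int i = 0; i < D; ++i) {
    double ai = a[i];
    if (ai == 0.0) continue;
    if (!invert_b) {
      for (int j = 0; j < D; ++j) {
        int k = i + j; if (k >= D) k -= D;
        out[k] += ai * b[j];
      }
    } else {
      for (int j = 0; j < D; ++j) {
        int jj = (j == 0) ? 0 : D - j;
        int k = i + j; if (k >= D) k -= D;
        out[k] += ai * b[jj];
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
List engine_run_cpp(List comps, List conns,
                    IntegerVector ext_comp, IntegerVector ext_on,
                    IntegerVector ext_off, NumericMatrix ext_vec,
                    NumericMatrix gates,
                    int n_steps, double dt,
                    IntegerVector probes, int record_every) {
  int n_comp = comps.size();
  int n_conn = conns.size();
  int n_ext = ext_comp.size();

  std::vector<int> kind(n_comp), dimin(n_comp), dimout(n_comp), G(n_comp), M(n_comp), ogate(n_comp);
  std::vector<double> g0(n_comp), inv_dg(n_comp), wta(n_comp), a_inh(n_comp);
  std::vector<Flat> tab(n_comp), Ein(n_comp), Eout(n_comp);
  for (int c = 0; c < n_comp; ++c) {
    List cc = comps[c];
    kind[c] = as<int>(cc["kind"]);
    dimin[c] = as<int>(cc["dim_in"]);
    dimout[c] = as<int>(cc["dim_out"]);
    ogate[c] = as<int>(cc["ogate"]);
    NumericVector gr = cc["grid"];
    g0[c] = gr[0];
    inv_dg[c] = 1.0 / (gr[1] - gr[0]);
    tab[c].from(as<NumericMatrix>(cc["table"]));
    G[c] = tab[c].ncol;
    if (kind[c] == 1) {
      Ein[c].from(as<NumericMatrix>(cc["Ein"]));
      Eout[c].from(as<NumericMatrix>(cc["Eout"]));
      M[c] = Ein[c].nrow;
      wta[c] = as<double>(cc["wta"]);
      double tau_inh = as<double>(cc["tau_inh"]);
      a_inh[c] = 1.0 - std::exp(-dt / tau_inh);
    } else {
      M[c] = 0; wta[c] = 0.0; a_inh[c] = 0.0;
    }
  }

  std::vector<int> csrc(n_conn), cdst(n_conn), ctype(n_conn), csrc2(n_conn), cgate(n_conn);
  std::vector<double> cgain(n_conn), calpha(n_conn);
  std::vector<Flat> ctrans(n_conn);
  for (int k = 0; k < n_conn; ++k) {
    List ck = conns[k];
    csrc[k] = as<int>(ck["src"]);
    cdst[k] = as<int>(ck["dst"]);
    ctype[k] = as<int>(ck["type"]);
    csrc2[k] = as<int>(ck["src2"]);
    cgate[k] = as<int>(ck["gate"]);
    cgain[k] = as<double>(ck["gain"]);
    double tau = as<double>(ck["tau"]);
    calpha[k] = 1.0 - std::exp(-dt / tau);
    if (ctype[k] == 1) ctrans[k].from(as<NumericMatrix>(ck["transform"]));
  }

  Flat gatesF; gatesF.from(gates);
  Flat extF; extF.from(ext_vec);

  std::vector<std::vector<double> > y(n_comp), u(n_comp), af(n_comp), sdet(n_comp);
  for (int c = 0; c < n_comp; ++c) {
    y[c].assign(dimout[c], 0.0);
    u[c].assign(dimin[c], 0.0);
    if (kind[c] == 1) { af[c].assign(M[c], 0.0); sdet[c].assign(M[c], 0.0); }
  }
  std::vector<std::vector<double> > s(n_conn);
  for (int k = 0; k < n_conn; ++k) s[k].assign(dimin[cdst[k]], 0.0);
  std::vector<double> scratch;

  int n_rec = (n_steps + record_every - 1) / record_every;
  int n_probe = probes.size();
  std::vector<NumericMatrix> rec(n_probe);
  for (int p = 0; p < n_probe; ++p) rec[p] = NumericMatrix(n_rec, dimout[probes[p]]);
  int rec_row = 0;

  for (int t = 0; t < n_steps; ++t) {
    // 1. accumulate inputs
    for (int c = 0; c < n_comp; ++c) std::fill(u[c].begin(), u[c].end(), 0.0);
    for (int e = 0; e < n_ext; ++e) {
      if (t >= ext_on[e] && t < ext_off[e]) {
        int c = ext_comp[e];
        const double* ev = extF.row(e);
        for (int j = 0; j < dimin[c]; ++j) u[c][j] += ev[j];
      }
    }
    for (int k = 0; k < n_conn; ++k) {
      double* uk = u[cdst[k]].data();
      const double* sk = s[k].data();
      int dd = (int)s[k].size();
      for (int j = 0; j < dd; ++j) uk[j] += sk[j];
    }

    // 2. component outputs
    for (int c = 0; c < n_comp; ++c) {
      if (kind[c] == 0) {
        const double gg0 = g0[c], idg = inv_dg[c];
        const int Gc = G[c];
        const int din = dimin[c];
        const double* tabd = tab[c].v.data();
        const double* uc = u[c].data();
        double* yc = y[c].data();
        for (int j = 0; j < din; ++j) {
          yc[j] = interp(tabd + (size_t)j * Gc, gg0, idg, Gc, uc[j]);
        }
      } else {
        const int m = M[c];
        const int din = dimin[c], dout = dimout[c];
        const double wtac = wta[c], ainh = a_inh[c];
        const double gg0 = g0[c], idg = inv_dg[c];
        const int Gc = G[c];
        double* afc = af[c].data();
        double* sd = sdet[c].data();
        const double* uc = u[c].data();
        const double* eind = Ein[c].v.data();
        const double* tabd = tab[c].v.data();
        double af_sum = 0.0;
        for (int i = 0; i < m; ++i) af_sum += afc[i];
        for (int i = 0; i < m; ++i) {
          const double* ei = eind + (size_t)i * din;
          double si = 0.0;
          for (int j = 0; j < din; ++j) si += ei[j] * uc[j];
          if (wtac > 0.0) si -= wtac * (af_sum - afc[i]);
          sd[i] = interp(tabd + (size_t)i * Gc, gg0, idg, Gc, si);
        }
        for (int i = 0; i < m; ++i) afc[i] += ainh * (sd[i] - afc[i]);
        std::fill(y[c].begin(), y[c].end(), 0.0);
        double* yc = y[c].data();
        const double* eoutd = Eout[c].v.data();
        for (int i = 0; i < m; ++i) {
          double a = sd[i];
          if (a == 0.0) continue;
          const double* eo = eoutd + (size_t)i * dout;
          for (int j = 0; j < dout; ++j) yc[j] += eo[j] * a;
        }
      }
      if (ogate[c] >= 0) {
        double gv = gatesF.v[(size_t)ogate[c] * gatesF.ncol + t];
        if (gv != 1.0) for (int j = 0; j < dimout[c]; ++j) y[c][j] *= gv;
      }
    }

    // 3. connection filters
    for (int k = 0; k < n_conn; ++k) {
      double gv = (cgate[k] >= 0) ? gatesF.v[(size_t)cgate[k] * gatesF.ncol + t] : 1.0;
      std::vector<double>& sk = s[k];
      const std::vector<double>& ys = y[csrc[k]];
      int dd = (int)sk.size();
      double a = calpha[k];
      if (ctype[k] == 0) {
        double gg = gv * cgain[k];
        for (int j = 0; j < dd; ++j) sk[j] += a * (gg * ys[j] - sk[j]);
      } else if (ctype[k] == 1) {
        double gg = gv * cgain[k];
        const Flat& T = ctrans[k];
        for (int j = 0; j < dd; ++j) {
          const double* tr = T.row(j);
          double acc = 0.0;
          for (size_t i = 0; i < ys.size(); ++i) acc += tr[i] * ys[i];
          sk[j] += a * (gg * acc - sk[j]);
        }
      } else {
        const std::vector<double>& y2 = y[csrc2[k]];
        scratch.resize(dd);
        circ_conv(ys, y2, scratch, ctype[k] == 3);
        double gg = gv * cgain[k];
        for (int j = 0; j < dd; ++j) sk[j] += a * (gg * scratch[j] - sk[j]);
      }
    }

    // 4. record
    if (t % record_every == 0) {
      for (int p = 0; p < n_probe; ++p) {
        int c = probes[p];
        for (int j = 0; j < dimout[c]; ++j) rec[p](rec_row, j) = y[c][j];
      }
      ++rec_row;
    }
  }

  List out(n_probe);
  for (int p = 0; p < n_probe; ++p) out[p] = rec[p];
  return out;
}

// Single-buffer simulator used to compare rate and spiking modes.
// J: per-neuron constant input current; dec: per-neuron decode weight
// (already masked); ens_id: 1-based ensemble index per neuron.
// [[Rcpp::export]]
NumericMatrix buffer_sim_cpp(NumericVector J, NumericVector dec,
                             IntegerVector ens_id, int D, int n_steps,
                             double dt, double tau_rc, double tau_ref,
                             double tau_syn, bool spiking,
                             NumericVector v0, NumericVector alive) {
  int N = J.size();
  NumericMatrix out(n_steps, D);
  double alpha = 1.0 - std::exp(-dt / tau_syn);
  std::vector<double> yf(D, 0.0), ydec(D, 0.0);

  if (!spiking) {
    for (int i = 0; i < N; ++i) {
      double r = (J[i] > 1.0) ? 1.0 / (tau_ref + tau_rc * std::log1p(1.0 / (J[i] - 1.0))) : 0.0;
      ydec[ens_id[i] - 1] += dec[i] * r;
    }
    for (int t = 0; t < n_steps; ++t) {
      for (int j = 0; j < D; ++j) {
        yf[j] += alpha * (ydec[j] - yf[j]);
        out(t, j) = yf[j];
      }
    }
  } else {
    std::vector<double> v(N), refr(N, 0.0);
    for (int i = 0; i < N; ++i) v[i] = (alive[i] > 0.0) ? v0[i] * 0.5 : 0.0;
    for (int t = 0; t < n_steps; ++t) {
      std::fill(ydec.begin(), ydec.end(), 0.0);
      for (int i = 0; i < N; ++i) {
        if (alive[i] == 0.0) continue;
        if (refr[i] > 0.0) { refr[i] -= dt; continue; }
        v[i] += dt / tau_rc * (J[i] - v[i]);
        if (v[i] >= 1.0) {
          v[i] = 0.0;
          refr[i] = tau_ref;
          ydec[ens_id[i] - 1] += dec[i] / dt;   // unit-area spike
        }
      }
      for (int j = 0; j < D; ++j) {
        yf[j] += alpha * (ydec[j] - yf[j]);
        out(t, j) = yf[j];
      }
    }
  }
  return out;
}

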