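// Time-stepped engine for the reduced olfactory bulb + piriform cortex
// circuit.  All model structure (connectivity, modulated parameters,
// plasticity constants) is resolved on the R side; this file only advances
// the coupled Euler updates, evaluates conductance kernels from last-spike
// times, draws Bernoulli spikes from R's RNG stream, and (optionally)
// applies the Hebbian coincidence rule to the association-fiber weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Pop {
  double tau, beta, tmin, tmax, vhyper;
  int refrac_steps;
};

Pop read_pop(const List& p, double dt) {
  Pop out;
  out.tau = as<double>(p["tau"]);
  out.beta = as<double>(p["beta"]);
  out.tmin = as<double>(p["theta_min"]);
  out.tmax = as<double>(p["theta_max"]);
  out.vhyper = as<double>(p["v_hyper"]);
  out.refrac_steps = (int)std::ceil(as<double>(p["t_refrac"]) / dt);
  return out;
}

// piecewise power-law transfer, elementwise
arma::vec transfer_vec(const arma::vec& v, const Pop& p) {
  arma::vec x = (v - p.tmin) / (p.tmax - p.tmin);
  x.transform([&p](double z) {
    if (z <= 0.0) return 0.0;
    if (z >= 1.0) return 1.0;
    return std::pow(z, p.beta);
  });
  return x;
}

// difference-of-exponentials kernel table sampled on the step grid,
// oriented so that with tau1 (rise) < tau2 (fall) values are >= 0
arma::vec kernel_table(double gmax, double tau1, double tau2, double dt) {
  int len = (int)std::ceil(10.0 * std::max(tau1, tau2) / dt) + 1;
  arma::vec tab(len);
  for (int k = 0; k < len; ++k) {
    double t = k * dt;
    tab[k] = gmax * (std::exp(-t / tau2) - std::exp(-t / tau1));
  }
  return tab;
}

// conductance per presynaptic neuron from steps-since-last-spike
arma::vec lookup(const arma::vec& tab, const arma::ivec& last_spike,
                 int step) {
  int len = tab.n_elem;
  arma::vec g(last_spike.n_elem, arma::fill::zeros);
  for (arma::uword i = 0; i < last_spike.n_elem; ++i) {
    int k = step - last_spike[i];
    if (k >= 0 && k < len) g[i] = tab[k];
  }
  return g;
}

// Bernoulli spiking with reset + refractory lockout; one uniform draw per
// neuron per step regardless of refractoriness, so the RNG stream layout
// is independent of network activity.
void spike_pop(arma::vec& v, arma::ivec& last_spike, arma::ivec& counts,
               std::vector<int>* raster_step, std::vector<int>* raster_id,
               const Pop& p, int step, int win_start, int win_end,
               double rate_scale) {
  arma::vec prob = transfer_vec(v, p) * rate_scale;
  for (arma::uword i = 0; i < v.n_elem; ++i) {
    double u = R::unif_rand();
    bool refractory = (step - last_spike[i]) < p.refrac_steps;
    if (!refractory && u < prob[i]) {
      v[i] = p.vhyper;
      last_spike[i] = step;
      if (step >= win_start && step < win_end) counts[i] += 1;
      if (raster_step) {
        raster_step->push_back(step);
        raster_id->push_back((int)i + 1);
      }
    }
  }
}

void euler(arma::vec& v, const arma::vec& vext, double tau, double dt) {
  v += (dt / tau) * (vext - v);
}

// zero-mean Gaussian membrane noise on the synaptic drive of spiking cells
arma::vec noise_vec(int n, double sd) {
  arma::vec z(n, arma::fill::zeros);
  if (sd > 0) {
    for (int i = 0; i < n; ++i) z[i] = sd * R::norm_rand();
  }
  return z;
}

void guard(const arma::vec& v, const char* pop, int step) {
  double m = arma::abs(v).max();
  if (!std::isfinite(m) || m > 1e3) {
    stop("membrane divergence in population '%s' at step %d (|v| = %f); "
         "check parameter overrides", pop, step, m);
  }
}

} // namespace

// [[Rcpp::export]]
List sim_engine_cpp(List pops, List paths, List mats, arma::vec osn_input,
                    int n_steps, double dt, int win_start, int win_end,
                    bool learn, List plast, bool record_raster,
                    double rate_scale, double noise_sd) {
  const Pop osn = read_pop(pops["osn"], dt);
  const Pop pg = read_pop(pops["pg"], dt);
  const Pop mia = read_pop(pops["mi_apical"], dt);
  const Pop mis = read_pop(pops["mi"], dt);
  const Pop gr = read_pop(pops["gr"], dt);
  const Pop ff = read_pop(pops["ff"], dt);
  const Pop pyr = read_pop(pops["pyr"], dt);
  const Pop fb = read_pop(pops["fb"], dt);

  const List ppyr = pops["pyr"];
  const double a_ahc = as<double>(ppyr["a_ahc"]);
  const double tau_ahc = as<double>(ppyr["tau_ahc"]);
  const double e_ahc = as<double>(ppyr["e_ahc"]);

  // pathway constants; gmax for the NE-modulated pathways arrives already
  // blended from the R side
  auto path = [&](const char* nm, double& gmax, double& E, double& t1,
                  double& t2) {
    List k = paths[nm];
    gmax = as<double>(k["g_max"]);
    E = as<double>(k["e_nernst"]);
    t1 = as<double>(k["tau1"]);
    t2 = as<double>(k["tau2"]);
  };
  double g_osnpg, E_osnpg, t1d, t2d;
  path("osn_pg", g_osnpg, E_osnpg, t1d, t2d);
  double g_osnmi, E_osnmi;
  path("osn_mi", g_osnmi, E_osnmi, t1d, t2d);
  double g_pgmi, E_pgmi;
  path("pg_mi", g_pgmi, E_pgmi, t1d, t2d);

  double gm, E_migr, T1, T2;
  path("mi_gr", gm, E_migr, T1, T2);
  arma::vec tab_migr = kernel_table(gm, T1, T2, dt);
  double E_grmi;
  path("gr_mi", gm, E_grmi, T1, T2);
  arma::vec tab_grmi = kernel_table(gm, T1, T2, dt);
  double E_miff;
  path("mi_ff", gm, E_miff, T1, T2);
  arma::vec tab_miff = kernel_table(gm, T1, T2, dt);
  double E_mipyr;
  path("mi_pyr", gm, E_mipyr, T1, T2);
  arma::vec tab_mipyr = kernel_table(gm, T1, T2, dt);
  double E_ffpyr;
  path("ff_pyr", gm, E_ffpyr, T1, T2);
  arma::vec tab_ffpyr = kernel_table(gm, T1, T2, dt);
  double E_pyrfb;
  path("pyr_fb", gm, E_pyrfb, T1, T2);
  arma::vec tab_pyrfb = kernel_table(gm, T1, T2, dt);
  double E_fbpyr;
  path("fb_pyr", gm, E_fbpyr, T1, T2);
  arma::vec tab_fbpyr = kernel_table(gm, T1, T2, dt);
  double E_pp;
  path("pyr_pyr", gm, E_pp, T1, T2);
  arma::vec tab_pp = kernel_table(gm, T1, T2, dt);

  // connectivity, stored post x pre so drive_post = M * g_pre
  const arma::mat M_grmi = as<arma::mat>(mats["grmi"]);
  const arma::mat M_migr = as<arma::mat>(mats["migr"]);
  const arma::mat M_miff = as<arma::mat>(mats["miff"]);
  const arma::mat M_mipyr = as<arma::mat>(mats["mipyr"]);
  const arma::mat M_ffpyr = as<arma::mat>(mats["ffpyr"]);
  const arma::mat M_fbpyr = as<arma::mat>(mats["fbpyr"]);
  const arma::mat M_pyrfb = as<arma::mat>(mats["pyrfb"]);
  const arma::mat M_pp = as<arma::mat>(mats["pp"]); // normalized weights^T

  const int n = osn_input.n_elem;

  // plasticity bookkeeping (raw weights are pre x post)
  arma::mat Wraw, adj;
  arma::vec tab_post, tab_glu;
  int delay_steps = 0;
  double tau_pp = 800.0;
  if (learn) {
    Wraw = as<arma::mat>(plast["w_raw"]);
    adj = as<arma::mat>(plast["adjacency"]);
    tau_pp = as<double>(plast["tau_pp"]);
    const double tau_post = as<double>(plast["tau_post"]);
    const double tau_f = as<double>(plast["tau_nmda_f"]);
    const double tau_r = as<double>(plast["tau_nmda_r"]);
    delay_steps = (int)std::round(as<double>(plast["t_delay"]) / dt);
    const bool printed = as<std::string>(plast["glu_form"]) == "printed";
    int lp = (int)std::ceil(10.0 * tau_post / dt) + 1;
    tab_post.set_size(lp);
    for (int k = 0; k < lp; ++k) {
      double t = k * dt;
      tab_post[k] = (t / tau_post) * std::exp(1.0 - t / tau_post);
    }
    int lg = (int)std::ceil(10.0 * tau_f / dt) + 1;
    tab_glu.set_size(lg);
    const double t_peak = tau_r * std::log((tau_f + tau_r) / tau_r);
    const double peak =
        std::exp(-t_peak / tau_f) * (1.0 - std::exp(-t_peak / tau_r));
    for (int k = 0; k < lg; ++k) {
      double t = k * dt;
      tab_glu[k] = printed
                       ? std::exp(-t / tau_f) * std::exp(1.0 - t / tau_r)
                       : std::exp(-t / tau_f) * (1.0 - std::exp(-t / tau_r)) /
                             peak;
    }
  }

  // state
  arma::vec v_osn(n, arma::fill::zeros), v_pg(n, arma::fill::zeros);
  arma::vec v_mia(n, arma::fill::zeros), v_mis(n, arma::fill::zeros);
  arma::vec v_gr(n, arma::fill::zeros), v_ff(n, arma::fill::zeros);
  arma::vec v_pyr(n, arma::fill::zeros), v_fb(n, arma::fill::zeros);
  arma::vec v_ahc(n, arma::fill::zeros);
  const int never = -1000000;
  arma::ivec spk_mi(n), spk_gr(n), spk_ff(n), spk_pyr(n), spk_fb(n);
  spk_mi.fill(never);
  spk_gr.fill(never);
  spk_ff.fill(never);
  spk_pyr.fill(never);
  spk_fb.fill(never);
  arma::ivec prev_pyr_spike(n, arma::fill::zeros);

  arma::ivec c_mi(n, arma::fill::zeros), c_gr(n, arma::fill::zeros),
      c_ff(n, arma::fill::zeros), c_pyr(n, arma::fill::zeros),
      c_fb(n, arma::fill::zeros);
  arma::vec out_osn(n, arma::fill::zeros), out_pg(n, arma::fill::zeros);

  std::vector<int> r_step[5], r_id[5];
  std::vector<int>* rs[5] = {nullptr, nullptr, nullptr, nullptr, nullptr};
  std::vector<int>* ri[5] = {nullptr, nullptr, nullptr, nullptr, nullptr};
  if (record_raster) {
    for (int k = 0; k < 5; ++k) {
      rs[k] = &r_step[k];
      ri[k] = &r_id[k];
    }
  }

  for (int s = 0; s < n_steps; ++s) {
    // olfactory sensory neurons (graded)
    euler(v_osn, osn_input, osn.tau, dt);
    arma::vec F_osn = transfer_vec(v_osn, osn);

    // periglomerular cells (graded), one-to-one from their glomerulus OSN
    arma::vec vext_pg = g_osnpg * F_osn % (E_osnpg - v_pg);
    euler(v_pg, vext_pg, pg.tau, dt);
    arma::vec F_pg = transfer_vec(v_pg, pg);

    // mitral apical compartment: OSN excitation + PG inhibition
    arma::vec vext_mia = g_osnmi * F_osn % (E_osnmi - v_mia) +
                         g_pgmi * F_pg % (E_pgmi - v_mia);
    euler(v_mia, vext_mia, mia.tau, dt);

    // mitral soma: granule inhibition + electrical coupling from apical
    arma::vec g_gr_pre = lookup(tab_grmi, spk_gr, s);
    arma::vec vext_mis = (M_grmi * g_gr_pre) % (E_grmi - v_mis) +
                         (v_mia - v_mis) + noise_vec(n, noise_sd);
    euler(v_mis, vext_mis, mis.tau, dt);
    spike_pop(v_mis, spk_mi, c_mi, rs[0], ri[0], mis, s, win_start, win_end,
              rate_scale);

    // granule cells, driven by mitral spikes
    arma::vec g_mi_pre = lookup(tab_migr, spk_mi, s);
    arma::vec vext_gr =
        (M_migr * g_mi_pre) % (E_migr - v_gr) + noise_vec(n, noise_sd);
    euler(v_gr, vext_gr, gr.tau, dt);
    spike_pop(v_gr, spk_gr, c_gr, rs[1], ri[1], gr, s, win_start, win_end,
              rate_scale);

    // cortical feedforward interneurons
    arma::vec g_mi_ff = lookup(tab_miff, spk_mi, s);
    arma::vec vext_ff =
        (M_miff * g_mi_ff) % (E_miff - v_ff) + noise_vec(n, noise_sd);
    euler(v_ff, vext_ff, ff.tau, dt);
    spike_pop(v_ff, spk_ff, c_ff, rs[2], ri[2], ff, s, win_start, win_end,
              rate_scale);

    // pyramidal cells: bulbar input, Ff/Fb inhibition, association fibers,
    // afterhyperpolarization
    v_ahc += (dt / tau_ahc) *
             (a_ahc * arma::conv_to<arma::vec>::from(prev_pyr_spike) - v_ahc);
    arma::vec g_mi_p = lookup(tab_mipyr, spk_mi, s);
    arma::vec g_ff_p = lookup(tab_ffpyr, spk_ff, s);
    arma::vec g_fb_p = lookup(tab_fbpyr, spk_fb, s);
    arma::vec g_pp = lookup(tab_pp, spk_pyr, s);
    arma::vec vext_pyr = (M_mipyr * g_mi_p) % (E_mipyr - v_pyr) +
                         (M_ffpyr * g_ff_p) % (E_ffpyr - v_pyr) +
                         (M_fbpyr * g_fb_p) % (E_fbpyr - v_pyr) +
                         (M_pp * g_pp) % (E_pp - v_pyr) +
                         v_ahc % (e_ahc - v_pyr) + noise_vec(n, noise_sd);
    euler(v_pyr, vext_pyr, pyr.tau, dt);
    arma::ivec before = spk_pyr;
    spike_pop(v_pyr, spk_pyr, c_pyr, rs[3], ri[3], pyr, s, win_start,
              win_end, rate_scale);
    for (int i = 0; i < n; ++i)
      prev_pyr_spike[i] = (spk_pyr[i] == s) ? 1 : 0;

    // Hebbian coincidence update on the raw association weights
    if (learn) {
      arma::vec glu(n), post(n);
      bool any = false;
      for (int i = 0; i < n; ++i) {
        int kg = s - spk_pyr[i] - delay_steps;
        glu[i] = (kg >= 0 && kg < (int)tab_glu.n_elem) ? tab_glu[kg] : 0.0;
        int kp = s - spk_pyr[i];
        post[i] = (kp >= 0 && kp < (int)tab_post.n_elem) ? tab_post[kp] : 0.0;
        if (glu[i] > 0 || post[i] > 0) any = true;
      }
      if (any) {
        Wraw += (dt / tau_pp) * ((1.0 - Wraw) % (glu * post.t())) % adj;
      }
    }

    // feedback interneurons, driven by pyramidal spikes
    arma::vec g_pyr_fb = lookup(tab_pyrfb, spk_pyr, s);
    arma::vec vext_fb =
        (M_pyrfb * g_pyr_fb) % (E_pyrfb - v_fb) + noise_vec(n, noise_sd);
    euler(v_fb, vext_fb, fb.tau, dt);
    spike_pop(v_fb, spk_fb, c_fb, rs[4], ri[4], fb, s, win_start, win_end,
              rate_scale);

    if (s % 50 == 0) {
      guard(v_mis, "mi", s);
      guard(v_pyr, "pyr", s);
      guard(v_gr, "gr", s);
    }

    // accumulate graded outputs over the analysis window
    if (s >= win_start && s < win_end) {
      out_osn += F_osn;
      out_pg += F_pg;
    }
  }

  const double win_n = std::max(1, win_end - win_start);
  List res = List::create(
      Named("counts") = List::create(
          Named("mi") = c_mi, Named("gr") = c_gr, Named("ff") = c_ff,
          Named("pyr") = c_pyr, Named("fb") = c_fb),
      Named("graded_mean") = List::create(Named("osn") = out_osn / win_n,
                                          Named("pg") = out_pg / win_n));
  if (record_raster) {
    const char* nm[5] = {"mi", "gr", "ff", "pyr", "fb"};
    List rl(5);
    CharacterVector rn(5);
    for (int k = 0; k < 5; ++k) {
      rl[k] = DataFrame::create(Named("step") = wrap(r_step[k]),
                                Named("neuron") = wrap(r_id[k]));
      rn[k] = nm[k];
    }
    rl.attr("names") = rn;
    res["raster"] = rl;
  }
  if (learn) res["w_raw"] = Wraw;
  return res;
}
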