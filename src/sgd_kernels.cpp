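// SGD inner loops for the two embedding learners. All randomness comes from
// the seeds passed in; results are bit-reproducible on a given platform.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double clamp_p(double p) {
  if (p < 1e-12) return 1e-12;
  if (p > 1.0 - 1e-12) return 1.0 - 1e-12;
  return p;
}

// Stochastic gradient ascent on the per-sample log objective
// L*log(P) + (1-L)*log(1-P), P = sigmoid(sum_k a_k * b_k * sigmoid(c_k)).
// Indices are 1-based (from R). Linear learning-rate decay over all updates.
// [[Rcpp::export]]
List hin2vec_sgd_cpp(NumericMatrix WM0, NumericMatrix WN0, NumericMatrix WR0,
                     IntegerVector m, IntegerVector n, IntegerVector r,
                     IntegerVector label, int epochs, double lr0, int seed,
                     bool tie) {
  // transposed (d x n) storage so one entity's vector is contiguous
  arma::mat WM = arma::trans(arma::mat(WM0.begin(), WM0.nrow(), WM0.ncol()));
  arma::mat WN = arma::trans(arma::mat(WN0.begin(), WN0.nrow(), WN0.ncol()));
  arma::mat WR = arma::trans(arma::mat(WR0.begin(), WR0.nrow(), WR0.ncol()));
  const int N = m.size();
  const int d = WM.n_rows;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  const double total = std::max(1.0, static_cast<double>(epochs) * N);
  double t = 0.0;
  NumericVector loss(epochs);
  std::vector<double> cq(d);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    for (int s = 0; s < N; ++s) {
      const int i = m[order[s]] - 1;
      const int j = n[order[s]] - 1;
      const int k = r[order[s]] - 1;
      const int L = label[order[s]];
      const double lr = lr0 * std::max(1e-4, 1.0 - t / total);
      t += 1.0;
      double *a = WM.colptr(i);
      double *b = tie ? WM.colptr(j) : WN.colptr(j);
      double *c = WR.colptr(k);
      double score = 0.0;
      for (int q = 0; q < d; ++q) {
        cq[q] = sigmoid(c[q]);
        score += a[q] * b[q] * cq[q];
      }
      const double P = clamp_p(sigmoid(score));
      const double g = static_cast<double>(L) - P;
      ep_loss += (L == 1) ? std::log(P) : std::log(1.0 - P);
      for (int q = 0; q < d; ++q) {
        const double aq = a[q], bq = b[q], sq = cq[q];
        a[q] += lr * g * bq * sq;
        b[q] += lr * g * aq * sq;
        c[q] += lr * g * aq * bq * sq * (1.0 - sq);
      }
    }
    loss[ep] = (N > 0) ? ep_loss / N : 0.0;
  }
  if (tie) WN = WM;
  return List::create(_["W_M"] = arma::trans(WM), _["W_N"] = arma::trans(WN),
                      _["W_R"] = arma::trans(WR), _["loss"] = loss);
}

// Alternating adversarial training. Discriminator: three binary
// cross-entropy terms per real edge (real as true, corrupted relation as
// false, generated fake neighbour as false). Generator: ascend log D of its
// fakes through a tanh output layer. Minibatch chunks of the shuffled edge
// pass are interleaved between the two players.
// [[Rcpp::export]]
List hegan_train_cpp(arma::mat dE, arma::cube dMr, arma::mat gE,
                     arma::cube gMr, IntegerVector eu, IntegerVector ev,
                     IntegerVector er, int n_rel, int epochs, int disc_steps,
                     int gen_steps, double lr_d, double lr_g,
                     double noise_sigma, int samples_per_edge, int seed) {
  const int E = eu.size();
  const int d = dE.n_cols;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_int_distribution<int> pick_rel(0, std::max(0, n_rel - 2));
  NumericVector disc_loss(epochs), gen_loss(epochs);

  const int M = E * samples_per_edge;
  std::vector<int> dorder(M), gorder(M);
  for (int i = 0; i < M; ++i) dorder[i] = gorder[i] = i % E;

  auto gen_fake = [&](int u, int r) {
    arma::rowvec z = gE.row(u) * gMr.slice(r);
    if (noise_sigma > 0) {
      for (int q = 0; q < d; ++q) z[q] += noise_sigma * gauss(rng);
    }
    return arma::rowvec(arma::tanh(z));
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(dorder.begin(), dorder.end(), rng);
    std::shuffle(gorder.begin(), gorder.end(), rng);
    double dl = 0.0, gl = 0.0;
    int dn = 0, gn = 0;
    const int steps = std::max(disc_steps, gen_steps);
    for (int st = 0; st < steps; ++st) {
      // discriminator chunk st of disc_steps
      if (st < disc_steps) {
        const int lo = (int)((double)M * st / disc_steps);
        const int hi = (int)((double)M * (st + 1) / disc_steps);
        for (int s = lo; s < hi; ++s) {
          const int u = eu[dorder[s]] - 1;
          const int v = ev[dorder[s]] - 1;
          const int r = er[dorder[s]] - 1;
          // (i) real triple, label 1
          {
            arma::rowvec e_u = dE.row(u), e_v = dE.row(v);
            arma::mat Mr = dMr.slice(r);
            arma::colvec Mv = Mr * e_v.t();
            const double p = clamp_p(sigmoid(arma::dot(e_u, Mv)));
            const double g = p - 1.0;
            dl += -std::log(p); ++dn;
            dE.row(u) -= lr_d * g * Mv.t();
            dE.row(v) -= lr_d * g * (e_u * Mr);
            dMr.slice(r) -= lr_d * g * (e_u.t() * e_v);
          }
          // (ii) corrupted relation, label 0
          if (n_rel > 1) {
            int r2 = pick_rel(rng);
            if (r2 >= r) ++r2;
            arma::rowvec e_u = dE.row(u), e_v = dE.row(v);
            arma::mat Mr2 = dMr.slice(r2);
            arma::colvec Mv = Mr2 * e_v.t();
            const double p = clamp_p(sigmoid(arma::dot(e_u, Mv)));
            const double g = p;
            dl += -std::log(1.0 - p); ++dn;
            dE.row(u) -= lr_d * g * Mv.t();
            dE.row(v) -= lr_d * g * (e_u * Mr2);
            dMr.slice(r2) -= lr_d * g * (e_u.t() * e_v);
          }
          // (iii) generated fake neighbour, label 0 (fake is not updated)
          {
            arma::rowvec f = gen_fake(u, r);
            arma::rowvec e_u = dE.row(u);
            arma::mat Mr = dMr.slice(r);
            arma::colvec Mf = Mr * f.t();
            const double p = clamp_p(sigmoid(arma::dot(e_u, Mf)));
            const double g = p;
            dl += -std::log(1.0 - p); ++dn;
            dE.row(u) -= lr_d * g * Mf.t();
            dMr.slice(r) -= lr_d * g * (e_u.t() * f);
          }
        }
      }
      // generator chunk st of gen_steps
      if (st < gen_steps) {
        const int lo = (int)((double)M * st / gen_steps);
        const int hi = (int)((double)M * (st + 1) / gen_steps);
        for (int s = lo; s < hi; ++s) {
          const int u = eu[gorder[s]] - 1;
          const int r = er[gorder[s]] - 1;
          arma::rowvec z = gE.row(u) * gMr.slice(r);
          if (noise_sigma > 0) {
            for (int q = 0; q < d; ++q) z[q] += noise_sigma * gauss(rng);
          }
          arma::rowvec f = arma::tanh(z);
          arma::rowvec e_u = dE.row(u);
          arma::mat Mr = dMr.slice(r);
          const double p = clamp_p(sigmoid(arma::as_scalar(e_u * Mr * f.t())));
          gl += -std::log(p); ++gn;
          arma::rowvec dldf = (p - 1.0) * (e_u * Mr);
          arma::rowvec dldz = dldf % (1.0 - f % f);
          arma::rowvec e_g = gE.row(u); // pre-update value for both grads
          gE.row(u) -= lr_g * (gMr.slice(r) * dldz.t()).t();
          gMr.slice(r) -= lr_g * (e_g.t() * dldz);
        }
      }
    }
    disc_loss[ep] = dn ? dl / dn : 0.0;
    gen_loss[ep] = gn ? gl / gn : 0.0;
  }
  return List::create(_["disc_emb"] = dE, _["disc_rel"] = dMr,
                      _["gen_emb"] = gE, _["gen_rel"] = gMr,
                      _["disc_loss"] = disc_loss, _["gen_loss"] = gen_loss);
}
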