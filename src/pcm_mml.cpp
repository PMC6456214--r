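#include <Rcpp.h>
using namespace Rcpp;

// Marginal negative log-likelihood and analytic gradient of the two-group
// latent-regression partial credit model, integrated by Gauss-Hermite
// quadrature.
//
// Parameter vector layout:
//   par = [gamma, log_sigma, delta_{1,1..K_1}, ..., delta_{J,1..K_J}, shifts]
// gamma is the latent mean difference (reference - focal): the reference
// group mean is fixed at 0, the focal group mean is -gamma, both groups share
// the latent SD sigma = exp(log_sigma).
//
// resp   : n x J integer matrix of category codes 0..K_j (NA = missing,
//          treated as a skipped likelihood term)
// group  : 0 = reference, 1 = focal
// kvec   : number of thresholds K_j per item (categories - 1)
// gh_x/w : Gauss-Hermite nodes/weights for integral of exp(-x^2) f(x)
// dif_mode: 0 none; 1 a single shared focal-group shift on item dif_item's
//          thresholds (1 extra parameter); 2 free per-threshold focal shifts
//          (K_j extra parameters).  dif_item is 0-based.
//
// Gradient bookkeeping uses the fact that the posterior node weights W_pq of
// each person sum to one, so the "observed" part of each score contribution
// collapses to a category count and the quadrature part aggregates over
// persons within a group (all persons in a group share the node grid).
// [[Rcpp::export]]
List pcm_mml_core(NumericVector par, IntegerMatrix resp, IntegerVector group,
                  IntegerVector kvec, NumericVector gh_x, NumericVector gh_w,
                  int dif_item, int dif_mode)
{
    const int n = resp.nrow(), J = resp.ncol(), Q = gh_x.size();
    const double gamma = par[0], sigma = std::exp(par[1]);
    const double SQ2 = std::sqrt(2.0), LSP = 0.5 * std::log(M_PI);

    std::vector<int> off(J);
    int tot = 0;
    for (int j = 0; j < J; ++j) { off[j] = 2 + tot; tot += kvec[j]; }
    const int nshift = dif_mode == 0 ? 0 : (dif_mode == 1 ? 1 : kvec[dif_item]);
    const int npar = 2 + tot + nshift;

    std::vector<double> theta(2 * Q), logw(Q);
    for (int q = 0; q < Q; ++q) {
        logw[q] = std::log(gh_w[q]) - LSP;
        theta[q]     = SQ2 * sigma * gh_x[q];          // reference, mean 0
        theta[Q + q] = -gamma + SQ2 * sigma * gh_x[q]; // focal, mean -gamma
    }

    // per (group, item, node): log P(X = k), survivor P(X >= m), E[X]
    int maxK1 = 0;
    for (int j = 0; j < J; ++j) maxK1 = std::max(maxK1, kvec[j] + 1);
    std::vector<double> lp((size_t)2 * J * Q * maxK1),
                        surv((size_t)2 * J * Q * maxK1, 0.0),
                        ex((size_t)2 * J * Q);
    std::vector<double> cum(maxK1), v(maxK1), p(maxK1);
    for (int g = 0; g < 2; ++g) {
        for (int j = 0; j < J; ++j) {
            const int K = kvec[j];
            cum[0] = 0.0;
            for (int m = 1; m <= K; ++m) {
                double d = par[off[j] + m - 1];
                if (g == 1 && dif_mode > 0 && j == dif_item)
                    d += (dif_mode == 1) ? par[2 + tot] : par[2 + tot + m - 1];
                cum[m] = cum[m - 1] + d;
            }
            for (int q = 0; q < Q; ++q) {
                const double th = theta[g * Q + q];
                double mx = -1e300;
                for (int k = 0; k <= K; ++k) {
                    v[k] = k * th - cum[k];
                    if (v[k] > mx) mx = v[k];
                }
                double Z = 0.0;
                for (int k = 0; k <= K; ++k) { p[k] = std::exp(v[k] - mx); Z += p[k]; }
                const double lZ = std::log(Z);
                const size_t base = ((size_t)(g * J + j) * Q + q) * maxK1;
                double e = 0.0;
                for (int k = 0; k <= K; ++k) {
                    p[k] /= Z;
                    lp[base + k] = v[k] - mx - lZ;
                    e += k * p[k];
                }
                double acc = 0.0;
                for (int m = K; m >= 1; --m) { acc += p[m]; surv[base + m] = acc; }
                ex[(size_t)(g * J + j) * Q + q] = e;
            }
        }
    }

    std::vector<char> item_has_na(J, 0);
    bool any_na = false;
    for (int j = 0; j < J; ++j) {
        for (int i = 0; i < n; ++i)
            if (resp(i, j) == NA_INTEGER) { item_has_na[j] = 1; any_na = true; break; }
    }

    NumericVector ll_person(n), grad(npar);
    std::vector<double> M(Q), A(Q);
    std::vector<double> Sg(2 * Q, 0.0), SgA(2 * Q, 0.0);
    std::vector<double> SgObs;
    if (any_na) SgObs.assign((size_t)2 * J * Q, 0.0);
    std::vector<double> cnt(tot, 0.0);
    std::vector<double> cnt_focal(dif_mode ? kvec[dif_item] : 0, 0.0);
    double nll = 0.0;

    for (int i = 0; i < n; ++i) {
        const int g = group[i];
        double mx = -1e300;
        for (int q = 0; q < Q; ++q) {
            double m_ = logw[q], a_ = 0.0;
            for (int j = 0; j < J; ++j) {
                const int x = resp(i, j);
                if (x == NA_INTEGER) continue;
                const size_t base = ((size_t)(g * J + j) * Q + q) * maxK1;
                m_ += lp[base + x];
                a_ += x - ex[(size_t)(g * J + j) * Q + q];
            }
            M[q] = m_; A[q] = a_;
            if (m_ > mx) mx = m_;
        }
        double L = 0.0;
        for (int q = 0; q < Q; ++q) { M[q] = std::exp(M[q] - mx); L += M[q]; }
        ll_person[i] = mx + std::log(L);
        nll -= ll_person[i];
        const double invL = 1.0 / L;
        for (int q = 0; q < Q; ++q) {
            const double W = M[q] * invL;
            Sg[g * Q + q] += W;
            SgA[g * Q + q] += W * A[q];
            if (any_na)
                for (int j = 0; j < J; ++j)
                    if (item_has_na[j] && resp(i, j) != NA_INTEGER)
                        SgObs[((size_t)(g * J + j)) * Q + q] += W;
        }
        for (int j = 0; j < J; ++j) {
            const int x = resp(i, j);
            if (x == NA_INTEGER) continue;
            for (int m = 1; m <= x; ++m) cnt[off[j] - 2 + m - 1] += 1.0;
            if (dif_mode > 0 && j == dif_item && g == 1)
                for (int m = 1; m <= x; ++m) cnt_focal[m - 1] += 1.0;
        }
    }

    // d nll / d gamma: theta of focal nodes moves by -1 per unit gamma
    double ggam = 0.0;
    for (int q = 0; q < Q; ++q) ggam += SgA[Q + q];
    grad[0] = ggam;
    // d nll / d log sigma: theta moves by sqrt(2) x_q sigma
    double gsig = 0.0;
    for (int g = 0; g < 2; ++g)
        for (int q = 0; q < Q; ++q)
            gsig += gh_x[q] * SgA[g * Q + q];
    grad[1] = -SQ2 * sigma * gsig;
    // d nll / d delta_{jm} = count(x_pj >= m) - sum_g sum_q S_gq P_g(X_j >= m)
    for (int j = 0; j < J; ++j) {
        const int K = kvec[j];
        for (int m = 1; m <= K; ++m) {
            double acc = 0.0;
            for (int g = 0; g < 2; ++g)
                for (int q = 0; q < Q; ++q) {
                    const double S = (any_na && item_has_na[j])
                        ? SgObs[((size_t)(g * J + j)) * Q + q] : Sg[g * Q + q];
                    acc += S * surv[((size_t)(g * J + j) * Q + q) * maxK1 + m];
                }
            grad[off[j] + m - 1] = cnt[off[j] - 2 + m - 1] - acc;
        }
    }
    // focal-group DIF shift parameters (focal persons only)
    if (dif_mode > 0) {
        const int j = dif_item, K = kvec[j];
        for (int m = 1; m <= K; ++m) {
            double acc = 0.0;
            for (int q = 0; q < Q; ++q) {
                const double S = (any_na && item_has_na[j])
                    ? SgObs[((size_t)(J + j)) * Q + q] : Sg[Q + q];
                acc += S * surv[((size_t)(J + j) * Q + q) * maxK1 + m];
            }
            const double gm = cnt_focal[m - 1] - acc;
            if (dif_mode == 1) grad[2 + tot] += gm;
            else grad[2 + tot + m - 1] = gm;
        }
    }

    return List::create(_["nll"] = nll, _["gradient"] = grad,
                        _["loglik_person"] = ll_person);
}
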