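#include <Rcpp.h>
using namespace Rcpp;

// One EM step of the admixture model. dz: individuals x loci dosages with
// missing entries as 0; two_obs: 2 * observation indicator (0 where
// missing). Q: n x K row-stochastic; F: K x L in (0,1).
// [[Rcpp::export(name = ".admixEmStepC")]]
List admix_em_step(IntegerMatrix dz, IntegerMatrix two_obs,
                   NumericMatrix Q, NumericMatrix F) {
    int n = dz.nrow(), L = dz.ncol(), K = Q.ncol();
    NumericMatrix Qn(n, K), Fnum(K, L), Fden(K, L);
    std::vector<double> qf(K), qg(K);
    for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
            int t = two_obs(i, l);
            if (t == 0) continue;
            int d = dz(i, l);
            double mu = 0.0, nu = 0.0;
            for (int k = 0; k < K; ++k) {
                qf[k] = Q(i, k) * F(k, l);
                qg[k] = Q(i, k) * (1.0 - F(k, l));
                mu += qf[k]; nu += qg[k];
            }
            if (mu < 1e-300) mu = 1e-300;
            if (nu < 1e-300) nu = 1e-300;
            for (int k = 0; k < K; ++k) {
                double a = d * qf[k] / mu;          // expected alt copies
                double b = (t - d) * qg[k] / nu;    // expected ref copies
                Qn(i, k) += a + b;
                Fnum(k, l) += a;
                Fden(k, l) += a + b;
            }
        }
    }
    for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += Qn(i, k);
        if (s <= 0) s = 1.0;
        for (int k = 0; k < K; ++k) Qn(i, k) /= s;
    }
    NumericMatrix Fn(K, L);
    for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) {
            double v = Fden(k, l) > 1e-300 ? Fnum(k, l) / Fden(k, l) : 0.5;
            if (v < 1e-6) v = 1e-6;
            if (v > 1 - 1e-6) v = 1 - 1e-6;
            Fn(k, l) = v;
        }
    return List::create(Named("Q") = Qn, Named("F") = Fn);
}

// log-likelihood of the admixture model under the same conventions
// [[Rcpp::export(name = ".admixLoglikC")]]
double admix_loglik(IntegerMatrix dz, IntegerMatrix two_obs,
                    NumericMatrix Q, NumericMatrix F) {
    int n = dz.nrow(), L = dz.ncol(), K = Q.ncol();
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l) {
            int t = two_obs(i, l);
            if (t == 0) continue;
            int d = dz(i, l);
            double mu = 0.0;
            for (int k = 0; k < K; ++k) mu += Q(i, k) * F(k, l);
            if (mu < 1e-300) mu = 1e-300;
            if (mu > 1 - 1e-300) mu = 1 - 1e-300;
            ll += d * log(mu) + (t - d) * log1p(-mu);
        }
    return ll;
}
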