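#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Shared genealogy buffers: nodes are 0..(2n-2); leaves first.
// parent[i], ntime[i]; after the tree is built, one mutation is placed on a
// branch chosen proportional to its length and the derived allele counts of
// the sampled populations are returned.

static void place_mutation(const std::vector<int> &parent,
                           const std::vector<double> &ntime,
                           const std::vector<int> &leaf_pop,
                           int n_leaves, int root, int n_pops,
                           std::vector<int> &derived) {
    int n_nodes = 2 * n_leaves - 1;
    double total = 0.0;
    std::vector<double> blen(n_nodes, 0.0);
    for (int i = 0; i < n_nodes; ++i) {
        if (i == root) continue;
        blen[i] = ntime[parent[i]] - ntime[i];
        total += blen[i];
    }
    double u = unif_rand() * total;
    int mut = -1;
    for (int i = 0; i < n_nodes; ++i) {
        if (i == root) continue;
        u -= blen[i];
        if (u <= 0) { mut = i; break; }
    }
    if (mut < 0) mut = root == n_nodes - 1 ? n_nodes - 2 : n_nodes - 1;
    std::fill(derived.begin(), derived.end(), 0);
    // leaves below 'mut': walk each leaf up to the root, checking passage
    for (int lf = 0; lf < n_leaves; ++lf) {
        int cur = lf;
        while (cur != -1) {
            if (cur == mut) { derived[leaf_pop[lf]] += 1; break; }
            cur = parent[cur];
        }
    }
}

// Scenario coalescent: piecewise-constant population sizes with
// split/admixture events, one segregating site per locus.
//
// sample_sizes: lineages sampled per population (0 for unsampled/ghost)
// pop_sizes:    initial diploid effective sizes per population
// events: rows (time, type, target, src1, src2, rate)
//         type 1 = split (lineages in target move to src1)
//         type 2 = admixture (each lineage in target moves to src1 with
//                  probability rate, else to src2)
//         type 3 = size change (population target gets new size = rate)
// Returns L x n_pops matrix of derived-allele counts among the samples.
// [[Rcpp::export(name = ".simScenarioCounts")]]
IntegerMatrix sim_scenario_counts(int n_loci, IntegerVector sample_sizes,
                                  NumericVector pop_sizes,
                                  NumericMatrix events) {
    int P = sample_sizes.size();
    int n_leaves = 0;
    for (int j = 0; j < P; ++j) n_leaves += sample_sizes[j];
    if (n_leaves < 2) stop("need at least two sampled lineages");
    int n_nodes = 2 * n_leaves - 1;
    IntegerMatrix out(n_loci, P);

    std::vector<int> parent(n_nodes), leaf_pop(n_leaves), derived(P);
    std::vector<double> ntime(n_nodes);
    std::vector<std::vector<int>> members(P);   // active lineages per pop
    std::vector<double> N(P);

    int li = 0;
    for (int j = 0; j < P; ++j)
        for (int k = 0; k < sample_sizes[j]; ++k) leaf_pop[li++] = j;

    int n_ev = events.nrow();
    for (int l = 0; l < n_loci; ++l) {
        for (int j = 0; j < P; ++j) {
            members[j].clear();
            N[j] = pop_sizes[j];
        }
        for (int i = 0; i < n_leaves; ++i) {
            members[leaf_pop[i]].push_back(i);
            parent[i] = -1; ntime[i] = 0.0;
        }
        int next_node = n_leaves;
        int active = n_leaves;
        double t = 0.0;
        int ev = 0;
        while (active > 1) {
            double rate = 0.0;
            for (int j = 0; j < P; ++j) {
                double k = (double)members[j].size();
                if (k >= 2) rate += k * (k - 1.0) / (4.0 * N[j]);
            }
            double t_next = (ev < n_ev) ? events(ev, 0) : R_PosInf;
            double dt = (rate > 0) ? exp_rand() / rate : R_PosInf;
            if (t + dt < t_next) {
                t += dt;
                // pick population proportional to its pair rate
                double u = unif_rand() * rate, acc = 0.0;
                int pj = -1;
                for (int j = 0; j < P; ++j) {
                    double k = (double)members[j].size();
                    if (k >= 2) acc += k * (k - 1.0) / (4.0 * N[j]);
                    if (u <= acc) { pj = j; break; }
                }
                if (pj < 0) pj = P - 1;
                std::vector<int> &mm = members[pj];
                int k = mm.size();
                int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
                int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
                if (i2 >= i1) ++i2;
                int a = mm[i1], b = mm[i2];
                int nd = next_node++;
                parent[a] = nd; parent[b] = nd;
                parent[nd] = -1; ntime[nd] = t;
                if (i1 > i2) std::swap(i1, i2);
                mm[i1] = nd; mm.erase(mm.begin() + i2);
                --active;
            } else {
                if (ev >= n_ev)
                    stop("genealogy cannot coalesce: isolated lineages");
                t = t_next;
                int type = (int)events(ev, 1);
                int target = (int)events(ev, 2);
                if (type == 3) {
                    N[target] = events(ev, 5);
                } else if (type == 1) {
                    int s1 = (int)events(ev, 3);
                    for (size_t q = 0; q < members[target].size(); ++q)
                        members[s1].push_back(members[target][q]);
                    members[target].clear();
                } else {
                    int s1 = (int)events(ev, 3), s2 = (int)events(ev, 4);
                    double r = events(ev, 5);
                    for (size_t q = 0; q < members[target].size(); ++q) {
                        if (unif_rand() < r)
                            members[s1].push_back(members[target][q]);
                        else
                            members[s2].push_back(members[target][q]);
                    }
                    members[target].clear();
                }
                ++ev;
            }
        }
        int root = next_node - 1;
        place_mutation(parent, ntime, leaf_pop, n_leaves, root, P, derived);
        for (int j = 0; j < P; ++j) out(l, j) = derived[j];
    }
    return out;
}

// Hierarchical island-model coalescent (finite island universe:
// n_groups groups x demes_per_group demes, deme size N diploids;
// per-lineage migration rates m_within to another deme of the same group
// and m_among to a deme of another group, per generation).
//
// Demes within a group are exchangeable, so the chain is lumped over
// co-location clusters (sets of lineages sharing a deme): migrations of a
// singleton lineage to an empty deme of its own group do not change the
// lumped state and are skipped, which removes almost all events at
// realistic migration rates. Remaining events: within-cluster
// coalescence, a lineage joining another cluster of its group, a lineage
// leaving a multi-lineage cluster for an empty deme, and among-group
// moves.
//
// sampled_group gives the group of each sampled deme (each sampled deme
// starts as its own cluster); lineages_per_deme lineages per sampled
// deme. Returns L x n_sampled matrix of derived-allele counts.
// [[Rcpp::export(name = ".simIslandCounts")]]
IntegerMatrix sim_island_counts(int n_loci, int n_groups,
                                int demes_per_group, double deme_size,
                                double m_within, double m_among,
                                IntegerVector sampled_group,
                                IntegerVector sampled_deme,
                                IntegerVector lineages_per_deme) {
    int S = sampled_group.size();
    int G = n_groups;
    double D = (double)demes_per_group;
    int n_leaves = 0;
    for (int s = 0; s < S; ++s) n_leaves += lineages_per_deme[s];
    int n_nodes = 2 * n_leaves - 1;
    IntegerMatrix out(n_loci, S);

    std::vector<int> parent(n_nodes), leaf_pop(n_leaves), derived(S);
    std::vector<double> ntime(n_nodes);

    struct Cluster { int group; std::vector<int> members; };
    std::vector<Cluster> cl;
    std::vector<int> n_cl(G), k_g(G);

    int li = 0;
    for (int s = 0; s < S; ++s)
        for (int k = 0; k < lineages_per_deme[s]; ++k) leaf_pop[li++] = s;

    for (int l = 0; l < n_loci; ++l) {
        cl.clear();
        std::fill(n_cl.begin(), n_cl.end(), 0);
        std::fill(k_g.begin(), k_g.end(), 0);
        int idx = 0;
        for (int s = 0; s < S; ++s) {
            Cluster c; c.group = sampled_group[s];
            for (int k = 0; k < lineages_per_deme[s]; ++k) {
                c.members.push_back(idx);
                parent[idx] = -1; ntime[idx] = 0.0; ++idx;
            }
            n_cl[c.group] += 1;
            k_g[c.group] += c.members.size();
            cl.push_back(c);
        }
        int next_node = n_leaves;
        int active = n_leaves;
        double t = 0.0;
        while (active > 1) {
            // rates
            double coal = 0.0, join = 0.0, leave = 0.0;
            for (size_t ci = 0; ci < cl.size(); ++ci) {
                double c = (double)cl[ci].members.size();
                int g = cl[ci].group;
                coal += c * (c - 1.0) / (4.0 * deme_size);
                join += c * m_within * (n_cl[g] - 1) / (D - 1.0);
                if (c >= 2) {
                    double empt = D - (double)n_cl[g];
                    if (empt > 0)
                        leave += c * m_within * empt / (D - 1.0);
                }
            }
            double among = (G > 1) ? active * m_among : 0.0;
            double rate = coal + join + leave + among;
            if (rate <= 0) stop("island coalescent stalled");
            t += exp_rand() / rate;
            double u = unif_rand() * rate;
            if (u < coal) {
                // coalescence: cluster ~ c(c-1)
                double acc = 0.0; int pick = -1;
                for (size_t ci = 0; ci < cl.size(); ++ci) {
                    double c = (double)cl[ci].members.size();
                    acc += c * (c - 1.0) / (4.0 * deme_size);
                    if (u <= acc) { pick = ci; break; }
                }
                if (pick < 0) pick = cl.size() - 1;
                std::vector<int> &mm = cl[pick].members;
                int k = mm.size();
                int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
                int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
                if (i2 >= i1) ++i2;
                int nd = next_node++;
                parent[mm[i1]] = nd; parent[mm[i2]] = nd;
                parent[nd] = -1; ntime[nd] = t;
                if (i1 > i2) std::swap(i1, i2);
                mm[i1] = nd; mm.erase(mm.begin() + i2);
                k_g[cl[pick].group] -= 1;
                --active;
            } else if (u < coal + join) {
                // a lineage joins another cluster of its group
                double u2 = u - coal, acc = 0.0; int pick = -1;
                for (size_t ci = 0; ci < cl.size(); ++ci) {
                    double c = (double)cl[ci].members.size();
                    int g = cl[ci].group;
                    acc += c * m_within * (n_cl[g] - 1) / (D - 1.0);
                    if (u2 <= acc) { pick = ci; break; }
                }
                if (pick < 0) pick = cl.size() - 1;
                int g = cl[pick].group;
                // uniform target among the other clusters of group g
                int n_tgt = n_cl[g] - 1;
                int step = (int)(unif_rand() * n_tgt); if (step >= n_tgt) step = n_tgt - 1;
                int tgt = -1;
                for (size_t ci = 0; ci < cl.size(); ++ci) {
                    if ((int)ci == pick || cl[ci].group != g) continue;
                    if (step == 0) { tgt = ci; break; }
                    --step;
                }
                if (tgt < 0) continue;
                std::vector<int> &mm = cl[pick].members;
                int k = mm.size();
                int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
                cl[tgt].members.push_back(mm[i1]);
                mm.erase(mm.begin() + i1);
                if (mm.empty()) {
                    n_cl[g] -= 1;
                    cl.erase(cl.begin() + pick);
                }
            } else if (u < coal + join + leave) {
                // a lineage leaves a multi-lineage cluster for an empty deme
                double u2 = u - coal - join, acc = 0.0; int pick = -1;
                for (size_t ci = 0; ci < cl.size(); ++ci) {
                    double c = (double)cl[ci].members.size();
                    int g = cl[ci].group;
                    if (c < 2) continue;
                    double empt = D - (double)n_cl[g];
                    if (empt <= 0) continue;
                    acc += c * m_within * empt / (D - 1.0);
                    if (u2 <= acc) { pick = ci; break; }
                }
                if (pick < 0) continue;
                std::vector<int> &mm = cl[pick].members;
                int k = mm.size();
                int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
                Cluster nc; nc.group = cl[pick].group;
                nc.members.push_back(mm[i1]);
                mm.erase(mm.begin() + i1);
                n_cl[nc.group] += 1;
                cl.push_back(nc);
            } else {
                // among-group move of a uniform lineage
                int step = (int)(unif_rand() * active); if (step >= active) step = active - 1;
                int pick = -1, off = -1;
                for (size_t ci = 0; ci < cl.size(); ++ci) {
                    int c = cl[ci].members.size();
                    if (step < c) { pick = ci; off = step; break; }
                    step -= c;
                }
                if (pick < 0) continue;
                int g = cl[pick].group;
                int h = (int)(unif_rand() * (G - 1)); if (h >= G - 1) h = G - 2;
                if (h >= g) ++h;
                int lin = cl[pick].members[off];
                cl[pick].members.erase(cl[pick].members.begin() + off);
                k_g[g] -= 1;
                if (cl[pick].members.empty()) {
                    n_cl[g] -= 1;
                    cl.erase(cl.begin() + pick);
                }
                k_g[h] += 1;
                if (unif_rand() * D < (double)n_cl[h]) {
                    int n_tgt = n_cl[h];
                    int st2 = (int)(unif_rand() * n_tgt); if (st2 >= n_tgt) st2 = n_tgt - 1;
                    for (size_t ci = 0; ci < cl.size(); ++ci) {
                        if (cl[ci].group != h) continue;
                        if (st2 == 0) { cl[ci].members.push_back(lin); break; }
                        --st2;
                    }
                } else {
                    Cluster nc; nc.group = h;
                    nc.members.push_back(lin);
                    n_cl[h] += 1;
                    cl.push_back(nc);
                }
            }
        }
        int root = next_node - 1;
        place_mutation(parent, ntime, leaf_pop, n_leaves, root, S, derived);
        for (int s = 0; s < S; ++s) out(l, s) = derived[s];
    }
    return out;
}


static inline double lbeta_(double a, double b) {
    return R::lbeta(a, b);
}

// log beta-binomial likelihood contribution of one locus given alpha
static double locus_loglik(int l, const IntegerMatrix &alt,
                           const IntegerMatrix &tot, double p,
                           double alpha, const std::vector<double> &beta) {
    int P = alt.ncol();
    double ll = 0.0;
    for (int j = 0; j < P; ++j) {
        int n = tot(l, j);
        if (n == 0) continue;
        double th = exp(-(alpha + beta[j]));   // (1-F)/F
        double u = th * p, v = th * (1.0 - p);
        ll += lbeta_(alt(l, j) + u, n - alt(l, j) + v) - lbeta_(u, v);
    }
    return ll;
}

// F-model reversible-jump MCMC (BayeScan-style).
// alt/tot: L x P allele counts (alt alleles / total genotyped alleles).
// Returns list(post_incl, alpha_mean, beta_mean).
// [[Rcpp::export(name = ".fmodelMcmc")]]
List fmodel_mcmc(IntegerMatrix alt, IntegerMatrix tot, int n_iter,
                 int burnin, double prior_odds, double alpha_sd_prior,
                 double beta_mean_prior, double beta_sd_prior) {
    int L = alt.nrow(), P = alt.ncol();
    std::vector<double> p(L), alpha(L, 0.0), beta(P, beta_mean_prior);
    std::vector<int> incl(L, 0);
    std::vector<double> post_incl(L, 0.0), alpha_sum(L, 0.0);
    std::vector<double> beta_sum(P, 0.0);
    int n_trace = (n_iter - burnin) / 10 + 1;
    NumericMatrix beta_trace(n_trace, P);
    int tr = 0;
    double log_prior_incl = -log1p(prior_odds);          // pi = 1/(1+odds)
    double log_prior_excl = log(prior_odds) - log1p(prior_odds);

    for (int l = 0; l < L; ++l) {
        double a = 1, n = 0;
        for (int j = 0; j < P; ++j) { a += alt(l, j); n += tot(l, j); }
        p[l] = a / (n + 2.0);
        if (p[l] <= 0.001) p[l] = 0.001;
        if (p[l] >= 0.999) p[l] = 0.999;
    }
    int kept = 0;
    for (int it = 0; it < n_iter; ++it) {
        // per-locus updates
        for (int l = 0; l < L; ++l) {
            double ll_cur = locus_loglik(l, alt, tot, p[l], alpha[l], beta);
            // 1. ancestral frequency: logit random walk
            double lp = log(p[l] / (1 - p[l])) + norm_rand() * 0.4;
            double pn = 1.0 / (1.0 + exp(-lp));
            if (pn > 0.001 && pn < 0.999) {
                double ll_new = locus_loglik(l, alt, tot, pn, alpha[l], beta);
                // uniform prior on p; Jacobian of the logit walk
                double lacc = ll_new - ll_cur +
                    log(pn * (1 - pn)) - log(p[l] * (1 - p[l]));
                if (log(unif_rand()) < lacc) { p[l] = pn; ll_cur = ll_new; }
            }
            // 2. alpha random walk when included
            if (incl[l]) {
                double an = alpha[l] + norm_rand() * 0.5;
                double ll_new = locus_loglik(l, alt, tot, p[l], an, beta);
                double lacc = ll_new - ll_cur +
                    R::dnorm(an, 0.0, alpha_sd_prior, 1) -
                    R::dnorm(alpha[l], 0.0, alpha_sd_prior, 1);
                if (log(unif_rand()) < lacc) { alpha[l] = an; ll_cur = ll_new; }
            }
            // 3. reversible jump: propose alpha from its prior
            if (!incl[l]) {
                double an = norm_rand() * alpha_sd_prior;
                double ll_new = locus_loglik(l, alt, tot, p[l], an, beta);
                double lacc = ll_new - ll_cur +
                    log_prior_incl - log_prior_excl;
                if (log(unif_rand()) < lacc) { incl[l] = 1; alpha[l] = an; }
            } else {
                double ll_new = locus_loglik(l, alt, tot, p[l], 0.0, beta);
                double lacc = ll_new - ll_cur +
                    log_prior_excl - log_prior_incl;
                if (log(unif_rand()) < lacc) { incl[l] = 0; alpha[l] = 0.0; }
            }
        }
        // beta updates (one RW step each, full conditional over loci)
        for (int j = 0; j < P; ++j) {
            double bn = beta[j] + norm_rand() * 0.2;
            double ll_cur = 0.0, ll_new = 0.0;
            for (int l = 0; l < L; ++l) {
                int n = tot(l, j);
                if (n == 0) continue;
                double thc = exp(-(alpha[l] + beta[j]));
                double thn = exp(-(alpha[l] + bn));
                double uc = thc * p[l], vc = thc * (1 - p[l]);
                double un = thn * p[l], vn = thn * (1 - p[l]);
                ll_cur += lbeta_(alt(l, j) + uc, n - alt(l, j) + vc) -
                    lbeta_(uc, vc);
                ll_new += lbeta_(alt(l, j) + un, n - alt(l, j) + vn) -
                    lbeta_(un, vn);
            }
            double lacc = ll_new - ll_cur +
                R::dnorm(bn, beta_mean_prior, beta_sd_prior, 1) -
                R::dnorm(beta[j], beta_mean_prior, beta_sd_prior, 1);
            if (log(unif_rand()) < lacc) beta[j] = bn;
        }
        if (it >= burnin) {
            ++kept;
            for (int l = 0; l < L; ++l) {
                post_incl[l] += incl[l];
                alpha_sum[l] += alpha[l];
            }
            for (int j = 0; j < P; ++j) beta_sum[j] += beta[j];
            if ((it - burnin) % 10 == 0 && tr < n_trace) {
                for (int j = 0; j < P; ++j) beta_trace(tr, j) = beta[j];
                ++tr;
            }
        }
    }
    NumericVector pi(L), am(L), bm(P);
    for (int l = 0; l < L; ++l) {
        pi[l] = post_incl[l] / kept;
        am[l] = alpha_sum[l] / kept;
    }
    for (int j = 0; j < P; ++j) bm[j] = beta_sum[j] / kept;
    return List::create(Named("post_incl") = pi,
                        Named("alpha_mean") = am,
                        Named("beta_mean") = bm,
                        Named("beta_trace") =
                            beta_trace(Range(0, tr - 1), _));
}
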