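## standardized population allele-frequency deviations:
## y_jl = (p_hat_jl - pbar_l) / sqrt(pbar_l (1 - pbar_l)), loci x pops,
## restricted to loci polymorphic in the pooled sample
.standardizedFreqs <- function(g) {
    pc <- .popCounts(dosage(g), .popFactor(g))
    p <- pc$alt / (2 * pc$n)
    pbar <- rowSums(pc$alt) / (2 * rowSums(pc$n))
    ok <- pbar > 0 & pbar < 1 & rowSums(!is.finite(p)) == 0
    y <- (p[ok, , drop = FALSE] - pbar[ok]) /
        sqrt(pbar[ok] * (1 - pbar[ok]))
    nbar <- colMeans(pc$n[ok, , drop = FALSE])
    list(y = y, levels = pc$levels, sampling_var = 1 / (2 * nbar),
         kept = rownames(dosage(g))[ok])
}

#' Neutral population allele-frequency covariance
#'
#' Posterior of the populations x populations covariance matrix Omega of
#' standardized allele-frequency deviations under the Gaussian model
#' `y_l = x_l + e_l`, `x_l ~ N(0, Omega)`, `e_l ~ N(0, D)` with `D` the
#' binomial sampling variance, sampled by a Gibbs chain alternating latent
#' frequency deviations (conjugate normal) and Omega (inverse-Wishart).
#' Returns the running posterior mean after burn-in plus thinned draws for
#' downstream runs of the association test. A non-positive-definite running
#' mean gets diagonal jitter, recorded in the result.
#'
#' @param g a [GenotypeData-class] object, ideally the putatively neutral
#'   panel (>= 3 populations, >= 200 loci recommended).
#' @param n_iter MCMC iterations (default 100000).
#' @param burnin burn-in iterations (default `n_iter / 5`).
#' @param n_draws thinned Omega draws to keep (default 50).
#' @param seed integer seed.
#' @return a `pop_cov` list: `omega` (posterior mean), `draws` (list of
#'   Omega draws), `n_iter`, `jittered`.
#' @export
estimatePopCov <- function(g, n_iter = 100000L, burnin = n_iter %/% 5L,
                           n_draws = 50L, seed = 1L) {
    set.seed(seed)
    sf <- .standardizedFreqs(g)
    Y <- sf$y
    L <- nrow(Y); P <- ncol(Y)
    if (P < 3) stop("need >= 3 populations")
    D <- diag(sf$sampling_var, P)
    nu0 <- P + 2
    Psi0 <- diag(1e-3, P)
    Omega <- diag(0.05, P)
    keep_at <- unique(round(seq(burnin + 1, n_iter, length.out = n_draws)))
    draws <- list(); di <- 0L
    mean_acc <- matrix(0, P, P); n_acc <- 0L
    for (it in seq_len(n_iter)) {
        ## latent deviations | Y, Omega
        Sinv <- solve(Omega + D)
        A <- Omega %*% Sinv
        condV <- Omega - A %*% Omega
        condV <- (condV + t(condV)) / 2
        ev <- eigen(condV, symmetric = TRUE)
        rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), P) %*%
            t(ev$vectors)
        X <- Y %*% t(A) + matrix(rnorm(L * P), L, P) %*% rt
        ## Omega | X
        S <- Psi0 + crossprod(X)
        W <- rWishart(1, nu0 + L, solve(S))[, , 1]
        Omega <- solve(W)
        Omega <- (Omega + t(Omega)) / 2
        if (it > burnin) {
            mean_acc <- mean_acc + Omega
            n_acc <- n_acc + 1L
            if (it %in% keep_at) {
                di <- di + 1L
                draws[[di]] <- Omega
            }
        }
    }
    omega <- mean_acc / n_acc
    jittered <- FALSE
    if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
        <= 0) {
        omega <- omega + diag(1e-8, P)
        jittered <- TRUE
    }
    dimnames(omega) <- list(sf$levels, sf$levels)
    structure(list(omega = omega, draws = draws,
                   sampling_var = sf$sampling_var, n_iter = n_iter,
                   jittered = jittered),
              class = "pop_cov")
}

#' Environmental-association Bayes factors
#'
#' For each locus, the Bayes factor of the linear-effect model (mean of the
#' standardized frequency deviations proportional to the standardized
#' covariate, effect size integrated over a Gaussian prior on a quadrature
#' grid) against the covariance-only null `y ~ N(0, Omega + D)`. The test
#' is run `n_runs` times, each with an independent Omega draw from the
#' [estimatePopCov()] posterior; the reported BF is the per-locus median
#' over runs, and significance requires BF > `bf_threshold` in *all* runs.
#'
#' @param g a [GenotypeData-class] object.
#' @param popcov a `pop_cov` from [estimatePopCov()].
#' @param covariate named numeric vector per population (e.g. annual mean
#'   temperature or latitude); standardized internally; constant covariate
#'   is an error.
#' @param n_runs independent runs (default 5).
#' @param seed integer seed (chooses the Omega draws).
#' @param beta_sd prior standard deviation of the effect size on the
#'   standardized-frequency scale (default 0.2). The Bayes factor of a
#'   locus exactly consistent with the null has the floor
#'   `sqrt(1 / (1 + c0 * beta_sd^2))` with `c0` the covariate precision
#'   `z' Sigma^-1 z`; the default keeps that floor inside Jeffreys'
#'   inconclusive band (above 1/3) for typical panel precisions while
#'   leaving essentially full power for latitudinal slopes of order 1.
#' @param n_grid quadrature points (default 61).
#' @param bf_threshold substantial-evidence threshold (default 3).
#' @return `list(bf = median BF per locus, bf_runs = loci x runs matrix,
#'   significant = logical per locus, locus_id =)`.
#' @export
envBayesFactor <- function(g, popcov, covariate, n_runs = 5L, seed = 1L,
                           beta_sd = 0.2, n_grid = 61L, bf_threshold = 3) {
    set.seed(seed)
    sf <- .standardizedFreqs(g)
    z <- covariate[sf$levels]
    if (anyNA(z)) stop("covariate missing for some population")
    if (sd(z) == 0) stop("constant covariate")
    z <- as.numeric(scale(z))
    D <- diag(sf$sampling_var, length(z))
    grid <- seq(-4, 4, length.out = n_grid) * beta_sd
    w <- stats::dnorm(grid, 0, beta_sd)
    w <- w / sum(w)
    draws <- popcov$draws
    if (length(draws) < n_runs)
        draws <- rep(draws, length.out = n_runs)
    use <- sample(seq_along(draws), n_runs)
    bfm <- matrix(NA_real_, nrow(sf$y), n_runs)
    for (rn in seq_len(n_runs)) {
        Sigma <- draws[[use[rn]]] + D
        Sinv <- solve(Sigma)
        c0 <- as.numeric(t(z) %*% Sinv %*% z)
        bhat <- as.numeric(sf$y %*% Sinv %*% z) / c0
        ## BF = sum_i w_i exp(-c0 b_i^2 / 2 + c0 b_i bhat)
        expo <- outer(bhat, grid, function(b, be)
            -c0 * be^2 / 2 + c0 * be * b)
        m <- apply(expo, 1L, max)
        bfm[, rn] <- exp(m) * as.numeric(exp(expo - m) %*% w)
    }
    bf <- apply(bfm, 1L, median)
    sig <- rowSums(bfm > bf_threshold) == n_runs
    list(bf = bf, bf_runs = bfm, significant = sig, locus_id = sf$kept,
         threshold = bf_threshold)
}

#' Loci associated with both temperature and latitude
#'
#' The intersection of the loci significant (BF above threshold in all
#' runs) for the temperature covariate and for the latitude covariate —
#' the consistency rule used to call latitudinal-gradient candidates when
#' the two covariates are nearly collinear.
#'
#' @param bf_temp,bf_lat results of [envBayesFactor()] over the same loci.
#' @return character vector of locus ids.
#' @export
latitudinalCandidates <- function(bf_temp, bf_lat) {
    stopifnot(identical(bf_temp$locus_id, bf_lat$locus_id))
    bf_temp$locus_id[bf_temp$significant & bf_lat$significant]
}

## per-locus WC theta from count matrices, expected-pairing heterozygosity
.thetaPerLocusFromCounts <- function(alt, n) {
    two_n <- 2 * n
    hbar_ind <- alt * (two_n - alt) / (pmax(two_n - 1, 1) * pmax(n, 1))
    N <- n
    Ntot <- rowSums(N)
    r <- rowSums(N > 0)
    p <- alt / (2 * N); p[N == 0] <- 0
    pbar <- rowSums(alt) / (2 * Ntot)
    hbar <- rowSums(hbar_ind * N) / Ntot
    nbar <- Ntot / r
    nc <- (Ntot - rowSums(N^2) / Ntot) / (r - 1)
    dev <- (p - pbar)^2; dev[N == 0] <- 0
    s2 <- rowSums(N * dev) / ((r - 1) * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                            hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    theta <- a / (a + b + cc)
    theta[!(r >= 2 & pbar > 0 & pbar < 1)] <- NA
    list(theta = theta, he = 2 * pbar * (1 - pbar))
}

#' Hierarchical island-model F(ST) outlier test
#'
#' Simulates the joint null distribution of (pooled heterozygosity,
#' per-locus theta) under a hierarchical island model — `n_groups`
#' simulated groups of `demes_per_group` demes each, with within-group and
#' among-group migration rates calibrated so the simulated global theta and
#' among-group differentiation match the observed values — sampling the
#' same deme/group configuration and sample sizes as the data. Each
#' observed locus is placed at its conditional theta quantile given its
#' heterozygosity bin; the high tail (quantile above `threshold` and
#' Benjamini-Hochberg FDR at most `fdr`) flags putative positive selection,
#' the symmetric low tail putative balancing selection.
#'
#' @param g a [GenotypeData-class] object whose populations belong to >= 2
#'   groups (`popMap(g)$group`).
#' @param n_sims simulated null loci (default 50000).
#' @param n_groups,demes_per_group island-universe dimensions (defaults 10
#'   and 100).
#' @param deme_size diploid deme size in the simulated universe.
#' @param threshold conditional-quantile threshold (default 0.995).
#' @param fdr false-discovery-rate cap (default 0.01, Benjamini-Hochberg).
#' @param n_bins heterozygosity bins (default 20).
#' @param n_cal loci per calibration round.
#' @param seed integer seed.
#' @return data.frame per locus: locus_id, he, theta, quantile, p_high,
#'   p_low, fdr_high, fdr_low, flag_positive, flag_balancing; calibration
#'   record in `attr(, "calibration")`.
#' @export
fdistHierOutliers <- function(g, n_sims = 50000L, n_groups = 10L,
                              demes_per_group = 100L, deme_size = 100,
                              threshold = 0.995, fdr = 0.01,
                              n_bins = 20L, n_cal = 3000L, seed = 1L) {
    set.seed(seed)
    pm <- popMap(g)
    groups <- unique(pm$group)
    if (length(groups) < 2) stop("populations must belong to >= 2 groups")
    if (length(groups) > n_groups)
        stop("more observed groups than simulated groups")
    pop <- .popFactor(g)
    pc <- .popCounts(dosage(g), pop)
    obs <- .thetaPerLocusFromCounts(pc$alt, pc$n)
    ## observed targets: global theta and among-group theta
    th_all <- .thetaOf(dosage(g), pm$population)
    grp_pool <- split(unique(pm$population),
                      pm$group[match(unique(pm$population),
                                     pm$population)])
    th_ct <- wcFst(g, pool_groups = grp_pool)$theta
    if (!is.finite(th_all) || th_all <= 0 || !is.finite(th_ct) ||
        th_ct <= 0)
        stop("cannot calibrate: observed differentiation is not positive ",
             "(theta = ", signif(th_all, 3), ", among-group = ",
             signif(th_ct, 3), ")")
    ## sampled configuration: one simulated group per observed group,
    ## one deme per observed population
    pop_group <- pm$group[match(pc$levels, pm$population)]
    s_group <- as.integer(factor(pop_group, levels = groups)) - 1L
    s_deme <- integer(length(pc$levels))
    for (gr in unique(s_group)) {
        ix <- which(s_group == gr)
        s_deme[ix] <- seq_along(ix) - 1L
    }
    lin <- as.integer(round(2 * colMeans(pc$n)))
    simf <- function(mw, ma, L) {
        cnt <- .simIslandCounts(as.integer(L), as.integer(n_groups),
                                as.integer(demes_per_group), deme_size,
                                mw, ma, s_group, s_deme, lin)
        nn <- matrix(rep(lin / 2, each = L), L)
        cnt_list <- list(alt = cnt, n = nn)
        cnt_list
    }
    ## calibration: fixed-point updates on the two migration rates
    mw <- 0.05; ma <- 0.005
    lin_f <- function(f) f / (1 - f)
    cal <- NULL
    for (round in seq_len(6)) {
        s <- simf(mw, ma, n_cal)
        th_s <- .thetaFromCounts(s$alt, s$n,
                                 s$alt * (2 * s$n - s$alt) /
                                     (pmax(2 * s$n - 1, 1) *
                                      pmax(s$n, 1)))
        ## among-group: pool demes by group
        galt <- t(rowsum(t(s$alt), s_group))
        gn <- t(rowsum(t(s$n), s_group))
        th_cs <- .thetaFromCounts(galt, gn,
                                  galt * (2 * gn - galt) /
                                      (pmax(2 * gn - 1, 1) * pmax(gn, 1)))
        if (!is.finite(th_s) || th_s <= 0) th_s <- 1e-4
        if (!is.finite(th_cs) || th_cs <= 0) th_cs <- 1e-4
        ma <- ma * lin_f(min(th_cs, 0.99)) / lin_f(th_ct)
        mw <- mw * lin_f(min(th_s, 0.99)) / lin_f(th_all)
        mw <- min(max(mw, 1e-5), 10); ma <- min(max(ma, 1e-6), 10)
        cal <- rbind(cal, data.frame(round = round, m_within = mw,
                                     m_among = ma, theta_sim = th_s,
                                     theta_ct_sim = th_cs))
    }
    ## null table at the calibrated rates
    s <- simf(mw, ma, n_sims)
    nul <- .thetaPerLocusFromCounts(s$alt, s$n)
    ok_n <- !is.na(nul$theta)
    nt <- nul$theta[ok_n]; nh <- nul$he[ok_n]
    breaks <- unique(quantile(nh, seq(0, 1, length.out = n_bins + 1)))
    breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
    nb <- cut(nh, breaks)
    qtl <- rep(NA_real_, length(obs$theta))
    ob <- cut(obs$he, breaks)
    for (b in levels(nb)) {
        in_b <- which(!is.na(ob) & ob == b & !is.na(obs$theta))
        if (!length(in_b)) next
        pool <- nt[nb == b]
        if (length(pool) < 20) pool <- nt
        F <- ecdf(pool)
        ## mid-quantile to keep ties away from the exact tails
        qtl[in_b] <- (F(obs$theta[in_b]) +
                      F(obs$theta[in_b] - 1e-12)) / 2
    }
    p_high <- 1 - qtl
    p_low <- qtl
    fdr_high <- p.adjust(p_high, "BH")
    fdr_low <- p.adjust(p_low, "BH")
    out <- data.frame(locus_id = rownames(dosage(g)),
                      he = obs$he, theta = obs$theta, quantile = qtl,
                      p_high = p_high, p_low = p_low,
                      fdr_high = fdr_high, fdr_low = fdr_low,
                      flag_positive = !is.na(qtl) & qtl > threshold &
                          fdr_high <= fdr,
                      flag_balancing = !is.na(qtl) & qtl < 1 - threshold &
                          fdr_low <= fdr)
    attr(out, "calibration") <- cal
    attr(out, "rates") <- c(m_within = mw, m_among = ma)
    out
}

#' Bayesian F-model outlier test (reversible-jump MCMC)
#'
#' Decomposes locus-by-population differentiation as
#' `logit(F_ST^(lj)) = alpha_l + beta_j` under a multinomial-Dirichlet
#' (beta-binomial) allele-count likelihood and samples the posterior with
#' a reversible-jump move over inclusion of the locus effects `alpha_l`.
#' The q-value of a locus is the running mean of the posterior error
#' (1 - inclusion probability) down the ranked locus list; outliers are
#' loci with q at most `q_threshold`, classified as positive
#' (`alpha > 0`) or balancing (`alpha < 0`) selection.
#'
#' @param g a [GenotypeData-class] object (>= 2 populations).
#' @param prior_odds prior odds for neutrality (default 10).
#' @param n_iter,burnin chain length and burn-in (defaults 4000 / 1000).
#' @param q_threshold outlier threshold on the q-value (default 0.05).
#' @param seed integer seed.
#' @param alpha_sd,beta_mean,beta_sd priors of the locus and population
#'   effects.
#' @return data.frame per locus: locus_id, post_prob, alpha, q, outlier,
#'   class; `attr(, "beta")` population effects, `attr(, "ess")` effective
#'   sample size of the slowest population effect (a warning below 50).
#' @export
fmodelOutliers <- function(g, prior_odds = 10, n_iter = 4000L,
                           burnin = 1000L, q_threshold = 0.05, seed = 1L,
                           alpha_sd = 2.5, beta_mean = -1, beta_sd = 1.8) {
    set.seed(seed)
    pop <- .popFactor(g)
    if (nlevels(pop) < 2) stop("need >= 2 populations")
    pc <- .popCounts(dosage(g), pop)
    res <- .fmodelMcmc(pc$alt, 2L * pc$n, as.integer(n_iter),
                       as.integer(burnin), prior_odds, alpha_sd,
                       beta_mean, beta_sd)
    pp <- res$post_incl
    ord <- order(pp, decreasing = TRUE)
    q <- numeric(length(pp))
    q[ord] <- cumsum(1 - pp[ord]) / seq_along(pp)
    ess <- apply(res$beta_trace, 2, .essOf)
    if (min(ess) < 50)
        warning("F-model chain mixing is poor (min ESS = ",
                round(min(ess)), "); results flagged")
    out <- data.frame(locus_id = rownames(dosage(g)),
                      post_prob = pp, alpha = res$alpha_mean, q = q,
                      outlier = q <= q_threshold,
                      class = ifelse(q > q_threshold, "none",
                                     ifelse(res$alpha_mean > 0,
                                            "positive", "balancing")))
    attr(out, "beta") <- stats::setNames(res$beta_mean, pc$levels)
    attr(out, "ess") <- ess
    out
}

.essOf <- function(x) {
    n <- length(x)
    if (sd(x) == 0) return(n)
    ac <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    cut <- if (length(pos)) pos[1] - 1 else length(ac)
    n / (1 + 2 * sum(ac[seq_len(cut)]))
}

#' Combine outlier sets and assess stability
#'
#' `combineOutlierSets()` performs the exact set algebra over named locus
#' sets sharing a universe: union size, pairwise intersection counts and
#' per-set sizes. `leaveOneOut()` reruns a scan dropping one population at
#' a time and reports, per replicate, the proportion of the full-data
#' outlier set recovered. `compareWholeReduced()` runs a scan on the whole
#' data and on the data without given individuals (e.g. flagged admixed
#' migrants) and reports the two sets and their overlap.
#'
#' @param sets named list of character vectors of locus ids.
#' @param universe character vector of all locus ids; ids outside it are an
#'   error.
#' @return `combineOutlierSets()`: list with `union`, `sizes`,
#'   `intersections` (named counts `A&B`), `union_size`.
#' @export
combineOutlierSets <- function(sets, universe = NULL) {
    if (!is.null(universe)) {
        for (nm in names(sets)) {
            bad <- setdiff(sets[[nm]], universe)
            if (length(bad))
                stop("set '", nm, "' references unknown loci: ",
                     paste(head(bad, 5), collapse = ", "))
        }
    }
    u <- unique(unlist(sets))
    inter <- list()
    nms <- names(sets)
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
        if (j <= i) next
        inter[[paste0(nms[i], "&", nms[j])]] <-
            length(intersect(sets[[i]], sets[[j]]))
    }
    list(union = u, union_size = length(u),
         sizes = lengths(sets), intersections = unlist(inter))
}

#' @rdname combineOutlierSets
#' @param g a [GenotypeData-class] object.
#' @param test function `g -> character vector of outlier locus ids`.
#' @param always_keep populations never dropped (e.g. the focal admixed
#'   population of a leave-one-out design).
#' @return `leaveOneOut()`: data.frame dropped population, set size,
#'   overlap with the full-data set, stability proportion; full-data set in
#'   `attr(, "full_set")`.
#' @export
leaveOneOut <- function(g, test, always_keep = character(0)) {
    pm <- popMap(g)
    full <- test(g)
    out <- NULL
    for (p in setdiff(unique(pm$population), always_keep)) {
        gi <- g[, pm$population != p]
        si <- test(gi)
        out <- rbind(out, data.frame(
            dropped = p, n_outliers = length(si),
            n_common = length(intersect(si, full)),
            stability = if (length(full))
                length(intersect(si, full)) / length(full) else NA_real_))
    }
    attr(out, "full_set") <- full
    out
}

#' @rdname combineOutlierSets
#' @param drop_individuals individual ids excluded from the reduced run.
#' @return `compareWholeReduced()`: list with `whole`, `reduced`,
#'   `common`, `n_common`.
#' @export
compareWholeReduced <- function(g, drop_individuals, test) {
    whole <- test(g)
    reduced <- test(g[, !(colnames(g) %in% drop_individuals)])
    list(whole = whole, reduced = reduced,
         common = intersect(whole, reduced),
         n_common = length(intersect(whole, reduced)))
}
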