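#' Maximum-likelihood admixture estimation
#'
#' Fits the standard admixture model: individual i's dosage at locus l is
#' Binomial(2, sum_k q_ik * f_kl) with row-stochastic ancestry fractions Q
#' and cluster allele frequencies F in `[0, 1]`. The log-likelihood
#' `sum_il [ g_il log(sum_k q_ik f_kl) + (2 - g_il) log(sum_k q_ik (1 -
#' f_kl)) ]` is maximized by EM over allele-copy responsibilities; missing
#' entries are dropped from the sums. Multiple random restarts keep the best
#' likelihood; the trace is non-decreasing within every restart.
#'
#' @param g a [GenotypeData-class] object (MAF-filtered input recommended).
#' @param K number of ancestral clusters (`1 <= K <=` individuals).
#' @param seed integer seed.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap per restart.
#' @param n_restarts random restarts.
#' @param init optional warm start: `list(Q =, F =)` used as the first
#'   restart's starting point (dimensions must match); remaining restarts
#'   stay random.
#' @return an `ancestry_result` list: `Q` (individuals x K), `F` (K x loci),
#'   `loglik`, `loglik_trace`, `K`, `seed`.
#' @export
fitAdmixture <- function(g, K, seed = 1L, tol = 1e-6, max_iter = 500L,
                         n_restarts = 5L, init = NULL) {
    d <- t(dosage(g))                    # individuals x loci
    n <- nrow(d); L <- ncol(d)
    if (K > n) stop("K exceeds the number of individuals")
    obs <- !is.na(d)
    dz <- d; dz[!obs] <- 0L
    storage.mode(dz) <- "integer"
    two_obs <- matrix(2L * obs, nrow(d), ncol(d))
    storage.mode(two_obs) <- "integer"
    set.seed(seed)
    if (K == 1L) {
        f <- colSums(dz) / pmax(colSums(two_obs), 1L)
        Q <- matrix(1, n, 1, dimnames = list(rownames(d), "K1"))
        ll <- .admixLoglik(dz, two_obs, Q, matrix(f, 1L))
        return(structure(list(Q = Q, F = matrix(f, 1L,
                                  dimnames = list("K1", colnames(d))),
                              loglik = ll, loglik_trace = ll, K = 1L,
                              seed = seed),
                         class = "ancestry_result"))
    }
    emStep <- function(Q, Fm) .admixEmStepC(dz, two_obs, Q, Fm)
    project <- function(th) {
        Q <- matrix(th[seq_len(n * K)], n, K)
        Fm <- matrix(th[-seq_len(n * K)], K, L)
        Q <- pmax(Q, 1e-9); Q <- Q / rowSums(Q)
        Fm <- pmin(pmax(Fm, 1e-6), 1 - 1e-6)
        list(Q = Q, F = Fm)
    }
    flat <- function(st) c(st$Q, st$F)
    best <- NULL
    for (rs in seq_len(n_restarts)) {
        if (rs == 1L && !is.null(init)) {
            Q <- pmax(unname(init$Q), 1e-6); Q <- Q / rowSums(Q)
            Fm <- pmin(pmax(unname(init$F), 1e-6), 1 - 1e-6)
        } else {
            Q <- matrix(rexp(n * K), n, K); Q <- Q / rowSums(Q)
            Fm <- matrix(runif(K * L, 0.05, 0.95), K, L)
        }
        st <- list(Q = Q, F = Fm)
        ll <- .admixLoglik(dz, two_obs, st$Q, st$F)
        trace <- ll
        ## SQUAREM-accelerated EM: each cycle takes two EM steps, forms the
        ## extrapolated iterate, and stabilizes it with one further EM step;
        ## a cycle that fails to improve the likelihood falls back to the
        ## plain double EM step, so the trace is non-decreasing.
        for (it in seq_len(max_iter)) {
            s1 <- emStep(st$Q, st$F)
            s2 <- emStep(s1$Q, s1$F)
            r <- flat(s1) - flat(st)
            v <- flat(s2) - flat(s1) - r
            nv <- sqrt(sum(v^2))
            alpha <- if (nv > 0) max(-sqrt(sum(r^2)) / nv, -32) else -1
            alpha <- min(alpha, -1)
            cand <- project(flat(st) - 2 * alpha * r + alpha^2 * v)
            cand <- emStep(cand$Q, cand$F)
            ll_cand <- .admixLoglik(dz, two_obs, cand$Q, cand$F)
            if (is.finite(ll_cand) && ll_cand >= trace[length(trace)]) {
                st <- cand
                ll_new <- ll_cand
            } else {
                st <- s2
                ll_new <- .admixLoglik(dz, two_obs, st$Q, st$F)
            }
            trace <- c(trace, ll_new)
            if (ll_new - trace[length(trace) - 1] < tol) break
        }
        ll <- trace[length(trace)]
        if (is.null(best) || ll > best$loglik)
            best <- list(Q = st$Q, F = st$F, loglik = ll,
                         loglik_trace = trace)
    }
    rownames(best$Q) <- rownames(d)
    colnames(best$Q) <- paste0("K", seq_len(K))
    rownames(best$F) <- paste0("K", seq_len(K))
    colnames(best$F) <- colnames(d)
    structure(c(best, list(K = K, seed = seed)), class = "ancestry_result")
}

.admixLoglik <- function(dz, two_obs, Q, Fm) {
    dz <- as.matrix(dz); storage.mode(dz) <- "integer"
    two_obs <- as.matrix(two_obs); storage.mode(two_obs) <- "integer"
    .admixLoglikC(dz, two_obs, as.matrix(Q), as.matrix(Fm))
}

#' @export
print.ancestry_result <- function(x, ...) {
    cat(sprintf("ancestry_result: K = %d, %d individuals, %d loci\n",
                x$K, nrow(x$Q), ncol(x$F)))
    cat(sprintf("log-likelihood: %.2f\n", x$loglik))
    invisible(x)
}

#' Cross-validation error over K
#'
#' Masks random folds of non-missing genotype entries, refits the admixture
#' model without them, and scores each masked entry by the squared deviance
#' between the observed dosage and its fitted expectation `2 * sum_k q_ik
#' f_kl`. Reports the mean error per K (root mean squared deviance, the
#' convention of the reference tool) and the K minimizing it; near-ties are
#' visible in the returned table rather than auto-resolved.
#'
#' @param g a [GenotypeData-class] object.
#' @param k_range candidate K values (default 1:12).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed.
#' @param n_restarts random restarts for the full-data fit per K (fold
#'   refits are warm-started and use one).
#' @param ... passed to [fitAdmixture()].
#' @return `list(cv = data.frame(K, cv_error), best_K =)`.
#' @export
cvErrorOverK <- function(g, k_range = 1:12, folds = 5L, seed = 1L,
                         n_restarts = 2L, ...) {
    d <- t(dosage(g))
    obs_idx <- which(!is.na(d))
    set.seed(seed)
    fold_of <- sample(rep_len(seq_len(folds), length(obs_idx)))
    err <- vapply(k_range, function(K) {
        se <- 0; cnt <- 0L
        ## warm start: fit once on the full data, then refit each fold
        ## from that solution (folds differ from the full data in a small
        ## masked subset, so few refinement cycles are needed)
        full <- fitAdmixture(g, K, seed = seed + K,
                             n_restarts = n_restarts, ...)
        for (fd in seq_len(folds)) {
            mask <- obs_idx[fold_of == fd]
            dm <- d
            dm[mask] <- NA
            if (any(colSums(!is.na(dm)) == 0L))
                stop("a fold emptied a locus column; reduce folds")
            gm <- g; SummarizedExperiment::assay(gm, "dosage") <- t(dm)
            fit <- fitAdmixture(gm, K, seed = seed + 1000L * fd + K,
                                init = list(Q = full$Q, F = full$F),
                                n_restarts = 1L, ...)
            pred <- 2 * (fit$Q %*% fit$F)
            se <- se + sum((d[mask] - pred[mask])^2)
            cnt <- cnt + length(mask)
        }
        sqrt(se / cnt)
    }, 0)
    cv <- data.frame(K = k_range, cv_error = err)
    list(cv = cv, best_K = k_range[which.min(err)])
}

#' Population-level ancestry composition
#'
#' Mean ancestry fraction per population (column means of Q within each
#' population).
#'
#' @param fit an `ancestry_result` from [fitAdmixture()].
#' @param popmap population map data.frame covering the fitted individuals.
#' @return populations x K matrix of mean ancestry fractions.
#' @export
populationComposition <- function(fit, popmap) {
    pm <- popmap[match(rownames(fit$Q), popmap$individual), ]
    pops <- unique(pm$population)
    t(vapply(pops, function(p)
        colMeans(fit$Q[pm$population == p, , drop = FALSE]),
        numeric(ncol(fit$Q))))
}

#' Label clusters by river-system group and flag alien individuals
#'
#' `labelClustersByGroup()` assigns each ancestry cluster the sampling group
#' whose individuals carry most of it (majority vote by mean ancestry); a
#' tie is a hard error requesting manual labels. `flagAlienIndividuals()`
#' returns the individuals whose summed ancestry from clusters *not*
#' labelled with their own population's native group is strictly greater
#' than `threshold`.
#'
#' @param fit an `ancestry_result`.
#' @param popmap population map data.frame.
#' @param native_groups optional character vector of group labels counted as
#'   native for the focal population (defaults to each individual's own
#'   group).
#' @param threshold alien-ancestry threshold (default 0.5, strict).
#' @param population restrict flagging to one population (default: all).
#' @return `labelClustersByGroup()`: named character vector cluster ->
#'   group. `flagAlienIndividuals()`: data.frame of flagged individuals
#'   with their alien-ancestry fraction.
#' @export
labelClustersByGroup <- function(fit, popmap) {
    pm <- popmap[match(rownames(fit$Q), popmap$individual), ]
    groups <- unique(pm$group)
    share <- vapply(groups, function(gr)
        colMeans(fit$Q[pm$group == gr, , drop = FALSE]),
        numeric(ncol(fit$Q)))
    if (is.null(dim(share))) share <- matrix(share, nrow = 1)
    lab <- character(ncol(fit$Q))
    for (k in seq_len(ncol(fit$Q))) {
        s <- share[k, ]
        top <- which(s == max(s))
        if (length(top) > 1)
            stop("ambiguous cluster labelling (tie between ",
                 paste(groups[top], collapse = ", "),
                 "); provide labels manually")
        lab[k] <- groups[top]
    }
    stats::setNames(lab, colnames(fit$Q))
}

#' @rdname labelClustersByGroup
#' @export
flagAlienIndividuals <- function(fit, popmap, native_groups = NULL,
                                 threshold = 0.5, population = NULL) {
    pm <- popmap[match(rownames(fit$Q), popmap$individual), ]
    cluster_group <- labelClustersByGroup(fit, popmap)
    keep <- if (is.null(population)) rep(TRUE, nrow(pm)) else
        pm$population %in% population
    out <- NULL
    for (i in which(keep)) {
        native <- if (is.null(native_groups)) pm$group[i] else native_groups
        alien <- sum(fit$Q[i, !(cluster_group %in% native)])
        if (alien > threshold)
            out <- rbind(out, data.frame(individual = pm$individual[i],
                                         population = pm$population[i],
                                         alien_ancestry = alien))
    }
    if (is.null(out))
        out <- data.frame(individual = character(0),
                          population = character(0),
                          alien_ancestry = numeric(0))
    out
}
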