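## Weir-Cockerham variance components per locus.
## d: loci x individuals dosage; pop: factor. Returns data.frame(a, b, c);
## NA rows where < 2 populations have data or the pooled sample is
## monomorphic.
.wcComponents <- function(d, pop) {
    pc <- .popCounts(d, pop)
    N <- pc$n
    Ntot <- rowSums(N)
    r <- rowSums(N > 0)
    p <- pc$alt / (2 * N)
    pbar <- rowSums(pc$alt) / (2 * Ntot)
    hbar <- rowSums(pc$het) / Ntot
    nbar <- Ntot / r
    nc <- (Ntot - rowSums(N^2) / Ntot) / (r - 1)
    dev <- (p - pbar)^2
    dev[N == 0] <- 0
    s2 <- rowSums(N * dev) / ((r - 1) * nbar)
    a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
             (nbar - 1))
    b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    bad <- r < 2 | pbar <= 0 | pbar >= 1 | nbar <= 1 | !is.finite(nc) |
        nc <= 0
    a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
    data.frame(a = a, b = b, c = cc, row.names = rownames(d))
}

#' Weir-Cockerham F(ST)
#'
#' Per-locus Weir-Cockerham variance components (a: among populations, b:
#' among individuals within populations, c: within individuals) and the
#' multi-locus estimator computed as the ratio of sums
#' `theta = sum(a) / sum(a + b + c)`. Loci monomorphic across the pooled
#' sample, or with fewer than two populations carrying data, are excluded.
#'
#' @param g a [GenotypeData-class] object.
#' @param pops optional character vector restricting to a subset of
#'   populations.
#' @param pool_groups optional named list mapping new pooled labels to
#'   vectors of population names; individuals are relabelled before
#'   estimation (used e.g. to compare two river systems as two units).
#' @return `list(theta = multi-locus estimate, per_locus = data.frame(a, b,
#'   c, theta))`.
#' @export
wcFst <- function(g, pops = NULL, pool_groups = NULL) {
    pm <- popMap(g)
    lab <- pm$population
    if (!is.null(pool_groups)) {
        lab <- rep(NA_character_, length(lab))
        for (nm in names(pool_groups))
            lab[pm$population %in% pool_groups[[nm]]] <- nm
        keep_ind <- !is.na(lab)
        g <- g[, keep_ind]; lab <- lab[keep_ind]
    } else if (!is.null(pops)) {
        keep_ind <- pm$population %in% pops
        g <- g[, keep_ind]; lab <- lab[keep_ind]
    }
    if (length(unique(lab)) < 2)
        stop("F(ST) needs at least two populations")
    comp <- .wcComponents(dosage(g), factor(lab, levels = unique(lab)))
    tot <- comp$a + comp$b + comp$c
    comp$theta <- ifelse(!is.na(tot) & tot != 0, comp$a / tot, NA_real_)
    ok <- !is.na(tot)
    list(theta = sum(comp$a[ok]) / sum(tot[ok]), per_locus = comp)
}

#' Per-population diversity statistics
#'
#' For each population: mean observed heterozygosity (fraction of
#' heterozygotes among genotyped individuals), mean unbiased expected
#' heterozygosity `2*p*(1-p) * 2n/(2n-1)`, and mean per-variant-site
#' nucleotide diversity (the average proportion of differing allele pairs
#' among the `2n` sampled alleles, which equals the unbiased expected
#' heterozygosity at a biallelic site). Means are over loci variant in the
#' population with at least `min_n` genotyped individuals there.
#'
#' @param g a [GenotypeData-class] object.
#' @param min_n minimum genotyped individuals per population per locus
#'   (default 2).
#' @return data.frame with columns population, n_individuals, n_variant,
#'   H_O, H_E, Pi.
#' @export
perPopDiversity <- function(g, min_n = 2L) {
    pop <- .popFactor(g)
    if (any(table(pop) == 0)) stop("empty population")
    pc <- .popCounts(dosage(g), pop)
    p <- pc$alt / (2 * pc$n)
    two_n <- 2 * pc$n
    he <- 2 * p * (1 - p) * two_n / (two_n - 1)
    ho <- pc$het / pc$n
    usable <- pc$n >= min_n
    variant <- usable & pc$alt > 0 & pc$alt < two_n
    out <- data.frame(
        population = pc$levels,
        n_individuals = as.integer(table(pop)[pc$levels]),
        n_variant = colSums(variant),
        H_O = vapply(seq_along(pc$levels), function(j)
            mean(ho[variant[, j], j]), 0),
        H_E = vapply(seq_along(pc$levels), function(j)
            mean(he[variant[, j], j]), 0),
        Pi = vapply(seq_along(pc$levels), function(j)
            mean(he[variant[, j], j]), 0))
    rownames(out) <- NULL
    out
}

.newDistanceMatrix <- function(m, kind) {
    stopifnot(isSymmetric(unname(m)))
    diag(m) <- 0
    attr(m, "kind") <- kind
    m
}

#' Pairwise F(ST) with permutation tests
#'
#' Observed pairwise multi-locus Weir-Cockerham theta for every population
#' pair, with significance from permuting individuals between the two
#' populations: `p = (1 + #(theta_perm >= theta_obs)) / (n_perm + 1)`.
#' Bonferroni significance flags use `alpha / n_pairs`.
#'
#' @param g a [GenotypeData-class] object.
#' @param n_perm permutations per pair (default 10000; a warning below 100).
#' @param seed integer seed.
#' @param alpha family significance level for the Bonferroni flags.
#' @return list with `fst` (distance matrix, kind `"fst"`), `p` (p-value
#'   matrix), `significant` (logical Bonferroni flags).
#' @export
pairwiseFstTest <- function(g, n_perm = 10000L, seed = 1L, alpha = 0.05) {
    if (n_perm < 100) warning("fewer than 100 permutations")
    set.seed(seed)
    pm <- popMap(g)
    pops <- unique(pm$population)
    P <- length(pops)
    if (P < 2) stop("need >= 2 populations")
    fst <- p <- matrix(0, P, P, dimnames = list(pops, pops))
    d <- dosage(g)
    n_pairs <- P * (P - 1) / 2
    for (i in seq_len(P - 1)) for (j in seq((i + 1), P)) {
        idx <- which(pm$population %in% pops[c(i, j)])
        dd <- d[, idx, drop = FALSE]
        lab <- pm$population[idx]
        obs <- .thetaOf(dd, lab)
        cnt <- 0L
        for (b in seq_len(n_perm))
            if (.thetaOf(dd, sample(lab)) >= obs) cnt <- cnt + 1L
        fst[i, j] <- fst[j, i] <- obs
        p[i, j] <- p[j, i] <- (1 + cnt) / (n_perm + 1)
    }
    sig <- p < alpha / n_pairs
    diag(sig) <- FALSE
    list(fst = .newDistanceMatrix(fst, "fst"), p = p, significant = sig)
}

.thetaOf <- function(d, lab) {
    comp <- .wcComponents(d, factor(lab))
    tot <- comp$a + comp$b + comp$c
    ok <- !is.na(tot)
    sum(comp$a[ok]) / sum(tot[ok])
}

#' Effective gene flow from F(ST)
#'
#' Island-model approximation `F(ST) = 1 / (4 Nm + 1)`, inverted to
#' `Nm = (1/F(ST) - 1) / 4`. Non-positive F(ST) has no defined Nm and
#' returns `NA` with a warning.
#'
#' @param fst F(ST) value(s) in (0, 1).
#' @return Nm value(s).
#' @export
nmFromFst <- function(fst) {
    out <- rep(NA_real_, length(fst))
    ok <- !is.na(fst) & fst > 0 & fst < 1
    out[ok] <- (1 / fst[ok] - 1) / 4
    if (any(!ok & !is.na(fst)))
        warning("Nm undefined for F(ST) outside (0, 1); returned NA")
    out
}

#' Linearized F(ST) distance
#'
#' Elementwise `fst / (1 - fst)`, the genetic-distance form used for
#' isolation-by-distance regressions. Monotone increasing in F(ST);
#' errors on `fst = 1`.
#'
#' @param fst a distance matrix of kind `"fst"` (or any numeric matrix).
#' @return a distance matrix of kind `"linearized_fst"`.
#' @export
linearizedFst <- function(fst) {
    if (any(fst >= 1)) stop("fst = 1 cannot be linearized")
    .newDistanceMatrix(fst / (1 - fst), "linearized_fst")
}

#' Geographic distance between sampling sites
#'
#' Great-circle (haversine) distance in km between site coordinates, in the
#' site-table population order. Planar (equirectangular) distance is
#' available with `method = "planar"` for comparison.
#'
#' @param site_table a site table (see [validateSiteTable()]).
#' @param method `"greatcircle"` (default) or `"planar"`.
#' @return a distance matrix of kind `"geographic_km"`.
#' @export
geographicDistance <- function(site_table, method = c("greatcircle",
                                                      "planar")) {
    method <- match.arg(method)
    st <- validateSiteTable(site_table)
    xy <- as.matrix(st[, c("longitude", "latitude")])
    P <- nrow(st)
    m <- matrix(0, P, P, dimnames = list(st$population, st$population))
    for (i in seq_len(P)) for (j in seq_len(P)) {
        if (i == j) next
        m[i, j] <- if (method == "greatcircle")
            geosphere::distHaversine(xy[i, ], xy[j, ]) / 1000
        else {
            dlat <- (xy[i, 2] - xy[j, 2]) * 111.32
            dlon <- (xy[i, 1] - xy[j, 1]) * 111.32 *
                cos(mean(xy[c(i, j), 2]) * pi / 180)
            sqrt(dlat^2 + dlon^2)
        }
    }
    .newDistanceMatrix(m, "geographic_km")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with a one-sided
#' (positive-association) permutation p-value from simultaneous row/column
#' permutation of the second matrix. Reports `R2 = r^2` alongside r.
#'
#' @param distA,distB square symmetric matrices over the same populations in
#'   the same order (n >= 4).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return `list(r =, R2 =, p =, n_perm =)`.
#' @export
mantelTest <- function(distA, distB, n_perm = 9999L, seed = 1L) {
    stopifnot(nrow(distA) == nrow(distB), nrow(distA) >= 4)
    set.seed(seed)
    low <- lower.tri(distA)
    a <- distA[low]
    if (sd(a) == 0 || sd(distB[low]) == 0)
        stop("Mantel r undefined for a constant distance matrix")
    r_obs <- cor(a, distB[low])
    n <- nrow(distB)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
        ix <- sample.int(n)
        if (cor(a, distB[ix, ix][low]) >= r_obs) cnt <- cnt + 1L
    }
    list(r = r_obs, R2 = r_obs^2, p = (1 + cnt) / (n_perm + 1),
         n_perm = n_perm)
}

#' Nei's standard genetic distance
#'
#' `D = -ln( J_XY / sqrt(J_X * J_Y) )` with the gene-identity terms `J`
#' summed over loci and alleles (biallelic: `p^2 + q^2` within, `p1*p2 +
#' q1*q2` between) before taking the ratio. Identical allele frequencies
#' give D = 0; `J_XY = 0` (fixed opposite alleles everywhere) is an error.
#'
#' @param g a [GenotypeData-class] object.
#' @return a distance matrix of kind `"nei_standard"`.
#' @export
neiDistance <- function(g) {
    pc <- .popCounts(dosage(g), .popFactor(g))
    neiFromCounts(pc$alt, pc$n, pc$levels)
}

## Nei D from alt-allele counts and sample sizes (shared with the ABC
## summary statistics)
neiFromCounts <- function(alt, n, levels) {
    p <- alt / (2 * n)
    P <- ncol(p)
    ok <- rowSums(!is.finite(p)) == 0
    p <- p[ok, , drop = FALSE]
    J <- crossprod(p) + crossprod(1 - p)   # sums over loci of pi*pj + qi*qj
    m <- matrix(0, P, P, dimnames = list(levels, levels))
    for (i in seq_len(P)) for (j in seq_len(P)) {
        if (i == j) next
        if (J[i, j] <= 0) stop("J_XY = 0: Nei distance infinite")
        m[i, j] <- -log(J[i, j] / sqrt(J[i, i] * J[j, j]))
    }
    .newDistanceMatrix(pmax(m, 0), "nei_standard")
}

#' Neighbour-joining tree with bootstrap over loci
#'
#' Builds the NJ tree on Nei's standard distance between populations and
#' attaches bipartition support from `n_boot` locus-bootstrap replicates
#' (fraction of replicate trees containing each internal bipartition).
#'
#' @param g a [GenotypeData-class] object with >= 3 populations.
#' @param n_boot bootstrap replicates over loci (default 1000).
#' @param seed integer seed.
#' @return an [ape::phylo] tree; node labels carry bootstrap proportions.
#' @export
njTree <- function(g, n_boot = 1000L, seed = 1L) {
    set.seed(seed)
    D <- neiDistance(g)
    if (nrow(D) < 3) stop("need >= 3 populations for a tree")
    tree <- ape::nj(as.dist(D))
    if (n_boot > 0) {
        d <- dosage(g)
        pop <- .popFactor(g)
        boots <- vector("list", n_boot)
        for (b in seq_len(n_boot)) {
            ix <- sample.int(nrow(d), replace = TRUE)
            pc <- .popCounts(d[ix, , drop = FALSE], pop)
            boots[[b]] <- ape::nj(as.dist(neiFromCounts(pc$alt, pc$n,
                                                        pc$levels)))
        }
        cl <- ape::prop.clades(tree, boots, rooted = FALSE)
        cl[is.na(cl)] <- 0L
        tree$node.label <- cl / n_boot
    }
    tree
}

#' PCA of genotypes with allele-frequency normalization
#'
#' Columns (loci) are mean-centred and scaled by `sqrt(p*(1-p))` with `p`
#' the pooled alternate-allele frequency; missing entries are mean-imputed
#' (zero after centring) before the decomposition. Zero-variance loci are
#' dropped with a warning.
#'
#' @param g a [GenotypeData-class] object.
#' @param n_comp number of leading components to return.
#' @return `list(coords = individuals x components, eigenvalues =,
#'   dropped_loci =)`. Eigenvalues are non-increasing and coordinates are
#'   projections on the corresponding eigenvectors.
#' @export
pcaGenotypes <- function(g, n_comp = 10L) {
    d <- t(dosage(g))          # individuals x loci
    n <- colSums(!is.na(d))
    p <- colSums(d, na.rm = TRUE) / (2 * n)
    keep <- is.finite(p) & p > 0 & p < 1
    if (any(!keep))
        warning(sum(!keep), " zero-variance loci dropped before PCA")
    d <- d[, keep, drop = FALSE]; p <- p[keep]
    x <- sweep(d, 2L, 2 * p, "-")
    x <- sweep(x, 2L, sqrt(p * (1 - p)), "/")
    x[is.na(x)] <- 0
    n_comp <- min(n_comp, nrow(x) - 1L, ncol(x))
    sv <- svd(x, nu = n_comp, nv = 0)
    coords <- sv$u %*% diag(sv$d[seq_len(n_comp)], n_comp)
    rownames(coords) <- rownames(x)
    colnames(coords) <- paste0("PC", seq_len(n_comp))
    list(coords = coords,
         eigenvalues = sv$d[seq_len(n_comp)]^2 / nrow(x),
         dropped_loci = sum(!keep))
}
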