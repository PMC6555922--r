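## small fixtures shared across tests; everything is generated in code

## a hand-sized GenotypeData: `pops` named vector population -> n
makeGenotypes <- function(dosage, pops, loci = NULL, site = NULL) {
    pm <- data.frame(
        individual = colnames(dosage),
        population = rep(names(pops), pops),
        group = rep(names(pops), pops),
        native = TRUE)
    GenotypeData(dosage, popmap = pm, loci = loci, site_table = site)
}

## dosage matrix (loci x individuals) drawn from per-population frequencies
## freq: loci x pops matrix
dosageFromFreq <- function(freq, n_per_pop) {
    P <- ncol(freq)
    d <- NULL
    for (j in seq_len(P))
        d <- cbind(d, matrix(rbinom(nrow(freq) * n_per_pop, 2,
                                    rep(freq[, j], n_per_pop)),
                             nrow(freq)))
    rownames(d) <- sprintf("L%04d", seq_len(nrow(d)))
    colnames(d) <- sprintf("i%03d", seq_len(ncol(d)))
    d
}

## star-topology Balding-Nichols design over `P` populations
starDesign <- function(P, c_drift, n, lat = NULL) {
    if (is.null(lat)) lat <- seq(20, 45, length.out = P)
    simulationDesign(
        pops = data.frame(population = paste0("P", seq_len(P)),
                          group = paste0("g", seq_len(P)),
                          native = TRUE, latitude = lat, longitude = 110,
                          n = n),
        branches = data.frame(node = paste0("P", seq_len(P)),
                              parent = NA, c = c_drift))
}

## Weir-Cockerham theta via the allele-level nested ANOVA mean squares --
## an independent oracle for the variance-components implementation
thetaAnovaOracle <- function(d, pop) {
    pop <- as.factor(pop)
    per_locus <- t(vapply(seq_len(nrow(d)), function(l) {
        x <- d[l, ]
        ok <- !is.na(x)
        x <- x[ok]; pp <- droplevels(pop[ok])
        ni <- as.numeric(table(pp))
        if (length(ni) < 2 || any(ni < 1)) return(c(NA, NA))
        r <- length(ni)
        n_tot <- sum(ni)
        p_i <- tapply(x, pp, sum) / (2 * ni)
        pbar <- sum(x) / (2 * n_tot)
        if (pbar <= 0 || pbar >= 1) return(c(NA, NA))
        ## allele-level sums of squares (2 alleles per individual)
        ## within individuals
        SSG <- sum(x * (2 - x) / 2)
        ## among individuals within populations
        SSI <- 2 * sum((x / 2 - p_i[as.integer(pp)])^2)
        ## among populations
        SSP <- 2 * sum(ni * (p_i - pbar)^2)
        MSG <- SSG / n_tot
        MSI <- SSI / (n_tot - r)
        MSP <- SSP / (r - 1)
        nc <- (n_tot - sum(ni^2) / n_tot) / (r - 1)
        s2G <- MSG
        s2I <- (MSI - MSG) / 2
        s2P <- (MSP - MSI) / (2 * nc)
        c(s2P, s2P + s2I + s2G)
    }, numeric(2)))
    ok <- !is.na(per_locus[, 1])
    sum(per_locus[ok, 1]) / sum(per_locus[ok, 2])
}

## exact HWE p by Monte-Carlo pairing of the allele vector -- an
## independent oracle for the enumeration test
hwePairingOracle <- function(n_het, n_a, n, B = 200000) {
    alleles <- c(rep(1L, n_a), rep(0L, 2 * n - n_a))
    hets <- replicate(B, {
        a <- sample(alleles)
        sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    })
    pmf <- table(hets) / B
    p_obs <- pmf[as.character(n_het)]
    sum(pmf[pmf <= as.numeric(p_obs) * (1 + 1e-7)])
}

## haversine distance oracle (pure trig, independent of geosphere)
haversineOracle <- function(lat1, lon1, lat2, lon2, R = 6378137) {
    to_rad <- pi / 180
    dlat <- (lat2 - lat1) * to_rad
    dlon <- (lon2 - lon1) * to_rad
    a <- sin(dlat / 2)^2 +
        cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
    2 * R * asin(sqrt(a)) / 1000
}

## match estimated Q columns to truth columns by best permutation (K <= 3)
bestQRmse <- function(Q, Qt) {
    K <- ncol(Q)
    perms <- switch(K,
                    list(1L),
                    list(1:2, 2:1),
                    list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                         c(3, 1, 2), c(3, 2, 1)))
    min(vapply(perms, function(pp) sqrt(mean((Q[, pp] - Qt)^2)), 0))
}

## a two-group fixture with loci spread along scaffolds
windowFixture <- function(n_loci, scaffolds, scaffold_len, c_drift = 0.1,
                          seed = 71, elevated = NULL,
                          elevated_factor = 8) {
    set.seed(seed)
    freqA <- runif(n_loci, 0.2, 0.8)
    drift <- rep(c_drift, n_loci)
    if (!is.null(elevated)) drift[elevated] <- c_drift * elevated_factor
    cc <- pmin(drift, 0.95)
    freqB <- rbeta(n_loci, freqA * (1 - cc) / cc,
                   (1 - freqA) * (1 - cc) / cc)
    d <- cbind(dosageFromFreq(cbind(freqA), 25),
               dosageFromFreq(cbind(freqB), 25))
    colnames(d) <- paste0("i", seq_len(ncol(d)))
    loci <- data.frame(locus_id = rownames(d),
                       tag_id = rownames(d),
                       scaffold = rep(scaffolds,
                                      each = ceiling(n_loci /
                                                     length(scaffolds)))[
                                          seq_len(n_loci)],
                       position = 0)
    for (sc in scaffolds) {
        k <- sum(loci$scaffold == sc)
        loci$position[loci$scaffold == sc] <-
            sort(sample.int(scaffold_len, k))
    }
    makeGenotypes(d, c(A = 25, B = 25), loci = loci)
}

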