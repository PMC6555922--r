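#' Per-population call-rate filter
#'
#' A locus is kept iff in *every* population the fraction of non-missing
#' genotypes is strictly greater than `min_prop` (a population sitting
#' exactly at the threshold removes the locus).
#'
#' @param g a [GenotypeData-class] object.
#' @param min_prop call-rate threshold (default 0.7).
#' @return the filtered [GenotypeData-class].
#' @family locus filters
#' @export
filterCallRate <- function(g, min_prop = 0.7) {
    pop <- .popFactor(g)
    if (any(table(pop) == 0)) stop("population of size 0")
    pc <- .popCounts(dosage(g), pop)
    sizes <- as.integer(table(pop)[pc$levels])
    rate <- sweep(pc$n, 2L, sizes, "/")
    keep <- rowSums(rate > min_prop) == length(sizes)
    g[keep, ]
}

#' Observed heterozygosity per locus
#'
#' Fraction of heterozygotes among genotyped individuals, across all
#' populations pooled.
#'
#' @param g a [GenotypeData-class] object.
#' @return numeric vector (NA where no individual is genotyped).
#' @export
observedHet <- function(g) {
    d <- dosage(g)
    het <- rowSums(d == 1L, na.rm = TRUE)
    n <- rowSums(!is.na(d))
    ifelse(n > 0, het / n, NA_real_)
}

#' Paralogous-tag filter
#'
#' Removes a whole RAD tag (all its SNPs) when any SNP on the tag looks
#' paralogous: more than two alleles, or observed heterozygosity above
#' `max_ho` across all genotyped individuals. Both are independent signals
#' of collapsed paralogues, so the default combines them with OR; the
#' literal conjunction (both at once) is available with
#' `rule = "and"`.
#'
#' @param g a [GenotypeData-class] object.
#' @param max_ho observed-heterozygosity ceiling (default 0.5, strict).
#' @param rule `"or"` (default) or `"and"`.
#' @return the filtered [GenotypeData-class].
#' @family locus filters
#' @export
filterParalogTags <- function(g, max_ho = 0.5, rule = c("or", "and")) {
    rule <- match.arg(rule)
    li <- locusInfo(g)
    ho <- observedHet(g)
    multi <- li$n_alleles > 2L
    high <- !is.na(ho) & ho > max_ho
    bad_snp <- if (rule == "or") multi | high else multi & high
    bad_tags <- unique(li$tag_id[bad_snp])
    g[!(li$tag_id %in% bad_tags), ]
}

#' Keep only the first SNP of each RAD tag
#'
#' Retains, per tag, the SNP with the lowest coordinate (ties broken by
#' locus id for determinism). Idempotent.
#'
#' @param g a [GenotypeData-class] object.
#' @return the thinned [GenotypeData-class].
#' @family locus filters
#' @export
thinFirstSnpPerTag <- function(g) {
    li <- locusInfo(g)
    ord <- order(li$tag_id, li$position, li$locus_id)
    first <- !duplicated(li$tag_id[ord])
    keep_ids <- li$locus_id[ord][first]
    g[rownames(g) %in% keep_ids, ]
}

#' Exact Hardy-Weinberg test by enumeration
#'
#' Probability of the observed heterozygote count under the Levene/Haldane
#' distribution of heterozygote counts conditional on allele counts,
#' two-sided: p is the sum of probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed one. Monomorphic
#' samples give p = 1.
#'
#' @param n_het observed heterozygote count(s).
#' @param n_a minor (or either) allele count(s) among the `2n` alleles.
#' @param n number(s) of genotyped diploids.
#' @return vector of exact p-values.
#' @export
hweExactP <- function(n_het, n_a, n) {
    mapply(function(h, na, nn) {
        if (nn == 0L || na == 0L || na == 2L * nn) return(1)
        na <- min(na, 2L * nn - na)
        hs <- seq(na %% 2L, na, by = 2L)
        ## P(h | n, na) ∝ n! / (nAA! h! naa!) * 2^h with nAA=(na-h)/2
        lp <- lgamma(nn + 1) - lgamma((na - hs) / 2 + 1) -
            lgamma(hs + 1) - lgamma(nn - (na + hs) / 2 + 1) +
            hs * log(2)
        pr <- exp(lp - max(lp))
        pr <- pr / sum(pr)
        obs <- pr[match(h, hs)]
        if (is.na(obs)) stop("impossible heterozygote count")
        sum(pr[pr <= obs * (1 + 1e-9)])
    }, n_het, n_a, n)
}

#' Per-population exact HWE filter
#'
#' Computes the exact HWE p-value ([hweExactP()]) for each locus in each
#' population and removes loci deviating at level `alpha`. `scope = "any"`
#' (default) removes a locus significant in at least one population — the
#' reading that purges null-allele tags most aggressively; `scope = "one"`
#' removes loci significant in exactly one population.
#'
#' @param g a [GenotypeData-class] object.
#' @param alpha significance level (default 0.01).
#' @param scope `"any"` or `"one"`.
#' @return the filtered [GenotypeData-class].
#' @family locus filters
#' @export
hweExactFilter <- function(g, alpha = 0.01, scope = c("any", "one")) {
    scope <- match.arg(scope)
    p <- hwePerPopulation(g)
    n_sig <- rowSums(p < alpha, na.rm = TRUE)
    keep <- if (scope == "any") n_sig == 0L else n_sig != 1L
    g[keep, ]
}

#' @rdname hweExactFilter
#' @return for `hwePerPopulation()`: a loci x populations matrix of exact
#'   p-values (1 where a population is monomorphic at the locus).
#' @export
hwePerPopulation <- function(g) {
    pc <- .popCounts(dosage(g), .popFactor(g))
    P <- length(pc$levels)
    out <- matrix(NA_real_, nrow(pc$alt), P,
                  dimnames = list(rownames(dosage(g)), pc$levels))
    ## memoise over distinct (n, n_a, het) triples
    key <- paste(as.vector(pc$n), as.vector(pc$alt), as.vector(pc$het))
    uk <- !duplicated(key)
    pv <- hweExactP(as.vector(pc$het)[uk], as.vector(pc$alt)[uk],
                    as.vector(pc$n)[uk])
    out[] <- pv[match(key, key[uk])]
    out
}

#' Pooled minor-allele-frequency filter
#'
#' Keeps loci whose pooled minor allele frequency is strictly greater than
#' `threshold`; missing genotypes are excluded from the allele counts.
#' Monomorphic loci (MAF 0) are always removed.
#'
#' @param g a [GenotypeData-class] object.
#' @param threshold MAF threshold (default 0.05).
#' @return the filtered [GenotypeData-class].
#' @family locus filters
#' @export
filterMaf <- function(g, threshold = 0.05) {
    maf <- pooledMaf(g)
    g[!is.na(maf) & maf > threshold, ]
}

#' @rdname filterMaf
#' @return for `pooledMaf()`: the vector of pooled minor allele frequencies.
#' @export
pooledMaf <- function(g) {
    d <- dosage(g)
    alt <- rowSums(d, na.rm = TRUE)
    n2 <- 2 * rowSums(!is.na(d))
    p <- ifelse(n2 > 0, alt / n2, NA_real_)
    pmin(p, 1 - p)
}

#' Overall-missingness filter
#'
#' Keeps loci whose overall fraction of missing calls is at most `cutoff`.
#'
#' @param g a [GenotypeData-class] object.
#' @param cutoff missingness cutoff (default 0.05; kept when `<=`).
#' @return the filtered [GenotypeData-class].
#' @family locus filters
#' @export
filterMissingFraction <- function(g, cutoff = 0.05) {
    miss <- rowMeans(is.na(dosage(g)))
    g[miss <= cutoff, ]
}

#' Greedy LD pruning on genotype correlation
#'
#' Scans loci in genome order (scaffold, position) and drops a candidate
#' locus when its squared genotype correlation with any previously kept
#' locus within `window_bp` on the same scaffold reaches `r2_max`. Pairs
#' involving a zero-variance locus have r^2 defined as 0. The kept set
#' therefore never contains a within-window pair at or above the threshold.
#'
#' @param g a [GenotypeData-class] object.
#' @param r2_max drop threshold on r^2 (default 0.05; dropped when `>=`).
#' @param window_bp comparison window in bp (default 500000); `Inf` compares
#'   against every kept locus on the same scaffold.
#' @return the pruned [GenotypeData-class].
#' @family locus filters
#' @export
ldPrune <- function(g, r2_max = 0.05, window_bp = 5e5) {
    li <- locusInfo(g)
    ord <- order(li$scaffold, li$position)
    d <- dosage(g)[ord, , drop = FALSE]
    sc <- li$scaffold[ord]; pos <- li$position[ord]
    L <- nrow(d)
    keep <- logical(L)
    kept_idx <- integer(0)
    for (i in seq_len(L)) {
        cand <- kept_idx[sc[kept_idx] == sc[i] &
                         pos[i] - pos[kept_idx] <= window_bp]
        ok <- TRUE
        if (length(cand)) {
            r2 <- vapply(cand, function(k) {
                cc <- suppressWarnings(cor(d[i, ], d[k, ],
                                           use = "pairwise.complete.obs"))
                if (is.na(cc)) 0 else cc^2
            }, 0)
            ok <- all(r2 < r2_max)
        }
        if (ok) { keep[i] <- TRUE; kept_idx <- c(kept_idx, i) }
    }
    g[rownames(g) %in% rownames(d)[keep], ]
}

#' Run the SNP quality-filter cascade
#'
#' Applies, in order: per-population call rate, paralogous-tag removal, one
#' SNP per tag, per-population exact HWE; optionally (for the marker subset
#' feeding demographic inference) pooled MAF, overall missingness and LD
#' pruning. Emits a per-stage report whose counts always satisfy
#' `loci_out = loci_in - removed` and compose across stages.
#'
#' @param g a [GenotypeData-class] object.
#' @param config a [runConfig()].
#' @param abc_subset also apply the MAF/missingness/LD stages (default
#'   FALSE).
#' @return `list(genotypes =, report =)` with `report` a data.frame of
#'   stage, loci_in, removed, loci_out and the parameter used.
#' @export
runFilterCascade <- function(g, config = runConfig(), abc_subset = FALSE) {
    stages <- list(
        list(name = "call_rate", fn = function(x)
            filterCallRate(x, config$min_call_rate),
            par = config$min_call_rate),
        list(name = "paralog_tags", fn = filterParalogTags, par = 0.5),
        list(name = "first_snp_per_tag", fn = thinFirstSnpPerTag, par = NA),
        list(name = "hwe_exact", fn = function(x)
            hweExactFilter(x, config$hwe_alpha), par = config$hwe_alpha))
    if (abc_subset) {
        stages <- c(stages, list(
            list(name = "missing_fraction", fn = function(x)
                filterMissingFraction(x, config$max_missing),
                par = config$max_missing),
            list(name = "maf", fn = function(x) filterMaf(x, config$maf),
                 par = config$maf),
            list(name = "ld_prune", fn = function(x)
                ldPrune(x, config$ld_r2), par = config$ld_r2)))
    }
    report <- NULL
    for (s in stages) {
        n_in <- nrow(g)
        g <- s$fn(g)
        report <- rbind(report,
                        data.frame(stage = s$name, loci_in = n_in,
                                   removed = n_in - nrow(g),
                                   loci_out = nrow(g),
                                   parameter = s$par))
        if (nrow(g) == 0L)
            stop("filter cascade emptied the matrix at stage '", s$name, "'")
    }
    list(genotypes = g, report = report)
}
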