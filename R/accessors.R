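#' Accessors for GenotypeData
#'
#' `dosage()` returns the loci x individuals integer dosage matrix (NA =
#' missing call); `popMap()` the per-individual population map; `locusInfo()`
#' a data.frame of locus metadata (locus_id, tag_id, scaffold, position, ...);
#' `siteTable()` the per-population site covariates or `NULL`; `nLoci()` and
#' `nIndividuals()` the two dimensions.
#'
#' @param x a [GenotypeData-class] object.
#' @return see description.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname genotype-accessors
#' @export
setMethod("dosage", "GenotypeData", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname genotype-accessors
#' @export
setGeneric("popMap", function(x) standardGeneric("popMap"))

#' @rdname genotype-accessors
#' @export
setMethod("popMap", "GenotypeData", function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(individual = colnames(x),
               population = as.character(cd$population),
               group = as.character(cd$group),
               native = as.logical(cd$native),
               row.names = NULL)
})

#' @rdname genotype-accessors
#' @export
setGeneric("locusInfo", function(x) standardGeneric("locusInfo"))

#' @rdname genotype-accessors
#' @export
setMethod("locusInfo", "GenotypeData", function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    df <- as.data.frame(S4Vectors::mcols(rr))
    data.frame(locus_id = rownames(x),
               tag_id = as.character(df$tag_id),
               scaffold = as.character(GenomicRanges::seqnames(rr)),
               position = GenomicRanges::start(rr),
               df[, setdiff(colnames(df), c("locus_id", "tag_id")),
                  drop = FALSE],
               row.names = NULL)
})

#' @rdname genotype-accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname genotype-accessors
#' @export
setMethod("siteTable", "GenotypeData", function(x)
    S4Vectors::metadata(x)$site_table)

#' @rdname genotype-accessors
#' @param value replacement site table (see [validateSiteTable()]).
#' @export
setGeneric("siteTable<-", function(x, value) standardGeneric("siteTable<-"))

#' @rdname genotype-accessors
#' @export
setMethod("siteTable<-", "GenotypeData", function(x, value) {
    validateSiteTable(value, populations = unique(popMap(x)$population))
    S4Vectors::metadata(x)$site_table <- as.data.frame(value)
    x
})

#' @rdname genotype-accessors
#' @export
nLoci <- function(x) nrow(x)

#' @rdname genotype-accessors
#' @export
nIndividuals <- function(x) ncol(x)

## population factor in a fixed order; used by every estimator
.popFactor <- function(x) {
    pm <- popMap(x)
    factor(pm$population, levels = unique(pm$population))
}

## per-population alt-allele counts and genotyped-individual counts
## returns list(alt = L x P matrix of alt-allele counts,
##              n   = L x P matrix of genotyped diploids,
##              het = L x P matrix of heterozygote counts)
.popCounts <- function(d, pop) {
    pop <- droplevels(as.factor(pop))
    M <- vapply(levels(pop), function(lv) as.numeric(pop == lv),
                numeric(length(pop)))
    if (is.null(dim(M))) M <- matrix(M, nrow = length(pop))
    colnames(M) <- levels(pop)
    dz <- d; dz[is.na(dz)] <- 0L
    alt <- dz %*% M
    n <- (!is.na(d)) %*% M
    het <- (dz == 1L & !is.na(d)) %*% M
    list(alt = alt, n = n, het = het, levels = levels(pop))
}
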