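#' @import methods
#' @importFrom stats approx aggregate as.dist binomial coef complete.cases
#'   cor cov dbeta dist ecdf lm median na.omit p.adjust pchisq pnorm
#'   prcomp predict quantile rbeta rbinom rexp rnorm rpois runif rWishart
#'   sd setNames uniroot var vcov
#' @importFrom utils head read.table tail write.table
NULL

#' GenotypeData: diploid SNP genotypes with locus and population metadata
#'
#' `GenotypeData` extends
#' [SummarizedExperiment::RangedSummarizedExperiment] to hold an allele-dosage
#' matrix (loci in rows, individuals in columns, entries counting copies of the
#' alternate allele: 0, 1, 2 or `NA` for a missing call), the locus metadata a
#' RAD-seq panel carries (RAD-tag id, scaffold and 1-based position, ref/alt
#' alleles and the number of alleles observed at the underlying tag position),
#' and the population map (sampling population, river-system group and a
#' native/introduced flag per individual).
#'
#' Subsetting with `[` behaves as for any SummarizedExperiment: rows are loci,
#' columns are individuals, and all metadata travel with the object, so every
#' locus filter in the package is a pure projection.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment]; the dosage
#'   matrix is the assay named `"dosage"`.
#'
#' @seealso [GenotypeData()] for the constructor, [dosage()], [popMap()],
#'   [locusInfo()], [siteTable()] for accessors.
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

.validGenotypeData <- function(object) {
    msg <- NULL
    if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
            msg <- c(msg, "non-missing dosage entries must be in {0, 1, 2}")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "individual ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "locus ids must be unique")
    cd <- SummarizedExperiment::colData(object)
    for (fld in c("population", "group", "native"))
        if (!fld %in% colnames(cd))
            msg <- c(msg, sprintf("colData field '%s' is required", fld))
    rd <- SummarizedExperiment::rowData(object)
    if (!"tag_id" %in% colnames(rd))
        msg <- c(msg, "rowData field 'tag_id' is required")
    if (is.null(msg)) TRUE else msg
}

setValidity("GenotypeData", .validGenotypeData)

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix of alternate-allele dosages with loci in rows
#'   and individuals in columns; entries 0/1/2 or `NA` (missing). A matrix with
#'   individuals in rows is accepted when row names match `popmap$individual`
#'   and is transposed.
#' @param popmap data.frame with columns `individual`, `population`, `group`,
#'   `native` (logical), one row per individual. Row order must cover all
#'   individuals of `dosage`.
#' @param loci optional data.frame of locus metadata with columns `locus_id`,
#'   `tag_id`, `scaffold`, `position` (1-based), and optionally `ref`, `alt`,
#'   `n_alleles`. Defaults place one locus per tag on an unplaced scaffold.
#' @param site_table optional data.frame with columns `population`,
#'   `latitude`, `longitude`, `temp_c`; stored in `metadata()` and validated
#'   by [validateSiteTable()].
#'
#' @return a [GenotypeData-class] object.
#' @examples
#' g <- GenotypeData(
#'   dosage = matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                   dimnames = list(c("L1", "L2"), c("i1", "i2"))),
#'   popmap = data.frame(individual = c("i1", "i2"),
#'                       population = "A", group = "G1", native = TRUE))
#' g
#' @export
GenotypeData <- function(dosage, popmap, loci = NULL, site_table = NULL) {
    dosage <- as.matrix(dosage)
    if (is.null(rownames(dosage)))
        rownames(dosage) <- paste0("L", seq_len(nrow(dosage)))
    if (is.null(colnames(dosage)))
        colnames(dosage) <- popmap$individual[seq_len(ncol(dosage))]
    if (!all(colnames(dosage) %in% popmap$individual) &&
        all(rownames(dosage) %in% popmap$individual)) {
        dosage <- t(dosage)
    }
    storage.mode(dosage) <- "integer"
    missing_map <- setdiff(colnames(dosage), popmap$individual)
    if (length(missing_map))
        stop("individuals present in genotypes but absent from the population ",
             "map: ", paste(missing_map, collapse = ", "))
    if (anyDuplicated(popmap$individual))
        stop("duplicate individual id in population map: ",
             paste(unique(popmap$individual[duplicated(popmap$individual)]),
                   collapse = ", "))
    popmap <- popmap[match(colnames(dosage), popmap$individual), , drop = FALSE]
    if (is.null(loci)) {
        loci <- data.frame(locus_id = rownames(dosage),
                           tag_id = rownames(dosage),
                           scaffold = "un",
                           position = seq_len(nrow(dosage)))
    }
    loci <- as.data.frame(loci)
    stopifnot(all(c("locus_id", "tag_id", "scaffold", "position") %in%
                  colnames(loci)))
    if (any(loci$position < 1)) stop("locus positions must be >= 1")
    loci <- loci[match(rownames(dosage), loci$locus_id), , drop = FALSE]
    if (anyNA(loci$locus_id))
        stop("every locus in the dosage matrix needs a row in 'loci'")
    key <- paste(loci$scaffold, loci$position)
    if (anyDuplicated(key))
        stop("duplicated (scaffold, position) among loci")
    if (!"n_alleles" %in% colnames(loci)) loci$n_alleles <- 2L
    rr <- GenomicRanges::GRanges(
        seqnames = loci$scaffold,
        ranges = IRanges::IRanges(start = loci$position, width = 1L))
    names(rr) <- loci$locus_id
    mcols_keep <- setdiff(colnames(loci), c("scaffold", "position"))
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(loci[, mcols_keep,
                                                      drop = FALSE])
    cd <- S4Vectors::DataFrame(popmap, row.names = popmap$individual)
    md <- list()
    if (!is.null(site_table)) {
        validateSiteTable(site_table, populations = unique(popmap$population))
        md$site_table <- as.data.frame(site_table)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = rr, colData = cd,
        metadata = md)
    methods::new("GenotypeData", se)
}

#' Validate a site covariate table
#'
#' Checks coordinate ranges and (optionally) that all populations of a
#' population map are present. Populations in the site table that are unknown
#' to the map only raise a warning.
#'
#' @param site_table data.frame with columns `population`, `latitude`,
#'   `longitude` and `temp_c`.
#' @param populations optional character vector of expected population labels.
#' @param require_temperature error when the temperature column is absent or
#'   all-NA (set by stages that need the covariate).
#' @return the validated table, invisibly.
#' @export
validateSiteTable <- function(site_table, populations = NULL,
                              require_temperature = FALSE) {
    st <- as.data.frame(site_table)
    stopifnot(all(c("population", "latitude", "longitude") %in% colnames(st)))
    if (any(st$latitude < -90 | st$latitude > 90))
        stop("latitude out of [-90, 90]")
    if (any(st$longitude < -180 | st$longitude > 180))
        stop("longitude out of [-180, 180]")
    if (require_temperature &&
        (!"temp_c" %in% colnames(st) || all(is.na(st$temp_c))))
        stop("site table must provide 'temp_c' for this stage")
    if (!is.null(populations)) {
        extra <- setdiff(st$population, populations)
        if (length(extra))
            warning("site table rows for unknown populations: ",
                    paste(extra, collapse = ", "))
    }
    invisible(st)
}

setMethod("show", "GenotypeData", function(object) {
    cat(sprintf("GenotypeData: %d loci x %d individuals\n",
                nrow(object), ncol(object)))
    pm <- popMap(object)
    cat(sprintf("populations: %s\n",
                paste(sprintf("%s(%d)", names(table(pm$population)),
                              as.integer(table(pm$population))),
                      collapse = " ")))
    d <- dosage(object)
    cat(sprintf("missing calls: %.2f%%\n", 100 * mean(is.na(d))))
    if (!is.null(siteTable(object)))
        cat("site covariates attached\n")
    invisible(NULL)
})
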