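#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) with diploid `GT` fields into a
#' [GenotypeData-class] object. Biallelic records become dosage columns
#' counting copies of the alternate allele; multi-allelic records are kept
#' with `n_alleles` recording the allele count (their dosage counts any
#' non-reference allele) so the paralogous-tag filter can act on them.
#' Missing genotypes (`./.`) become `NA`.
#'
#' RAD-tag ids are taken from the VCF `ID` column when formatted as
#' `tag:offset`, else each locus is its own tag.
#'
#' @param path VCF file path.
#' @param popmap population map data.frame (see [readPopulationMap()]); when
#'   `NULL` a single population `"pop1"` is assumed.
#' @return a [GenotypeData-class] object.
#' @export
readVcfGenotypes <- function(path, popmap = NULL) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix))
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt)))
        gt <- matrix(gt, nrow = nrow(fix),
                     dimnames = list(NULL, names(gt)))
    ploidy_bad <- grepl("^[0-9.]+$|([/|][^/|]*){2,}", gt[!is.na(gt)])
    if (any(ploidy_bad))
        stop("unsupported ploidy: GT fields must be diploid (a/b)")
    alleles1 <- substr(gt, 1, 1)
    alleles2 <- substr(gt, 3, 3)
    miss <- is.na(gt) | alleles1 == "." | alleles2 == "."
    d <- (alleles1 != "0") + (alleles2 != "0")
    d[miss] <- NA
    storage.mode(d) <- "integer"
    ids <- fix[, "ID"]
    no_id <- is.na(ids) | ids == "."
    ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
    rownames(d) <- ids
    n_alleles <- 1L + lengths(strsplit(fix[, "ALT"], ",", fixed = TRUE))
    n_alleles[is.na(fix[, "ALT"]) | fix[, "ALT"] == "."] <- 1L
    info <- v@fix[, "INFO"]
    tag <- ifelse(!is.na(info) & grepl("(^|;)TAG=", info),
                  sub("^.*(^|;)TAG=([^;]+).*$", "\\2", info),
           ifelse(grepl(":", ids), sub(":.*$", "", ids), ids))
    loci <- data.frame(locus_id = ids, tag_id = tag,
                       scaffold = fix[, "CHROM"],
                       position = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       n_alleles = n_alleles)
    if (is.null(popmap))
        popmap <- data.frame(individual = colnames(d), population = "pop1",
                             group = "g1", native = TRUE)
    GenotypeData(d, popmap = popmap, loci = loci)
}

#' Write genotypes to a VCF file
#'
#' Plain-text VCF 4.2 with one `GT` field per individual; dosages 0/1/2 map
#' to `0/0`, `0/1`, `1/1` and missing calls to `./.`. Locus ids go in the
#' `ID` column (the tag id is recoverable from ids of the form
#' `tag:offset`).
#'
#' @param g a [GenotypeData-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(g, path) {
    li <- locusInfo(g)
    d <- dosage(g)
    ref <- if ("ref" %in% colnames(li)) as.character(li$ref) else
        rep("A", nrow(li))
    alt <- if ("alt" %in% colnames(li)) as.character(li$alt) else
        rep("T", nrow(li))
    ref[is.na(ref)] <- "A"; alt[is.na(alt)] <- "T"
    gtxt <- matrix("./.", nrow(d), ncol(d))
    gtxt[!is.na(d) & d == 0L] <- "0/0"
    gtxt[!is.na(d) & d == 1L] <- "0/1"
    gtxt[!is.na(d) & d == 2L] <- "1/1"
    body <- cbind(li$scaffold, li$position, li$locus_id, ref, alt,
                  ".", "PASS", paste0("TAG=", li$tag_id), "GT", gtxt)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(d)),
                       collapse = "\t")), con)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}

#' Read the tab-separated metadata tables
#'
#' `readPopulationMap()` expects columns `individual`, `population`, `group`,
#' `native`; `readSiteTable()` expects `population`, `latitude`, `longitude`,
#' `temp_c`; `readGenotypeTable()` reads an individuals x loci table of
#' dosages 0/1/2/NA (first column = individual id, header = locus ids).
#'
#' @param path file path (tab-separated, header row).
#' @return a validated data.frame, or for `readGenotypeTable()` a dosage
#'   matrix (individuals in rows) suitable for [GenotypeData()].
#' @export
readPopulationMap <- function(path) {
    pm <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    stopifnot(all(c("individual", "population", "group", "native") %in%
                  colnames(pm)))
    if (anyDuplicated(pm$individual))
        stop("duplicate individual id in population map: ",
             paste(unique(pm$individual[duplicated(pm$individual)]),
                   collapse = ", "))
    pm$native <- as.logical(pm$native)
    sizes <- table(pm$population)
    if (any(sizes < 1)) stop("every population needs >= 1 individual")
    pm
}

#' @rdname readPopulationMap
#' @export
readSiteTable <- function(path) {
    st <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    validateSiteTable(st)
    st
}

#' @rdname readPopulationMap
#' @export
readGenotypeTable <- function(path) {
    tb <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                     na.strings = c("NA", "./."), check.names = FALSE)
    m <- as.matrix(tb)
    storage.mode(m) <- "integer"
    bad <- m[!is.na(m)]
    if (length(bad) && !all(bad %in% 0:2))
        stop("genotype table entries must be 0/1/2/NA")
    m
}

#' @rdname readPopulationMap
#' @param g a [GenotypeData-class] object.
#' @export
writeGenotypeTable <- function(g, path) {
    m <- t(dosage(g))
    df <- data.frame(individual = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run configuration and stage manifests
#'
#' `runConfig()` bundles the seed and the filter thresholds used across the
#' pipeline, with range validation; `writeManifest()` records a stage's
#' inputs, seed, thresholds and counts as JSON for provenance.
#'
#' @param seed integer seed recorded in all stage manifests and used by every
#'   randomized stage.
#' @param min_call_rate per-population call-rate threshold (locus kept if the
#'   genotyped fraction is strictly greater in every population).
#' @param hwe_alpha per-population exact Hardy-Weinberg significance level.
#' @param maf minor-allele-frequency threshold (strictly greater to keep).
#' @param max_missing overall missingness cutoff (kept when <=).
#' @param ld_r2 genotype-correlation threshold for LD pruning (dropped when
#'   r^2 >= threshold).
#' @param out_dir output directory for stage artefacts.
#' @return a `run_config` list.
#' @export
runConfig <- function(seed = 1L, min_call_rate = 0.7, hwe_alpha = 0.01,
                      maf = 0.05, max_missing = 0.05, ld_r2 = 0.05,
                      out_dir = ".") {
    stopifnot(min_call_rate >= 0, min_call_rate <= 1,
              hwe_alpha > 0, hwe_alpha < 1,
              maf >= 0, maf < 0.5,
              max_missing >= 0, max_missing <= 1,
              ld_r2 > 0, ld_r2 <= 1)
    structure(list(seed = as.integer(seed), min_call_rate = min_call_rate,
                   hwe_alpha = hwe_alpha, maf = maf,
                   max_missing = max_missing, ld_r2 = ld_r2,
                   out_dir = out_dir),
              class = "run_config")
}

#' @rdname runConfig
#' @param stage stage name.
#' @param inputs named list describing stage inputs.
#' @param counts named list of counts (loci in/out etc.).
#' @param extra further fields to record.
#' @param config a `run_config`.
#' @param path output JSON path; defaults to `<out_dir>/<stage>_manifest.json`.
#' @export
writeManifest <- function(stage, config, inputs = list(), counts = list(),
                          extra = list(), path = NULL) {
    if (is.null(path))
        path <- file.path(config$out_dir,
                          paste0(stage, "_manifest.json"))
    manifest <- list(stage = stage, seed = config$seed,
                     thresholds = config[setdiff(names(config),
                                                 c("seed", "out_dir"))],
                     inputs = inputs, counts = counts,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    manifest <- c(manifest, extra)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}
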