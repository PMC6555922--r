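#' Sliding-window F(ST) along scaffolds
#'
#' Tiles each scaffold with windows of `window_size` bp (tumbling by
#' default: `step = window_size`; any step is supported) and reports, per
#' window, the number of SNPs and the mean per-locus Weir-Cockerham theta
#' between the two pooled groups over SNPs whose position falls in
#' `[start, end)`. Windows with fewer than `min_snps` informative SNPs are
#' reported with an undefined mean; a trailing partial window is retained
#' and flagged. Coordinates in the output are half-open 0-based
#' `[start, end)` (BED convention); locus positions are 1-based.
#'
#' @param g a [GenotypeData-class] object with scaffold coordinates.
#' @param groupA,groupB character vectors of population names pooled into
#'   the two units being compared.
#' @param window_size window size in bp (> 0).
#' @param step step in bp (default `window_size`).
#' @param min_snps minimum informative SNPs for a defined mean (default 3).
#' @param scaffold_lengths optional named lengths; defaults to the largest
#'   locus position per scaffold.
#' @return a `window_table` data.frame: scaffold, start, end, n_snps,
#'   mean_theta, partial.
#' @export
windowFst <- function(g, groupA, groupB, window_size, step = window_size,
                      min_snps = 3L, scaffold_lengths = NULL) {
    if (window_size <= 0) stop("window size must be > 0")
    if (step <= 0) stop("step must be > 0")
    li <- locusInfo(g)
    th <- wcFst(g, pool_groups = list(A = groupA, B = groupB))$per_locus
    theta <- th$theta
    out <- NULL
    for (sc in unique(li$scaffold)) {
        on_sc <- li$scaffold == sc
        pos0 <- li$position[on_sc] - 1L      # to 0-based
        th_sc <- theta[on_sc]
        len <- if (!is.null(scaffold_lengths) &&
                   sc %in% names(scaffold_lengths))
            scaffold_lengths[[sc]] else max(li$position[on_sc])
        starts <- seq(0, max(0, len - 1), by = step)
        ends <- pmin(starts + window_size, len)
        for (w in seq_along(starts)) {
            inw <- pos0 >= starts[w] & pos0 < ends[w]
            thw <- th_sc[inw & !is.na(th_sc)]
            out <- rbind(out, data.frame(
                scaffold = sc, start = starts[w], end = ends[w],
                n_snps = sum(inw),
                mean_theta = if (length(thw) >= min_snps) mean(thw)
                             else NA_real_,
                partial = (ends[w] - starts[w]) < window_size))
        }
    }
    class(out) <- c("window_table", "data.frame")
    out
}

#' SNP density per window and its independence from differentiation
#'
#' `snpDensity()` adds `density = n_snps / (end - start)` (SNPs per bp).
#' `densityIndependence()` reports the Spearman correlation between window
#' mean theta and SNP density over defined windows, with a permutation
#' p-value; a constant density (or constant theta) makes the correlation
#' undefined and is reported as 0 with a flag.
#'
#' @param wt a `window_table` from [windowFst()].
#' @return `snpDensity()`: the table with a `density` column.
#' @export
snpDensity <- function(wt) {
    wt$density <- wt$n_snps / (wt$end - wt$start)
    wt
}

#' @rdname snpDensity
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return `densityIndependence()`: `list(rho =, p =, n_windows =,
#'   undefined =)`.
#' @export
densityIndependence <- function(wt, n_perm = 999L, seed = 1L) {
    set.seed(seed)
    wt <- snpDensity(wt)
    def <- !is.na(wt$mean_theta)
    if (sum(def) < 20) stop("need >= 20 defined windows")
    x <- wt$mean_theta[def]; y <- wt$density[def]
    if (sd(x) == 0 || sd(y) == 0)
        return(list(rho = 0, p = NA_real_, n_windows = sum(def),
                    undefined = TRUE))
    rho <- cor(x, y, method = "spearman")
    cnt <- 0L
    for (b in seq_len(n_perm))
        if (abs(cor(x, sample(y), method = "spearman")) >= abs(rho))
            cnt <- cnt + 1L
    list(rho = rho, p = (1 + cnt) / (n_perm + 1), n_windows = sum(def),
         undefined = FALSE)
}

#' Detect genomic islands of differentiation
#'
#' A window is *elevated* when its mean theta exceeds the background mean
#' by `z_threshold` standard deviations (background = all defined
#' windows). An island is a maximal run of adjacent elevated windows on
#' one scaffold containing at least `min_outliers` outlier SNPs; a single
#' non-elevated window breaks a run. Island size is `end - start` in bp.
#'
#' @param wt a `window_table` from [windowFst()].
#' @param outlier_loci data.frame with columns `scaffold`, `position` of
#'   outlier SNPs (e.g. from an outlier scan joined to [locusInfo()]);
#'   `NULL` counts every window as having enough outliers.
#' @param z_threshold elevation threshold in background SDs (default 3).
#' @param min_outliers minimum outlier SNPs per island (default 1; ignored
#'   when `outlier_loci` is NULL).
#' @return data.frame of islands: scaffold, start, end, size, n_windows,
#'   n_outlier_snps, max_theta.
#' @export
detectIslands <- function(wt, outlier_loci = NULL, z_threshold = 3,
                          min_outliers = 1L) {
    def <- !is.na(wt$mean_theta)
    if (!any(def)) stop("no defined windows")
    bg_mean <- mean(wt$mean_theta[def])
    bg_sd <- sd(wt$mean_theta[def])
    elevated <- def & wt$mean_theta > bg_mean + z_threshold * bg_sd
    n_out <- integer(nrow(wt))
    if (!is.null(outlier_loci)) {
        for (i in which(elevated)) {
            n_out[i] <- sum(outlier_loci$scaffold == wt$scaffold[i] &
                            outlier_loci$position - 1 >= wt$start[i] &
                            outlier_loci$position - 1 < wt$end[i])
        }
    }
    islands <- NULL
    i <- 1L
    while (i <= nrow(wt)) {
        if (!elevated[i]) { i <- i + 1L; next }
        j <- i
        while (j + 1L <= nrow(wt) && elevated[j + 1L] &&
               wt$scaffold[j + 1L] == wt$scaffold[i] &&
               wt$start[j + 1L] == wt$end[j]) j <- j + 1L
        n_o <- if (is.null(outlier_loci)) NA_integer_ else
            sum(n_out[i:j])
        if (is.null(outlier_loci) || n_o >= min_outliers)
            islands <- rbind(islands, data.frame(
                scaffold = wt$scaffold[i], start = wt$start[i],
                end = wt$end[j], size = wt$end[j] - wt$start[i],
                n_windows = j - i + 1L, n_outlier_snps = n_o,
                max_theta = max(wt$mean_theta[i:j])))
        i <- j + 1L
    }
    if (is.null(islands))
        islands <- data.frame(scaffold = character(0), start = numeric(0),
                              end = numeric(0), size = numeric(0),
                              n_windows = integer(0),
                              n_outlier_snps = integer(0),
                              max_theta = numeric(0))
    islands
}

#' Write a window table as BED-compatible TSV
#'
#' Columns scaffold, start, end (0-based half-open), then score columns.
#'
#' @param wt a `window_table`.
#' @param path output path.
#' @export
writeWindowBed <- function(wt, path) {
    write.table(wt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
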