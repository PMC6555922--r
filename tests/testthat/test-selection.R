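test_that("population covariance recovers a star design and duplicates", {
    set.seed(61)
    g <- simulateMetapopulation(starDesign(5, 0.06, 25), 1200, seed = 21)
    g <- filterMaf(g, 0.05)
    pcov <- estimatePopCov(g, n_iter = 3000, burnin = 1000, seed = 1)
    om <- pcov$omega
    ## diagonal near the drift level, off-diagonals near zero
    expect_lt(abs(mean(diag(om)) - 0.06), 0.03)
    off <- om[upper.tri(om)]
    expect_lt(max(abs(off)), 0.03)
    ## two chains agree within 10% on the diagonal scale
    pcov2 <- estimatePopCov(g, n_iter = 3000, burnin = 1000, seed = 2)
    expect_lt(abs(mean(diag(pcov2$omega)) - mean(diag(om))) /
              mean(diag(om)), 0.1)
})

test_that("a duplicated population shows covariance equal to its variance", {
    set.seed(62)
    g <- simulateMetapopulation(starDesign(3, 0.08, 30), 900, seed = 22)
    d <- dosage(g)
    dd <- cbind(d, d[, popMap(g)$population == "P3"])
    colnames(dd) <- paste0("i", seq_len(ncol(dd)))
    g2 <- makeGenotypes(dd, c(P1 = 30, P2 = 30, P3 = 30, P3b = 30))
    g2 <- filterMaf(g2, 0.05)
    pcov <- estimatePopCov(g2, n_iter = 2500, burnin = 800, seed = 3)
    om <- pcov$omega
    expect_gt(om["P3", "P3b"], 0.6 * sqrt(om["P3", "P3"] *
                                          om["P3b", "P3b"]))
})

test_that("environmental BF: null loci sit in the inconclusive band and
           clinal loci are detected", {
    set.seed(63)
    des <- grassCarpDesign(n_per_pop = 20)
    plan <- selectionPlan(n_clinal = 40, slope = 2)
    g <- simulateWithSelection(des, 1200, plan, seed = 23)
    g <- filterMaf(g, 0.02)
    tr <- S4Vectors::metadata(g)$truth
    tr <- tr[match(rownames(g), tr$locus_id), ]
    pcov <- estimatePopCov(g[tr$class == "neutral", ],
                           n_iter = 2500, burnin = 800, seed = 4)
    st <- siteTable(g)
    temp <- setNames(st$temp_c, st$population)
    bf <- envBayesFactor(g, pcov, temp, n_runs = 3, seed = 5)
    cls <- tr$class[match(bf$locus_id, tr$locus_id)]
    ## neutral calibration: BF > 3 rare, most in [1/3, 3]
    expect_lt(mean(bf$significant[cls == "neutral"]), 0.05)
    expect_gt(mean(bf$bf[cls == "neutral"] > 1 / 3 &
                   bf$bf[cls == "neutral"] < 3), 0.9)
    ## power on planted clinal loci
    expect_gt(mean(bf$significant[cls == "clinal"]), 0.5)
    expect_error(envBayesFactor(g, pcov, temp * 0 + 1), "constant")
})

test_that("temperature and latitude candidate sets overlap strongly when
           the covariates are collinear", {
    set.seed(64)
    des <- grassCarpDesign(n_per_pop = 20)
    plan <- selectionPlan(n_clinal = 50, slope = 2.5)
    g <- simulateWithSelection(des, 900, plan, seed = 24)
    g <- filterMaf(g, 0.02)
    tr <- S4Vectors::metadata(g)$truth
    tr <- tr[match(rownames(g), tr$locus_id), ]
    pcov <- estimatePopCov(g[tr$class == "neutral", ],
                           n_iter = 2000, burnin = 600, seed = 6)
    st <- siteTable(g)
    bf_t <- envBayesFactor(g, pcov, setNames(st$temp_c, st$population),
                           n_runs = 3, seed = 7)
    bf_l <- envBayesFactor(g, pcov, setNames(st$latitude, st$population),
                           n_runs = 3, seed = 8)
    cand <- latitudinalCandidates(bf_t, bf_l)
    sig_t <- bf_t$locus_id[bf_t$significant]
    sig_l <- bf_l$locus_id[bf_l$significant]
    skip_if(length(sig_t) < 5, "too few significant loci to compare")
    expect_gt(length(intersect(sig_t, sig_l)) /
              length(union(sig_t, sig_l)), 0.8)
    ## a temperature-only locus cannot be a latitudinal candidate
    fake_t <- bf_t; fake_l <- bf_l
    fake_l$significant[] <- FALSE
    expect_identical(latitudinalCandidates(fake_t, fake_l), character(0))
})

test_that("hierarchical island outliers: null median locus sits at
           quantile one half; planted divergence is detected", {
    set.seed(65)
    des <- grassCarpDesign(n_per_pop = 15)
    plan <- selectionPlan(n_divergent = 40, divergent_factor = 6)
    g <- simulateWithSelection(des, 900, plan, seed = 25)
    g <- filterMaf(g, 0.02)
    out <- fdistHierOutliers(g, n_sims = 8000, n_cal = 1200, seed = 9)
    tr <- S4Vectors::metadata(g)$truth
    cls <- tr$class[match(out$locus_id, tr$locus_id)]
    ## power on planted divergent loci at the stated thresholds
    expect_gt(mean(out$flag_positive[cls == "divergent"]), 0.5)
    ## neutral loci essentially never flagged after FDR
    expect_lt(mean(out$flag_positive[cls == "neutral"]), 0.01)
    ## a locus with theta at the null median has quantile near 0.5
    med_th <- median(out$theta, na.rm = TRUE)
    near <- which(abs(out$theta - med_th) < 0.005)
    expect_lt(abs(mean(out$quantile[near], na.rm = TRUE) - 0.5), 0.2)
    expect_error(fdistHierOutliers(g[, popMap(g)$group == "Yangtze"]),
                 ">= 2 groups")
})

test_that("F-model flags planted divergent loci positive and balanced loci
           balancing; population relabelling leaves flags unchanged", {
    set.seed(66)
    des <- grassCarpDesign(n_per_pop = 15)
    plan <- selectionPlan(n_divergent = 30, divergent_factor = 7,
                          n_balanced = 30, balanced_c = 0.002)
    g <- simulateWithSelection(des, 600, plan, seed = 26)
    g <- filterMaf(g, 0.05)
    out <- suppressWarnings(
        fmodelOutliers(g, n_iter = 1500, burnin = 500, seed = 10))
    tr <- S4Vectors::metadata(g)$truth
    cls <- tr$class[match(out$locus_id, tr$locus_id)]
    div_flag <- out$outlier & out$alpha > 0
    bal_flag <- out$outlier & out$alpha < 0
    expect_gt(mean(div_flag[cls == "divergent"]), 0.4)
    expect_gt(mean(out$alpha[cls == "divergent"]),
              mean(out$alpha[cls == "neutral"]))
    expect_lt(mean(out$alpha[cls == "balanced"]),
              mean(out$alpha[cls == "neutral"]))
    ## relabelling populations permutes beta but not locus flags
    pm <- popMap(g)
    relab <- setNames(sample(unique(pm$population)),
                      unique(pm$population))
    pm2 <- pm; pm2$population <- relab[pm$population]
    ord <- order(match(pm2$population, unique(pm2$population)))
    g2 <- GenotypeData(dosage(g), pm2, loci = locusInfo(g))
    out2 <- suppressWarnings(
        fmodelOutliers(g2, n_iter = 1500, burnin = 500, seed = 10))
    expect_gt(cor(out$post_prob, out2$post_prob), 0.95)
})

test_that("outlier set algebra reproduces hand counts", {
    universe <- paste0("L", 1:1000)
    a <- paste0("L", 1:343)
    b <- paste0("L", 401:609)                      # 209, disjoint from a
    cc <- c(paste0("L", 1:4), paste0("L", 701:766)) # 70, overlap 4 with a
    res <- combineOutlierSets(list(positive = a, balancing = b,
                                   latitudinal = cc),
                              universe = universe)
    expect_identical(res$union_size, 614L + 4L)     # 618
    expect_identical(unname(res$sizes), c(343L, 209L, 70L))
    expect_identical(unname(res$intersections["positive&latitudinal"]), 4L)
    expect_identical(unname(res$intersections["positive&balancing"]), 0L)
    ## disjoint sets: union equals the size sum
    res2 <- combineOutlierSets(list(x = a, y = b))
    expect_identical(res2$union_size, 552L)
    expect_error(combineOutlierSets(list(x = "Lbad"), universe = universe),
                 "unknown loci")
})

test_that("leave-one-out and whole-vs-reduced comparisons track stability", {
    set.seed(67)
    des <- grassCarpDesign(n_per_pop = 12)
    plan <- selectionPlan(n_divergent = 25, divergent_factor = 8)
    g <- simulateWithSelection(des, 400, plan, seed = 27)
    g <- filterMaf(g, 0.05)
    ## a cheap deterministic scan: top decile of per-locus theta
    test_fn <- function(gg) {
        th <- wcFst(gg)$per_locus$theta
        rownames(gg)[!is.na(th) & th > quantile(th, 0.9, na.rm = TRUE)]
    }
    loo <- leaveOneOut(g, test_fn, always_keep = "Nenjiang")
    expect_identical(nrow(loo), 8L)
    expect_true(all(loo$stability >= 0 & loo$stability <= 1))
    expect_true(all(loo$n_common <= loo$n_outliers))
    ## planted signal is more stable than pure noise
    g_null <- simulateMetapopulation(grassCarpDesign(n_per_pop = 12), 400,
                                     seed = 28)
    g_null <- filterMaf(g_null, 0.05)
    loo_null <- leaveOneOut(g_null, test_fn, always_keep = "Nenjiang")
    expect_gt(mean(loo$stability), mean(loo_null$stability))
    ## whole-vs-reduced bookkeeping
    drop_ids <- popMap(g)$individual[popMap(g)$population == "Nenjiang"][1:5]
    cmp <- compareWholeReduced(g, drop_ids, test_fn)
    expect_true(all(cmp$common %in% cmp$whole))
    expect_identical(cmp$n_common, length(cmp$common))
})
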