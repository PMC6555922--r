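test_that("call-rate filter is strict per population", {
    ## 2 populations x 10; locus 1 typed 8/10 in both, locus 2 typed 7/10
    ## in population B (exactly at the threshold -> removed)
    d <- matrix(1L, 3, 20,
                dimnames = list(paste0("L", 1:3), paste0("i", 1:20)))
    d[1, c(1, 2, 11, 12)] <- NA             # 8/10 in both pops
    d[2, 11:13] <- NA                       # 7/10 in B only
    g <- makeGenotypes(d, c(A = 10, B = 10))
    kept <- rownames(filterCallRate(g, 0.7))
    expect_identical(kept, c("L1", "L3"))
})

test_that("call-rate survivors equal a brute-force per-population tally", {
    set.seed(21)
    d <- dosageFromFreq(matrix(runif(300, .1, .9), 100, 3), 8)
    d[sample(length(d), 600)] <- NA
    g <- makeGenotypes(d, c(A = 8, B = 8, C = 8))
    kept <- rownames(filterCallRate(g, 0.7))
    pops <- rep(c("A", "B", "C"), each = 8)
    brute <- rownames(d)[apply(d, 1, function(x)
        all(tapply(!is.na(x), pops, mean) > 0.7))]
    expect_identical(kept, brute)
})

test_that("paralog rule removes whole tags (OR of >2 alleles / high H_O)", {
    ## 10 tags x 2 SNPs; tags 1-3 violate via one SNP each
    ## deterministic low-heterozygosity base (H_O = 0.2 everywhere)
    d <- matrix(rep(c(0L, 0L, 1L, 0L, 2L, 1L, 0L, 2L, 0L, 0L), 20),
                20, 10, byrow = TRUE,
                dimnames = list(paste0("L", 1:20), paste0("i", 1:10)))
    d[1, ] <- c(rep(1L, 6), 0L, 0L, 2L, 2L)   # H_O = 0.6 on tag 1
    d[3, ] <- rep(c(0L, 1L), 5)               # H_O = 0.5 on tag 2: kept
    loci <- data.frame(locus_id = rownames(d),
                       tag_id = rep(paste0("t", 1:10), each = 2),
                       scaffold = "s", position = 1:20,
                       n_alleles = c(rep(2L, 3), 3L,      # tag 2 SNP 2
                                     4L, rep(2L, 15)))    # tag 3 SNP 1
    g <- makeGenotypes(d, c(A = 10), loci = loci)
    out <- filterParalogTags(g)
    tags_left <- unique(locusInfo(out)$tag_id)
    expect_false(any(c("t1", "t2", "t3") %in% tags_left))
    expect_identical(length(tags_left), 7L)
    ## literal AND keeps tags violating only one condition
    out_and <- filterParalogTags(g, rule = "and")
    expect_true(all(c("t1", "t2", "t3") %in%
                    unique(locusInfo(out_and)$tag_id)))
})

test_that("thinning keeps the lowest-coordinate SNP per tag, idempotently", {
    d <- matrix(rbinom(30, 2, .4), 3, 10,
                dimnames = list(paste0("L", 1:3), paste0("i", 1:10)))
    loci <- data.frame(locus_id = paste0("L", 1:3), tag_id = "t1",
                       scaffold = "s", position = c(57, 12, 88))
    g <- makeGenotypes(d, c(A = 10), loci = loci)
    thin <- thinFirstSnpPerTag(g)
    expect_identical(rownames(thin), "L2")   # position 12
    expect_identical(rownames(thinFirstSnpPerTag(thin)), "L2")
})

test_that("exact HWE p matches enumeration and a random-pairing oracle", {
    ## counts (AA=3, Aa=4, aa=3): enumeration over het counts 0,2,...,10
    hs <- seq(0, 10, 2)
    lp <- lgamma(11) - lgamma((10 - hs) / 2 + 1) - lgamma(hs + 1) -
        lgamma(10 - (10 + hs) / 2 + 1) + hs * log(2)
    pr <- exp(lp) / sum(exp(lp))
    p_manual <- sum(pr[pr <= pr[hs == 4] * (1 + 1e-9)])
    expect_equal(hweExactP(4, 10, 10), p_manual, tolerance = 1e-12)
    ## independent Monte-Carlo pairing oracle
    set.seed(22)
    p_mc <- hwePairingOracle(4, 10, 10, B = 100000)
    expect_equal(hweExactP(4, 10, 10), p_mc, tolerance = 0.02)
    ## monomorphic -> p = 1
    expect_identical(hweExactP(0, 0, 12), 1)
    expect_identical(hweExactP(0, 24, 12), 1)
})

test_that("HWE filter removes all-heterozygote loci and keeps HWE ones", {
    n <- 20
    d <- rbind(L1 = rep(1L, n),                       # all het
               L2 = rep(c(0L, 1L, 1L, 2L), n / 4))    # near-perfect HWE
    colnames(d) <- paste0("i", 1:n)
    g <- makeGenotypes(d, c(A = n))
    expect_lt(hwePerPopulation(g)["L1", "A"], 0.01)
    out <- hweExactFilter(g, alpha = 0.01)
    expect_identical(rownames(out), "L2")
})

test_that("HWE scope 'one' differs from 'any' as specified", {
    n <- 20
    d_bad <- rep(1L, n)
    d <- rbind(L1 = c(d_bad, d_bad),                  # deviates in both pops
               L2 = c(d_bad, rep(c(0L, 1L, 1L, 2L), n / 4)))  # in A only
    colnames(d) <- paste0("i", 1:(2 * n))
    g <- makeGenotypes(d, c(A = n, B = n))
    expect_identical(rownames(hweExactFilter(g, scope = "any")),
                     character(0))
    ## 'one' removes only loci deviating in exactly one location
    expect_identical(rownames(hweExactFilter(g, scope = "one")), "L1")
})

test_that("MAF filter is strict at the boundary and matches brute force", {
    ## 10 diploids, 1 alt allele: MAF exactly 0.05 -> removed
    d <- rbind(L1 = c(1L, rep(0L, 9)),
               L2 = rep(0L, 10),                       # monomorphic
               L3 = c(2L, 1L, rep(0L, 8)))             # MAF 0.15
    colnames(d) <- paste0("i", 1:10)
    g <- makeGenotypes(d, c(A = 10))
    expect_identical(rownames(filterMaf(g, 0.05)), "L3")
    set.seed(23)
    d2 <- dosageFromFreq(matrix(runif(200, 0, .5), 100, 2), 10)
    d2[sample(length(d2), 100)] <- NA
    g2 <- makeGenotypes(d2, c(A = 10, B = 10))
    brute <- rownames(d2)[vapply(seq_len(nrow(d2)), function(l) {
        x <- d2[l, ][!is.na(d2[l, ])]
        p <- sum(x) / (2 * length(x))
        min(p, 1 - p) > 0.05
    }, TRUE)]
    expect_identical(rownames(filterMaf(g2, 0.05)), brute)
})

test_that("missingness filter keeps loci at or below the cutoff", {
    d <- matrix(0L, 2, 20, dimnames = list(c("L1", "L2"),
                                           paste0("i", 1:20)))
    d[1, 1] <- NA                                     # 5% missing: kept
    d[2, 1:2] <- NA                                   # 10%: removed
    g <- makeGenotypes(d + rbinom(40, 1, .5), c(A = 20))
    expect_identical(rownames(filterMissingFraction(g, 0.05)), "L1")
})

test_that("LD pruning drops duplicates and respects its own postcondition", {
    set.seed(24)
    base <- rbinom(30, 2, .5)
    d <- rbind(L1 = base, L2 = base,                  # r2 = 1
               L3 = rbinom(30, 2, .5))
    colnames(d) <- paste0("i", 1:30)
    loci <- data.frame(locus_id = rownames(d), tag_id = rownames(d),
                       scaffold = "s", position = c(100, 200, 300))
    g <- makeGenotypes(d, c(A = 30), loci = loci)
    pruned <- ldPrune(g, r2_max = 0.05)
    expect_false("L2" %in% rownames(pruned))
    expect_true("L1" %in% rownames(pruned))
    ## postcondition replay: no kept within-window pair at r2 >= threshold
    dd <- dosage(pruned)
    if (nrow(dd) > 1) {
        cors <- cor(t(dd), use = "pairwise.complete.obs")^2
        expect_true(all(cors[upper.tri(cors)] < 0.05))
    }
    ## independent loci: pruning removes almost nothing
    ## with enough individuals the r2 noise floor sits far below the
    ## threshold, so independent loci are essentially never pruned
    set.seed(25)
    d3 <- dosageFromFreq(matrix(runif(100, .3, .7), 100, 1), 400)
    loci3 <- data.frame(locus_id = rownames(d3), tag_id = rownames(d3),
                        scaffold = "s",
                        position = seq(1, by = 1e4, length.out = 100))
    g3 <- makeGenotypes(d3, c(A = 400), loci = loci3)
    expect_gt(nrow(ldPrune(g3, r2_max = 0.05, window_bp = Inf)) /
              nrow(g3), 0.95)
})

test_that("cascade counts compose, match planted truth, and are pure", {
    set.seed(26)
    n <- 20
    ## 12 tags x 1 SNP, clean base
    d <- dosageFromFreq(matrix(runif(12, .1, .2), 12, 1), n)
    ## plant: L1 fails call rate; L2 paralog H_O; L3+L4 same tag (thinning
    ## removes one); L5 heterozygote deficit (fails HWE, passes paralog)
    d[1, 1:7] <- NA
    d[2, ] <- c(rep(1L, 13), rep(0L, 4), rep(2L, 3))
    d[5, ] <- rep(c(0L, 2L), n / 2)
    loci <- data.frame(locus_id = rownames(d),
                       tag_id = c("t1", "t2", "t3", "t3", "t5",
                                  paste0("t", 6:12)),
                       scaffold = "s", position = 1:12)
    g <- makeGenotypes(d, c(A = n), loci = loci)
    res <- runFilterCascade(g, runConfig())
    rep_ <- res$report
    expect_identical(rep_$removed, c(1L, 1L, 1L, 1L))
    ## conservation at every stage and composition across stages
    expect_identical(rep_$loci_out, rep_$loci_in - rep_$removed)
    expect_identical(rep_$loci_in[-1], rep_$loci_out[-nrow(rep_)])
    ## manual composition gives the same survivor set
    manual <- hweExactFilter(thinFirstSnpPerTag(filterParalogTags(
        filterCallRate(g, 0.7))), 0.01)
    expect_identical(rownames(res$genotypes), rownames(manual))
    ## surviving genotypes are untouched
    expect_identical(dosage(res$genotypes),
                     dosage(g)[rownames(res$genotypes), ])
    ## an already-clean matrix passes unchanged
    clean <- res$genotypes
    res2 <- runFilterCascade(clean, runConfig())
    expect_identical(rownames(res2$genotypes), rownames(clean))
    expect_identical(sum(res2$report$removed), 0L)
})
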