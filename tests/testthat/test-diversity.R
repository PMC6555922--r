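test_that("per-population diversity matches closed forms", {
    ## all heterozygotes: H_O = 1, p = 0.5
    d <- rbind(L1 = rep(1L, 8))
    colnames(d) <- paste0("i", 1:8)
    g <- makeGenotypes(d, c(A = 8))
    dv <- perPopDiversity(g)
    expect_equal(dv$H_O, 1)
    expect_equal(dv$H_E, 2 * .5 * .5 * 16 / 15)
    ## n = 2 with genotypes {0, 2}: 2x2 differing pairs among C(4,2) = 6
    d2 <- rbind(L1 = c(0L, 2L))
    colnames(d2) <- c("i1", "i2")
    g2 <- makeGenotypes(d2, c(A = 2))
    expect_equal(perPopDiversity(g2)$Pi, 2 / 3)
})

test_that("unbiased H_E estimator is unbiased under binomial sampling", {
    set.seed(31)
    p <- 0.3; n <- 6
    he_true <- 2 * p * (1 - p)
    reps <- replicate(10000, {
        x <- rbinom(n, 2, p)
        ph <- sum(x) / (2 * n)
        2 * ph * (1 - ph) * 2 * n / (2 * n - 1)
    })
    expect_lt(abs(mean(reps) - he_true), 3 * sd(reps) / sqrt(10000))
})

test_that("Weir-Cockerham theta matches the allele-level ANOVA oracle", {
    ## limits first
    n <- 200
    d_fix <- rbind(L1 = c(rep(0L, n), rep(2L, n)))
    colnames(d_fix) <- paste0("i", 1:(2 * n))
    g_fix <- makeGenotypes(d_fix, c(A = n, B = n))
    expect_gt(wcFst(g_fix)$theta, 0.99)
    ## randomized small instances against the independent oracle
    set.seed(32)
    for (rep_i in 1:8) {
        P <- sample(2:6, 1)
        L <- sample(10:50, 1)
        npp <- sample(4:10, 1)
        freq <- matrix(runif(L * P, 0.05, 0.95), L, P)
        d <- dosageFromFreq(freq, npp)
        d[sample(length(d), round(length(d) * 0.05))] <- NA
        g <- makeGenotypes(d, setNames(rep(npp, P), paste0("p", 1:P)))
        ours <- wcFst(g)$theta
        oracle <- thetaAnovaOracle(d, rep(paste0("p", 1:P), each = npp))
        expect_equal(ours, oracle, tolerance = 1e-10)
    }
})

test_that("theta is near zero for identical frequencies at large n", {
    set.seed(33)
    freq <- matrix(runif(400, .2, .8), 400, 1)
    d <- dosageFromFreq(cbind(freq, freq), 150)
    g <- makeGenotypes(d, c(A = 150, B = 150))
    expect_lt(abs(wcFst(g)$theta), 0.01)
})

test_that("pairwise permutation p is invariant to allele relabeling", {
    set.seed(34)
    d <- dosageFromFreq(matrix(runif(60, .2, .8), 30, 2), 10)
    g <- makeGenotypes(d, c(A = 10, B = 10))
    r1 <- pairwiseFstTest(g, n_perm = 200, seed = 5)
    d2 <- 2L - dosage(g)                    # swap 0 <-> 2
    g2 <- makeGenotypes(d2, c(A = 10, B = 10))
    r2 <- pairwiseFstTest(g2, n_perm = 200, seed = 5)
    expect_equal(r1$p, r2$p)
    expect_equal(r1$fst, r2$fst)
})

test_that("duplicated population gives theta <= 0 and p near 1", {
    set.seed(35)
    freq <- matrix(runif(200, .2, .8), 200, 1)
    d1 <- dosageFromFreq(freq, 20)
    dd <- cbind(d1, d1)
    colnames(dd) <- paste0("i", seq_len(ncol(dd)))
    g <- makeGenotypes(dd, c(A = 20, B = 20))
    r <- pairwiseFstTest(g, n_perm = 200, seed = 6)
    expect_lte(r$fst["A", "B"], 0)
    expect_gt(r$p["A", "B"], 0.5)
})

test_that("Nm inversion follows the island-model closed form", {
    expect_equal(nmFromFst(0.2), 1)
    expect_equal(nmFromFst(1 / (4 * 12.505 + 1)), 12.505)
    ## monotone divergence toward 0+
    f <- c(0.2, 0.1, 0.01, 0.001)
    expect_true(all(diff(nmFromFst(f)) > 0))
    expect_warning(nm0 <- nmFromFst(0), "undefined")
    expect_true(is.na(nm0))
})

test_that("linearized F(ST) is exact and monotone; F(ST)=1 errors", {
    m <- matrix(c(0, 0.052, 0.052, 0), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
    lf <- linearizedFst(m)
    expect_equal(lf["A", "B"], 0.052 / (1 - 0.052))
    f <- seq(0.01, 0.9, 0.05)
    expect_true(all(diff(f / (1 - f)) > 0))
    m[1, 2] <- m[2, 1] <- 1
    expect_error(linearizedFst(m), "cannot be linearized")
})

test_that("geographic distance matches a haversine oracle", {
    st <- data.frame(population = c("a", "b", "c"),
                     latitude = c(10, 10, -10),
                     longitude = c(20, 20, -160),
                     temp_c = 20)
    D <- geographicDistance(st)
    expect_equal(D["a", "b"], 0)
    ## antipodal points: half the Earth circumference
    expect_equal(D["a", "c"], haversineOracle(10, 20, -10, -160),
                 tolerance = 1e-6)
    expect_gt(D["a", "c"], 19900)
    expect_lt(D["a", "c"], 20100)
    ## every entry against the oracle
    for (i in 1:3) for (j in 1:3)
        expect_equal(D[i, j],
                     haversineOracle(st$latitude[i], st$longitude[i],
                                     st$latitude[j], st$longitude[j]),
                     tolerance = 1e-6)
})

test_that("Mantel test: identity gives r = 1 and agrees with vegan", {
    set.seed(36)
    P <- 7
    xy <- matrix(runif(P * 2), P)
    A <- as.matrix(dist(xy))
    r <- mantelTest(A, A, n_perm = 99, seed = 1)
    expect_equal(r$r, 1)
    expect_equal(r$R2, 1)
    B <- as.matrix(dist(matrix(runif(P * 2), P))) + 0.3 * A
    ours <- mantelTest(A, B, n_perm = 999, seed = 2)
    vg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
    expect_equal(ours$r, unname(vg$statistic), tolerance = 1e-12)
    expect_lt(abs(ours$p - vg$signif), 0.05)
    expect_error(mantelTest(A * 0, A, n_perm = 99), "constant")
})

test_that("Nei distance is 0 for identical frequencies and positive otherwise", {
    set.seed(37)
    freq <- matrix(runif(300, .2, .8), 300, 1)
    d <- dosageFromFreq(cbind(freq, freq), 100)
    ## identical genotype copies -> identical sample frequencies
    d2 <- cbind(d[, 1:100], d[, 1:100])
    colnames(d2) <- paste0("i", seq_len(ncol(d2)))
    g <- makeGenotypes(d2, c(A = 100, B = 100))
    expect_equal(unname(neiDistance(g)["A", "B"]), 0, tolerance = 1e-12)
})

test_that("NJ recovers an additive 4-taxon topology and 3-taxon lengths", {
    ## additive matrix from a known tree ((A:1,B:2):1,(C:3,D:4))
    D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    D["A", "B"] <- D["B", "A"] <- 3
    D["A", "C"] <- D["C", "A"] <- 5
    D["A", "D"] <- D["D", "A"] <- 6
    D["B", "C"] <- D["C", "B"] <- 6
    D["B", "D"] <- D["D", "B"] <- 7
    D["C", "D"] <- D["D", "C"] <- 7
    tr <- ape::nj(as.dist(D))
    ## AB | CD split present
    parts <- ape::prop.part(tr)
    tips <- tr$tip.label
    has_ab <- any(vapply(parts, function(p)
        setequal(tips[p], c("A", "B")) || setequal(tips[p], c("C", "D")),
        TRUE))
    expect_true(has_ab)
    expect_equal(sum(tr$edge.length), 11)   # total length of the true tree
    ## three-taxon closed form: a = (dAB + dAC - dBC) / 2 etc.
    D3 <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3, 3,
                 dimnames = list(LETTERS[1:3], LETTERS[1:3]))
    tr3 <- ape::nj(as.dist(D3))
    a <- (5 + 7 - 8) / 2
    b <- (5 + 8 - 7) / 2
    cc <- (7 + 8 - 5) / 2
    expect_equal(sort(tr3$edge.length), sort(c(a, b, cc)))
})

test_that("locus-bootstrap NJ tree carries support on a clustered design", {
    set.seed(38)
    ## two tight clusters of populations
    des <- simulationDesign(
        pops = data.frame(population = paste0("P", 1:4),
                          group = c("g1", "g1", "g2", "g2"),
                          native = TRUE, latitude = c(20, 21, 40, 41),
                          longitude = 110, n = 15),
        branches = data.frame(
            node = c("n1", "n2", paste0("P", 1:4)),
            parent = c(NA, NA, "n1", "n1", "n2", "n2"),
            c = c(0.15, 0.15, 0.02, 0.02, 0.02, 0.02)))
    g <- simulateMetapopulation(des, 400, seed = 9)
    tr <- njTree(g, n_boot = 100, seed = 2)
    expect_s3_class(tr, "phylo")
    expect_true(all(tr$node.label >= 0 & tr$node.label <= 1))
    ## the P1P2 | P3P4 bipartition should be strongly supported
    expect_gt(max(tr$node.label), 0.9)
})

test_that("genotype PCA separates diverged clusters, handles duplicates", {
    set.seed(39)
    des <- starDesign(2, 0.2, 25)
    g <- simulateMetapopulation(des, 300, seed = 10)
    pc <- suppressWarnings(pcaGenotypes(g, 3))
    pop <- popMap(g)$population
    margin <- min(pc$coords[pop == "P1", 1]) > max(pc$coords[pop == "P2", 1]) ||
        min(pc$coords[pop == "P2", 1]) > max(pc$coords[pop == "P1", 1])
    expect_true(margin)
    expect_true(all(diff(pc$eigenvalues) <= 1e-9))
    expect_true(all(pc$eigenvalues >= 0))
    ## a duplicated individual projects to identical coordinates
    d <- dosage(g); d <- cbind(d, dup = d[, 1])
    colnames(d)[ncol(d)] <- "dup"
    pm <- rbind(popMap(g),
                data.frame(individual = "dup", population = "P1",
                           group = "g1", native = TRUE))
    g2 <- GenotypeData(d, pm)
    pc2 <- suppressWarnings(pcaGenotypes(g2, 2))
    expect_equal(pc2$coords["dup", ], pc2$coords[1, ],
                 tolerance = 1e-8, ignore_attr = TRUE)
})
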