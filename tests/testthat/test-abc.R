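test_that("prior draws satisfy every ordering constraint, deterministically", {
    pr <- priorSet()
    set.seed(51)
    for (i in 1:200) {
        p <- samplePrior(pr)
        expect_true(p["t3"] > p["t2"])
        expect_true(p["t2"] > p["t1"])
        expect_true(p["t1"] > p["db"])
        expect_true(p["N_I"] > p["Nm"])
        expect_true(p["r"] > 0 && p["r"] < 1)
    }
    set.seed(7); a <- samplePrior(pr)
    set.seed(7); b <- samplePrior(pr)
    expect_identical(a, b)
})

test_that("P(N_I > Nm) acceptance matches the discrete-uniform closed form", {
    ## for iid discrete uniforms on {10..10000}: P(X > Y) = (1 - 1/K) / 2
    K <- 10000 - 10 + 1
    p_exact <- (1 - 1 / K) / 2
    set.seed(52)
    draws <- matrix(floor(runif(2 * 20000, 10, 10001)), ncol = 2)
    p_mc <- mean(draws[, 1] > draws[, 2])
    expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 20000))
})

test_that("unsatisfiable priors error out", {
    pr <- priorSet(t1 = c(100, 150), t2 = c(1, 50))   # t2 > t1 impossible
    set.seed(53)
    expect_error(samplePrior(pr), "unsatisfiable")
})

test_that("a single panmictic population shows no differentiation
           between its two halves", {
    set.seed(54)
    ev <- matrix(numeric(0), 0, 6)
    cnt <- RadPopGen:::.simScenarioCounts(3000L, c(60L, 0L, 0L, 0L),
                                          c(1000, 1000, 1000, 1000), ev)
    ## split the 60 lineages arbitrarily into two pseudo-populations:
    ## lineages are exchangeable, so resample counts hypergeometrically
    kA <- stats::rhyper(3000, 30, 30, cnt[, 1])
    alt <- cbind(kA, cnt[, 1] - kA)
    n <- matrix(15, 3000, 2)
    th <- RadPopGen:::.thetaFromCounts(alt, n,
        alt * (2 * n - alt) / ((2 * n - 1) * n))
    expect_lt(abs(th), 0.02)
})

test_that("coalescent simulator agrees with msprime on diversity and
           F(ST) for three parameter sets", {
    skip_if(Sys.which("python") == "", "python not available")
    have <- system2("python", c("-c", shQuote("import msprime")),
                    stdout = FALSE, stderr = FALSE)
    skip_if(have != 0, "msprime not available")
    py <- '
import msprime, sys
N, t, n, reps = float(sys.argv[1]), float(sys.argv[2]), int(sys.argv[3]), int(sys.argv[4])
dem = msprime.Demography()
dem.add_population(name="A", initial_size=N)
dem.add_population(name="B", initial_size=N)
dem.add_population(name="anc", initial_size=N)
dem.add_population_split(time=t, derived=["A", "B"], ancestral="anc")
import numpy as np
rng = np.random.default_rng(99)
rows = []
for ts in msprime.sim_ancestry(samples={"A": n, "B": n}, demography=dem,
                               sequence_length=1, discrete_genome=False,
                               num_replicates=reps, random_seed=99):
    tr = ts.first()
    nodes = [u for u in tr.nodes() if tr.parent(u) != -1]
    lens = np.array([tr.branch_length(u) for u in nodes])
    u = nodes[rng.choice(len(nodes), p=lens / lens.sum())]
    der = set(tr.samples(u))
    popA = ts.samples(population=0); popB = ts.samples(population=1)
    rows.append((sum(1 for s in popA if s in der),
                 sum(1 for s in popB if s in der)))
print("\\n".join("%d\\t%d" % r for r in rows))
'
    params <- list(c(N = 1000, t = 2000), c(N = 2000, t = 500),
                   c(N = 500, t = 1500))
    for (ps in params) {
        n_dip <- 12L
        out <- system2("python", c("-", ps["N"], ps["t"], n_dip, 1500),
                       input = py, stdout = TRUE)
        mat <- do.call(rbind, lapply(strsplit(out, "\t"), as.integer))
        skip_if(is.null(mat) || nrow(mat) < 300, "msprime output empty")
        ## our simulator under the same demography
        spec <- scenarioSpec("custom", events = function(par)
            rbind(c(par[["t3"]], 1, 1, 0, 0, 0)))
        par <- c(N_A = unname(ps["N"]), N_B = unname(ps["N"]), N_I = 10,
                 N_M = 10, Nm = 5, t1 = 2, t2 = 3, t3 = unname(ps["t"]),
                 db = 1, r = 0.5)
        set.seed(55)
        cnt <- RadPopGen:::.simScenarioCounts(4000L,
            c(2L * n_dip, 2L * n_dip, 0L, 0L),
            as.numeric(par[c("N_A", "N_B", "N_I", "N_M")]),
            rbind(c(par[["t3"]], 1, 1, 0, 0, 0)))
        statFor <- function(m) {
            nn <- matrix(n_dip, nrow(m), 2)
            he <- m * (2 * nn - m) / ((2 * nn - 1) * nn) / 2 * 2
            th <- RadPopGen:::.thetaFromCounts(m, nn, he)
            c(div = mean(2 * (m / (2 * nn)) * (1 - m / (2 * nn))),
              fst = th)
        }
        ours <- statFor(cnt[, 1:2])
        orac <- statFor(mat)
        ## 3 Monte-Carlo SEs on each statistic
        se_div <- sd(rowMeans(2 * (mat / (2 * n_dip)) *
                              (1 - mat / (2 * n_dip)))) / sqrt(nrow(mat))
        expect_lt(abs(ours["div"] - orac["div"]),
                  3 * se_div + 0.02 * orac["div"])
        expect_lt(abs(ours["fst"] - orac["fst"]), 0.05)
    }
})

test_that("full admixture (r = 1) reproduces the direct-split scenario", {
    set.seed(56)
    par <- c(N_A = 2000, N_B = 2000, N_I = 1000, N_M = 2000, Nm = 100,
             t1 = 50, t2 = 51, t3 = 3000, db = 20, r = 1)
    s_adm <- scenarioSpec("admixture")
    s_a <- scenarioSpec("split_A")
    stats_of <- function(spec, B) {
        t(replicate(B, {
            cnt <- RadPopGen:::.scenarioCountsMatrix(spec, par, 400, 10)
            summaryStatsFromCounts(cnt, matrix(10, 400, 3),
                                   c("A", "B", "I"))
        }))
    }
    sa <- stats_of(s_adm, 60)
    sb <- stats_of(s_a, 60)
    ## two-sample KS on each key statistic family at the 5% level with a
    ## Bonferroni guard across statistics
    key <- c("div_I", "fst_A_I", "fst_B_I", "nei_A_I", "nei_B_I")
    ps <- vapply(key, function(k)
        suppressWarnings(stats::ks.test(sa[, k], sb[, k])$p.value), 0)
    expect_true(all(ps > 0.05 / length(ps)))
})

test_that("summary statistics are deterministic, complete and degenerate-safe", {
    set.seed(57)
    d <- dosageFromFreq(matrix(runif(150, .2, .8), 50, 3), 8)
    g <- makeGenotypes(d, c(A = 8, B = 8, C = 8))
    s1 <- summaryStats(g)
    s2 <- summaryStats(g)
    expect_identical(s1, s2)
    ## panel size for 3 populations: 3 div + 3 var + 3 fst + 3 nei + 9 maf
    expect_identical(length(s1), 21L)
    expect_false(any(!is.finite(s1)))
    ## three identical populations: distances near zero
    freq <- matrix(runif(200, .2, .8), 200, 1)
    dd <- dosageFromFreq(cbind(freq, freq, freq), 30)
    gg <- makeGenotypes(dd, c(A = 30, B = 30, C = 30))
    ss <- summaryStats(gg)
    expect_lt(abs(ss["fst_A_B"]), 0.02)
    expect_lt(ss["nei_A_B"], 0.02)
})

test_that("reference tables are stratified, seeded and well-shaped", {
    specs <- list(adm = scenarioSpec("admixture"),
                  yangtze = scenarioSpec("split_A"),
                  pearl = scenarioSpec("split_B"))
    pr <- priorSet()
    ref <- buildReferenceTable(specs, pr, n_sims = 30, n_loci = 100,
                               n_diploids = 6, seed = 2)
    expect_identical(as.integer(table(ref$scenario)), c(10L, 10L, 10L))
    ## columns: scenario + 10 parameters + 21 statistics
    expect_identical(ncol(ref), 32L)
    ref2 <- buildReferenceTable(specs, pr, n_sims = 30, n_loci = 100,
                                n_diploids = 6, seed = 2)
    expect_identical(ref, ref2)
})

test_that("model choice returns a proper posterior with symmetry for
           duplicated scenarios", {
    specs <- list(s1 = scenarioSpec("split_A"), s2 = scenarioSpec("split_A"))
    pr <- priorSet()
    set.seed(58)
    ref <- buildReferenceTable(specs, pr, n_sims = 400, n_loci = 150,
                               n_diploids = 8, seed = 3)
    par <- samplePrior(pr)
    cnt <- RadPopGen:::.scenarioCountsMatrix(specs$s1, par, 150, 8)
    obs <- summaryStatsFromCounts(cnt, matrix(8, 150, 3), c("A", "B", "I"))
    mc <- modelChoice(ref, obs, top_frac = 0.25)
    expect_equal(sum(mc$posterior), 1, tolerance = 1e-6)
    ## identical scenarios: no scenario should dominate
    expect_lt(abs(mc$posterior[1] - 0.5), 0.35)
    expect_true(all(mc$ci_upper >= mc$posterior - 1e-9, na.rm = TRUE))
})

test_that("parameter estimation at top_frac = 1 returns the prior sample", {
    specs <- list(adm = scenarioSpec("admixture"),
                  spl = scenarioSpec("split_A"))
    pr <- priorSet()
    ref <- buildReferenceTable(specs, pr, n_sims = 300, n_loci = 80,
                               n_diploids = 6, seed = 4)
    obs <- unlist(ref[1, RadPopGen:::.statCols(ref)])
    est <- estimateParameters(ref, obs, "adm", top_frac = 1)
    draws <- attr(est, "draws")
    sub <- ref[ref$scenario == "adm", ]
    ## the r draws are exactly the retained prior draws
    expect_equal(sort(draws$r), sort(sub$r), tolerance = 1e-6)
    ## medians close to the prior medians
    expect_lt(abs(est$median[est$parameter == "r"] - median(sub$r)), 1e-9)
})

test_that("PCA model check places self-simulated data inside the cloud", {
    specs <- list(adm = scenarioSpec("admixture"),
                  spl = scenarioSpec("split_A"))
    pr <- priorSet()
    ref <- buildReferenceTable(specs, pr, n_sims = 200, n_loci = 80,
                               n_diploids = 6, seed = 5)
    sn <- RadPopGen:::.statCols(ref)
    obs <- unlist(ref[7, sn])
    pred <- as.matrix(ref[ref$scenario == "adm", sn])
    chk <- modelCheckPca(ref, obs, predictive = pred)
    expect_true(chk$obs_inside)
    expect_identical(ncol(chk$ref_coords), 2L)
})
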