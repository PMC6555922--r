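#' Simulation design for a structured metapopulation
#'
#' Describes the population graph the synthetic generator draws from: a drift
#' tree over populations (Balding-Nichols branches), admixture recipes and
#' founder bottlenecks, together with per-population sample sizes and site
#' covariates. Allele-frequency drift along a branch with parameter `c`
#' draws the child frequency from a Beta distribution with mean equal to the
#' parent frequency and variance `c * p * (1 - p)`, so `c` equals the
#' expected Weir-Cockerham F(ST) between parent and child.
#'
#' @param pops data.frame with one row per sampled population: `population`,
#'   `group`, `native` (logical), `latitude`, `longitude`, `n` (diploid
#'   sample size, >= 2).
#' @param branches data.frame of tree edges: `node`, `parent` (NA for the
#'   root), `c` (drift in `[0, 1)`). Nodes may be internal labels or sampled
#'   population names; a population absent from `branches` and from
#'   `admixture` is an error.
#' @param admixture optional list of recipes `list(target =, sources =,
#'   proportions =, c =)`: the target's frequency is the proportion-weighted
#'   mix of the source nodes' frequencies, followed by an extra drift step
#'   `c` (default 0). Proportions must sum to 1.
#' @param bottlenecks optional data.frame `population`, `Nm` (founder size),
#'   `db` (duration, generations): adds founder drift
#'   `c_f = 1 - (1 - 1/(2*Nm))^db`, the Wright-Fisher expectation for a
#'   `db`-generation bottleneck at size `Nm`.
#' @param individual_ancestry optional list of recipes
#'   `list(target =, weights =, ancestry = matrix)` describing populations
#'   whose *individuals* are heterogeneous mixtures: individuals are split
#'   into components by `weights`; a component's row of `ancestry` gives
#'   its ancestry fractions over the named source nodes (columns), and an
#'   individual's genotype at a locus is Binomial(2, q . p_nodes). This
#'   emulates a population containing both pure residents and recently
#'   admixed migrants, which is what makes population-level admixture
#'   recoverable (a pure anchor exists) and individual flagging
#'   meaningful.
#' @param temp_slope,temp_intercept,temp_sd annual-mean temperature is
#'   generated as `temp_intercept + temp_slope * latitude` plus Gaussian
#'   noise, reproducing the strong temperature-latitude collinearity of
#'   wide-latitude sampling designs.
#' @return a `simulation_design` list.
#' @seealso [grassCarpDesign()] for the package's default nine-population
#'   design; [simulateMetapopulation()].
#' @export
simulationDesign <- function(pops, branches, admixture = list(),
                             bottlenecks = NULL,
                             individual_ancestry = list(),
                             temp_slope = -0.5,
                             temp_intercept = 28.5, temp_sd = 0.3) {
    stopifnot(all(c("population", "group", "native", "latitude",
                    "longitude", "n") %in% colnames(pops)))
    if (any(pops$n < 2)) stop("sample sizes must be >= 2")
    if (any(branches$c < 0 | branches$c >= 1))
        stop("drift parameters must be in [0, 1)")
    for (a in admixture) {
        if (abs(sum(a$proportions) - 1) > 1e-8)
            stop("admixture proportions for '", a$target,
                 "' must sum to 1")
    }
    for (ia in individual_ancestry) {
        if (abs(sum(ia$weights) - 1) > 1e-8)
            stop("individual-ancestry weights for '", ia$target,
                 "' must sum to 1")
        if (any(abs(rowSums(ia$ancestry) - 1) > 1e-8))
            stop("individual ancestries for '", ia$target,
                 "' must be row-stochastic")
    }
    targets <- vapply(admixture, `[[`, "", "target")
    nodes <- c(branches$node, targets,
               vapply(individual_ancestry, `[[`, "", "target"))
    if (anyDuplicated(nodes))
        stop("each node must have exactly one derivation")
    if (!all(pops$population %in% nodes))
        stop("sampled populations missing from the graph: ",
             paste(setdiff(pops$population, nodes), collapse = ", "))
    ## cycle check: every node must reach the root
    parent_of <- c(stats::setNames(branches$parent, branches$node))
    for (nd in branches$node) {
        seen <- character(); cur <- nd
        while (!is.na(cur)) {
            if (cur %in% seen) stop("design graph contains a cycle at ", cur)
            seen <- c(seen, cur)
            cur <- if (cur %in% names(parent_of)) parent_of[[cur]] else NA
        }
    }
    structure(list(pops = as.data.frame(pops), branches = branches,
                   admixture = admixture, bottlenecks = bottlenecks,
                   individual_ancestry = individual_ancestry,
                   temp_slope = temp_slope, temp_intercept = temp_intercept,
                   temp_sd = temp_sd),
              class = "simulation_design")
}

#' Default nine-population design
#'
#' Six native populations in three river-system clusters (one of them an
#' admixed population combining all three clusters), and three introduced
#' populations founded by a bottleneck from an admixture of the two southern
#' clusters — the sampling structure of a wide-latitude river-system survey
#' with recorded introductions. Default drift levels put native-native
#' F(ST) at the few-percent level and native-introduced F(ST) an order of
#' magnitude higher, matching the differentiation ranges such surveys
#' report.
#'
#' @param n_per_pop diploid individuals sampled per population (recycled
#'   to 9; the default totals 197 individuals).
#' @param c_among among-cluster drift; `c_within` within-cluster drift.
#' @param c_within within-cluster drift.
#' @param admix_props mixing proportions (cluster H, Y, P) of the admixed
#'   northern population.
#' @param Nm_founder,db_founder founder-bottleneck size and duration for the
#'   introduced populations.
#' @return a `simulation_design`.
#' @export
grassCarpDesign <- function(n_per_pop = c(22, 22, 22, 22, 22, 22, 22,
                                          22, 21),
                            c_among = 0.03,
                            c_within = 0.012,
                            admix_props = c(0.488, 0.436, 0.075) / 0.999,
                            Nm_founder = 100, db_founder = 30) {
    pops <- data.frame(
        population = c("Nenjiang", "Hanjiang", "Jiujiang", "Shishou",
                       "Zhaoqing", "Vietnam", "Malaysia", "India", "Nepal"),
        group = c("Heilongjiang", "Yangtze", "Yangtze", "Yangtze",
                  "Pearl", "Pearl", "introduced", "introduced",
                  "introduced"),
        native = c(rep(TRUE, 6), rep(FALSE, 3)),
        latitude = c(49.2, 30.5, 29.7, 29.7, 23.0, 21.0, 3.1, 13.1, 27.7),
        longitude = c(125.2, 113.0, 116.0, 112.4, 112.5, 105.8, 101.7,
                      80.3, 85.3),
        n = rep_len(n_per_pop, 9L))
    branches <- data.frame(
        node = c("Hnode", "Ynode", "Pnode",
                 "Hanjiang", "Jiujiang", "Shishou", "Zhaoqing", "Vietnam",
                 "Mnode"),
        parent = c(NA, NA, NA,
                   "Ynode", "Ynode", "Ynode", "Pnode", "Pnode",
                   NA),
        c = c(c_among, c_among, c_among,
              rep(c_within, 5),
              0))
    ## the admixed-source node for introductions mixes the two southern
    ## clusters; the resident northern gene pool is its own node
    admixture <- list(
        list(target = "Mnode_mix", sources = c("Ynode", "Pnode"),
             proportions = c(0.5, 0.5), c = 0),
        list(target = "NenH", sources = "Hnode",
             proportions = 1, c = 0.005),
        list(target = "Malaysia", sources = "Mnode_mix",
             proportions = 1, c = 0.01),
        list(target = "India", sources = "Mnode_mix",
             proportions = 1, c = 0.01),
        list(target = "Nepal", sources = "India",
             proportions = 1, c = 0.005))
    bottlenecks <- data.frame(
        population = c("Malaysia", "India", "Nepal"),
        Nm = Nm_founder, db = db_founder)
    ## the northern population mixes pure residents with recently admixed
    ## migrants; the weight/ancestry split reproduces the target mean
    ## composition while leaving a pure anchor for the resident cluster
    w_pure <- 0.45
    q_mig <- (admix_props - w_pure * c(1, 0, 0)) / (1 - w_pure)
    anc <- rbind(c(1, 0, 0), q_mig)
    colnames(anc) <- c("NenH", "Ynode", "Pnode")
    individual_ancestry <- list(list(target = "Nenjiang",
                                     weights = c(w_pure, 1 - w_pure),
                                     ancestry = anc))
    simulationDesign(pops, branches, admixture, bottlenecks,
                     individual_ancestry = individual_ancestry)
}

.founderDrift <- function(Nm, db) 1 - (1 - 1 / (2 * Nm))^db

## per-population allele frequencies for n_loci loci under a design;
## returns L x P matrix plus ancestral p0
.designFrequencies <- function(design, n_loci,
                               divergent_idx = integer(0),
                               divergent_factor = 1) {
    p0 <- runif(n_loci, 0.05, 0.95)
    infl <- rep(1, n_loci)
    infl[divergent_idx] <- divergent_factor
    br <- design$branches
    freq <- list()
    ## resolve tree nodes in topological order (parents first)
    resolved <- character()
    pending <- br$node
    while (length(pending)) {
        ready <- pending[vapply(pending, function(nd) {
            par <- br$parent[br$node == nd]
            is.na(par) || par %in% resolved
        }, TRUE)]
        if (!length(ready)) stop("unresolvable design graph")
        for (nd in ready) {
            par <- br$parent[br$node == nd]
            cc <- pmin(br$c[br$node == nd] * infl, 0.999)
            src <- if (is.na(par)) p0 else freq[[par]]
            freq[[nd]] <- .bnDrawVec(src, cc)
        }
        resolved <- c(resolved, ready)
        pending <- setdiff(pending, ready)
    }
    ## admixture targets (may chain; resolve in dependency order)
    adm <- design$admixture
    done <- rep(FALSE, length(adm))
    while (!all(done)) {
        progressed <- FALSE
        for (i in seq_along(adm)) {
            if (done[i]) next
            a <- adm[[i]]
            if (!all(a$sources %in% names(freq))) next
            mix <- Reduce(`+`, Map(function(s, w) w * freq[[s]],
                                   a$sources, a$proportions))
            cc <- pmin((if (is.null(a$c)) 0 else a$c) * infl, 0.999)
            freq[[a$target]] <- .bnDrawVec(mix, cc)
            done[i] <- TRUE; progressed <- TRUE
        }
        if (!progressed) stop("unresolvable admixture recipes")
    }
    ## founder bottlenecks: one extra drift increment
    if (!is.null(design$bottlenecks)) {
        for (i in seq_len(nrow(design$bottlenecks))) {
            b <- design$bottlenecks[i, ]
            cf <- pmin(.founderDrift(b$Nm, b$db) * infl, 0.999)
            freq[[b$population]] <- .bnDrawVec(freq[[b$population]], cf)
        }
    }
    ## individual-ancestry populations: the population-level frequency is
    ## the weight-averaged mixture (used for truth bookkeeping; genotypes
    ## are drawn per individual component)
    for (ia in design$individual_ancestry) {
        src <- colnames(ia$ancestry)
        q_mean <- as.numeric(ia$weights %*% ia$ancestry)
        freq[[ia$target]] <- Reduce(`+`, Map(function(s0, w) w * freq[[s0]],
                                             src, q_mean))
    }
    P <- design$pops$population
    list(p0 = p0,
         freq = do.call(cbind, stats::setNames(freq[P], P)),
         node_freq = freq)
}

## vectorized Balding-Nichols with per-locus c
.bnDrawVec <- function(p, c) {
    out <- p
    idx <- which(c > 0)
    if (length(idx)) {
        cc <- if (length(c) == 1L) rep(c, length(p)) else c
        a <- p[idx] * (1 - cc[idx]) / cc[idx]
        b <- (1 - p[idx]) * (1 - cc[idx]) / cc[idx]
        out[idx] <- rbeta(length(idx), pmax(a, 1e-8), pmax(b, 1e-8))
    }
    out
}

#' Simulate genotypes for a metapopulation design
#'
#' Per locus, an ancestral frequency is drawn uniformly on (0.05, 0.95),
#' drifted along each branch of the design tree (Balding-Nichols Beta
#' steps), mixed at admixture events and given founder drift in bottlenecked
#' populations; genotypes are then binomial(2, p) draws per individual.
#' The generating truth (ancestral and per-population frequencies, locus
#' class labels) is stored in `metadata(g)$truth` and survives filtering
#' because locus ids are stable.
#'
#' @param design a [simulationDesign()].
#' @param n_loci number of loci.
#' @param seed integer seed (all randomness is drawn from R's RNG).
#' @param layout optional [tagLayout()] used to give loci RAD-tag ids and
#'   scaffold coordinates; default assigns one locus per tag on a single
#'   scaffold.
#' @param missing_rate fraction of genotype calls set to missing at random.
#' @return a [GenotypeData-class] object with site covariates attached.
#' @export
simulateMetapopulation <- function(design, n_loci, seed = 1L, layout = NULL,
                                   missing_rate = 0) {
    stopifnot(n_loci >= 1)
    set.seed(seed)
    fr <- .designFrequencies(design, n_loci)
    g <- .genotypesFromFrequencies(fr$freq, design, missing_rate,
                                   layout = layout,
                                   node_freq = fr$node_freq)
    truth <- data.frame(locus_id = rownames(dosage(g)),
                        class = "neutral", p0 = fr$p0)
    S4Vectors::metadata(g)$truth <- truth
    S4Vectors::metadata(g)$true_freq <- fr$freq
    g
}

.genotypesFromFrequencies <- function(freq, design, missing_rate = 0,
                                      layout = NULL, node_freq = NULL,
                                      override_idx = integer(0)) {
    pops <- design$pops
    n_loci <- nrow(freq)
    ia_of <- stats::setNames(design$individual_ancestry,
                             vapply(design$individual_ancestry, `[[`, "",
                                    "target"))
    cols <- list()
    ind_ids <- character(0)
    pm <- NULL
    ind_ancestry <- NULL
    for (j in seq_len(nrow(pops))) {
        n <- pops$n[j]
        popname <- pops$population[j]
        if (popname %in% names(ia_of) && !is.null(node_freq)) {
            ia <- ia_of[[popname]]
            src <- colnames(ia$ancestry)
            n_comp <- round(ia$weights * n)
            n_comp[length(n_comp)] <- n - sum(head(n_comp, -1))
            d <- matrix(0L, n_loci, n)
            at <- 0L
            for (cmp in seq_along(n_comp)) {
                if (n_comp[cmp] == 0) next
                p_i <- Reduce(`+`, Map(function(s0, w) w * node_freq[[s0]],
                                       src, ia$ancestry[cmp, ]))
                if (length(override_idx))
                    p_i[override_idx] <- freq[override_idx, popname]
                nn <- n_comp[cmp]
                d[, at + seq_len(nn)] <-
                    matrix(rbinom(n_loci * nn, 2L, rep(p_i, nn)),
                           nrow = n_loci)
                ind_ancestry <- rbind(ind_ancestry, data.frame(
                    individual = sprintf("%s_%02d", popname,
                                         at + seq_len(nn)),
                    component = cmp,
                    t(replicate(nn, ia$ancestry[cmp, ]))))
                at <- at + nn
            }
        } else {
            p <- freq[, popname]
            d <- matrix(rbinom(n_loci * n, 2L, rep(p, n)), nrow = n_loci)
        }
        cols[[j]] <- d
        ids <- sprintf("%s_%02d", popname, seq_len(n))
        ind_ids <- c(ind_ids, ids)
        pm <- rbind(pm, data.frame(individual = ids,
                                   population = popname,
                                   group = pops$group[j],
                                   native = pops$native[j]))
    }
    d <- do.call(cbind, cols)
    if (missing_rate > 0) {
        miss <- runif(length(d)) < missing_rate
        d[miss] <- NA
    }
    rownames(d) <- sprintf("L%06d", seq_len(n_loci))
    colnames(d) <- ind_ids
    loci <- if (is.null(layout)) NULL else
        assignTagsAndCoords(rownames(d), layout)
    st <- data.frame(population = pops$population,
                     latitude = pops$latitude,
                     longitude = pops$longitude,
                     temp_c = design$temp_intercept +
                         design$temp_slope * pops$latitude +
                         rnorm(nrow(pops), 0, design$temp_sd))
    g <- GenotypeData(d, popmap = pm, loci = loci, site_table = st)
    if (!is.null(ind_ancestry))
        S4Vectors::metadata(g)$individual_ancestry <- ind_ancestry
    g
}

#' Plan of loci under selection to plant into a simulation
#'
#' @param n_clinal loci whose population frequency follows
#'   `logit(p) = logit(p0) + slope * standardized(latitude)` — a latitudinal
#'   cline tied to the latitude/temperature covariate.
#' @param slope clinal slope on the logit scale (warning when 0: such loci
#'   are indistinguishable from neutral ones).
#' @param n_divergent loci whose branch drift is inflated by
#'   `divergent_factor` (positive-selection-like excess differentiation).
#' @param divergent_factor multiplier on branch drift variance.
#' @param n_balanced loci whose per-population frequencies are drawn around
#'   0.5 with small variance (balancing-selection-like excess
#'   heterozygosity and deficient differentiation).
#' @param balanced_c Beta variance parameter of balanced loci.
#' @return a `selection_plan` list.
#' @export
selectionPlan <- function(n_clinal = 0, slope = 2, n_divergent = 0,
                          divergent_factor = 5, n_balanced = 0,
                          balanced_c = 0.005) {
    if (n_clinal > 0 && slope == 0)
        warning("clinal loci with slope 0 are indistinguishable from neutral")
    structure(list(n_clinal = n_clinal, slope = slope,
                   n_divergent = n_divergent,
                   divergent_factor = divergent_factor,
                   n_balanced = n_balanced, balanced_c = balanced_c),
              class = "selection_plan")
}

#' Simulate a metapopulation with planted selected loci
#'
#' Runs [simulateMetapopulation()] and replaces disjoint random subsets of
#' loci with clinal, divergent and balanced loci per the plan. Truth labels
#' are recorded in `metadata(g)$truth$class` so that power and false
#' discovery rates can be scored after any filter cascade.
#'
#' @inheritParams simulateMetapopulation
#' @param plan a [selectionPlan()].
#' @return a [GenotypeData-class] object.
#' @export
simulateWithSelection <- function(design, n_loci, plan, seed = 1L,
                                  layout = NULL, missing_rate = 0) {
    n_planted <- plan$n_clinal + plan$n_divergent + plan$n_balanced
    stopifnot(n_planted <= n_loci)
    set.seed(seed)
    idx <- sample.int(n_loci, n_planted)
    idx_clinal <- idx[seq_len(plan$n_clinal)]
    idx_div <- idx[plan$n_clinal + seq_len(plan$n_divergent)]
    idx_bal <- idx[plan$n_clinal + plan$n_divergent +
                   seq_len(plan$n_balanced)]
    fr <- .designFrequencies(design, n_loci,
                             divergent_idx = idx_div,
                             divergent_factor = plan$divergent_factor)
    freq <- fr$freq
    pops <- design$pops
    if (length(idx_clinal)) {
        lat_z <- as.numeric(scale(pops$latitude))
        lp0 <- stats::qlogis(fr$p0[idx_clinal])
        for (j in seq_len(nrow(pops)))
            freq[idx_clinal, j] <- stats::plogis(lp0 +
                                                 plan$slope * lat_z[j])
    }
    if (length(idx_bal)) {
        cc <- plan$balanced_c
        a <- 0.5 * (1 - cc) / cc
        freq[idx_bal, ] <- matrix(rbeta(length(idx_bal) * nrow(pops), a, a),
                                  nrow = length(idx_bal))
    }
    ## clinal and balanced loci are planted at the population level and
    ## override any individual-ancestry mixture at those loci
    g <- .genotypesFromFrequencies(freq, design, missing_rate,
                                   layout = layout,
                                   node_freq = fr$node_freq,
                                   override_idx = c(idx_clinal, idx_bal))
    truth <- data.frame(locus_id = rownames(dosage(g)),
                        class = "neutral", p0 = fr$p0)
    truth$class[idx_clinal] <- "clinal"
    truth$class[idx_div] <- "divergent"
    truth$class[idx_bal] <- "balanced"
    S4Vectors::metadata(g)$truth <- truth
    S4Vectors::metadata(g)$true_freq <- freq
    g
}

#' RAD-tag layout for locus coordinates
#'
#' @param scaffold_lengths named numeric vector of scaffold lengths in bp;
#'   default 24 scaffolds spanning 9.6-19.1 Mb, the long-scaffold tier of a
#'   draft fish genome.
#' @param mean_snps_per_tag target mean number of SNPs per RAD tag
#'   (zero-SNP tags allowed; the mean is over all tags).
#' @param tag_length tag length in bp; SNPs on one tag fall within it.
#' @return a `tag_layout` list.
#' @export
tagLayout <- function(scaffold_lengths = NULL, mean_snps_per_tag = 0.61,
                      tag_length = 100L) {
    if (mean_snps_per_tag <= 0) stop("mean SNPs per tag must be > 0")
    if (is.null(scaffold_lengths)) {
        scaffold_lengths <- stats::setNames(
            round(seq(19.1e6, 9.6e6, length.out = 24)),
            sprintf("CI%08d", seq_len(24)))
    }
    structure(list(scaffold_lengths = scaffold_lengths,
                   mean_snps_per_tag = mean_snps_per_tag,
                   tag_length = as.integer(tag_length)),
              class = "tag_layout")
}

#' Draw per-tag SNP counts
#'
#' SNPs per tag are Poisson with the layout's target mean, truncated above
#' at the number of positions on a tag; most tags carry no SNP at a mean
#' well below 1.
#'
#' @param n_tags number of RAD tags.
#' @param layout a [tagLayout()].
#' @return integer vector of SNP counts per tag.
#' @export
simulateTagSnpCounts <- function(n_tags, layout = tagLayout()) {
    pmin(rpois(n_tags, layout$mean_snps_per_tag), layout$tag_length)
}

#' Assign loci to RAD tags and scaffold coordinates
#'
#' Tags are placed uniformly along the layout's scaffolds; SNPs-per-tag
#' counts follow [simulateTagSnpCounts()] and tags are drawn until the given
#' loci are covered. Within a tag, SNP offsets are distinct positions inside
#' the tag length, so loci sharing a tag are within `tag_length` bp;
#' coordinates are strictly increasing within a scaffold.
#'
#' @param locus_ids character vector of locus ids to place.
#' @param layout a [tagLayout()].
#' @return data.frame of locus metadata suitable for [GenotypeData()].
#' @export
assignTagsAndCoords <- function(locus_ids, layout = tagLayout()) {
    n <- length(locus_ids)
    counts <- integer(0)
    while (sum(counts) < n)
        counts <- c(counts, simulateTagSnpCounts(max(64L, n), layout))
    counts <- counts[counts > 0]
    cum <- cumsum(counts)
    n_tags <- which(cum >= n)[1L]
    counts <- counts[seq_len(n_tags)]
    counts[n_tags] <- counts[n_tags] - (sum(counts) - n)
    sl <- layout$scaffold_lengths
    scaffold <- sample(names(sl), n_tags, replace = TRUE,
                       prob = sl / sum(sl))
    tag_start <- floor(runif(n_tags) *
                       (sl[scaffold] - layout$tag_length)) + 1
    ## enforce distinct, sorted tag starts within scaffold
    ord <- order(scaffold, tag_start)
    scaffold <- scaffold[ord]; tag_start <- tag_start[ord]
    counts <- counts[ord]
    dup <- duplicated(paste(scaffold, tag_start))
    while (any(dup)) {
        tag_start[dup] <- floor(runif(sum(dup)) *
                                (sl[scaffold[dup]] - layout$tag_length)) + 1
        ord <- order(scaffold, tag_start)
        scaffold <- scaffold[ord]; tag_start <- tag_start[ord]
        counts <- counts[ord]
        dup <- duplicated(paste(scaffold, tag_start))
    }
    tag_id <- sprintf("tag%06d", seq_len(n_tags))
    offs <- lapply(counts, function(k)
        sort(sample.int(layout$tag_length, k)) - 1L)
    loci <- data.frame(
        locus_id = locus_ids,
        tag_id = rep(tag_id, counts),
        scaffold = rep(scaffold, counts),
        position = rep(tag_start, counts) + unlist(offs))
    ## a locus id must map to one (scaffold, position); collisions across
    ## tags are impossible because tag starts are distinct and offsets
    ## are within the tag
    loci[order(loci$scaffold, loci$position), c("locus_id", "tag_id",
                                                "scaffold", "position")] ->
        out
    out$locus_id <- locus_ids   # keep caller's id order tied to coordinates
    rownames(out) <- NULL
    out
}
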