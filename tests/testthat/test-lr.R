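test_that("directed candidates follow the secreted/membrane rule", {
    m1 <- LRModel(secreted = "L", membrane = "R", pairs = rbind(c("L", "R")))
    expect_identical(lrPairs(m1),
                     data.frame(ligand = "L", receptor = "R",
                                stringsAsFactors = FALSE))
    ## dual-annotated genes qualify in both directions
    m2 <- LRModel(secreted = c("X", "Y"), membrane = c("X", "Y"),
                  pairs = rbind(c("X", "Y")))
    p2 <- lrPairs(m2)
    expect_equal(nrow(p2), 2L)
    expect_setequal(paste(p2$ligand, p2$receptor), c("X Y", "Y X"))
    ## two secreted-only genes produce nothing
    m3 <- LRModel(secreted = c("S1", "S2"), membrane = character(),
                  pairs = rbind(c("S1", "S2")))
    expect_equal(nrow(lrPairs(m3)), 0L)
})

test_that("intensity is the mean-product sum with sorted contributions", {
    toy <- lrToy()
    r <- lrIntensity(toy$v, toy$ann, toy$model, "A", "B")
    expect_equal(intensity(r), 6)  # mean(2,4) * mean(1,3)
    ## silent ligand contributes zero
    r0 <- lrIntensity(toy$v, toy$ann, toy$model, "B", "A")
    expect_equal(pairContributions(r0)$contribution, 0)
    ## two pairs: total is the sum, top pair listed first
    v <- matrix(c(2, 4, 0, 0,
                  0, 0, 1, 3,
                  1, 1, 0, 0,
                  0, 0, 1, 1), 4, 4, byrow = TRUE,
                dimnames = list(c("L1", "R1", "L2", "R2"), paste0("c", 1:4)))
    mod <- LRModel(secreted = c("L1", "L2"), membrane = c("R1", "R2"),
                   pairs = rbind(c("L1", "R1"), c("L2", "R2")))
    r2 <- lrIntensity(v, toy$ann, mod, "A", "B")
    expect_equal(intensity(r2), 6 + 1)
    expect_identical(pairContributions(r2)$ligand, c("L1", "L2"))
    ## invariance to cell and gene order
    perm <- c(4, 2, 1, 3)
    r3 <- lrIntensity(v[c(3, 1, 4, 2), perm], toy$ann[perm, , drop = FALSE],
                      mod, "A", "B")
    expect_equal(intensity(r3), intensity(r2))
    ## monotonicity: scaling source ligand values scales contributions
    v4 <- v; v4[c("L1", "L2"), toy$ann$subgroup == "A"] <-
        3 * v4[c("L1", "L2"), toy$ann$subgroup == "A"]
    r4 <- lrIntensity(v4, toy$ann, mod, "A", "B")
    expect_equal(pairContributions(r4)$contribution,
                 3 * pairContributions(r2)$contribution)
    ## no usable pairs: zero intensity with a warning
    modEmpty <- LRModel(secreted = "Q", membrane = "W",
                        pairs = rbind(c("Q", "W")))
    expect_warning(rE <- lrIntensity(v, toy$ann, modEmpty, "A", "B"),
                   "no usable")
    expect_equal(intensity(rE), 0)
})

test_that("exhaustive permutation p on the 4-cell toy is exactly 1/6", {
    toy <- lrToy()
    ## the 6 arrangements of {A,A,B,B}: observed (c1c2|c3c4) gives 6, the
    ## unique maximum -> exact rank p = 1/6
    r <- lrPermutationP(toy$v, toy$ann, toy$model, "A", "B")
    expect_identical(r@method, "exhaustive")
    expect_equal(r@nPerm, 6L)
    expect_equal(pPerm(r), 1 / 6)
    ## enumerate by hand for the record
    arr <- combn(4, 2, simplify = FALSE)
    stats <- vapply(arr, function(a) {
        b <- setdiff(1:4, a)
        mean(toy$v["L", a]) * mean(toy$v["R", b])
    }, numeric(1))
    expect_equal(sum(stats >= 6) / 6, 1 / 6)
})

test_that("sampled permutation p converges to the exhaustive value", {
    toy <- lrToy()
    for (seed in c(2, 77)) {
        r <- lrPermutationP(toy$v, toy$ann, toy$model, "A", "B",
                            nPerm = 10000, seed = seed, exhaustiveCap = 0)
        expect_identical(r@method, "sampled")
        expect_lt(abs(pPerm(r) - 1 / 6), 0.02)
    }
})

test_that("degenerate and extreme permutation cases", {
    toy <- lrToy()
    ## autocrine with every cell in the subgroup: a single arrangement
    annAll <- data.frame(subgroup = rep("A", 4),
                         row.names = colnames(toy$v))
    modAuto <- LRModel(secreted = "L", membrane = "R",
                       pairs = rbind(c("L", "R")))
    rA <- lrPermutationP(toy$v, annAll, modAuto, "A", "A")
    expect_equal(pPerm(rA), 1)
    ## observed above all sampled permutations hits the add-one floor
    sim <- simulateSC(nGenes = 40, cellsPerSubgroup = c(60, 60),
                      nSubgroups = 2, markersPerSubgroup = 0,
                      lrPlant = list(ligand = "G0001", receptor = "G0002",
                                     source = "SG1", target = "SG2",
                                     fold = 40),
                      seed = 8)
    v <- log2CPM(as.matrix(assay(sim$sce, "counts")))
    mod <- LRModel(secreted = "G0001", membrane = "G0002",
                   pairs = rbind(c("G0001", "G0002")))
    r <- lrPermutationP(v, colData(sim$sce), mod, "SG1", "SG2",
                        nPerm = 1000, seed = 4, exhaustiveCap = 0)
    expect_equal(pPerm(r), 1 / 1001)
    expect_error(lrPermutationP(v, colData(sim$sce), mod, "SG1", "SG2",
                                nPerm = 0), "nPerm")
})

test_that("pair ranking pools, sorts and tie-breaks deterministically", {
    mk <- function(lig, contr, src, tgt) {
        pc <- data.frame(ligand = lig, receptor = paste0(lig, "r"),
                         contribution = contr, stringsAsFactors = FALSE)
        pc <- pc[order(-pc$contribution, pc$ligand), ]
        rownames(pc) <- NULL
        new("LRIntensity", source = src, target = tgt,
            intensity = sum(contr), pairContributions = pc,
            pPerm = NA_real_, nPerm = 0L, method = "none",
            seed = NA_integer_)
    }
    res <- list(mk(c("a", "b"), c(6, 3), "A", "B"),
                mk("c", 1, "B", "A"))
    top2 <- rankPairs(res, topK = 2)
    expect_equal(top2$contribution, c(6, 3))
    ## ties broken lexicographically -> stable across runs
    tie <- list(mk("zz", 5, "A", "B"), mk("aa", 5, "A", "B"))
    expect_identical(rankPairs(tie, topK = 2)$ligand, c("aa", "zz"))
    ## k larger than available returns everything
    expect_equal(nrow(rankPairs(res, topK = 50)), 3L)
})
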