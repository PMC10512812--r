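test_that("module score is the sum of z-values and is linear in the set", {
    z <- matrix(c(0.5, -0.5, 2), 3, 1,
                dimnames = list(c("gA", "gB", "gC"), "cell1"))
    expect_equal(unname(moduleScore(z, GeneSet("s", c("gA", "gB", "gC")))),
                 2.0, ignore_attr = TRUE)
    ## all-zero row contributes nothing; cancellation gives zero scores
    z2 <- rbind(gA = c(1, -2, 0.3), gB = c(-1, 2, -0.3))
    colnames(z2) <- paste0("c", 1:3)
    expect_equal(unname(moduleScore(z2, c("gA", "gB"))), c(0, 0, 0),
                 ignore_attr = TRUE)
    ## linearity over disjoint sets (exact)
    set.seed(21)
    z3 <- matrix(rnorm(50), 10, 5,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:5)))
    s1 <- moduleScore(z3, paste0("g", 1:4))
    s2 <- moduleScore(z3, paste0("g", 5:10))
    s12 <- moduleScore(z3, paste0("g", 1:10))
    expect_equal(unname(s12), unname(s1 + s2), ignore_attr = TRUE)
    ## absent genes are skipped with a message; zero overlap is fatal
    expect_message(sk <- moduleScore(z3, c("g1", "nope")), "nope")
    expect_identical(attr(sk, "genesSkipped"), "nope")
    expect_error(moduleScore(z3, c("x", "y")), "no genes")
})

test_that("score comparison is a Welch t-test with reporting stars", {
    s <- setNames(as.numeric(1:6), paste0("u", 1:6))
    cmp <- compareScores(s, paste0("u", 1:3), paste0("u", 4:6))
    expect_equal(cmp$t, -3.674235, tolerance = 1e-6)
    expect_equal(cmp$p, 0.02131, tolerance = 1e-4)
    expect_identical(cmp$stars, "*")
    ## identical groups: degenerate, p = 1, t = 0
    s2 <- setNames(rep(2, 4), paste0("u", 1:4))
    cmp2 <- compareScores(s2, c("u1", "u2"), c("u3", "u4"))
    expect_equal(cmp2$t, 0)
    expect_equal(cmp2$p, 1)
    expect_true(cmp2$degenerate)
    ## location invariance
    cmp3 <- compareScores(s + 100, paste0("u", 1:3), paste0("u", 4:6))
    expect_equal(cmp3$t, cmp$t)
    expect_equal(cmp3$p, cmp$p)
    ## reference Welch implementation on random inputs
    set.seed(13)
    for (i in 1:20) {
        a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.4, 2)
        sc <- setNames(c(a, b), paste0("v", seq_along(c(a, b))))
        cmp <- compareScores(sc, paste0("v", seq_along(a)),
                             paste0("v", length(a) + seq_along(b)))
        tt <- t.test(a, b)
        expect_equal(cmp$t, unname(tt$statistic), tolerance = 1e-10)
        expect_equal(cmp$p, tt$p.value, tolerance = 1e-10)
    }
})

test_that("featured-gene calls require strict max, significance and fraction", {
    ## toy: one gene high in B only, expressed in 3/5 B cells, plus
    ## bystander genes giving the BH family some members
    set.seed(5)
    nCell <- 15
    v <- rbind(gFeat = c(rep(0, 5), 2, 2, 2, 0, 0, rep(0, 5)),
               gFlat = rep(1, nCell),
               gNoise = abs(rnorm(nCell, 1, 0.05)),
               gRare = c(rep(0, 5), 9, rep(0, 4), rep(0, 5)))
    colnames(v) <- paste0("c", seq_len(nCell))
    ann <- data.frame(subgroup = rep(c("A", "B", "C"), each = 5))
    fg <- featuredGenes(v, ann, d0 = 0)
    expect_true("gFeat" %in% fg$gene)
    expect_identical(fg$subgroup[fg$gene == "gFeat"], "B")
    expect_equal(fg$expressed_fraction[fg$gene == "gFeat"], 0.6)
    ## constant gene: no strict max, never called
    expect_false("gFlat" %in% fg$gene)
    ## huge mean in 1/5 cells fails the 20% fraction filter
    expect_false("gRare" %in% fg$gene)
})

test_that("featured genes recover planted markers on one simulated cohort", {
    r <- featuredRecoveryOneSeed(101)
    expect_gte(r[["recovered"]] / r[["planted"]], 0.9)
    expect_lte(r[["false"]] / r[["nonMarkers"]], 0.01)
})

test_that("bulk panel scoring is linear, scale-invariant and recovers shifts", {
    sim <- simulateBulk(panel = crpcPanel12(), panelShift = 1.5, seed = 17)
    s6 <- panelScoreBulk(sim$se, crpcPanel6())
    added <- GeneSet("added", setdiff(geneIds(crpcPanel12()),
                                      geneIds(crpcPanel6())))
    sAdd <- panelScoreBulk(sim$se, added)
    s12 <- panelScoreBulk(sim$se, crpcPanel12())
    expect_equal(unname(s12), unname(s6 + sAdd), tolerance = 1e-12,
                 ignore_attr = TRUE)
    ## gene order within the panel is irrelevant
    s6r <- panelScoreBulk(sim$se, GeneSet("rev", rev(geneIds(crpcPanel6()))))
    expect_equal(unname(s6r), unname(s6), ignore_attr = TRUE)
    ## per-gene affine rescaling (slope > 0) of already-log input
    m <- log2(as.matrix(assay(sim$se, "expr")) + 1)
    sA <- panelScoreBulk(m, crpcPanel6(), log2Transform = FALSE)
    sB <- panelScoreBulk(2.5 * m + 3, crpcPanel6(), log2Transform = FALSE)
    expect_equal(unname(sB), unname(sA), tolerance = 1e-10,
                 ignore_attr = TRUE)
    ## planted shift separates the recurrent HT group
    st <- stratifyCohort(sim$se)
    expect_gt(mean(s12[st$HT_YES]), mean(s12[st$HT_NO]))
    ## identical samples: zero-variance rule zeroes all scores
    mc <- matrix(5, 6, 4, dimnames = list(geneIds(crpcPanel6()),
                                          paste0("s", 1:4)))
    expect_equal(unname(panelScoreBulk(mc, crpcPanel6())), rep(0, 4),
                 ignore_attr = TRUE)
})
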