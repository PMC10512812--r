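test_that("single-cell simulation is reproducible and plants markers", {
    a <- simulateSC(nGenes = 60, cellsPerSubgroup = c(30, 30), seed = 1,
                    markersPerSubgroup = 5)
    b <- simulateSC(nGenes = 60, cellsPerSubgroup = c(30, 30), seed = 1,
                    markersPerSubgroup = 5)
    expect_identical(as.matrix(assay(a$sce, "counts")),
                     as.matrix(assay(b$sce, "counts")))
    c2 <- simulateSC(nGenes = 60, cellsPerSubgroup = c(30, 30), seed = 2,
                     markersPerSubgroup = 5)
    expect_false(identical(as.matrix(assay(a$sce, "counts")),
                           as.matrix(assay(c2$sce, "counts"))))
    ## planted markers have their highest mean log2(CPM+1) at home
    sim <- simulateSC(seed = 6)  # defaults: log2FC 3, 200 cells/subgroup
    v <- log2CPM(as.matrix(assay(sim$sce, "counts")))
    ann <- as.data.frame(colData(sim$sce))
    prof <- subgroupMeanProfiles(v, ann)
    for (i in seq_len(nrow(sim$truth))) {
        g <- sim$truth$gene[i]
        expect_identical(rownames(prof)[which.max(prof[, g])],
                         sim$truth$subgroup[i])
    }
    ## too many markers for the gene universe is fatal
    expect_error(simulateSC(nGenes = 10, markersPerSubgroup = 5,
                            nSubgroups = 3), "more planted markers")
})

test_that("dispersion zero approaches the Poisson variance-mean identity", {
    sim <- simulateSC(nGenes = 200, cellsPerSubgroup = c(400, 400),
                      markersPerSubgroup = 0, nbDispersion = 0,
                      libSizeSd = 0, baselineMean = 5, seed = 9)
    m <- as.matrix(assay(sim$sce, "counts"))
    ratio <- apply(m, 1, var) / rowMeans(m)
    expect_equal(mean(ratio), 1, tolerance = 0.05)
    ## positive dispersion inflates variance above the mean
    sim2 <- simulateSC(nGenes = 200, cellsPerSubgroup = c(400, 400),
                       markersPerSubgroup = 0, nbDispersion = 0.5,
                       libSizeSd = 0, baselineMean = 5, seed = 9)
    m2 <- as.matrix(assay(sim2$sce, "counts"))
    expect_gt(mean(apply(m2, 1, var) / rowMeans(m2)), 2)
})

test_that("ligand-receptor planting elevates the targeted subgroup means", {
    sim <- simulateSC(nGenes = 50, cellsPerSubgroup = c(100, 100),
                      nSubgroups = 2, markersPerSubgroup = 0,
                      lrPlant = list(ligand = "G0001", receptor = "G0002",
                                     source = "SG1", target = "SG2",
                                     fold = 8),
                      seed = 12)
    m <- as.matrix(assay(sim$sce, "counts"))
    sub <- colData(sim$sce)$subgroup
    expect_gt(mean(m["G0001", sub == "SG1"]), 3 * mean(m["G0001", sub == "SG2"]))
    expect_gt(mean(m["G0002", sub == "SG2"]), 3 * mean(m["G0002", sub == "SG1"]))
})

test_that("bulk simulation reproduces requested strata exactly", {
    sim <- simulateBulk(seed = 4)  # defaults: HT_rec 14, HT_norec 53
    st <- stratifyCohort(sim$se)
    expect_length(st$HT_YES, 14L)
    expect_length(st$HT_NO, 53L)
    expect_length(st$normal, 52L)
    cd <- as.data.frame(colData(sim$se))
    ## recurrence times only on recurrent samples, all positive
    expect_true(all(is.na(cd$recurrence_time_days[!cd$group %in%
                                                  c("tumor_rec", "HT_rec")])))
    expect_true(all(cd$recurrence_time_days[cd$group %in%
                                            c("tumor_rec", "HT_rec")] > 0))
    expect_true(all(cd$therapy_type[cd$group %in% c("HT_norec", "HT_rec")] ==
                    "Hormone Therapy"))
    ## determinism
    sim2 <- simulateBulk(seed = 4)
    expect_identical(as.matrix(assay(sim$se, "expr")),
                     as.matrix(assay(sim2$se, "expr")))
})

test_that("null bulk configurations carry no panel signal", {
    n <- c(normal = 80, tumor_norec = 80, tumor_rec = 80, HT_norec = 80,
           HT_rec = 80)
    sim <- simulateBulk(nPerGroup = n, panelShift = 0, nGenes = 300,
                        seed = 19)
    ev <- evaluatePanel(sim$se, crpcPanel6())
    expect_true(all(abs(ev$contrasts$auc - 0.5) < 0.15))
    ## timeBeta = 0: no score-time association beyond noise
    sim2 <- simulateBulk(nPerGroup = n, panelShift = 2, timeBeta = 0,
                         nGenes = 300, seed = 20)
    ev2 <- evaluatePanel(sim2$se, crpcPanel6())
    expect_lt(abs(ev2$timeAnalyses$HT_YES$correlation$r), 0.3)
})

test_that("simulated cohorts round-trip through the writers and readers", {
    sim <- simulateBulk(nPerGroup = c(normal = 4, tumor_norec = 5,
                                      tumor_rec = 5, HT_norec = 4,
                                      HT_rec = 4),
                        nGenes = 20, seed = 2)
    d <- withr::local_tempdir()
    writeBulkCohort(sim$se, d)
    se2 <- readBulkCohort(file.path(d, "expr.tsv"), file.path(d, "pheno.tsv"))
    expect_equal(as.matrix(assay(se2, "expr")),
                 as.matrix(assay(sim$se, "expr")), tolerance = 1e-10)
    st1 <- stratifyCohort(sim$se); st2 <- stratifyCohort(se2)
    expect_identical(st1[names(st1)], st2[names(st1)])
})
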