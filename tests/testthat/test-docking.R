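mkAtomStruct <- function(xyz, names = sprintf("C%d", seq_len(nrow(xyz))),
                         element = "C", resSeq = 1L, chain = "A") {
    n <- nrow(xyz)
    Structure(data.frame(serial = seq_len(n), name = names,
                         element = element, resName = "TOY",
                         resSeq = resSeq, chain = chain,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         vdw = vdwRadius(rep(element, n))))
}

test_that("pose sampling is centred, uniform in the ball, and seed-reproducible", {
    cx <- makeToyComplex(toyComplexSpec(seed = 1))
    cfg <- dockingConfig(samplingCenter = c(1, 2, 3), samplingRadius = 1e-9,
                         seed = 1)
    set.seed(1)
    p <- samplePose(cx@ligand, cfg)
    cen <- colMeans(coords(applyTransform(p@transform, cx@ligand)))
    expect_equal(cen, c(1, 2, 3), tolerance = 1e-7)
    # centroid mean over many draws matches the uniform-ball expectation
    R <- 2.5
    cfg2 <- dockingConfig(samplingCenter = c(0, 0, 0), samplingRadius = R)
    set.seed(2)
    cents <- t(replicate(4000, {
        q <- samplePose(cx@ligand, cfg2)
        colMeans(coords(applyTransform(q@transform, cx@ligand)))
    }))
    se <- R / sqrt(5 * nrow(cents))   # per-axis sd of U(ball) = R/sqrt(5)
    expect_true(all(abs(colMeans(cents)) < 3 * se + 1e-12))
    # fixed seed reproduces the pose sequence bit-identically
    draw <- function() replicate(5, samplePose(cx@ligand, cfg2)@transform@translation)
    set.seed(7); a <- draw()
    set.seed(7); b <- draw()
    expect_identical(a, b)
})

test_that("the true pose of a zero-noise toy complex scores zero", {
    cx <- makeToyComplex(toyComplexSpec(seed = 6))
    act <- deriveActiveResidues(cx@peaks, cx@protonGroups, cx@siteLabels)
    airs <- buildResidueAIRs(cx@ligand, cx@receptor, act)
    cfg <- dockingConfig(samplingCenter = c(0, 0, 0))
    truth <- new("Pose", transform = cx@truePose, receptorIndex = 1L)
    sc <- scorePose(truth, cx@receptor, cx@ligand, airs, cfg)
    expect_equal(sc@eAir, 0)
    expect_equal(sc@eSteric, 0)
    expect_equal(sc@score, 0)
})

test_that("a single AIR exceeded by 0.5 Angstrom scores 0.25 with no clash", {
    lig <- mkAtomStruct(matrix(c(0, 0, 0), ncol = 3), names = "C1")
    rec <- mkAtomStruct(matrix(c(5.5, 0, 0), ncol = 3), names = "CM",
                        resSeq = 101L)
    airs <- RestraintSet(list(list(
        id = "AIR-101",
        groupA = list(owner = "ligand", atoms = "C1", residue = NA_integer_),
        groupB = list(owner = "receptor", atoms = "CM", residue = 101L),
        lower = 0.5, upper = 5.0, level = "heavy")))
    cfg <- dockingConfig(wAir = 1, wSteric = 1)
    pose <- new("Pose", transform = RigidTransform(), receptorIndex = 1L)
    sc <- scorePose(pose, rec, lig, airs, cfg)
    expect_equal(sc@eAir, 0.25, tolerance = 1e-12)
    expect_equal(sc@eSteric, 0)
    expect_equal(sc@score, 0.25, tolerance = 1e-12)
})

test_that("the steric penalty equals the hand-computed soft-core sum", {
    # three receptor carbons at 2.0, 2.5 and 3.0 Angstrom from one ligand C;
    # soft-core limit is (1.7 + 1.7) * 0.8 = 2.72
    lig <- mkAtomStruct(matrix(c(0, 0, 0), ncol = 3), names = "C1")
    rec <- mkAtomStruct(rbind(c(2, 0, 0), c(0, 2.5, 0), c(0, 0, 3)),
                        names = c("A1", "A2", "A3"), resSeq = 101L)
    cfg <- dockingConfig()
    pose <- new("Pose", transform = RigidTransform(), receptorIndex = 1L)
    sc <- scorePose(pose, rec, lig, RestraintSet(), cfg)
    expect_equal(sc@eAir, 0)
    expect_equal(sc@eSteric, (2.72 - 2)^2 + (2.72 - 2.5)^2,
                 tolerance = 1e-12)
})

test_that("score decomposition is exact for arbitrary weights", {
    cx <- makeToyComplex(toyComplexSpec(seed = 2))
    act <- deriveActiveResidues(cx@peaks, cx@protonGroups, cx@siteLabels)
    airs <- buildResidueAIRs(cx@ligand, cx@receptor, act)
    cfg <- dockingConfig(wAir = 0.7, wSteric = 2.3,
                         samplingCenter = c(0, 0, 0), samplingRadius = 4)
    set.seed(3)
    for (i in 1:10) {
        p <- scorePose(samplePose(cx@ligand, cfg), cx@receptor, cx@ligand,
                       airs, cfg)
        expect_equal(p@score, 0.7 * p@eAir + 2.3 * p@eSteric,
                     tolerance = 1e-12)
        expect_gte(p@eAir, 0); expect_gte(p@eSteric, 0)
    }
})

test_that("minimization is monotone, rigid, and recovers a smooth funnel", {
    cx <- makeToyComplex(toyComplexSpec(seed = 4))
    act <- deriveActiveResidues(cx@peaks, cx@protonGroups, cx@siteLabels)
    airs <- buildResidueAIRs(cx@ligand, cx@receptor, act)
    ip <- calibratePeaks(cx@peaks, cx@protonGroups)
    both <- RestraintSet(c(restraints(airs), restraints(ip)))
    cfg <- dockingConfig(samplingCenter = c(0, 0, 0),
                         maxMinimizerEvals = 400)
    # a zero-score pose is returned unchanged
    truth <- new("Pose", transform = cx@truePose, receptorIndex = 1L)
    t0 <- scorePose(truth, cx@receptor, cx@ligand, both, cfg)
    expect_identical(minimizePose(t0, cx@receptor, cx@ligand, both, cfg), t0)
    # displaced 2 Angstrom along one axis: minimization re-enters the funnel
    disp <- new("Pose", transform = composeTransforms(
        RigidTransform(diag(3), c(2, 0, 0)), cx@truePose),
        receptorIndex = 1L)
    d0 <- scorePose(disp, cx@receptor, cx@ligand, both, cfg)
    expect_gt(d0@score, 1e-3)
    dmin <- minimizePose(d0, cx@receptor, cx@ligand, both, cfg)
    expect_lt(dmin@score, 1e-3)
    expect_lte(dmin@score, d0@score)
    # rigidity: internal distances unchanged
    l0 <- coords(applyTransform(d0@transform, cx@ligand))
    l1 <- coords(applyTransform(dmin@transform, cx@ligand))
    expect_equal(as.numeric(stats::dist(l1)), as.numeric(stats::dist(l0)),
                 tolerance = 1e-9)
})

test_that("ensemble docking produces receptors x poses models, sorted and
           seed-stable", {
    cx <- makeToyComplex(toyComplexSpec(seed = 5))
    act <- deriveActiveResidues(cx@peaks, cx@protonGroups, cx@siteLabels)
    recs <- makeReceptorEnsemble(cx@receptor, 3, seed = 15)
    cfg <- dockingConfig(nPosesPerConformation = 8,
                         samplingCenter = c(0, 0, 0),
                         maxMinimizerEvals = 30, seed = 99)
    poses <- dockEnsemble(recs, cx@ligand, act, cfg)
    expect_length(poses, 24)
    expect_equal(sort(unique(vapply(poses, function(p) p@receptorIndex, 1L))),
                 1:3)
    sc <- vapply(poses, poseScore, 1)
    expect_false(is.unsorted(sc))
    poses2 <- dockEnsemble(recs, cx@ligand, act, cfg)
    expect_identical(vapply(poses2, poseScore, 1), sc)
    one <- dockEnsemble(recs[1], cx@ligand, act,
                        dockingConfig(nPosesPerConformation = 1,
                                      samplingCenter = c(0, 0, 0), seed = 1))
    expect_length(one, 1)
    expect_error(dockEnsemble(list(), cx@ligand, act, cfg), ">= 1 receptor")
})

test_that("restraint-guided docking recovers the planted pose", {
    for (seed in c(31, 32)) {
        r <- runToyRecovery(seed)
        expect_lte(r$minRmsd, 1.5)
        expect_equal(r$satFraction, 1)
    }
})
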