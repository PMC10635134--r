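test_that("intensity-class calibration applies the 2.8/3.5/5.0 uppers and 1.8 lower", {
    fx <- loadRestraintFixture("kg655")
    rs <- restraints(calibratePeaks(fx$peaks, fx$groups))
    expect_length(rs, 12)
    cls <- fx$peaks$class
    for (i in seq_along(rs)) {
        expect_equal(rs[[i]]$lower, 1.8)
        expect_equal(rs[[i]]$upper,
                     c(strong = 2.8, medium = 3.5, weak = 5.0)[[cls[i]]])
        expect_equal(rs[[i]]$level, "interproton")
    }
    expect_length(restraints(calibratePeaks(fx$peaks[0, ], fx$groups)), 0)
})

test_that("calibration rejects unknown classes, groups and non-monotone tables", {
    fx <- loadRestraintFixture("kg655")
    pk <- fx$peaks; pk$class[1] <- "huge"
    expect_error(calibratePeaks(pk, fx$groups), "unknown intensity class")
    pk <- fx$peaks; pk$ligandGroup[1] <- "nope"
    expect_error(calibratePeaks(pk, fx$groups), "unknown proton group")
    expect_error(calibrationTable(upper = c(strong = 3.6, medium = 3.5,
                                            weak = 5.0)), "increase")
    expect_error(calibrationTable(lower = 3.0), "lower")
    tab <- calibrationTable()
    expect_true(all(diff(tab$upper) > 0))   # stronger class, tighter bound
})

test_that("active residues are the cavity-labelled peak residues (7 and 6)", {
    fx655 <- loadRestraintFixture("kg655")
    act655 <- deriveActiveResidues(fx655$peaks, fx655$groups, fx655$siteLabels)
    expect_equal(act655, c(396, 408, 415, 418, 423, 425, 457))
    fx279 <- loadRestraintFixture("kg279")
    act279 <- deriveActiveResidues(fx279$peaks, fx279$groups, fx279$siteLabels)
    expect_equal(act279, c(396, 408, 415, 423, 425, 457))  # no L418
    # all-surface labels: empty set with a warning; unlabeled residue: error
    allSurf <- stats::setNames(rep("surface", length(fx655$siteLabels)),
                               names(fx655$siteLabels))
    expect_warning(act <- deriveActiveResidues(fx655$peaks, fx655$groups,
                                               allSurf), "no cavity")
    expect_length(act, 0)
    expect_error(deriveActiveResidues(fx655$peaks, fx655$groups,
                                      fx655$siteLabels[-1]), "unlabeled")
})

test_that("heavy-atom extension reproduces the 12->19 and 28->31 counts", {
    fx <- loadRestraintFixture("kg655")
    ip <- calibratePeaks(fx$peaks, fx$groups)
    expect_equal(length(extendToHeavyAtoms(ip, fx$groups)), 19L)
    fx <- loadRestraintFixture("kg279")
    ip <- calibratePeaks(fx$peaks, fx$groups)
    expect_equal(length(extendToHeavyAtoms(ip, fx$groups)), 31L)
})

test_that("heavy-atom extension shifts both bounds by +1 and multiplies by
           distinct heavy-atom pairs", {
    fx <- loadRestraintFixture("kg655")
    ip <- calibratePeaks(fx$peaks, fx$groups)
    hv <- extendToHeavyAtoms(ip, fx$groups)
    # a weak non-degenerate restraint becomes one distance (2.8, 6.0)
    weakIdx <- which(fx$peaks$class == "weak" & fx$peaks$ligandGroup == "H4")[1]
    src <- restraints(ip)[[weakIdx]]
    hit <- Filter(function(r) startsWith(r$id, src$id), restraints(hv))
    expect_length(hit, 1)
    expect_equal(hit[[1]]$lower, 2.8)
    expect_equal(hit[[1]]$upper, 6.0)
    # count identity: sum over restraints of distinct-pair products
    expected <- sum(vapply(restraints(ip), function(r) {
        lg <- fx$groups[[r$groupA$groupId]]
        rg <- fx$groups[[r$groupB$groupId]]
        length(unique(lg$heavies)) * length(unique(rg$heavies))
    }, 1))
    expect_equal(length(hv), expected)
})

test_that("effective distance matches the r^-6 sum and its limits", {
    a <- matrix(c(0, 0, 0), ncol = 3)
    expect_equal(effectiveDistance(a, matrix(c(3, 0, 0), ncol = 3)), 3.0)
    # two pairs both at distance d -> d * 2^(-1/6)
    B <- rbind(c(2, 0, 0), c(-2, 0, 0))
    expect_equal(effectiveDistance(a, B), 2 * 2^(-1 / 6), tolerance = 1e-12)
    # pairs at 2 and 4 Angstrom: direct evaluation of the formula
    A2 <- rbind(c(0, 0, 0))
    B2 <- rbind(c(2, 0, 0), c(-4, 0, 0))
    expect_equal(effectiveDistance(A2, B2), (2^-6 + 4^-6)^(-1 / 6),
                 tolerance = 1e-12)
    expect_equal((2^-6 + 4^-6)^(-1 / 6), 1.9948, tolerance = 1e-4)
    expect_error(effectiveDistance(a, a), "coincident")
})

test_that("effective distance never exceeds the minimum pairwise distance and
           decreases as group atoms are added", {
    set.seed(21)
    for (i in 1:10) {
        A <- matrix(rnorm(9, sd = 2), ncol = 3)
        B <- matrix(rnorm(12, sd = 2), ncol = 3) + 5
        dmin <- min(as.matrix(stats::dist(rbind(A, B)))[1:3, 4:7])
        d <- effectiveDistance(A, B)
        expect_lte(d, dmin + 1e-12)
        expect_lt(effectiveDistance(A, rbind(B, c(5, 5, 5))), d)
    }
})

test_that("violations measure distance excess beyond either bound", {
    rec <- Structure(data.frame(serial = 1L, name = "CM", element = "C",
                                resName = "PRB", resSeq = 101L, chain = "R",
                                x = 0, y = 0, z = 0, vdw = 1.7))
    mkLig <- function(x) Structure(data.frame(
        serial = 1L, name = "C1", element = "C", resName = "LIG",
        resSeq = 1L, chain = "L", x = x, y = 0, z = 0, vdw = 1.7))
    rs <- RestraintSet(list(list(
        id = "t", groupA = list(owner = "ligand", atoms = "C1",
                                residue = NA_integer_),
        groupB = list(owner = "receptor", atoms = "CM", residue = 101L),
        lower = 1.8, upper = 6.0, level = "heavy")))
    ok <- evaluateViolations(rs, rec, mkLig(4.0), tolerance = 0.3)
    expect_equal(ok$violation, 0)
    expect_true(ok$satisfied)
    over <- evaluateViolations(rs, rec, mkLig(6.35), tolerance = 0.3)
    expect_equal(over$violation, 0.35, tolerance = 1e-9)
    expect_false(over$satisfied)
    under <- evaluateViolations(rs, rec, mkLig(1.0), tolerance = 0.3)
    expect_equal(under$violation, 0.8, tolerance = 1e-9)
    expect_false(under$satisfied)
    bad <- RestraintSet(list(modifyList(restraints(rs)[[1]],
        list(groupA = list(owner = "ligand", atoms = "QQ",
                           residue = NA_integer_)))))
    expect_error(evaluateViolations(bad, rec, mkLig(4)), "QQ")
})

test_that("restraints fabricated from the true pose have zero violations there", {
    for (seed in c(1, 9, 23)) {
        cx <- makeToyComplex(toyComplexSpec(seed = seed))
        ip <- calibratePeaks(cx@peaks, cx@protonGroups)
        v <- evaluateViolations(ip, cx@receptor,
                                applyTransform(cx@truePose, cx@ligand),
                                tolerance = 0)
        expect_equal(max(v$violation), 0)
    }
})

test_that("ensemble satisfaction uses the any-pose rule", {
    cx <- makeToyComplex(toyComplexSpec(seed = 4))
    ip <- calibratePeaks(cx@peaks, cx@protonGroups)
    truth <- new("Pose", transform = cx@truePose, receptorIndex = 1L)
    decoys <- makeDecoyPoses(cx, 2, minRmsdFromTruth = 4, seed = 8)
    decoys <- lapply(decoys, function(p) { p@receptorIndex <- 1L; p })
    recs <- list(cx@receptor)
    # truth alone satisfies everything
    all <- ensembleSatisfaction(ip, recs, cx@ligand, list(truth))
    expect_equal(all$nSatisfied, all$nTotal)
    expect_true(all(all$perResidue))
    # adding poses can only add satisfied restraints (any-pose rule)
    mixed <- ensembleSatisfaction(ip, recs, cx@ligand,
                                  c(decoys, list(truth)))
    expect_equal(mixed$nSatisfied, mixed$nTotal)
    # decoys alone satisfy strictly fewer
    d <- ensembleSatisfaction(ip, recs, cx@ligand, decoys)
    expect_lt(d$nSatisfied, d$nTotal)
    expect_error(ensembleSatisfaction(ip, recs, cx@ligand, list()),
                 "empty pose list")
})

test_that("restraint TSV and CNS exports round-trip the key fields", {
    fx <- loadRestraintFixture("kg655")
    ip <- calibratePeaks(fx$peaks, fx$groups)
    hv <- extendToHeavyAtoms(ip, fx$groups)
    tsv <- tempfile(fileext = ".tsv")
    writeRestraintTable(hv, tsv)
    back <- utils::read.delim(tsv)
    expect_equal(nrow(back), length(hv))
    expect_equal(back$upper - back$lower,
                 vapply(restraints(hv), function(r) r$upper - r$lower, 1))
    cns <- tempfile(fileext = ".cns")
    exportCNSRestraints(hv, cns)
    lines <- readLines(cns)
    expect_length(lines, length(hv))
    expect_true(all(grepl("^assign \\(", lines)))
})
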