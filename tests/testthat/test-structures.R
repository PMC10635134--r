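test_that("a minimal one-atom PDB parses to the written coordinates", {
    p <- writeTempPDB(atomLine(1, "CA", "GLY", "A", 1, 1, 2, 3))
    st <- readPDB(p)
    expect_equal(nAtoms(st), 1L)
    expect_equal(as.numeric(coords(st)), c(1, 2, 3))
    expect_equal(atoms(st)$name, "CA")
})

test_that("write/read round trip preserves atoms, serials and coordinates", {
    cx <- makeToyComplex(toyComplexSpec(seed = 2))
    p <- tempfile(fileext = ".pdb")
    writePDB(cx@receptor, p)
    back <- readPDB(p)
    expect_equal(atoms(back)$serial, atoms(cx@receptor)$serial)
    expect_equal(atoms(back)$name, atoms(cx@receptor)$name)
    expect_equal(atoms(back)$resSeq, atoms(cx@receptor)$resSeq)
    expect_equal(atoms(back)$element, atoms(cx@receptor)$element)
    expect_equal(coords(back), round(coords(cx@receptor), 3))
})

test_that("a CA-only chain of 5 residues reads in file order", {
    lines <- sapply(1:5, function(i)
        atomLine(i, "CA", "ALA", "A", i, i * 1.5, 0, 0))
    st <- readPDB(writeTempPDB(lines))
    expect_equal(nAtoms(st), 5L)
    expect_equal(atoms(st)$resSeq, 1:5)
    st5 <- selectAtoms(st, atomNames = "CA")
    expect_equal(nAtoms(st5), 5L)
})

test_that("parse errors name the offending line; empty files error", {
    bad <- c(atomLine(1, "CA", "GLY", "A", 1, 1, 2, 3),
             "ATOM      2  CB  GLY A   1       x.bad   2.000   3.000")
    expect_error(readPDB(writeTempPDB(bad)), "line 2")
    expect_error(readPDB(writeTempPDB("REMARK nothing here")),
                 "no ATOM/HETATM")
    expect_error(readPDB(tempfile()), "no such file")
})

test_that("altLoc records other than blank/'A' are dropped with a warning", {
    l1 <- atomLine(1, "CA", "GLY", "A", 1, 0, 0, 0)
    l2 <- atomLine(2, "CB", "GLY", "A", 1, 1, 0, 0)
    substr(l2, 17, 17) <- "B"
    expect_warning(st <- readPDB(writeTempPDB(c(l1, l2))), "altLoc")
    expect_equal(nAtoms(st), 1L)
})

test_that("element inference and vdW radii follow the Bondi table", {
    expect_equal(vdwRadius(c("C", "O", "H", "CL")), c(1.70, 1.52, 1.20, 1.75))
    expect_equal(vdwRadius("XX"), 1.7)                    # unknown fallback
    expect_equal(vdwRadius("C", table = c(C = 2.0)), 2.0) # override
})

test_that("selectAtoms subsets by residue and atom name, preserving order", {
    cx <- makeToyComplex(toyComplexSpec(seed = 2))
    one <- selectAtoms(cx@receptor, resSeq = 101)
    expect_true(all(atoms(one)$resSeq == 101))
    expect_equal(nAtoms(selectAtoms(cx@receptor, resSeq = integer(0))), 0L)
    cm <- selectAtoms(cx@receptor, atomNames = "CM")
    expect_true(all(atoms(cm)$name == "CM"))
    expect_false(is.unsorted(atoms(cm)$serial))
})

test_that("readPDB coordinates agree with the bio3d parser", {
    cx <- makeToyComplex(toyComplexSpec(seed = 5))
    p <- tempfile(fileext = ".pdb")
    writePDB(cx@receptor, p)
    ours <- readPDB(p)
    ref <- bio3d::read.pdb(p)
    expect_equal(coords(ours),
                 matrix(ref$xyz, ncol = 3, byrow = TRUE))
    expect_equal(atoms(ours)$resSeq, ref$atom$resno)
})

test_that("superpose recovers exact rigid copies with zero RMSD", {
    set.seed(1)
    x <- matrix(rnorm(30), ncol = 3)
    id <- superpose(x, x)
    expect_lt(id$rmsd, 1e-12)
    expect_equal(id$transform@rotation, diag(3), tolerance = 1e-9)
    Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
    y <- sweep(x %*% t(Rz), 2, c(5, 0, 0), `+`)
    expect_lt(superpose(x, y)$rmsd, 1e-9)
})

test_that("superpose refuses improper rotations: mirrored chiral points keep
           a residual matching a proper-rotation grid search", {
    tet <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.0, 0), c(0.3, 0.4, 1.4))
    mir <- tet %*% diag(c(1, 1, -1))
    fit <- superpose(mir, tet)
    expect_gt(fit$rmsd, 0.1)
    expect_equal(det(fit$transform@rotation), 1, tolerance = 1e-9)
    # brute force over discretized proper rotations (axis lattice x angles)
    ctet <- sweep(tet, 2, colMeans(tet))
    cmir <- sweep(mir, 2, colMeans(mir))
    axes <- matrix(rnorm(3 * 300), ncol = 3)
    axes <- axes / sqrt(rowSums(axes^2))
    best <- Inf
    for (k in seq_len(nrow(axes))) for (ang in seq(0, 2 * pi, length.out = 60)) {
        R <- rotationFromVector(axes[k, ] * ang)
        best <- min(best, sqrt(mean(rowSums((cmir %*% t(R) - ctet)^2))))
    }
    expect_gte(best + 1e-9, fit$rmsd)        # Kabsch is the optimum
    expect_lt(best - fit$rmsd, 0.05 * fit$rmsd + 0.02)
})

test_that("superpose RMSD is invariant to proper rigid motion of the mobile set", {
    set.seed(7)
    x <- matrix(rnorm(24), ncol = 3)
    y <- x + matrix(rnorm(24, sd = 0.3), ncol = 3)
    base <- superpose(x, y)$rmsd
    for (i in 1:5) {
        tr <- RigidTransform(randomRotation(), rnorm(3, sd = 4))
        expect_equal(superpose(applyTransform(tr, x), y)$rmsd, base,
                     tolerance = 1e-9)
    }
})

test_that("superpose input contracts are enforced", {
    x <- matrix(rnorm(9), ncol = 3)
    expect_error(superpose(x, x[1:2, ]), "counts differ")
    expect_error(superpose(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("rmsdNoFit matches closed forms and is symmetric", {
    a <- matrix(c(0, 0, 0), ncol = 3)
    expect_equal(rmsdNoFit(a, a), 0)
    expect_equal(rmsdNoFit(a, a + c(1.5, 0, 0)), 1.5)
    b <- rbind(c(0, 0, 0), c(10, 0, 0))
    b2 <- rbind(c(3, 0, 0), c(10, 4, 0))   # displacements 3 and 4
    expect_equal(rmsdNoFit(b, b2), sqrt((9 + 16) / 2))
    expect_equal(rmsdNoFit(b2, b), rmsdNoFit(b, b2))
    expect_error(rmsdNoFit(b, a), "counts differ")
})

test_that("rmsdNoFit obeys the triangle-like bound on equal-size sets", {
    set.seed(11)
    for (i in 1:20) {
        a <- matrix(rnorm(15), ncol = 3)
        b <- matrix(rnorm(15), ncol = 3)
        c <- matrix(rnorm(15), ncol = 3)
        expect_lte(rmsdNoFit(a, c),
                   rmsdNoFit(a, b) + rmsdNoFit(b, c) + 1e-12)
    }
})

test_that("superposition agrees with the bio3d fitting oracle", {
    set.seed(3)
    x <- matrix(rnorm(36), ncol = 3)
    y <- x + matrix(rnorm(36, sd = 0.5), ncol = 3)
    ours <- superpose(x, y)$rmsd
    ref <- bio3d::rmsd(as.numeric(t(y)), as.numeric(t(x)), fit = TRUE)
    expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("rigid transforms validate orthonormality and compose correctly", {
    expect_error(RigidTransform(diag(c(1, 1, -1))), "proper")
    expect_error(RigidTransform(matrix(rnorm(9), 3, 3)), "orthonormal")
    set.seed(5)
    t1 <- RigidTransform(randomRotation(), rnorm(3))
    t2 <- RigidTransform(randomRotation(), rnorm(3))
    x <- matrix(rnorm(12), ncol = 3)
    expect_equal(applyTransform(composeTransforms(t2, t1), x),
                 applyTransform(t2, applyTransform(t1, x)),
                 tolerance = 1e-12)
})
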