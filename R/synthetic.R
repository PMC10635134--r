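## Ground-truth fixture generators: toy pocket complexes with fabricated NOE
## tables, decoy poses, clustered toy trajectories.

.mkAtoms <- function(name, element, resName, resSeq, xyz, chain = "A",
                     serialStart = 1L) {
    data.frame(serial = seq_along(name) + serialStart - 1L, name = name,
               element = element, resName = resName,
               resSeq = as.integer(resSeq), chain = chain,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               vdw = vdwRadius(element), stringsAsFactors = FALSE)
}

## hexagonal aromatic ring (radius 1.4 A) in the xy-plane, C1 on +x
.ringXYZ <- function(r = 1.4) {
    ang <- (0:5) * pi / 3
    cbind(r * cos(ang), r * sin(ang), 0)
}

#' Build a toy ligand
#'
#' "c2_symmetric": a phenol-like ring with a hydroxyl on the C2 axis
#' (atoms C1..C6, O1; protons H2, H3, H5, H6 on the ring and HO on the
#' oxygen).  The symmetry axis runs through C1, C4 and O1, and the flip
#' maps H2<->H6 and H3<->H5 (chemically equivalent pairs).
#' "asymmetric": same ring with a chlorine on C3 breaking the symmetry;
#' every proton is its own group.
#'
#' @param template "c2_symmetric" or "asymmetric".
#' @return list with \code{structure} ([Structure]), \code{groups} (ligand
#'   [protonGroup]s) and \code{symmetryAtoms} (heavy-atom names for
#'   symmetry-corrected RMSD).
#' @export
makeToyLigand <- function(template = c("c2_symmetric", "asymmetric")) {
    template <- match.arg(template)
    ring <- .ringXYZ(1.4)
    hpos <- .ringXYZ(2.48)
    if (template == "c2_symmetric") {
        name <- c("C1", "C2", "C3", "C4", "C5", "C6", "O1",
                  "H2", "H3", "H5", "H6", "HO")
        elem <- c(rep("C", 6), "O", rep("H", 5))
        xyz <- rbind(ring, c(2.75, 0, 0),
                     hpos[2:3, ], hpos[5:6, ], c(3.55, 0, 0))
        groups <- list(
            H2H6 = protonGroup("H2H6", c("H2", "H6"), c("C2", "C6"), "ligand"),
            H3H5 = protonGroup("H3H5", c("H3", "H5"), c("C3", "C5"), "ligand"),
            HO = protonGroup("HO", "HO", "O1", "ligand"))
        sym <- c("C1", "C4", "O1")     # on the two-fold axis
    } else {
        name <- c("C1", "C2", "C3", "C4", "C5", "C6", "O1", "CL1",
                  "H2", "H4", "H5", "H6", "HO")
        elem <- c(rep("C", 6), "O", "CL", rep("H", 4), "H")
        cl <- ring[3, ] * (3.1 / 1.4)
        xyz <- rbind(ring, c(2.75, 0, 0), cl,
                     hpos[2, ], hpos[4:6, ], c(3.55, 0, 0))
        groups <- list(
            H2 = protonGroup("H2", "H2", "C2", "ligand"),
            H4 = protonGroup("H4", "H4", "C4", "ligand"),
            H5 = protonGroup("H5", "H5", "C5", "ligand"),
            H6 = protonGroup("H6", "H6", "C6", "ligand"),
            HO = protonGroup("HO", "HO", "O1", "ligand"))
        sym <- c("C1", "C2", "C3", "C4", "C5", "C6", "O1", "CL1")
    }
    st <- Structure(.mkAtoms(name, elem, "LIG", 1L, xyz, chain = "L"),
                    label = template)
    list(structure = st, groups = groups, symmetryAtoms = sym)
}

## quasi-uniform directions on the pocket cap (z below zMax), via the
## deterministic sphere lattice
.capDirections <- function(n, zMax = 0.5) {
    lat <- .sphereLattice(max(n * 3, 24))
    lat <- lat[lat[, 3] < zMax, , drop = FALSE]
    lat[round(seq(1, nrow(lat), length.out = n)), , drop = FALSE]
}

#' Toy-complex generation parameters
#'
#' @param nPocketProbes methyl-probe pseudo-residues lining the pocket
#'   (>= 4).
#' @param pocketRadius distance of probe methyl carbons from the pocket
#'   centre, Angstrom.
#' @param ligandTemplate see [makeToyLigand].
#' @param peakNoiseRate fraction of fabricated peaks misclassified by one
#'   intensity class (0 to 0.5), emulating spin-diffusion artifacts.
#' @param seed integer seed; generation is deterministic given it.
#' @return list of class "ToyComplexSpec".
#' @export
toyComplexSpec <- function(nPocketProbes = 8, pocketRadius = 6.5,
                           ligandTemplate = "c2_symmetric",
                           peakNoiseRate = 0, seed = 1) {
    stopifnot(nPocketProbes >= 4, peakNoiseRate >= 0, peakNoiseRate <= 0.5)
    structure(list(nPocketProbes = as.integer(nPocketProbes),
                   pocketRadius = pocketRadius,
                   ligandTemplate = ligandTemplate,
                   peakNoiseRate = peakNoiseRate, seed = as.integer(seed)),
              class = "ToyComplexSpec")
}

#' Generate a synthetic receptor-ligand complex with known ground truth
#'
#' The receptor is a concave pocket: \code{nPocketProbes} methyl-probe
#' pseudo-residues (atoms CA / CM / HM along the outward radial direction)
#' on a spherical cap around the true ligand position, backed by a wall of
#' blocker atoms, plus one "surface" probe near the pocket rim and one
#' distant "outlier" probe (labelled accordingly).  The true pose is a
#' random proper rotation placing the ligand at the pocket centre, and the
#' NOE peak table is fabricated from true interproton distances.
#'
#' @param spec A [toyComplexSpec].
#' @return A [ToyComplex].
#' @export
makeToyComplex <- function(spec = toyComplexSpec()) {
    lig <- makeToyLigand(spec$ligandTemplate)
    ligMax <- max(sqrt(rowSums(coords(heavyAtoms(lig$structure))^2)))
    if (ligMax + 2.8 > spec$pocketRadius)
        stop("makeToyComplex: ligand (extent ", round(ligMax, 2),
             " A) too large for pocket radius ", spec$pocketRadius)
    dirs <- .capDirections(spec$nPocketProbes, zMax = 0.5)
    probes <- list(); resSeq <- integer(0)
    serial <- 1L
    addProbe <- function(dir, res, resName) {
        xyz <- rbind(dir * (spec$pocketRadius + 1.5),   # CA backing
                     dir * spec$pocketRadius,           # CM methyl carbon
                     dir * (spec$pocketRadius - 1.0))   # HM methyl proton
        a <- .mkAtoms(c("CA", "CM", "HM"), c("C", "C", "H"), resName, res,
                      xyz, chain = "R", serialStart = serial)
        serial <<- serial + 3L
        a
    }
    for (i in seq_len(spec$nPocketProbes))
        probes[[i]] <- addProbe(dirs[i, ], 100L + i, "PRB")
    surfDir <- c(0, 0.8, 0.6); surfDir <- surfDir / sqrt(sum(surfDir^2))
    surfRes <- 100L + spec$nPocketProbes + 1L
    probes[[length(probes) + 1L]] <- addProbe(surfDir, surfRes, "SRF")
    outRes <- surfRes + 1L
    outA <- .mkAtoms(c("CA", "CM", "HM"), c("C", "C", "H"), "OUT", outRes,
                     rbind(c(0, 0, spec$pocketRadius + 7.5),
                           c(0, 0, spec$pocketRadius + 6.0),
                           c(0, 0, spec$pocketRadius + 5.0)),
                     chain = "R", serialStart = serial)
    serial <- serial + 3L
    probes[[length(probes) + 1L]] <- outA
    wallDirs <- .capDirections(3L * spec$nPocketProbes, zMax = 0.5)
    wall <- .mkAtoms(sprintf("W%d", seq_len(nrow(wallDirs))),
                     rep("C", nrow(wallDirs)), "WAL", 99L,
                     wallDirs * (spec$pocketRadius + 2.5), chain = "R",
                     serialStart = serial)
    receptor <- Structure(do.call(rbind, c(probes, list(wall))),
                          label = "toy-receptor")
    siteLabels <- c(stats::setNames(rep("cavity", spec$nPocketProbes),
                                    100L + seq_len(spec$nPocketProbes)),
                    stats::setNames("surface", surfRes),
                    stats::setNames("outlier", outRes))
    probeRes <- c(100L + seq_len(spec$nPocketProbes), surfRes, outRes)
    recGroups <- stats::setNames(lapply(probeRes, function(r)
        protonGroup(sprintf("M%d", r), "HM", "CM", "receptor", r)),
        sprintf("M%d", probeRes))
    truePose <- withSeed(spec$seed, RigidTransform(randomRotation(), c(0, 0, 0)))
    cx <- new("ToyComplex", receptor = receptor, ligand = lig$structure,
              truePose = truePose, peaks = data.frame(),
              protonGroups = c(lig$groups, recGroups),
              siteLabels = siteLabels, symmetryAtoms = lig$symmetryAtoms)
    cx@peaks <- fabricateNoePeaks(cx, noiseRate = spec$peakNoiseRate,
                                  seed = spec$seed + 1L)
    cx
}

#' Fabricate classified NOE peaks from the true pose
#'
#' For every (ligand proton group, receptor methyl group) pair the r^-6
#' effective interproton distance d under the true pose is classified with
#' the calibration thresholds (d <= 2.8 strong, <= 3.5 medium, <= 5.0 weak,
#' otherwise no peak), so calibrating the fabricated peaks back into
#' restraints is self-consistent with the true pose by construction.
#' Optional class noise shifts a fraction of peaks by one intensity class.
#'
#' @param complex A [ToyComplex].
#' @param table A [calibrationTable].
#' @param noiseRate misclassification fraction (0 to 0.5).
#' @param seed RNG seed for the noise draws.
#' @return peak data.frame (ligandGroup, receptorGroup, class, distance).
#' @export
fabricateNoePeaks <- function(complex, table = calibrationTable(),
                              noiseRate = 0, seed = 1) {
    ligTrue <- applyTransform(complex@truePose, complex@ligand)
    groups <- complex@protonGroups
    isLig <- vapply(groups, function(g) g$owner == "ligand", TRUE)
    classes <- names(table$upper)
    rows <- list()
    for (lg in groups[isLig]) for (rg in groups[!isLig]) {
        d <- effectiveDistance(
            coords(selectAtoms(ligTrue, atomNames = lg$protons)),
            coords(selectAtoms(complex@receptor, resSeq = rg$residue,
                               atomNames = rg$protons)))
        if (d <= max(table$upper))
            rows[[length(rows) + 1L]] <- data.frame(
                ligandGroup = lg$id, receptorGroup = rg$id,
                class = classes[max(1, findInterval(d, table$upper,
                                                    left.open = TRUE) + 1)],
                distance = d, stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, rows)
    if (!is.null(peaks) && noiseRate > 0) {
        withSeed(seed, {
            flip <- stats::runif(nrow(peaks)) < noiseRate
            for (i in which(flip)) {
                k <- match(peaks$class[i], classes)
                step <- if (k == 1L) 1L
                        else if (k == length(classes)) -1L
                        else sample(c(-1L, 1L), 1)
                peaks$class[i] <- classes[k + step]
            }
        })
    }
    if (is.null(peaks))
        peaks <- data.frame(ligandGroup = character(), receptorGroup = character(),
                            class = character(), distance = numeric())
    peaks
}

#' Generate decoy poses away from the truth
#'
#' Random rigid placements rejected until each lies at least
#' \code{minRmsdFromTruth} (symmetry-aware RMSD) from the true pose.
#'
#' @param complex A [ToyComplex].
#' @param n number of decoys (>= 1).
#' @param minRmsdFromTruth minimum symmetry-RMSD from the true pose,
#'   Angstrom.
#' @param seed RNG seed.
#' @param maxAttempts sampling budget before giving up with an error.
#' @return list of unscored [Pose]s.
#' @export
makeDecoyPoses <- function(complex, n, minRmsdFromTruth = 3.0, seed = 1,
                           maxAttempts = 1000 * n) {
    if (n < 1) stop("makeDecoyPoses: n must be >= 1")
    sym <- ligandSymmetry(complex@symmetryAtoms)
    symFn <- .symCoordsFn(complex@ligand, sym)
    truthPose <- new("Pose", transform = complex@truePose,
                     receptorIndex = 1L)
    cfg <- dockingConfig(samplingRadius = 3.0, seed = seed)
    withSeed(seed, {
        out <- list(); tries <- 0L
        while (length(out) < n) {
            tries <- tries + 1L
            if (tries > maxAttempts)
                stop("makeDecoyPoses: could not reach minRmsdFromTruth within budget")
            p <- samplePose(complex@ligand, cfg)
            if (rmsdNoFit(symFn(p), symFn(truthPose)) >= minRmsdFromTruth)
                out[[length(out) + 1L]] <- p
        }
        out
    })
}

#' Generate a toy trajectory with planted cluster structure
#'
#' Frames are Gaussian perturbations (per-coordinate sd \code{blobSigma})
#' of \code{nBlobs} well-separated base conformations; the generating blob
#' of every frame is returned as the ground-truth label.  Base separations
#' are enforced to exceed both 4*blobSigma and 3 Angstrom of superposed
#' RMSD.
#'
#' @param nBlobs number of conformational blobs.
#' @param framesPerBlob frames drawn from each blob.
#' @param blobSigma per-coordinate perturbation sd, Angstrom.
#' @param nAtomsPerFrame atoms in the toy conformation.
#' @param seed RNG seed.
#' @return list with \code{frames} (list of [Structure]s) and \code{labels}
#'   (integer blob of each frame).
#' @export
makeToyTrajectory <- function(nBlobs = 10, framesPerBlob = 3,
                              blobSigma = 0.2, nAtomsPerFrame = 20,
                              seed = 1) {
    stopifnot(nBlobs >= 1, framesPerBlob >= 1, blobSigma >= 0)
    minSep <- max(4 * blobSigma, 3)
    withSeed(seed, {
        base <- matrix(stats::rnorm(nAtomsPerFrame * 3, sd = 3), ncol = 3)
        for (try in 1:50) {
            blobs <- lapply(seq_len(nBlobs), function(b)
                base + matrix(stats::rnorm(nAtomsPerFrame * 3, sd = 3),
                              ncol = 3))
            if (nBlobs == 1) break
            sep <- Inf
            for (i in seq_len(nBlobs - 1)) for (j in (i + 1):nBlobs)
                sep <- min(sep, superpose(blobs[[i]], blobs[[j]])$rmsd)
            if (sep > minSep) break
        }
        tmpl <- .mkAtoms(rep("CA", nAtomsPerFrame), rep("C", nAtomsPerFrame),
                         "GLY", seq_len(nAtomsPerFrame),
                         matrix(0, nAtomsPerFrame, 3))
        frames <- list(); labels <- integer(0)
        for (b in seq_len(nBlobs)) for (f in seq_len(framesPerBlob)) {
            xyz <- blobs[[b]] + matrix(stats::rnorm(nAtomsPerFrame * 3,
                                                    sd = blobSigma), ncol = 3)
            st <- Structure(tmpl, label = sprintf("blob%d_frame%d", b, f))
            coords(st) <- xyz
            frames[[length(frames) + 1L]] <- st
            labels <- c(labels, b)
        }
        list(frames = frames, labels = labels)
    })
}

#' Perturbed receptor ensemble for toy docking
#'
#' The original receptor plus n-1 copies with small Gaussian coordinate
#' jitter, standing in for distinct conformations of an opening pathway.
#'
#' @param receptor receptor [Structure].
#' @param n ensemble size.
#' @param sigma per-coordinate jitter sd, Angstrom.
#' @param seed RNG seed.
#' @return list of [Structure]s (first = original).
#' @export
makeReceptorEnsemble <- function(receptor, n = 2, sigma = 0.05, seed = 1) {
    stopifnot(n >= 1)
    withSeed(seed, {
        out <- list(receptor)
        for (i in seq_len(n - 1)) {
            r <- receptor
            coords(r) <- coords(r) +
                matrix(stats::rnorm(3 * nAtoms(r), sd = sigma), ncol = 3)
            out[[i + 1L]] <- r
        }
        out
    })
}

#' Write a toy complex to a directory as plain-text inputs
#'
#' Writes receptor.pdb, ligand.pdb, true_pose.json, peaks.tsv, groups.tsv
#' and site_labels.tsv — the on-disk form consumed by [runPipeline].
#'
#' @param complex A [ToyComplex].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeToyComplex <- function(complex, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writePDB(complex@receptor, file.path(dir, "receptor.pdb"))
    writePDB(complex@ligand, file.path(dir, "ligand.pdb"), hetatm = TRUE)
    jsonlite::write_json(
        list(rotation = complex@truePose@rotation,
             translation = complex@truePose@translation),
        file.path(dir, "true_pose.json"), digits = NA, auto_unbox = FALSE)
    g <- complex@protonGroups
    utils::write.table(
        data.frame(id = vapply(g, `[[`, "", "id"),
                   owner = vapply(g, `[[`, "", "owner"),
                   residue = vapply(g, `[[`, 1L, "residue"),
                   protons = vapply(g, function(x) paste(x$protons, collapse = ","), ""),
                   heavies = vapply(g, function(x) paste(x$heavies, collapse = ","), "")),
        file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    resOf <- function(id) g[[id]]$residue
    utils::write.table(
        data.frame(ligand_group = complex@peaks$ligandGroup,
                   receptor_residue = vapply(complex@peaks$receptorGroup, resOf, 1L),
                   receptor_group = complex@peaks$receptorGroup,
                   class = complex@peaks$class),
        file.path(dir, "peaks.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(
        data.frame(residue = names(complex@siteLabels),
                   site = unname(complex@siteLabels)),
        file.path(dir, "site_labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    writeLines(complex@symmetryAtoms, file.path(dir, "symmetry_atoms.txt"))
    invisible(dir)
}
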