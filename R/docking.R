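## Restraint-guided rigid-body docking: random orientation sampling, an
## AIR + soft-steric score, and derivative-free rigid-body minimization.

#' Docking configuration
#'
#' @param nPosesPerConformation poses sampled per receptor conformation.
#' @param samplingCenter 3-vector, Angstrom: centre of the sampling sphere
#'   (the cavity centroid).
#' @param samplingRadius sampling sphere radius, Angstrom (> 0).
#' @param wAir,wSteric nonnegative score weights (score =
#'   wAir*eAir + wSteric*eSteric).
#' @param airUpper upper bound of the per-residue ambiguous restraints,
#'   Angstrom (mirrors the weak-NOE 5.0 Angstrom contact limit).
#' @param stericSoftness soft-core scale s: a receptor-ligand heavy-atom
#'   pair is penalized below (ri+rj)*s.
#' @param maxMinimizerEvals evaluation budget of the rigid-body minimizer.
#' @param seed integer seed; the full pose list is reproducible from it.
#' @return list of class "DockingConfig".
#' @export
dockingConfig <- function(nPosesPerConformation = 1000,
                          samplingCenter = c(0, 0, 0), samplingRadius = 2.0,
                          wAir = 1, wSteric = 1, airUpper = 5.0,
                          stericSoftness = 0.8, maxMinimizerEvals = 150,
                          seed = 1) {
    stopifnot(nPosesPerConformation >= 1, samplingRadius > 0,
              wAir >= 0, wSteric >= 0)
    structure(list(nPosesPerConformation = as.integer(nPosesPerConformation),
                   samplingCenter = as.numeric(samplingCenter),
                   samplingRadius = samplingRadius, wAir = wAir,
                   wSteric = wSteric, airUpper = airUpper,
                   stericSoftness = stericSoftness,
                   maxMinimizerEvals = as.integer(maxMinimizerEvals),
                   seed = as.integer(seed)), class = "DockingConfig")
}

#' Build per-residue ambiguous interaction restraints
#'
#' One ambiguous restraint per active residue, from every ligand heavy atom
#' to every side-chain heavy atom of the residue (backbone N/CA/C/O
#' excluded), with the configured upper bound.
#'
#' @param ligand ligand [Structure].
#' @param receptor receptor [Structure].
#' @param activeResidues integer vector of active residue numbers.
#' @param upper AIR upper bound, Angstrom.
#' @return A [RestraintSet] with one ambiguous "heavy" restraint per residue.
#' @export
buildResidueAIRs <- function(ligand, receptor, activeResidues, upper = 5.0) {
    ligNames <- atoms(heavyAtoms(ligand))$name
    out <- lapply(activeResidues, function(res) {
        sc <- heavyAtoms(selectAtoms(receptor, resSeq = res))
        scNames <- setdiff(atoms(sc)$name, c("N", "CA", "C", "O"))
        if (!length(scNames))
            stop("buildResidueAIRs: residue ", res, " has no side-chain heavy atoms")
        list(id = sprintf("AIR-%d", res),
             groupA = list(owner = "ligand", atoms = ligNames,
                           residue = NA_integer_, groupId = NA_character_),
             groupB = list(owner = "receptor", atoms = scNames,
                           residue = as.integer(res), groupId = NA_character_),
             lower = 0.5, upper = upper, level = "heavy")
    })
    RestraintSet(out)
}

## precompute everything the 6-dof objective needs: ligand coordinates,
## receptor heavy atoms + radii, and resolved restraint groups
.dockPrep <- function(receptor, ligand, airSet, config) {
    ligAll <- coords(ligand)
    ligIsH <- atoms(ligand)$element == "H"
    recH <- heavyAtoms(receptor)
    ## stack every restraint's receptor-side atoms into one matrix so the
    ## objective computes a single ligand x receptor cross-distance matrix
    Brows <- list(); aIdxs <- list(); bIdxs <- list(); uppers <- numeric(0)
    off <- 0L
    for (r in restraints(airSet)) {
        aIdx <- which(atoms(ligand)$name %in% r$groupA$atoms)
        if (!length(aIdx))
            stop("dock: cannot resolve ligand atoms for ", r$id)
        B <- .groupCoords(r$groupB, receptor, ligand)
        Brows[[length(Brows) + 1L]] <- B
        aIdxs[[length(aIdxs) + 1L]] <- aIdx
        bIdxs[[length(bIdxs) + 1L]] <- off + seq_len(nrow(B))
        off <- off + nrow(B)
        uppers <- c(uppers, r$upper)
    }
    B <- if (length(Brows)) do.call(rbind, Brows)
         else matrix(numeric(0), 0, 3)
    list(ligAll = ligAll, ligHeavy = ligAll[!ligIsH, , drop = FALSE],
         heavyRowsIdx = which(!ligIsH),
         ligHeavyRad = atoms(ligand)$vdw[!ligIsH],
         recXYZ = coords(recH), recRad = atoms(recH)$vdw,
         recN2 = rowSums(coords(recH)^2),
         airB = B, airBN2 = rowSums(B^2), airA = aIdxs, airBrows = bIdxs,
         airUpper = uppers, wAir = config$wAir, wSteric = config$wSteric,
         soft = config$stericSoftness)
}

## energy components for ligand coordinates already placed in the receptor
.poseEnergy <- function(ligAllXYZ, ligHeavyXYZ, pre) {
    eAir <- 0
    if (length(pre$airUpper)) {
        D2 <- outer(rowSums(ligAllXYZ^2), pre$airBN2, `+`) -
            2 * ligAllXYZ %*% t(pre$airB)
        D2 <- pmax(D2, 1e-12)^(-3)
        for (k in seq_along(pre$airUpper)) {
            deff <- sum(D2[pre$airA[[k]], pre$airBrows[[k]]])^(-1 / 6)
            eAir <- eAir + max(0, deff - pre$airUpper[k])^2
        }
    }
    d2 <- outer(rowSums(ligHeavyXYZ^2), pre$recN2, `+`) -
        2 * ligHeavyXYZ %*% t(pre$recXYZ)
    lim <- outer(pre$ligHeavyRad, pre$recRad, `+`) * pre$soft
    ov <- pmax(0, lim - sqrt(pmax(d2, 0)))
    c(eAir = eAir, eSteric = sum(ov^2))
}

#' Sample an unscored random rigid-body pose
#'
#' Rotation uniform over proper rotations (Gaussian quaternion); translation
#' placing the ligand centroid uniformly inside the sampling sphere.
#' Consumes a fixed number of RNG draws, so a seeded stream yields an
#' identical pose sequence.
#'
#' @param ligand reference ligand [Structure].
#' @param config A [dockingConfig].
#' @param receptorIndex receptor conformation index to stamp on the pose.
#' @return an unscored [Pose].
#' @export
samplePose <- function(ligand, config, receptorIndex = 1L) {
    R <- randomRotation()
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    r <- config$samplingRadius * stats::runif(1)^(1 / 3)
    cen <- colMeans(coords(ligand))
    tr <- config$samplingCenter + r * dir - as.numeric(R %*% cen)
    new("Pose", transform = RigidTransform(R, tr),
        receptorIndex = as.integer(receptorIndex))
}

#' Score a pose
#'
#' eAir is the summed squared upper-bound excess of the r^-6 effective
#' distance of each ambiguous restraint; eSteric the soft-core overlap
#' penalty over receptor-ligand heavy-atom pairs; the total score is their
#' weighted sum (exact decomposition).
#'
#' @param pose A [Pose].
#' @param receptor receptor [Structure].
#' @param ligand reference ligand [Structure].
#' @param airSet ambiguous [RestraintSet] (per-residue AIRs, optionally plus
#'   calibrated NOE restraints).
#' @param config A [dockingConfig].
#' @return the scored [Pose].
#' @export
scorePose <- function(pose, receptor, ligand, airSet, config) {
    pre <- .dockPrep(receptor, ligand, airSet, config)
    .scorePosePre(pose, pre)
}

.scorePosePre <- function(pose, pre) {
    R <- pose@transform@rotation; tv <- pose@transform@translation
    allXYZ <- sweep(pre$ligAll %*% t(R), 2, tv, `+`)
    hXYZ <- sweep(pre$ligHeavy %*% t(R), 2, tv, `+`)
    e <- .poseEnergy(allXYZ, hXYZ, pre)
    pose@eAir <- unname(e["eAir"]); pose@eSteric <- unname(e["eSteric"])
    pose@score <- pre$wAir * pose@eAir + pre$wSteric * pose@eSteric
    pose
}

#' Rigid-body local minimization of a pose
#'
#' Derivative-free (Nelder-Mead) search over the 6 rigid-body degrees of
#' freedom (rotation vector about the current ligand centroid +
#' translation) with a fixed evaluation budget.  The returned score never
#' exceeds the input score and the ligand's internal geometry is unchanged.
#'
#' @param pose scored [Pose].
#' @param receptor,ligand,airSet,config as in [scorePose].
#' @return minimized, rescored [Pose]; \code{@converged} is FALSE when the
#'   evaluation budget was exhausted.
#' @export
minimizePose <- function(pose, receptor, ligand, airSet, config) {
    pre <- .dockPrep(receptor, ligand, airSet, config)
    .minimizePosePre(pose, pre, config)
}

.minimizePosePre <- function(pose, pre, config) {
    if (is.na(pose@score)) pose <- .scorePosePre(pose, pre)
    if (pose@score <= 0) return(pose)       # already optimal
    R0 <- pose@transform@rotation; t0 <- pose@transform@translation
    g <- colMeans(sweep(pre$ligAll %*% t(R0), 2, t0, `+`))
    par2rt <- function(p) {
        Rv <- rotationFromVector(p[1:3])
        list(R = Rv %*% R0, t = as.numeric(Rv %*% (t0 - g)) + g + p[4:6])
    }
    fn <- function(p) {
        rt <- par2rt(p)
        allXYZ <- pre$ligAll %*% t(rt$R)
        allXYZ[, 1] <- allXYZ[, 1] + rt$t[1]
        allXYZ[, 2] <- allXYZ[, 2] + rt$t[2]
        allXYZ[, 3] <- allXYZ[, 3] + rt$t[3]
        hXYZ <- allXYZ[pre$heavyRowsIdx, , drop = FALSE]
        e <- .poseEnergy(allXYZ, hXYZ, pre)
        pre$wAir * e[["eAir"]] + pre$wSteric * e[["eSteric"]]
    }
    opt <- stats::optim(rep(0, 6), fn, method = "Nelder-Mead",
                        control = list(maxit = config$maxMinimizerEvals,
                                       warn.1d.NelderMead = FALSE))
    out <- pose
    rt <- par2rt(opt$par)
    out@transform <- RigidTransform(rt$R, rt$t)
    out@converged <- opt$convergence == 0L
    out <- .scorePosePre(out, pre)
    if (out@score > pose@score) pose else out   # monotone guarantee
}

#' Dock a ligand against an ensemble of receptor conformations
#'
#' For every receptor conformation, samples
#' \code{config$nPosesPerConformation} random rigid poses, scores them and
#' locally minimizes each one; the pooled pose list is returned sorted
#' ascending by score.  Fully deterministic under the config seed.
#'
#' @param receptors list of receptor [Structure]s (>= 1).
#' @param ligand reference ligand [Structure].
#' @param activeResidues integer vector of docking-active residue numbers.
#' @param config A [dockingConfig].
#' @param extraRestraints optional [RestraintSet] added to the ambiguous
#'   set (e.g. calibrated NOE restraints), so the NOE information shapes
#'   the rigid-body objective.
#' @param minimize logical; FALSE returns scored but unminimized poses.
#' @return list of scored [Pose]s, best first.
#' @export
dockEnsemble <- function(receptors, ligand, activeResidues, config,
                         extraRestraints = NULL, minimize = TRUE) {
    if (!length(receptors)) stop("dockEnsemble: need >= 1 receptor")
    poses <- list()
    for (ri in seq_along(receptors)) {
        airs <- buildResidueAIRs(ligand, receptors[[ri]], activeResidues,
                                 upper = config$airUpper)
        if (!is.null(extraRestraints))
            airs <- RestraintSet(c(restraints(airs),
                                   restraints(extraRestraints)))
        pre <- .dockPrep(receptors[[ri]], ligand, airs, config)
        rp <- withSeed(config$seed * 100003 + ri, {
            lapply(seq_len(config$nPosesPerConformation), function(k) {
                p <- samplePose(ligand, config, receptorIndex = ri)
                p <- .scorePosePre(p, pre)
                if (minimize) p <- .minimizePosePre(p, pre, config)
                p
            })
        })
        poses <- c(poses, rp)
    }
    poses[order(vapply(poses, poseScore, 1))]
}
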