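## Post-docking funnel: symmetry-aware ligand RMSD, leader clustering,
## top-k-average ranking, best-pose-per-cluster selection and NOE filtering.

#' Ligand symmetry declaration for pose RMSD
#'
#' For a C2-symmetric ligand, restrict pose RMSD to the heavy atoms lying on
#' the symmetry axis so that poses related by the two-fold flip are not
#' double-counted; for an asymmetric ligand pass all heavy-atom names.
#'
#' @param rmsdAtomNames nonempty character vector of ligand heavy-atom names
#'   (>= 3 recommended).
#' @return list of class "LigandSymmetry".
#' @export
ligandSymmetry <- function(rmsdAtomNames) {
    stopifnot(length(rmsdAtomNames) >= 1)
    structure(list(rmsdAtomNames = rmsdAtomNames), class = "LigandSymmetry")
}

#' Pose selection configuration
#'
#' @param clusterCutoff leader-clustering RMSD cutoff, Angstrom.
#' @param violationTolerance NOE violation threshold for discarding poses,
#'   Angstrom.
#' @param rankTopK number of best poses averaged when ranking clusters.
#' @param alignAtomNames receptor atom names used for frame alignment
#'   (default all Calpha atoms).
#' @return list of class "SelectionConfig".
#' @export
selectionConfig <- function(clusterCutoff = 1.5, violationTolerance = 0.3,
                            rankTopK = 4, alignAtomNames = "CA") {
    stopifnot(clusterCutoff > 0, violationTolerance >= 0, rankTopK >= 1)
    structure(list(clusterCutoff = clusterCutoff,
                   violationTolerance = violationTolerance,
                   rankTopK = as.integer(rankTopK),
                   alignAtomNames = alignAtomNames),
              class = "SelectionConfig")
}

## memoized Kabsch transform taking receptor[j]'s frame onto receptor[i]'s
.receptorAligner <- function(receptors, alignAtomNames) {
    sel <- lapply(receptors, function(r)
        coords(selectAtoms(r, atomNames = alignAtomNames)))
    ok <- vapply(sel, nrow, 1L) >= 3L
    if (!all(ok))
        stop("pose alignment: receptor lacks >= 3 '",
             paste(alignAtomNames, collapse = ","), "' atoms")
    cache <- new.env(parent = emptyenv())
    function(i, j) {
        if (i == j) return(RigidTransform())
        key <- paste(i, j)
        if (!is.null(cache[[key]])) return(cache[[key]])
        tr <- superpose(sel[[j]], sel[[i]])$transform
        cache[[key]] <- tr
        tr
    }
}

#' Symmetry-aware RMSD between two poses
#'
#' Superposes pose B's receptor onto pose A's receptor on the alignment
#' atoms (Calpha by default), applies that transform to B's ligand, and
#' returns the no-fit RMSD over the symmetry atom subset.
#'
#' @param poseA,poseB [Pose]s referencing the same ligand template.
#' @param ligand reference ligand [Structure].
#' @param receptors list of receptor [Structure]s indexed by the poses.
#' @param symmetry A [ligandSymmetry].
#' @param config A [selectionConfig] (alignment atom names).
#' @return RMSD in Angstrom.
#' @export
poseRMSD <- function(poseA, poseB, ligand, receptors, symmetry,
                     config = selectionConfig()) {
    aligner <- .receptorAligner(receptors, config$alignAtomNames)
    .poseRMSD(poseA, poseB, .symCoordsFn(ligand, symmetry), aligner)
}

.symCoordsFn <- function(ligand, symmetry) {
    idx <- which(atoms(ligand)$name %in% symmetry$rmsdAtomNames)
    if (length(idx) < length(symmetry$rmsdAtomNames))
        stop("poseRMSD: symmetry atoms missing from ligand: ",
             paste(setdiff(symmetry$rmsdAtomNames, atoms(ligand)$name),
                   collapse = ", "))
    ref <- coords(ligand)[idx, , drop = FALSE]
    function(pose) applyTransform(pose@transform, ref)
}

.poseRMSD <- function(poseA, poseB, symFn, aligner) {
    xa <- symFn(poseA)
    xb <- symFn(poseB)
    tr <- aligner(poseA@receptorIndex, poseB@receptorIndex)
    rmsdNoFit(xa, applyTransform(tr, xb))
}

#' Leader clustering of score-sorted poses
#'
#' The best-ranked unassigned pose becomes a leader; every unassigned pose
#' within the cutoff of that leader joins its cluster; repeat.  Leaders are
#' therefore mutually more than the cutoff apart, every member lies within
#' the cutoff of its leader, and the procedure is deterministic.
#'
#' @param poses list of [Pose]s sorted ascending by score.
#' @param ligand reference ligand [Structure].
#' @param receptors list of receptor [Structure]s.
#' @param symmetry A [ligandSymmetry].
#' @param config A [selectionConfig].
#' @return A [ClusterResult]; representatives are the leaders.
#' @export
clusterPoses <- function(poses, ligand, receptors, symmetry,
                         config = selectionConfig()) {
    stopifnot(length(poses) >= 1)
    sc <- vapply(poses, poseScore, 1)
    if (is.unsorted(sc)) stop("clusterPoses: poses must be sorted by score")
    symFn <- .symCoordsFn(ligand, symmetry)
    aligner <- .receptorAligner(receptors, config$alignAtomNames)
    n <- length(poses)
    assign <- rep(NA_integer_, n)
    leaders <- integer(0)
    cl <- 0L
    while (anyNA(assign)) {
        lead <- which(is.na(assign))[1]      # best-scoring unassigned pose
        cl <- cl + 1L
        assign[lead] <- cl
        leaders[cl] <- lead
        for (i in which(is.na(assign))) {
            if (.poseRMSD(poses[[lead]], poses[[i]], symFn, aligner) <=
                config$clusterCutoff)
                assign[i] <- cl
        }
    }
    new("ClusterResult", assignments = assign, representatives = leaders,
        radius = config$clusterCutoff)
}

#' Rank pose clusters by the average score of their top poses
#'
#' The rank key of a cluster is the mean score of its best
#' min(rankTopK, size) poses; clusters sort ascending by key, with ties
#' going to the larger cluster and then the lower cluster id.
#'
#' @param clusterResult A [ClusterResult] from [clusterPoses].
#' @param poses the pose list that was clustered.
#' @param config A [selectionConfig].
#' @return data.frame (cluster, size, rankKey) in rank order.
#' @export
rankClusters <- function(clusterResult, poses, config = selectionConfig()) {
    sc <- vapply(poses, poseScore, 1)
    assign <- clusterAssignments(clusterResult)
    k <- nClusters(clusterResult)
    size <- integer(k); key <- numeric(k)
    for (c in seq_len(k)) {
        s <- sort(sc[assign == c])
        size[c] <- length(s)
        key[c] <- mean(s[seq_len(min(config$rankTopK, length(s)))])
    }
    d <- data.frame(cluster = seq_len(k), size = size, rankKey = key)
    d[order(d$rankKey, -d$size, d$cluster), , drop = FALSE]
}

#' Final pose selection with NOE-violation filtering
#'
#' Takes the best-scoring pose of each cluster in rank order, discards any
#' whose maximum NOE violation exceeds the tolerance, and reports ensemble
#' restraint satisfaction over the survivors.  An empty final set is a
#' valid outcome reported in the summary, not an error.
#'
#' @param rankedClusters data.frame from [rankClusters].
#' @param clusterResult the [ClusterResult] that was ranked.
#' @param poses the clustered pose list (score-sorted).
#' @param restraintSet [RestraintSet] used for the violation filter.
#' @param receptors list of receptor [Structure]s.
#' @param ligand reference ligand [Structure].
#' @param config A [selectionConfig].
#' @return list with \code{poses} (surviving [Pose]s, rank order),
#'   \code{table} (per-candidate data.frame: cluster, poseIndex, score,
#'   maxViolation, kept), and \code{satisfaction} (from
#'   [ensembleSatisfaction], NULL when no pose survived).
#' @export
selectFinalPoses <- function(rankedClusters, clusterResult, poses,
                             restraintSet, receptors, ligand,
                             config = selectionConfig()) {
    stopifnot(nrow(rankedClusters) >= 1)
    assign <- clusterAssignments(clusterResult)
    sc <- vapply(poses, poseScore, 1)
    rows <- list(); final <- list()
    for (c in rankedClusters$cluster) {
        members <- which(assign == c)
        best <- members[which.min(sc[members])]
        p <- poses[[best]]
        viol <- evaluateViolations(restraintSet,
                                   receptors[[p@receptorIndex]],
                                   applyTransform(p@transform, ligand),
                                   config$violationTolerance)
        keep <- max(viol$violation) <= config$violationTolerance
        rows[[length(rows) + 1L]] <- data.frame(
            cluster = c, poseIndex = best, score = sc[best],
            maxViolation = max(viol$violation), kept = keep)
        if (keep) final[[length(final) + 1L]] <- p
    }
    sat <- if (length(final))
        ensembleSatisfaction(restraintSet, receptors, ligand, final,
                             config$violationTolerance) else NULL
    list(poses = final, table = do.call(rbind, rows), satisfaction = sat)
}
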