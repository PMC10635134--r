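## Conformational-ensemble selection: pairwise RMSD, quality-threshold
## clustering and medoid representatives.

#' Pairwise superposed-RMSD matrix over a frame set
#'
#' Entry (i, j) is the least-squares superposed RMSD between frames i and j
#' over the selected atoms; the matrix is symmetric with zero diagonal.
#'
#' @param frames list of [Structure]s with identical atom ordering (>= 2).
#' @param atomNames atom-name selection (NULL = all atoms); heavy-atom
#'   clustering passes the heavy-atom names.
#' @param heavyOnly drop hydrogens before comparison.
#' @return symmetric numeric matrix, Angstrom.
#' @export
pairwiseRMSDMatrix <- function(frames, atomNames = NULL, heavyOnly = TRUE) {
    if (length(frames) < 2L) stop("pairwiseRMSDMatrix: need >= 2 frames")
    sel <- lapply(frames, function(f) {
        if (heavyOnly) f <- heavyAtoms(f)
        f <- selectAtoms(f, atomNames = atomNames)
        if (nAtoms(f) == 0L) stop("pairwiseRMSDMatrix: empty selection")
        coords(f)
    })
    n <- length(sel)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- superpose(sel[[i]], sel[[j]])$rmsd
    }
    m
}

#' RMSD of each frame from a reference structure
#'
#' 1-D alternative similarity for trajectories described by their distance
#' from an initial (e.g. equilibrated) structure.
#' @param frames list of [Structure]s.
#' @param reference reference [Structure].
#' @param atomNames,heavyOnly see [pairwiseRMSDMatrix].
#' @return numeric vector of superposed RMSDs, Angstrom.
#' @export
referenceRMSD <- function(frames, reference, atomNames = NULL,
                          heavyOnly = TRUE) {
    prep <- function(f) {
        if (heavyOnly) f <- heavyAtoms(f)
        coords(selectAtoms(f, atomNames = atomNames))
    }
    ref <- prep(reference)
    vapply(frames, function(f) superpose(prep(f), ref)$rmsd, 1)
}

#' Quality-threshold clustering of a distance matrix
#'
#' Greedy QT scheme: for every unassigned item form the candidate cluster of
#' all unassigned items within \code{radius} of it; commit the largest
#' candidate (ties broken by the lowest seed index); repeat until everything
#' is assigned.  Every member ends within \code{radius} of its cluster's
#' seed.  Deterministic: the same matrix always yields the same partition.
#'
#' @param mat square symmetric nonnegative distance matrix.
#' @param radius quality threshold (cluster radius), > 0.
#' @return A [ClusterResult]; representatives are the cluster seeds (medoid
#'   representatives are chosen separately, see [representativeFrames]).
#' @export
qtCluster <- function(mat, radius) {
    if (radius <= 0) stop("qtCluster: radius must be positive")
    mat <- as.matrix(mat)
    stopifnot(nrow(mat) == ncol(mat), max(abs(mat - t(mat))) < 1e-9)
    n <- nrow(mat)
    assign <- rep(NA_integer_, n)
    seeds <- integer(0)
    cl <- 0L
    while (anyNA(assign)) {
        un <- which(is.na(assign))
        best <- NULL; bestSize <- -1L
        for (s in un) {
            cand <- un[mat[s, un] <= radius]
            if (length(cand) > bestSize) {   # ties: earlier (lower) seed wins
                best <- list(seed = s, members = cand)
                bestSize <- length(cand)
            }
        }
        cl <- cl + 1L
        assign[best$members] <- cl
        seeds[cl] <- best$seed
    }
    new("ClusterResult", assignments = assign, representatives = seeds,
        radius = radius)
}

#' Medoid representative frames per cluster
#'
#' The representative of a cluster is the member minimizing the mean squared
#' RMSD to all other members (the medoid, a physical stand-in for the
#' centroid); ties go to the lowest frame index.  Singleton clusters return
#' their only frame.
#'
#' @param mat the distance matrix used for clustering.
#' @param clusterResult A [ClusterResult] over the same items.
#' @return A [ClusterResult] whose representatives are the medoids.
#' @export
medoidRepresentatives <- function(mat, clusterResult) {
    mat <- as.matrix(mat)
    assign <- clusterAssignments(clusterResult)
    reps <- integer(nClusters(clusterResult))
    for (c in seq_len(nClusters(clusterResult))) {
        members <- which(assign == c)
        if (length(members) == 1L) { reps[c] <- members; next }
        cost <- vapply(members, function(i)
            mean(mat[i, setdiff(members, i)]^2), 1)
        reps[c] <- members[which.min(cost)]
    }
    new("ClusterResult", assignments = assign, representatives = reps,
        radius = clusterResult@radius)
}

#' Select representative structures for docking
#'
#' Clusters a trajectory by heavy-atom pairwise RMSD with the quality
#' threshold, then returns the medoid structure of each cluster — the route
#' from a sampled opening pathway to a small docking-receptor ensemble.
#'
#' @param frames list of [Structure]s.
#' @param radius QT cluster radius, Angstrom (default 2.0).
#' @param atomNames optional atom-name selection.
#' @return list with \code{representatives} (list of [Structure]s),
#'   \code{clusters} (the medoid [ClusterResult]) and \code{matrix}.
#' @export
representativeFrames <- function(frames, radius = 2.0, atomNames = NULL) {
    mat <- pairwiseRMSDMatrix(frames, atomNames = atomNames)
    cl <- medoidRepresentatives(mat, qtCluster(mat, radius))
    list(representatives = frames[clusterRepresentatives(cl)],
         clusters = cl, matrix = mat)
}
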