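# Shared fixtures and independent oracles.

# write PDB text lines to a temp file and return its path
writeTempPDB <- function(lines) {
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    path
}

# a well-formed fixed-width ATOM line (wwPDB v3.3 columns)
atomLine <- function(serial, name, resName, chain, resSeq, x, y, z,
                     element = "C") {
    nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
    sprintf("ATOM  %5d %s %-3s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, nm, resName, chain, resSeq, x, y, z, element)
}

extdata <- function(...) system.file("extdata", ..., package = "NOEDock")

loadRestraintFixture <- function(ligand = c("kg655", "kg279")) {
    ligand <- match.arg(ligand)
    groups <- readProtonGroups(extdata(sprintf("%s_synthetic_groups.tsv", ligand)))
    peaks <- readNoePeaks(extdata(sprintf("%s_synthetic_peaks.tsv", ligand)), groups)
    sites <- utils::read.delim(extdata(sprintf("%s_synthetic_sites.tsv", ligand)))
    list(groups = groups, peaks = peaks,
         siteLabels = stats::setNames(sites$site, sites$residue))
}

# Monte-Carlo surface-integration oracle for SASA, independent of the
# deterministic lattice used by the implementation
mcSasa <- function(structure, probeRadius = 1.4, nSamples = 2e5, seed = 42) {
    xyz <- coords(structure)
    rad <- atoms(structure)$vdw + probeRadius
    n <- nrow(xyz)
    set.seed(seed)
    vapply(seq_len(n), function(i) {
        pts <- matrix(rnorm(nSamples * 3), ncol = 3)
        pts <- pts / sqrt(rowSums(pts^2)) * rad[i]
        pts <- sweep(pts, 2, xyz[i, ], `+`)
        acc <- rep(TRUE, nSamples)
        for (j in setdiff(seq_len(n), i)) {
            d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
            acc <- acc & d2 >= rad[j]^2
        }
        4 * pi * rad[i]^2 * mean(acc)
    }, 1)
}

# independent re-implementation of the greedy QT commit rule (largest
# candidate cluster, ties to the lowest seed index), for n <= 8 instances
bruteQT <- function(mat, radius) {
    n <- nrow(mat)
    assign <- rep(NA_integer_, n)
    cl <- 0L
    while (anyNA(assign)) {
        un <- which(is.na(assign))
        cands <- lapply(un, function(s) un[mat[s, un] <= radius])
        sizes <- lengths(cands)
        pick <- which(sizes == max(sizes))[1]
        cl <- cl + 1L
        assign[cands[[pick]]] <- cl
    }
    assign
}

# independent leader-clustering oracle over a precomputed distance matrix
bruteLeader <- function(mat, cutoff) {
    n <- nrow(mat)
    assign <- rep(NA_integer_, n)
    cl <- 0L
    while (anyNA(assign)) {
        lead <- which(is.na(assign))[1]
        cl <- cl + 1L
        join <- which(is.na(assign) & mat[lead, ] <= cutoff)
        assign[unique(c(lead, join))] <- cl
    }
    assign
}

# weighted two-sample Kolmogorov-Smirnov distance on a value grid
weightedKS <- function(x1, w1, x2, w2 = rep(1 / length(x2), length(x2))) {
    grid <- sort(unique(c(x1, x2)))
    F1 <- c(0, cumsum(w1[order(x1)]))[findInterval(grid, sort(x1)) + 1]
    F2 <- c(0, cumsum(w2[order(x2)]))[findInterval(grid, sort(x2)) + 1]
    max(abs(F1 / sum(w1) - F2 / sum(w2)))
}

# run the full toy pipeline in memory (fabricate -> calibrate -> dock ->
# select); returns the minimum symmetry-RMSD of the final set from the
# truth and the ensemble-satisfaction fraction
runToyRecovery <- function(seed, nPoses = 150, minimEvals = 200) {
    cx <- makeToyComplex(toyComplexSpec(seed = seed))
    ip <- calibratePeaks(cx@peaks, cx@protonGroups)
    act <- deriveActiveResidues(cx@peaks, cx@protonGroups, cx@siteLabels)
    recs <- makeReceptorEnsemble(cx@receptor, 2, seed = seed + 100)
    dcfg <- dockingConfig(nPosesPerConformation = nPoses,
                          samplingCenter = c(0, 0, 0), samplingRadius = 2.5,
                          maxMinimizerEvals = minimEvals, seed = seed + 200)
    poses <- dockEnsemble(recs, cx@ligand, act, dcfg, extraRestraints = ip)
    sym <- ligandSymmetry(cx@symmetryAtoms)
    truth <- new("Pose", transform = cx@truePose, receptorIndex = 1L)
    cl <- clusterPoses(poses, cx@ligand, recs, sym)
    rk <- rankClusters(cl, poses)
    sel <- selectFinalPoses(rk, cl, poses, ip, recs, cx@ligand)
    if (!length(sel$poses))
        return(list(minRmsd = Inf, satFraction = 0))
    rmsds <- vapply(sel$poses, function(p)
        poseRMSD(truth, p, cx@ligand, recs, sym), 1)
    list(minRmsd = min(rmsds),
         satFraction = sel$satisfaction$nSatisfied / sel$satisfaction$nTotal)
}

# quasi-uniform unit-sphere directions for building blocker shells
unitSpherePoints <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
    cbind(r * cos(phi), r * sin(phi), z)
}
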