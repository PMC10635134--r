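#' @import methods
NULL

#' Molecular structure as an ordered atom table
#'
#' Minimal container for a set of atoms read from a PDB file or built
#' synthetically.  Atoms are stored as an ordered \code{data.frame} with one
#' row per atom and columns \code{serial}, \code{name}, \code{element},
#' \code{resName}, \code{resSeq}, \code{chain}, \code{x}, \code{y}, \code{z},
#' \code{vdw} (van der Waals radius, Angstrom).  Order is preserved across
#' read/write round trips; residue numbers are taken verbatim from the source
#' (author numbering such as ARNT 356-470 is legal).
#'
#' @slot atoms data.frame of per-atom records (see above).
#' @slot label free-text label.
#' @export
setClass("Structure",
    representation(atoms = "data.frame", label = "character"),
    prototype(atoms = data.frame(), label = ""))

setValidity("Structure", function(object) {
    a <- object@atoms
    need <- c("serial", "name", "element", "resName", "resSeq", "chain",
              "x", "y", "z", "vdw")
    if (!all(need %in% names(a)))
        return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (nrow(a) == 0L) return(TRUE)
    if (anyDuplicated(a$serial)) return("atom serials must be unique")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
        return("coordinates must be finite")
    if (!all(a$vdw > 0)) return("vdW radii must be positive")
    TRUE
})

#' Proper rigid-body transform
#'
#' Rotation + translation with determinant +1 (no improper rotations, so a
#' mirror image can never be produced by applying one).
#'
#' @slot rotation 3x3 orthonormal matrix, det = +1 within 1e-9.
#' @slot translation length-3 numeric, Angstrom.
#' @export
setClass("RigidTransform",
    representation(rotation = "matrix", translation = "numeric"),
    prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (length(object@translation) != 3L) return("translation must be length 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
        return("rotation must be orthonormal (R'R = I within 1e-9)")
    if (abs(det(R) - 1) > 1e-9)
        return("rotation must be proper (det = +1 within 1e-9)")
    TRUE
})

#' A set of distance restraints between atom groups
#'
#' Each restraint is a list with elements \code{id}, \code{groupA} and
#' \code{groupB} (each a list with \code{owner} = "ligand"/"receptor",
#' \code{atoms} = character vector of atom names, and \code{residue} =
#' integer or NA), \code{lower}, \code{upper} (Angstrom) and \code{level}
#' ("interproton" or "heavy").  Group distances are evaluated with the
#' r^-6-summed effective distance, so multi-atom groups behave as ambiguous
#' restraints.
#'
#' @slot restraints list of restraint records (see above).
#' @export
setClass("RestraintSet", representation(restraints = "list"),
    prototype(restraints = list()))

setValidity("RestraintSet", function(object) {
    for (r in object@restraints) {
        if (!all(c("id", "groupA", "groupB", "lower", "upper", "level")
                 %in% names(r)))
            return("each restraint needs id, groupA, groupB, lower, upper, level")
        if (!(r$lower > 0 && r$lower < r$upper))
            return(sprintf("restraint %s: need 0 < lower < upper", r$id))
        if (length(r$groupA$atoms) < 1L || length(r$groupB$atoms) < 1L)
            return(sprintf("restraint %s: empty atom group", r$id))
        if (!r$level %in% c("interproton", "heavy"))
            return(sprintf("restraint %s: bad level", r$id))
    }
    TRUE
})

#' Rigid-body placement of a ligand with score diagnostics
#'
#' @slot transform [RigidTransform] applied to the reference ligand.
#' @slot receptorIndex which receptor conformation the pose was docked into.
#' @slot score total score (lower is better), = wAir*eAir + wSteric*eSteric.
#' @slot eAir ambiguous-restraint penalty (>= 0).
#' @slot eSteric soft-core steric penalty (>= 0).
#' @slot converged FALSE when the minimizer hit its evaluation budget.
#' @export
setClass("Pose",
    representation(transform = "RigidTransform", receptorIndex = "integer",
                   score = "numeric", eAir = "numeric", eSteric = "numeric",
                   converged = "logical"),
    prototype(receptorIndex = 1L, score = NA_real_, eAir = NA_real_,
              eSteric = NA_real_, converged = TRUE))

setValidity("Pose", function(object) {
    if (!is.na(object@eAir) && object@eAir < -1e-12) return("eAir must be >= 0")
    if (!is.na(object@eSteric) && object@eSteric < -1e-12)
        return("eSteric must be >= 0")
    TRUE
})

#' Assignment of frames or poses to clusters
#'
#' @slot assignments integer vector, item -> cluster id (1-based, dense).
#' @slot representatives integer vector, cluster id -> item index.
#' @slot radius the clustering radius/cutoff used, Angstrom.
#' @export
setClass("ClusterResult",
    representation(assignments = "integer", representatives = "integer",
                   radius = "numeric"))

setValidity("ClusterResult", function(object) {
    k <- length(object@representatives)
    if (k > 0 && !all(object@assignments %in% seq_len(k)))
        return("assignments must reference existing clusters")
    for (c in seq_len(k)) {
        rep <- object@representatives[c]
        if (object@assignments[rep] != c)
            return("each representative must belong to its cluster")
    }
    TRUE
})

#' Weighted-ensemble walker population
#'
#' @slot states list of opaque propagator states (one per walker).
#' @slot pcoords numeric progress-coordinate values.
#' @slot weights positive probability masses.
#' @export
setClass("WalkerSet",
    representation(states = "list", pcoords = "numeric", weights = "numeric"))

setValidity("WalkerSet", function(object) {
    n <- length(object@states)
    if (length(object@pcoords) != n || length(object@weights) != n)
        return("states, pcoords and weights must have equal length")
    if (n > 0 && !all(object@weights > 0)) return("weights must be positive")
    if (n > 0 && !all(is.finite(object@pcoords)))
        return("pcoords must be finite")
    TRUE
})

#' Synthetic receptor-ligand complex with known ground truth
#'
#' @slot receptor [Structure]: pocket-probe pseudo-residues + wall atoms.
#' @slot ligand [Structure]: reference (untransformed) ligand.
#' @slot truePose [RigidTransform] placing the ligand in the pocket.
#' @slot peaks data.frame of fabricated NOE peaks
#'   (ligandGroup, receptorGroup, class).
#' @slot protonGroups named list of proton-group records
#'   (protons, heavies, owner, residue).
#' @slot siteLabels named character: residue number -> "cavity"/"surface"/"outlier".
#' @slot symmetryAtoms atom names used for symmetry-corrected ligand RMSD.
#' @export
setClass("ToyComplex",
    representation(receptor = "Structure", ligand = "Structure",
                   truePose = "RigidTransform", peaks = "data.frame",
                   protonGroups = "list", siteLabels = "character",
                   symmetryAtoms = "character"))

## ---- constructors ----

#' Build a Structure from an atom table
#' @param atoms data.frame with the Structure atom columns.
#' @param label free-text label.
#' @return A [Structure].
#' @export
Structure <- function(atoms, label = "") {
    rownames(atoms) <- NULL
    new("Structure", atoms = atoms, label = label)
}

#' Build a proper rigid transform
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric (Angstrom).
#' @return A [RigidTransform].
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
    new("RigidTransform", rotation = rotation,
        translation = as.numeric(translation))
}

#' @export
RestraintSet <- function(restraints = list()) {
    new("RestraintSet", restraints = restraints)
}

#' @export
WalkerSet <- function(states, pcoords, weights) {
    new("WalkerSet", states = states, pcoords = as.numeric(pcoords),
        weights = as.numeric(weights))
}

## ---- accessors ----

#' Number of atoms in a structure
#' @param x A [Structure].
#' @return Integer atom count.
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' Atom table of a structure
#' @param x A [Structure].
#' @return The atoms data.frame.
#' @export
atoms <- function(x) x@atoms

#' Coordinate matrix of a structure
#' @param x A [Structure].
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(x) {
    m <- as.matrix(x@atoms[, c("x", "y", "z")])
    dimnames(m) <- NULL
    m
}

#' Replace the coordinates of a structure
#' @param x A [Structure].
#' @param value n x 3 matrix.
#' @return The modified [Structure].
#' @export
`coords<-` <- function(x, value) {
    stopifnot(nrow(value) == nAtoms(x), ncol(value) == 3L)
    x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
    x
}

#' Restraint list of a RestraintSet
#' @param x A [RestraintSet].
#' @return list of restraint records.
#' @export
restraints <- function(x) x@restraints

#' @export
setMethod("length", "RestraintSet", function(x) length(x@restraints))

#' @export
setMethod("length", "WalkerSet", function(x) length(x@weights))

#' Walker weights
#' @param x A [WalkerSet].
#' @return numeric vector of weights.
#' @export
weights <- function(x) x@weights

#' Walker progress-coordinate values
#' @param x A [WalkerSet].
#' @return numeric vector.
#' @export
pcoords <- function(x) x@pcoords

#' Number of clusters in a ClusterResult
#' @param x A [ClusterResult].
#' @return integer.
#' @export
nClusters <- function(x) length(x@representatives)

#' Cluster assignments
#' @param x A [ClusterResult].
#' @return integer vector mapping items to cluster ids.
#' @export
clusterAssignments <- function(x) x@assignments

#' Cluster representative indices
#' @param x A [ClusterResult].
#' @return integer vector, cluster id -> item index.
#' @export
clusterRepresentatives <- function(x) x@representatives

#' Pose score
#' @param x A [Pose].
#' @return numeric score (lower better).
#' @export
poseScore <- function(x) x@score

#' Pose transform
#' @param x A [Pose].
#' @return The pose's [RigidTransform].
#' @export
poseTransform <- function(x) x@transform

## ---- show methods ----

setMethod("show", "Structure", function(object) {
    a <- object@atoms
    cat(sprintf("Structure '%s': %d atoms, %d residues\n",
                object@label, nrow(a),
                length(unique(paste(a$chain, a$resSeq)))))
    if (nrow(a) > 0)
        cat(sprintf("  elements: %s\n",
                    paste(sort(unique(a$element)), collapse = " ")))
})

setMethod("show", "RigidTransform", function(object) {
    ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
    cat(sprintf("RigidTransform: rotation %.1f deg, translation (%.2f, %.2f, %.2f) A\n",
                ang * 180 / pi, object@translation[1], object@translation[2],
                object@translation[3]))
})

setMethod("show", "RestraintSet", function(object) {
    lv <- vapply(object@restraints, `[[`, "", "level")
    cat(sprintf("RestraintSet: %d restraints (%d interproton, %d heavy)\n",
                length(object@restraints), sum(lv == "interproton"),
                sum(lv == "heavy")))
})

setMethod("show", "Pose", function(object) {
    cat(sprintf("Pose: receptor %d, score %.4g (eAir %.4g, eSteric %.4g)\n",
                object@receptorIndex, object@score, object@eAir,
                object@eSteric))
})

setMethod("show", "ClusterResult", function(object) {
    cat(sprintf("ClusterResult: %d items in %d clusters (radius %.2f A)\n",
                length(object@assignments), nClusters(object), object@radius))
})

setMethod("show", "WalkerSet", function(object) {
    cat(sprintf("WalkerSet: %d walkers, total weight %.6f, pcoord [%.3g, %.3g]\n",
                length(object), sum(object@weights),
                min(object@pcoords), max(object@pcoords)))
})

setMethod("show", "ToyComplex", function(object) {
    cat(sprintf("ToyComplex: receptor %d atoms, ligand %d atoms, %d NOE peaks\n",
                nAtoms(object@receptor), nAtoms(object@ligand),
                nrow(object@peaks)))
})
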