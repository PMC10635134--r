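## End-to-end orchestration: restraints -> receptor ensemble -> docking ->
## pose selection, with a JSON run manifest and a human-readable report.

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Default pipeline configuration
#'
#' Every tunable surfaces the method's printed constant as its default:
#' 2.8/3.5/5.0 Angstrom class calibration with 1.8 Angstrom lower bound,
#' +1 Angstrom heavy-atom extension, 2 Angstrom QT ensemble radius,
#' 1.5 Angstrom pose-cluster cutoff, top-4 score averaging, 0.3 Angstrom
#' violation tolerance.
#'
#' @param receptors character vector of receptor PDB paths (ensemble
#'   members), or NULL when \code{trajectory} is given.
#' @param trajectory character vector of trajectory-frame PDB paths to be
#'   reduced by QT clustering (alternative to \code{receptors}).
#' @param ligand ligand PDB path.
#' @param peaks,groups,siteLabels restraint-table TSV paths.
#' @param symmetryAtoms ligand heavy-atom names for pose RMSD (NULL = all
#'   heavy atoms; a path to a one-name-per-line file is also accepted).
#' @param outputDir run output directory.
#' @param ensembleRadius QT cluster radius for the trajectory, Angstrom.
#' @param docking list of [dockingConfig] overrides.
#' @param selection list of [selectionConfig] overrides.
#' @param calibration list(upper=named numeric, lower) overriding
#'   [calibrationTable].
#' @param seed master seed.
#' @return nested config list of class "PipelineConfig".
#' @export
pipelineConfig <- function(receptors = NULL, trajectory = NULL, ligand,
                           peaks, groups, siteLabels, symmetryAtoms = NULL,
                           outputDir = "noedock-run", ensembleRadius = 2.0,
                           docking = list(), selection = list(),
                           calibration = list(), seed = 1) {
    structure(list(receptors = receptors, trajectory = trajectory,
                   ligand = ligand, peaks = peaks, groups = groups,
                   siteLabels = siteLabels, symmetryAtoms = symmetryAtoms,
                   outputDir = outputDir, ensembleRadius = ensembleRadius,
                   docking = docking, selection = selection,
                   calibration = calibration, seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Read a pipeline config from YAML
#' @param path YAML file whose keys mirror [pipelineConfig] arguments.
#' @return a "PipelineConfig" list.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(pipelineConfig, y)
}

#' Run the full docking pipeline
#'
#' Stages: (1) parse proton groups, NOE peaks and site labels; calibrate
#' peaks into interproton restraints, derive active residues and extend to
#' heavy-atom distances; (2) build the receptor ensemble, either directly
#' from the given conformations or by quality-threshold clustering of a
#' trajectory; (3) restraint-guided rigid-body docking of every pose
#' against every conformation; (4) symmetry-aware leader clustering,
#' top-k ranking, best-pose selection and NOE-violation filtering.  All
#' randomness derives from the config seed, so reruns are byte-identical.
#'
#' @param config a "PipelineConfig" list (or path to a YAML file).
#' @return the run manifest (list), invisibly; written as manifest.json in
#'   the output directory together with TSV/PDB/JSON stage outputs.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(...) file.path(config$outputDir, ...)

    ## stage 1: restraints
    st1 <- .stage("restraints", {
        groups <- readProtonGroups(config$groups)
        peaks <- readNoePeaks(config$peaks, groups)
        labs <- utils::read.delim(config$siteLabels,
                                  stringsAsFactors = FALSE)
        siteLabels <- stats::setNames(labs$site, labs$residue)
        table <- do.call(calibrationTable, config$calibration)
        ip <- calibratePeaks(peaks, groups, table)
        active <- deriveActiveResidues(peaks, groups, siteLabels)
        heavy <- extendToHeavyAtoms(ip, groups)
        writeRestraintTable(ip, out("restraints_interproton.tsv"))
        writeRestraintTable(heavy, out("restraints_heavy.tsv"))
        exportCNSRestraints(heavy, out("restraints_heavy.cns"))
        list(groups = groups, peaks = peaks, interproton = ip,
             heavy = heavy, active = active)
    })

    ## stage 2: receptor ensemble
    st2 <- .stage("ensemble", {
        ligand <- readPDB(config$ligand)
        if (!is.null(config$trajectory)) {
            frames <- lapply(config$trajectory, readPDB)
            rf <- representativeFrames(frames, radius = config$ensembleRadius)
            receptors <- rf$representatives
            utils::write.table(
                data.frame(frame = seq_along(frames),
                           cluster = clusterAssignments(rf$clusters)),
                out("ensemble_clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
        } else {
            if (is.null(config$receptors))
                stop("need 'receptors' or 'trajectory'")
            receptors <- lapply(config$receptors, readPDB)
        }
        list(ligand = ligand, receptors = receptors)
    })

    ## stage 3: docking
    st3 <- .stage("docking", {
        dockArgs <- config$docking
        if (is.null(dockArgs$samplingCenter)) {
            sc <- heavyAtoms(selectAtoms(st2$receptors[[1]],
                                         resSeq = st1$active))
            scn <- atoms(sc)$name != "CA"
            dockArgs$samplingCenter <- colMeans(coords(sc)[scn, , drop = FALSE])
        }
        if (is.null(dockArgs$seed)) dockArgs$seed <- config$seed
        dcfg <- do.call(dockingConfig, dockArgs)
        poses <- dockEnsemble(st2$receptors, st2$ligand, st1$active, dcfg,
                              extraRestraints = st1$interproton)
        utils::write.table(
            data.frame(pose = seq_along(poses),
                       receptor = vapply(poses, function(p) p@receptorIndex, 1L),
                       score = vapply(poses, poseScore, 1),
                       eAir = vapply(poses, function(p) p@eAir, 1),
                       eSteric = vapply(poses, function(p) p@eSteric, 1)),
            out("poses.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        list(poses = poses, config = dcfg)
    })

    ## stage 4: selection
    st4 <- .stage("selection", {
        symNames <- config$symmetryAtoms
        if (is.character(symNames) && length(symNames) == 1 &&
            file.exists(symNames)) symNames <- readLines(symNames)
        if (is.null(symNames))
            symNames <- atoms(heavyAtoms(st2$ligand))$name
        sym <- ligandSymmetry(symNames)
        scfg <- do.call(selectionConfig, config$selection)
        cl <- clusterPoses(st3$poses, st2$ligand, st2$receptors, sym, scfg)
        ranked <- rankClusters(cl, st3$poses, scfg)
        sel <- selectFinalPoses(ranked, cl, st3$poses, st1$interproton,
                                st2$receptors, st2$ligand, scfg)
        utils::write.table(
            data.frame(pose = seq_along(st3$poses),
                       cluster = clusterAssignments(cl)),
            out("pose_clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        dir.create(out("final_poses"), showWarnings = FALSE)
        for (k in seq_along(sel$poses)) {
            p <- sel$poses[[k]]
            rec <- st2$receptors[[p@receptorIndex]]
            lig <- applyTransform(p@transform, st2$ligand)
            la <- atoms(lig)
            la$serial <- la$serial + max(atoms(rec)$serial)
            comb <- Structure(rbind(atoms(rec), la))
            writePDB(comb, out("final_poses", sprintf("pose_%d.pdb", k)))
        }
        list(clusters = cl, ranked = ranked, selection = sel,
             config = scfg)
    })

    sat <- st4$selection$satisfaction
    manifest <- list(
        seed = config$seed,
        counts = list(
            peaks = nrow(st1$peaks),
            restraints_interproton = length(st1$interproton),
            restraints_heavy = length(st1$heavy),
            active_residues = length(st1$active),
            receptors = length(st2$receptors),
            poses_total = length(st3$poses),
            pose_clusters = nClusters(st4$clusters),
            final_poses = length(st4$selection$poses)),
        active_residues = st1$active,
        violation_tolerance = st4$config$violationTolerance,
        satisfaction = if (is.null(sat)) NULL else list(
            n_satisfied = sat$nSatisfied, n_total = sat$nTotal,
            residues_satisfied = sum(sat$perResidue),
            residues_total = length(sat$perResidue)),
        selection_table = st4$selection$table,
        ranked_clusters = st4$ranked)
    jsonlite::write_json(manifest, out("selection_report.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
    files <- list.files(config$outputDir, recursive = TRUE,
                        full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$files <- as.list(stats::setNames(
        unname(tools::md5sum(sort(files))),
        sub(paste0("^", config$outputDir, "/?"), "", sort(files))))
    jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                         auto_unbox = TRUE, null = "null")
    invisible(manifest)
}

#' Print a human-readable summary of a pipeline run
#'
#' @param manifest manifest list from [runPipeline] or the path to a
#'   manifest.json.
#' @return the manifest, invisibly.
#' @export
pipelineReport <- function(manifest) {
    if (is.character(manifest)) {
        if (!file.exists(manifest)) stop("pipelineReport: no such manifest: ",
                                         manifest)
        manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    }
    co <- manifest$counts
    cat(sprintf("NOE-guided ensemble docking run (seed %d)\n", manifest$seed))
    cat(sprintf("  %d peaks -> %d interproton restraints -> %d heavy-atom distances\n",
                co$peaks, co$restraints_interproton, co$restraints_heavy))
    cat(sprintf("  %d active residues; %d receptor conformations; %d poses docked\n",
                co$active_residues, co$receptors, co$poses_total))
    cat(sprintf("  %d pose clusters -> %d final poses\n",
                co$pose_clusters, co$final_poses))
    if (co$final_poses == 0) {
        cat(sprintf("  no poses passed the %.1f A violation filter\n",
                    manifest$violation_tolerance))
    } else {
        s <- manifest$satisfaction
        cat(sprintf("  as an ensemble, satisfied %d of %d restraints; %d of %d residues\n",
                    s$n_satisfied, s$n_total, s$residues_satisfied,
                    s$residues_total))
    }
    invisible(manifest)
}
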