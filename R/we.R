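## Weighted-ensemble resampling with minimal adaptive binning (MAB), plus the
## 1-D double-well Brownian propagator used as the desk-scale test system.

#' Weighted-ensemble run configuration
#'
#' Defaults mirror the production settings of the method this implements:
#' 15 bins and a target of 8 trajectories per bin; \code{tauSteps} is the
#' propagation length per iteration in propagator steps.
#'
#' @param nBins number of bins (>= 3; two are reserved for the lagging and
#'   leading walkers).
#' @param targetPerBin walkers per occupied bin after resampling (>= 1).
#' @param nIterations WE iterations to run.
#' @param tauSteps propagator steps per iteration.
#' @param seed integer master seed; every stream is derived from it.
#' @return list of class "WEConfig".
#' @export
weConfig <- function(nBins = 15, targetPerBin = 8, nIterations = 100,
                     tauSteps = 50, seed = 1) {
    stopifnot(nBins >= 3, targetPerBin >= 1, nIterations >= 0, tauSteps >= 1)
    structure(list(nBins = as.integer(nBins),
                   targetPerBin = as.integer(targetPerBin),
                   nIterations = as.integer(nIterations),
                   tauSteps = as.integer(tauSteps),
                   seed = as.integer(seed)), class = "WEConfig")
}

#' Minimal adaptive bin layout
#'
#' Reserves one bin for the current minimum (lagging) walker and one for the
#' maximum (leading) walker; the remaining nBins-2 bins are linearly spaced
#' between the current min and max.  Degenerate all-equal input yields a
#' symmetric epsilon-width layout.
#'
#' @param pcoords numeric progress-coordinate values (>= 1).
#' @param nBins number of bins (>= 3).
#' @return list of class "BinLayout" with elements \code{min}, \code{max},
#'   \code{boundaries} (interior boundaries, strictly increasing) and
#'   \code{nBins}.
#' @export
mabBins <- function(pcoords, nBins = 15) {
    if (nBins < 3) stop("mabBins: need nBins >= 3")
    if (!length(pcoords)) stop("mabBins: no pcoords")
    lo <- min(pcoords); hi <- max(pcoords)
    if (hi - lo < 1e-12) {            # degenerate: symmetric epsilon layout
        eps <- max(1e-8, abs(lo) * 1e-8)
        lo <- lo - eps; hi <- hi + eps
    }
    structure(list(min = lo, max = hi,
                   boundaries = seq(lo, hi, length.out = nBins - 1),
                   nBins = as.integer(nBins)), class = "BinLayout")
}

#' Assign walkers to MAB bins
#'
#' The single lagging (minimum-pcoord) walker goes to bin 1 and the leading
#' (maximum) walker to bin nBins (first index wins ties); all others fall
#' into the linear interior bins.
#'
#' @param pcoords numeric pcoord values.
#' @param layout A [mabBins] layout.
#' @return integer bin index per walker.
#' @export
binAssignments <- function(pcoords, layout) {
    n <- layout$nBins
    idx <- 2L + pmin(n - 3L, pmax(0L, findInterval(
        pcoords, layout$boundaries, rightmost.closed = TRUE) - 1L))
    idx[which.min(pcoords)] <- 1L
    idx[which.max(pcoords)] <- n
    idx
}

## split walker weights proportionally: walker i receives c_i >= 1 copies by
## largest remainder on w_i * m / W; each copy carries w_i / c_i
.splitBin <- function(idx, w, m) {
    k <- length(idx)
    quota <- w * m / sum(w)
    c_i <- pmax(1L, floor(quota))
    while (sum(c_i) < m) {                 # largest remainder, heaviest first
        rem <- quota - c_i
        j <- which(rem == max(rem))[1]
        c_i[j] <- c_i[j] + 1L
    }
    while (sum(c_i) > m) {                 # can overshoot via the floor >= 1
        cand <- which(c_i > 1L)
        j <- cand[which.min((quota - c_i)[cand])]
        c_i[j] <- c_i[j] - 1L
    }
    list(src = rep(idx, c_i), w = rep(w / c_i, c_i))
}

## merge lowest-weight pairs until m walkers remain; survivor drawn with
## probability proportional to weight and absorbs the pair's weight
.mergeBin <- function(idx, w, m) {
    while (length(idx) > m) {
        ord <- order(w, idx)               # ties: lowest walker index first
        a <- ord[1]; b <- ord[2]
        keepA <- stats::runif(1) < w[a] / (w[a] + w[b])
        surv <- if (keepA) a else b
        dead <- if (keepA) b else a
        w[surv] <- w[a] + w[b]
        idx <- idx[-dead]; w <- w[-dead]
    }
    list(src = idx, w = w)
}

#' Split/merge resampling to the per-bin target count
#'
#' Every occupied bin ends with exactly \code{targetPerBin} walkers:
#' under-populated bins split their highest-weight walkers into equal-weight
#' copies (proportional allocation, so one walker of weight w at target m
#' becomes m copies of w/m); over-populated bins iteratively merge their two
#' lowest-weight walkers, the survivor drawn with probability proportional
#' to weight and carrying the summed weight.  Total weight is conserved to
#' machine precision; empty bins are untouched.
#'
#' @param walkers A [WalkerSet].
#' @param layout A [mabBins] layout.
#' @param targetPerBin target walkers per occupied bin.
#' @return resampled [WalkerSet].
#' @export
splitMerge <- function(walkers, layout, targetPerBin) {
    bins <- binAssignments(pcoords(walkers), layout)
    srcAll <- integer(0); wAll <- numeric(0)
    for (b in sort(unique(bins))) {
        idx <- which(bins == b)
        w <- weights(walkers)[idx]
        r <- if (length(idx) < targetPerBin) .splitBin(idx, w, targetPerBin)
             else if (length(idx) > targetPerBin) .mergeBin(idx, w, targetPerBin)
             else list(src = idx, w = w)
        srcAll <- c(srcAll, r$src); wAll <- c(wAll, r$w)
    }
    WalkerSet(states = walkers@states[srcAll],
              pcoords = pcoords(walkers)[srcAll],
              weights = wAll)
}

#' Run a weighted-ensemble simulation
#'
#' Per iteration: propagate every walker for tau steps, recompute progress
#' coordinates, rebuild the adaptive bins, and split/merge to the per-bin
#' target.  Total weight stays 1 throughout and the run is fully
#' reproducible from the config seed (one derived RNG stream per iteration
#' covering both propagation noise and merge decisions).
#'
#' @param propagator function(states, nSteps) -> states; must be
#'   deterministic given the RNG state. \code{states} is the WalkerSet's
#'   state list.
#' @param pcoordFn function(states) -> numeric pcoords.
#' @param config A [weConfig].
#' @param init initial [WalkerSet] (weights are renormalized to 1).
#' @return list with \code{walkers} (final [WalkerSet]) and \code{history}
#'   (data.frame: iteration, walker, pcoord, weight).
#' @export
runWE <- function(propagator, pcoordFn, config, init) {
    walkers <- WalkerSet(init@states, init@pcoords,
                         init@weights / sum(init@weights))
    hist <- vector("list", config$nIterations)
    for (it in seq_len(config$nIterations)) {
        withSeed(config$seed * 1000003 + it, {
            states <- tryCatch(propagator(walkers@states, config$tauSteps),
                               error = function(e)
                                   stop("runWE: propagator failed at iteration ",
                                        it, ": ", conditionMessage(e),
                                        call. = FALSE))
            pc <- pcoordFn(states)
            walkers <- WalkerSet(states, pc, weights(walkers))
            layout <- mabBins(pc, config$nBins)
            walkers <- splitMerge(walkers, layout, config$targetPerBin)
        })
        stopifnot(abs(sum(weights(walkers)) - 1) < 1e-12)
        hist[[it]] <- data.frame(iteration = it,
                                 walker = seq_along(weights(walkers)),
                                 pcoord = pcoords(walkers),
                                 weight = weights(walkers))
    }
    list(walkers = walkers, history = do.call(rbind, hist))
}

#' Double-well potential energy
#'
#' U(x) = h ((x/w)^2 - 1)^2: minima at +/- w, barrier height h at x = 0.
#' @param x position(s).
#' @param h barrier height (energy units of kT when kT = 1).
#' @param w half-separation of the wells.
#' @return potential energy at x.
#' @export
doubleWellPotential <- function(x, h = 4, w = 1) h * ((x / w)^2 - 1)^2

#' Overdamped Langevin propagator on the double well
#'
#' Euler-Maruyama steps x <- x - U'(x) dt + sqrt(2 kT dt) N(0,1) with unit
#' mobility; vectorized over walkers.  With kT = 0 a minimum of the
#' potential is a fixed point.  Consumes \code{nSteps * length(x)} normal
#' deviates from the current RNG stream, so trajectories are bit-identical
#' under a fixed seed.
#'
#' @param x numeric start position(s).
#' @param nSteps number of steps (>= 1).
#' @param dt time step (> 0).
#' @param kT thermal energy (>= 0).
#' @param h,w potential parameters, see [doubleWellPotential].
#' @return numeric end position(s).
#' @export
doubleWellPropagator <- function(x, nSteps, dt = 0.005, kT = 1, h = 4, w = 1) {
    if (dt <= 0) stop("doubleWellPropagator: dt must be positive")
    stopifnot(all(is.finite(x)), nSteps >= 1)
    sig <- sqrt(2 * kT * dt)
    for (s in seq_len(nSteps)) {
        grad <- 4 * h * x * ((x / w)^2 - 1) / w^2
        x <- x - grad * dt + if (kT > 0) sig * stats::rnorm(length(x)) else 0
    }
    x
}

#' Boltzmann probability of the positive well by quadrature
#'
#' Numerically integrates exp(-U/kT) to give the equilibrium probability of
#' x > 0 for the double well; the independent oracle for WE stationary
#' estimates.
#' @param h,w potential parameters.
#' @param kT thermal energy (> 0).
#' @return probability in [0, 1].
#' @export
doubleWellBoltzmannRight <- function(h = 4, w = 1, kT = 1) {
    f <- function(x) exp(-doubleWellPotential(x, h, w) / kT)
    lim <- w * 6
    right <- stats::integrate(f, 0, lim, rel.tol = 1e-10)$value
    total <- stats::integrate(f, -lim, lim, rel.tol = 1e-10)$value
    right / total
}

#' Write a WE history table as TSV
#' @param history history data.frame from [runWE].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWEHistory <- function(history, path) {
    utils::write.table(history, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
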