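#' @include synthworm.R
NULL

.alignerRegistry <- new.env(parent = emptyenv())

#' Register or list alignment methods
#'
#' Alignment methods are registered by name so the benchmark harness can
#' sweep over them. A method is a function \code{(unlabeled, atlas, cfg,
#' ...)} returning a list with at least a \code{cloud} element (the
#' transformed unlabeled cloud). External baselines (e.g. a coherent
#' point drift wrapper) can be plugged in the same way.
#'
#' @param name method name.
#' @param fun the aligner function.
#' @param nativeColors TRUE when the method exploits color labels
#'   itself; methods without native color support are run once per color
#'   class in the color-sweep scenario.
#' @return \code{registerAligner}: invisibly, \code{name};
#'   \code{listAligners}: character vector of registered names.
#' @export
registerAligner <- function(name, fun, nativeColors = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, list(fun = fun, nativeColors = nativeColors),
         envir = .alignerRegistry)
  invisible(name)
}

#' @rdname registerAligner
#' @export
listAligners <- function() sort(ls(.alignerRegistry))

.getAligner <- function(name) {
  if (!exists(name, envir = .alignerRegistry, inherits = FALSE))
    stop("unknown method '", name, "'; registered: ",
         paste(listAligners(), collapse = ", "))
  get(name, envir = .alignerRegistry, inherits = FALSE)
}

#' Identification accuracy of an assignment
#'
#' Fraction of unlabeled neurons assigned their true name; unmatched
#' neurons count as wrong.
#'
#' @param assignment an [Assignment-class].
#' @param truth character vector of true names, one per unlabeled neuron
#'   (positional: \code{truth[i]} is the true identity of unlabeled
#'   index i).
#' @return fraction in [0, 1].
#' @export
accuracy <- function(assignment, truth) {
  stopifnot(is(assignment, "Assignment"))
  n <- length(assignment@index) + length(assignment@unmatched)
  if (n == 0L) stop("empty assignment")
  if (length(truth) < max(c(assignment@index, assignment@unmatched, 0L)))
    stop("truth must cover all assessed neurons")
  sum(assignment@name == truth[assignment@index]) / n
}

#' ExperimentSpec: an accuracy-versus-perturbation study
#'
#' @slot scenario one of "cropping", "dropout", "bionoise",
#'   "color_sweep".
#' @slot sweep numeric vector of perturbation settings (cropping: atlas
#'   crop thresholds in um; dropout: neurons removed; bionoise:
#'   influence radius sigma in um; color_sweep: number of colors).
#' @slot nReps replicates per setting (default 40).
#' @slot methods registered aligner names.
#' @slot seed base seed; replicate r at any setting uses seed + r - 1.
#' @slot substrate the ground-truth labeled cloud.
#' @slot maxShift rigid-jitter bound applied to the atlas copy, um.
#' @slot nCenters deformation centers for the realistic aligner.
#' @seealso [experimentSpec()], [runExperiment()]
#' @export
setClass("ExperimentSpec",
  representation(scenario = "character", sweep = "numeric",
                 nReps = "integer", methods = "character",
                 seed = "integer", substrate = "NeuronPointCloud",
                 maxShift = "numeric", nCenters = "integer"))

setValidity("ExperimentSpec", function(object) {
  msgs <- character(0)
  if (!object@scenario %in% c("cropping", "dropout", "bionoise",
                              "color_sweep"))
    msgs <- c(msgs, "unknown scenario")
  if (!length(object@sweep)) msgs <- c(msgs, "sweep must be non-empty")
  if (object@nReps < 1L) msgs <- c(msgs, "nReps must be >= 1")
  if (!length(object@methods)) msgs <- c(msgs, "no methods given")
  if (!length(neuronIds(object@substrate)))
    msgs <- c(msgs, "substrate must be labeled")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ExperimentSpec-class
#' @param scenario,sweep,nReps,methods,seed,substrate,maxShift,nCenters
#'   see the class slots
#' @export
experimentSpec <- function(scenario, sweep, substrate, nReps = 40L,
                           methods = "gm-realistic", seed = 0L,
                           maxShift = 5, nCenters = 100L) {
  new("ExperimentSpec", scenario = scenario, sweep = as.numeric(sweep),
      nReps = as.integer(nReps), methods = methods,
      seed = as.integer(seed), substrate = substrate,
      maxShift = as.numeric(maxShift), nCenters = as.integer(nCenters))
}

## isotropically rescale + shift a cloud so its x-range becomes target
.rescaleX <- function(cloud, target) {
  P <- coords(cloud)
  rng <- range(P[, 1])
  sc <- (target[2] - target[1]) / diff(rng)
  .withCoords(cloud, cbind(
    (P[, 1] - rng[1]) * sc + target[1], P[, 2] * sc, P[, 3] * sc))
}

## one (scenario, sweep value, rep) cell: returns per-method accuracies
.runCell <- function(spec, sweepValue, rep, cfg) {
  seed <- spec@seed + rep - 1L
  sub <- spec@substrate
  colorSplit <- NULL
  if (spec@scenario == "cropping") {
    sub <- .rescaleX(sub, c(-600, 200))
    unlab <- cropCloud(sub, "x", lo = 0)
    atlasCloud <- cropCloud(sub, "x", lo = sweepValue)
    atlasCloud <- rigidJitter(atlasCloud, spec@maxShift, seed)$cloud
  } else if (spec@scenario == "dropout") {
    unlab <- dropoutNeurons(sub, as.integer(sweepValue), seed)$cloud
    atlasCloud <- rigidJitter(sub, spec@maxShift, seed)$cloud
  } else if (spec@scenario == "bionoise") {
    bn <- bioNoise(sub, bioNoiseSpec(sigma = sweepValue, seed = seed))
    unlab <- bn$cloud
    atlasCloud <- rigidJitter(sub, spec@maxShift, seed)$cloud
  } else { # color_sweep
    atlasCloud <- rigidJitter(sub, spec@maxShift, seed)$cloud
    k <- as.integer(sweepValue)
    rc <- assignRandomColors(sub, atlasCloud, k, seed,
                             unique = k >= nNeurons(sub))
    unlab <- rc$cloudA
    atlasCloud <- rc$cloudB
  }
  truth <- neuronIds(unlab)
  ## identities and colors of the moving cloud are hidden from aligners
  hidden <- pointCloud(coords(unlab),
                       colors = if (length(unlab@colors)) unlab@colors
                                else NULL)
  vapply(spec@methods, function(mname) {
    m <- .getAligner(mname)
    if (length(hidden@colors) && !m$nativeColors) {
      ## per-color alignment for color-blind baselines
      res <- integer(0)
      correct <- 0
      for (cc in unique(hidden@colors)) {
        ju <- which(hidden@colors == cc)
        ja <- which(neuronColors(atlasCloud) == cc)
        if (!length(ja)) next
        fit <- m$fun(hidden[ju], atlasCloud[ja], cfg,
                     nCenters = spec@nCenters)
        asn <- assignIds(fit$cloud, atlasCloud[ja])
        correct <- correct + sum(asn@name == truth[ju][asn@index])
      }
      correct / nNeurons(hidden)
    } else {
      fit <- m$fun(hidden, atlasCloud, cfg, nCenters = spec@nCenters)
      accuracy(assignIds(fit$cloud, atlasCloud), truth)
    }
  }, numeric(1))
}

#' Run an accuracy-versus-perturbation experiment
#'
#' For every sweep value and replicate: perturb a copy of the substrate
#' cloud according to the scenario (cropping: head cloud vs atlas
#' cropped at the threshold; dropout: remove n neurons; bionoise: apply
#' a random Gaussian-mixture deformation at the swept influence radius;
#' color_sweep: assign k random colors to both clouds), rigid-jitter the
#' atlas copy, align with each registered method, assign identities, and
#' score accuracy against the hidden true names. Accuracies are averaged
#' over replicates.
#'
#' @param spec an [ExperimentSpec-class].
#' @param cfg a [GMConfig-class] passed to the aligners.
#' @return data.frame with columns \code{method}, \code{sweep_value},
#'   \code{mean_accuracy}, \code{stderr}, \code{n_reps}.
#' @export
runExperiment <- function(spec, cfg = gmConfig()) {
  validObject(spec)
  for (m in spec@methods) .getAligner(m)
  rows <- list()
  for (sv in spec@sweep) {
    acc <- vapply(seq_len(spec@nReps),
                  function(r) .runCell(spec, sv, r, cfg),
                  numeric(length(spec@methods)))
    acc <- matrix(acc, nrow = length(spec@methods))
    for (mi in seq_along(spec@methods)) {
      a <- acc[mi, ]
      rows[[length(rows) + 1L]] <- data.frame(
        method = spec@methods[mi], sweep_value = sv,
        mean_accuracy = mean(a),
        stderr = stats::sd(a) / sqrt(length(a)),
        n_reps = length(a), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Random-plus-local hyperparameter search
#'
#' Draws \code{budget} random points uniformly from the box
#' \code{space}, then refines the best draw by coordinate-wise local
#' search: each parameter is probed one step up and down, the step
#' halving whenever no move improves, until every step falls below
#' 1/1024 of its parameter range.
#'
#' @param objective function taking a named numeric vector, returning a
#'   scalar score.
#' @param space named list of c(lo, hi) bounds per parameter.
#' @param budget number of random draws (>= 1).
#' @param seed integer seed.
#' @param maximize maximize (default) or minimize the objective.
#' @return list with \code{best} (named parameter vector), \code{value}
#'   and \code{trace} (data.frame of evaluations).
#' @export
tuneHyperparameters <- function(objective, space, budget, seed = 0L,
                                maximize = TRUE) {
  if (budget < 1L) stop("budget must be >= 1")
  stopifnot(length(space) >= 1L, !is.null(names(space)))
  lo <- vapply(space, `[`, numeric(1), 1)
  hi <- vapply(space, `[`, numeric(1), 2)
  stopifnot(all(hi > lo))
  sgn <- if (maximize) 1 else -1
  draws <- withr::with_seed(seed,
    matrix(stats::runif(budget * length(space)), budget))
  evals <- list()
  score <- function(x) {
    v <- objective(x)
    evals[[length(evals) + 1L]] <<- c(x, score = v)
    sgn * v
  }
  best <- NULL; bestVal <- -Inf
  for (b in seq_len(budget)) {
    x <- lo + draws[b, ] * (hi - lo)
    names(x) <- names(space)
    v <- score(x)
    if (v > bestVal) { bestVal <- v; best <- x }
  }
  step <- (hi - lo) / 4
  while (any(step >= (hi - lo) / 1024)) {
    improved <- FALSE
    for (p in seq_along(space)) {
      for (dir in c(-1, 1)) {
        cand <- best
        cand[p] <- min(hi[p], max(lo[p], best[p] + dir * step[p]))
        if (cand[p] == best[p]) next
        v <- score(cand)
        if (v > bestVal) { bestVal <- v; best <- cand; improved <- TRUE }
      }
    }
    if (!improved) step <- step / 2
  }
  trace <- as.data.frame(do.call(rbind, evals))
  list(best = best, value = sgn * bestVal, trace = trace)
}
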