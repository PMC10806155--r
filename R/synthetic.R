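#' @include AllClasses.R
NULL

#' Scenario configuration for the synthetic multi-source generator
#'
#' Describes a simulated multi-instrument study: per-class sample counts,
#' per-source feature counts, class-template separation, and within-class
#' noise. Defaults emulate a four-class herbal-authentication design: classes
#' BS/GE/PO/BOS with 45/30/30/29 batches and four sources of 10 (electronic
#' nose), 85 (electronic eye), 8 (electronic tongue) and 20 (HPLC peak areas)
#' features.
#'
#' Scenarios:
#' \describe{
#'   \item{strong}{every class pair is separated in every source.}
#'   \item{complementary}{each source collapses one designated class pair
#'     (their templates coincide on that source's coordinates only), while the
#'     union of sources separates all pairs — fusion is demonstrably needed.}
#'   \item{confusable}{the BS and BOS templates sit at
#'     \code{confusableDistance} in every source.}
#' }
#'
#' @param classSizes named integer vector of per-class sample counts, all
#'   >= 2; names define the class set order.
#' @param sourceDims named integer vector of per-source feature counts.
#' @param separation per-source Euclidean distance between the closest pair of
#'   class templates, in response units. Scalar or per-source vector; default
#'   \code{2.5 * sqrt(sourceDims)} so each coordinate carries on average about
#'   2.5 noise standard deviations of signal.
#' @param confusableDistance BS-to-BOS template distance in the
#'   \code{"confusable"} scenario (>= 0).
#' @param noiseSd within-class standard deviation of the isotropic Gaussian
#'   noise (>= 0).
#' @param seed integer RNG seed; identical seeds give bit-identical datasets.
#' @param scenario one of \code{"strong"}, \code{"complementary"},
#'   \code{"confusable"}.
#' @return A validated list of class \code{"ScenarioConfig"}.
#' @seealso [generateDataset()]
#' @export
scenarioConfig <- function(
    classSizes = c(BS = 45L, GE = 30L, PO = 30L, BOS = 29L),
    sourceDims = c(EN = 10L, EE = 85L, ET = 8L, HPLC = 20L),
    separation = NULL,
    confusableDistance = 1.5,
    noiseSd = 1,
    seed = 1L,
    scenario = c("strong", "complementary", "confusable")) {
  scenario <- match.arg(scenario)
  if (is.null(names(classSizes)) || is.null(names(sourceDims)))
    stop("classSizes and sourceDims must be named", call. = FALSE)
  classSizes <- stats::setNames(as.integer(classSizes), names(classSizes))
  sourceDims <- stats::setNames(as.integer(sourceDims), names(sourceDims))
  if (any(classSizes < 1L))
    stop("zero samples in a class", call. = FALSE)
  if (any(classSizes < 2L))
    stop("all class sizes must be >= 2", call. = FALSE)
  if (noiseSd < 0) stop("negative noiseSd", call. = FALSE)
  if (confusableDistance < 0)
    stop("confusableDistance must be >= 0", call. = FALSE)
  if (is.null(separation)) separation <- 2.5 * sqrt(sourceDims)
  if (length(separation) == 1L)
    separation <- stats::setNames(rep(separation, length(sourceDims)),
      names(sourceDims))
  structure(list(classSizes = classSizes, sourceDims = sourceDims,
    separation = separation, confusableDistance = confusableDistance,
    noiseSd = noiseSd, seed = as.integer(seed), scenario = scenario),
    class = "ScenarioConfig")
}

# class pair collapsed by source s in the complementary scenario
.collapsedPair <- function(sourceIndex, nClasses) {
  pairs <- utils::combn(nClasses, 2L)
  pairs[, ((sourceIndex - 1L) %% ncol(pairs)) + 1L]
}

# draw class templates for every source; one draw per (seed, scenario)
.drawTemplates <- function(config) {
  K <- length(config$classSizes)
  cls <- names(config$classSizes)
  templates <- vector("list", length(config$sourceDims))
  names(templates) <- names(config$sourceDims)
  for (s in seq_along(config$sourceDims)) {
    p <- config$sourceDims[[s]]
    tpl <- matrix(stats::runif(K * p, -1, 1), nrow = K,
      dimnames = list(cls, NULL))
    d <- as.matrix(stats::dist(tpl))
    dmin <- min(d[upper.tri(d)])
    tpl <- tpl * (config$separation[[s]] / dmin)
    if (config$scenario == "confusable" && all(c("BS", "BOS") %in% cls)) {
      dir <- tpl["BOS", ] - tpl["BS", ]
      dir <- dir / sqrt(sum(dir^2))
      tpl["BOS", ] <- tpl["BS", ] + config$confusableDistance * dir
    }
    if (config$scenario == "complementary") {
      pr <- .collapsedPair(s, K)
      tpl[pr[2L], ] <- tpl[pr[1L], ]
    }
    templates[[s]] <- tpl
  }
  templates
}

#' Generate a synthetic multi-source dataset
#'
#' For each source, each class has a fixed template vector (drawn once per
#' seed and scenario from a uniform range, then rescaled so the closest
#' template pair sits at the requested separation); samples are
#' template + independent isotropic Gaussian noise. Identical seeds give
#' bit-identical datasets. Sample IDs are \code{S1...Sn} in class-block order.
#'
#' @param config a \code{ScenarioConfig} from [scenarioConfig()].
#' @return A \linkS4class{MultiSourceDataset}. The per-source template
#'   matrices are attached as \code{attr(x, "templates")} and the generating
#'   config as \code{attr(x, "scenarioConfig")}.
#' @examples
#' ds <- generateDataset(scenarioConfig(seed = 7))
#' ds
#' @export
generateDataset <- function(config) {
  if (!inherits(config, "ScenarioConfig"))
    config <- do.call(scenarioConfig, config)
  set.seed(config$seed)
  templates <- .drawTemplates(config)
  n <- sum(config$classSizes)
  ids <- paste0("S", seq_len(n))
  labels <- rep(names(config$classSizes), times = config$classSizes)
  blockList <- vector("list", length(config$sourceDims))
  for (s in seq_along(config$sourceDims)) {
    p <- config$sourceDims[[s]]
    src <- names(config$sourceDims)[s]
    mu <- templates[[s]][labels, , drop = FALSE]
    noise <- matrix(stats::rnorm(n * p, 0, config$noiseSd), n, p)
    v <- mu + noise
    dimnames(v) <- list(ids, paste0(src, "_f", seq_len(p)))
    blockList[[s]] <- SourceBlock(v, src)
  }
  ds <- MultiSourceDataset(blockList,
    structure(labels, names = ids))
  attr(ds, "templates") <- templates
  attr(ds, "scenarioConfig") <- config
  ds
}
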