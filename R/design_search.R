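#' @include AllClasses.R AllGenerics.R culture.R
NULL

# run code with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample candidate scaffold designs
#'
#' Draws `n` designs with one displacement per fiber pair (indicator points
#' on the same face share a displacement), each drawn independently and
#' uniformly from `rangeUm`. Reproducible for a fixed seed; the caller's
#' RNG state is untouched.
#'
#' @param n number of candidates (>= 1).
#' @param seed integer RNG seed.
#' @param rangeUm sampling interval (um), within `(0, r]`.
#' @param r half-edge of the imaginary cube (um).
#' @param culturedSurfaces cultured faces of every candidate.
#' @return list of [UnitDesign-class] objects.
#' @export
sampleCandidates <- function(n, seed, rangeUm = c(0, 100), r = 100,
                             culturedSurfaces = "bottom") {
  stopifnot(n >= 1)
  if (length(rangeUm) != 2 || rangeUm[2] <= rangeUm[1])
    stop("rangeUm must be an increasing interval")
  if (rangeUm[1] < 0 || rangeUm[2] > r)
    stop("rangeUm must lie within (0, r]")
  .withSeed(as.integer(seed), {
    dy <- runif(n, rangeUm[1], rangeUm[2])
    dz <- runif(n, rangeUm[1], rangeUm[2])
    lapply(seq_len(n), function(i)
      unitDesign(dy[i], dz[i], r = r, culturedSurfaces = culturedSurfaces))
  })
}

#' Run a generate-and-test design campaign
#'
#' Evaluates every candidate design by its culture efficiency and ranks
#' them. Failed candidates are recorded and excluded from the ranking; ties
#' in CE are broken by larger attachment area, then lower candidate index.
#' A custom `evaluator(design)` returning a CE (or a
#' [CultureResult-class]) may replace the full simulation, e.g. for
#' verification with a known objective.
#'
#' @param n number of candidates (ignored when `candidates` given).
#' @param seed campaign seed.
#' @param oc an [OperatingConditions-class] shared by all candidates.
#' @param p a [KineticParams-class].
#' @param candidates optional list of [UnitDesign-class] (overrides
#'   sampling).
#' @param rangeUm sampling interval (um).
#' @param resolution voxels per edge used for candidate evaluation.
#' @param control solver settings per candidate.
#' @param evaluator optional function(design) -> numeric CE or
#'   CultureResult.
#' @param culturedSurfaces cultured faces of sampled candidates.
#' @return a [DesignCampaign-class].
#' @export
runCampaign <- function(n = 10L, seed = 1L, oc = operatingConditions(),
                        p = kineticParams(), candidates = NULL,
                        rangeUm = c(0, 100), resolution = 16L,
                        control = list(), evaluator = NULL,
                        culturedSurfaces = "bottom") {
  if (is.null(candidates))
    candidates <- sampleCandidates(n, seed, rangeUm = rangeUm,
                                   culturedSurfaces = culturedSurfaces)
  n <- length(candidates)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- candidates[[i]]
    D1 <- primaryDiameter(d)
    D2 <- secondaryDiameter(d)
    ratio <- if (d@deltaZ > 0) abs(d@deltaY / d@deltaZ) else Inf
    area <- .designAttachmentArea(d)
    ceVal <- NA_real_
    meanShear <- NA_real_
    status <- "ok"
    res <- tryCatch({
      if (is.null(evaluator))
        runCulture(d, oc, p, resolution = resolution, control = control)
      else evaluator(d)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status <- conditionMessage(res)
    } else if (is(res, "CultureResult")) {
      ceVal <- res@ce
      meanShear <- res@metrics$meanShearBiomass
    } else {
      ceVal <- as.numeric(res)
    }
    rows[[i]] <- data.frame(candidate = i, deltaY = d@deltaY,
                            deltaZ = d@deltaZ, D1 = D1, D2 = D2,
                            ratio = ratio, ce = ceVal,
                            attachmentArea = area, meanShear = meanShear,
                            status = status, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  done <- which(results$status == "ok" & !is.na(results$ce))
  if (!length(done)) stop("design campaign failed: no candidate completed")
  ord <- done[order(-results$ce[done], -results$attachmentArea[done],
                    results$candidate[done])]
  best <- ord[1]
  new("DesignCampaign", nCandidates = as.integer(n),
      seed = as.integer(seed), deltaRange = as.numeric(rangeUm),
      results = results, candidates = candidates, best = as.integer(best))
}

#' Culture efficiency against the displacement ratio
#'
#' Bins the campaign's CE values against `|deltaY/deltaZ|` and flags the
#' favourable band (ratio in [0, 1]) and the risk band (ratio > 5.5) in
#' which negative culture efficiencies concentrate. Candidates with
#' `deltaZ = 0` (flat secondary walls) fall in an infinite-ratio band.
#'
#' @param campaign a [DesignCampaign-class].
#' @param breaks bin edges for the ratio (default `c(0, 1, 2, 3, 4, 5.5,
#'   Inf)`).
#' @return data.frame with one row per non-empty bin: ratio interval, n,
#'   mean/min/max CE, and a `band` flag ("favourable", "risk" or "").
#' @export
ratioReport <- function(campaign, breaks = c(0, 1, 2, 3, 4, 5.5, Inf)) {
  res <- campaign@results
  res <- res[res$status == "ok" & !is.na(res$ce), , drop = FALSE]
  if (!nrow(res)) stop("campaign has no completed candidates")
  finite <- is.finite(res$ratio)
  bins <- rep(NA_character_, nrow(res))
  if (any(finite))
    bins[finite] <- as.character(cut(res$ratio[finite], breaks,
                                     include.lowest = TRUE, right = TRUE))
  bins[!finite] <- "infinite (flat secondary wall)"
  agg <- lapply(split(seq_len(nrow(res)), bins), function(ii) {
    data.frame(bin = bins[ii[1]], n = length(ii),
               meanCE = mean(res$ce[ii]), minCE = min(res$ce[ii]),
               maxCE = max(res$ce[ii]),
               meanRatio = mean(res$ratio[ii]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, agg)
  tab <- tab[order(tab$meanRatio), , drop = FALSE]
  tab$band <- ifelse(is.finite(tab$meanRatio) & tab$meanRatio <= 1,
                     "favourable",
                     ifelse(tab$meanRatio > 5.5, "risk", ""))
  rownames(tab) <- NULL
  tab
}
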