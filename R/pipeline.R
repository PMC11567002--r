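# End-to-end orchestration: movie -> events -> sites -> geometry ->
# statistics, trace -> retrieval kinetics, group comparisons, and
# reporting.

#' Summarize release mapping from an assigned event table
#'
#' Takes localized events already assigned to synapses and computes, per
#' synapse: release probability, release-site partition, AZ geometry and
#' distance statistics. This is the analysis core shared by
#' [runReleaseMapping()] (movie input) and simulation studies (event
#' input).
#'
#' @param events data.frame with columns `synapse_id`, `frame`, `x_nm`,
#'   `y_nm`.
#' @param protocol the [StimulusProtocol-class] used for stimulation.
#' @param clusteringDiameterNm release-site clustering diameter (nm).
#' @param binWidthNm histogram bin width for distance distributions.
#'
#' @return list with `summary` (one row per synapse: `synapse_id`,
#'   `n_events`, `pr`, `n_sites`, `az_area_nm2`, `degenerate`,
#'   `mean_dist_center_nm`, `mean_consec_nm`), `sites` (list of
#'   [ReleaseSiteSet-class]), `geometries` (list of
#'   [AZGeometry-class]), and pooled `distCenter` / `distConsecutive`
#'   event-level distances.
#' @export
mapReleaseSites <- function(events, protocol, clusteringDiameterNm = 50,
                            binWidthNm = 10) {
  stopifnot(is.data.frame(events),
            all(c("synapse_id", "frame", "x_nm", "y_nm") %in% names(events)),
            is(protocol, "StimulusProtocol"))
  ids <- unique(events$synapse_id)
  sites <- list(); geoms <- list()
  rows <- vector("list", length(ids))
  dCenter <- list(); dConsec <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    ev <- events[events$synapse_id == id, , drop = FALSE]
    pos <- cbind(ev$x_nm, ev$y_nm)
    rs <- clusterEvents(pos, clusteringDiameterNm, synapseId = id)
    g <- azHull(pos, synapseId = id)
    dc <- distancesToCenter(pos, g, binWidthNm)$distances
    cc <- if (nrow(ev) >= 2L)
      consecutiveEventDistances(ev, binWidthNm)$distances else numeric(0)
    sites[[id]] <- rs; geoms[[id]] <- g
    dCenter[[id]] <- dc; dConsec[[id]] <- cc
    rows[[i]] <- data.frame(
      synapse_id = id,
      n_events = nrow(ev),
      pr = as.numeric(releaseProbability(nrow(ev), protocol)),
      n_sites = nSites(rs),
      az_area_nm2 = azArea(g),
      degenerate = isDegenerate(g),
      mean_dist_center_nm = mean(dc),
      mean_consec_nm = if (length(cc)) mean(cc) else NA_real_
    )
  }
  list(summary = do.call(rbind, rows), sites = sites, geometries = geoms,
       distCenter = unlist(dCenter, use.names = FALSE),
       distConsecutive = unlist(dConsec, use.names = FALSE))
}

#' Run the full release-mapping pipeline on movies
#'
#' For each movie: candidate detection, mixture-model localization,
#' cross-frame merging, ROI assignment, then per-synapse release-site
#' clustering, AZ geometry and distance statistics via
#' [mapReleaseSites()]. The run is deterministic for a given
#' configuration; a manifest hash of the configuration is recorded in
#' the report, together with per-stage counts.
#'
#' @param movies named list of [Movie-class] objects (names are
#'   field-of-view ids).
#' @param rois a [RoiSet-class], or a named list of them parallel to
#'   `movies`.
#' @param protocol the [StimulusProtocol-class] used for stimulation.
#' @param cfg a [detectionConfig()].
#' @param clusteringDiameterNm release-site clustering diameter (nm).
#' @param groups optional named character vector mapping movie names to
#'   group labels (default: all `"control"`).
#' @param outputDir optional directory; when given, event, site, AZ and
#'   summary CSV tables plus a JSON run manifest are written there.
#'
#' @return list with `summary` (per-synapse table including `group` and
#'   `fov`), `events` (assigned event table), `sites`, `geometries`,
#'   pooled distances by group (`distCenter`, `distConsecutive`), and
#'   `report` (per-stage counts and the manifest hash).
#' @export
runReleaseMapping <- function(movies, rois, protocol,
                              cfg = detectionConfig(),
                              clusteringDiameterNm = 50, groups = NULL,
                              outputDir = NULL) {
  if (is(movies, "Movie")) movies <- list(fov1 = movies)
  stopifnot(length(movies) >= 1L, !is.null(names(movies)))
  if (is(rois, "RoiSet"))
    rois <- stats::setNames(rep(list(rois), length(movies)), names(movies))
  if (is.null(groups))
    groups <- stats::setNames(rep("control", length(movies)), names(movies))

  allEvents <- list(); stage <- list()
  summaries <- list(); sites <- list(); geoms <- list()
  dCenter <- list(); dConsec <- list()
  for (nm in names(movies)) {
    mv <- movies[[nm]]
    cand <- detectCandidates(mv, cfg)
    fitted <- fitSpots(mv, cand, cfg)
    merged <- mergeEvents(fitted, cfg$mergeGapFrames, cfg$mergeRadiusNm)
    asg <- assignToSynapses(merged, rois[[nm]])
    ev <- asg$assigned
    if (nrow(ev)) {
      ev$synapse_id <- paste(nm, ev$synapse_id, sep = "/")
      ev$fov <- nm
    }
    allEvents[[nm]] <- ev
    stage[[nm]] <- list(
      candidates = nrow(cand), fitted = nrow(fitted),
      discarded = as.list(attr(fitted, "discards")),
      merged = attr(merged, "n_merged"), raw = attr(merged, "n_raw"),
      unassigned = nrow(asg$unassigned)
    )
    if (nrow(ev) == 0L) {
      warning(sprintf("movie '%s': no events assigned to any ROI", nm))
      next
    }
    res <- mapReleaseSites(ev, protocol, clusteringDiameterNm)
    res$summary$group <- unname(groups[nm])
    res$summary$fov <- nm
    summaries[[nm]] <- res$summary
    sites <- c(sites, res$sites)
    geoms <- c(geoms, res$geometries)
    g <- unname(groups[nm])
    dCenter[[g]] <- c(dCenter[[g]], res$distCenter)
    dConsec[[g]] <- c(dConsec[[g]], res$distConsecutive)
  }
  summary <- do.call(rbind, summaries)
  if (is.null(summary))
    summary <- data.frame(synapse_id = character(), n_events = integer(),
                          pr = numeric(), n_sites = integer(),
                          az_area_nm2 = numeric(), degenerate = logical(),
                          mean_dist_center_nm = numeric(),
                          mean_consec_nm = numeric(), group = character(),
                          fov = character())
  rownames(summary) <- NULL
  events <- do.call(rbind, allEvents)
  rownames(events) <- NULL

  manifest <- list(
    clustering_diameter_nm = clusteringDiameterNm,
    detection = unclass(cfg),
    protocol = list(n_pulses = nPulses(protocol),
                    frequency_hz = stimulusFrequency(protocol),
                    frame_interval_s = frameInterval(protocol),
                    n_baseline_frames = nBaselineFrames(protocol)),
    groups = as.list(groups)
  )
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  report <- list(stages = stage, manifestHash = hash,
                 nSynapses = nrow(summary))

  out <- list(summary = summary, events = events, sites = sites,
              geometries = geoms, distCenter = dCenter,
              distConsecutive = dConsec, report = report)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeEventTable(events, file.path(outputDir, "events.csv"))
    if (length(sites)) writeSiteTable(sites, file.path(outputDir, "sites.csv"))
    if (length(geoms)) writeAZTable(geoms, file.path(outputDir, "az.csv"))
    utils::write.csv(summary, file.path(outputDir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(manifest, list(manifest_hash = hash)),
                         file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Simulate a two-condition release-mapping experiment
#'
#' Generates assigned event tables for many synapses directly from
#' ground-truth AZs (no movie rendering), emulating a control condition
#' and an "inhibited" condition in which mitochondrial-pyruvate-uptake
#' block is modeled as halved per-site release rates with peripheral
#' sites (beyond `centralFractionActive` of the AZ radius) silenced.
#'
#' Default scales follow the single-AP mapping regime: ~200 stimuli at
#' 1 Hz, AZ radius 250 nm, 10-14 sites per AZ with per-site per-stimulus
#' release probability around 0.006 (log-normal heterogeneity), and
#' 27 nm localization noise.
#'
#' @param nSynapses number of synapses to simulate.
#' @param protocol a [StimulusProtocol-class].
#' @param seed integer RNG seed.
#' @param condition `"control"` or `"inhibited"`.
#' @param nSitesRange integer(2), uniform range of true sites per AZ.
#' @param azRadiusNm AZ radius (nm).
#' @param meanRate median per-site release probability per stimulus.
#' @param rateSdLog log-normal sd of per-site rates.
#' @param localizationSigmaNm localization noise SD (nm).
#' @param rateScale multiplier applied to all rates under inhibition.
#' @param centralFractionActive under inhibition, sites farther than
#'   this fraction of the AZ radius from the AZ origin are silenced.
#'
#' @return list with `events` (event table with `synapse_id`) and
#'   `groundTruth` (per-synapse [GroundTruthAZ-class] list).
#' @export
simulateReleaseExperiment <- function(nSynapses, protocol, seed,
                                      condition = c("control", "inhibited"),
                                      nSitesRange = c(10L, 14L),
                                      azRadiusNm = 250, meanRate = 0.006,
                                      rateSdLog = 0.4,
                                      localizationSigmaNm = 27,
                                      rateScale = 0.5,
                                      centralFractionActive = 0.5) {
  condition <- match.arg(condition)
  stopifnot(nSynapses >= 1L, is(protocol, "StimulusProtocol"))
  .withSeed(seed, {
    evList <- vector("list", nSynapses)
    gtList <- vector("list", nSynapses)
    for (i in seq_len(nSynapses)) {
      k <- sample(nSitesRange[1]:nSitesRange[2], 1L)
      rates <- pmin(1, stats::rlnorm(k, meanlog = log(meanRate),
                                     sdlog = rateSdLog))
      az <- makeAZ(k, azRadiusNm, rates, seed = NULL,
                   localizationSigmaNm = localizationSigmaNm)
      if (condition == "inhibited") {
        r <- sqrt(rowSums(sitePositions(az)^2))
        rates <- rates * rateScale
        rates[r > centralFractionActive * azRadiusNm] <- 0
        az <- new("GroundTruthAZ", sitePositions = sitePositions(az),
                  siteRates = rates, azRadiusNm = azRadius(az),
                  localizationSigmaNm = localizationSigma(az))
      }
      ev <- sampleEvents(az, protocol, seed = NULL)
      if (nrow(ev)) ev$synapse_id <- sprintf("syn%04d", i)
      evList[[i]] <- ev
      gtList[[i]] <- az
    }
    events <- do.call(rbind, evList)
    list(events = events, groundTruth = gtList)
  })
}

#' Run the retrieval-block analysis on a set of traces
#'
#' Normalizes every trace to dF/F0, fits the endocytic time constant,
#' computes the control-group mean tau from converged control fits, and
#' applies it (as `2*controlTau`) to every group's fractional retrieval
#' block. Non-converged fits are excluded from the control mean and
#' counted.
#'
#' @param traces named list of [Trace-class] objects.
#' @param groups named character vector (same names) of group labels.
#' @param controlGroup the designated control group label.
#' @param anchored see [fitEndocyticTau()].
#' @param reference see [fractionalRetrievalBlock()].
#'
#' @return list with `table` (per-trace `roi_id`, `group`, `tau_s`,
#'   `converged`, `block`), `controlTauS`, and `nNonConverged`.
#' @export
runRetrievalAnalysis <- function(traces, groups, controlGroup = "control",
                                 anchored = TRUE,
                                 reference = c("baseline", "finf")) {
  reference <- match.arg(reference)
  stopifnot(length(traces) >= 1L, !is.null(names(traces)),
            all(names(traces) %in% names(groups)))
  groups <- groups[names(traces)]
  if (!controlGroup %in% groups)
    stop(sprintf("control group '%s' has no traces", controlGroup))
  dffs <- lapply(traces, normalizeDFF)
  fits <- lapply(dffs, fitEndocyticTau, anchored = anchored)
  taus <- vapply(fits, endoTau, numeric(1))
  conv <- vapply(fits, hasConverged, logical(1))
  ctrlTaus <- taus[conv & groups == controlGroup]
  if (!length(ctrlTaus))
    stop("no converged endocytic fits in the control group")
  controlTauS <- mean(ctrlTaus)
  block <- vapply(seq_along(dffs), function(i) {
    tryCatch(fractionalRetrievalBlock(dffs[[i]], controlTauS, reference),
             error = function(e) NA_real_)
  }, numeric(1))
  tab <- data.frame(
    roi_id = names(traces), group = unname(groups),
    tau_s = taus, converged = conv, block = block
  )
  rownames(tab) <- NULL
  list(table = tab, controlTauS = controlTauS,
       nNonConverged = sum(!conv))
}

#' Compare a metric between groups
#'
#' Delegates to standard tests: a two-sample Kolmogorov-Smirnov test for
#' event-level distributions, a Wilcoxon rank-sum test for per-synapse
#' metrics with two groups, and a Kruskal-Wallis rank test for three or
#' more groups. Effect sizes (difference of means and medians for two
#' groups) are reported alongside p-values.
#'
#' @param values numeric metric values.
#' @param groups group label per value (>= 2 groups).
#' @param level `"synapse"` (rank-sum / Kruskal-Wallis) or `"event"`
#'   (Kolmogorov-Smirnov; two groups only).
#'
#' @return data.frame with `test`, `statistic`, `p_value`, `mean_diff`,
#'   `median_diff` (second group minus first, two-group case only).
#' @export
compareGroups <- function(values, groups, level = c("synapse", "event")) {
  level <- match.arg(level)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) >= 2L, length(values) == length(groups))
  lv <- levels(groups)
  if (nlevels(groups) == 2L) {
    a <- values[groups == lv[1]]; b <- values[groups == lv[2]]
    if (level == "event") {
      ht <- suppressWarnings(stats::ks.test(a, b))
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a, b))
    }
    data.frame(test = ht$method, statistic = unname(ht$statistic),
               p_value = ht$p.value, mean_diff = mean(b) - mean(a),
               median_diff = stats::median(b) - stats::median(a))
  } else {
    ht <- stats::kruskal.test(values, groups)
    data.frame(test = ht$method, statistic = unname(ht$statistic),
               p_value = ht$p.value, mean_diff = NA_real_,
               median_diff = NA_real_)
  }
}

#' Grubbs outlier filter
#'
#' Iterative two-sided Grubbs test, removing at most one extreme value
#' per iteration until no value is significant at `alpha`. Intended as
#' an optional pre-test filter; off by default everywhere.
#'
#' @param x numeric vector (n >= 3).
#' @param alpha significance level (default 0.05).
#'
#' @return logical vector, TRUE for values kept; removed indices in the
#'   attribute `"removed"`.
#' @export
grubbsOutliers <- function(x, alpha = 0.05) {
  stopifnot(length(x) >= 3L)
  keep <- rep(TRUE, length(x))
  repeat {
    xi <- x[keep]
    n <- length(xi)
    if (n < 3L) break
    dev <- abs(xi - mean(xi))
    G <- max(dev) / stats::sd(xi)
    tc <- stats::qt(1 - alpha / (2 * n), n - 2)
    Gcrit <- ((n - 1) / sqrt(n)) * sqrt(tc^2 / (n - 2 + tc^2))
    if (!is.finite(G) || G <= Gcrit) break
    worst <- which(keep)[which.max(dev)]
    keep[worst] <- FALSE
  }
  attr(keep, "removed") <- which(!keep)
  keep
}
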