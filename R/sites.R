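# Release-site definition by complete-linkage clustering with a fixed
# clustering diameter, and site-utilization statistics.

#' Cluster event localizations into release sites
#'
#' Complete-linkage agglomerative clustering of 2-d event positions, with
#' the dendrogram cut so that every cluster's maximum intra-cluster
#' pairwise distance is at most `clusteringDiameterNm` (threshold
#' inclusive). With complete linkage the merge height equals the cluster
#' diameter, so cutting by height and bounding the diameter coincide. A
#' single event forms a single cluster of diameter zero.
#'
#' @param positions numeric matrix (nEvents x 2) of positions in nm, or a
#'   data.frame with columns `x_nm`, `y_nm`.
#' @param clusteringDiameterNm the clustering diameter in nm (default 50,
#'   the established value for hippocampal release-site mapping).
#' @param synapseId identifier stored in the result.
#'
#' @return A [ReleaseSiteSet-class].
#' @examples
#' pts <- rbind(c(0, 0), c(30, 0), c(200, 0))
#' clusterEvents(pts, 50)
#' @export
clusterEvents <- function(positions, clusteringDiameterNm = 50,
                          synapseId = "synapse") {
  if (is.data.frame(positions))
    positions <- cbind(positions$x_nm, positions$y_nm)
  stopifnot(is.matrix(positions), ncol(positions) == 2L,
            nrow(positions) >= 1L, clusteringDiameterNm > 0)
  n <- nrow(positions)
  if (n == 1L) {
    assignment <- 1L
  } else {
    hc <- stats::hclust(stats::dist(positions), method = "complete")
    assignment <- unname(stats::cutree(hc, h = clusteringDiameterNm))
  }
  # relabel clusters in order of first appearance for determinism
  first <- match(unique(assignment), assignment)
  relabel <- order(order(first))
  assignment <- relabel[match(assignment, unique(assignment))]
  k <- max(assignment)
  centroids <- t(vapply(seq_len(k), function(i) {
    colMeans(positions[assignment == i, , drop = FALSE])
  }, numeric(2)))
  colnames(centroids) <- c("x", "y")
  diameters <- vapply(seq_len(k), function(i) {
    m <- positions[assignment == i, , drop = FALSE]
    if (nrow(m) < 2L) 0 else max(stats::dist(m))
  }, numeric(1))
  new("ReleaseSiteSet", synapseId = as.character(synapseId),
      positions = positions, assignment = as.integer(assignment),
      centroids = centroids, diametersNm = diameters,
      clusteringDiameterNm = as.numeric(clusteringDiameterNm))
}

#' Per-synapse release-site counts
#'
#' @param sets a list of [ReleaseSiteSet-class] objects.
#'
#' @return list with `perSynapse` (data.frame `synapse_id`, `n_sites`),
#'   `mean` and `sem` of the counts.
#' @export
siteCounts <- function(sets) {
  stopifnot(length(sets) >= 1L)
  df <- data.frame(
    synapse_id = vapply(sets, synapseId, character(1)),
    n_sites = vapply(sets, nSites, integer(1))
  )
  list(perSynapse = df, mean = mean(df$n_sites),
       sem = if (nrow(df) > 1L) .sem(df$n_sites) else NA_real_)
}

#' Distribution of events per release site
#'
#' Histogram of the number of events each release site received, as a
#' fraction of all sites, with its cumulative distribution.
#'
#' @param sets a list of [ReleaseSiteSet-class] objects.
#'
#' @return data.frame with columns `n_events`, `n_sites`, `fraction`,
#'   `cumulative`; the attribute `"per_site"` holds the raw per-site
#'   event counts.
#' @export
eventsPerSite <- function(sets) {
  stopifnot(length(sets) >= 1L)
  counts <- unlist(lapply(sets, function(s) {
    tabulate(siteAssignments(s), nbins = nSites(s))
  }))
  tb <- table(counts)
  df <- data.frame(
    n_events = as.integer(names(tb)),
    n_sites = as.integer(tb)
  )
  df$fraction <- df$n_sites / sum(df$n_sites)
  df$cumulative <- cumsum(df$fraction)
  attr(df, "per_site") <- as.integer(counts)
  df
}
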