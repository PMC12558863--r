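#' Within-cluster sum of squares across a range of k
#'
#' For each candidate number of clusters, runs seeded k-means
#' (Hartigan-Wong, squared Euclidean distance on the 24-dimensional hourly
#' profiles) with `nRestarts` random starts and records the best (minimum)
#' total within-cluster sum of squares. Deterministic given `seed`.
#'
#' @param profiles `n x 24` numeric matrix of hourly profiles.
#' @param kRange Contiguous increasing integer vector of candidate k.
#' @param seed Integer seed.
#' @param nRestarts Random restarts per k (default 10).
#' @param standardize If `TRUE`, z-score each hour column first (off by
#'   default: absolute activity levels are meaningful).
#' @return Named numeric vector, WCSS by k.
#' @seealso [selectK()], [clusterProfiles()]
#' @export
wcssCurve <- function(profiles, kRange = 2:12, seed = 1L, nRestarts = 10L,
                      standardize = FALSE) {
  profiles <- as.matrix(profiles)
  stopIfNot(nrow(profiles) >= max(kRange),
            "need at least max(kRange) = %d profiles, got %d",
            max(kRange), nrow(profiles))
  if (standardize) profiles <- scale(profiles)
  wcss <- vapply(kRange, function(k) {
    bestKmeans(profiles, k, seed, nRestarts)$tot.withinss
  }, numeric(1))
  stats::setNames(wcss, kRange)
}

# Seeded best-of-restarts k-means; retries with fresh starts if an empty
# cluster makes a run fail, errors if that persists.
bestKmeans <- function(x, k, seed, nRestarts, maxAttempts = 5L) {
  # Hartigan-Wong needs k < n; at k == n every point is its own cluster
  algo <- if (k >= nrow(x)) "Lloyd" else "Hartigan-Wong"
  for (attempt in seq_len(maxAttempts)) {
    set.seed(as.integer(seed) + as.integer(k) + (attempt - 1L) * 100003L)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = as.integer(k),
                                     nstart = nRestarts, iter.max = 100L,
                                     algorithm = algo)),
      error = function(e) e)
    if (!inherits(km, "error")) return(km)
  }
  stop(sprintf("k-means failed for k = %d: %s", k, conditionMessage(km)),
       call. = FALSE)
}

#' Select the number of clusters from the WCSS curve
#'
#' Implements curvature-based selection: the number of clusters is the value
#' of k just before the second derivative of the WCSS curve reaches its
#' minimum, i.e. just before the curve becomes flat and additional clusters
#' yield diminishing returns. Curvature is measured by the centered second
#' difference `W(k-1) - 2 W(k) + W(k+1)`; because past the true structure
#' the second difference hovers around zero with optimization noise, "reaches
#' its minimum" is read as reaching the curvature floor: the first k whose
#' second difference lies within `plateauTol` of the curvature range above
#' the observed minimum. The selected k is that k minus one, clipped into
#' the explored range; ties break toward smaller k.
#'
#' @param wcssByK Named numeric vector from [wcssCurve()] (names are k).
#' @param plateauTol Relative tolerance defining the curvature floor
#'   (default 0.05 of the curvature range).
#' @return Selected k (integer).
#' @examples
#' selectK(setNames(c(100, 40, 12, 10, 9, 8.5), 1:6))  # 3
#' @export
selectK <- function(wcssByK, plateauTol = 0.05) {
  ks <- as.integer(names(wcssByK))
  stopIfNot(length(ks) >= 4L && !anyNA(ks),
            "wcssByK needs at least 4 named points")
  stopIfNot(all(diff(ks) == 1L), "kRange must be contiguous")
  w <- as.numeric(wcssByK)
  m <- length(w)
  d2 <- w[1:(m - 2L)] - 2 * w[2:(m - 1L)] + w[3:m]   # curvature at ks[2..m-1]
  kAt <- ks[2:(m - 1L)]
  span <- max(d2) - min(d2)
  thr <- min(d2) + plateauTol * span
  kFlat <- kAt[which(d2 <= thr)[1L]]
  as.integer(max(min(ks), min(max(ks), kFlat - 1L)))
}

#' Cluster hourly profiles with k-means
#'
#' Standard k-means on the raw (unstandardized by default) 24-hour profiles,
#' best of `nRestarts` seeded random starts. Each returned center is the
#' mean of its member profiles. When `k` is `NULL`, the WCSS curve over
#' `kRange` is computed and k chosen by [selectK()].
#'
#' @param profiles `n x 24` numeric matrix with row names = subject ids.
#' @param k Number of clusters, or `NULL` to select automatically.
#' @param seed Integer seed.
#' @param nRestarts Random restarts (default 10).
#' @param kRange Candidate k values used when `k` is `NULL`.
#' @param standardize Z-score hour columns before clustering (default off).
#' @return A [ClusteringResult-class].
#' @export
clusterProfiles <- function(profiles, k = NULL, seed = 1L, nRestarts = 10L,
                            kRange = 2:12, standardize = FALSE) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("subject_%d", seq_len(nrow(profiles)))
  wcssByK <- stats::setNames(numeric(0), character(0))
  if (is.null(k)) {
    kRange <- kRange[kRange <= nrow(profiles)]
    wcssByK <- wcssCurve(profiles, kRange, seed, nRestarts, standardize)
    k <- selectK(wcssByK)
  }
  stopIfNot(nrow(profiles) >= k, "need at least k = %d profiles", k)
  x <- if (standardize) scale(profiles) else profiles
  km <- bestKmeans(x, k, seed, nRestarts)
  # centers on the original scale: means of member profiles
  centers <- do.call(rbind, lapply(seq_len(k), function(j)
    colMeans(profiles[km$cluster == j, , drop = FALSE])))
  new("ClusteringResult", k = as.integer(k), centers = centers,
      labels = stats::setNames(as.integer(km$cluster), rownames(profiles)),
      clusterCounts = as.integer(tabulate(km$cluster, k)),
      wcssByK = wcssByK, seed = as.integer(seed))
}
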