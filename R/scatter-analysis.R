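# Bimodality diagnostics for control-strain scatter data: 2-means
# clustering on log-log scatter coordinates, per-cluster vs pooled
# regression, and per-cluster GFP density comparison.

#' Two-means clustering of scatter measurements
#'
#' Clusters events on (log10 FSC_A, log10 SSC_A) with k-means (k = 2,
#' k-means++-style multiple restarts via `nstart`), then relabels the
#' clusters deterministically: cluster 1 is the one whose *center* has the
#' higher SSC_A/FSC_A ratio (equivalently, higher log-SSC minus log-FSC).
#' That cluster is the candidate unhealthy/stationary-phase population.
#' Pearson correlations of log10(SSC_A) on log10(FSC_A) are reported per
#' cluster and pooled: genuinely bimodal scatter shows per-cluster r
#' values clearly above the pooled r, because pooling two offset clouds
#' attenuates the within-cloud linear relationship.
#'
#' A centroid-based (simplified) silhouette score summarizes cluster
#' separation; `bimodal` is `TRUE` when it exceeds `silhouette_min`,
#' preventing a two-cluster claim on unimodal data.
#'
#' @param events tibble with columns `fsc_a`, `ssc_a` (and optionally
#'   `gfp`) in linear a.u.; values at or below 0 are dropped before logs.
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @param silhouette_min separation score above which the two-cluster
#'   structure is considered real. A 2-means split of a *single* bivariate
#'   log-normal cloud scores up to ~0.66 regardless of its elongation (an
#'   artefact of splitting unimodal data), while genuinely separated
#'   clouds score 0.70-0.85; the 0.68 default sits just above the unimodal
#'   ceiling. See the methods vignette for the calibration.
#' @return An object of class `scatter_clusters`: list with `labels`
#'   (per-event 1/2), `centers` (2x2, log10 units, rows in cluster order),
#'   `counts`, `r_cluster1`, `r_cluster2`, `r_pooled`, `silhouette`,
#'   `bimodal`, and `data` (the log10 coordinates with labels and any gfp
#'   carried through).
#' @export
cluster_scatter <- function(events, seed = 1L, nstart = 10L,
                            silhouette_min = 0.68) {
  stopifnot(all(c("fsc_a", "ssc_a") %in% names(events)))
  ok <- events$fsc_a > 0 & events$ssc_a > 0
  ev <- events[ok, , drop = FALSE]
  x <- cbind(lfsc = log10(ev$fsc_a), lssc = log10(ev$ssc_a))
  if (nrow(unique(x)) < 2) {
    abort("need at least 2 distinct scatter coordinates to cluster",
          class = "gatescore_degenerate_error")
  }
  km <- with_seed(seed, stats::kmeans(x, centers = 2L, nstart = nstart,
                                      iter.max = 100L))
  # deterministic naming: cluster 1 = higher SSC/FSC ratio at its center
  ratio <- km$centers[, "lssc"] - km$centers[, "lfsc"]
  ord <- order(ratio, decreasing = TRUE)
  relabel <- match(seq_len(2L), ord)
  labels <- relabel[km$cluster]
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- c("cluster1", "cluster2")

  r_of <- function(idx) {
    if (sum(idx) < 3 || stats::sd(x[idx, 1]) == 0 || stats::sd(x[idx, 2]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[idx, 1], x[idx, 2])
  }
  r1 <- r_of(labels == 1L)
  r2 <- r_of(labels == 2L)
  rp <- r_of(rep(TRUE, nrow(x)))

  sil <- simplified_silhouette(x, labels, centers)
  dat <- tibble(
    log_fsc = x[, 1], log_ssc = x[, 2], cluster = labels,
    gfp = if ("gfp" %in% names(ev)) ev$gfp else NA_real_
  )
  structure(
    list(labels = labels, centers = centers,
         counts = c(cluster1 = sum(labels == 1L), cluster2 = sum(labels == 2L)),
         r_cluster1 = r1, r_cluster2 = r2, r_pooled = rp,
         silhouette = sil, bimodal = is.finite(sil) && sil > silhouette_min,
         data = dat),
    class = "scatter_clusters"
  )
}

# Mean simplified silhouette: per event, (b - a) / max(a, b) with a the
# Euclidean distance to its own centroid and b to the other centroid.
# Collapsed (duplicate) centers give 0 separation.
simplified_silhouette <- function(x, labels, centers) {
  if (sqrt(sum((centers[1, ] - centers[2, ])^2)) < 1e-9) return(0)
  d <- function(k) sqrt((x[, 1] - centers[k, 1])^2 + (x[, 2] - centers[k, 2])^2)
  d1 <- d(1L); d2 <- d(2L)
  a <- ifelse(labels == 1L, d1, d2)
  b <- ifelse(labels == 1L, d2, d1)
  mean((b - a) / pmax(a, b))
}

#' @export
print.scatter_clusters <- function(x, ...) {
  cat("<scatter_clusters>  (cluster 1 = higher SSC/FSC ratio)\n")
  print(tidy(x))
  cat(sprintf("silhouette %.3f -> %s\n", x$silhouette,
              if (x$bimodal) "bimodal" else "no clear bimodality"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-cluster regression summary (Table-1 shape)
#'
#' @param x a `scatter_clusters` object.
#' @param ... unused.
#' @return Tibble with one row per cluster plus a pooled row: `group`,
#'   `r_value`, `events`.
#' @method tidy scatter_clusters
#' @export
tidy.scatter_clusters <- function(x, ...) {
  tibble(
    group = c("cluster1", "cluster2", "pooled"),
    r_value = c(x$r_cluster1, x$r_cluster2, x$r_pooled),
    events = c(unname(x$counts), sum(x$counts))
  )
}

#' @rdname tidy.scatter_clusters
#' @method glance scatter_clusters
#' @export
glance.scatter_clusters <- function(x, ...) {
  tibble(
    r_cluster1 = x$r_cluster1, r_cluster2 = x$r_cluster2,
    r_pooled = x$r_pooled, silhouette = x$silhouette, bimodal = x$bimodal,
    n = sum(x$counts)
  )
}

#' Compare GFP distributions between the two scatter clusters
#'
#' Kernel density estimate of log10 GFP per cluster plus the difference of
#' cluster means — the check of whether the second scatter population
#' (higher SSC/FSC ratio) fluoresces differently from the first. A large
#' difference would mean the extra cluster biases correctness calls; a
#' small one means it is benign.
#'
#' @param clusters a [cluster_scatter()] result whose input carried a
#'   `gfp` column.
#' @param gfp_floor clamp for the log10 transform.
#' @param bw kernel bandwidth passed to [stats::density()]; the default
#'   `"nrd0"` is deterministic given the data.
#' @return List of class `cluster_gfp`: `densities` (tibble: `cluster`,
#'   `log_gfp`, `density`), `mean_diff` (cluster1 minus cluster2 mean
#'   log10 GFP), `means`.
#' @export
compare_cluster_gfp <- function(clusters, gfp_floor = 1, bw = "nrd0") {
  stopifnot(inherits(clusters, "scatter_clusters"))
  dat <- clusters$data
  if (all(is.na(dat$gfp))) {
    abort("clustered events carried no gfp channel", class = "gatescore_degenerate_error")
  }
  lg <- log10(pmax(dat$gfp, gfp_floor))
  means <- c(NA_real_, NA_real_)
  dens <- list()
  for (k in 1:2) {
    v <- lg[dat$cluster == k]
    if (length(v) == 0) {
      warn(paste0("cluster ", k, " is empty; its density curve is omitted"))
      next
    }
    means[k] <- mean(v)
    if (length(v) >= 2 && stats::sd(v) > 0) {
      d <- stats::density(v, bw = bw)
      dens[[length(dens) + 1L]] <- tibble(cluster = k, log_gfp = d$x, density = d$y)
    }
  }
  structure(
    list(densities = bind_rows(dens),
         mean_diff = means[1] - means[2],
         means = setNames(means, c("cluster1", "cluster2"))),
    class = "cluster_gfp"
  )
}
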