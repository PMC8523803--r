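#' Binary k-means clustering of heart-failure subjects
#'
#' Clusters subjects into two groups with restarted k-means (Lloyd iterations,
#' random initial centers, best of `restarts` solutions by within-cluster sum
#' of squared Euclidean distances). The cluster with the lower centroid is
#' labeled NIC and the higher one IC; for a single feature the discrimination
#' threshold is the mean of the two centroids.
#'
#' @param features numeric vector (one feature) or matrix/data frame with one
#'   row per subject. Features are not standardized; with multiple features
#'   on different scales the largest-scale feature dominates (a warning is
#'   issued).
#' @param restarts number of random restarts (50 as in the study protocol).
#' @param seed integer seed making the restart sequence deterministic.
#' @return List of class `clustering_result`: `labels` (factor IC/NIC),
#'   `centroids` (2 x p), `inertia`, `threshold` (1D only, else `NA`),
#'   `degenerate`.
#' @export
kmeans_binary <- function(features, restarts = 50, seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing feature values")
  if (nrow(x) < 2) stop("need at least 2 subjects")
  if (ncol(x) > 1) {
    sds <- apply(x, 2, sd)
    if (max(sds) > 20 * max(min(sds), 1e-12)) {
      warning("feature scales differ strongly; unstandardized k-means will be dominated by the largest-scale feature")
    }
  }
  if (all(apply(x, 2, function(col) diff(range(col)) == 0))) {
    # all points identical: degenerate clustering, everything in one cluster
    labels <- factor(rep("NIC", nrow(x)), levels = c("NIC", "IC"))
    return(structure(
      list(
        labels = labels, centroids = rbind(x[1, ], x[1, ]),
        inertia = 0, threshold = if (ncol(x) == 1) x[1, 1] else NA_real_,
        degenerate = TRUE
      ),
      class = "clustering_result"
    ))
  }
  km <- with_seed(seed, kmeans(x, centers = 2, nstart = restarts,
                               iter.max = 100, algorithm = "Lloyd"))
  # order clusters by centroid level (mean over features): lower -> NIC
  level <- rowMeans(km$centers)
  nic_cluster <- which.min(level)
  labels <- factor(ifelse(km$cluster == nic_cluster, "NIC", "IC"),
                   levels = c("NIC", "IC"))
  centroids <- km$centers[order(level), , drop = FALSE]
  rownames(centroids) <- c("NIC", "IC")
  structure(
    list(
      labels = labels,
      centroids = centroids,
      inertia = km$tot.withinss,
      threshold = if (ncol(x) == 1) mean(km$centers[, 1]) else NA_real_,
      degenerate = FALSE
    ),
    class = "clustering_result"
  )
}

#' Classification metrics with IC as the positive class
#'
#' @param predicted,truth vectors of labels (`"IC"`/`"NIC"`, or anything
#'   coercible to those two levels) of equal length.
#' @return List of class `classification_metrics`: confusion counts
#'   (`TP`, `FN`, `TN`, `FP`), `accuracy`, `sensitivity`, `specificity`
#'   (percent), `ppv`, `npv` (proportions).
#' @export
score_classification <- function(predicted, truth) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  p_ic <- as.character(predicted) == "IC"
  t_ic <- as.character(truth) == "IC"
  tp <- sum(p_ic & t_ic); fn <- sum(!p_ic & t_ic)
  tn <- sum(!p_ic & !t_ic); fp <- sum(p_ic & !t_ic)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(
    list(
      TP = tp, FN = fn, TN = tn, FP = fp,
      accuracy = 100 * (tp + tn) / length(predicted),
      sensitivity = 100 * safe_div(tp, tp + fn),
      specificity = 100 * safe_div(tn, tn + fp),
      ppv = safe_div(tp, tp + fp),
      npv = safe_div(tn, tn + fn)
    ),
    class = "classification_metrics"
  )
}

#' Compare fibrosis features as etiology classifiers
#'
#' Runs [kmeans_binary()] on each feature set in turn and scores the
#' resulting IC/NIC labels against the true etiologies, producing one row per
#' feature set (the layout of the study's feature-comparison table).
#'
#' @param feature_table data frame of per-subject features (e.g. from
#'   [quantify_cohort()], HF subjects only).
#' @param truth true etiology labels (`"IC"`/`"NIC"`).
#' @param feature_sets named list of character vectors of column names; each
#'   entry defines one clustering run.
#' @param restarts,seed passed to [kmeans_binary()].
#' @return Data frame with columns `features`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `threshold`, `skipped`.
#' @export
feature_comparison <- function(feature_table, truth,
                               feature_sets = list(
                                 sigma_intra = "sigma_intra",
                                 V_nm = "V_nm",
                                 largest_patch = "largest_patch_area_um2"
                               ),
                               restarts = 50, seed = 1L) {
  stopifnot(nrow(feature_table) == length(truth))
  rows <- lapply(names(feature_sets), function(nm) {
    cols <- feature_sets[[nm]]
    if (!all(cols %in% names(feature_table))) {
      stop("unknown feature columns: ", paste(setdiff(cols, names(feature_table)), collapse = ", "))
    }
    x <- as.matrix(feature_table[, cols, drop = FALSE])
    if (all(apply(x, 2, function(col) diff(range(col)) == 0))) {
      return(data.frame(
        features = nm, accuracy = NA_real_, sensitivity = NA_real_,
        specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
        threshold = NA_real_, skipped = TRUE
      ))
    }
    cl <- suppressWarnings(kmeans_binary(x, restarts = restarts, seed = seed))
    sc <- score_classification(cl$labels, truth)
    data.frame(
      features = nm, accuracy = sc$accuracy, sensitivity = sc$sensitivity,
      specificity = sc$specificity, ppv = sc$ppv, npv = sc$npv,
      threshold = cl$threshold, skipped = FALSE
    )
  })
  do.call(rbind, rows)
}
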