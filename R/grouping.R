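#' Classify samples into sensory groups by PCA and k-means
#'
#' Codifies the panel-score grouping procedure: metrics are centered and
#' unit-scaled, reduced by PCA (singular value decomposition), and the
#' natural (non-tobacco) samples are partitioned by seeded k-means on the
#' first two principal-component scores. Subgroups are then named by their
#' sensory semantics: the cluster whose centroid lies nearest the tobacco
#' centroid in PC space is `N2` ("closely aligned with tobacco"), the
#' cluster with the highest mean astringency + nasal moistening among the
#' remainder is `N1` (the advantaged group), and what is left is `N3`.
#' Tobacco samples keep the label `T`.
#'
#' Zero-variance metrics are dropped with a warning before scaling. If the
#' natural samples collapse to fewer distinct profiles than requested
#' clusters, a single subgroup is returned and a warning raised.
#'
#' @param profiles Wide profile tibble from [sample_sensory_profile()]
#'   (`sample_id` plus one column per metric).
#' @param tobacco_ids Sample ids of the tobacco (T) group.
#' @param n_subgroups Number of natural subgroups (default 3).
#' @param seed Integer seed for k-means (50 restarts).
#' @return An object of class `sensory_grouping`: list with `assignments`
#'   (tibble `sample_id`, `group`), `pc_scores`, `loadings`,
#'   `explained_variance` (fractions summing to 1), `centers`.
#' @export
classify_samples <- function(profiles, tobacco_ids, n_subgroups = 3,
                             seed = 1) {
  metrics <- setdiff(names(profiles), c("sample_id", "group"))
  stopifnot(length(metrics) >= 2)
  x <- as.matrix(profiles[, metrics])
  rownames(x) <- profiles$sample_id
  keep <- apply(x, 2, sd) > 0
  if (!all(keep)) {
    warn(sprintf("dropping zero-variance metric(s): %s",
                 paste(metrics[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) < 2) abort("fewer than 2 informative metrics")
  pca <- prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  sc <- pca$x[, 1:2, drop = FALSE]

  natural <- setdiff(profiles$sample_id, tobacco_ids)
  stopifnot(length(natural) >= n_subgroups)
  nat_sc <- sc[natural, , drop = FALSE]

  set.seed(seed)
  km <- tryCatch(
    kmeans(nat_sc, centers = n_subgroups, nstart = 50),
    error = function(e) {
      warn(paste("k-means degenerate, returning a single subgroup:",
                 conditionMessage(e)))
      NULL
    }
  )
  if (is.null(km)) {
    cl <- setNames(rep(1L, length(natural)), natural)
    centers <- matrix(colMeans(nat_sc), 1)
    labels <- c("N2")
  } else {
    cl <- setNames(km$cluster, natural)
    centers <- km$centers
    t_centroid <- colMeans(sc[tobacco_ids, , drop = FALSE])
    d_t <- sqrt(rowSums(sweep(centers, 2, t_centroid)^2))
    n2 <- which.min(d_t)
    adv_metrics <- intersect(c("astringency", "nasal_moistening"), colnames(x))
    adv <- vapply(seq_len(nrow(centers)), function(j) {
      mean(x[natural[cl == j], adv_metrics, drop = FALSE])
    }, numeric(1))
    rest <- setdiff(seq_len(nrow(centers)), n2)
    n1 <- rest[which.max(adv[rest])]
    labels <- rep("N3", nrow(centers))
    labels[n2] <- "N2"
    labels[n1] <- "N1"
  }

  assignments <- tibble(
    sample_id = profiles$sample_id,
    group = ifelse(profiles$sample_id %in% tobacco_ids, "T",
                   labels[cl[profiles$sample_id]])
  )
  structure(
    list(assignments = assignments,
         pc_scores = as_tibble(sc, rownames = "sample_id"),
         loadings = as_tibble(pca$rotation, rownames = "metric"),
         explained_variance = expl,
         centers = centers),
    class = "sensory_grouping"
  )
}

#' @export
print.sensory_grouping <- function(x, ...) {
  cat("<sensory_grouping>\n")
  print(table(x$assignments$group))
  cat(sprintf("PC1/PC2 explained variance: %.1f%% / %.1f%%\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  invisible(x)
}

#' Tidy a sensory grouping
#'
#' One row per sample with its assigned group and PC coordinates.
#'
#' @param x A `sensory_grouping`.
#' @param ... Unused.
#' @export
tidy.sensory_grouping <- function(x, ...) {
  left_join(x$assignments, x$pc_scores, by = "sample_id")
}

#' One-line summary of a sensory grouping
#'
#' @param x A `sensory_grouping`.
#' @param ... Unused.
#' @export
glance.sensory_grouping <- function(x, ...) {
  tibble(
    n_samples = nrow(x$assignments),
    n_groups = dplyr::n_distinct(x$assignments$group),
    pc1_var = x$explained_variance[1],
    pc2_var = x$explained_variance[2]
  )
}

#' PCA plot of a sensory grouping
#'
#' @param object A `sensory_grouping`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensory_grouping <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  color = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2]),
      color = "group") +
    ggplot2::theme_minimal()
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
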