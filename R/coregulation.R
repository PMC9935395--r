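#' Filter regulated phosphosites
#'
#' Retains sites showing more than a twofold change (|log2FC| strictly above
#' `log2fc_threshold`) in at least `min_conditions` conditions ("more than
#' two" conditions = at least 3, the default).
#'
#' @param fc Fold-change tibble: columns `protein`, `position`, then one
#'   column per condition holding log2 fold changes (NA allowed). Set
#'   `ratio = TRUE` if values are raw ratios to be log2-transformed.
#' @param log2fc_threshold Strict absolute log2 fold-change threshold,
#'   default 1 (= twofold).
#' @param min_conditions Minimum number of qualifying conditions, default 3.
#' @param ratio Input values are raw ratios, default `FALSE`.
#' @return The filtered tibble (possibly 0 rows, with a warning).
#' @export
filter_regulated <- function(fc, log2fc_threshold = 1, min_conditions = 3,
                             ratio = FALSE) {
  m <- fc_values(fc)
  if (ratio) {
    m <- log2(m)
    fc[, -(1:2)] <- as.data.frame(m)
  }
  n_qual <- rowSums(abs(m) > log2fc_threshold, na.rm = TRUE)
  out <- fc[n_qual >= min_conditions, , drop = FALSE]
  if (nrow(out) == 0)
    warn("no site passes the regulation filter; returning an empty matrix")
  out
}

fc_values <- function(fc) {
  if (!all(c("protein", "position") %in% names(fc)[1:2]))
    abort("fold-change table must start with columns protein, position")
  m <- as.matrix(fc[, -(1:2), drop = FALSE])
  rownames(m) <- site_key(fc$protein, fc$position)
  storage.mode(m) <- "double"
  m
}

#' Pairwise Pearson correlations between phosphosites
#'
#' Correlates sites across the conditions observed in both (pairwise-complete
#' Pearson). Pairs with fewer than `min_overlap` shared conditions, and pairs
#' involving a constant profile, are set to 0 (so downstream clustering sees
#' "no evidence of co-regulation"), with a warning for constants.
#'
#' @inheritParams filter_regulated
#' @param min_overlap Minimum shared observed conditions per pair, default 5.
#' @return A symmetric site x site correlation matrix with unit diagonal,
#'   rows/columns named `protein_position`.
#' @export
correlation_matrix <- function(fc, min_overlap = 5) {
  m <- fc_values(fc)
  if (nrow(m) < 2) abort("need at least 2 sites to correlate")
  obs <- !is.na(m)
  overlap <- tcrossprod(obs * 1)
  cc <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
  sds <- apply(m, 1, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    warn("constant site profile(s): correlations set to 0")
  cc[overlap < min_overlap] <- 0
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Cluster phosphosites by their correlation profiles
#'
#' Each site is represented by its row of the correlation matrix; pairwise
#' Euclidean distances between these rows are clustered with Ward's
#' minimum-variance linkage (the `ward.D2` variant, which operates on the
#' distances themselves) and flat clusters are produced by cutting the
#' dendrogram at `cut_height`, or into `n_clusters` groups.
#'
#' @param correlations Square correlation matrix from [correlation_matrix()].
#' @param cut_height Dendrogram cut height (same scale as the Ward merge
#'   heights). Ignored when `n_clusters` is given.
#' @param n_clusters Target number of flat clusters.
#' @return A `cf_clusters`: `labels` (named integer vector, contiguous ids
#'   from 1 in dendrogram order), the `hclust` tree, and the cut used.
#' @export
cluster_sites <- function(correlations, cut_height = NULL, n_clusters = NULL) {
  stopifnot(is.matrix(correlations), nrow(correlations) == ncol(correlations))
  if (is.null(cut_height) && is.null(n_clusters))
    abort("supply cut_height or n_clusters")
  tree <- hclust(dist(correlations), method = "ward.D2")
  if (!is.null(n_clusters)) {
    labels <- cutree(tree, k = min(n_clusters, nrow(correlations)))
  } else {
    if (cut_height > max(tree$height))
      warn("cut_height is above the dendrogram root; one cluster returned")
    labels <- cutree(tree, h = cut_height)
  }
  structure(list(labels = labels, tree = tree, cut_height = cut_height,
                 n_clusters = length(unique(labels))),
            class = "cf_clusters")
}

#' @export
print.cf_clusters <- function(x, ...) {
  cat("<cf_clusters> ", length(x$labels), " sites in ", x$n_clusters,
      " clusters\n", sep = "")
  invisible(x)
}

#' Per-cluster, per-condition regulation test
#'
#' For each cluster and condition, compares the cluster's fold changes with
#' the overall distribution of fold changes in that condition by a Z test:
#' `z = (mean_cluster - mean_background) / (sd_background / sqrt(n_cluster))`,
#' with a one-sided p-value on the side of the observed deviation. The
#' signed statistic `signed_log10_p` is `-log10(p)`, positive when the
#' cluster median exceeds the background median, negative otherwise.
#'
#' @inheritParams filter_regulated
#' @param labels Named integer vector of cluster labels covering the rows of
#'   `fc` (a `cf_clusters` is accepted).
#' @param exclude_cluster_from_background Drop the cluster's own values from
#'   the background distribution (default `FALSE`: the background is the
#'   entire condition).
#' @return Tibble: `cluster`, `condition`, `n`, `z`, `p_value`,
#'   `signed_log10_p` (NA when fewer than 2 cluster values are observed).
#' @export
cluster_condition_test <- function(fc, labels,
                                   exclude_cluster_from_background = FALSE) {
  if (inherits(labels, "cf_clusters")) labels <- labels$labels
  m <- fc_values(fc)
  if (is.null(names(labels))) {
    if (length(labels) != nrow(m)) abort("labels must cover the matrix rows")
    names(labels) <- rownames(m)
  }
  if (!all(rownames(m) %in% names(labels)))
    abort("labels must cover the matrix rows")
  lab <- labels[rownames(m)]
  out <- list()
  for (cond in colnames(m)) {
    col <- m[, cond]
    bg_all <- col[!is.na(col)]
    for (cl in sort(unique(lab))) {
      vals <- col[lab == cl & !is.na(col)]
      bg <- if (exclude_cluster_from_background)
        col[lab != cl & !is.na(col)] else bg_all
      if (length(vals) < 2 || length(bg) < 2 || sd(bg) == 0) {
        out[[length(out) + 1]] <- tibble(cluster = cl, condition = cond,
                                         n = length(vals), z = NA_real_,
                                         p_value = NA_real_,
                                         signed_log10_p = NA_real_)
        next
      }
      z <- (mean(vals) - mean(bg)) / (sd(bg) / sqrt(length(vals)))
      p <- pnorm(-abs(z))
      s <- if (median(vals) > median(bg)) 1 else -1
      out[[length(out) + 1]] <- tibble(cluster = cl, condition = cond,
                                       n = length(vals), z = z, p_value = p,
                                       signed_log10_p = s * -log10(p))
    }
  }
  bind_rows(out)
}

#' Term over-representation by the hypergeometric test
#'
#' One-sided upper-tail hypergeometric test per term: the probability of
#' drawing at least the observed number of term members when sampling
#' `|selected|` items from the population. Terms with no population members
#' are skipped; p-values are Benjamini-Hochberg adjusted across terms.
#'
#' @param selected Character vector of selected items (must be a subset of
#'   `population`).
#' @param annotations Named list of character vectors (term -> members), or a
#'   tibble with columns `term`, `member`.
#' @param population Character vector: the item universe.
#' @return Tibble: `term`, `n_selected_in_term` (k), `n_term` (K in
#'   population), `n_selected` (n), `n_population` (N), `fold_enrichment`
#'   `(k/n)/(K/N)`, `p_value`, `q_value` (BH).
#' @export
over_representation <- function(selected, annotations, population) {
  if (length(selected) == 0) abort("selection is empty")
  selected <- unique(selected)
  population <- unique(population)
  if (!all(selected %in% population))
    abort("selected must be a subset of population")
  if (is.data.frame(annotations))
    annotations <- split(annotations$member, annotations$term)
  n <- length(selected)
  big_n <- length(population)
  rows <- list()
  for (term in names(annotations)) {
    members <- intersect(unique(annotations[[term]]), population)
    big_k <- length(members)
    if (big_k == 0) next
    k <- length(intersect(selected, members))
    p <- phyper(k - 1, big_k, big_n - big_k, n, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- tibble(
      term = term, n_selected_in_term = k, n_term = big_k, n_selected = n,
      n_population = big_n,
      fold_enrichment = (k / n) / (big_k / big_n), p_value = p)
  }
  if (length(rows) == 0)
    return(tibble(term = character(), n_selected_in_term = integer(),
                  n_term = integer(), n_selected = integer(),
                  n_population = integer(), fold_enrichment = numeric(),
                  p_value = numeric(), q_value = numeric()))
  out <- bind_rows(rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value)
}
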