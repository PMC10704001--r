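#' The consonant inventory for C/a/ confusion analysis
#'
#' The 16 consonants presented in consonant-vowel (C/a/) context:
#' p t k b d g m n f θ s ʃ v ð z ʒ.
#'
#' @return Character vector of the 16 consonant labels (IPA, UTF-8).
#' @export
consonant_labels <- function() {
  c("p", "t", "k", "b", "d", "g", "m", "n",
    "f", "θ", "s", "ʃ", "v", "ð", "z", "ʒ")
}

#' Build a consonant confusion matrix from response records
#'
#' Tallies presented-by-responded counts; the diagonal holds correct
#' identifications. Row probabilities are row-normalized over rows with at
#' least one presentation.
#'
#' @param records Data frame with columns `presented` and `responded`, both
#'   drawn from `labels`.
#' @param labels Label set (defaults to [consonant_labels()]).
#' @return An object of class `confusion_matrix` with `labels`, `counts`
#'   (integer matrix), and `row_probs`.
#' @export
build_confusion_matrix <- function(records, labels = consonant_labels()) {
  stopifnot(all(c("presented", "responded") %in% names(records)))
  bad <- setdiff(unique(c(records$presented, records$responded)), labels)
  if (length(bad)) {
    stop("unknown consonant label(s): ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(records$presented, levels = labels),
                  factor(records$responded, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(presented = labels, responded = labels))
  rs <- rowSums(counts)
  row_probs <- counts / ifelse(rs > 0, rs, 1)
  row_probs[rs == 0, ] <- NA_real_
  structure(list(labels = labels, counts = counts, row_probs = row_probs),
            class = "confusion_matrix")
}

#' Overall accuracy of a confusion matrix
#' @param matrix A [build_confusion_matrix()] result.
#' @return `trace / total` as a fraction.
#' @export
confusion_accuracy <- function(matrix) {
  stopifnot(inherits(matrix, "confusion_matrix"))
  sum(diag(matrix$counts)) / sum(matrix$counts)
}

#' Mean identification scores for consonant groups
#'
#' Scores each group of consonants by the mean of its members' diagonal
#' (correct-identification) probabilities and reports the groups in
#' ascending score order; ties are reported as such.
#'
#' @param matrix A [build_confusion_matrix()] result.
#' @param groups Named list of non-overlapping character vectors of labels.
#' @return A data frame with columns `group`, `score`, ordered by ascending
#'   score, plus attribute `ties` (`TRUE` when any scores coincide).
#' @export
consonant_group_scores <- function(matrix, groups) {
  stopifnot(inherits(matrix, "confusion_matrix"))
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  if (any(lengths(groups) == 0)) stop("empty consonant group")
  all_members <- unlist(groups)
  if (anyDuplicated(all_members)) stop("groups must be disjoint")
  bad <- setdiff(all_members, matrix$labels)
  if (length(bad)) stop("unknown label(s) in groups: ",
                        paste(bad, collapse = ", "))
  diag_p <- diag(matrix$row_probs)
  names(diag_p) <- matrix$labels
  scores <- vapply(groups, function(g) mean(diag_p[g]), numeric(1))
  out <- data.frame(group = names(scores), score = unname(scores),
                    row.names = NULL)
  out <- out[order(out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ties") <- anyDuplicated(signif(scores, 12)) > 0
  out
}

#' Agglomerative clustering of consonant confusions
#'
#' Uses the probability of confusion between a pair of consonants as the
#' (inverse) distance: pairwise similarity is the symmetrized off-diagonal
#' confusion probability `(p(i -> j) + p(j -> i)) / 2`, converted to a
#' distance by `1 - s / max(s)`. Clusters are merged agglomeratively
#' (average linkage by default) and the merge threshold is swept to the
#' largest height yielding exactly `target_n_clusters` clusters, singletons
#' included.
#'
#' @param matrix A [build_confusion_matrix()] result.
#' @param target_n_clusters Desired number of clusters (including
#'   singletons).
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @return An object of class `confusion_partition`: `assignments` (named
#'   integer vector), `clusters` (list of label sets), `n_clusters`,
#'   `merge_heights`, `threshold`, and the `hclust` tree.
#' @export
cluster_confusions <- function(matrix, target_n_clusters,
                               linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(matrix, "confusion_matrix"))
  labels <- matrix$labels
  k <- length(labels)
  if (k < 2) stop("need at least 2 labels to cluster")
  p <- matrix$row_probs
  p[is.na(p)] <- 0
  sim <- (p + t(p)) / 2
  diag(sim) <- 0
  smax <- max(sim)
  d <- if (smax > 0) 1 - sim / smax else matrix(1, k, k)
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  heights <- tree$height
  if (!target_n_clusters %in% seq_len(k)) {
    stop("target_n_clusters must lie in 1..", k)
  }
  # cluster counts attainable by a height threshold: cutting just below
  # each unique merge height (ties can merge several clusters at once)
  uh <- sort(unique(heights))
  attainable <- c(k, vapply(uh, function(h) {
    max(stats::cutree(tree, h = h))
  }, numeric(1)))
  if (!target_n_clusters %in% attainable) {
    stop("target_n_clusters = ", target_n_clusters,
         " unattainable by a height threshold; attainable counts: ",
         paste(sort(unique(attainable), decreasing = TRUE), collapse = ", "))
  }
  # largest threshold that still yields the target count
  if (target_n_clusters == k) {
    threshold <- if (length(uh)) uh[1] / 2 else 0
    assignments <- stats::cutree(tree, k = k)
  } else {
    cand <- uh[vapply(uh, function(h) max(stats::cutree(tree, h = h)),
                      numeric(1)) == target_n_clusters]
    threshold <- max(cand)
    assignments <- stats::cutree(tree, h = threshold)
  }
  names(assignments) <- labels
  clusters <- split(labels, assignments)
  structure(
    list(assignments = assignments, clusters = unname(clusters),
         n_clusters = length(clusters), merge_heights = heights,
         threshold = threshold, tree = tree, linkage = linkage),
    class = "confusion_partition"
  )
}

#' @export
print.confusion_partition <- function(x, ...) {
  cat(sprintf("<confusion_partition> %d clusters (%s linkage):\n",
              x$n_clusters, x$linkage))
  for (cl in x$clusters) cat("  {", paste(cl, collapse = " "), "}\n")
  invisible(x)
}
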