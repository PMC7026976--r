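#' Pairwise exceedance probability between two sample groups
#'
#' Estimates \eqn{P\{Y_k < Y_d\}} as the fraction of ordered pairs
#' \eqn{(i, j)} for which the group-k value lies strictly below the group-d
#' value. The indicator is strict: tied pairs contribute 0, never 0.5, so a
#' feature with identical values in both groups scores 0. This is the
#' two-group building block of the SPECS score and equals the Mann-Whitney
#' U statistic (without tie correction) divided by \eqn{n_k n_d}.
#'
#' @param values_k Numeric vector of observations in the reference group k.
#' @param values_d Numeric vector of observations in the candidate group d.
#'
#' @return A probability in [0, 1], exactly equal to the brute-force double
#'   sum over all ordered pairs.
#' @export
#' @examples
#' pairwise_probability(c(1, 2), c(3, 4))  # complete separation: 1
#' pairwise_probability(c(1, 3), c(2, 4))  # 3 of 4 pairs: 0.75
pairwise_probability <- function(values_k, values_d) {
  if (length(values_k) == 0L || length(values_d) == 0L)
    stop("pairwise probability is undefined for an empty group")
  if (!all(is.finite(values_k)) || !all(is.finite(values_d)))
    stop("observations must be finite")
  # findInterval with left.open counts elements of sorted values_k strictly
  # below each value_d; exact for ties, O(n log n).
  less <- findInterval(values_d, sort(values_k), left.open = TRUE)
  sum(less) / (length(values_k) * length(values_d))
}

# All pairwise strict-exceedance probabilities for one feature.
# y: per-sample values; f: state factor. Returns an m x m matrix P with
# P[k, d] = fraction of ordered pairs with a state-k value strictly below a
# state-d value. Diagonal is NA (never used by the score).
.pairwise_matrix <- function(y, f) {
  lev <- levels(f)
  m <- length(lev)
  split_y <- split(y, f)
  n <- lengths(split_y)
  if (any(n == 0L))
    stop("state with zero samples: ", paste(lev[n == 0L], collapse = ", "))
  sorted <- lapply(split_y, sort)
  P <- matrix(NA_real_, m, m, dimnames = list(lev, lev))
  for (k in seq_len(m)) {
    sk <- sorted[[k]]
    for (d in seq_len(m)) {
      if (d == k) next
      P[k, d] <- sum(findInterval(split_y[[d]], sk, left.open = TRUE)) /
        (n[[k]] * n[[d]])
    }
  }
  P
}

# Collapse a pairwise matrix into per-state SPECS scores with weights pi.
# For each target d the weights over k != d are renormalized to sum to 1 so
# a perfectly separated target attains exactly 1.
.scores_from_pairwise <- function(P, pi) {
  lev <- colnames(P)
  vapply(lev, function(d) {
    k <- setdiff(lev, d)
    w <- pi[k] / sum(pi[k])
    sum(P[k, d] * w)
  }, numeric(1))
}

#' SPECS score of one feature for one target state
#'
#' Computes \eqn{\hat p_d = \sum_{k \ne d} \hat P_{kd}\, \pi_k} where
#' \eqn{\hat P_{kd}} is the empirical probability that an observation from
#' state k lies strictly below one from the target state d, and the
#' prevalence weights \eqn{\pi_k} are renormalized over \eqn{k \ne d}. A
#' score of 1 means the target state's distribution lies entirely above all
#' others; 0 means entirely below (or all ties, e.g. an all-zero feature).
#' In equilibrated mode the score is the unweighted mean of the
#' \eqn{m - 1} pairwise probabilities.
#'
#' @param feature_values Numeric vector of per-sample abundances, named by
#'   sample id (or in the grouping's sample order when unnamed).
#' @param grouping A \code{\link{sample_grouping}}.
#' @param target_state The state the score is computed for.
#' @param prevalences \code{NULL} for equilibrated weights, or a vector
#'   accepted by \code{\link{prevalence_weights}}.
#'
#' @return A single score in [0, 1].
#' @export
#' @examples
#' grp <- sample_grouping(paste0("s", 1:6), rep(c("A", "B", "C"), each = 2))
#' specs_score(c(5, 6, 1, 2, 3, 4), grp, "A")  # perfect separation: 1
specs_score <- function(feature_values, grouping, target_state,
                        prevalences = NULL) {
  stopifnot(inherits(grouping, "sample_grouping"))
  if (!target_state %in% grouping$states)
    stop("unknown target state: ", target_state)
  ids <- names(grouping$assignment)
  if (!is.null(names(feature_values))) {
    miss <- setdiff(ids, names(feature_values))
    if (length(miss)) stop("feature values missing for samples: ",
                           paste(utils::head(miss, 10), collapse = ", "))
    feature_values <- feature_values[ids]
  } else if (length(feature_values) != length(ids)) {
    stop("unnamed feature values must match the number of samples")
  }
  f <- .grouping_factor(grouping, ids)
  pi <- prevalence_weights(grouping, prevalences)
  P <- .pairwise_matrix(as.numeric(feature_values), f)
  unname(.scores_from_pairwise(P, pi)[target_state])
}

#' SPECS scores for every feature and state
#'
#' Vectorizes \code{\link{specs_score}} over all rows of a count matrix and
#' all states.
#'
#' @param counts Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Values must be non-negative
#'   and finite; any abundance scale works since the score is rank-based.
#' @param grouping A \code{\link{sample_grouping}} covering every column.
#' @param prevalences As in \code{\link{specs_score}}.
#'
#' @return Numeric matrix features x states of scores in [0, 1], rows in the
#'   input feature order, columns in the grouping's state order.
#' @export
specs_scores <- function(counts, grouping, prevalences = NULL) {
  counts <- .validate_counts(counts)
  stopifnot(inherits(grouping, "sample_grouping"))
  extra <- setdiff(colnames(counts), names(grouping$assignment))
  missing_samp <- setdiff(names(grouping$assignment), colnames(counts))
  if (length(extra) || length(missing_samp))
    stop("sample sets disagree; ",
         if (length(extra)) paste0("in matrix only: ",
           paste(utils::head(extra, 10), collapse = ", "), "; ") else "",
         if (length(missing_samp)) paste0("in grouping only: ",
           paste(utils::head(missing_samp, 10), collapse = ", ")) else "")
  f <- .grouping_factor(grouping, colnames(counts))
  pi <- prevalence_weights(grouping, prevalences)
  out <- t(apply(counts, 1L, function(y)
    .scores_from_pairwise(.pairwise_matrix(y, f), pi)))
  if (nrow(counts) == 1L)  # apply() drops to a vector for a single row
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(counts), grouping$states))
  colnames(out) <- grouping$states
  rownames(out) <- rownames(counts)
  out
}

.validate_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (!all(is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  counts
}

#' Classify features as specifically present or absent per state
#'
#' A feature is specifically present in a state when its score there is
#' strictly above \code{upper} (default 0.95) and specifically absent
#' ("disallowed") when strictly below \code{lower} (default 0.05). If several
#' states qualify the feature is labelled for all of them; features with no
#' qualifying state receive no label.
#'
#' @param scores Features x states score matrix from \code{\link{specs_scores}}.
#' @param upper,lower Classification thresholds, \code{0 <= lower < upper <= 1}.
#'
#' @return A \code{specs_result}: list with the score matrix, a data frame
#'   \code{labels} (columns \code{gene_id}, \code{state}, \code{direction}
#'   with direction \code{"present"} or \code{"absent"}), and the thresholds.
#' @export
classify_features <- function(scores, upper = 0.95, lower = 0.05) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("'scores' must be a numeric score matrix")
  if (!(lower >= 0 && lower < upper && upper <= 1))
    stop("thresholds must satisfy 0 <= lower < upper <= 1")
  if (any(scores < 0 | scores > 1, na.rm = TRUE))
    stop("scores must lie in [0, 1]")
  hit_hi <- which(scores > upper, arr.ind = TRUE)
  hit_lo <- which(scores < lower, arr.ind = TRUE)
  labels <- rbind(
    data.frame(gene_id = rownames(scores)[hit_hi[, 1L]],
               state = colnames(scores)[hit_hi[, 2L]],
               direction = rep("present", nrow(hit_hi)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = rownames(scores)[hit_lo[, 1L]],
               state = colnames(scores)[hit_lo[, 2L]],
               direction = rep("absent", nrow(hit_lo)),
               stringsAsFactors = FALSE))
  labels <- labels[order(match(labels$gene_id, rownames(scores)),
                         match(labels$state, colnames(scores))), , drop = FALSE]
  rownames(labels) <- NULL
  structure(list(scores = scores, labels = labels,
                 thresholds = c(upper = upper, lower = lower)),
            class = "specs_result")
}

#' @export
print.specs_result <- function(x, ...) {
  cat("specs_result:", nrow(x$scores), "features x", ncol(x$scores),
      "states;", nrow(x$labels), "specificity labels",
      sprintf("(> %.2f present, < %.2f absent)\n",
              x$thresholds[["upper"]], x$thresholds[["lower"]]))
  invisible(x)
}
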