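#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over reference
#' features, of the ratio of the sample's count to the feature's geometric
#' mean across samples. Reference features are those with strictly positive
#' counts in every sample (a zero anywhere excludes the feature). Dividing
#' each column by its factor makes samples comparable in sequencing depth.
#'
#' @param counts Numeric feature x sample matrix of raw counts.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
#' @examples
#' m <- matrix(c(2, 6, 4, 12), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' size_factors(m)  # ~0.707, ~1.414
size_factors <- function(counts) {
  counts <- .validate_counts(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no feature has positive counts in every sample; ",
         "median-of-ratios size factors are undefined for this matrix")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc - loggeo, 2L, function(v) exp(stats::median(v)))
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts Numeric feature x sample matrix.
#' @param factors Size factors from \code{\link{size_factors}}; computed
#'   when omitted.
#' @return Matrix of normalized counts (counts divided column-wise).
#' @export
normalize_counts <- function(counts, factors = NULL) {
  counts <- .validate_counts(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  if (!all(is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite")
  sweep(counts, 2L, factors[colnames(counts)], "/")
}

#' Select a low-abundance stable background gene set
#'
#' From normalized counts, keeps genes whose overall mean lies strictly
#' between the mean bounds (default 0.1-10 normalized counts) and returns
#' the \code{size} genes with the smallest standard deviation computed
#' across per-state mean values, i.e. the genes most stable between tissue
#' types. Ties are broken deterministically by gene id.
#'
#' @param normalized Numeric feature x sample matrix of normalized counts.
#' @param grouping A \code{\link{sample_grouping}}.
#' @param size Number of background genes to select (default 1000).
#' @param mean_bounds Length-2 numeric, exclusive bounds on the overall mean.
#'
#' @return Character vector of the selected gene ids, in increasing order of
#'   between-state standard deviation.
#' @export
select_background <- function(normalized, grouping, size = 1000,
                              mean_bounds = c(0.1, 10)) {
  normalized <- .validate_counts(normalized)
  stopifnot(length(mean_bounds) == 2L, mean_bounds[1] < mean_bounds[2],
            size >= 1L)
  mu <- rowMeans(normalized)
  ok <- mu > mean_bounds[1] & mu < mean_bounds[2]
  if (sum(ok) < size)
    stop("only ", sum(ok), " genes satisfy the mean bounds, ", size,
         " requested")
  prof <- .profile_matrix(normalized[ok, , drop = FALSE], grouping)
  sds <- apply(prof, 1L, stats::sd)
  ids <- rownames(prof)
  ord <- order(sds, ids)  # stable tie-break by gene id
  ids[ord][seq_len(size)]
}
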