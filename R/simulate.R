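#' Default benchmark-like group sizes
#'
#' Ten groups with log-spaced sizes between 11 and 490 samples, mirroring a
#' strongly unbalanced multi-tissue compendium. \code{scale} shrinks every
#' group proportionally (floored at 2 samples) for fast tests.
#'
#' @param n_groups Number of groups (default 10).
#' @param min_size,max_size Smallest and largest group size before scaling.
#' @param scale Multiplicative shrink factor in (0, 1].
#' @return Named integer vector of group sizes (names "g01", "g02", ...).
#' @export
benchmark_group_sizes <- function(n_groups = 10, min_size = 11,
                                  max_size = 490, scale = 1) {
  stopifnot(n_groups >= 2, min_size >= 2, max_size >= min_size,
            scale > 0, scale <= 1)
  sizes <- round(exp(seq(log(min_size), log(max_size), length.out = n_groups)))
  sizes <- pmax(2L, as.integer(round(sizes * scale)))
  stats::setNames(sizes, sprintf("g%02d", seq_len(n_groups)))
}

#' Simulate a background count matrix with unbalanced groups
#'
#' Draws negative-binomial counts for \code{n_genes} features across groups
#' of the given sizes. Each gene's mean is drawn log-uniformly from
#' \code{mean_range} (default 0.1-10, the low-abundance background regime)
#' and is identical across groups, so no gene carries intrinsic
#' specificity; a shared dispersion controls overdispersion
#' (variance = mu + dispersion * mu^2). Fully deterministic given a seed.
#'
#' @param n_genes Number of features.
#' @param group_sizes Named integer vector of samples per group (the names
#'   become state labels); defaults to \code{benchmark_group_sizes()}.
#' @param mean_range Length-2 range for per-gene means.
#' @param dispersion Negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param seed Integer seed.
#'
#' @return List with \code{counts} (feature x sample integer matrix) and
#'   \code{grouping} (a \code{\link{sample_grouping}}).
#' @export
#' @examples
#' sim <- simulate_counts(20, c(A = 5, B = 8, C = 3), seed = 1)
#' dim(sim$counts)
simulate_counts <- function(n_genes, group_sizes = benchmark_group_sizes(),
                            mean_range = c(0.1, 10), dispersion = 0.5,
                            seed = NULL) {
  stopifnot(n_genes >= 1, length(group_sizes) >= 2, all(group_sizes >= 2),
            length(mean_range) == 2L, all(mean_range > 0),
            mean_range[1] <= mean_range[2], dispersion >= 0)
  if (is.null(names(group_sizes)))
    names(group_sizes) <- sprintf("g%02d", seq_along(group_sizes))
  if (!is.null(seed)) set.seed(seed)
  n_samples <- sum(group_sizes)
  mu <- exp(stats::runif(n_genes, log(mean_range[1]), log(mean_range[2])))
  draw <- function(n, m) {
    if (dispersion == 0) stats::rpois(n, m)
    else stats::rnbinom(n, size = 1 / dispersion, mu = m)
  }
  counts <- matrix(draw(n_genes * n_samples, rep(mu, times = n_samples)),
                   nrow = n_genes, ncol = n_samples)
  rownames(counts) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(counts) <- sprintf("sample%04d", seq_len(n_samples))
  states <- rep(names(group_sizes), times = group_sizes)
  list(counts = counts,
       grouping = sample_grouping(colnames(counts), states,
                                  state_order = names(group_sizes)))
}

#' Simulate a feature with known ground-truth specificity
#'
#' Generates one background feature and adds \code{shift} counts to every
#' sample of the target state, yielding a positive control whose true
#' specific state is known. \code{shift = 0} is plain background.
#'
#' @param group_sizes,mean_range,dispersion,seed As in
#'   \code{\link{simulate_counts}}.
#' @param target_state State receiving the shift.
#' @param shift Non-negative count added to the target state's samples.
#'
#' @return List with \code{counts} (1 x samples matrix), \code{grouping},
#'   and \code{target_state}.
#' @export
simulate_specific_gene <- function(group_sizes, target_state, shift,
                                   mean_range = c(0.1, 10), dispersion = 0.5,
                                   seed = NULL) {
  stopifnot(shift >= 0)
  sim <- simulate_counts(1, group_sizes, mean_range, dispersion, seed)
  if (!target_state %in% sim$grouping$states)
    stop("unknown target state: ", target_state)
  f <- .grouping_factor(sim$grouping, colnames(sim$counts))
  sim$counts[1, f == target_state] <- sim$counts[1, f == target_state] + shift
  sim$target_state <- target_state
  sim
}
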