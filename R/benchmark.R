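# One-way ANOVA p-value with a deterministic degenerate rule: a (numerically)
# constant response carries no evidence of a group effect, so p = 1 rather
# than the 0/0 noise aov() would produce.
.anova_p <- function(response, group) {
  if (length(unique(group)) < 2L)
    stop("ANOVA needs at least 2 groups")
  if (stats::var(response) < 1e-20 * max(1, mean(response)^2)) return(1)
  d <- data.frame(response = response, group = factor(group))
  stats::anova(stats::aov(response ~ group, data = d))[["Pr(>F)"]][1]
}

#' Induce artificial specificity in a count matrix
#'
#' Creates known-positive specific features by modifying the entries of the
#' chosen genes in one target state only. In \code{multiply} mode entries
#' are scaled by \code{factor}, so zero counts remain zero and low counts
#' can still overlap the background. In \code{add} mode \code{factor} is
#' added to every targeted entry, which excludes zeros and preserves the
#' variance; \code{variance_factor > 1} additionally inflates the spread of
#' the targeted entries around their post-addition per-gene mean by
#' \eqn{\sqrt{f}} (a mean-preserving map \eqn{v \mapsto m + \sqrt f (v - m)}),
#' clipped at zero and rounded when the input matrix is integral.
#'
#' @param counts Numeric feature x sample matrix.
#' @param grouping A \code{\link{sample_grouping}}.
#' @param genes Character vector of feature ids to modify.
#' @param target_state State whose samples are modified.
#' @param mode \code{"multiply"} or \code{"add"}.
#' @param factor Positive multiplication factor or added constant.
#' @param variance_factor Variance inflation (>= 1), \code{add} mode only.
#'
#' @return The modified count matrix; all other entries untouched.
#' @export
induce_specificity <- function(counts, grouping, genes, target_state,
                               mode = c("multiply", "add"), factor,
                               variance_factor = 1) {
  counts <- .validate_counts(counts)
  mode <- match.arg(mode)
  stopifnot(factor > 0, variance_factor >= 1)
  if (!target_state %in% grouping$states)
    stop("unknown target state: ", target_state)
  bad <- setdiff(genes, rownames(counts))
  if (length(bad)) stop("unknown genes: ", paste(utils::head(bad, 10), collapse = ", "))
  if (mode == "multiply" && variance_factor != 1)
    stop("variance inflation applies to 'add' mode only")
  f <- .grouping_factor(grouping, colnames(counts))
  cols <- which(f == target_state)
  integral <- all(counts == round(counts))
  block <- counts[genes, cols, drop = FALSE]
  if (mode == "multiply") {
    block <- block * factor
  } else {
    block <- block + factor
    if (variance_factor > 1) {
      m <- rowMeans(block)
      block <- m + sqrt(variance_factor) * (block - m)
      block <- pmax(block, 0)
      if (integral) block <- round(block)
    }
  }
  counts[genes, cols] <- block
  counts
}

#' Rank-sum overlap of a feature's target group
#'
#' Ranks all samples by decreasing abundance (rank 1 = highest; ties get the
#' average rank) and sums the ranks of the target-state samples. The minimum
#' \eqn{n_d(n_d+1)/2} is attained when the target group sits strictly above
#' everything else (no distributional overlap); larger sums indicate
#' overlap with the other groups.
#'
#' @param feature_values Per-sample abundances (named by sample id, or in
#'   grouping order).
#' @param grouping A \code{\link{sample_grouping}}.
#' @param target_state The group whose ranks are summed.
#' @return The rank sum (integer, or half-integer under ties).
#' @export
rank_sum_overlap <- function(feature_values, grouping, target_state) {
  if (!target_state %in% grouping$states)
    stop("unknown target state: ", target_state)
  ids <- names(grouping$assignment)
  if (!is.null(names(feature_values))) feature_values <- feature_values[ids]
  f <- .grouping_factor(grouping, ids)
  r <- rank(-as.numeric(feature_values), ties.method = "average")
  sum(r[f == target_state])
}

#' Rank scores so rank 1 is the most specific feature
#'
#' All supported metrics are oriented so that a larger value means more
#' specific; ties receive average ranks and missing values are ranked last
#' (deterministically after every observed score).
#'
#' @param scores Numeric vector of per-feature scores for one metric.
#' @return Numeric vector of ranks (1 = most specific).
#' @export
rank_scores <- function(scores) {
  r <- rank(-scores, ties.method = "average", na.last = "keep")
  if (anyNA(r)) {
    n_ok <- sum(!is.na(r))
    n_na <- sum(is.na(r))
    r[is.na(r)] <- n_ok + (n_na + 1) / 2  # average rank of the NA block
  }
  r
}

# Per-metric score vectors used for ranking: the target-state component for
# the per-tissue metrics, the single value for Gini/Tau/TSI.
.metric_scores <- function(tab, target_state) {
  list(SPECS = tab[[paste0("SPECS_", target_state)]],
       zscore = tab[[paste0("z_", target_state)]],
       JSD = tab[[paste0("JSD_", target_state)]],
       Gini = tab$Gini, Tau = tab$Tau, TSI = tab$TSI)
}

#' Run seeded cycles of the specificity-induction benchmark
#'
#' Per cycle: draw \code{n_induced} genes and a random target state, induce
#' specificity (\code{\link{induce_specificity}}), score every gene with all
#' six metrics, rank each metric over all genes
#' (\code{\link{rank_scores}}), and record the induced genes' score ranks,
#' their expression rank-sum overlaps and each metric's summed rank. Across
#' cycles a one-way ANOVA tests whether the summed ranks differ between
#' metrics. A well-behaved metric gives the induced genes low ranks, hence a
#' low summed rank.
#'
#' @param counts Background feature x sample matrix (no intrinsic signal).
#' @param grouping A \code{\link{sample_grouping}}.
#' @param mode,factor,variance_factor Induction parameters, see
#'   \code{\link{induce_specificity}}.
#' @param n_induced Genes induced per cycle (default 50).
#' @param n_cycles Number of independent cycles (default 5).
#' @param seed Integer seed; expanded into one sub-stream per cycle.
#'
#' @return List with \code{runs} (one record per cycle: target state, genes,
#'   per-metric summed ranks, a tidy per-gene data frame and the cycle
#'   seed), \code{rank_sums} (cycle x metric matrix), \code{anova_p}, and
#'   \code{detail} (all cycles' per-gene rows bound together: cycle, metric,
#'   gene, score, rank, rank_sum_overlap).
#' @export
run_benchmark <- function(counts, grouping, mode = c("multiply", "add"),
                          factor, variance_factor = 1, n_induced = 50,
                          n_cycles = 5, seed = 1) {
  counts <- .validate_counts(counts)
  mode <- match.arg(mode)
  stopifnot(n_induced >= 1, nrow(counts) >= n_induced, n_cycles >= 1)
  set.seed(seed)
  cycle_seeds <- sample.int(.Machine$integer.max, n_cycles)
  metrics <- c("SPECS", "zscore", "JSD", "Gini", "Tau", "TSI")
  runs <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    set.seed(cycle_seeds[cyc])
    genes <- sample(rownames(counts), n_induced)
    target <- sample(grouping$states, 1L)
    induced <- induce_specificity(counts, grouping, genes, target,
                                  mode = mode, factor = factor,
                                  variance_factor = variance_factor)
    tab <- score_all_metrics(induced, grouping)
    per_metric <- .metric_scores(tab, target)
    ranks <- lapply(per_metric, rank_scores)
    idx <- match(genes, tab$gene_id)
    overlap <- vapply(genes, function(g)
      rank_sum_overlap(induced[g, ], grouping, target), numeric(1))
    detail <- do.call(rbind, lapply(metrics, function(m)
      data.frame(cycle = cyc, metric = m, gene = genes,
                 score = per_metric[[m]][idx], rank = ranks[[m]][idx],
                 rank_sum_overlap = unname(overlap),
                 stringsAsFactors = FALSE)))
    rank_sums <- vapply(metrics, function(m) sum(ranks[[m]][idx]), numeric(1))
    runs[[cyc]] <- list(cycle = cyc, target_state = target, genes = genes,
                        rank_sums = rank_sums, detail = detail,
                        seed = cycle_seeds[cyc])
  }
  rs <- t(vapply(runs, `[[`, numeric(length(metrics)), "rank_sums"))
  dimnames(rs) <- list(paste0("cycle", seq_len(n_cycles)), metrics)
  detail <- do.call(rbind, lapply(runs, `[[`, "detail"))
  anova_p <- if (n_cycles >= 2) {
    .anova_p(as.vector(rs), rep(metrics, each = n_cycles))
  } else NA_real_
  list(runs = runs, rank_sums = rs, anova_p = anova_p, detail = detail,
       mode = mode, factor = factor, variance_factor = variance_factor,
       seed = seed)
}

#' Group-size stability of the SPECS score under subsampling
#'
#' Induces specificity by adding \code{constant} counts to \code{n_induced}
#' genes in a randomly chosen target state, then subsamples a fraction of
#' that state's samples (without replacement) over a grid of fractions and
#' recomputes the induced genes' SPECS scores. Repeated for several
#' randomly chosen target states; a one-way ANOVA across fractions tests
#' for a systematic group-size effect (none is expected).
#'
#' @param counts Background feature x sample matrix.
#' @param grouping A \code{\link{sample_grouping}}.
#' @param constant Count added to induce specificity (default 100).
#' @param n_induced Genes induced per repeat (default 50).
#' @param fractions Subsample fractions of the target group (default
#'   0.2, 0.4, ..., 1.0).
#' @param n_repeats Number of repeats with fresh random target states.
#' @param seed Integer seed.
#'
#' @return List with \code{scores} (data frame: repeat, target state,
#'   fraction, gene, SPECS score), \code{anova_p} (score ~ fraction, pooled
#'   over repeats), \code{per_repeat_p} (one score ~ fraction p-value per
#'   repeat), and the configuration.
#' @export
subsample_experiment <- function(counts, grouping, constant = 100,
                                 n_induced = 50,
                                 fractions = seq(0.2, 1, by = 0.2),
                                 n_repeats = 5, seed = 1) {
  counts <- .validate_counts(counts)
  stopifnot(all(fractions > 0), all(fractions <= 1), n_repeats >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_repeats)
  ids <- names(grouping$assignment)
  rows <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(rep_seeds[r])
    genes <- sample(rownames(counts), n_induced)
    target <- sample(grouping$states, 1L)
    induced <- induce_specificity(counts, grouping, genes, target,
                                  mode = "add", factor = constant)
    target_ids <- ids[grouping$assignment[ids] == target]
    for (fr in fractions) {
      keep_n <- round(fr * length(target_ids))
      if (keep_n < 2)
        stop("fraction ", fr, " leaves fewer than 2 samples in group '",
             target, "'")
      keep <- if (fr == 1) target_ids else sample(target_ids, keep_n)
      sub_ids <- c(setdiff(ids, target_ids), keep)
      sub_grp <- sample_grouping(sub_ids, grouping$assignment[sub_ids],
                                 state_order = grouping$states)
      sc <- specs_scores(induced[genes, sub_ids, drop = FALSE], sub_grp)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, target_state = target, fraction = fr, gene = genes,
        score = sc[, target], stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  anova_p <- if (length(fractions) >= 2) {
    .anova_p(scores$score, scores$fraction)
  } else NA_real_
  per_repeat_p <- if (length(fractions) >= 2) {
    vapply(split(scores, scores$rep),
           function(x) .anova_p(x$score, x$fraction), numeric(1))
  } else rep(NA_real_, n_repeats)
  list(scores = scores, anova_p = anova_p, per_repeat_p = per_repeat_p,
       constant = constant, fractions = fractions, seed = seed)
}

#' Fold change of the specific state over the runner-up state
#'
#' Ratio of the specific state's profile value to the largest value among
#' the remaining states, with a pseudocount added to numerator and
#' denominator to keep the ratio finite for states with zero expression.
#'
#' @param profile Named numeric per-state profile.
#' @param specific_state The state of interest.
#' @param pseudocount Non-negative constant added to both terms (default 0).
#' @return Positive fold change; values below 1 mean the specific state is
#'   not the top-expressed state.
#' @export
fold_change_to_second <- function(profile, specific_state, pseudocount = 0) {
  profile <- .check_profile(profile)
  if (!specific_state %in% names(profile))
    stop("unknown state: ", specific_state)
  stopifnot(pseudocount >= 0)
  rest <- profile[setdiff(names(profile), specific_state)]
  (profile[[specific_state]] + pseudocount) / (max(rest) + pseudocount)
}
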