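#' Collapse a feature to a per-state mean profile
#'
#' The classical specificity metrics (z-score, Gini, Tau, TSI, JSD) operate
#' on one summary value per tissue; replicates are collapsed by the
#' arithmetic mean.
#'
#' @param counts Numeric feature x sample matrix (see \code{\link{specs_scores}}).
#' @param grouping A \code{\link{sample_grouping}}.
#' @param gene Feature id (rowname) to collapse.
#'
#' @return Named numeric vector of per-state means, in state order.
#' @export
collapse_to_profile <- function(counts, grouping, gene) {
  counts <- .validate_counts(counts)
  if (!gene %in% rownames(counts)) stop("unknown gene: ", gene)
  f <- .grouping_factor(grouping, colnames(counts))
  y <- counts[gene, ]
  vapply(split(y, f), mean, numeric(1))[grouping$states]
}

# Per-state mean profiles for all features at once (features x states).
.profile_matrix <- function(counts, grouping) {
  f <- .grouping_factor(grouping, colnames(counts))
  prof <- vapply(grouping$states,
                 function(s) rowMeans(counts[, f == s, drop = FALSE]),
                 numeric(nrow(counts)))
  if (nrow(counts) == 1L)
    prof <- matrix(prof, nrow = 1L, dimnames = list(rownames(counts), grouping$states))
  prof
}

.check_profile <- function(profile) {
  if (!is.numeric(profile) || length(profile) < 2L)
    stop("a profile needs at least 2 states")
  if (!all(is.finite(profile)) || any(profile < 0))
    stop("profile values must be finite and non-negative")
  profile
}

#' Z-score specificity per state
#'
#' Standardizes the per-state profile: \eqn{z_i = (x_i - \mu) / \sigma}. A
#' constant profile has \eqn{\sigma = 0} and yields \code{NA} for every
#' state rather than an error.
#'
#' @param profile Named numeric per-state profile.
#' @param sd_denominator \code{"sample"} (n - 1, default) or
#'   \code{"population"} (n).
#' @return Numeric vector of z-scores (NA when the profile is constant).
#' @export
zscore <- function(profile, sd_denominator = c("sample", "population")) {
  profile <- .check_profile(profile)
  sd_denominator <- match.arg(sd_denominator)
  n <- length(profile)
  mu <- mean(profile)
  s <- stats::sd(profile)
  if (sd_denominator == "population") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0)
    return(stats::setNames(rep(NA_real_, n), names(profile)))
  (profile - mu) / s
}

#' Gini coefficient of a tissue profile
#'
#' \eqn{Gini = (n+1)/n - 2 \sum_i (n+1-i) x_{(i)} / (n \sum_i x_i)} with the
#' values sorted ascending. 0 for a uniform profile, \eqn{(n-1)/n} for a
#' one-hot profile; \code{NA} when all values are zero.
#'
#' @param profile Named numeric per-state profile.
#' @return Gini coefficient in [0, (n-1)/n], or NA.
#' @export
gini <- function(profile) {
  profile <- .check_profile(profile)
  n <- length(profile)
  tot <- sum(profile)
  if (tot <= 0) return(NA_real_)
  x <- sort(profile)
  (n + 1) / n - 2 * sum((n + 1 - seq_len(n)) * x) / (n * tot)
}

#' Tau specificity index
#'
#' \eqn{\tau = \sum_i (1 - \hat x_i) / (n - 1)} with
#' \eqn{\hat x_i = x_i / \max_j x_j}. 1 for a one-hot profile, 0 for a
#' uniform one; \code{NA} when all values are zero.
#'
#' @param profile Named numeric per-state profile.
#' @return Tau in [0, 1], or NA.
#' @export
tau <- function(profile) {
  profile <- .check_profile(profile)
  mx <- max(profile)
  if (mx <= 0) return(NA_real_)
  sum(1 - profile / mx) / (length(profile) - 1)
}

#' Tissue specificity index (TSI)
#'
#' \eqn{TSI = \max_i x_i / \sum_i x_i}: 1 for a one-hot profile, \eqn{1/n}
#' for a uniform one; \code{NA} when all values are zero.
#'
#' @param profile Named numeric per-state profile.
#' @return TSI in (0, 1], or NA.
#' @export
tsi <- function(profile) {
  profile <- .check_profile(profile)
  tot <- sum(profile)
  if (tot <= 0) return(NA_real_)
  max(profile) / tot
}

# Shannon entropy in bits; 0 * log(0) taken as 0.
.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon distance specificity score
#'
#' The profile is normalized to a probability vector p and compared against
#' the idealized one-hot pattern \eqn{e^t} that is expressed in the target
#' state only: \eqn{score = 1 - \sqrt{JS(p, e^t)}} with
#' \eqn{JS(a, b) = H((a+b)/2) - (H(a) + H(b))/2} and base-2 entropy, so the
#' score lies in [0, 1]. The per-feature specificity summary is the maximum
#' over target states.
#'
#' @param profile Named numeric per-state profile.
#' @param target_state State to compare against; \code{NULL} returns the
#'   vector of per-state scores.
#' @return A score in [0, 1] (or a per-state vector), NA for an all-zero
#'   profile.
#' @export
jsd_score <- function(profile, target_state = NULL) {
  profile <- .check_profile(profile)
  tot <- sum(profile)
  n <- length(profile)
  if (tot <= 0) {
    out <- stats::setNames(rep(NA_real_, n), names(profile))
    return(if (is.null(target_state)) out else out[[target_state]])
  }
  p <- profile / tot
  hp <- .entropy2(p)
  score_one <- function(t) {
    m <- p / 2
    m[t] <- m[t] + 0.5
    js <- .entropy2(m) - hp / 2  # H(e^t) = 0 for a point mass
    1 - sqrt(max(js, 0))
  }
  out <- vapply(seq_len(n), score_one, numeric(1))
  names(out) <- names(profile)
  if (is.null(target_state)) out else {
    if (!target_state %in% names(profile)) stop("unknown state: ", target_state)
    out[[target_state]]
  }
}

#' All specificity metrics for every feature
#'
#' Computes SPECS on the raw replicates and the five profile-based
#' comparators on mean-collapsed per-state profiles, returning one row per
#' feature. Missing values (all-zero or constant profiles) are propagated as
#' NA, never silently zeroed.
#'
#' @param counts Numeric feature x sample matrix.
#' @param grouping A \code{\link{sample_grouping}}.
#' @param prevalences Passed to \code{\link{specs_scores}}.
#'
#' @return A data frame with columns \code{gene_id}, \code{SPECS_<state>}
#'   and \code{z_<state>} and \code{JSD_<state>} for every state,
#'   \code{JSD_max}, \code{Gini}, \code{Tau}, \code{TSI}.
#' @export
score_all_metrics <- function(counts, grouping, prevalences = NULL) {
  counts <- .validate_counts(counts)
  sp <- specs_scores(counts, grouping, prevalences)
  prof <- .profile_matrix(counts, grouping)
  z <- t(apply(prof, 1L, zscore))
  jsd <- t(apply(prof, 1L, jsd_score))
  if (nrow(counts) == 1L) {  # apply() drops single rows
    z <- matrix(z, nrow = 1L); jsd <- matrix(jsd, nrow = 1L)
  }
  st <- grouping$states
  out <- data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  out[paste0("SPECS_", st)] <- as.data.frame(sp)
  out[paste0("z_", st)] <- as.data.frame(z)
  out[paste0("JSD_", st)] <- as.data.frame(jsd)
  out$JSD_max <- suppressWarnings(apply(jsd, 1L, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)))
  out$Gini <- apply(prof, 1L, gini)
  out$Tau <- apply(prof, 1L, tau)
  out$TSI <- apply(prof, 1L, tsi)
  rownames(out) <- NULL
  out
}
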