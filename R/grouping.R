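#' Construct a sample grouping
#'
#' Maps each sample to exactly one state (e.g. a tissue type) and fixes the
#' state order used by all downstream score matrices.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param states Character vector (or factor) of state labels, one per sample.
#' @param state_order Optional character vector giving the ordering of the
#'   distinct states; defaults to order of first appearance.
#'
#' @return An object of class \code{sample_grouping}: a list with elements
#'   \code{assignment} (named character vector sample -> state),
#'   \code{states} (ordered distinct labels) and \code{sizes} (named integer
#'   vector of per-state sample counts).
#' @export
#' @examples
#' grp <- sample_grouping(paste0("s", 1:6), rep(c("liver", "brain"), each = 3))
#' grp$sizes
sample_grouping <- function(sample_ids, states, state_order = NULL) {
  sample_ids <- as.character(sample_ids)
  states <- as.character(states)
  if (length(sample_ids) != length(states))
    stop("'sample_ids' and 'states' must have the same length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(sample_ids) || anyNA(states))
    stop("sample ids and states must not contain missing values")
  uniq <- unique(states)
  if (is.null(state_order)) {
    state_order <- uniq
  } else {
    state_order <- as.character(state_order)
    if (!setequal(state_order, uniq))
      stop("'state_order' must contain exactly the observed states")
  }
  if (length(state_order) < 2L)
    stop("at least 2 states are required, got ", length(state_order))
  assignment <- stats::setNames(states, sample_ids)
  sizes <- stats::setNames(
    vapply(state_order, function(s) sum(states == s), integer(1)), state_order)
  structure(
    list(assignment = assignment, states = state_order, sizes = sizes),
    class = "sample_grouping")
}

#' @export
print.sample_grouping <- function(x, ...) {
  cat("sample_grouping:", length(x$assignment), "samples in",
      length(x$states), "states\n")
  print(x$sizes)
  invisible(x)
}

# Factor of states (levels in state order) aligned to `sample_ids`.
.grouping_factor <- function(grouping, sample_ids) {
  stopifnot(inherits(grouping, "sample_grouping"))
  miss <- setdiff(sample_ids, names(grouping$assignment))
  if (length(miss))
    stop("samples absent from grouping: ", paste(utils::head(miss, 10), collapse = ", "))
  factor(grouping$assignment[sample_ids], levels = grouping$states)
}

#' Prevalence weights over states
#'
#' Per-state weights pi_d used by the SPECS score. In equilibrated mode every
#' state receives the same weight, which removes the influence of unbalanced
#' sample sizes; alternatively population prevalences can be supplied.
#'
#' @param grouping A \code{\link{sample_grouping}}.
#' @param weights Either \code{NULL} / \code{"equilibrated"} for equal
#'   weights, or a named non-negative numeric vector covering every state
#'   (it is normalized to sum to one).
#'
#' @return Named numeric vector of weights in state order, summing to 1.
#' @export
prevalence_weights <- function(grouping, weights = NULL) {
  stopifnot(inherits(grouping, "sample_grouping"))
  m <- length(grouping$states)
  if (is.null(weights) || identical(weights, "equilibrated"))
    return(stats::setNames(rep(1 / m, m), grouping$states))
  if (is.null(names(weights)))
    stop("'weights' must be named by state")
  miss <- setdiff(grouping$states, names(weights))
  if (length(miss))
    stop("missing prevalence for states: ", paste(miss, collapse = ", "))
  w <- as.numeric(weights[grouping$states])
  if (anyNA(w) || any(w < 0) || !all(is.finite(w)))
    stop("prevalences must be finite and non-negative")
  if (sum(w) <= 0) stop("prevalences must not all be zero")
  stats::setNames(w / sum(w), grouping$states)
}
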