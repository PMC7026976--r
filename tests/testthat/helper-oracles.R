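# Brute-force oracles and small fixture builders shared across tests.
# The oracles deliberately use the O(n^2) double sum so they stay
# independent of the rank-based implementation they validate.

# P{Y_k < Y_d} by enumerating all ordered pairs.
brute_pairwise <- function(values_k, values_d) {
  mean(outer(values_k, values_d, "<"))
}

# SPECS score by the double sum, equilibrated or weighted.
brute_specs <- function(feature_values, grouping, target_state,
                        prevalences = NULL) {
  ids <- names(grouping$assignment)
  if (!is.null(names(feature_values))) feature_values <- feature_values[ids]
  by_state <- split(as.numeric(feature_values), grouping$assignment[ids])
  others <- setdiff(grouping$states, target_state)
  pi <- if (is.null(prevalences)) {
    setNames(rep(1 / length(others), length(others)), others)
  } else {
    w <- prevalences[others]
    w / sum(w)
  }
  sum(vapply(others, function(k)
    brute_pairwise(by_state[[k]], by_state[[target_state]]) * pi[[k]],
    numeric(1)))
}

# Tiny three-group fixture used across modules.
toy_grouping <- function() {
  sample_grouping(paste0("s", 1:6), rep(c("A", "B", "C"), each = 2))
}

toy_counts <- function() {
  m <- rbind(
    up_in_A   = c(5, 6, 1, 2, 3, 4),
    flat      = c(2, 2, 2, 2, 2, 2),
    absent_A  = c(0, 0, 3, 5, 2, 7))
  colnames(m) <- paste0("s", 1:6)
  m
}

# Random instance for oracle-equivalence loops: <= 5 groups, <= 30 samples,
# counts drawn with heavy ties to exercise the strict-inequality handling.
random_instance <- function() {
  m <- sample(2:5, 1)
  sizes <- sample(2:7, m, replace = TRUE)
  n <- sum(sizes)
  y <- sample(0:6, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
  grp <- sample_grouping(paste0("s", seq_len(n)),
                         rep(LETTERS[seq_len(m)], times = sizes))
  list(values = setNames(y, paste0("s", seq_len(n))), grouping = grp)
}
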