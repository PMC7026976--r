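#' Read a feature x sample abundance matrix
#'
#' Supports two plain-text dialects: \code{tsv} (header row of sample ids,
#' first column feature ids) and \code{gct} (GCT v1.2: a "#1.2" line, a
#' dimensions line, then a header with Name and Description columns; the
#' Description column is dropped). Matrix orientation is fixed as
#' features-in-rows; a transposed file is rejected, never auto-detected.
#' Comment lines starting with '#' before the header are skipped in tsv
#' mode.
#'
#' @param path File path.
#' @param dialect \code{"tsv"} (default) or \code{"gct"}.
#' @return Validated numeric matrix with feature rownames, sample colnames.
#' @export
read_count_matrix <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  skip <- 0L
  if (dialect == "gct") {
    head2 <- readLines(path, n = 2L)
    if (length(head2) < 2L || !startsWith(head2[1], "#1.2"))
      stop(path, ": not a GCT v1.2 file (missing '#1.2' header)")
    skip <- 2L
  }
  df <- utils::read.delim(path, skip = skip, header = TRUE,
                          check.names = FALSE, comment.char = if (dialect == "tsv") "#" else "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(path, ": expected a feature-id column plus samples")
  if (dialect == "gct") {
    if (!identical(tolower(names(df)[1:2]), c("name", "description")))
      stop(path, ": GCT header must start with Name and Description columns")
    ids <- as.character(df[[1L]])
    df <- df[, -(1:2), drop = FALSE]
  } else {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (anyDuplicated(ids))
    stop(path, ": duplicate feature ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v))
        stop(path, ": non-numeric value in column '", names(df)[j],
             "' (first at data line ",
             which(is.na(vn) & !is.na(v))[1], ")")
      df[[j]] <- vn
    }
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(path, ": negative or non-finite value at feature '",
         ids[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]], "'")
  .validate_counts(m)
}

#' Read a sample annotation table
#'
#' Tab-delimited with columns \code{sample_id} and \code{state}. When a
#' count matrix is supplied, annotation samples absent from the matrix are
#' reported with a warning; states with a single sample are accepted with a
#' warning (the score tolerates n = 1 groups).
#'
#' @param path File path.
#' @param counts Optional count matrix to cross-check sample ids against.
#' @return A \code{\link{sample_grouping}}.
#' @export
read_annotation <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "state")
  if (!all(need %in% names(df)))
    stop(path, ": annotation needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop(path, ": duplicate sample rows: ",
         paste(utils::head(unique(df$sample_id[duplicated(df$sample_id)]), 5),
               collapse = ", "))
  if (!is.null(counts)) {
    extra <- setdiff(df$sample_id, colnames(counts))
    if (length(extra))
      warning(length(extra), " annotated sample(s) absent from the matrix: ",
              paste(utils::head(extra, 10), collapse = ", "))
  }
  grp <- sample_grouping(df$sample_id, df$state)
  singletons <- names(grp$sizes)[grp$sizes == 1L]
  if (length(singletons))
    warning("state(s) with a single sample: ",
            paste(singletons, collapse = ", "))
  grp
}

#' Read a prevalence table
#'
#' Tab-delimited with columns \code{state} and \code{weight}.
#'
#' @param path File path.
#' @return Named numeric vector of weights.
#' @export
read_prevalences <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("state", "weight") %in% names(df)))
    stop(path, ": prevalence table needs columns state, weight")
  stats::setNames(as.numeric(df$weight), df$state)
}

.provenance_header <- function(seed = NULL, thresholds = NULL) {
  lines <- c(
    paste0("# specs version ",
           as.character(utils::packageVersion("specs"))),
    paste0("# date ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  if (!is.null(seed)) lines <- c(lines, paste0("# seed ", seed))
  if (!is.null(thresholds))
    lines <- c(lines, paste0("# thresholds upper=", thresholds[["upper"]],
                             " lower=", thresholds[["lower"]]))
  lines
}

#' Write a score matrix (and optionally labels) to TSV
#'
#' Scores are written with 6 decimal places, states in grouping order, with
#' '#'-prefixed provenance header lines (package version, seed,
#' thresholds). When given a classified \code{specs_result} and a
#' \code{labels_path}, a second TSV with one row per (gene, state,
#' direction) is written.
#'
#' @param result A score matrix or a \code{specs_result} from
#'   \code{\link{classify_features}}.
#' @param path Output path for the score TSV.
#' @param labels_path Optional output path for the labels TSV.
#' @param seed Seed to record in the provenance header.
#' @return Invisibly, \code{path}.
#' @export
write_scores <- function(result, path, labels_path = NULL, seed = NULL) {
  if (inherits(result, "specs_result")) {
    scores <- result$scores
    thresholds <- result$thresholds
    labels <- result$labels
  } else {
    scores <- result
    thresholds <- NULL
    labels <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(.provenance_header(seed, thresholds), con)
  writeLines(paste(c("gene_id", colnames(scores)), collapse = "\t"), con)
  if (nrow(scores))
    writeLines(paste(rownames(scores),
                     apply(scores, 1L, function(v)
                       paste(formatC(v, digits = 6, format = "f"),
                             collapse = "\t")),
                     sep = "\t"), con)
  if (!is.null(labels_path)) {
    if (is.null(labels)) stop("labels requested but 'result' carries none")
    lcon <- file(labels_path, "w")
    on.exit(close(lcon), add = TRUE)
    writeLines(.provenance_header(seed, thresholds), lcon)
    writeLines("gene_id\tstate\tdirection", lcon)
    if (nrow(labels))
      writeLines(paste(labels$gene_id, labels$state, labels$direction,
                       sep = "\t"), lcon)
  }
  invisible(path)
}

#' Write a count matrix in the tsv dialect
#'
#' @param counts Feature x sample matrix.
#' @param path Output path.
#' @param id_column Header name of the feature-id column.
#' @return Invisibly, \code{path}.
#' @export
write_count_matrix <- function(counts, path, id_column = "gene_id") {
  counts <- .validate_counts(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample annotation table
#'
#' @param grouping A \code{\link{sample_grouping}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_annotation <- function(grouping, path) {
  stopifnot(inherits(grouping, "sample_grouping"))
  df <- data.frame(sample_id = names(grouping$assignment),
                   state = unname(grouping$assignment),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
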