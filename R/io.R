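#' Construct a sample x fungal-OTU count matrix
#'
#' @param x numeric matrix (samples in rows, fungal OTUs in columns) with
#'   unique row and column names and non-negative integer entries.
#' @param state `"raw"` for as-sequenced read counts, `"rarefied"` after
#'   subsampling to a common depth (every row sum then equals that depth).
#' @return a `count_matrix` object (a matrix with a `state` attribute).
#' @export
count_matrix <- function(x, state = c("raw", "rarefied")) {
  state <- match.arg(state)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("counts must be numeric", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count matrix needs sample (row) and OTU (column) names", call. = FALSE)
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup) > 0) {
    stop("duplicate sample IDs: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup) > 0) {
    stop("duplicate OTU IDs: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative count for sample '", rownames(x)[neg[1, 1]],
         "', OTU '", colnames(x)[neg[1, 2]], "'", call. = FALSE)
  }
  if (any(x != floor(x))) stop("counts must be integers", call. = FALSE)
  structure(x, state = state, class = c("count_matrix", class(matrix())))
}

#' @rdname count_matrix
#' @param counts a `count_matrix`.
#' @export
matrix_state <- function(counts) attr(counts, "state")

#' Read / write a sample x OTU count table (TSV)
#'
#' Tables are tab-delimited UTF-8 with the sample ID in the first column and
#' one column per fungal OTU.
#'
#' @param path file path.
#' @param state state flag to attach, see [count_matrix()].
#' @return `read_count_matrix()` returns a [count_matrix()];
#'   `write_count_matrix()` invisibly returns `path`.
#' @export
read_count_matrix <- function(path, state = c("raw", "rarefied")) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  count_matrix(m, state = match.arg(state))
}

#' @rdname read_count_matrix
#' @param counts a [count_matrix()].
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), unclass(counts),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Host clustering levels
#'
#' Host plants are clustered from their barcode sequences at four nested
#' similarity cutoffs; `"99.8"` is the finest partition and `"97"` the
#' coarsest.
#'
#' @return character vector of level labels, fine to coarse.
#' @export
host_levels <- function() c("99.8", "99", "98", "97")

host_level_col <- function(level) {
  level <- as.character(level)
  if (!level %in% host_levels()) {
    stop("unknown host clustering level '", level, "'; expected one of ",
         paste(host_levels(), collapse = ", "), call. = FALSE)
  }
  paste0("plant_otu_", level)
}

#' Validate and classify a host assignment table
#'
#' A host assignment maps each root sample to a plant OTU at each of the four
#' nested clustering levels, with the host family and a dipterocarp flag.
#' Partitions must be nested: every fine-level plant OTU maps to exactly one
#' plant OTU at each coarser level.
#'
#' @param df data frame with columns `sample_id`, `plant_otu_99.8`,
#'   `plant_otu_99`, `plant_otu_98`, `plant_otu_97`, `family`,
#'   `is_dipterocarp`.
#' @return the validated data frame with class `host_assignment`.
#' @export
host_assignment <- function(df) {
  need <- c("sample_id", paste0("plant_otu_", host_levels()),
            "family", "is_dipterocarp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("host table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample IDs in host table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  lv <- host_levels()
  for (k in seq_len(length(lv) - 1)) {
    fine <- df[[host_level_col(lv[k])]]
    coarse <- df[[host_level_col(lv[k + 1])]]
    n_parents <- tapply(coarse, fine, function(z) length(unique(z)))
    bad <- names(n_parents)[n_parents > 1]
    if (length(bad) > 0) {
      stop("nesting violation: plant OTU '", bad[1], "' at level ", lv[k],
           " maps to multiple OTUs at level ", lv[k + 1], call. = FALSE)
    }
  }
  if (!is.logical(df$is_dipterocarp)) {
    df$is_dipterocarp <- as.logical(df$is_dipterocarp)
  }
  if (anyNA(df$is_dipterocarp)) {
    stop("is_dipterocarp flags contain NA", call. = FALSE)
  }
  class(df) <- c("host_assignment", "data.frame")
  df
}

#' @rdname host_assignment
#' @param path TSV file path.
#' @export
read_hosts <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  host_assignment(df)
}

#' @rdname host_assignment
#' @param hosts a `host_assignment`.
#' @export
write_hosts <- function(hosts, path) {
  write.table(as.data.frame(hosts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / validate a square distance matrix (TSV)
#'
#' Distance files are square tab-delimited tables with matching row and
#' column labels. Matrices must be symmetric, non-negative, and have a zero
#' diagonal; violations raise errors naming the offending pair.
#'
#' @param path file path.
#' @param kind free-text label (`"genetic"`, `"geographic"`, `"community"`).
#' @return numeric matrix with a `kind` attribute.
#' @export
read_distance <- function(path, kind = "genetic") {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  m <- validate_distance(m, name = paste(kind, "distance matrix"))
  attr(m, "kind") <- kind
  m
}

#' @rdname read_distance
#' @param d distance matrix.
#' @export
write_distance <- function(d, path) {
  df <- data.frame(id = rownames(d), as.data.frame(unclass(d)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
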