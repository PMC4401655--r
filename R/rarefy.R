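#' Rarefy a raw count matrix to a common depth
#'
#' Each retained sample is an exact without-replacement subsample of its
#' reads down to `depth`; samples whose total read count is below `depth`
#' are dropped and listed. A sample with exactly `depth` reads is returned
#' unchanged.
#'
#' Seeding policy: when `seed` is given, sample `i` (by its position in the
#' input matrix) is subsampled under seed `seed + i`, so any single sample
#' can be re-rarefied reproducibly in isolation.
#'
#' @param counts a raw [count_matrix()].
#' @param depth rarefaction depth (reads per sample); default 100.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return list with `counts` (a rarefied [count_matrix()]) and `dropped`
#'   (IDs of removed samples).
#' @export
rarefy <- function(counts, depth = 100, seed = NULL) {
  if (!inherits(counts, "count_matrix") || matrix_state(counts) != "raw") {
    stop("rarefy() expects a raw count_matrix", call. = FALSE)
  }
  if (depth <= 0) stop("rarefaction depth must be positive", call. = FALSE)
  rs <- rowSums(counts)
  keep <- which(rs >= depth)
  dropped <- rownames(counts)[rs < depth]
  out <- matrix(0L, length(keep), ncol(counts),
                dimnames = list(rownames(counts)[keep], colnames(counts)))
  for (r in seq_along(keep)) {
    i <- keep[r]
    x <- counts[i, ]
    if (rs[i] == depth) {
      out[r, ] <- as.integer(x)
      next
    }
    if (!is.null(seed)) set.seed((seed + i) %% .Machine$integer.max)
    reads <- rep.int(seq_along(x), x)
    out[r, ] <- tabulate(reads[sample.int(length(reads), depth)],
                         nbins = length(x))
  }
  list(counts = count_matrix(out, "rarefied"), dropped = dropped)
}

#' Convert a rarefied count matrix to presence/absence
#'
#' Thresholds rarefied counts at >= 1 read. Fungal OTUs absent from every
#' retained sample are dropped and recorded in the `dropped_otus` attribute
#' so they do not inflate downstream OTU counts. Applying the conversion to
#' its own output is the identity.
#'
#' @param counts a rarefied [count_matrix()] (raw input is an error), or an
#'   existing `occurrence_matrix` (returned unchanged).
#' @return binary `occurrence_matrix` (samples x fungal OTUs).
#' @export
to_presence_absence <- function(counts) {
  if (inherits(counts, "occurrence_matrix")) return(counts)
  if (!inherits(counts, "count_matrix")) {
    stop("to_presence_absence() expects a count_matrix", call. = FALSE)
  }
  if (matrix_state(counts) != "rarefied") {
    stop("to_presence_absence() requires rarefied counts; call rarefy() first",
         call. = FALSE)
  }
  occ <- (unclass(counts) >= 1) * 1L
  zero <- colSums(occ) == 0
  out <- occ[, !zero, drop = FALSE]
  structure(out, dropped_otus = colnames(occ)[zero],
            class = c("occurrence_matrix", class(matrix())))
}

#' @rdname to_presence_absence
#' @param x binary matrix (samples x OTUs) to mark as an occurrence matrix.
#' @export
occurrence_matrix <- function(x) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("occurrence matrix must be binary",
                                 call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("occurrence matrix needs sample and OTU names", call. = FALSE)
  }
  structure(x, class = c("occurrence_matrix", class(matrix())))
}

#' Build a plant x fungal association matrix at a clustering level
#'
#' Aggregates the sample-level occurrence matrix by host plant OTU at the
#' requested clustering level: entry `y[i, j]` is the number of samples
#' assigned to plant OTU `j` in which fungal OTU `i` is present. The margins
#' `T_j` (samples per plant OTU) and `N_i` (total occurrences per fungal
#' OTU) are carried as attributes; fungal OTUs with `N_i = 0` are dropped.
#'
#' @param occ an occurrence matrix (samples x fungal OTUs).
#' @param hosts a [host_assignment()] covering the samples.
#' @param level clustering level, one of [host_levels()].
#' @return `association_matrix`: fungal OTU x plant OTU integer matrix with
#'   attributes `T` (named, samples per plant OTU), `N` (named, per fungal
#'   OTU), `level`, and `dropped_otus`.
#' @export
build_association <- function(occ, hosts, level = "99.8") {
  col <- host_level_col(level)
  idx <- match(rownames(occ), hosts$sample_id)
  if (anyNA(idx)) {
    stop("sample '", rownames(occ)[which(is.na(idx))[1]],
         "' has no host label at level ", level, call. = FALSE)
  }
  labels <- hosts[[col]][idx]
  if (anyNA(labels)) {
    stop("sample '", rownames(occ)[which(is.na(labels))[1]],
         "' has no host label at level ", level, call. = FALSE)
  }
  y <- t(rowsum(unclass(occ), group = labels))
  Tj <- as.integer(table(labels)[colnames(y)])
  names(Tj) <- colnames(y)
  Ni <- rowSums(y)
  dropped <- rownames(y)[Ni == 0]
  y <- y[Ni > 0, , drop = FALSE]
  storage.mode(y) <- "integer"
  structure(y, T = Tj, N = rowSums(y), level = as.character(level),
            dropped_otus = dropped,
            class = c("association_matrix", class(matrix())))
}

#' @rdname build_association
#' @param assoc an `association_matrix`.
#' @param min_n minimum total occurrence count `N_i` for a fungal OTU to be
#'   retained for preference modelling (the customary display threshold is
#'   5 occurrences).
#' @export
filter_min_occurrences <- function(assoc, min_n = 5) {
  keep <- attr(assoc, "N") >= min_n
  y <- unclass(assoc)[keep, , drop = FALSE]
  structure(y, T = attr(assoc, "T"), N = rowSums(y),
            level = attr(assoc, "level"),
            dropped_otus = c(attr(assoc, "dropped_otus"),
                             rownames(assoc)[!keep]),
            class = c("association_matrix", class(matrix())))
}

#' Sample-based OTU accumulation curve
#'
#' Expected OTU richness as a function of the number of samples, with a 95%
#' confidence band (mean +/- 1.96 sd). The exact method uses the analytic
#' sample-based rarefaction estimator
#' \eqn{E[S(t)] = \sum_k (1 - C(M - m_k, t) / C(M, t))} (equal to the
#' average over all sample orderings); the random method averages `n_perm`
#' random orderings.
#'
#' @param occ occurrence matrix (samples x fungal OTUs).
#' @param subset optional character vector of OTU IDs (e.g. one phylum, or
#'   the ECM Basidiomycota) to restrict the curve to.
#' @param method `"exact"` or `"random"`.
#' @param n_perm number of orderings for the random method.
#' @param seed RNG seed for the random method.
#' @return data frame with columns `sites`, `richness`, `sd`, `lower`,
#'   `upper`.
#' @export
accumulation_curve <- function(occ, subset = NULL,
                               method = c("exact", "random"),
                               n_perm = 100, seed = NULL) {
  method <- match.arg(method)
  if (nrow(occ) < 1) stop("need at least one sample", call. = FALSE)
  m <- unclass(occ)
  if (!is.null(subset)) {
    miss <- setdiff(subset, colnames(m))
    if (length(miss) > 0) {
      stop("OTUs not in matrix: ", paste(utils::head(miss, 3), collapse = ", "),
           call. = FALSE)
    }
    m <- m[, subset, drop = FALSE]
  }
  sa <- with_seed(seed, vegan::specaccum(m, method = method,
                                         permutations = n_perm))
  sdv <- sa$sd %||% rep(0, length(sa$richness))
  data.frame(sites = sa$sites, richness = as.numeric(sa$richness),
             sd = as.numeric(sdv),
             lower = as.numeric(sa$richness) - 1.96 * as.numeric(sdv),
             upper = as.numeric(sa$richness) + 1.96 * as.numeric(sdv))
}
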