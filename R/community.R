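#' Pool sample-level occurrences by plant OTU
#'
#' Collapses the sample x fungal-OTU occurrence matrix to community units
#' (plant OTUs at a clustering level): a fungal OTU is present in a unit
#' when it occurs in at least one of the unit's samples.
#'
#' @param occ occurrence matrix (samples x fungal OTUs).
#' @param hosts a [host_assignment()].
#' @param level clustering level, one of [host_levels()].
#' @param min_samples drop units represented by fewer samples.
#' @return binary unit x fungal-OTU matrix with an `n_samples` attribute.
#' @export
pool_by_plant_otu <- function(occ, hosts, level = "99.8", min_samples = 1) {
  col <- host_level_col(level)
  idx <- match(rownames(occ), hosts$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from host table", call. = FALSE)
  }
  labels <- hosts[[col]][idx]
  m <- (rowsum(unclass(occ), group = labels) > 0) * 1L
  n_samp <- as.integer(table(labels)[rownames(m)])
  keep <- n_samp >= min_samples
  structure(m[keep, , drop = FALSE],
            n_samples = stats::setNames(n_samp[keep], rownames(m)[keep]))
}

#' Raup-Crick null-model beta-diversity
#'
#' Probability-scaled community dissimilarity between units, comparing the
#' observed number of shared fungal OTUs of each pair to a null in which
#' each unit's OTU richness is preserved and OTUs are drawn without
#' replacement with probability proportional to their occurrence frequency
#' across units. With ties counted half, the dissimilarity is
#' `1 - (#\{null shared < observed\} + 0.5 #\{ties\}) / n_null`, so pairs
#' sharing more OTUs than expected under the null score below 0.5.
#'
#' The null model is the occurrence-frequency-weighted, richness-preserving
#' construction (the "r1"-style null): by default OTU weights are the
#' observed occurrence frequencies across units, and each null community
#' redraws a unit's OTUs without replacement with those weights. A custom
#' `freq` vector substitutes a known generating frequency profile (e.g. for
#' calibration studies against the null itself).
#'
#' @param units binary unit x fungal-OTU matrix (e.g. from
#'   [pool_by_plant_otu()]); at least 2 units, each with at least one OTU.
#' @param n_null number of null communities.
#' @param seed RNG seed.
#' @param freq optional per-OTU sampling weights for the null (default:
#'   observed occurrence frequencies).
#' @return `dist` of dissimilarities in \[0, 1\].
#' @export
raup_crick <- function(units, n_null = 999, seed = NULL, freq = NULL) {
  m <- as.matrix(units)
  if (!all(m %in% c(0, 1))) stop("units matrix must be binary", call. = FALSE)
  if (nrow(m) < 2) stop("need at least two units", call. = FALSE)
  empty <- rowSums(m) == 0
  if (any(empty)) {
    stop("unit '", rownames(m)[which(empty)[1]], "' contains no OTUs",
         call. = FALSE)
  }
  U <- nrow(m); S <- ncol(m)
  f <- freq %||% colSums(m)
  if (length(f) != S || any(f < 0)) {
    stop("freq must give a non-negative weight per OTU", call. = FALSE)
  }
  richness <- rowSums(m)
  if (any(richness > sum(f > 0))) {
    stop("unit richness exceeds the OTU pool available to the null",
         call. = FALSE)
  }
  obs <- tcrossprod(m)
  less <- matrix(0, U, U)
  ties <- matrix(0, U, U)
  with_seed(seed, {
    for (b in seq_len(n_null)) {
      nullm <- matrix(0L, U, S)
      for (u in seq_len(U)) {
        nullm[u, sample.int(S, richness[u], prob = f)] <- 1L
      }
      ns <- tcrossprod(nullm)
      less <- less + (ns < obs)
      ties <- ties + (ns == obs)
    }
  })
  d <- 1 - (less + 0.5 * ties) / n_null
  dimnames(d) <- list(rownames(m), rownames(m))
  stats::as.dist(d)
}

as_square <- function(d, name) {
  m <- as.matrix(d)
  validate_distance(m, name = name)
}

align_to <- function(m, labels, name) {
  if (!is.null(rownames(m)) && !is.null(labels)) {
    if (!setequal(rownames(m), labels)) {
      stop(name, ": labels do not match", call. = FALSE)
    }
    m <- m[labels, labels, drop = FALSE]
  }
  m
}

spearman_lt <- function(m1, m2) {
  cor(lower_tri(m1), lower_tri(m2), method = "spearman")
}

#' Mantel test between two distance matrices
#'
#' Spearman rank correlation `r` of the lower-triangle entries, with
#' significance from random row/column label permutations of the second
#' matrix. The default alternative is one-sided positive association with
#' the add-one permutation p-value `(1 + #\{r_perm >= r\}) / (1 + n_perm)`;
#' `alternative = "two.sided"` compares `|r_perm|` to `|r|`.
#'
#' @param d1,d2 distance matrices (matrix or `dist`) over the same labels
#'   (at least 4); matching labels are aligned by name when present.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param permutations optional integer matrix of permutation index rows to
#'   use instead of random draws (e.g. all relabelings for an exact test);
#'   when supplied, `p = #\{r_perm >= r\} / nrow` with the identity
#'   permutation expected among the rows.
#' @return `mantel_result` list: `statistic`, `p.value`, `n_perm`,
#'   `alternative`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL,
                        alternative = c("greater", "two.sided"),
                        permutations = NULL) {
  alternative <- match.arg(alternative)
  m1 <- as_square(d1, "d1")
  m2 <- as_square(d2, "d2")
  m2 <- align_to(m2, rownames(m1), "d2")
  n <- nrow(m1)
  if (n < 4) stop("need at least 4 labels", call. = FALSE)
  if (nrow(m2) != n) stop("d1 and d2 have different sizes", call. = FALSE)
  v1 <- lower_tri(m1); v2 <- lower_tri(m2)
  if (length(unique(v1)) == 1 || length(unique(v2)) == 1) {
    stop("constant lower triangle: rank correlation undefined", call. = FALSE)
  }
  r <- cor(v1, v2, method = "spearman")
  stat_perm <- function(idx) cor(v1, lower_tri(m2[idx, idx]),
                                 method = "spearman")
  if (!is.null(permutations)) {
    r_perm <- apply(permutations, 1, stat_perm)
    p <- switch(alternative,
                greater = mean(r_perm >= r - 1e-12),
                two.sided = mean(abs(r_perm) >= abs(r) - 1e-12))
    n_perm <- nrow(permutations)
  } else {
    r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      stat_perm(sample.int(n))
    }, numeric(1)))
    p <- switch(alternative,
                greater = (1 + sum(r_perm >= r - 1e-12)) / (1 + n_perm),
                two.sided = (1 + sum(abs(r_perm) >= abs(r) - 1e-12)) /
                  (1 + n_perm))
  }
  structure(list(statistic = r, p.value = p, n_perm = n_perm,
                 alternative = alternative, method = "Mantel (Spearman)"),
            class = "mantel_result")
}

#' Partial Mantel test controlling for a third matrix
#'
#' First-order partial Spearman correlation
#' \eqn{r_{12 \cdot 3} = (r_{12} - r_{13} r_{23}) /
#'   \sqrt{(1 - r_{13}^2)(1 - r_{23}^2)}} between `d1` and `d2` given
#' `d_control`, with significance from permutations of `d1`'s labels
#' (recomputing the partial statistic each time).
#'
#' @inheritParams mantel_test
#' @param d_control controlling distance matrix; a control perfectly rank
#'   correlated with either input (`|r| = 1`) is a degenerate-control error.
#' @return `mantel_result` with a `controlled` label.
#' @export
partial_mantel_test <- function(d1, d2, d_control, n_perm = 9999, seed = NULL,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  m1 <- as_square(d1, "d1")
  m2 <- align_to(as_square(d2, "d2"), rownames(m1), "d2")
  mc <- align_to(as_square(d_control, "d_control"), rownames(m1), "d_control")
  n <- nrow(m1)
  if (n < 4) stop("need at least 4 labels", call. = FALSE)
  v1 <- lower_tri(m1); v2 <- lower_tri(m2); vc <- lower_tri(mc)
  if (length(unique(v1)) == 1 || length(unique(v2)) == 1 ||
      length(unique(vc)) == 1) {
    stop("constant lower triangle: rank correlation undefined", call. = FALSE)
  }
  partial_r <- function(r12, r13, r23) {
    (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  }
  r13 <- cor(v1, vc, method = "spearman")
  r23 <- cor(v2, vc, method = "spearman")
  if (abs(r13) >= 1 - 1e-12 || abs(r23) >= 1 - 1e-12) {
    stop("degenerate control: |r| = 1 with a compared matrix", call. = FALSE)
  }
  r12 <- cor(v1, v2, method = "spearman")
  r_obs <- partial_r(r12, r13, r23)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    v1p <- lower_tri(m1[idx, idx])
    partial_r(cor(v1p, v2, method = "spearman"),
              cor(v1p, vc, method = "spearman"), r23)
  }, numeric(1)))
  p <- switch(alternative,
              greater = (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm),
              two.sided = (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) /
                (1 + n_perm))
  structure(list(statistic = r_obs, p.value = p, n_perm = n_perm,
                 alternative = alternative, controlled = "d_control",
                 method = "partial Mantel (Spearman)"),
            class = "mantel_result")
}

#' Moran's I spatial autocorrelation along the transect
#'
#' \eqn{I = (n / \sum_{ij} w_{ij}) \sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2}
#' with centred values `z` and inverse-distance weights
#' `w_ij = 1 / |x_i - x_j|` (zero diagonal, no row standardization), the
#' conventional weighting for a linear transect. Expectation under the
#' randomization null is `-1/(n-1)`; the two-sided p-value uses the normal
#' approximation with the exact randomization variance (kurtosis-corrected).
#'
#' @param values numeric vector per sample (e.g. occurrence of one fungal
#'   OTU); must not be constant.
#' @param coords sample positions in metres; duplicates are an error
#'   (infinite weight).
#' @param weight optional custom weight matrix overriding inverse distance.
#' @return list with `I`, `expected`, `sd`, `p.value`.
#' @export
morans_i <- function(values, coords, weight = NULL) {
  n <- length(values)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  if (length(coords) != n) stop("values and coords differ in length",
                                call. = FALSE)
  if (length(unique(values)) == 1) stop("values are constant", call. = FALSE)
  if (is.null(weight)) {
    if (anyDuplicated(coords)) {
      stop("duplicate coordinates give infinite inverse-distance weights",
           call. = FALSE)
    }
    weight <- 1 / abs(outer(coords, coords, "-"))
    diag(weight) <- 0
  }
  w <- as.matrix(weight)
  z <- values - mean(values)
  S0 <- sum(w)
  I <- (n / S0) * sum(w * outer(z, z)) / sum(z^2)
  EI <- -1 / (n - 1)
  ## randomization variance (Cliff & Ord), with sample kurtosis b2
  S1 <- 0.5 * sum((w + t(w))^2)
  S2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  sdI <- sqrt(varI)
  list(I = I, expected = EI, sd = sdI,
       p.value = 2 * pnorm(-abs((I - EI) / sdI)))
}

#' Split an occurrence matrix into dipterocarp and non-dipterocarp datasets
#'
#' @param occ occurrence matrix (samples x fungal OTUs).
#' @param hosts a [host_assignment()] with `is_dipterocarp` flags.
#' @return list with `dipterocarp` and `non_dipterocarp` occurrence
#'   matrices; an empty subset is an error.
#' @export
split_by_host <- function(occ, hosts) {
  idx <- match(rownames(occ), hosts$sample_id)
  if (anyNA(idx)) stop("samples missing from host table", call. = FALSE)
  dip <- hosts$is_dipterocarp[idx]
  if (sum(dip) == 0) stop("dipterocarp subset is empty", call. = FALSE)
  if (sum(!dip) == 0) stop("non-dipterocarp subset is empty", call. = FALSE)
  list(dipterocarp = occ[dip, , drop = FALSE],
       non_dipterocarp = occ[!dip, , drop = FALSE])
}

#' Geographic distance between plant OTUs along the transect
#'
#' Distance between the mean transect positions of the samples of each
#' plant OTU, for use as the spatial control in partial Mantel tests.
#'
#' @param hosts a [host_assignment()].
#' @param coords sample positions (same order as `hosts`).
#' @param level clustering level.
#' @return square distance matrix over plant OTUs at `level`.
#' @export
geographic_distance <- function(hosts, coords, level = "99.8") {
  col <- host_level_col(level)
  pos <- tapply(coords, hosts[[col]], mean)
  d <- abs(outer(as.numeric(pos), as.numeric(pos), "-"))
  dimnames(d) <- list(names(pos), names(pos))
  attr(d, "kind") <- "geographic"
  d
}
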