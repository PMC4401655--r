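# Fixture builders and independent oracles shared across the suite.

make_cm <- function(m, state = "raw") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("F%02d", seq_len(ncol(m)))
  count_matrix(m, state = state)
}

make_occ <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("F%02d", seq_len(ncol(m)))
  occurrence_matrix(m)
}

## Host table where sample i belongs to finest OTU finest[i]; coarser levels
## derived through explicit nesting maps (level k label = map applied k times).
make_hosts <- function(finest, maps = NULL, dip = NULL, family = NULL,
                       sample_ids = NULL) {
  k1 <- max(finest)
  maps <- maps %||% list(seq_len(k1), seq_len(k1), seq_len(k1))
  dip <- dip %||% rep(TRUE, k1)
  family <- family %||% ifelse(dip, "Dipterocarpaceae", "Burseraceae")
  idx <- finest
  lv <- host_levels()
  df <- data.frame(sample_id = sample_ids %||% sprintf("S%02d", seq_along(finest)),
                   stringsAsFactors = FALSE)
  df[[paste0("plant_otu_", lv[1])]] <- sprintf("P998.%03d", idx)
  idx2 <- maps[[1]][idx]
  df[[paste0("plant_otu_", lv[2])]] <- sprintf("P99.%03d", idx2)
  idx3 <- maps[[2]][idx2]
  df[[paste0("plant_otu_", lv[3])]] <- sprintf("P98.%03d", idx3)
  idx4 <- maps[[3]][idx3]
  df[[paste0("plant_otu_", lv[4])]] <- sprintf("P97.%03d", idx4)
  df$family <- family[finest]
  df$is_dipterocarp <- dip[finest]
  host_assignment(df)
}

## Association matrix built directly from its margins (bypassing the
## occurrence pipeline) for model-level tests.
make_assoc <- function(y, T_j) {
  if (is.null(rownames(y))) rownames(y) <- sprintf("F%03d", seq_len(nrow(y)))
  if (is.null(colnames(y))) colnames(y) <- names(T_j) %||%
      sprintf("P%02d", seq_len(ncol(y)))
  structure(y, T = T_j, N = rowSums(y), level = "99.8", dropped_otus = character(),
            class = c("association_matrix", class(matrix())))
}

## Draw an occurrence pattern of n samples over host groups with sizes T_j
## and tabulate it per group (guarantees y <= T and rowSums = n).
draw_y_row <- function(n, T_j) {
  grp <- rep(names(T_j), T_j)
  as.integer(table(factor(sample(grp, n), levels = names(T_j))))
}

## Independent two-sided Fisher oracle: enumerate all 2x2 tables with the
## observed margins, summing hypergeometric probabilities <= observed's.
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

## Random symmetric zero-diagonal matrix with labels.
rand_dist <- function(n, labels = paste0("L", seq_len(n))) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(labels, labels)
  m
}

taxonomy_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}
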