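`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimals with exact halves moving away from zero, the
#' convention used for percentage reporting in published frequency tables
#' (base R's `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.25, -0.25), 1) # 0.3, -0.3
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

lower_tri <- function(m) m[lower.tri(m)]

## Shared validation for square distance matrices; `name` labels error text.
validate_distance <- function(d, name = "distance matrix", tol = 1e-12) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) {
    stop(name, " must be square, got ", nrow(d), " x ", ncol(d), call. = FALSE)
  }
  if (!is.null(rownames(d)) && !is.null(colnames(d)) &&
      !identical(rownames(d), colnames(d))) {
    stop(name, ": row and column labels differ", call. = FALSE)
  }
  bad <- which(abs(d - t(d)) > tol & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    lab <- if (!is.null(rownames(d))) {
      paste0("(", rownames(d)[i], ", ", colnames(d)[j], ")")
    } else {
      paste0("(", i, ", ", j, ")")
    }
    stop(name, " is asymmetric at pair ", lab, call. = FALSE)
  }
  if (any(abs(diag(d)) > tol)) {
    stop(name, " must have a zero diagonal", call. = FALSE)
  }
  if (any(d < -tol)) {
    stop(name, " has negative entries", call. = FALSE)
  }
  d
}
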