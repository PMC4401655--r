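#' Dirichlet prior of the host-association model
#'
#' Under random host selection, fungal OTU `i` with `N_i` total occurrences
#' is expected to be found in plant OTU `j` in proportion to the sampling
#' effort `T_j`, giving the Dirichlet parameter
#' \eqn{\alpha_{i,j} = T_j N_i / \sum_j T_j}. Each row sums to `N_i`, and
#' the prior mean of every row is `T / sum(T)` regardless of the fungus.
#'
#' @param assoc an [build_association()] matrix (`y`, fungal x plant, with
#'   `T` and `N` margins).
#' @return `dirichlet_prior`: matrix of alpha values with `T` and `N`
#'   attributes.
#' @export
compute_alpha <- function(assoc) {
  Tj <- attr(assoc, "T")
  Ni <- attr(assoc, "N")
  if (is.null(Tj) || is.null(Ni)) {
    stop("assoc must carry T and N margins (see build_association)",
         call. = FALSE)
  }
  if (ncol(assoc) < 2) {
    stop("preference undefined for a single host taxon", call. = FALSE)
  }
  if (any(Ni < 1) || any(Tj < 1)) {
    stop("margins must be positive (N_i >= 1, T_j >= 1)", call. = FALSE)
  }
  a <- outer(as.numeric(Ni), as.numeric(Tj)) / sum(Tj)
  dimnames(a) <- dimnames(assoc)
  structure(a, T = Tj, N = Ni,
            class = c("dirichlet_prior", class(matrix())))
}

#' Draw from the posterior of host-association proportions
#'
#' The observed occurrence vector of each fungal OTU follows a multinomial
#' law with proportions `pi`, with the Dirichlet prior of [compute_alpha()].
#' The posterior is therefore Dirichlet with parameter `alpha + y`.
#' `mode = "conjugate"` draws from this exact posterior directly;
#' `mode = "gibbs"` runs a Markov chain Monte Carlo sampler (componentwise
#' Metropolis updates on the gamma representation of the Dirichlet, with the
#' stated chains, burn-in and thinning) targeting the same posterior,
#' mirroring a BUGS-style fit and serving as a mutual oracle for the
#' conjugate mode.
#'
#' Burn-in counts raw iterations before thinning: each chain retains
#' `floor((iterations - burn_in) / thin)` draws.
#'
#' @param assoc an association matrix from [build_association()].
#' @param prior optional [compute_alpha()] result (recomputed if missing).
#' @param mode `"conjugate"` (default) or `"gibbs"`.
#' @param draws number of posterior draws (conjugate mode).
#' @param chains,iterations,burn_in,thin MCMC settings (gibbs mode).
#' @param seed integer seed; both modes are seed-reproducible.
#' @return `posterior_draws`: list with `pi` (per fungal OTU, a draws x
#'   hosts matrix), `chain` (chain index of each retained draw), margins and
#'   settings.
#' @export
sample_posterior <- function(assoc, prior = NULL,
                             mode = c("conjugate", "gibbs"),
                             draws = 50000, chains = 3, iterations = 100000,
                             burn_in = 40000, thin = 20, seed = NULL) {
  mode <- match.arg(mode)
  prior <- prior %||% compute_alpha(assoc)
  Tj <- attr(prior, "T")
  Ni <- attr(prior, "N")
  y <- unclass(assoc)
  if (any(sweep(y, 2, Tj) > 0)) {
    stop("y[i, j] cannot exceed T_j", call. = FALSE)
  }
  if (any(abs(rowSums(y) - Ni) > 0)) {
    stop("row sums of y must equal N_i", call. = FALSE)
  }
  a_post <- unclass(prior) + y
  I <- nrow(a_post); J <- ncol(a_post)
  if (mode == "conjugate") {
    if (draws <= 0) stop("draws must be positive", call. = FALSE)
    pi_draws <- with_seed(seed, lapply(seq_len(I), function(i) {
      g <- matrix(rgamma(draws * J, shape = rep(a_post[i, ], each = draws)),
                  draws, J)
      g / rowSums(g)
    }))
    chain <- rep(1L, draws)
    settings <- list(mode = mode, draws = draws)
  } else {
    if (iterations <= 0) stop("iterations must be positive", call. = FALSE)
    if (burn_in >= iterations) {
      stop("burn_in must be smaller than iterations", call. = FALSE)
    }
    if (chains < 1) stop("need at least one chain", call. = FALSE)
    rpc <- floor((iterations - burn_in) / thin)
    if (rpc < 1) stop("no draws retained: increase iterations or lower thin",
                      call. = FALSE)
    ## log-scale random-walk Metropolis on the gamma representation:
    ## target per cell is Gamma(a_post, 1); proposal sd ~ posterior log-scale sd
    prop_sd <- pmin(pmax(2.4 / sqrt(a_post), 0.05), 2.5)
    pi_draws <- lapply(seq_len(I), function(i) {
      matrix(NA_real_, rpc * chains, J)
    })
    chain <- integer(0)
    with_seed(seed, {
      for (ch in seq_len(chains)) {
        ## overdispersed initial values per chain
        g <- matrix(rgamma(I * J, shape = a_post), I, J) *
          exp(matrix(rnorm(I * J, 0, 1), I, J))
        kept <- 0L
        for (it in seq_len(iterations)) {
          eps <- matrix(rnorm(I * J, 0, prop_sd), I, J)
          gp <- g * exp(eps)
          logr <- a_post * eps - (gp - g)
          acc <- matrix(log(runif(I * J)), I, J) < logr
          g[acc] <- gp[acc]
          if (it > burn_in && (it - burn_in) %% thin == 0 && kept < rpc) {
            kept <- kept + 1L
            p <- g / rowSums(g)
            row <- (ch - 1L) * rpc + kept
            for (i in seq_len(I)) pi_draws[[i]][row, ] <- p[i, ]
          }
        }
      }
    })
    chain <- rep(seq_len(chains), each = rpc)
    settings <- list(mode = mode, chains = chains, iterations = iterations,
                     burn_in = burn_in, thin = thin, draws_per_chain = rpc)
  }
  for (i in seq_len(I)) colnames(pi_draws[[i]]) <- colnames(a_post)
  structure(list(pi = stats::setNames(pi_draws, rownames(a_post)),
                 chain = chain, T = Tj, N = Ni, a_post = a_post,
                 settings = settings),
            class = "posterior_draws")
}

#' Posterior host-preference deviation statistics
#'
#' For each posterior draw of the association proportions `pi` of fungal OTU
#' `i`, the normalized deviation from random host selection is
#' \deqn{\bar D_{i,j} = (\pi_{i,j} - E(\pi_{i,j})) /
#'   \sqrt{\sum_j (\pi_{i,j} - E(\pi_{i,j}))^2},}
#' with \eqn{E(\pi_{i,j}) = T_j / \sum_j T_j} the expected association
#' frequency under random host selection. Every accepted draw vector sums to
#' 0 and has unit L2 norm, so \eqn{\bar D} ranges from -1 to 1; positive
#' values mean the fungus occurs on that host more often than expected by
#' chance. `D_hat` is the across-draw mean, and 95%/99% equal-tailed
#' credible intervals are taken from the draw quantiles; a host is flagged
#' significant when its interval excludes 0.
#'
#' Draws whose deviation vector has an L2 norm below `1e-12` (numerically at
#' the prior mean) are rejected and counted; more than 1% rejected draws for
#' any fungal OTU is an error.
#'
#' @param post a [sample_posterior()] result (at least 100 draws, 2 hosts).
#' @param keep_draws keep the per-draw `D_bar` matrices (memory permitting).
#' @return `host_preference`: list with matrices `D_hat`, `ci95_lo`,
#'   `ci95_hi`, `ci99_lo`, `ci99_hi`, logical `sig95`/`sig99`, per-OTU
#'   rejected-draw counts, margins, and optionally `D_bar` draw matrices.
#' @export
compute_D <- function(post, keep_draws = FALSE) {
  stopifnot(inherits(post, "posterior_draws"))
  Tj <- post$T
  J <- length(Tj)
  if (J < 2) stop("need at least two host taxa", call. = FALSE)
  ndraw <- nrow(post$pi[[1]])
  if (ndraw < 100) stop("need at least 100 posterior draws", call. = FALSE)
  Epi <- as.numeric(Tj) / sum(Tj)
  I <- length(post$pi)
  otus <- names(post$pi)
  mk <- function() matrix(NA_real_, I, J, dimnames = list(otus, names(Tj)))
  D_hat <- mk(); lo95 <- mk(); hi95 <- mk(); lo99 <- mk(); hi99 <- mk()
  n_rej <- stats::setNames(integer(I), otus)
  D_bar <- if (keep_draws) vector("list", I)
  for (i in seq_len(I)) {
    dev <- sweep(post$pi[[i]], 2, Epi)
    nrm <- sqrt(rowSums(dev^2))
    rej <- nrm < 1e-12
    n_rej[i] <- sum(rej)
    if (n_rej[i] > 0.01 * nrow(dev)) {
      stop("more than 1% of draws rejected (degenerate deviation vector) ",
           "for fungal OTU '", otus[i], "'", call. = FALSE)
    }
    Db <- dev[!rej, , drop = FALSE] / nrm[!rej]
    D_hat[i, ] <- colMeans(Db)
    q <- apply(Db, 2, quantile, probs = c(0.025, 0.975, 0.005, 0.995),
               names = FALSE)
    lo95[i, ] <- q[1, ]; hi95[i, ] <- q[2, ]
    lo99[i, ] <- q[3, ]; hi99[i, ] <- q[4, ]
    if (keep_draws) D_bar[[i]] <- Db
  }
  structure(list(D_hat = D_hat, ci95_lo = lo95, ci95_hi = hi95,
                 ci99_lo = lo99, ci99_hi = hi99,
                 sig95 = lo95 > 0 | hi95 < 0, sig99 = lo99 > 0 | hi99 < 0,
                 n_rejected = n_rej, T = Tj, N = post$N,
                 settings = post$settings,
                 D_bar = if (keep_draws) stats::setNames(D_bar, otus)),
            class = "host_preference")
}

#' @rdname compute_D
#' @param x a `host_preference` object.
#' @param ... unused.
#' @export
as.data.frame.host_preference <- function(x, ...) {
  I <- nrow(x$D_hat); J <- ncol(x$D_hat)
  data.frame(
    otu = rep(rownames(x$D_hat), J),
    host = rep(colnames(x$D_hat), each = I),
    D_hat = as.vector(x$D_hat),
    ci95_lo = as.vector(x$ci95_lo), ci95_hi = as.vector(x$ci95_hi),
    ci99_lo = as.vector(x$ci99_lo), ci99_hi = as.vector(x$ci99_hi),
    flag = ifelse(as.vector(x$sig99), "*",
                  ifelse(as.vector(x$sig95), "+", "")),
    stringsAsFactors = FALSE
  )
}

#' Per-fungus maximum preference (Chebyshev summary)
#'
#' The signed maximum of `D_hat` over hosts, per fungal OTU, summarizing the
#' most distinct host-association pattern of the fungus. The signed maximum
#' follows the statistic as printed; rows where `max(|D_hat|)` is attained
#' by a negative value (so the signed max differs from the absolute max) are
#' flagged in the `abs_differs` attribute rather than silently reinterpreted.
#'
#' @param pref a [compute_D()] result or a `D_hat` matrix.
#' @return named numeric vector of `D_hat_max` values with an `abs_differs`
#'   logical attribute.
#' @export
compute_Dmax <- function(pref) {
  D <- if (inherits(pref, "host_preference")) pref$D_hat else as.matrix(pref)
  dmax <- apply(D, 1, max)
  abs_differs <- apply(abs(D), 1, max) != dmax
  structure(dmax, abs_differs = abs_differs)
}

#' @rdname compute_Dmax
#' @param prefs named list of [compute_D()] results, one per clustering
#'   level, over the same fungal OTUs.
#' @return `dmax_table()`: fungal OTU x level matrix of `D_hat_max` values.
#' @export
dmax_table <- function(prefs) {
  otus <- rownames(if (inherits(prefs[[1]], "host_preference"))
    prefs[[1]]$D_hat else prefs[[1]])
  cols <- lapply(prefs, function(p) {
    v <- compute_Dmax(p)
    if (!identical(names(v), otus)) {
      stop("all levels must cover the same fungal OTU set", call. = FALSE)
    }
    as.numeric(v)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(otus, names(prefs))
  m
}

#' Gelman-Rubin potential scale reduction factor
#'
#' \eqn{\hat R = \sqrt{((n - 1)/n \, W + B/n) / W}} with `W` the mean
#' within-chain variance and `B` the between-chain variance of chain means
#' (times `n`). Chains that are exact copies give exactly 1.
#'
#' @param x either a matrix with one chain per column, a list of
#'   equal-length numeric chains, or a gibbs-mode [sample_posterior()]
#'   result (returning one `R_hat` per `pi` parameter).
#' @return numeric `R_hat` (scalar, or fungal OTU x host matrix).
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "posterior_draws")) {
    chains <- sort(unique(x$chain))
    if (length(chains) < 2) {
      stop("Gelman-Rubin needs at least two chains (gibbs mode)",
           call. = FALSE)
    }
    I <- length(x$pi); J <- ncol(x$pi[[1]])
    out <- matrix(NA_real_, I, J,
                  dimnames = list(names(x$pi), colnames(x$pi[[1]])))
    for (i in seq_len(I)) {
      for (j in seq_len(J)) {
        cm <- vapply(chains, function(ch) x$pi[[i]][x$chain == ch, j],
                     numeric(sum(x$chain == chains[1])))
        out[i, j] <- gelman_rubin(cm)
      }
    }
    return(out)
  }
  if (is.list(x)) {
    if (length(unique(lengths(x))) != 1) {
      stop("chains must have equal lengths", call. = FALSE)
    }
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  if (n < 10) stop("chains must have length >= 10", call. = FALSE)
  W <- mean(apply(x, 2, var))
  if (W == 0) stop("zero within-chain variance in all chains", call. = FALSE)
  B <- n * var(colMeans(x))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Exact / approximate Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired signed-rank test. Zero differences are discarded;
#' absolute differences are mid-ranked. For `n <= exact_limit` non-zero
#' pairs the null distribution of the positive-rank sum is computed exactly
#' by enumerating all sign assignments (tied ranks handled exactly), and the
#' two-sided p doubles the smaller tail (capped at 1). Larger samples use
#' the normal approximation with tie correction.
#'
#' @param x,y paired numeric vectors.
#' @param exact_limit maximum `n` for exact enumeration.
#' @return list with `statistic` (positive-rank sum `V`), `p.value`, `n`
#'   (non-zero pairs), and `exact` flag.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p.value = 1, n = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_limit) {
    ## distribution of V over all 2^n sign assignments, via the generating
    ## polynomial prod_k (1 + z^(2 r_k)) on doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    dist <- numeric(sum(r2) + 1)  # index = doubled rank-sum + 1
    dist[1] <- 1
    top <- 1L
    for (rk in r2) {
      nw <- dist
      nw[(rk + 1):(top + rk)] <- nw[(rk + 1):(top + rk)] + dist[1:top]
      dist <- nw
      top <- top + rk
    }
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * V))
    p_lo <- sum(dist[seq_len(v2 + 1)])
    p_hi <- sum(dist[(v2 + 1):length(dist)])
    p <- min(1, 2 * min(p_lo, p_hi))
    list(statistic = V, p.value = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    list(statistic = V, p.value = min(1, 2 * pnorm(-abs(z))), n = n,
         exact = FALSE)
  }
}

## Compact letter display: maximal groups of levels with no significant
## internal pair each get one letter (brute force over subsets; few levels).
cld_letters <- function(levels, sig_pairs) {
  k <- length(levels)
  subsets <- list()
  for (code in seq_len(2^k - 1)) {
    memb <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    ok <- TRUE
    if (length(memb) > 1) {
      for (a in seq_along(memb)) for (b in seq_along(memb)) {
        if (a < b && sig_pairs[memb[a], memb[b]]) ok <- FALSE
      }
    }
    if (ok) subsets <- c(subsets, list(memb))
  }
  maximal <- Filter(function(s) {
    !any(vapply(subsets, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, subsets)
  maximal <- maximal[order(vapply(maximal, min, numeric(1)))]
  out <- stats::setNames(rep("", k), levels)
  for (g in seq_along(maximal)) {
    out[maximal[[g]]] <- paste0(out[maximal[[g]]], letters[g])
  }
  out
}

#' Compare D_hat_max across host clustering levels
#'
#' Pairwise two-sided Wilcoxon signed-rank tests on paired per-OTU
#' `D_hat_max` values between every pair of clustering levels, with Holm
#' correction across the level pairs, plus a compact letter display (levels
#' sharing a letter do not differ significantly).
#'
#' @param dmax fungal OTU x level matrix from [dmax_table()] (>= 6 OTUs).
#' @param alpha significance level for the letter display.
#' @return data frame of level pairs with raw and Holm-adjusted p-values and
#'   significance flags; the letter display is in the `letters` attribute.
#' @export
compare_Dmax_levels <- function(dmax, alpha = 0.05) {
  dmax <- as.matrix(dmax)
  if (nrow(dmax) < 6) stop("need at least 6 fungal OTUs", call. = FALSE)
  if (ncol(dmax) < 2) stop("need at least 2 levels", call. = FALSE)
  lv <- colnames(dmax) %||% paste0("L", seq_len(ncol(dmax)))
  prs <- combn(ncol(dmax), 2)
  res <- apply(prs, 2, function(pr) {
    w <- wilcoxon_signed_rank(dmax[, pr[1]], dmax[, pr[2]])
    w$p.value
  })
  out <- data.frame(level_a = lv[prs[1, ]], level_b = lv[prs[2, ]],
                    p = res, p_holm = p.adjust(res, method = "holm"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_holm < alpha
  sig <- matrix(FALSE, ncol(dmax), ncol(dmax))
  for (q in seq_len(ncol(prs))) {
    sig[prs[1, q], prs[2, q]] <- sig[prs[2, q], prs[1, q]] <- out$significant[q]
  }
  attr(out, "letters") <- cld_letters(lv, sig)
  out
}
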