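#' Configuration for the synthetic root-sample community generator
#'
#' Defines the study design emulated by the generator: root samples taken at
#' 1-m intervals along a linear transect, each assigned to a host plant OTU
#' in a nested four-level clustering, and colonized by fungal OTUs with a
#' long-tailed abundance distribution, per-sample sequencing-depth variation,
#' and configurable host-preference structure.
#'
#' Per-sample read depths follow a lognormal law rounded to integers with a
#' floor of `depth_min`; the defaults put roughly a fifth of samples below
#' the 100-read rarefaction threshold so the sample-dropping branch of the
#' pipeline is exercised. Fungal base abundances decay geometrically with
#' rank, giving a few dominant and many rare OTUs.
#'
#' @param n_samples number of root samples (transect positions).
#' @param n_plant_otus integer vector of plant OTU counts at the four nested
#'   clustering levels, fine to coarse (99.8, 99, 98, 97 percent similarity);
#'   must be non-increasing.
#' @param n_fungal_otus number of fungal OTUs.
#' @param depth_meanlog,depth_sdlog,depth_min lognormal read-depth
#'   parameters and integer floor.
#' @param host_frequencies relative sampling frequencies of the finest-level
#'   plant OTUs (recycled/normalized), or `NULL` for a geometric rank series
#'   with ratio `host_freq_ratio`.
#' @param host_freq_ratio geometric decay of host frequencies when
#'   `host_frequencies` is `NULL`.
#' @param dipterocarp_fraction expected fraction of finest-level plant OTUs
#'   flagged as Dipterocarpaceae.
#' @param abundance_ratio geometric decay of fungal base abundances.
#' @param preference_matrix `n_fungal_otus` x `n_plant_otus[1]` matrix of
#'   relative colonization weights per finest-level host (rows non-negative,
#'   not all zero), or `NULL` for the no-preference null (all-equal rows).
#' @param spatial_aggregation exponential range (in metres) of per-OTU
#'   along-transect clustering of colonization odds; 0 disables it. Scalar
#'   or per-fungal-OTU vector.
#' @param tier_heights genetic distances between plant OTUs first merging at
#'   the 99, 98, 97 percent levels, and not merging at all (increasing).
#' @param distance_jitter relative uniform jitter applied to host genetic
#'   distances (0 keeps the matrix exactly ultrametric).
#' @param rng_seed integer seed; all generator output is reproducible
#'   bit-for-bit given the seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 600,
                              n_plant_otus = c(148, 96, 64, 40),
                              n_fungal_otus = 1700,
                              depth_meanlog = 5.09,
                              depth_sdlog = 0.56,
                              depth_min = 1,
                              host_frequencies = NULL,
                              host_freq_ratio = 0.97,
                              dipterocarp_fraction = 0.45,
                              abundance_ratio = 0.996,
                              preference_matrix = NULL,
                              spatial_aggregation = 0,
                              tier_heights = c(0.005, 0.015, 0.03, 0.06),
                              distance_jitter = 0,
                              rng_seed = 1) {
  if (length(n_plant_otus) != 4 || any(n_plant_otus < 1)) {
    stop("n_plant_otus must give positive counts at the 4 clustering levels",
         call. = FALSE)
  }
  if (any(diff(n_plant_otus) > 0)) {
    stop("n_plant_otus must be non-increasing from fine to coarse levels",
         call. = FALSE)
  }
  if (!is.null(preference_matrix)) {
    preference_matrix <- as.matrix(preference_matrix)
    if (nrow(preference_matrix) != n_fungal_otus ||
        ncol(preference_matrix) != n_plant_otus[1]) {
      stop("preference_matrix must be n_fungal_otus x n_plant_otus[1]",
           call. = FALSE)
    }
    if (any(preference_matrix < 0)) {
      stop("preference_matrix rows must be non-negative", call. = FALSE)
    }
    if (any(rowSums(preference_matrix) == 0)) {
      stop("preference_matrix rows must not be all zero", call. = FALSE)
    }
  }
  if (!is.null(host_frequencies)) {
    if (length(host_frequencies) != n_plant_otus[1] ||
        any(host_frequencies <= 0)) {
      stop("host_frequencies must give a positive weight per finest plant OTU",
           call. = FALSE)
    }
  }
  if (length(tier_heights) != 4 || any(diff(tier_heights) <= 0)) {
    stop("tier_heights must be 4 strictly increasing distances", call. = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples),
    n_plant_otus = as.integer(n_plant_otus),
    n_fungal_otus = as.integer(n_fungal_otus),
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    depth_min = as.integer(depth_min),
    host_frequencies = host_frequencies, host_freq_ratio = host_freq_ratio,
    dipterocarp_fraction = dipterocarp_fraction,
    abundance_ratio = abundance_ratio,
    preference_matrix = preference_matrix,
    spatial_aggregation = spatial_aggregation,
    tier_heights = tier_heights, distance_jitter = distance_jitter,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

## Assign n_child labels to n_parent coarser labels so every parent is used.
make_nesting_map <- function(n_child, n_parent) {
  p <- c(seq_len(n_parent),
         if (n_child > n_parent) sample.int(n_parent, n_child - n_parent,
                                            replace = TRUE))
  sample(p)
}

plant_otu_labels <- function(level, n) {
  sprintf("P%s.%03d", gsub("\\.", "", level), seq_len(n))
}

#' Generate host assignments and transect coordinates
#'
#' Draws one host plant OTU per sample from the finest-level host frequency
#' law, derives the three coarser-level labels through randomly built nested
#' partitions, and assigns each finest-level plant OTU a family and
#' dipterocarp flag. Samples sit at 1-m intervals along the transect.
#'
#' @param config a [simulation_config()].
#' @return list with `hosts` (a [host_assignment()]; nesting maps, per-OTU
#'   family/dipterocarp tables and host frequencies are kept as attributes)
#'   and `coordinates` (metres along the transect, strictly increasing).
#' @export
generate_hosts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$n_plant_otus
  n <- config$n_samples
  if (k[1] > n) {
    stop("n_plant_otus (", k[1], ") exceeds n_samples (", n,
         "): cannot realize all finest-level labels", call. = FALSE)
  }
  with_seed(config$rng_seed + 1L, {
    lv <- host_levels()
    maps <- list()
    for (j in 1:3) maps[[j]] <- make_nesting_map(k[j], k[j + 1])
    freq <- config$host_frequencies %||% config$host_freq_ratio^(0:(k[1] - 1))
    freq <- freq / sum(freq)
    host_idx <- sample.int(k[1], n, replace = TRUE, prob = freq)

    if (k[1] == 1) {
      dip_otus <- runif(1) < config$dipterocarp_fraction
    } else {
      n_dip <- max(1L, min(k[1] - 1L,
                           rbinom(1, k[1], config$dipterocarp_fraction)))
      dip_otus <- logical(k[1])
      dip_otus[sample.int(k[1], n_dip)] <- TRUE
    }
    nondip_pool <- c("Burseraceae", "Euphorbiaceae", "Myristicaceae",
                     "Clusiaceae", "Myrtaceae", "Fabaceae", "Anacardiaceae")
    fam_otus <- ifelse(dip_otus, "Dipterocarpaceae",
                       sample(nondip_pool, k[1], replace = TRUE))

    labels <- lapply(seq_along(lv), function(j) plant_otu_labels(lv[j], k[j]))
    idx <- host_idx
    cols <- list(labels[[1]][idx])
    for (j in 1:3) {
      idx <- maps[[j]][idx]
      cols[[j + 1]] <- labels[[j + 1]][idx]
    }
    df <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                     stringsAsFactors = FALSE)
    for (j in seq_along(lv)) df[[host_level_col(lv[j])]] <- cols[[j]]
    df$family <- fam_otus[host_idx]
    df$is_dipterocarp <- dip_otus[host_idx]
    hosts <- host_assignment(df)
    attr(hosts, "nesting_maps") <- maps
    attr(hosts, "finest_labels") <- labels[[1]]
    attr(hosts, "otu_family") <- stats::setNames(fam_otus, labels[[1]])
    attr(hosts, "otu_is_dipterocarp") <- stats::setNames(dip_otus, labels[[1]])
    attr(hosts, "host_frequencies") <- stats::setNames(freq, labels[[1]])
    list(hosts = hosts, coordinates = as.numeric(seq_len(n) - 1))
  })
}

#' Generate a read-count matrix with known preference structure
#'
#' For each sample, a sequencing depth is drawn from the lognormal depth law
#' and reads are allocated to fungal OTUs by a multinomial draw with weights
#' proportional to (geometric base abundance) x (preference weight for the
#' sample's host) x (spatial kernel). The returned ground truth records
#' everything needed for parameter-recovery tests.
#'
#' @param config a [simulation_config()].
#' @param hosts output of [generate_hosts()] run on the same config.
#' @return list with `counts` (a raw [count_matrix()]) and `truth`, a
#'   `ground_truth` list holding the preference matrix actually used, host
#'   labels, coordinates, drawn depths, and per-host expected relative
#'   colonization probabilities (`expected_marginals`, fungal OTU x host,
#'   columns summing to 1; computed without the spatial kernel).
#' @export
generate_counts <- function(config, hosts) {
  stopifnot(inherits(config, "simulation_config"))
  h <- hosts$hosts
  coords <- hosts$coordinates
  n <- config$n_samples
  if (nrow(h) != n) stop("hosts were not generated from this config",
                         call. = FALSE)
  K <- config$n_fungal_otus
  finest <- attr(h, "finest_labels")
  host_idx <- match(h[[host_level_col("99.8")]], finest)
  with_seed(config$rng_seed + 2L, {
    depths <- pmax(config$depth_min, as.integer(round(
      rlnorm(n, config$depth_meanlog, config$depth_sdlog))))
    base <- config$abundance_ratio^(0:(K - 1))
    W <- config$preference_matrix %||% matrix(1, K, length(finest))
    ranges <- rep_len(config$spatial_aggregation, K)
    use_spatial <- any(ranges > 0)
    if (use_spatial) {
      centres <- runif(K, min(coords), max(coords))
      kern <- exp(-abs(outer(coords, centres, "-")) /
                    rep(pmax(ranges, 1e-9), each = n))
      kern[, ranges <= 0] <- 1
    }
    counts <- matrix(0L, n, K,
                     dimnames = list(h$sample_id, sprintf("F%04d", 1:K)))
    for (s in seq_len(n)) {
      w <- base * W[, host_idx[s]]
      if (use_spatial) w <- w * kern[s, ]
      if (sum(w) <= 0) {
        stop("zero total colonization weight for sample '", h$sample_id[s],
             "'", call. = FALSE)
      }
      counts[s, ] <- rmultinom(1, depths[s], w)
    }
    em <- base * W
    em <- sweep(em, 2, colSums(em), "/")
    dimnames(em) <- list(colnames(counts), finest)
    truth <- structure(list(
      true_preference_matrix = W,
      host_labels = stats::setNames(h[[host_level_col("99.8")]], h$sample_id),
      coordinates = coords,
      depths = stats::setNames(depths, h$sample_id),
      expected_marginals = em
    ), class = "ground_truth")
    list(counts = count_matrix(counts, "raw"), truth = truth)
  })
}

#' Generate host genetic distances consistent with the nested clustering
#'
#' Builds a symmetric zero-diagonal distance matrix over the finest-level
#' plant OTUs in which the distance between two OTUs is the tier height of
#' the finest clustering level at which they merge, so distances are
#' monotone in partition level (OTUs merging at 99% are closer than OTUs
#' merging only at 97%). With `distance_jitter = 0` the matrix is exactly
#' ultrametric.
#'
#' @param hosts output of [generate_hosts()].
#' @param config the same [simulation_config()].
#' @return square distance matrix over finest-level plant OTUs.
#' @export
generate_host_distances <- function(hosts, config) {
  stopifnot(inherits(config, "simulation_config"))
  h <- hosts$hosts
  maps <- attr(h, "nesting_maps")
  finest <- attr(h, "finest_labels")
  k1 <- length(finest)
  if (k1 == 1) {
    d <- matrix(0, 1, 1, dimnames = list(finest, finest))
    attr(d, "kind") <- "genetic"
    return(d)
  }
  m2 <- maps[[1]]
  m3 <- maps[[2]][m2]
  m4 <- maps[[3]][m3]
  hgt <- config$tier_heights
  d <- matrix(hgt[4], k1, k1, dimnames = list(finest, finest))
  same4 <- outer(m4, m4, "==")
  same3 <- outer(m3, m3, "==")
  same2 <- outer(m2, m2, "==")
  d[same4] <- hgt[3]
  d[same3] <- hgt[2]
  d[same2] <- hgt[1]
  diag(d) <- 0
  j <- config$distance_jitter
  if (j > 0) {
    with_seed(config$rng_seed + 3L, {
      f <- matrix(1, k1, k1)
      f[upper.tri(f)] <- 1 + runif(k1 * (k1 - 1) / 2, -j, j)
      f[lower.tri(f)] <- t(f)[lower.tri(f)]
      d <- d * f
    })
  }
  attr(d, "kind") <- "genetic"
  d
}

#' Preference-matrix constructors for the generator
#'
#' Helpers building the `preference_matrix` of a [simulation_config()].
#' `preference_null()` encodes random host selection (all-equal rows).
#' `preference_exclusive()` gives each fungal OTU weight 1 on one focal
#' finest-level host and `background` elsewhere (0 = strict exclusivity).
#' `preference_group()` gives each OTU elevated weight on every finest-level
#' host belonging to one randomly chosen cluster at a coarser level,
#' emulating genus/family-level rather than species-level preference.
#' `preference_distance()` makes weights decay exponentially with host
#' genetic distance from a focal host chosen among `within` (all hosts by
#' default), with `background` weight outside `within`; this couples fungal
#' community turnover to host genetic distance.
#'
#' All random choices use the current RNG stream; seed the stream (or wrap
#' in a fixed-seed block) for reproducibility.
#'
#' @param n_fungal_otus number of fungal OTUs (rows).
#' @param n_hosts number of finest-level plant OTUs (columns).
#' @param focal integer vector of focal host indices per OTU (recycled);
#'   random by default.
#' @param background relative weight on non-focal hosts.
#' @return a weight matrix usable as `preference_matrix`.
#' @export
preference_null <- function(n_fungal_otus, n_hosts) {
  matrix(1, n_fungal_otus, n_hosts)
}

#' @rdname preference_null
#' @export
preference_exclusive <- function(n_fungal_otus, n_hosts, focal = NULL,
                                 background = 0) {
  focal <- rep_len(focal %||% sample.int(n_hosts, n_fungal_otus,
                                         replace = TRUE), n_fungal_otus)
  W <- matrix(background, n_fungal_otus, n_hosts)
  W[cbind(seq_len(n_fungal_otus), focal)] <- 1
  W
}

#' @rdname preference_null
#' @param hosts output of [generate_hosts()].
#' @param level coarser clustering level whose clusters are preferred.
#' @param strength weight multiplier inside the preferred cluster.
#' @export
preference_group <- function(hosts, level, n_fungal_otus, strength = 8,
                             background = 1) {
  h <- hosts$hosts
  maps <- attr(h, "nesting_maps")
  k1 <- length(attr(h, "finest_labels"))
  lvl_pos <- match(as.character(level), host_levels())
  if (is.na(lvl_pos)) stop("unknown level '", level, "'", call. = FALSE)
  memb <- seq_len(k1)
  if (lvl_pos > 1) for (j in seq_len(lvl_pos - 1)) memb <- maps[[j]][memb]
  clusters <- unique(memb)
  W <- matrix(background, n_fungal_otus, k1)
  pick <- sample(clusters, n_fungal_otus, replace = TRUE)
  for (i in seq_len(n_fungal_otus)) {
    W[i, memb == pick[i]] <- strength * background
    if (background == 0) W[i, memb == pick[i]] <- strength
  }
  W
}

#' @rdname preference_null
#' @param gdist host genetic distance matrix over finest-level plant OTUs
#'   (e.g. from [generate_host_distances()]).
#' @param scale e-folding genetic distance of the preference decay.
#' @param within optional logical/integer subset of hosts among which focal
#'   hosts are drawn and the decay applies; other hosts get `background`.
#' @export
preference_distance <- function(gdist, n_fungal_otus, scale = 0.01,
                                within = NULL, background = 0.1) {
  k1 <- nrow(gdist)
  within <- if (is.null(within)) {
    seq_len(k1)
  } else if (is.logical(within)) {
    which(within)
  } else {
    as.integer(within)
  }
  focal <- sample(within, n_fungal_otus, replace = TRUE)
  W <- matrix(background, n_fungal_otus, k1)
  for (i in seq_len(n_fungal_otus)) {
    W[i, within] <- exp(-gdist[focal[i], within] / scale)
  }
  W
}

#' Write all generator outputs as a TSV bundle
#'
#' Writes the count matrix, host table, coordinates, host genetic distances,
#' and ground-truth preference matrix in the same TSV formats the readers of
#' this package consume.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of written file paths.
#' @export
write_synthetic_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hs <- generate_hosts(config)
  cc <- generate_counts(config, hs)
  gd <- generate_host_distances(hs, config)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             hosts = file.path(dir, "hosts.tsv"),
             coords = file.path(dir, "coordinates.tsv"),
             gdist = file.path(dir, "host_distances.tsv"),
             truth = file.path(dir, "true_preference.tsv"))
  write_count_matrix(cc$counts, paths["counts"])
  write_hosts(hs$hosts, paths["hosts"])
  write.table(data.frame(sample_id = hs$hosts$sample_id,
                         position_m = hs$coordinates),
              paths["coords"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_distance(gd, paths["gdist"])
  W <- cc$truth$true_preference_matrix
  dimnames(W) <- dimnames(cc$truth$expected_marginals)
  write.table(data.frame(otu_id = rownames(W), W, check.names = FALSE),
              paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
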