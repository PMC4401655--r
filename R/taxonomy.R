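#' Default whitelist of ectomycorrhizal basidiomycete families
#'
#' Families of Basidiomycota treated as putatively ectomycorrhizal (ECM) when
#' flagging fungal OTUs. The default list ships as an editable text file
#' (`inst/extdata/ecm_basidiomycota_families.txt`, one family per line, `#`
#' comments) seeded with the classic ECM lineages of published guild reviews;
#' supply your own file to override it.
#'
#' @param path optional path to a custom whitelist file.
#' @return character vector of family names.
#' @export
ecm_whitelist <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ecm_basidiomycota_families.txt",
                                package = "hostpref", mustWork = TRUE)
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Construct / read a fungal taxonomy table
#'
#' The taxonomy table assigns each fungal OTU a (possibly incomplete)
#' classification and derives an `is_ecm` flag: an OTU is putatively
#' ectomycorrhizal when its phylum is Basidiomycota and its family is on the
#' ECM whitelist. Missing ranks are encoded as `NA` (empty strings in files
#' are read as `NA`).
#'
#' @param df data frame with columns `otu_id`, `phylum`, `order`, `family`,
#'   `genus`.
#' @param whitelist character vector of ECM families, see [ecm_whitelist()].
#' @return the validated data frame with an `is_ecm` column and class
#'   `taxonomy_table`.
#' @export
taxonomy_table <- function(df, whitelist = ecm_whitelist()) {
  need <- c("otu_id", "phylum", "order", "family", "genus")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("taxonomy table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- df$otu_id[duplicated(df$otu_id)]
  if (length(dup) > 0) {
    stop("duplicate OTU IDs in taxonomy table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (r in c("phylum", "order", "family", "genus")) {
    v <- as.character(df[[r]])
    v[!is.na(v) & !nzchar(v)] <- NA
    df[[r]] <- v
  }
  df$is_ecm <- !is.na(df$phylum) & df$phylum == "Basidiomycota" &
    !is.na(df$family) & df$family %in% whitelist
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' @rdname taxonomy_table
#' @param path TSV file path.
#' @export
read_taxonomy <- function(path, whitelist = ecm_whitelist()) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  taxonomy_table(df, whitelist = whitelist)
}

#' Per-rank taxon shares of a fungal community
#'
#' For each taxonomic rank, counts the OTUs per taxon among the OTUs that are
#' assigned at that rank, and reports each taxon's percentage share of that
#' denominator (rounded half away from zero to one decimal). Optionally also
#' reports the share of putative ECM OTUs within Basidiomycota as a derived
#' "guild" row.
#'
#' @param tax a [taxonomy_table()].
#' @param ranks ranks to summarize.
#' @param include_ecm_guild add an `ecm_guild` row giving the percentage of
#'   Basidiomycota OTUs flagged as putatively ectomycorrhizal.
#' @return data frame with columns `rank`, `taxon`, `n_otus`, `n_assigned`
#'   (the denominator at that rank), and `pct`.
#' @export
summarize_taxonomy <- function(tax,
                               ranks = c("phylum", "order", "family", "genus"),
                               include_ecm_guild = TRUE) {
  if (nrow(tax) == 0) stop("taxonomy table is empty", call. = FALSE)
  out <- lapply(ranks, function(r) {
    v <- tax[[r]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    tab <- sort(table(v), decreasing = TRUE)
    data.frame(rank = r, taxon = names(tab), n_otus = as.integer(tab),
               n_assigned = length(v),
               pct = round_half_up(100 * as.integer(tab) / length(v), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (include_ecm_guild) {
    basid <- !is.na(tax$phylum) & tax$phylum == "Basidiomycota"
    if (any(basid)) {
      out <- rbind(out, data.frame(
        rank = "ecm_guild", taxon = "ECM Basidiomycota",
        n_otus = sum(tax$is_ecm & basid), n_assigned = sum(basid),
        pct = round_half_up(100 * sum(tax$is_ecm & basid) / sum(basid), 1),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Taxon occurrence frequencies in dipterocarp vs non-dipterocarp samples
#'
#' For every taxon at a given rank, computes the percentage of root samples
#' containing at least one OTU of the taxon, overall and separately for
#' samples of dipterocarp and non-dipterocarp host plants. Each taxon is
#' tested for a dipterocarp / non-dipterocarp difference with a two-sided
#' Fisher exact test on the 2x2 presence-by-host-group table, Holm-corrected
#' across all taxa in the table.
#'
#' @param occ an [occurrence_matrix()] (samples x fungal OTUs, binary).
#' @param tax a [taxonomy_table()] covering the OTUs of `occ`.
#' @param hosts a [host_assignment()] covering the samples of `occ`.
#' @param rank taxonomic rank to group OTUs by (`"phylum"`, `"order"`,
#'   `"family"`, or `"genus"`).
#' @param include_ecm append a pooled "ECM Basidiomycota" taxon built from
#'   the `is_ecm` flags.
#' @param alpha significance level for the Holm-adjusted flag.
#' @return data frame with per-taxon OTU counts, frequencies (percent, one
#'   decimal) in all / dipterocarp / non-dipterocarp samples, raw and
#'   Holm-adjusted Fisher p-values, and a significance flag.
#' @export
frequency_table <- function(occ, tax, hosts, rank = "family",
                            include_ecm = TRUE, alpha = 0.05) {
  if (!rank %in% c("phylum", "order", "family", "genus")) {
    stop("unknown rank '", rank, "'", call. = FALSE)
  }
  idx <- match(rownames(occ), hosts$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from host table: ",
         paste(utils::head(rownames(occ)[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  dip <- hosts$is_dipterocarp[idx]
  if (sum(dip) == 0 || sum(!dip) == 0) {
    stop("a host group (dipterocarp or non-dipterocarp) has zero samples",
         call. = FALSE)
  }
  tax <- tax[tax$otu_id %in% colnames(occ), , drop = FALSE]
  groups <- split(tax$otu_id, tax[[rank]])
  groups <- groups[lengths(groups) > 0]
  if (include_ecm && any(tax$is_ecm)) {
    groups <- c(groups, list(`ECM Basidiomycota` = tax$otu_id[tax$is_ecm]))
  }
  if (length(groups) == 0) stop("no taxa assigned at rank '", rank, "'",
                                call. = FALSE)
  rows <- lapply(names(groups), function(g) {
    pres <- rowSums(occ[, groups[[g]], drop = FALSE]) > 0
    tab <- matrix(c(sum(pres & dip), sum(pres & !dip),
                    sum(!pres & dip), sum(!pres & !dip)), nrow = 2)
    data.frame(taxon = g, n_otus = length(groups[[g]]),
               freq_all = round_half_up(100 * mean(pres), 1),
               freq_dip = round_half_up(100 * mean(pres[dip]), 1),
               freq_nondip = round_half_up(100 * mean(pres[!dip]), 1),
               p = fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p, method = "holm")
  out$significant <- out$p_holm < alpha
  rownames(out) <- NULL
  out
}
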