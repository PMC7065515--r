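# Aggregation of OTU count tables into taxon/clade profiles across the three
# deep habitats (bottom seawater, sediment, basaltic crust): relative
# abundance ratios, habitat summaries, within-family clade profiles, and the
# OTU-by-sample heatmap table.

HABITAT_LEVELS <- c("seawater", "sediment", "basalt")

#' Community count table
#'
#' A samples-by-OTU count matrix with per-sample habitat/depth metadata and
#' per-OTU taxonomy (family and clade labels, possibly "unclassified").
#'
#' @param counts Numeric matrix of non-negative counts; rownames are sample
#'   ids, colnames OTU ids.
#' @param metadata data.frame with columns `sample`, `habitat` (one of
#'   `"seawater"`, `"sediment"`, `"basalt"`), `depth_mbsf`; one row per
#'   sample of `counts`.
#' @param taxonomy data.frame with columns `otu`, `family`, `clade`; OTUs of
#'   `counts` missing from it are filled in as "unclassified".
#' @return A list of class `community_table`.
#' @export
community_table <- function(counts, metadata, taxonomy) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), !is.null(rownames(counts)),
            !is.null(colnames(counts)),
            all(c("sample", "habitat", "depth_mbsf") %in% names(metadata)),
            all(c("otu", "family", "clade") %in% names(taxonomy)))
  if (!all(rownames(counts) %in% metadata$sample)) {
    stop("every sample needs a metadata row")
  }
  if (!all(metadata$habitat %in% HABITAT_LEVELS)) {
    stop("habitat must be one of: ", paste(HABITAT_LEVELS, collapse = ", "))
  }
  metadata <- metadata[match(rownames(counts), metadata$sample), , drop = FALSE]
  missing <- setdiff(colnames(counts), taxonomy$otu)
  if (length(missing) > 0) {
    taxonomy <- rbind(taxonomy[, c("otu", "family", "clade")],
                      data.frame(otu = missing, family = "unclassified",
                                 clade = "unclassified"))
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu), , drop = FALSE]
  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "community_table")
}

#' Read a community table from TSV files
#'
#' @param counts_path Long-format TSV with columns `otu_id`, `sample`,
#'   `count`.
#' @param taxonomy_path TSV with columns `otu`, `family`, `clade`.
#' @param metadata_path TSV with columns `sample`, `habitat`, `depth_mbsf`.
#' @return A [community_table()].
#' @export
read_community_table <- function(counts_path, taxonomy_path, metadata_path) {
  long <- utils::read.delim(counts_path, comment.char = "#")
  stopifnot(all(c("otu_id", "sample", "count") %in% names(long)))
  counts <- stats::xtabs(count ~ sample + otu_id, data = long)
  counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  community_table(counts,
                  utils::read.delim(metadata_path, comment.char = "#"),
                  utils::read.delim(taxonomy_path, comment.char = "#"))
}

# Resolve a taxon selector into OTU column names. A selector is "total" (all
# OTUs), a character vector of OTU ids, or a list with `family` and/or
# `clade` elements.
select_otus <- function(table, selector) {
  tax <- table$taxonomy
  otus <- if (identical(selector, "total")) {
    colnames(table$counts)
  } else if (is.character(selector)) {
    unknown <- setdiff(selector, colnames(table$counts))
    if (length(unknown) > 0) stop("unknown OTUs: ", paste(unknown, collapse = ", "))
    selector
  } else if (is.list(selector)) {
    keep <- rep(TRUE, nrow(tax))
    if (!is.null(selector$family)) keep <- keep & tax$family %in% selector$family
    if (!is.null(selector$clade)) keep <- keep & tax$clade %in% selector$clade
    tax$otu[keep]
  } else {
    stop("selector must be 'total', OTU ids, or list(family=, clade=)")
  }
  if (length(otus) == 0) stop("selector matches no OTUs")
  otus
}

#' Per-sample relative abundance of one taxon group within another
#'
#' 100 x (numerator reads / denominator reads) per sample, e.g. the focal
#' family within the total community or within a domain. Samples whose
#' denominator is zero are flagged and their percent set to NA so they drop
#' out of downstream summaries.
#'
#' @param table A [community_table()].
#' @param numerator,denominator Taxon selectors: `"total"`, a character
#'   vector of OTU ids, or `list(family = ..., clade = ...)`.
#' @return A data.frame with columns `sample`, `habitat`, `depth_mbsf`,
#'   `numerator_reads`, `denominator_reads`, `percent`, `flagged`.
#' @export
relative_abundance <- function(table, numerator, denominator = "total") {
  stopifnot(inherits(table, "community_table"))
  num <- rowSums(table$counts[, select_otus(table, numerator), drop = FALSE])
  den <- rowSums(table$counts[, select_otus(table, denominator), drop = FALSE])
  flagged <- den == 0
  pct <- ifelse(flagged, NA_real_, 100 * num / den)
  data.frame(sample = rownames(table$counts),
             habitat = table$metadata$habitat,
             depth_mbsf = table$metadata$depth_mbsf,
             numerator_reads = num, denominator_reads = den,
             percent = pct, flagged = flagged, row.names = NULL)
}

#' Summarize per-sample percentages by habitat
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) per
#' habitat group; single-sample groups report SD 0. NA percentages (flagged
#' samples) are excluded.
#'
#' @param percents Either the data.frame returned by [relative_abundance()]
#'   or a numeric vector of percentages.
#' @param grouping Habitat tags, required when `percents` is a bare vector.
#' @return A data.frame with columns `group`, `mean_percent`, `sd_percent`,
#'   `n`.
#' @export
habitat_summary <- function(percents, grouping = NULL) {
  if (is.data.frame(percents)) {
    grouping <- percents$habitat
    percents <- percents$percent
  }
  stopifnot(length(percents) == length(grouping))
  keep <- !is.na(percents)
  percents <- percents[keep]
  grouping <- grouping[keep]
  groups <- unique(grouping)
  out <- lapply(groups, function(g) {
    v <- percents[grouping == g]
    data.frame(group = g, mean_percent = mean(v),
               sd_percent = if (length(v) == 1) 0 else stats::sd(v),
               n = length(v))
  })
  do.call(rbind, out)
}

# seawater first, then sediment by depth, then basalt by depth
habitat_order <- function(metadata) {
  order(match(metadata$habitat, HABITAT_LEVELS), metadata$depth_mbsf)
}

#' Within-family clade composition per sample
#'
#' For the OTUs of one family, the proportion of the family's reads in each
#' clade, per sample, ordered seawater, then sediment and basalt by depth
#' (the layout of depth-profile figures). Samples with no reads in the
#' family are flagged with NA proportions.
#'
#' @param table A [community_table()].
#' @param family Family label present in the taxonomy.
#' @return A data.frame with `sample`, `habitat`, `depth_mbsf`,
#'   `family_reads`, `flagged`, and one proportion column per clade (rows
#'   sum to 1 for unflagged samples).
#' @export
clade_profile <- function(table, family) {
  stopifnot(inherits(table, "community_table"))
  otus <- select_otus(table, list(family = family))
  clades <- table$taxonomy$clade[match(otus, table$taxonomy$otu)]
  fam_counts <- table$counts[, otus, drop = FALSE]
  clade_levels <- unique(clades)
  agg <- sapply(clade_levels, function(cl) {
    rowSums(fam_counts[, clades == cl, drop = FALSE])
  })
  agg <- matrix(agg, nrow = nrow(fam_counts),
                dimnames = list(rownames(fam_counts), clade_levels))
  tot <- rowSums(agg)
  props <- agg / ifelse(tot == 0, NA_real_, tot)
  ord <- habitat_order(table$metadata)
  out <- data.frame(sample = rownames(table$counts),
                    habitat = table$metadata$habitat,
                    depth_mbsf = table$metadata$depth_mbsf,
                    family_reads = tot, flagged = tot == 0,
                    row.names = NULL)
  out <- cbind(out, as.data.frame(props))
  out[ord, , drop = FALSE]
}

#' OTU-by-sample heatmap table for one family
#'
#' Relative abundance (percent of each sample's total reads) of each OTU of
#' the family, with samples ordered seawater, then sediment and basalt by
#' depth, and OTU columns grouped by clade. Row sums equal the family's
#' per-sample relative abundance. Samples with no reads in the family carry
#' NA (blank) rather than zero, matching how absences are drawn in heatmap
#' figures.
#'
#' @param table A [community_table()].
#' @param family Family label.
#' @return A numeric matrix (samples x OTUs, percent) with attributes
#'   `clade` (per-column clade labels) and `metadata` (ordered sample
#'   metadata).
#' @export
heatmap_table <- function(table, family) {
  stopifnot(inherits(table, "community_table"))
  if (!family %in% table$taxonomy$family) {
    ord <- habitat_order(table$metadata)
    m <- matrix(numeric(0), nrow = nrow(table$counts), ncol = 0,
                dimnames = list(rownames(table$counts)[ord], NULL))
    attr(m, "clade") <- character(0)
    attr(m, "metadata") <- table$metadata[ord, , drop = FALSE]
    return(m)
  }
  otus <- select_otus(table, list(family = family))
  clades <- table$taxonomy$clade[match(otus, table$taxonomy$otu)]
  col_ord <- order(match(clades, unique(clades)))
  otus <- otus[col_ord]
  clades <- clades[col_ord]
  ord <- habitat_order(table$metadata)
  fam <- table$counts[ord, otus, drop = FALSE]
  tot <- rowSums(table$counts)[ord]
  m <- 100 * fam / tot
  m[rowSums(fam) == 0, ] <- NA_real_
  attr(m, "clade") <- stats::setNames(clades, otus)
  attr(m, "metadata") <- table$metadata[ord, , drop = FALSE]
  m
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("Community table: %d samples x %d OTUs, %d families\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$taxonomy$family))))
  print(table(x$metadata$habitat))
  invisible(x)
}
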