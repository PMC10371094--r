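RANK_SCHEMA <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Read a taxa abundance table
#'
#' TSV with columns `taxon_id`, `lineage` (semicolon-separated
#' kingdom;phylum;class;order;family;genus, possibly truncated), `rank`
#' (the taxon's own rank, or `host`) and one count column per sample.
#' Rows with rank `host` (secondary human-aligned reads reported by a
#' classifier) are carried through but excluded from every microbial
#' computation.
#'
#' @param path TSV path.
#' @return a `data.table` of class `TaxaTable`.
#' @export
read_taxa_table <- function(path) {
  if (!file.exists(path)) stop("taxa table not found: ", path)
  tt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("taxon_id", "lineage", "rank")
  if (!all(need %in% names(tt)))
    stop("taxa table must have columns taxon_id, lineage, rank")
  smp <- taxa_sample_cols(tt)
  if (length(smp) == 0L) stop("taxa table has no sample columns")
  neg <- vapply(smp, function(s) any(tt[[s]] < 0), logical(1))
  if (any(neg)) stop("negative counts in taxa table")
  data.table::setattr(tt, "class", c("TaxaTable", class(tt)))
  tt
}

taxa_sample_cols <- function(table) {
  setdiff(names(table), c("taxon_id", "lineage", "rank"))
}

is_host_row <- function(table) {
  tolower(table$rank) == "host" |
    tolower(sub(";.*$", "", table$lineage)) == "host"
}

#' Microbial count matrix of a taxa table (host rows dropped)
#' @param table a `TaxaTable`.
#' @return numeric matrix taxa x samples, rownames `taxon_id`.
#' @export
taxa_counts <- function(table) {
  tt <- table[!is_host_row(table), ]
  m <- as.matrix(tt[, taxa_sample_cols(table), with = FALSE])
  rownames(m) <- tt$taxon_id
  storage.mode(m) <- "numeric"
  m
}

#' Aggregate a taxa table to a taxonomic rank
#'
#' Counts are summed over taxa sharing the label at the requested rank of
#' their lineage; taxa whose lineage does not reach that rank are pooled
#' into `unclassified`. Host rows are excluded. Aggregation conserves the
#' per-sample microbial totals.
#'
#' @param table a `TaxaTable`.
#' @param rank one of phylum, class, order, family, genus (or kingdom).
#' @return a rank-level `TaxaTable`.
#' @export
aggregate_rank <- function(table, rank = c("phylum", "class", "order",
                                           "family", "genus", "kingdom")) {
  rank <- match.arg(rank)
  pos <- match(rank, RANK_SCHEMA)
  tt <- table[!is_host_row(table), ]
  smp <- taxa_sample_cols(table)
  if (nrow(tt) == 0L) {
    out <- data.table::data.table(taxon_id = character(),
                                  lineage = character(),
                                  rank = character())
    for (s in smp) out[[s]] <- numeric()
    data.table::setattr(out, "class", c("TaxaTable", class(out)))
    return(out)
  }
  parts <- strsplit(tt$lineage, ";", fixed = TRUE)
  label <- vapply(parts, function(p) {
    if (length(p) >= pos && nzchar(trimws(p[pos]))) trimws(p[pos])
    else "unclassified"
  }, character(1))
  agg <- tt[, lapply(.SD, sum), by = .(taxon_id = label),
            .SDcols = smp]
  out <- data.table::data.table(taxon_id = agg$taxon_id,
                                lineage = agg$taxon_id,
                                rank = rank)
  out <- cbind(out, agg[, ..smp])
  data.table::setattr(out, "class", c("TaxaTable", class(out)))
  out
}

#' Per-sample relative abundances (microbial taxa only)
#' @param table a `TaxaTable`.
#' @return matrix of per-sample fractions summing to 1 (columns with zero
#'   microbial reads are `NaN`).
#' @export
relative_abundance <- function(table) {
  m <- taxa_counts(table)
  sweep(m, 2, colSums(m), "/")
}

#' Shannon alpha diversity
#'
#' `H = -sum p ln p` over a sample's relative microbial abundances, in
#' nats (the ecology convention); computed with [vegan::diversity()].
#'
#' @param x a `TaxaTable` (one value per sample) or a nonnegative count
#'   vector for a single sample.
#' @return named numeric vector of diversities.
#' @export
alpha_diversity <- function(x) {
  if (inherits(x, "TaxaTable")) {
    m <- taxa_counts(x)
    if (any(colSums(m) == 0)) stop("sample with zero microbial reads")
    return(apply(m, 2, function(v) vegan::diversity(v, index = "shannon")))
  }
  v <- as.numeric(x)
  if (any(v < 0)) stop("negative counts")
  if (sum(v) == 0) stop("all-zero sample")
  vegan::diversity(v, index = "shannon")
}

#' Read-origin percentages
#'
#' Splits a sample's total reads into human-aligned, microbial-aligned and
#' unmapped percentages.
#'
#' @param human_mapped,microbial_mapped,total read counts with
#'   `total >= human_mapped + microbial_mapped`, `total > 0`.
#' @return named numeric vector `c(human_pct, microbial_pct, unmapped_pct)`
#'   summing to 100.
#' @export
microbial_read_percent <- function(human_mapped, microbial_mapped, total) {
  stopifnot(human_mapped >= 0, microbial_mapped >= 0)
  if (total <= 0) stop("total read count must be positive")
  if (total < human_mapped + microbial_mapped)
    stop("total must be at least human + microbial")
  c(human_pct = 100 * human_mapped / total,
    microbial_pct = 100 * microbial_mapped / total,
    unmapped_pct = 100 * (total - human_mapped - microbial_mapped) / total)
}

#' Write a taxa table TSV
#' @param table a `TaxaTable`.
#' @param path output path.
#' @export
write_taxa_table <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}
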