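# Tabular and graph I/O plus taxonomic aggregation.
#
# The canonical on-disk formats are plain TSV (counts, taxonomy, sample
# metadata) and GraphML / CSV edge lists (networks).  A count table in
# memory is an integer-valued base matrix, rows = samples, columns = OTUs,
# with unique dimnames -- the orientation vegan expects.

#' Validate a count table
#'
#' Checks the invariants every analysis operation relies on: unique sample
#' and OTU identifiers, non-negative integer counts, at least two samples
#' and two OTUs.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns, with
#'   dimnames.
#' @return the validated matrix (invisibly unchanged).
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    fail("count table must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    fail("count table must carry sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    fail("duplicate sample IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    fail("duplicate OTU IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is_wholenumber(counts) | counts < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    fail("non-integer or negative count at sample '", rownames(counts)[i[1]],
         "', OTU '", colnames(counts)[i[2]], "' (value ", counts[bad[1]], ")")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2)
    fail("count table needs at least 2 samples and 2 OTUs")
  invisible(counts)
}

#' Read a sample-by-OTU count table from TSV
#'
#' @param path TSV file with a header row of IDs; by default OTUs are rows
#'   (the common QIIME export) and samples are columns.
#' @param orientation `"otus_as_rows"` (default) or `"samples_as_rows"`.
#' @return integer matrix, samples x OTUs.
#' @export
read_count_table <- function(path, orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(df) < 2) fail("count table TSV needs an ID column plus data columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    fail("duplicate row IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    fail("non-numeric cell in ", path, " at row '", ids[bad[1, 1]], "', column '",
         colnames(df)[-1][bad[1, 2]], "'")
  }
  rownames(m) <- ids
  if (orientation == "otus_as_rows") m <- t(m)
  storage.mode(m) <- "double"
  validate_count_table(m)
  m
}

#' Write a count table to TSV
#'
#' Written in the same orientation [read_count_table()] expects, so
#' write-then-read is the identity.
#'
#' @param counts samples x OTUs matrix.
#' @param path output TSV.
#' @param orientation row convention for the file (default OTUs as rows).
#' @export
write_count_table <- function(counts, path,
                              orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  validate_count_table(counts)
  m <- if (orientation == "otus_as_rows") t(counts) else counts
  df <- data.frame(ID = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- if (orientation == "otus_as_rows") "otu_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a QIIME-style taxonomy TSV
#'
#' Expects two columns: OTU ID and a rank-prefixed lineage string such as
#' `k__Fungi; p__Basidiomycota; c__...; o__Tremellales; f__; g__`.
#' A missing or empty name, or the literal `unclassified`, marks the rank
#' unclassified (stored as `NA`).
#'
#' @param path TSV with header.
#' @return data.frame with columns `otu_id`, `kingdom` ... `genus`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) fail("taxonomy TSV needs otu_id and lineage columns")
  parse_lineage_strings(as.character(df[[1]]), as.character(df[[2]]))
}

parse_lineage_strings <- function(otu_ids, lineages) {
  out <- matrix(NA_character_, nrow = length(otu_ids), ncol = length(RANKS),
                dimnames = list(NULL, RANKS))
  for (i in seq_along(lineages)) {
    parts <- trimws(strsplit(lineages[i], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      if (!grepl("^[kpcofg]__", p)) next
      letter <- substr(p, 1, 1)
      rank <- names(RANK_LETTERS)[RANK_LETTERS == letter]
      name <- sub("^[kpcofg]__", "", p)
      if (nzchar(name) && !grepl("^unclassified$", name, ignore.case = TRUE))
        out[i, rank] <- name
    }
  }
  data.frame(otu_id = otu_ids, out, stringsAsFactors = FALSE)
}

#' Write a taxonomy table as rank-prefixed lineage strings
#'
#' @param tax data.frame as returned by [read_taxonomy()].
#' @param path output TSV.
#' @export
write_taxonomy <- function(tax, path) {
  lineage <- apply(tax[, RANKS, drop = FALSE], 1, function(row) {
    paste(paste0(RANK_LETTERS, "__", ifelse(is.na(row), "", row)), collapse = "; ")
  })
  utils::write.table(data.frame(otu_id = tax$otu_id, taxonomy = lineage),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (group, site, soil variables) from TSV
#'
#' @param path TSV with columns `sample_id`, `group`, `site` and any soil
#'   variable columns (e.g. pH, TC, TN, TP, AN, NN, AP).
#' @return data.frame keyed by `sample_id`.
#' @export
read_sample_frame <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "site")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) fail("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    fail("duplicate sample IDs in metadata")
  soil <- setdiff(colnames(df), need)
  for (v in soil) if (any(!is.finite(df[[v]])))
    fail("non-finite value in soil variable '", v, "'")
  df
}

#' Write sample metadata to TSV
#' @param samples data.frame as returned by [read_sample_frame()].
#' @param path output TSV.
#' @export
write_sample_frame <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate OTU counts to a higher taxonomic rank
#'
#' OTUs classified at `rank` are pooled under the rank name.  An OTU
#' unclassified at `rank` contributes to a composite column named after its
#' deepest classified ancestor, pattern
#' `<rankletter>_unclassified_<ancestorletter>__<name>` (e.g. an OTU known
#' only to order Tremellales aggregates at family level into
#' `f_unclassified_o__Tremellales`).  An OTU with no classified rank at all,
#' or absent from the taxonomy, falls into `<rankletter>_unclassified`.
#' Total counts are conserved at every rank.
#'
#' @param counts samples x OTUs matrix.
#' @param tax taxonomy data.frame ([read_taxonomy()]).
#' @param rank one of kingdom, phylum, class, order, family, genus.
#' @return samples x taxa matrix.
#' @export
aggregate_to_rank <- function(counts, tax, rank) {
  if (!rank %in% RANKS) fail("unknown rank '", rank, "'")
  validate_count_table(counts)
  ri <- match(rank, RANKS)
  idx <- match(colnames(counts), tax$otu_id)
  tm <- as.matrix(tax[, RANKS])          # character matrix, NA preserved
  labels <- vapply(seq_along(idx), function(j) {
    if (is.na(idx[j])) return(paste0(RANK_LETTERS[ri], "_unclassified"))
    row <- tm[idx[j], ]
    if (!is.na(row[ri])) return(row[ri])
    above <- seq_len(ri - 1L)
    cls <- above[!is.na(row[above])]
    if (!length(cls)) return(paste0(RANK_LETTERS[ri], "_unclassified"))
    deepest <- max(cls)
    paste0(RANK_LETTERS[ri], "_unclassified_", RANK_LETTERS[deepest], "__", row[deepest])
  }, character(1))
  agg <- t(rowsum(t(counts), group = labels))
  agg[, order(colnames(agg)), drop = FALSE]
}

#' Export a co-occurrence network
#'
#' Nodes carry abundance, phylum and module attributes; edges carry the
#' signed Spearman rho, its absolute value as weight, and a
#' positive/negative sign label, so the file loads directly into Gephi.
#'
#' @param net igraph object (see [build_cooccurrence_network()]).
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"` (CSV).
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (igraph::vcount(net) == 0) warning("writing an empty network")
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(net, what = "edges")
    utils::write.csv(el, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path GraphML file.
#' @return igraph object.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
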