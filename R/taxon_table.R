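#' Construct a genus-level taxon table
#'
#' A taxon table couples a samples-by-genera count matrix with a taxonomy map
#' assigning each genus to a phylum. It is the container every compositional
#' feature is computed from.
#'
#' @param counts numeric matrix of non-negative counts, samples in rows
#'   (rownames = sample ids), genera in columns (colnames = genus names).
#' @param taxonomy data.frame with columns `genus` and `phylum`, covering at
#'   least every genus in `counts`.
#' @return an object of class `taxon_table`: a list with elements `counts`
#'   and `taxonomy`.
#' @export
taxon_table <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  stop_if(is.null(rownames(counts)) || is.null(colnames(counts)),
          "counts must have sample rownames and genus colnames")
  stop_if(anyDuplicated(rownames(counts)) > 0, "sample ids must be unique")
  stop_if(any(counts < 0) || any(!is.finite(counts)), "counts must be finite and non-negative")
  stop_if(!all(c("genus", "phylum") %in% names(taxonomy)),
          "taxonomy needs columns 'genus' and 'phylum'")
  taxonomy$genus <- as.character(taxonomy$genus)
  taxonomy$phylum <- as.character(taxonomy$phylum)
  missing_tax <- setdiff(colnames(counts), taxonomy$genus)
  stop_if(length(missing_tax) > 0, "genera without taxonomy entry: %s",
          paste(missing_tax, collapse = ", "))
  structure(list(counts = counts, taxonomy = taxonomy), class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d samples x %d genera (%d phyla)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$taxonomy$phylum[x$taxonomy$genus %in% colnames(x$counts)]))))
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$counts)

# phylum label per column of the count matrix
phylum_of <- function(tt) {
  tax <- tt$taxonomy$phylum[match(colnames(tt$counts), tt$taxonomy$genus)]
  names(tax) <- colnames(tt$counts)
  tax
}

#' Read / write taxon tables as TSV
#'
#' Counts are stored as a TSV with a `sample_id` first column and one column
#' per genus; taxonomy as a two-column TSV `genus<TAB>phylum`.
#'
#' @param counts_path path to the count TSV.
#' @param taxonomy_path path to the taxonomy TSV.
#' @return `read_taxon_table` returns a [taxon_table()].
#' @export
read_taxon_table <- function(counts_path, taxonomy_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(names(df)[1] != "sample_id", "count TSV must start with a sample_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  tax <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  taxon_table(m, tax)
}

#' @rdname read_taxon_table
#' @param tt a [taxon_table()].
#' @export
write_taxon_table <- function(tt, counts_path, taxonomy_path) {
  df <- data.frame(sample_id = rownames(tt$counts), tt$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tt$taxonomy[, c("genus", "phylum")], taxonomy_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, taxonomy_path))
}

#' Curated short-chain fatty acid producer genera
#'
#' The default proxy definition: 17 genera with documented genetic potential
#' to produce acetate, propionate and/or butyrate, together with the
#' metabolite each produces. The aggregated count of these genera serves as a
#' per-sample proxy for unmeasured SCFA production capacity.
#'
#' @return data.frame with columns `genus`, `phylum`, `scfa`.
#' @export
scfa_producers <- function() {
  path <- system.file("extdata", "scfa_producers.tsv", package = "microgrowth")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# whitespace/case-normalised genus matching key
genus_key <- function(x) tolower(trimws(gsub("\\s+", " ", x)))
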