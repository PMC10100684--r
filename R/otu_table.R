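#' Construct an OTU table
#'
#' An OTU table holds non-negative integer read counts for taxa (rows) across
#' samples (columns), with optional per-taxon taxonomy strings and a domain
#' flag distinguishing prokaryotes from microeukaryotes. It is the common
#' currency of every analysis stage in the package.
#'
#' @param counts numeric matrix of non-negative integers, taxa x samples.
#'   Row and column names are required and must be unique; they become the
#'   taxon and sample identifiers.
#' @param taxonomy optional character vector of lineage strings, one per taxon.
#' @param domain optional character vector, one per taxon, each either
#'   `"prokaryote"` or `"microeukaryote"`.
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxon_ids`, `sample_ids`, `taxonomy`, `domain`.
#' @examples
#' m <- matrix(c(5L, 3L, 1L, 1L, 0L, 2L), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
#' tab <- otu_table(m)
#' tab
#' @export
otu_table <- function(counts, taxonomy = NULL, domain = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix (taxa x samples)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must have row (taxon) and column (sample) names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("taxon and sample identifiers must be unique")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy) && length(taxonomy) != nrow(counts)) {
    stop("'taxonomy' must have one entry per taxon")
  }
  if (!is.null(domain)) {
    if (length(domain) != nrow(counts)) {
      stop("'domain' must have one entry per taxon")
    }
    if (!all(domain %in% c("prokaryote", "microeukaryote"))) {
      stop("'domain' entries must be 'prokaryote' or 'microeukaryote'")
    }
  }
  empty <- colSums(counts) == 0
  if (any(empty)) {
    stop("samples with all-zero counts: ",
         paste(colnames(counts)[empty], collapse = ", "))
  }
  structure(
    list(counts = counts,
         taxon_ids = rownames(counts),
         sample_ids = colnames(counts),
         taxonomy = taxonomy,
         domain = domain),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d taxa x %d samples, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  if (!is.null(x$domain)) {
    cat("  domains:", paste(sprintf("%s=%d", names(table(x$domain)),
                                    table(x$domain)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an OTU table
#'
#' @param table an [otu_table].
#' @param taxa,samples character or logical or integer indices; `NULL` keeps all.
#' @param drop_empty drop samples whose counts become all zero after taxon
#'   subsetting (default `FALSE`, which errors instead, preserving the class
#'   invariant explicitly).
#' @return An [otu_table].
#' @export
subset_otu_table <- function(table, taxa = NULL, samples = NULL,
                             drop_empty = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  cnt <- table$counts
  ti <- if (is.null(taxa)) seq_len(nrow(cnt)) else taxa
  si <- if (is.null(samples)) seq_len(ncol(cnt)) else samples
  cnt <- cnt[ti, si, drop = FALSE]
  if (drop_empty) cnt <- cnt[, colSums(cnt) > 0, drop = FALSE]
  keep <- if (is.character(ti)) match(ti, table$taxon_ids) else which(
    if (is.logical(ti)) ti else seq_len(length(table$taxon_ids)) %in% ti)
  otu_table(cnt,
            taxonomy = if (!is.null(table$taxonomy)) table$taxonomy[keep],
            domain = if (!is.null(table$domain)) table$domain[keep])
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table].
#' @return Numeric matrix, taxa x samples, columns summing to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  sweep(table$counts, 2, colSums(table$counts), "/")
}

#' Read an OTU table from TSV
#'
#' Expects the first column to hold taxon identifiers, one column per sample,
#' and optionally a final `taxonomy` column whose strings may carry a domain
#' prefix `"prok|"` or `"euk|"`.
#'
#' @param path file path.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  taxon_ids <- as.character(df[[1L]])
  df <- df[-1L]
  taxonomy <- NULL
  domain <- NULL
  if (ncol(df) > 0 && names(df)[ncol(df)] == "taxonomy") {
    taxonomy <- as.character(df[[ncol(df)]])
    df <- df[-ncol(df)]
    pre <- sub("\\|.*$", "", taxonomy)
    if (all(pre %in% c("prok", "euk"))) {
      domain <- ifelse(pre == "prok", "prokaryote", "microeukaryote")
      taxonomy <- sub("^(prok|euk)\\|", "", taxonomy)
    }
  }
  cnt <- as.matrix(df)
  rownames(cnt) <- taxon_ids
  otu_table(cnt, taxonomy = taxonomy, domain = domain)
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table()]: first column `taxon_id`, one column per
#' sample, and a final `taxonomy` column (domain-prefixed) when taxonomy or
#' domain annotations are present.
#'
#' @param table an [otu_table].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(taxon_id = table$taxon_ids, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$domain) || !is.null(table$taxonomy)) {
    tax <- table$taxonomy %||% rep("", length(table$taxon_ids))
    if (!is.null(table$domain)) {
      tax <- paste0(ifelse(table$domain == "prokaryote", "prok|", "euk|"), tax)
    }
    df$taxonomy <- tax
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write sample metadata TSV
#'
#' Metadata tables have columns `sample_id`, `salinity`, `temperature`,
#' `region`.
#'
#' @param path file path.
#' @return `read_metadata` returns a data.frame; `write_metadata` returns
#'   `path` invisibly.
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_metadata
#' @param metadata data.frame of per-sample metadata.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
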