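#' Per-sample alpha diversity
#'
#' Computes, for every sample, the six indices customarily reported for
#' amplicon surveys: observed richness, Shannon-Wiener H' (natural log),
#' Gini-Simpson 1 - sum(p^2), Pielou's evenness H'/ln(richness) (0 for a
#' single-taxon sample), bias-corrected Chao1 and ACE (rare-taxon cutoff 10).
#' Richness estimators are delegated to [vegan::estimateR()].
#'
#' @param table an [otu_table]; every sample must have total count >= 1.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson`, `pielou`, `chao1`, `ace`.
#' @examples
#' m <- matrix(rep(5L, 4), 4, 1, dimnames = list(paste0("t", 1:4), "S1"))
#' compute_alpha(otu_table(m))  # shannon = log(4), pielou = 1
#' @export
compute_alpha <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  x <- t(table$counts)  # samples x taxa, vegan orientation
  tot <- rowSums(x)
  if (any(tot < 1)) {
    stop("empty sample(s): ", paste(rownames(x)[tot < 1], collapse = ", "))
  }
  sh <- vegan::diversity(x, index = "shannon")
  si <- vegan::diversity(x, index = "simpson")
  rich <- vegan::specnumber(x)
  est <- vegan::estimateR(x)
  ace <- as.numeric(est["S.ACE", ])
  # with no rare taxa (all counts above the cutoff) ACE reduces to the
  # observed richness; estimateR returns NaN for that 0/0 corner
  ace[is.nan(ace)] <- rich[is.nan(ace)]
  pielou <- ifelse(rich > 1, sh / log(rich), 0)
  data.frame(sample_id = rownames(x),
             richness = as.integer(rich),
             shannon = as.numeric(sh),
             simpson = as.numeric(si),
             pielou = as.numeric(pielou),
             chao1 = as.numeric(est["S.chao1", ]),
             ace = ace,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rarefaction curves
#'
#' Mean observed richness over random subsamples drawn without replacement at
#' each depth, per sample. Depths exceeding a sample's total are skipped for
#' that sample with a warning (reported as `NA`).
#'
#' @param table an [otu_table].
#' @param depths increasing vector of subsampling depths.
#' @param replicates number of random subsamples per depth (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `depth`, `richness`.
#' @export
rarefaction_curve <- function(table, depths, replicates = 50, seed = 1L) {
  stopifnot(inherits(table, "otu_table"))
  if (replicates < 1) stop("'replicates' must be >= 1")
  depths <- sort(unique(as.integer(depths)))
  cnt <- table$counts
  with_seed(derive_seed(seed, "rarefaction"), function() {
    out <- expand.grid(sample_id = colnames(cnt), depth = depths,
                       stringsAsFactors = FALSE)
    out$richness <- NA_real_
    skipped <- FALSE
    for (r in seq_len(nrow(out))) {
      j <- out$sample_id[r]
      d <- out$depth[r]
      tot <- sum(cnt[, j])
      if (d > tot) { skipped <- TRUE; next }
      pool <- rep(seq_len(nrow(cnt)), cnt[, j])
      out$richness[r] <- mean(vapply(seq_len(replicates), function(i) {
        length(unique(pool[sample.int(tot, d)]))
      }, numeric(1)))
    }
    if (skipped) warning("depths larger than some sample totals were skipped")
    out
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) on optionally transformed
#' abundances, via [vegan::vegdist()].
#'
#' @param table an [otu_table] with >= 2 samples.
#' @param transform `"none"`, `"log1p"` or `"sqrt"`, applied to counts before
#'   the distance; always explicit, never implicit.
#' @return A `dist` object over samples with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(table, transform = c("none", "log1p", "sqrt")) {
  stopifnot(inherits(table, "otu_table"))
  transform <- match.arg(transform)
  x <- t(table$counts)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (any(rowSums(x) == 0)) stop("all-zero sample makes Bray-Curtis undefined")
  x <- switch(transform, none = x, log1p = log1p(x), sqrt = sqrt(x))
  vegan::vegdist(x, method = "bray")
}

#' Spearman correlations of alpha diversity with environmental variables
#'
#' The standard estuary-survey table: Spearman's r (average ranks for ties)
#' and two-sided p from the t approximation, for every diversity index
#' against every requested metadata variable. A constant variable or index
#' yields a flagged `NA` row rather than an error.
#'
#' @param alpha data.frame from [compute_alpha()].
#' @param metadata data.frame with `sample_id` plus the variables.
#' @param variables character vector of metadata column names
#'   (default `c("salinity", "temperature")`).
#' @param transform `"none"` or `"log1p"` applied to the index values
#'   (mirrors correlating log-transformed biotic data).
#' @return data.frame with columns `index`, `variable`, `spearman_r`, `p`,
#'   `note`.
#' @export
env_correlations <- function(alpha, metadata,
                             variables = c("salinity", "temperature"),
                             transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  stopifnot(all(c("sample_id") %in% names(metadata)),
            all(variables %in% names(metadata)))
  md <- metadata[match(alpha$sample_id, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata is missing some samples")
  if (nrow(alpha) < 4) stop("need at least 4 samples for correlations")
  indices <- c("richness", "shannon", "simpson", "pielou", "chao1", "ace")
  out <- expand.grid(index = indices, variable = variables,
                     stringsAsFactors = FALSE)
  out$spearman_r <- NA_real_
  out$p <- NA_real_
  out$note <- ""
  for (r in seq_len(nrow(out))) {
    y <- alpha[[out$index[r]]]
    if (transform == "log1p") y <- log1p(y)
    v <- md[[out$variable[r]]]
    if (stats::sd(v) == 0 || stats::sd(y) == 0) {
      out$note[r] <- "constant input; correlation undefined"
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(y, v, method = "spearman", exact = FALSE))
    out$spearman_r[r] <- unname(ct$estimate)
    out$p[r] <- ct$p.value
  }
  out
}
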