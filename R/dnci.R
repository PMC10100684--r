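#' SIMPER profile on presence-absence data
#'
#' Classic similarity-percentage decomposition: the mean between-group
#' Bray-Curtis dissimilarity (computed on occurrences) is split into
#' per-taxon contributions, expressed as percentages summing to 100 and
#' returned sorted in decreasing order. Taxa absent from every site are
#' dropped with a warning.
#'
#' @param pa binary matrix, taxa x sites (any positive entry is treated as
#'   presence).
#' @param groups per-site labels with exactly two levels, each with >= 2
#'   sites.
#' @return data.frame with columns `taxon_id`, `contribution` (percent),
#'   sorted decreasing.
#' @export
simper_profile <- function(pa, groups) {
  pa <- (as.matrix(pa) > 0) * 1
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly 2 groups required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 sites")
  if (ncol(pa) != length(groups)) stop("'groups' must match the sites")
  absent <- rowSums(pa) == 0
  if (any(absent)) {
    warning(sprintf("%d taxa absent everywhere dropped", sum(absent)))
    pa <- pa[!absent, , drop = FALSE]
  }
  contr <- simper_contributions(pa, groups)
  if (sum(contr) == 0) stop("no turnover: all between-group dissimilarities are 0")
  out <- data.frame(taxon_id = rownames(pa) %||% paste0("t", seq_len(nrow(pa))),
                    contribution = 100 * contr / sum(contr),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$contribution), , drop = FALSE]
}

# raw per-taxon SIMPER contributions (unnormalised), vectorised over all
# between-group site pairs; binary input assumed
simper_contributions <- function(pa, groups) {
  lv <- levels(groups)
  A <- pa[, groups == lv[1], drop = FALSE]
  B <- pa[, groups == lv[2], drop = FALSE]
  sA <- colSums(A)
  sB <- colSums(B)
  W <- 1 / outer(sA, sB, "+")           # per-pair denominators
  W[!is.finite(W)] <- 0                 # both-empty site pairs contribute 0
  # |x_a - x_b| = x_a + x_b - 2 x_a x_b for binary x
  as.numeric(A %*% rowSums(W) + B %*% colSums(W) - 2 * rowSums((A %*% W) * B))
}

# Rank-ordered ABSOLUTE contribution profile over ALL taxa (fixed length):
# each value is a taxon's mean contribution to between-group Bray-Curtis,
# in percentage points of dissimilarity (the profile sums to 100 x mean
# between-group dissimilarity). Unlike the shape-normalised SIMPER table,
# this curve retains the magnitude of between-group turnover, which is what
# lets the constrained nulls be told apart: a null that scatters
# group-concentrated taxa shrinks the whole curve, not just reshapes it.
ranked_profile <- function(pa, groups) {
  contr <- simper_contributions(pa, groups)
  n_pairs <- prod(table(groups))
  sort(100 * contr / n_pairs, decreasing = TRUE)
}

#' Constrained null matrices for PER-SIMPER
#'
#' Generates randomised presence-absence matrices under one of three
#' constraint schemes: `fix_taxa_totals` keeps each taxon's occupancy count
#' and shuffles which sites it occupies (the dispersal-type null);
#' `fix_site_totals` keeps each site's richness and shuffles which taxa fill
#' it (the niche-type null); `fix_both` preserves both margins via a
#' swap-based MCMC (the sequential "swap" sampler of [vegan::nullmodel()],
#' burn-in 10x matrix fill, thinning fill/2). All schemes preserve the total
#' fill. If the matrix admits no 2x2 checkerboard, `fix_both` cannot move and
#' returns copies of the input with a warning.
#'
#' @param pa binary matrix, taxa x sites, with no empty rows or columns.
#' @param scheme `"fix_taxa_totals"`, `"fix_site_totals"` or `"fix_both"`.
#' @param n number of null matrices.
#' @param seed integer seed.
#' @return A list of `n` binary matrices with the dimensions of `pa`.
#' @export
null_matrices <- function(pa, scheme = c("fix_taxa_totals", "fix_site_totals",
                                         "fix_both"),
                          n, seed = 1L) {
  scheme <- match.arg(scheme)
  pa <- (as.matrix(pa) > 0) * 1
  if (any(rowSums(pa) == 0) || any(colSums(pa) == 0)) {
    stop("matrix must have no empty rows or columns")
  }
  nt <- nrow(pa); ns <- ncol(pa)
  with_seed(derive_seed(seed, paste0("null_", scheme)), function() {
    if (scheme == "fix_taxa_totals") {
      lapply(seq_len(n), function(i) {
        out <- matrix(0, nt, ns, dimnames = dimnames(pa))
        rs <- rowSums(pa)
        for (r in seq_len(nt)) out[r, sample.int(ns, rs[r])] <- 1
        out
      })
    } else if (scheme == "fix_site_totals") {
      lapply(seq_len(n), function(i) {
        out <- matrix(0, nt, ns, dimnames = dimnames(pa))
        cs <- colSums(pa)
        for (s in seq_len(ns)) out[sample.int(nt, cs[s]), s] <- 1
        out
      })
    } else {
      if (!has_checkerboard(pa)) {
        warning("no 2x2 checkerboard: fix_both sampler cannot mix; returning copies")
        return(lapply(seq_len(n), function(i) pa))
      }
      fill <- sum(pa)
      nm <- vegan::nullmodel(t(pa), "swap")  # vegan wants sites x species
      sims <- stats::simulate(nm, nsim = n, burnin = 10 * fill,
                              thin = max(1, floor(fill / 2)))
      lapply(seq_len(n), function(i) {
        out <- t(sims[, , i])
        dimnames(out) <- dimnames(pa)
        out
      })
    }
  })
}

# TRUE if some 2x2 submatrix is a checkerboard (10/01), i.e. the swap chain
# has at least one move
has_checkerboard <- function(pa) {
  cp <- tcrossprod(pa)          # co-occurrences between taxon rows
  rs <- rowSums(pa)
  # rows i, j admit a swap iff (sites i-only) > 0 and (sites j-only) > 0
  any(outer(rs, rs, function(a, b) a) - cp > 0 &
        t(outer(rs, rs, function(a, b) a) - cp) > 0 &
        upper.tri(cp))
}

#' PER-SIMPER deviation statistic E
#'
#' Deviation between an observed rank-ordered SIMPER contribution profile and
#' a profile from a permuted matrix: E = log10 of the sum of squared
#' differences across rank positions. A zero deviation is floored at -12
#' rather than returning -Inf.
#'
#' @param observed_profile,permuted_profile numeric vectors of contribution
#'   percentages ordered by rank, same length.
#' @return E value (scalar).
#' @export
e_metric <- function(observed_profile, permuted_profile) {
  if (length(observed_profile) != length(permuted_profile)) {
    stop("profiles must have the same length")
  }
  ss <- sum((observed_profile - permuted_profile)^2)
  if (ss == 0) return(-12)
  max(log10(ss), -12)
}

#' Dispersal-niche continuum index (DNCI)
#'
#' PER-SIMPER inference of the dominant assembly process for a pair of site
#' groups. The observed table is reduced to presence-absence; the rank-ordered
#' SIMPER profile between the two groups is compared (via [e_metric()]) with
#' profiles from permuted matrices under the three null schemes of
#' [null_matrices()]. Standardised effect sizes are
#' SES_x = (mean(E_x) - mean(E_both)) / sd(E_both) for x in dispersal
#' (taxon totals fixed) and niche (site totals fixed), and
#' DNCI = SES_dispersal - SES_niche. Negative DNCI indicates
#' dispersal-dominated assembly, positive niche-dominated. With more than two
#' groups every pair is analysed and an overall mean reported.
#'
#' @param table an [otu_table] (or binary matrix taxa x sites).
#' @param groups per-sample group labels.
#' @param n_permutations permutations per null scheme (default 999).
#' @param seed integer seed.
#' @return For two groups, a list of class `dnci_result` with `group_pair`,
#'   `e_dispersal`, `e_niche`, `e_both` (length `n_permutations` each),
#'   `ses_dispersal`, `ses_niche`, `dnci`, `n_permutations`. For more
#'   groups, a list of class `dnci_set` with per-pair results and
#'   `mean_dnci`.
#' @export
dnci <- function(table, groups, n_permutations = 999, seed = 1L) {
  pa <- if (inherits(table, "otu_table")) (table$counts > 0) * 1 else
    (as.matrix(table) > 0) * 1
  groups <- droplevels(as.factor(groups))
  if (ncol(pa) != length(groups)) stop("'groups' must match the samples")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (nlevels(groups) == 2) {
    return(dnci_pair(pa, groups, n_permutations, seed))
  }
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    sel <- groups %in% pr
    dnci_pair(pa[, sel, drop = FALSE], droplevels(groups[sel]),
              n_permutations, seed)
  })
  names(res) <- vapply(pairs, paste, character(1), collapse = " vs ")
  structure(list(pairs = res,
                 mean_dnci = mean(vapply(res, `[[`, numeric(1), "dnci"))),
            class = "dnci_set")
}

dnci_pair <- function(pa, groups, n_permutations, seed) {
  if (any(table(groups) < 4)) {
    warning("group(s) with fewer than 4 sites; DNCI may be unstable")
  }
  keep <- rowSums(pa) > 0
  pa <- pa[keep, , drop = FALSE]
  if (all(rowSums(pa) == ncol(pa))) {
    stop("every taxon present at every site: no turnover, DNCI undefined")
  }
  obs <- ranked_profile(pa, groups)
  if (sum(obs) == 0) stop("no between-group turnover; DNCI undefined")
  e_for_scheme <- function(scheme) {
    nulls <- null_matrices(pa, scheme, n_permutations,
                           seed = derive_seed(seed, scheme))
    vapply(nulls, function(m) e_metric(obs, ranked_profile(m, groups)),
           numeric(1))
  }
  e_disp <- e_for_scheme("fix_taxa_totals")
  e_nich <- e_for_scheme("fix_site_totals")
  e_both <- e_for_scheme("fix_both")
  if (stats::sd(e_both) == 0) {
    stop("fix_both E distribution is degenerate (sd = 0); SES undefined")
  }
  ses_d <- (mean(e_disp) - mean(e_both)) / stats::sd(e_both)
  ses_n <- (mean(e_nich) - mean(e_both)) / stats::sd(e_both)
  structure(list(group_pair = levels(groups),
                 e_dispersal = e_disp, e_niche = e_nich, e_both = e_both,
                 ses_dispersal = ses_d, ses_niche = ses_n,
                 dnci = ses_d - ses_n,
                 n_permutations = as.integer(n_permutations)),
            class = "dnci_result")
}

#' @export
print.dnci_result <- function(x, ...) {
  cat(sprintf("DNCI (%s vs %s): %.3f  [SES dispersal %.3f, SES niche %.3f, %d permutations]\n",
              x$group_pair[1], x$group_pair[2], x$dnci, x$ses_dispersal,
              x$ses_niche, x$n_permutations))
  cat(if (x$dnci < 0) "  dispersal-dominated assembly\n" else
    "  niche-dominated assembly\n")
  invisible(x)
}

#' @export
print.dnci_set <- function(x, ...) {
  for (r in x$pairs) print(r)
  cat(sprintf("mean DNCI over %d pairs: %.3f\n", length(x$pairs), x$mean_dnci))
  invisible(x)
}

#' Write DNCI results to disk
#'
#' JSON per pair (`SES_d`, `SES_n`, `DNCI`, `n_perm`) and a long-format TSV
#' of E values (`scheme`, `permutation`, `E`) for null-deviation plots.
#'
#' @param result a `dnci_result` or `dnci_set`.
#' @param json_path,tsv_path output paths.
#' @return `json_path`, invisibly.
#' @export
write_dnci <- function(result, json_path, tsv_path) {
  pairs <- if (inherits(result, "dnci_set")) result$pairs else
    stats::setNames(list(result), paste(result$group_pair, collapse = " vs "))
  jsonlite::write_json(
    lapply(pairs, function(r) list(SES_d = r$ses_dispersal,
                                   SES_n = r$ses_niche, DNCI = r$dnci,
                                   n_perm = r$n_permutations)),
    json_path, auto_unbox = TRUE, digits = NA)
  ev <- do.call(rbind, lapply(names(pairs), function(nm) {
    r <- pairs[[nm]]
    data.frame(pair = nm,
               scheme = rep(c("dispersal", "niche", "both"),
                            each = r$n_permutations),
               permutation = rep(seq_len(r$n_permutations), 3),
               E = c(r$e_dispersal, r$e_niche, r$e_both))
  }))
  utils::write.table(ev, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(json_path)
}
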