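#' Abundance-weighted environmental niche estimate per taxon
#'
#' `niche_i = sum_k (x_ik / sum_k x_ik) * env_k`: the abundance-weighted mean
#' of the covariate over the sites where the taxon occurs. Bounded by the
#' covariate's observed range.
#'
#' @param community sites-by-taxa matrix.
#' @param env numeric covariate, one value per site (named or in site
#'   order).
#' @return named numeric vector, one value per taxon.
#' @export
taxon_niche <- function(community, env) {
  community <- as_community_matrix(community)
  if (!is.null(names(env))) {
    missing <- setdiff(rownames(community), names(env))
    if (length(missing))
      stop("covariate missing for site(s): ", paste(missing, collapse = ", "))
    env <- env[rownames(community)]
  }
  if (length(env) != nrow(community))
    stop("covariate length does not match the number of sites")
  if (any(!is.finite(env))) stop("covariate contains non-finite values")
  totals <- colSums(community)
  drop <- totals <= 0
  if (any(drop)) {
    warning(sum(drop), " zero-abundance taxa excluded from niche estimates")
    community <- community[, !drop, drop = FALSE]
    totals <- totals[!drop]
  }
  colSums(community * env) / totals
}

#' Mantel correlogram test for phylogenetic signal in niche differences
#'
#' The gate for phylogenetic-turnover inference: between-taxon niche
#' differences (`|niche_i - niche_j|`) are correlated with phylogenetic
#' distance within distance classes via a Mantel correlogram
#' ([vegan::mantel.correlog], permutation test, progressive Holm
#' correction). Ecological inference from beta-MNTD presumes significantly
#' positive correlation at short phylogenetic distances; when no class is
#' significant a warning is emitted, but the result is advisory and does not
#' block downstream analysis.
#'
#' @param niche named numeric vector from [taxon_niche()].
#' @param coph cophenetic matrix over the same taxa.
#' @param n_classes number of phylogenetic distance classes; default
#'   Sturges' rule on the number of distance pairs.
#' @param n_perm permutations for the per-class tests (default 999).
#' @param seed integer seed.
#' @return object of class `phylo_correlogram`: data.frame with one row per
#'   class (`class_midpoint`, `n_pairs`, `mantel_r`, `p_value`,
#'   `p_corrected`, `significant`), with attribute `degenerate = TRUE` when
#'   niche distances have zero variance (all `mantel_r` defined as 0).
#' @export
phylo_signal <- function(niche, coph, n_classes = NULL, n_perm = 999,
                         seed = 1L) {
  taxa <- names(niche)
  if (is.null(taxa) || !all(taxa %in% rownames(coph)))
    stop("niche estimates and cophenetic matrix must cover the same taxa")
  coph <- coph[taxa, taxa]
  if (n_perm < 99) stop("use at least 99 permutations")
  nd <- stats::dist(niche)
  pd <- stats::as.dist(coph)
  if (stats::sd(nd) < 1e-15) {
    brk <- pretty(range(pd), n = n_classes %||% nclass.Sturges(as.numeric(pd)))
    out <- data.frame(class_midpoint = (brk[-1] + brk[-length(brk)]) / 2,
                      n_pairs = NA_integer_, mantel_r = 0,
                      p_value = NA_real_, p_corrected = NA_real_,
                      significant = FALSE)
    class(out) <- c("phylo_correlogram", "data.frame")
    attr(out, "degenerate") <- TRUE
    warning("niche distances have zero variance; correlation defined as 0")
    return(out)
  }
  mc <- with_seed(seed, vegan::mantel.correlog(
    D.eco = nd, D.geo = pd, n.class = n_classes %||% 0,
    nperm = n_perm, mult = "holm", progressive = TRUE))
  m <- as.data.frame(mc$mantel.res)
  out <- data.frame(class_midpoint = m[["class.index"]],
                    n_pairs = as.integer(m[["n.dist"]]),
                    mantel_r = m[["Mantel.cor"]],
                    p_value = m[["Pr(Mantel)"]],
                    p_corrected = m[["Pr(corrected)"]],
                    significant = !is.na(m[["Pr(corrected)"]]) &
                      m[["Pr(corrected)"]] < 0.05)
  dropped <- is.na(out$mantel_r)
  if (any(dropped)) {
    message(sum(dropped), " distance class(es) with too few pairs dropped")
    out <- out[!dropped, , drop = FALSE]
  }
  class(out) <- c("phylo_correlogram", "data.frame")
  attr(out, "degenerate") <- FALSE
  if (!any(out$significant))
    warning("no distance class shows significant phylogenetic signal; ",
            "phylogenetic turnover inference may be unreliable")
  out
}

#' @export
print.phylo_correlogram <- function(x, ...) {
  cat("Mantel correlogram of niche differences vs phylogenetic distance\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
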