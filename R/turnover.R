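#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' Tip-to-tip path distances in branch-length units, ordered to match the
#' columns of `community` when supplied. Computed once and reused everywhere:
#' taxon removal only masks rows/columns, it never changes path lengths among
#' the remaining tips.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @param community optional sites-by-taxa matrix used to order the taxa.
#' @return symmetric matrix of patristic distances.
#' @export
cophenetic_matrix <- function(tree, community = NULL) {
  D <- stats::cophenetic(validate_tree(tree))
  if (!is.null(community)) {
    taxa <- colnames(community)
    missing <- setdiff(taxa, rownames(D))
    if (length(missing))
      stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
    D <- D[taxa, taxa]
  }
  D
}

#' Site-wise relative abundances
#'
#' @param community sites-by-taxa matrix with positive site totals.
#' @return matrix of the same shape; each row sums to 1, zeros preserved.
#' @export
relative_abundances <- function(community) {
  totals <- rowSums(community)
  if (any(totals <= 0))
    stop("site(s) with zero total abundance: ",
         paste(rownames(community)[totals <= 0], collapse = ", "))
  sweep(community, 1, totals, "/")
}

#' Abundance-weighted beta mean nearest taxon distance for one site pair
#'
#' For communities k and m,
#' \deqn{\beta MNTD = \frac{1}{2}\left[\sum_i f_{ik}\,\min_j d_{ij} +
#'   \sum_i f_{im}\,\min_j d_{ij}\right]}
#' where the first sum runs over taxa present in k with the minimum over taxa
#' present in m (and vice versa), f are within-site relative abundances, and
#' d are patristic distances. A taxon shared by both sites has nearest-taxon
#' distance 0 (itself), so identical communities score 0.
#'
#' @param f_k,f_m relative-abundance vectors of the two sites, aligned to the
#'   rows of `coph`.
#' @param coph cophenetic matrix over the same taxa.
#' @return non-negative scalar, symmetric in the two sites.
#' @export
beta_mntd_pair <- function(f_k, f_m, coph) {
  idx_k <- which(f_k > 0)
  idx_m <- which(f_m > 0)
  if (!length(idx_k) || !length(idx_m))
    stop("beta_mntd_pair: a site has no taxa with positive abundance")
  beta_mntd_obs_kernel(coph, idx_k, f_k[idx_k], idx_m, f_m[idx_m])
}

#' All pairwise beta-MNTD values
#'
#' @param community sites-by-taxa matrix.
#' @param coph cophenetic matrix ordered to `colnames(community)` (see
#'   [cophenetic_matrix()]).
#' @return symmetric sites-by-sites matrix with zero diagonal.
#' @export
beta_mntd <- function(community, coph) {
  community <- as_community_matrix(community)
  stopifnot(identical(colnames(community), rownames(coph)))
  f <- relative_abundances(community)
  n <- nrow(f)
  out <- matrix(0, n, n, dimnames = list(rownames(f), rownames(f)))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      out[i, j] <- out[j, i] <- beta_mntd_pair(f[i, ], f[j, ], coph)
    }
  }
  out
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`: 0 for identical vectors,
#' 1 for disjoint support.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
bray_curtis_pair <- function(x, y) {
  sx <- sum(x); sy <- sum(y)
  if (sx <= 0 || sy <= 0) stop("bray_curtis_pair: empty site")
  1 - 2 * sum(pmin(x, y)) / (sx + sy)
}

#' All pairwise Bray-Curtis dissimilarities
#' @param community sites-by-taxa matrix.
#' @return symmetric sites-by-sites matrix with zero diagonal.
#' @export
bray_curtis <- function(community) {
  community <- as_community_matrix(community)
  n <- nrow(community)
  out <- matrix(0, n, n, dimnames = list(rownames(community), rownames(community)))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      out[i, j] <- out[j, i] <- bray_curtis_pair(community[i, ], community[j, ])
    }
  }
  out
}
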