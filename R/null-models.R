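#' Five community assembly process labels
#' @export
assembly_processes <- function() {
  c("heterogeneous_selection", "homogeneous_selection",
    "dispersal_limitation", "homogenizing_dispersal", "drift")
}

#' Null-model configuration
#'
#' @param seed integer seed governing every randomization; recorded in all
#'   outputs. Mandatory: the removal analysis must replay the identical
#'   permutation streams.
#' @param n_reps number of randomizations (default 500; 999 also customary).
#' @param ses_cut absolute SES threshold for selection (default 2); the
#'   comparisons are strict (`ses > 2`, `ses < -2`), boundary values fall
#'   through to the Raup-Crick step.
#' @param rc_cut absolute Raup-Crick threshold for the dispersal processes
#'   (default 0.95), also strict.
#' @param rule_labels labeling convention for removal decision rules 3 and 4:
#'   `"consistent"` (default) labels the `rc > rc_cut` pattern dispersal
#'   limitation, matching the pair-level classification; `"paper-literal"`
#'   swaps the two dispersal labels, reproducing the printed form of the
#'   rules.
#' @return object of class `null_config`.
#' @export
null_config <- function(seed, n_reps = 500, ses_cut = 2, rc_cut = 0.95,
                        rule_labels = c("consistent", "paper-literal")) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("null_config: a seed is required for reproducible randomization")
  stopifnot(n_reps >= 2, ses_cut > 0, rc_cut > 0)
  structure(list(seed = as.integer(seed), n_reps = as.integer(n_reps),
                 ses_cut = ses_cut, rc_cut = rc_cut,
                 rule_labels = match.arg(rule_labels)),
            class = "null_config")
}

# All unordered site pairs in site order (i < j); pair_id indexes this list
# and anchors the per-pair Raup-Crick randomization stream, so a pair keeps
# its stream no matter which subset of pairs is evaluated.
site_pairs <- function(site_ids) {
  n <- length(site_ids)
  if (n < 2) stop("at least 2 sites are required for pairwise analysis")
  idx <- utils::combn(n, 2)
  data.frame(pair_id = seq_len(ncol(idx)),
             idx_a = idx[1, ], idx_b = idx[2, ],
             site_a = site_ids[idx[1, ]], site_b = site_ids[idx[2, ]],
             stringsAsFactors = FALSE)
}

# Core: observed beta-MNTD and tip-shuffle null for the given pair rows.
# f may contain NaN rows for emptied sites as long as those rows are not
# referenced by `pairs`.
ses_pairs_core <- function(f, coph, perms, pairs) {
  res <- data.frame(pairs,
                    beta_mntd = NA_real_, null_mean = NA_real_,
                    null_sd = NA_real_, ses = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  for (p in seq_len(nrow(pairs))) {
    fa <- f[pairs$idx_a[p], ]
    fb <- f[pairs$idx_b[p], ]
    ia <- which(fa > 0); ib <- which(fb > 0)
    obs <- beta_mntd_obs_kernel(coph, ia, fa[ia], ib, fb[ib])
    nulls <- beta_mntd_null_kernel(coph, perms, ia, fa[ia], ib, fb[ib])
    mu <- mean(nulls); s <- stats::sd(nulls)
    res$beta_mntd[p] <- obs
    res$null_mean[p] <- mu
    res$null_sd[p] <- s
    if (is.na(s) || s < 1e-12) {
      res$status[p] <- "degenerate"
    } else {
      res$ses[p] <- (obs - mu) / s
    }
  }
  res
}

#' Standardized effect size of beta-MNTD for every site pair
#'
#' The null model permutes taxon identities on the cophenetic matrix across
#' the regional pool (all taxa of the community matrix) while abundances stay
#' fixed; `ses = (obs - mean(null)) / sd(null)`. Pairs whose null ensemble
#' has zero spread (e.g. a star phylogeny) are flagged `"degenerate"` with
#' `ses = NA` and are excluded from classification.
#'
#' @param community aligned sites-by-taxa matrix.
#' @param coph cophenetic matrix ordered to the community's taxa.
#' @param cfg a [null_config()].
#' @param perms optional precomputed permutation matrix (`n_reps` rows); by
#'   default derived from `cfg$seed` and the pool size only, so any analysis
#'   of a table with the same number of taxa replays the same stream.
#' @return data.frame with one row per pair: `beta_mntd`, `null_mean`,
#'   `null_sd`, `ses`, `status`.
#' @export
ses_beta_mntd <- function(community, coph, cfg, perms = NULL) {
  community <- as_community_matrix(community)
  stopifnot(identical(colnames(community), rownames(coph)))
  if (is.null(perms))
    perms <- make_tip_perms(cfg$seed, ncol(community), cfg$n_reps)
  f <- relative_abundances(community)
  ses_pairs_core(f, coph, perms, site_pairs(rownames(community)))
}

# Community matrix coerced to integer counts for the Raup-Crick null, which
# draws individuals; real-valued tables are rounded with a warning.
rc_integer_counts <- function(community) {
  m <- round(community)
  if (max(abs(m - community)) > 1e-8)
    warning("real-valued abundances rounded to integers for the Raup-Crick null")
  if (any(rowSums(m) <= 0))
    stop("rounding left site(s) empty: ",
         paste(rownames(m)[rowSums(m) <= 0], collapse = ", "))
  storage.mode(m) <- "double"
  m
}

# One null assemblage for a site: draw the site's observed richness from the
# regional pool with probability proportional to occupancy (range size), give
# each drawn taxon one individual, then allocate the remaining individuals
# multinomially with probability proportional to pooled relative abundance.
rc_null_site <- function(n_sp, total, occupancy, pooled) {
  taxa <- sample.int(length(occupancy), n_sp, replace = FALSE, prob = occupancy)
  counts <- 1 + stats::rmultinom(1, total - n_sp, prob = pooled[taxa])[, 1]
  list(taxa = taxa, counts = counts)
}

# Core: Raup-Crick for the given pair rows of integer matrix m. Pool
# statistics (occupancy, pooled abundance) span all sites of m, including
# any all-zero rows, which contribute nothing.
rc_pairs_core <- function(m, cfg, pairs) {
  occupancy <- colSums(m > 0)
  pooled <- colSums(m)
  richness <- rowSums(m > 0)
  totals <- rowSums(m)
  if (any(richness > ncol(m))) stop("site richness exceeds pool size")
  vapply(seq_len(nrow(pairs)), function(p) {
    ia <- pairs$idx_a[p]; ib <- pairs$idx_b[p]
    obs <- bray_curtis_pair(m[ia, ], m[ib, ])
    with_seed(derive_seed(cfg$seed, pairs$pair_id[p]), {
      nulls <- vapply(seq_len(cfg$n_reps), function(r) {
        a <- rc_null_site(richness[ia], totals[ia], occupancy, pooled)
        b <- rc_null_site(richness[ib], totals[ib], occupancy, pooled)
        mm <- match(a$taxa, b$taxa)
        sh <- !is.na(mm)
        1 - 2 * sum(pmin(a$counts[sh], b$counts[mm[sh]])) /
          (totals[ia] + totals[ib])
      }, numeric(1))
      2 * ((sum(nulls < obs - 1e-12) + 0.5 * sum(abs(nulls - obs) <= 1e-12)) /
             cfg$n_reps - 0.5)
    })
  }, numeric(1))
}

#' Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' For each requested pair, builds `n_reps` null assemblage pairs under the
#' fixed-richness, occupancy/abundance-proportional null (each drawn taxon
#' receives one individual, the site's remaining individuals are allocated
#' multinomially with probability proportional to pooled relative abundance)
#' and scales the rank of the observed Bray-Curtis among the nulls to
#' `RC = 2 * ((#null < obs + 0.5 * #null == obs) / n_reps - 0.5)` in
#' `[-1, 1]`.
#'
#' @param community aligned sites-by-taxa matrix (integer counts; real
#'   values are rounded with a warning).
#' @param cfg a [null_config()].
#' @param pair_ids indices into [site_pairs()] of the community's sites;
#'   default all pairs.
#' @return data.frame `pair_id`, `site_a`, `site_b`, `rc`.
#' @export
rc_bray <- function(community, cfg, pair_ids = NULL) {
  community <- as_community_matrix(community)
  m <- rc_integer_counts(community)
  pairs <- site_pairs(rownames(m))
  if (is.null(pair_ids)) pair_ids <- pairs$pair_id
  sub <- pairs[match(pair_ids, pairs$pair_id), , drop = FALSE]
  data.frame(pair_id = sub$pair_id, site_a = sub$site_a, site_b = sub$site_b,
             rc = rc_pairs_core(m, cfg, sub), stringsAsFactors = FALSE)
}

#' Classify site pairs into assembly processes
#'
#' Step 1: `ses > ses_cut` is heterogeneous selection, `ses < -ses_cut`
#' homogeneous selection. Step 2, for the remaining pairs: `rc > rc_cut` is
#' dispersal limitation, `rc < -rc_cut` homogenizing dispersal, anything
#' else drift. All comparisons strict; `NA` ses (degenerate null) gives
#' `NA`.
#'
#' @param ses numeric vector of SES values.
#' @param rc numeric vector of Raup-Crick values (`NA` allowed where
#'   `|ses| > ses_cut`).
#' @param ses_cut,rc_cut thresholds, see [null_config()].
#' @return character vector of process labels.
#' @export
classify_process <- function(ses, rc, ses_cut = 2, rc_cut = 0.95) {
  out <- rep(NA_character_, length(ses))
  het <- !is.na(ses) & ses > ses_cut
  hom <- !is.na(ses) & ses < -ses_cut
  out[het] <- "heterogeneous_selection"
  out[hom] <- "homogeneous_selection"
  rest <- !is.na(ses) & !het & !hom
  if (any(rest & is.na(rc)))
    stop("classify_process: rc required when |ses| <= ses_cut")
  out[rest & !is.na(rc) & rc > rc_cut] <- "dispersal_limitation"
  out[rest & !is.na(rc) & rc < -rc_cut] <- "homogenizing_dispersal"
  out[rest & is.na(out)] <- "drift"
  out
}

#' Two-step classification of every site pair
#'
#' Runs the full pair-level analysis: aligns the table and tree, computes
#' observed beta-MNTD and its tip-shuffle null ([ses_beta_mntd()]), computes
#' [rc_bray()] for the pairs without significant SES, and labels each pair
#' with [classify_process()].
#'
#' @param community sites-by-taxa matrix.
#' @param tree rooted [ape::phylo] covering the community's taxa.
#' @param cfg a [null_config()].
#' @return data.frame of class `assembly_pairs`: one row per site pair with
#'   `beta_mntd`, `null_mean`, `null_sd`, `ses`, `rc`, `process`, `status`.
#'   Degenerate pairs carry `status = "degenerate"` and `process = NA`; they
#'   are excluded from every downstream fraction.
#' @export
classify_communities <- function(community, tree, cfg) {
  stopifnot(inherits(cfg, "null_config"))
  al <- align_community_tree(community, tree)
  comm <- al$community
  coph <- cophenetic_matrix(al$tree, comm)
  res <- ses_beta_mntd(comm, coph, cfg)
  res$rc <- NA_real_
  need_rc <- res$status == "ok" & abs(res$ses) <= cfg$ses_cut
  if (any(need_rc)) {
    rcv <- rc_bray(comm, cfg, pair_ids = res$pair_id[need_rc])
    res$rc[need_rc] <- rcv$rc
  }
  res$process <- classify_process(res$ses, res$rc, cfg$ses_cut, cfg$rc_cut)
  out <- res[, c("pair_id", "site_a", "site_b", "beta_mntd", "null_mean",
                 "null_sd", "ses", "rc", "process", "status")]
  class(out) <- c("assembly_pairs", "data.frame")
  attr(out, "cfg") <- cfg
  attr(out, "seed") <- cfg$seed
  attr(out, "n_taxa") <- ncol(comm)
  out
}

#' @export
print.assembly_pairs <- function(x, ...) {
  cat("Pairwise assembly classification:", nrow(x), "site pairs,",
      attr(x, "n_taxa") %||% "?", "taxa\n")
  ok <- x$status == "ok"
  if (any(!ok)) cat("  degenerate pairs excluded:", sum(!ok), "\n")
  tab <- table(factor(x$process[ok], levels = assembly_processes()))
  for (p in names(tab)) cat(sprintf("  %-24s %d\n", p, tab[[p]]))
  invisible(x)
}
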