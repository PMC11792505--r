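#' Define a removal target (taxon or taxonomic group)
#'
#' @param id target name.
#' @param taxa character vector of member taxon IDs; a singleton for a single
#'   taxon, all members of a rank label for a group.
#' @return object of class `removal_target`.
#' @export
removal_target <- function(id, taxa) {
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("removal_target: empty member set for '", id, "'")
  structure(list(id = as.character(id), taxa = taxa), class = "removal_target")
}

#' One singleton removal target per taxon
#' @param community sites-by-taxa matrix.
#' @return list of [removal_target()]s, in column order.
#' @export
taxon_targets <- function(community) {
  lapply(colnames(community), function(tx) removal_target(tx, tx))
}

#' Group removal targets from a taxonomy map
#'
#' One target per distinct label of `rank`, whose members are all taxa
#' carrying that label. Taxa missing from the taxonomy are collected under
#' `"Unclassified"`.
#'
#' @param taxonomy data.frame from [read_taxonomy()].
#' @param rank column of `taxonomy` to group by (e.g. `"phylum"`,
#'   `"family"`).
#' @param community optional matrix used to restrict and complete the taxon
#'   set.
#' @return named list of [removal_target()]s.
#' @export
taxonomy_targets <- function(taxonomy, rank, community = NULL) {
  if (!rank %in% names(taxonomy))
    stop("rank '", rank, "' not found in taxonomy (has: ",
         paste(names(taxonomy), collapse = ", "), ")")
  taxa <- rownames(taxonomy)
  labels <- as.character(taxonomy[[rank]])
  if (!is.null(community)) {
    extra <- setdiff(colnames(community), taxa)
    taxa <- c(taxa, extra)
    labels <- c(labels, rep("Unclassified", length(extra)))
    keep <- taxa %in% colnames(community)
    taxa <- taxa[keep]; labels <- labels[keep]
  }
  out <- lapply(split(taxa, labels), function(members) members)
  stats::setNames(
    lapply(names(out), function(lab) removal_target(lab, out[[lab]])),
    names(out))
}

#' Recompute pair metrics with a target removed
#'
#' Removes the target taxa from every site of the table and recomputes
#' SES.beta-MNTD (and Raup-Crick where requested) on the reduced community,
#' under the randomization streams shared with the full-community run: tip
#' permutations depend only on the seed and the pool size, Raup-Crick streams
#' only on the seed and the pair's position in the full pair list. The result
#' is therefore identical to running [classify_communities()] from scratch on
#' the pre-filtered table with the same seed.
#'
#' Pairs in which removal empties a site are flagged `"inapplicable"`. Target
#' members absent from the table are ignored with a warning; a target with no
#' member in the table leaves every metric untouched.
#'
#' @param community sites-by-taxa matrix (aligned to `tree`).
#' @param tree rooted [ape::phylo].
#' @param target a [removal_target()].
#' @param cfg the same [null_config()] used for the full-community run.
#' @param rc_pair_ids which pairs to compute the removed-target Raup-Crick
#'   for: `NULL` (default) mirrors [classify_communities()] and covers every
#'   pair with `|ses| <= ses_cut`; a vector of pair ids restricts to those.
#' @return data.frame per pair: `beta_mntd_i`, `ses_i`, `rc_i`, `status_i`.
#' @export
remove_and_recompute <- function(community, tree, target, cfg,
                                 rc_pair_ids = NULL) {
  stopifnot(inherits(target, "removal_target"), inherits(cfg, "null_config"))
  al <- align_community_tree(community, tree)
  comm <- al$community
  coph <- cophenetic_matrix(al$tree, comm)
  remove_core(comm, coph, target, cfg, rc_pair_ids)
}

# Core used by both the exported wrapper and attribute_taxa (which passes
# pre-aligned objects and a lazy rc pair set).
remove_core <- function(comm, coph, target, cfg, rc_pair_ids) {
  members <- intersect(target$taxa, colnames(comm))
  absent <- setdiff(target$taxa, colnames(comm))
  if (length(absent))
    warning("target '", target$id, "': ", length(absent),
            " member taxa not in the table are ignored")
  keep <- setdiff(colnames(comm), members)
  if (!length(keep))
    stop("target '", target$id, "' removes every taxon in the table")
  m <- comm[, keep, drop = FALSE]
  cop <- coph[keep, keep, drop = FALSE]
  pairs <- site_pairs(rownames(comm))
  totals <- rowSums(m)
  applicable <- totals[pairs$idx_a] > 0 & totals[pairs$idx_b] > 0

  res <- data.frame(pairs, beta_mntd_i = NA_real_, ses_i = NA_real_,
                    rc_i = NA_real_, status_i = "inapplicable",
                    stringsAsFactors = FALSE)
  if (any(applicable)) {
    f <- m / ifelse(totals > 0, totals, NA_real_)
    perms <- make_tip_perms(cfg$seed, ncol(m), cfg$n_reps)
    ses_res <- ses_pairs_core(f, cop, perms, pairs[applicable, , drop = FALSE])
    res$beta_mntd_i[applicable] <- ses_res$beta_mntd
    res$ses_i[applicable] <- ses_res$ses
    res$status_i[applicable] <- ses_res$status

    if (is.null(rc_pair_ids)) {
      rc_pair_ids <- res$pair_id[res$status_i == "ok" &
                                   abs(res$ses_i) <= cfg$ses_cut]
    } else {
      rc_pair_ids <- intersect(
        rc_pair_ids,
        res$pair_id[res$status_i == "ok" & abs(res$ses_i) <= cfg$ses_cut])
    }
    if (length(rc_pair_ids)) {
      mi <- rc_integer_counts_quiet(m)
      sub <- pairs[match(rc_pair_ids, pairs$pair_id), , drop = FALSE]
      res$rc_i[match(rc_pair_ids, res$pair_id)] <- rc_pairs_core(mi, cfg, sub)
    }
  }
  res[, c("pair_id", "site_a", "site_b", "beta_mntd_i", "ses_i", "rc_i",
          "status_i")]
}

# As rc_integer_counts() but tolerates emptied sites (they are never paired).
rc_integer_counts_quiet <- function(m) {
  mm <- round(m)
  if (max(abs(mm - m)) > 1e-8)
    warning("real-valued abundances rounded to integers for the Raup-Crick null")
  storage.mode(mm) <- "double"
  mm
}

#' Five-way removal decision rules
#'
#' Attributes a pair's process to the removed target by comparing the full
#' and removed-target metrics (all four computed under shared
#' randomizations):
#' * rule 1: `ses > ses_cut` and `ses_i < ses_cut` — heterogeneous selection;
#' * rule 2: `ses < -ses_cut` and `ses_i > -ses_cut` — homogeneous selection;
#' * rule 3: both SES within `[-ses_cut, ses_cut]`, `rc > rc_cut` and
#'   `rc_i <= rc_cut`;
#' * rule 4: both SES within `[-ses_cut, ses_cut]`, `rc < -rc_cut` and
#'   `rc_i >= -rc_cut`;
#' * rule 5: none of the above — drift.
#'
#' With `rule_labels = "consistent"` (default) rule 3 is labeled dispersal
#' limitation and rule 4 homogenizing dispersal, matching the step-2
#' pair-level definitions; `"paper-literal"` swaps the two dispersal labels,
#' reproducing the printed form of the rules.
#'
#' The reverse flips (a metric nonsignificant before removal turning
#' significant after) have no printed rule; they are reported in the
#' `masking` flag and do not enter the five-way attribution.
#'
#' @param ses,ses_i,rc,rc_i numeric vectors of full and removed-target
#'   metrics; `rc`/`rc_i` may be `NA` where not required.
#' @param ses_cut,rc_cut,rule_labels see [null_config()].
#' @return data.frame with `process` (attributed label) and `masking`
#'   (logical diagnostic).
#' @export
decision_rules <- function(ses, ses_i, rc = NA_real_, rc_i = NA_real_,
                           ses_cut = 2, rc_cut = 0.95,
                           rule_labels = c("consistent", "paper-literal")) {
  rule_labels <- match.arg(rule_labels)
  n <- length(ses)
  rc <- rep_len(rc, n); rc_i <- rep_len(rc_i, n)
  if (any(is.na(ses) | is.na(ses_i)))
    stop("decision_rules: ses and ses_i must be present for every pair")
  within <- abs(ses) <= ses_cut & abs(ses_i) <= ses_cut
  if (any(within & is.na(rc)))
    stop("decision_rules: rc required when both SES are within the cut")
  if (any(within & abs(rc) > rc_cut & is.na(rc_i)))
    stop("decision_rules: rc_i required when both SES are within the cut and |rc| exceeds the cut")
  r1 <- ses > ses_cut & ses_i < ses_cut
  r2 <- ses < -ses_cut & ses_i > -ses_cut
  r3 <- within & !is.na(rc) & !is.na(rc_i) & rc > rc_cut & rc_i <= rc_cut
  r4 <- within & !is.na(rc) & !is.na(rc_i) & rc < -rc_cut & rc_i >= -rc_cut
  lab3 <- if (rule_labels == "consistent") "dispersal_limitation" else "homogenizing_dispersal"
  lab4 <- if (rule_labels == "consistent") "homogenizing_dispersal" else "dispersal_limitation"
  process <- rep("drift", n)
  process[r1] <- "heterogeneous_selection"
  process[r2] <- "homogeneous_selection"
  process[r3] <- lab3
  process[r4] <- lab4
  masking <- (abs(ses) <= ses_cut & abs(ses_i) > ses_cut) |
    (within & !is.na(rc) & !is.na(rc_i) & abs(rc) <= rc_cut & abs(rc_i) > rc_cut)
  data.frame(process = process, masking = masking, stringsAsFactors = FALSE)
}

#' Attribute assembly processes to taxa or taxonomic groups
#'
#' For each removal target, recomputes the pair metrics with the target
#' removed ([remove_and_recompute()]) under the randomizations shared with
#' the full-community run, applies the five [decision_rules()] to every
#' evaluable pair, and reports the fraction of evaluable pairs attributed to
#' each process. The removed-target Raup-Crick is computed only for pairs
#' where rules 3/4 (or the masking diagnostic) can apply, i.e. both SES
#' within the cut and the full-community `rc` available.
#'
#' @param community sites-by-taxa matrix.
#' @param tree rooted [ape::phylo].
#' @param targets list of [removal_target()]s (see [taxon_targets()],
#'   [taxonomy_targets()]).
#' @param cfg a [null_config()].
#' @param pairs optional result of `classify_communities(community, tree,
#'   cfg)`; recomputed when absent. Must come from the same `cfg`.
#' @return object of class `dtu_attribution`: list with `attribution` (one
#'   row per target: `n_evaluable`, five per-process fraction columns summing
#'   to 1, `n_masking`) and `outcomes` (per target x pair metrics and
#'   attributed process).
#' @export
attribute_taxa <- function(community, tree, targets, cfg, pairs = NULL) {
  stopifnot(inherits(cfg, "null_config"))
  if (inherits(targets, "removal_target")) targets <- list(targets)
  al <- align_community_tree(community, tree)
  comm <- al$community
  coph <- cophenetic_matrix(al$tree, comm)
  if (is.null(pairs)) pairs <- classify_communities(comm, al$tree, cfg)
  procs <- assembly_processes()

  rows <- vector("list", length(targets))
  outs <- vector("list", length(targets))
  for (t in seq_along(targets)) {
    tg <- targets[[t]]
    lazy_rc <- pairs$pair_id[pairs$status == "ok" & !is.na(pairs$rc)]
    rr <- remove_core(comm, coph, tg, cfg, rc_pair_ids = lazy_rc)
    idx <- match(pairs$pair_id, rr$pair_id)
    evaluable <- pairs$status == "ok" & rr$status_i[idx] == "ok"
    out <- data.frame(target_id = tg$id, pairs[, c("pair_id", "site_a", "site_b")],
                      ses = pairs$ses, ses_i = rr$ses_i[idx],
                      rc = pairs$rc, rc_i = rr$rc_i[idx],
                      status = ifelse(evaluable, "ok",
                                      ifelse(pairs$status != "ok", pairs$status,
                                             rr$status_i[idx])),
                      process = NA_character_, masking = NA,
                      stringsAsFactors = FALSE)
    if (any(evaluable)) {
      dr <- decision_rules(out$ses[evaluable], out$ses_i[evaluable],
                           out$rc[evaluable], out$rc_i[evaluable],
                           cfg$ses_cut, cfg$rc_cut, cfg$rule_labels)
      out$process[evaluable] <- dr$process
      out$masking[evaluable] <- dr$masking
    }
    outs[[t]] <- out
    n_eval <- sum(evaluable)
    frac <- if (n_eval > 0) {
      as.numeric(table(factor(out$process[evaluable], levels = procs))) / n_eval
    } else rep(NA_real_, length(procs))
    rows[[t]] <- data.frame(target_id = tg$id, n_taxa = length(tg$taxa),
                            n_evaluable = n_eval,
                            as.list(stats::setNames(frac, procs)),
                            n_masking = sum(out$masking[evaluable]),
                            stringsAsFactors = FALSE)
  }
  structure(list(attribution = do.call(rbind, rows),
                 outcomes = do.call(rbind, outs), cfg = cfg),
            class = "dtu_attribution")
}

#' @export
print.dtu_attribution <- function(x, ...) {
  cat("Taxon (DTU) attribution:", nrow(x$attribution), "targets\n")
  print(utils::head(x$attribution, 10), row.names = FALSE)
  if (nrow(x$attribution) > 10) cat("...\n")
  invisible(x)
}
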