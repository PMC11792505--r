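#' Define a sampling-unit (DSU) target
#'
#' @param id target name.
#' @param sites character vector of member site IDs (singleton for a single
#'   sampling unit, several for a group such as an altitude band).
#' @return object of class `dsu_target`.
#' @export
dsu_target <- function(id, sites) {
  sites <- unique(as.character(sites))
  if (!length(sites)) stop("dsu_target: empty member set for '", id, "'")
  structure(list(id = as.character(id), sites = sites), class = "dsu_target")
}

#' Site pairs involving a DSU target
#'
#' All unordered site pairs with at least one endpoint in the target, in
#' lexicographic order. For a single site among `n` there are `n - 1` such
#' pairs; for a group of `g` sites there are `C(n,2) - C(n-g,2)`. Pairs with
#' both endpoints inside the target (within-group pairs) are included unless
#' `between_only = TRUE`.
#'
#' @param target a [dsu_target()] (or character vector of site IDs).
#' @param all_sites character vector of every site ID.
#' @param between_only exclude within-target pairs.
#' @return data.frame with columns `site_a`, `site_b` (lexicographic,
#'   `site_a < site_b`).
#' @export
pairs_involving <- function(target, all_sites, between_only = FALSE) {
  if (!inherits(target, "dsu_target")) target <- dsu_target("target", target)
  if (length(all_sites) < 2) stop("at least 2 sites required")
  missing <- setdiff(target$sites, all_sites)
  if (length(missing))
    stop("target sites not present: ", paste(missing, collapse = ", "))
  sites <- sort(all_sites)
  idx <- utils::combn(sites, 2)
  a_in <- idx[1, ] %in% target$sites
  b_in <- idx[2, ] %in% target$sites
  keep <- if (between_only) xor(a_in, b_in) else a_in | b_in
  data.frame(site_a = idx[1, keep], site_b = idx[2, keep],
             stringsAsFactors = FALSE)
}

# Canonical unordered pair key, orientation-free.
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Attribute assembly processes to sampling units or groups
#'
#' For each target, collects the classified pairs that involve at least one
#' member site and reports, over the evaluable (non-degenerate) involved
#' pairs, the fraction attributed to each process, plus the headline
#' significant fraction: the share of involved pairs with a significant
#' SES.beta-MNTD or Raup-Crick result (i.e. any label other than drift).
#'
#' @param pairs an `assembly_pairs` data.frame from
#'   [classify_communities()].
#' @param targets list of [dsu_target()]s (a single target is also
#'   accepted).
#' @param between_only exclude within-target pairs, see [pairs_involving()].
#' @return data.frame of class `dsu_contribution`: one row per target with
#'   `n_involved`, `n_evaluable`, five per-process fraction columns (summing
#'   to 1 over evaluable pairs), `significant_fraction` and `stochasticity`
#'   (dispersal limitation + homogenizing dispersal + drift).
#' @export
attribute_sites <- function(pairs, targets, between_only = FALSE) {
  if (inherits(targets, "dsu_target")) targets <- list(targets)
  all_sites <- sort(unique(c(pairs$site_a, pairs$site_b)))
  keys <- pair_key(pairs$site_a, pairs$site_b)
  procs <- assembly_processes()
  stochastic <- c("dispersal_limitation", "homogenizing_dispersal", "drift")
  rows <- lapply(targets, function(tg) {
    inv <- pairs_involving(tg, all_sites, between_only = between_only)
    if (!nrow(inv)) stop("target '", tg$id, "' has no involved pairs")
    sel <- pairs[match(pair_key(inv$site_a, inv$site_b), keys), , drop = FALSE]
    ok <- sel$status == "ok"
    n_eval <- sum(ok)
    if (n_eval > 0) {
      counts <- as.numeric(table(factor(sel$process[ok], levels = procs)))
      frac <- counts / n_eval
      sig <- sum(counts[procs != "drift"]) / n_eval
      stoch <- sum(frac[procs %in% stochastic])
    } else {
      frac <- rep(NA_real_, length(procs)); sig <- NA_real_; stoch <- NA_real_
    }
    data.frame(target_id = tg$id, n_sites = length(tg$sites),
               n_involved = nrow(inv), n_evaluable = n_eval,
               as.list(stats::setNames(frac, procs)),
               significant_fraction = sig, stochasticity = stoch,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dsu_contribution", "data.frame")
  attr(out, "seed") <- attr(pairs, "seed")
  out
}

#' Build DSU group targets from sample metadata
#'
#' One target per distinct value of `group_col` (e.g. low/medium/high
#' altitude bands), containing the sites carrying that value.
#'
#' @param metadata data.frame from [read_metadata()].
#' @param group_col grouping column name.
#' @param sites optional vector of site IDs that must all be mapped.
#' @return named list of [dsu_target()]s.
#' @export
dsu_groups <- function(metadata, group_col, sites = NULL) {
  if (!group_col %in% names(metadata))
    stop("group column '", group_col, "' not found in metadata")
  if (!is.null(sites)) {
    unmapped <- setdiff(sites, rownames(metadata))
    if (length(unmapped))
      stop("site(s) without metadata: ", paste(unmapped, collapse = ", "))
    metadata <- metadata[rownames(metadata) %in% sites, , drop = FALSE]
  }
  grp <- split(rownames(metadata), as.character(metadata[[group_col]]))
  stats::setNames(
    lapply(names(grp), function(g) dsu_target(g, grp[[g]])),
    names(grp))
}

#' Per-group process profiles along a metadata grouping
#'
#' Convenience wrapper: builds one DSU target per level of `group_col` and
#' runs [attribute_sites()], giving the per-group process profile and the
#' stochasticity trend (fraction attributed to dispersal limitation,
#' homogenizing dispersal or drift).
#'
#' @inheritParams attribute_sites
#' @param metadata data.frame from [read_metadata()] covering every site in
#'   `pairs`.
#' @param group_col grouping column name.
#' @return `dsu_contribution` data.frame, one row per group.
#' @export
group_summary <- function(pairs, metadata, group_col, between_only = FALSE) {
  sites <- unique(c(pairs$site_a, pairs$site_b))
  targets <- dsu_groups(metadata, group_col, sites = sites)
  attribute_sites(pairs, targets, between_only = between_only)
}
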