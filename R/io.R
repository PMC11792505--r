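#' Validate a community abundance matrix
#'
#' Coerces `x` to a sites-by-taxa numeric matrix and enforces the container
#' invariants: non-negative finite abundances, unique site and taxon names,
#' every site total positive. Taxa with zero total abundance are dropped with
#' a warning (they carry no information for turnover and would break the
#' nearest-taxon minima); the dropped names are kept in
#' `attr(, "dropped_taxa")`.
#'
#' @param x matrix or data.frame of abundances.
#' @param sites_as_rows logical; if `FALSE`, `x` is transposed first.
#' @return numeric matrix, sites in rows, taxa in columns.
#' @export
as_community_matrix <- function(x, sites_as_rows = TRUE) {
  x <- as.matrix(x)
  if (!sites_as_rows) x <- t(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("community matrix must have site (row) and taxon (column) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate site IDs: ", paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate taxon IDs: ", paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    stop("community matrix contains non-finite values")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at site '%s', taxon '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  zero_sites <- rownames(x)[rowSums(x) <= 0]
  if (length(zero_sites))
    stop("site(s) with zero total abundance: ", paste(zero_sites, collapse = ", "))
  zero_taxa <- colnames(x)[colSums(x) <= 0]
  if (length(zero_taxa)) {
    warning(length(zero_taxa), " all-zero taxa dropped: ",
            paste(utils::head(zero_taxa, 5), collapse = ", "),
            if (length(zero_taxa) > 5) ", ..." else "")
    x <- x[, colSums(x) > 0, drop = FALSE]
  }
  attr(x, "dropped_taxa") <- zero_taxa
  x
}

#' Read a community abundance table
#'
#' Reads a TSV abundance table (UTF-8, `#` comment lines ignored, first column
#' = row identifiers). The default orientation is taxa as rows and samples as
#' columns, the usual export convention of amplicon pipelines; set
#' `orientation = "sites_rows"` for the transposed layout.
#'
#' @param path path to a tab-separated file.
#' @param orientation `"taxa_rows"` (default) or `"sites_rows"`.
#' @return sites-by-taxa matrix, see [as_community_matrix()].
#' @export
read_community_table <- function(path, orientation = c("taxa_rows", "sites_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("community table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  rownames(m) <- ids
  as_community_matrix(m, sites_as_rows = orientation == "sites_rows")
}

#' Read a phylogeny from a newick file
#'
#' Requires unique, non-empty tip labels and a branch length on every edge
#' (zero-length branches are allowed and retained). Multifurcating trees are
#' accepted: the patristic distances used downstream are root-independent.
#'
#' @param path newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stop("tree has unlabeled tips")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("tree is missing branch lengths on one or more edges")
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  # multifurcations (including a star-like root) are allowed: patristic
  # distances are root-independent path sums
  tr
}

#' Write a phylogeny to newick
#' @param tree an [ape::phylo] object.
#' @param path output file.
#' @export
write_tree <- function(tree, path) ape::write.tree(tree, file = path)

#' Align a community matrix and a phylogeny on their shared taxa
#'
#' Prunes the tree to the taxa present in the table and drops table taxa with
#' no tip (beta-MNTD is undefined for a taxon without a tip). Idempotent.
#'
#' @param community sites-by-taxa matrix.
#' @param tree an [ape::phylo] object.
#' @return list with elements `community`, `tree`, `dropped_taxa`
#'   (table taxa absent from the tree).
#' @export
align_community_tree <- function(community, tree) {
  community <- as_community_matrix(community)
  tree <- validate_tree(tree)
  shared <- intersect(colnames(community), tree$tip.label)
  if (!length(shared))
    stop("no taxa shared between the community table and the tree")
  dropped <- setdiff(colnames(community), tree$tip.label)
  if (length(dropped))
    message(length(dropped), " table taxa absent from the tree were dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  community <- as_community_matrix(community[, shared, drop = FALSE])
  if (length(tree$tip.label) > length(shared))
    tree <- ape::keep.tip(tree, shared)
  list(community = community, tree = tree, dropped_taxa = dropped)
}

#' Read a taxonomy map
#'
#' Accepts either a TSV with one column per rank, or a two-column TSV whose
#' second column holds QIIME2-style lineage strings
#' (`"k__...; p__...; c__..."`), which are split into rank columns. Missing
#' ranks become `"Unclassified"`.
#'
#' @param path TSV file; first column taxon IDs.
#' @param ranks rank names assumed for lineage strings.
#' @return data.frame with rownames = taxon IDs and one column per rank.
#' @export
read_taxonomy <- function(path,
                          ranks = c("kingdom", "phylum", "class", "order", "family", "genus")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate taxon IDs in taxonomy: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  if (ncol(body) == 1 && any(grepl(";", body[[1]], fixed = TRUE))) {
    parts <- strsplit(as.character(body[[1]]), ";")
    parts <- lapply(parts, function(p) {
      p <- sub("^\\s*[a-z]__", "", trimws(p))
      p[!nzchar(p)] <- NA_character_
      length(p) <- length(ranks)
      p
    })
    body <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(body) <- ranks
  }
  body[] <- lapply(body, function(col) {
    col <- as.character(col)
    col[is.na(col) | !nzchar(col)] <- "Unclassified"
    col
  })
  rownames(body) <- ids
  body
}

#' Read a sample metadata table
#' @param path TSV file; first column site IDs.
#' @return data.frame with rownames = site IDs.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate site IDs in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  rownames(body) <- ids
  body
}

#' Write a result table as TSV
#'
#' Plain tab-separated output, no quoting, `NA` written as empty string.
#' A `# seed: <s>` comment header records the randomization seed when the
#' object carries one.
#'
#' @param x data.frame or matrix.
#' @param path output file.
#' @param row_names write row names as a first `id` column.
#' @export
write_tsv <- function(x, path, row_names = FALSE) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  seed <- attr(x, "seed", exact = TRUE)
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (row_names) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a community matrix as a TSV table
#' @param community sites-by-taxa matrix.
#' @param path output file.
#' @param orientation layout to write, as in [read_community_table()].
#' @export
write_community_table <- function(community, path,
                                  orientation = c("taxa_rows", "sites_rows")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "taxa_rows") t(community) else community
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (orientation == "taxa_rows") "taxon_id" else "site_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
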