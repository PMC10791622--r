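.complete_matrix <- function(m) {
  # error naming the first missing unordered pair
  miss <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    g <- rownames(m)
    stop(sprintf("missing ANI for pair (%s, %s)",
                 g[miss[1, 1]], g[miss[1, 2]]))
  }
  invisible(m)
}

.single_linkage <- function(m, threshold) {
  # connected components of the graph with edges value > threshold (strict)
  adj <- m > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

.complete_linkage <- function(m, threshold) {
  d <- stats::as.dist(100 - m)
  hc <- stats::hclust(d, method = "complete")
  # merge while every within-cluster pair keeps value > threshold (strict)
  stats::cutree(hc, h = (100 - threshold) - 1e-9)
}

.canonical_ids <- function(membership, prefix) {
  # cluster id = prefix + lexicographically smallest member genome id
  genomes <- names(membership)
  reps <- vapply(split(genomes, membership), function(g) min(g), "")
  stats::setNames(paste0(prefix, reps[as.character(membership)]), genomes)
}

.same_partition <- function(a, b) {
  # equality of two partitions given as named membership vectors
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

#' Partition a genome collection into genomovars
#'
#' Genomovars are the single-linkage connected components of the graph whose
#' edges join genome pairs with ANI strictly above `threshold` (default 99.5,
#' the conservative lower edge of the intra-species ANI gap). A
#' complete-linkage partition at the same threshold is computed as a
#' diagnostic: when the two partitions differ the assignment is flagged
#' linkage-sensitive, which cannot happen when the data carry a genuine ANI
#' gap spanning the threshold. Pairs within 0.1 ANI points of the threshold
#' are reported as straddling.
#'
#' @param tab an `ani_table` covering all pairs of the genome set (or a
#'   symmetric ANI matrix).
#' @param threshold genomovar ANI threshold in percent (strict `>`).
#' @return A data.frame of class `unit_assignment` with columns `genome_id`
#'   and `genomovar_id`, and attributes `linkage_sensitive` (logical),
#'   `complete_linkage` (named membership under complete linkage),
#'   `straddling_pairs` (data.frame), `threshold`.
#' @export
assign_genomovars <- function(tab, threshold = 99.5) {
  m <- if (is.matrix(tab)) tab else ani_matrix(tab)
  .complete_matrix(m)
  single <- .single_linkage(m, threshold)
  compl <- .complete_linkage(m, threshold)
  ids <- .canonical_ids(single, "gv_")
  cl_ids <- .canonical_ids(compl, "gv_")
  ut <- upper.tri(m)
  strad <- which(abs(m - threshold) <= 0.1 & ut, arr.ind = TRUE)
  straddling <- data.frame(
    genome_a = rownames(m)[strad[, 1]],
    genome_b = colnames(m)[strad[, 2]],
    ani = m[strad], stringsAsFactors = FALSE
  )
  out <- data.frame(genome_id = rownames(m),
                    genomovar_id = unname(ids[rownames(m)]),
                    stringsAsFactors = FALSE)
  attr(out, "linkage_sensitive") <- !.same_partition(ids, cl_ids)
  attr(out, "complete_linkage") <- cl_ids
  attr(out, "straddling_pairs") <- straddling
  attr(out, "threshold") <- threshold
  class(out) <- c("unit_assignment", "data.frame")
  out
}

#' Partition genomes into strains within genomovars
#'
#' Strain edges require BOTH ANI strictly above `ani_threshold` (default
#' 99.99) AND shared gene content strictly above `share_threshold` (default
#' 99.0); strains are single-linkage components of that graph, forced to nest
#' inside genomovars (edges crossing genomovar boundaries are dropped with a
#' warning). The preferred gene-share source is the orthology module's shared
#' gene fraction ([shared_gene_fraction()]); the aligned fraction of the ANI
#' table is the documented fallback.
#'
#' @param tab an `ani_table` (or symmetric ANI matrix).
#' @param gene_share symmetric matrix of pairwise shared-gene percentages
#'   (rows/cols = genome ids), or NULL to fall back to the aligned fraction
#'   from `tab`.
#' @param genomovars a `unit_assignment` from [assign_genomovars()]; computed
#'   at `genomovar_threshold` when NULL.
#' @param ani_threshold,share_threshold strain thresholds (strict `>`).
#' @param genomovar_threshold used only when `genomovars` is NULL.
#' @return A `unit_assignment` data.frame with columns `genome_id`,
#'   `genomovar_id`, `strain_id`; attribute `share_source` records whether the
#'   gene-share matrix or the aligned-fraction fallback was used.
#' @export
assign_strains <- function(tab, gene_share = NULL, genomovars = NULL,
                           ani_threshold = 99.99, share_threshold = 99,
                           genomovar_threshold = 99.5) {
  m <- if (is.matrix(tab)) tab else ani_matrix(tab)
  .complete_matrix(m)
  if (is.null(genomovars))
    genomovars <- assign_genomovars(tab, genomovar_threshold)
  gv <- stats::setNames(genomovars$genomovar_id, genomovars$genome_id)
  if (!setequal(names(gv), rownames(m)))
    stop("genomovar assignment does not cover the ANI table's genomes")
  share_source <- "gene_share"
  if (is.null(gene_share)) {
    gene_share <- if (is.matrix(tab)) {
      stop("gene_share is required when 'tab' is a plain matrix")
    } else {
      ani_matrix(tab, value = "aligned_fraction")
    }
    share_source <- "aligned_fraction"
  }
  g <- rownames(m)
  gene_share <- gene_share[g, g]
  if (anyNA(gene_share[upper.tri(gene_share)]))
    stop("gene_share matrix is incomplete")
  adj <- (m > ani_threshold) & (gene_share > share_threshold)
  diag(adj) <- FALSE
  cross <- adj & outer(gv[g], gv[g], "!=")
  if (any(cross)) {
    warning(sum(cross[upper.tri(cross)]),
            " strain edge(s) crossing genomovar boundaries dropped")
    adj[cross] <- FALSE
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(gr)$membership
  ids <- .canonical_ids(memb, "st_")
  out <- data.frame(genome_id = g,
                    genomovar_id = unname(gv[g]),
                    strain_id = unname(ids[g]),
                    stringsAsFactors = FALSE)
  attr(out, "linkage_sensitive") <- attr(genomovars, "linkage_sensitive")
  attr(out, "straddling_pairs") <- attr(genomovars, "straddling_pairs")
  attr(out, "share_source") <- share_source
  attr(out, "ani_threshold") <- ani_threshold
  attr(out, "share_threshold") <- share_threshold
  class(out) <- c("unit_assignment", "data.frame")
  # invariant: strains nest within genomovars
  tab2 <- table(out$strain_id, out$genomovar_id)
  if (any(rowSums(tab2 > 0) > 1L))
    stop("internal error: strain partition does not refine genomovars")
  out
}

#' Pick a representative genome (medoid) per genomovar
#'
#' The medoid maximises the summed ANI to its co-members; ties are broken
#' lexicographically. Singletons represent themselves. One representative per
#' genomovar is the reference set used for competitive read recruitment, which
#' avoids best-hit ties between near-identical genomes of one genomovar.
#'
#' @param assignment a `unit_assignment` with a `genomovar_id` column.
#' @param tab the `ani_table` (or symmetric matrix) the assignment was built
#'   from.
#' @return Named character vector: genomovar_id -> representative genome_id.
#' @export
pick_representatives <- function(assignment, tab) {
  m <- if (is.matrix(tab)) tab else ani_matrix(tab)
  groups <- split(assignment$genome_id, assignment$genomovar_id)
  vapply(groups, function(members) {
    members <- sort(members)
    if (length(members) == 1L) return(members)
    sums <- vapply(members, function(g)
      sum(m[g, setdiff(members, g)]), numeric(1))
    members[which.max(sums)]  # which.max takes the first (lexicographic) tie
  }, "")
}
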