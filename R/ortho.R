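#' Global percent identity between two nucleotide sequences
#'
#' Equal-length sequences are compared position-wise (Hamming identity), which
#' is exact for indel-free homologs; unequal-length sequences fall back to a
#' global (end-to-end) pairwise alignment with unit gap costs and the identity
#' is taken over the mean sequence length (so truncation counts against it).
#'
#' @param a,b character strings (nucleotide sequences).
#' @return Percent identity in \[0, 100\].
#' @export
seq_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == lb) {
    ra <- charToRaw(a); rb <- charToRaw(b)
    return(100 * sum(ra == rb) / la)
  }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       gapOpening = 1, gapExtension = 1)
  # PID4: matches over the mean sequence length, so end gaps (missing
  # sequence) count against the identity
  Biostrings::pid(aln, type = "PID4")
}

# identity of one raw sequence against a list of raw sequences (same length),
# with a sparse-position prescreen to skip obviously unrelated pairs
.hamming_identity_vec <- function(ra, raws, screen_floor = NULL) {
  L <- length(ra)
  out <- numeric(length(raws))
  if (!is.null(screen_floor) && L > 120L) {
    probe <- seq(1L, L, by = 15L)
    rap <- ra[probe]
    for (i in seq_along(raws)) {
      est <- 100 * sum(rap == raws[[i]][probe]) / length(probe)
      out[i] <- if (est < screen_floor - 15) est else
        100 * sum(ra == raws[[i]]) / L
    }
  } else {
    for (i in seq_along(raws)) out[i] <- 100 * sum(ra == raws[[i]]) / L
  }
  out
}

#' Build orthologous groups by reciprocal best hit
#'
#' All-versus-all comparison of gene sequences between genome pairs; the best
#' match per gene and target genome is chosen by score (identity x alignment
#' length); reciprocal best-hit (RBH) edges meeting both the identity and the
#' query-coverage cut-off are kept; orthologous groups (OGs) are the connected
#' components of the RBH graph. Within-genome gene pairs meeting the same
#' cut-offs (recent paralogs) are linked too, so components drawing two or
#' more genes from one genome are flagged as containing paralogs (not
#' single-copy).
#'
#' @param genes data.frame with columns `genome_id`, `gene_id`, `seq`
#'   (see [read_gene_sets()] or [population_genes()]). Gene ids must be
#'   globally unique.
#' @param identity percent identity cut-off (default 90).
#' @param coverage percent query-coverage cut-off (default 90).
#' @return A list of class `og_set`: `assignment` (data.frame gene_id,
#'   genome_id, og_id), `ogs` (data.frame og_id, n_genomes, n_genes,
#'   core_single_copy), `n_genomes` (genomes contributing at least one gene).
#' @export
build_ogs <- function(genes, identity = 90, coverage = 90) {
  stopifnot(all(c("genome_id", "gene_id", "seq") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be globally unique")
  counts <- table(genes$genome_id)
  empty <- setdiff(unique(genes$genome_id), names(counts[counts > 0]))
  genomes <- sort(names(counts[counts > 0]))
  if (length(genomes) < 2L) stop("need genes from at least 2 genomes")
  by_gen <- split(genes[, c("gene_id", "seq")], genes$genome_id)

  # per-genome prep: raw bytes, grouped by length
  prep <- lapply(by_gen, function(d) {
    d <- d[order(d$gene_id), ]
    list(ids = d$gene_id, seqs = d$seq, raws = lapply(d$seq, charToRaw),
         lens = nchar(d$seq))
  })

  edges_a <- character(0); edges_b <- character(0)
  # within-genome comparisons catch recent paralogs: near-identical copies in
  # one genome join the component and mark it non-single-copy
  for (gn in genomes) {
    P <- prep[[gn]]
    if (length(P$ids) < 2L) next
    sc <- .pair_scores(P, P, identity, coverage)
    if (is.null(sc)) next
    keep <- sc$a < sc$b  # unordered pairs, skip self
    if (any(keep)) {
      edges_a <- c(edges_a, sc$a[keep])
      edges_b <- c(edges_b, sc$b[keep])
    }
  }
  for (i in seq_len(length(genomes) - 1L)) {
    for (j in (i + 1L):length(genomes)) {
      A <- prep[[genomes[i]]]; B <- prep[[genomes[j]]]
      sc <- .pair_scores(A, B, identity, coverage)
      if (is.null(sc)) next
      # best hit per A gene and per B gene, reciprocal pairs become edges
      bestA <- tapply(seq_len(nrow(sc)), sc$a, function(k)
        k[order(-sc$score[k], sc$b[k])][1])
      bestB <- tapply(seq_len(nrow(sc)), sc$b, function(k)
        k[order(-sc$score[k], sc$a[k])][1])
      recip <- intersect(unlist(bestA), unlist(bestB))
      if (length(recip)) {
        edges_a <- c(edges_a, sc$a[recip])
        edges_b <- c(edges_b, sc$b[recip])
      }
    }
  }
  all_ids <- sort(genes$gene_id)
  g <- igraph::make_empty_graph(n = length(all_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_ids)
  if (length(edges_a))
    g <- igraph::add_edges(g, rbind(match(edges_a, all_ids),
                                    match(edges_b, all_ids)))
  memb <- igraph::components(g)$membership
  og_of <- .canonical_ids(stats::setNames(memb, all_ids), "og_")
  assignment <- data.frame(gene_id = all_ids,
                           genome_id = genes$genome_id[match(all_ids, genes$gene_id)],
                           og_id = unname(og_of[all_ids]),
                           stringsAsFactors = FALSE)
  sp <- split(assignment$genome_id, assignment$og_id)
  ogs <- data.frame(
    og_id = names(sp),
    n_genomes = vapply(sp, function(x) length(unique(x)), integer(1)),
    n_genes = lengths(sp),
    stringsAsFactors = FALSE
  )
  ogs$core_single_copy <- ogs$n_genomes == length(genomes) &
    ogs$n_genes == length(genomes)
  rownames(ogs) <- NULL
  if (length(empty))
    warning("genome(s) with zero genes excluded: ",
            paste(empty, collapse = ", "))
  structure(list(assignment = assignment, ogs = ogs,
                 n_genomes = length(genomes)),
            class = "og_set")
}

# candidate scores between the genes of two genomes; identity via Hamming for
# equal lengths, global alignment otherwise; pairs that cannot meet the
# coverage cut-off are skipped
.pair_scores <- function(A, B, identity, coverage) {
  a_idx <- integer(0); b_idx <- integer(0); idv <- numeric(0)
  for (ai in seq_along(A$ids)) {
    la <- A$lens[ai]
    same <- which(B$lens == la)
    if (length(same)) {
      ids <- .hamming_identity_vec(A$raws[[ai]], B$raws[same],
                                   screen_floor = identity)
      keep <- ids >= identity
      if (any(keep)) {
        a_idx <- c(a_idx, rep(ai, sum(keep)))
        b_idx <- c(b_idx, same[keep])
        idv <- c(idv, ids[keep])
      }
    }
    diff <- which(B$lens != la &
                    100 * pmin(B$lens, la) / pmax(B$lens, la) >= coverage)
    for (bi in diff) {
      id <- seq_identity(A$seqs[ai], B$seqs[bi])
      if (id >= identity) {
        a_idx <- c(a_idx, ai); b_idx <- c(b_idx, bi); idv <- c(idv, id)
      }
    }
  }
  if (!length(a_idx)) return(NULL)
  alen <- pmin(A$lens[a_idx], B$lens[b_idx])
  data.frame(a = A$ids[a_idx], b = B$ids[b_idx], identity = idv,
             score = idv / 100 * alen, stringsAsFactors = FALSE)
}

#' Core single-copy orthologous groups
#'
#' Keeps OGs present in every genome with exactly one member each.
#'
#' @param ogs an `og_set` from [build_ogs()].
#' @param n_genomes number of genomes the core is defined over (defaults to
#'   the number of genomes seen by [build_ogs()]).
#' @return Character vector of core single-copy og ids.
#' @export
core_single_copy_ogs <- function(ogs, n_genomes = ogs$n_genomes) {
  stopifnot(inherits(ogs, "og_set"))
  ogs$ogs$og_id[ogs$ogs$n_genomes == n_genomes &
                  ogs$ogs$n_genes == n_genomes]
}

#' Dereplicate the alleles of one core gene
#'
#' Greedy incremental clustering in lexicographic gene-id order: a sequence
#' joins the first existing cluster whose representative it matches at or
#' above the identity floor (global identity), otherwise it founds a new
#' cluster. With a floor of 99.8% two alleles are distinct when they differ at
#' more than ~0.2% of positions; the greedy result matches exhaustive
#' clustering whenever pairwise identities stay clear of the floor.
#'
#' @param seqs named character vector of allele sequences (names = gene ids).
#' @param floor identity floor in percent (default 99.8; membership uses
#'   `>= floor`).
#' @return A data.frame with columns `gene_id`, `allele_id` (1-based cluster
#'   index in founding order), `representative` (logical).
#' @export
dereplicate_alleles <- function(seqs, floor = 99.8) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("'seqs' must be uniquely named by gene_id")
  ord <- order(names(seqs))
  seqs <- seqs[ord]
  reps <- integer(0)  # indices of cluster representatives
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (seq_identity(seqs[[i]], seqs[[reps[ci]]]) >= floor) {
        assign[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  data.frame(gene_id = names(seqs), allele_id = assign,
             representative = seq_along(seqs) %in% reps,
             stringsAsFactors = FALSE)
}

#' Allele catalog over the core single-copy OGs
#'
#' Applies [dereplicate_alleles()] to every core single-copy OG and collects
#' the assignments.
#'
#' @param genes gene data.frame (`genome_id`, `gene_id`, `seq`).
#' @param ogs an `og_set`.
#' @param floor allele identity floor (default 99.8).
#' @return A list of class `allele_catalog`: `alleles` (data.frame `og_id`,
#'   `gene_id`, `genome_id`, `allele_id`, `representative`), `n_alleles`
#'   (named vector per og), `core_ogs`.
#' @export
allele_catalog <- function(genes, ogs, floor = 99.8) {
  core <- core_single_copy_ogs(ogs)
  if (!length(core)) stop("no core single-copy OGs")
  asn <- ogs$assignment
  rows <- vector("list", length(core))
  for (k in seq_along(core)) {
    members <- asn$gene_id[asn$og_id == core[k]]
    ss <- stats::setNames(genes$seq[match(members, genes$gene_id)], members)
    d <- dereplicate_alleles(ss, floor)
    d$og_id <- core[k]
    d$genome_id <- asn$genome_id[match(d$gene_id, asn$gene_id)]
    rows[[k]] <- d
  }
  alleles <- do.call(rbind, rows)
  alleles <- alleles[, c("og_id", "gene_id", "genome_id", "allele_id",
                         "representative")]
  n_alleles <- vapply(split(alleles$allele_id, alleles$og_id), max, integer(1))
  structure(list(alleles = alleles, n_alleles = n_alleles, core_ogs = core),
            class = "allele_catalog")
}

#' Shared core-gene alleles between genomovars
#'
#' For every genomovar pair, the percent of core single-copy OGs whose allele
#' sets intersect. The diagonal reports within-genomovar cohesion: the percent
#' of OGs in which all members of the genomovar carry a single shared allele.
#'
#' @param catalog an `allele_catalog`.
#' @param units a `unit_assignment` with a `genomovar_id` column covering all
#'   genomes in the catalog.
#' @return Symmetric numeric matrix (genomovar x genomovar) of shared-allele
#'   percentages.
#' @export
allele_sharing <- function(catalog, units) {
  al <- catalog$alleles
  gv <- stats::setNames(units$genomovar_id, units$genome_id)
  if (!all(al$genome_id %in% names(gv)))
    stop("genome missing from unit assignment: ",
         paste(utils::head(setdiff(al$genome_id, names(gv))), collapse = ", "))
  al$gv <- gv[al$genome_id]
  gvs <- sort(unique(al$gv))
  core <- catalog$core_ogs
  # per OG, per genomovar: set of allele ids
  sets <- lapply(split(al[, c("allele_id", "gv")], al$og_id), function(d)
    lapply(split(d$allele_id, d$gv), unique))
  out <- matrix(NA_real_, length(gvs), length(gvs),
                dimnames = list(gvs, gvs))
  for (i in seq_along(gvs)) {
    for (j in i:length(gvs)) {
      if (i == j) {
        mono <- vapply(core, function(og)
          length(sets[[og]][[gvs[i]]]) == 1L, logical(1))
        out[i, i] <- 100 * mean(mono)
      } else {
        shared <- vapply(core, function(og)
          length(intersect(sets[[og]][[gvs[i]]],
                           sets[[og]][[gvs[j]]])) > 0L, logical(1))
        out[i, j] <- out[j, i] <- 100 * mean(shared)
      }
    }
  }
  out
}

#' Shared gene fraction between two genomes
#'
#' `100 * |OGs containing both genomes| / mean(|genes_a|, |genes_b|)` — the
#' gene-content analogue of the aligned genome fraction, used as input to the
#' strain definition (shared gene content > 99%).
#'
#' @param genome_a,genome_b genome ids.
#' @param ogs an `og_set` covering both genomes.
#' @return Percent of shared gene content.
#' @export
shared_gene_fraction <- function(genome_a, genome_b, ogs) {
  asn <- ogs$assignment
  na <- sum(asn$genome_id == genome_a)
  nb <- sum(asn$genome_id == genome_b)
  if (na == 0L || nb == 0L) stop("empty gene set for ",
                                 if (na == 0L) genome_a else genome_b)
  oga <- unique(asn$og_id[asn$genome_id == genome_a])
  ogb <- unique(asn$og_id[asn$genome_id == genome_b])
  100 * length(intersect(oga, ogb)) / mean(c(na, nb))
}

#' Pairwise shared-gene-fraction matrix
#' @param ogs an `og_set`.
#' @return Symmetric matrix of [shared_gene_fraction()] values (diagonal 100).
#' @export
gene_share_matrix <- function(ogs) {
  genomes <- sort(unique(ogs$assignment$genome_id))
  n <- length(genomes)
  m <- matrix(100, n, n, dimnames = list(genomes, genomes))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- shared_gene_fraction(genomes[i], genomes[j], ogs)
    }
  }
  m
}

#' Percent of values inside a closed range
#'
#' Small summary helper used to report allele-diversity statistics, e.g. the
#' share of core OGs whose allele count falls within a band.
#'
#' @param x numeric vector (e.g. alleles per core OG).
#' @param lo,hi closed range bounds.
#' @return `100 * mean(lo <= x & x <= hi)`.
#' @examples
#' percent_in_range(c(10, 25, 30, 111), 22, 37)  # 50
#' @export
percent_in_range <- function(x, lo, hi) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty input")
  100 * mean(x >= lo & x <= hi)
}
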