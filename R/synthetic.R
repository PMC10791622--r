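.BASES_RAW <- charToRaw("ACGT")

.rand_seq_raw <- function(L) .BASES_RAW[sample.int(4L, L, replace = TRUE)]

# substitute n positions (distinct) with a different base each
.mutate_raw <- function(x, n) {
  if (n <= 0L) return(x)
  pos <- sample.int(length(x), n)
  cur <- match(x[pos], .BASES_RAW)
  new <- (cur - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
  x[pos] <- .BASES_RAW[new]
  x
}

#' Specification of a synthetic intra-species population
#'
#' Describes a planted world: G genomovars separated by a forbidden ANI band,
#' strains nested within genomovars, gene content (conserved, core, backbone,
#' accessory), a long-tailed rank-abundance distribution, and short-read
#' sequencing parameters. Divergence intervals are PAIRWISE targets: branch
#' mutation rates are drawn from half the interval so that two lineages
#' diverging from a common ancestor land inside it.
#'
#' With the defaults, between-genomovar ANI falls in ~\[97.0, 99.15\],
#' within-genomovar (between-strain) ANI in \[99.8, 99.9\], and within-strain
#' ANI above 99.99, leaving the planted gap (no pairs in (99.2, 99.8)) that
#' the delimitation thresholds assume. Strain- and isolate-level mutations
#' are confined to intergenic backbone so that members of one genomovar share
#' every core-gene allele.
#'
#' @param n_genomovars number of genomovars (default 10).
#' @param strains_per_genomovar strains per genomovar (default 3).
#' @param isolates_per_strain sequenced isolates per strain (default 1).
#' @param genome_length length in bp of the universal (shared) genome portion
#'   (default 50000; accessory genes add to it).
#' @param between_divergence pairwise substitution-rate interval between
#'   genomovars (default `c(0.008, 0.03)`, i.e. ANI 97.0-99.2).
#' @param within_divergence pairwise rate interval between strains of one
#'   genomovar (default `c(0.001, 0.002)`, i.e. ANI 99.8-99.9; the lower
#'   bound keeps distinct strains distinguishable at the 99.99 threshold).
#' @param strain_divergence pairwise rate between isolates of one strain
#'   (default 4e-5, i.e. ANI ~99.996).
#' @param n_core_genes,n_conserved_genes,gene_length core single-copy genes
#'   (default 40 x 900 bp) and fully conserved, rRNA-like genes (default 2)
#'   shared by every genome.
#' @param n_accessory_genes size of the accessory family pool (default 20).
#' @param accessory_loss per-genomovar probability of lacking an accessory
#'   family (default 0.3).
#' @param abundance_model `"geometric"` or `"lognormal"`.
#' @param geometric_ratio common ratio of the geometric rank-abundance series
#'   (default 0.8).
#' @param lognormal_sdlog sdlog of the lognormal alternative (default 1).
#' @param read_length read length in bp (default 150).
#' @param per_base_error per-base substitution error rate (default 0.001).
#' @param n_reads default number of simulated reads (default 1e5).
#' @param rng_seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `population_spec`.
#' @export
population_spec <- function(n_genomovars = 10L,
                            strains_per_genomovar = 3L,
                            isolates_per_strain = 1L,
                            genome_length = 50000L,
                            between_divergence = c(0.008, 0.03),
                            within_divergence = c(0.001, 0.002),
                            strain_divergence = 4e-5,
                            n_core_genes = 40L,
                            n_conserved_genes = 2L,
                            gene_length = 900L,
                            n_accessory_genes = 20L,
                            accessory_loss = 0.3,
                            abundance_model = c("geometric", "lognormal"),
                            geometric_ratio = 0.8,
                            lognormal_sdlog = 1,
                            read_length = 150L,
                            per_base_error = 0.001,
                            n_reads = 100000L,
                            rng_seed = 1L) {
  spec <- list(
    n_genomovars = as.integer(n_genomovars),
    strains_per_genomovar = as.integer(strains_per_genomovar),
    isolates_per_strain = as.integer(isolates_per_strain),
    genome_length = as.integer(genome_length),
    between_divergence = as.numeric(between_divergence),
    within_divergence = as.numeric(within_divergence),
    strain_divergence = as.numeric(strain_divergence),
    n_core_genes = as.integer(n_core_genes),
    n_conserved_genes = as.integer(n_conserved_genes),
    gene_length = as.integer(gene_length),
    n_accessory_genes = as.integer(n_accessory_genes),
    accessory_loss = as.numeric(accessory_loss),
    abundance_model = match.arg(abundance_model),
    geometric_ratio = as.numeric(geometric_ratio),
    lognormal_sdlog = as.numeric(lognormal_sdlog),
    read_length = as.integer(read_length),
    per_base_error = as.numeric(per_base_error),
    n_reads = as.integer(n_reads),
    rng_seed = as.integer(rng_seed)
  )
  rates <- c(spec$between_divergence, spec$within_divergence,
             spec$strain_divergence, spec$per_base_error)
  if (any(rates < 0 | rates > 0.1)) stop("rates must lie in [0, 0.1]")
  if (spec$between_divergence[1] <= spec$within_divergence[2])
    stop("between_divergence must exceed within_divergence: ",
         "no planted ANI gap would exist")
  if (spec$strain_divergence >= spec$within_divergence[1])
    stop("strain_divergence must be below within_divergence")
  gene_span <- (spec$n_core_genes + spec$n_conserved_genes) * spec$gene_length
  if (gene_span >= spec$genome_length)
    stop("gene span exceeds genome: ", gene_span, " >= ", spec$genome_length)
  bb <- spec$genome_length - gene_span
  max_muts <- ceiling(spec$within_divergence[2] / 2 * spec$genome_length) +
    ceiling(spec$strain_divergence / 2 * spec$genome_length) + 1L
  if (bb < 10L * max_muts)
    stop("backbone too short to host within-genomovar divergence; ",
         "reduce gene count or within_divergence")
  spec$forbidden_band <- c(100 * (1 - spec$between_divergence[1]),
                           100 * (1 - spec$within_divergence[2]))
  structure(spec, class = "population_spec")
}

.abundances <- function(spec) {
  G <- spec$n_genomovars
  w <- switch(spec$abundance_model,
              geometric = spec$geometric_ratio^(seq_len(G) - 1),
              lognormal = sort(stats::rlnorm(G, 0, spec$lognormal_sdlog),
                               decreasing = TRUE))
  w / sum(w)
}

#' Generate a synthetic population with a complete truth manifest
#'
#' Draws an ancestor genome, derives genomovar founders, strains and isolates
#' by planted substitutions (no indels anywhere, so homologous coordinates are
#' shared population-wide and every identity is exactly computable), assigns
#' accessory gene content per genomovar, and records the full ground truth.
#' Fully reproducible from `spec$rng_seed`.
#'
#' @param spec a [population_spec()].
#' @param verify_gap assert that no realised genome pair falls inside the
#'   planted forbidden ANI band (construction guarantee; default TRUE).
#' @return An object of class `synthetic_population` with elements `spec`,
#'   `families` (data.frame: family_id, class, length), `genomovars`,
#'   `genomes` (data.frame: genome_id, genomovar_id, strain_id), `manifest`
#'   (truth: genomes, abundances, gene inventory, forbidden band). Genome
#'   sequences are materialised with [as_genome_set()], gene sets with
#'   [population_genes()], exact ANI with [truth_ani_table()].
#' @export
generate_population <- function(spec, verify_gap = TRUE) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$rng_seed)
  gl <- spec$gene_length
  cons <- if (spec$n_conserved_genes > 0L)
    sprintf("cons%02d", seq_len(spec$n_conserved_genes)) else character(0)
  core <- sprintf("core%02d", seq_len(spec$n_core_genes))
  bb_total <- spec$genome_length -
    (spec$n_core_genes + spec$n_conserved_genes) * gl
  n_bb <- max(1L, round(bb_total / 1000))
  bb_len <- diff(round(seq(0, bb_total, length.out = n_bb + 1L)))
  bbs <- sprintf("bb%02d", seq_len(n_bb))
  acc <- if (spec$n_accessory_genes > 0L)
    sprintf("acc%02d", seq_len(spec$n_accessory_genes)) else character(0)
  families <- data.frame(
    family_id = c(cons, core, bbs, acc),
    class = c(rep("conserved", length(cons)), rep("core", length(core)),
              rep("backbone", length(bbs)), rep("accessory", length(acc))),
    length = c(rep(gl, length(cons) + length(core)), bb_len,
               rep(gl, length(acc))),
    stringsAsFactors = FALSE
  )
  anc <- lapply(stats::setNames(families$length, families$family_id),
                .rand_seq_raw)

  G <- spec$n_genomovars
  gv_ids <- sprintf("gv%02d", seq_len(G))
  carry <- matrix(stats::runif(G * length(acc)) >= spec$accessory_loss,
                  nrow = G, dimnames = list(gv_ids, acc))

  # Founder phylogeny: genomovars come in sister pairs so that some pairwise
  # ANI values approach the lower edge of the planted gap (as observed in real
  # populations), while the remaining pairs spread down to the far end of the
  # between interval. Branch rates are halves of pairwise targets; conserved
  # families never mutate, so mutable families take a compensating factor to
  # keep genome-wide divergence on target. Falls back to a star phylogeny when
  # the between interval is too narrow for the sister construction.
  b1 <- spec$between_divergence[1]; b2 <- spec$between_divergence[2]
  eff <- spec$genome_length /
    (spec$genome_length - spec$n_conserved_genes * gl)
  u_hi <- 1.25 * b1
  r_lo <- 0.51 * b1
  r_sister_hi <- (b2 - 2 * u_hi) / 2
  n_pairs <- if (r_sister_hi > r_lo && G >= 4L)
    min(G %/% 2L, max(1L, ceiling(G / 5))) else 0L
  # sister pairs occupy the low-abundance tail: (G-1, G), (G-3, G-2), ...
  is_sister <- seq_len(G) %in% (G - 2L * seq_len(n_pairs) + 2L)
  is_sister_parent <- seq_len(G) %in% (G - 2L * seq_len(n_pairs) + 1L)
  r_branch <- stats::runif(G, r_lo, b2 / 2)
  if (n_pairs > 0L)
    r_branch[is_sister_parent] <- stats::runif(n_pairs, r_lo, r_sister_hi)
  u_sister <- stats::runif(G, 1.02 * b1, max(u_hi, 1.03 * b1))

  mutable <- c(core, bbs)  # conserved families never mutate
  gv_copies <- vector("list", G); names(gv_copies) <- gv_ids
  gv_rate <- numeric(G)  # realised divergence from the ancestor
  for (g in seq_len(G)) {
    fams_g <- c(mutable, acc[carry[g, ]])
    if (is_sister[g]) {
      p <- g - 1L
      gv_rate[g] <- gv_rate[p] + u_sister[g]
      cp <- anc[c(cons, fams_g)]
      for (f in fams_g) {
        from_parent <- f %in% names(gv_copies[[p]])
        base <- if (from_parent) gv_copies[[p]][[f]] else anc[[f]]
        rate <- if (from_parent) u_sister[g] else gv_rate[g]
        cp[[f]] <- .mutate_raw(base, round(eff * rate * length(base)))
      }
    } else {
      gv_rate[g] <- r_branch[g]
      cp <- anc[c(cons, fams_g)]
      for (f in fams_g) {
        cp[[f]] <- .mutate_raw(cp[[f]],
                               round(eff * gv_rate[g] * length(cp[[f]])))
      }
    }
    gv_copies[[g]] <- cp
  }

  bb_cum <- cumsum(families$length[match(bbs, families$family_id)])
  place_backbone_muts <- function(cp, n) {
    if (n <= 0L) return(cp)
    pos <- sample.int(bb_cum[length(bb_cum)], n)
    fam_i <- findInterval(pos - 1L, c(0L, bb_cum), rightmost.closed = FALSE)
    off <- pos - c(0L, bb_cum)[fam_i]
    for (k in seq_len(n)) {
      f <- bbs[fam_i[k]]
      cp[[f]] <- .mutate_raw_at(cp[[f]], off[k])
    }
    cp
  }

  genomes <- list(); copies <- list()
  S <- spec$strains_per_genomovar; I <- spec$isolates_per_strain
  for (g in seq_len(G)) {
    s_rate <- stats::runif(S, spec$within_divergence[1] / 2,
                           spec$within_divergence[2] / 2)
    for (s in seq_len(S)) {
      strain_bb <- place_backbone_muts(
        gv_copies[[g]][bbs], round(s_rate[s] * spec$genome_length))
      for (i in seq_len(I)) {
        gid <- sprintf("%s.s%02d.i%02d", gv_ids[g], s, i)
        iso_bb <- place_backbone_muts(
          strain_bb, round(spec$strain_divergence / 2 * spec$genome_length))
        cp <- gv_copies[[g]]
        cp[bbs] <- iso_bb
        copies[[gid]] <- cp
        genomes[[gid]] <- data.frame(
          genome_id = gid, genomovar_id = gv_ids[g],
          strain_id = sprintf("%s.s%02d", gv_ids[g], s),
          stringsAsFactors = FALSE)
      }
    }
  }
  genome_df <- do.call(rbind, genomes)
  rownames(genome_df) <- NULL

  inventory <- do.call(rbind, lapply(genome_df$genome_id, function(gid) {
    data.frame(genome_id = gid, family_id = names(copies[[gid]]),
               stringsAsFactors = FALSE)
  }))
  ab <- .abundances(spec)
  manifest <- list(
    genomes = genome_df,
    abundances = data.frame(genomovar_id = gv_ids, abundance = ab,
                            stringsAsFactors = FALSE),
    gene_inventory = inventory,
    accessory_carriage = carry,
    forbidden_band = spec$forbidden_band
  )
  pop <- structure(list(spec = spec, families = families, copies = copies,
                        genomes = genome_df, gv_ids = gv_ids,
                        manifest = manifest),
                   class = "synthetic_population")
  if (verify_gap) {
    tab <- truth_ani_table(pop)
    bad <- tab$ani > spec$forbidden_band[1] + 1e-9 &
      tab$ani < spec$forbidden_band[2] - 1e-9
    if (any(bad))
      stop("construction guarantee violated: ANI value inside the planted ",
           "forbidden band (", paste(round(tab$ani[bad], 3), collapse = ", "),
           ")")
  }
  pop
}

.mutate_raw_at <- function(x, pos) {
  cur <- match(x[pos], .BASES_RAW)
  x[pos] <- .BASES_RAW[(cur - 1L + sample.int(3L, 1L)) %% 4L + 1L]
  x
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("Synthetic population: %d genomovars, %d genomes, %d families (%d bp universal)\n",
              length(x$gv_ids), nrow(x$genomes), nrow(x$families),
              x$spec$genome_length))
  cat(sprintf("  planted forbidden ANI band: (%.2f, %.2f)\n",
              x$spec$forbidden_band[1], x$spec$forbidden_band[2]))
  invisible(x)
}

#' Truth manifest of a synthetic population
#' @param pop a `synthetic_population`.
#' @return The manifest list (genome truth table, abundances, gene inventory,
#'   accessory carriage, forbidden band).
#' @export
truth_manifest <- function(pop) {
  stopifnot(inherits(pop, "synthetic_population"))
  pop$manifest
}

#' Materialise genome sequences of a synthetic population
#' @param pop a `synthetic_population`.
#' @param ids genomes to materialise (default all).
#' @return A `genome_set`: named list of single-contig
#'   [Biostrings::DNAStringSet] objects.
#' @export
as_genome_set <- function(pop, ids = pop$genomes$genome_id) {
  out <- lapply(stats::setNames(ids, ids), function(gid) {
    chr <- rawToChar(unlist(pop$copies[[gid]], use.names = FALSE))
    ss <- Biostrings::DNAStringSet(chr)
    names(ss) <- gid
    ss
  })
  structure(out, class = "genome_set")
}

#' Gene sets of a synthetic population
#' @param pop a `synthetic_population`.
#' @param ids genomes to extract (default all).
#' @return data.frame `genome_id`, `gene_id`, `seq` covering conserved, core
#'   and accessory genes (backbone is intergenic). Gene ids are
#'   `"<genome>|<family>"`.
#' @export
population_genes <- function(pop, ids = pop$genomes$genome_id) {
  gene_fams <- pop$families$family_id[pop$families$class != "backbone"]
  rows <- lapply(ids, function(gid) {
    fams <- intersect(names(pop$copies[[gid]]), gene_fams)
    data.frame(genome_id = gid,
               gene_id = paste0(gid, "|", fams),
               seq = vapply(pop$copies[[gid]][fams], rawToChar, ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact pairwise ANI of a synthetic population (oracle)
#'
#' Because the generator plants substitutions only, homologous positions are
#' shared population-wide and the Hamming identity over shared families is the
#' exact ANI. The aligned fraction is the shared length over the mean genome
#' length of the pair. This is the oracle the fragment-based estimator is
#' validated against.
#'
#' @param pop a `synthetic_population`.
#' @param ids genomes to compare (default all).
#' @return An `ani_table` with one row per unordered pair.
#' @export
truth_ani_table <- function(pop, ids = pop$genomes$genome_id) {
  ids <- sort(ids)
  n <- length(ids)
  rows <- vector("list", n * (n - 1L) %/% 2L)
  r <- 0L
  for (i in seq_len(n - 1L)) {
    ci <- pop$copies[[ids[i]]]
    li <- sum(lengths(ci))
    for (j in (i + 1L):n) {
      cj <- pop$copies[[ids[j]]]
      shared <- intersect(names(ci), names(cj))
      mism <- 0L; tot <- 0L
      for (f in shared) {
        mism <- mism + sum(ci[[f]] != cj[[f]])
        tot <- tot + length(ci[[f]])
      }
      r <- r + 1L
      rows[[r]] <- data.frame(
        query_id = ids[i], subject_id = ids[j],
        ani = 100 * (tot - mism) / tot,
        aligned_fraction = 100 * 2 * tot / (li + sum(lengths(cj))),
        n_fragments_matched = NA_integer_, n_fragments_total = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  ani_table(do.call(rbind, rows))
}

#' Exact pairwise shared-gene-fraction matrix (oracle)
#' @param pop a `synthetic_population`.
#' @param ids genomes to compare (default all).
#' @return Symmetric matrix of shared gene content percentages computed from
#'   the planted gene inventories (diagonal 100).
#' @export
truth_gene_share <- function(pop, ids = pop$genomes$genome_id) {
  gene_fams <- pop$families$family_id[pop$families$class != "backbone"]
  sets <- lapply(stats::setNames(ids, ids), function(gid)
    intersect(names(pop$copies[[gid]]), gene_fams))
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sh <- length(intersect(sets[[i]], sets[[j]]))
      m[i, j] <- m[j, i] <-
        100 * sh / mean(c(length(sets[[i]]), length(sets[[j]])))
    }
  }
  m
}

#' Planted allele counts per core gene (oracle)
#'
#' Groups the realised per-genomovar copies of each core single-copy family at
#' the allele identity floor (single linkage on exact Hamming identities).
#' Because strain-level mutations never touch core genes, all members of one
#' genomovar carry the founder's allele and the planted count per family is
#' the number of distinct founder alleles.
#'
#' @param pop a `synthetic_population`.
#' @param floor allele identity floor (default 99.8).
#' @return Named integer vector: core family -> planted allele count.
#' @export
truth_allele_counts <- function(pop, floor = 99.8) {
  core <- pop$families$family_id[pop$families$class == "core"]
  gv <- pop$gv_ids
  first_genome <- vapply(gv, function(g)
    min(pop$genomes$genome_id[pop$genomes$genomovar_id == g]), "")
  vapply(stats::setNames(core, core), function(f) {
    cps <- lapply(first_genome, function(gid) pop$copies[[gid]][[f]])
    G <- length(cps)
    m <- matrix(100, G, G, dimnames = list(gv, gv))
    for (i in seq_len(G - 1L)) for (j in (i + 1L):G) {
      m[i, j] <- m[j, i] <-
        100 * sum(cps[[i]] == cps[[j]]) / length(cps[[i]])
    }
    as.integer(max(.single_linkage(m, floor - 1e-9)))  # components >= floor
  }, integer(1))
}
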