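#' Simulate metagenomic reads and an exact competitive hit table
#'
#' Reads are drawn from the population's genomovars according to the planted
#' abundances (genome within genomovar uniform), with uniform start positions
#' inside a single gene/backbone segment and independent per-base substitution
#' errors. Because the generator plants no indels, the identity of every read
#' to every target genome follows from the known homologous coordinates, so
#' the emitted 12-column hit table is a noise-free competitive-mapping fixture
#' (each read's alignment to each target carrying its source segment, at the
#' exact Hamming identity). Bit scores follow an ungapped
#' +2 match / -3 mismatch scheme, so reads from regions identical in two
#' targets produce genuine best-hit ties.
#'
#' @param pop a `synthetic_population`.
#' @param n_reads number of reads (default `spec$n_reads`).
#' @param targets genome ids entering the hit table (default all genomes);
#'   reads are still drawn from the whole population, so targets can be a
#'   subset (e.g. representatives only, or a sampled fraction of genomovars).
#' @param abundances named vector genomovar -> fraction (default the
#'   manifest's planted abundances; must sum to 1).
#' @param per_base_error substitution error rate (default from spec).
#' @param errors_per_read force an exact error count per read (overrides
#'   `per_base_error`; used to realise e.g. the one-mismatch = 99.33% case).
#' @param representatives named vector genomovar -> genome id used for the
#'   genomovar-uniqueness truth flag (default: lexicographically first target
#'   of each genomovar present among targets).
#' @param hit_identity_floor hits below this identity are not emitted
#'   (default 90).
#' @param emit_reads materialise read sequences (default TRUE).
#' @param track_uniqueness compute the `genomovar_unique` truth flag (default
#'   TRUE; disable to speed up large simulations that do not need it).
#' @param seed integer seed (default `spec$rng_seed`).
#' @return A list of class `read_simulation`: `hits` (a `hit_table`), `truth`
#'   (data.frame: read_id, genome_id, genomovar_id, family_id, offset,
#'   n_errors, genomovar_unique), `reads` ([Biostrings::DNAStringSet] or
#'   NULL), `n_reads`, `representatives`. `genomovar_unique` is TRUE when the
#'   read comes from a region diagnostic for its genomovar: the error-free
#'   source window is identical to the homologous window of the genomovar's
#'   own representative (a region shared by the genomovar, i.e. not
#'   strain-variable) and differs at >= 2 positions from every other
#'   genomovar's representative (so a one-error read can never reach the
#'   99.3% rule on a wrong genomovar).
#' @export
simulate_reads <- function(pop, n_reads = pop$spec$n_reads,
                           targets = pop$genomes$genome_id,
                           abundances = NULL,
                           per_base_error = pop$spec$per_base_error,
                           errors_per_read = NULL,
                           representatives = NULL,
                           hit_identity_floor = 90,
                           emit_reads = TRUE,
                           track_uniqueness = TRUE,
                           seed = pop$spec$rng_seed) {
  stopifnot(inherits(pop, "synthetic_population"))
  if (n_reads <= 0L) stop("n_reads must be positive")
  rl <- pop$spec$read_length
  if (is.null(abundances)) {
    abundances <- stats::setNames(pop$manifest$abundances$abundance,
                                  pop$manifest$abundances$genomovar_id)
  }
  if (abs(sum(abundances) - 1) > 1e-6) stop("abundances must sum to 1")
  gv_of <- stats::setNames(pop$genomes$genomovar_id, pop$genomes$genome_id)
  if (is.null(representatives)) {
    tgv <- split(targets, gv_of[targets])
    representatives <- vapply(tgv, function(g) min(g), "")
  }
  set.seed(seed)

  # ---- sample sources -------------------------------------------------------
  gvs <- names(abundances)
  read_gv <- gvs[sample.int(length(gvs), n_reads, replace = TRUE,
                            prob = abundances)]
  members <- split(pop$genomes$genome_id, pop$genomes$genomovar_id)
  read_gid <- character(n_reads)
  for (g in unique(read_gv)) {
    idx <- which(read_gv == g)
    m <- members[[g]]
    read_gid[idx] <- if (length(m) == 1L) m else
      m[sample.int(length(m), length(idx), replace = TRUE)]
  }

  # segment and offset: uniform over valid start positions of each genome
  fam_len <- stats::setNames(pop$families$length, pop$families$family_id)
  read_fam <- character(n_reads); read_off <- integer(n_reads)
  for (gid in unique(read_gid)) {
    idx <- which(read_gid == gid)
    fams <- names(pop$copies[[gid]])
    valid <- pmax(fam_len[fams] - rl + 1L, 0L)
    fi <- sample.int(length(fams), length(idx), replace = TRUE,
                     prob = valid / sum(valid))
    read_fam[idx] <- fams[fi]
    read_off[idx] <- 1L + floor(stats::runif(length(idx)) * valid[fi])
  }

  n_err <- if (is.null(errors_per_read)) {
    stats::rbinom(n_reads, rl, per_base_error)
  } else rep(as.integer(errors_per_read), n_reads)

  # ---- per-family target matrices ------------------------------------------
  fam_ids <- pop$families$family_id
  carriers <- lapply(stats::setNames(fam_ids, fam_ids), function(f)
    targets[vapply(targets, function(t) f %in% names(pop$copies[[t]]),
                   logical(1))])
  fam_mat <- lapply(stats::setNames(fam_ids, fam_ids), function(f) {
    tg <- carriers[[f]]
    if (!length(tg)) return(NULL)
    vapply(tg, function(t) pop$copies[[t]][[f]],
           raw(fam_len[[f]]))
  })
  # subject start coordinate of each family within each target genome
  coord <- lapply(stats::setNames(targets, targets), function(t) {
    lens <- lengths(pop$copies[[t]])
    stats::setNames(cumsum(c(0L, lens[-length(lens)])) + 1L, names(lens))
  })
  rep_gv_of_col <- lapply(stats::setNames(fam_ids, fam_ids), function(f) {
    tg <- carriers[[f]]
    is_rep <- tg %in% representatives
    stats::setNames(ifelse(is_rep, gv_of[tg], NA_character_), tg)
  })

  # ---- per-read identities --------------------------------------------------
  t_per_fam <- lengths(carriers)
  ub <- sum(t_per_fam[read_fam])
  h_read <- character(ub); h_tgt <- character(ub)
  h_mism <- integer(ub); h_sstart <- integer(ub)
  n_out <- 0L
  unique_flag <- logical(n_reads)
  read_seq <- if (emit_reads) character(n_reads) else NULL
  read_ids <- sprintf("read_%07d", seq_len(n_reads))
  max_mism <- floor((100 - hit_identity_floor) / 100 * rl + 1e-9)

  for (i in seq_len(n_reads)) {
    f <- read_fam[i]
    tg <- carriers[[f]]
    o <- read_off[i]
    win <- o:(o + rl - 1L)
    srcw <- pop$copies[[read_gid[i]]][[f]][win]
    readb <- if (n_err[i] > 0L) .mutate_raw(srcw, n_err[i]) else srcw
    if (emit_reads) read_seq[i] <- rawToChar(readb)
    repgv <- rep_gv_of_col[[f]]
    if (length(tg)) {
      slice <- fam_mat[[f]][win, , drop = FALSE]
      mism <- colSums(slice != readb)
      if (track_uniqueness) {
        other <- !is.na(repgv) & repgv != read_gv[i]
        own <- which(!is.na(repgv) & repgv == read_gv[i])
        unique_flag[i] <- length(own) == 1L &&
          sum(slice[, own] != srcw) == 0L &&
          (!any(other) ||
             all(colSums(slice[, other, drop = FALSE] != srcw) >= 2L))
      }
      keep <- which(mism <= max_mism)
      nk <- length(keep)
      if (nk) {
        rows <- (n_out + 1L):(n_out + nk)
        h_read[rows] <- read_ids[i]
        h_tgt[rows] <- tg[keep]
        h_mism[rows] <- mism[keep]
        h_sstart[rows] <- vapply(tg[keep], function(t)
          coord[[t]][[f]], integer(1)) + o - 1L
        n_out <- n_out + nk
      }
    } else {
      unique_flag[i] <- TRUE
    }
  }

  mism <- h_mism[seq_len(n_out)]
  bitscore <- 2 * (rl - mism) - 3 * mism
  hits <- hit_table(data.frame(
    read_id = h_read[seq_len(n_out)],
    genome_id = h_tgt[seq_len(n_out)],
    identity = round(100 * (rl - mism) / rl, 3),
    alignment_length = rl, mismatches = mism, gap_opens = 0L,
    qstart = 1L, qend = rl,
    sstart = h_sstart[seq_len(n_out)],
    send = h_sstart[seq_len(n_out)] + rl - 1L,
    evalue = signif(rl * 4e6 * 2^(-bitscore), 3),
    bitscore = bitscore,
    stringsAsFactors = FALSE
  ), nominal_read_length = rl)

  truth <- data.frame(read_id = read_ids, genome_id = read_gid,
                      genomovar_id = read_gv, family_id = read_fam,
                      offset = read_off, n_errors = n_err,
                      genomovar_unique = unique_flag,
                      stringsAsFactors = FALSE)
  reads <- NULL
  if (emit_reads) {
    reads <- Biostrings::DNAStringSet(read_seq)
    names(reads) <- read_ids
  }
  structure(list(hits = hits, truth = truth, reads = reads,
                 n_reads = n_reads, representatives = representatives),
            class = "read_simulation")
}

#' Emulate re-assembly replicates of one genome
#'
#' Models the split-the-reads-in-half re-assembly check used to quantify
#' sequencing/assembly noise: two independently error-perturbed copies of a
#' genome, each fragmented into contigs at random breakpoints. With a small
#' error rate the replicate pair is expected to satisfy the strain criteria
#' (ANI > 99.99%, high aligned fraction).
#'
#' @param genome a genome: [Biostrings::DNAStringSet] of contigs, a
#'   `DNAString`, or a character string.
#' @param n_fragments contigs per replicate (default 20).
#' @param error_rate per-base substitution rate (must be <= 1e-4;
#'   default 5e-5).
#' @param seed integer seed.
#' @return A `genome_set` with two genomes, `rep1` and `rep2`.
#' @export
replicate_with_noise <- function(genome, n_fragments = 20L,
                                 error_rate = 5e-5, seed = 1L) {
  if (error_rate > 1e-4) stop("error_rate must be <= 1e-4")
  x <- .as_contigs(genome)
  chr <- paste(as.character(x), collapse = "")
  L <- nchar(chr)
  set.seed(seed)
  one <- function() {
    r <- .mutate_raw(charToRaw(chr), stats::rbinom(1L, L, error_rate))
    cuts <- sort(sample.int(L - 1L, max(0L, n_fragments - 1L)))
    starts <- c(1L, cuts + 1L); ends <- c(cuts, L)
    Biostrings::DNAStringSet(vapply(seq_along(starts), function(k)
      rawToChar(r[starts[k]:ends[k]]), ""))
  }
  structure(list(rep1 = one(), rep2 = one()), class = "genome_set")
}
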