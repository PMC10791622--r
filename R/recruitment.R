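#' Best hit per read, with tie flagging
#'
#' Retains the single hit of maximal bit score per read (competitive
#' recruitment). Exact bit-score ties across different genomes are flagged;
#' tied reads are not counted downstream, which avoids double-counting reads
#' from regions conserved across references.
#'
#' @param hits a `hit_table`.
#' @param min_alignment_length optional filter applied before best-hit
#'   selection (default 0 = off).
#' @return A data.frame (one row per read): the best hit's columns plus
#'   `is_tie`.
#' @export
best_hits <- function(hits, min_alignment_length = 0L) {
  dt <- data.table::as.data.table(hits)
  if (min_alignment_length > 0L)
    dt <- dt[dt$alignment_length >= min_alignment_length]
  if (nrow(dt) == 0L) stop("no hits after filtering")
  data.table::setorderv(dt, c("read_id", "bitscore", "genome_id"),
                        order = c(1L, -1L, 1L))
  best <- dt[, {
    mx <- bitscore[1L]
    tie <- sum(bitscore == mx & !duplicated(genome_id)) > 1L
    c(.SD[1L], list(is_tie = tie))
  }, by = "read_id"]
  data.table::setDF(best)
  best
}

#' Species-level read filter
#'
#' Keeps reads whose best hit reaches the species identity floor (>= 95%) and
#' whose alignment covers at least the configured fraction of the read length
#' (>= 70%). This defines the species read set: all metagenome reads
#' attributable to the species.
#'
#' @param best best-hit data.frame from [best_hits()].
#' @param config an [analysis_config()].
#' @return The subset of `best` passing both rules (ties retained; they are
#'   accounted separately downstream).
#' @export
species_filter <- function(best, config = analysis_config()) {
  config <- .as_config(config)
  if (any(is.na(best$read_length)))
    stop("unknown read length; supply read lengths or a nominal length")
  keep <- best$identity >= config$species_identity_floor &
    100 * best$alignment_length / best$read_length >=
      config$species_read_coverage_floor
  best[keep, , drop = FALSE]
}

#' Genomovar-level read assignment
#'
#' A read is assigned to genomovar g iff it matches g's representative at
#' identity >= 99.3% and every other representative at < 99.3%; reads
#' reaching the threshold for two or more representatives are ambiguous and
#' reads reaching it for none are sub-threshold. Only representative genomes
#' (one per genomovar) enter the comparison.
#'
#' @param hits a `hit_table` containing ALL hits per read (not best-only).
#' @param representatives named character vector genomovar_id ->
#'   representative genome_id (see [pick_representatives()]).
#' @param config an [analysis_config()].
#' @param reads optional read-id vector to restrict to (e.g. the non-tied
#'   species read set).
#' @return A data.frame `read_id`, `genomovar_id` (NA when unassigned),
#'   `status` (one of `"assigned"`, `"ambiguous"`, `"sub_threshold"`).
#' @export
genomovar_assign <- function(hits, representatives,
                             config = analysis_config(), reads = NULL) {
  config <- .as_config(config)
  if (length(representatives) == 0L) stop("representative set is empty")
  dt <- data.table::as.data.table(hits)
  if (!is.null(reads)) dt <- dt[dt$read_id %in% reads]
  all_reads <- unique(dt$read_id)
  dt <- dt[dt$genome_id %in% representatives]
  dt$genomovar_id <- names(representatives)[match(dt$genome_id,
                                                  representatives)]
  qual <- dt$identity >= config$genomovar_read_identity
  if (config$coverage_at_genomovar_step)
    qual <- qual & (100 * dt$alignment_length / dt$read_length >=
                      config$species_read_coverage_floor)
  dt <- dt[qual]
  per <- dt[, list(n_gv = length(unique(genomovar_id)),
                   gv = genomovar_id[1L]), by = "read_id"]
  status <- rep("sub_threshold", length(all_reads))
  gv_out <- rep(NA_character_, length(all_reads))
  idx <- match(per$read_id, all_reads)
  status[idx] <- ifelse(per$n_gv == 1L, "assigned", "ambiguous")
  gv_out[idx] <- ifelse(per$n_gv == 1L, per$gv, NA_character_)
  data.frame(read_id = all_reads, genomovar_id = gv_out, status = status,
             stringsAsFactors = FALSE)
}

#' Per-sample genomovar abundance profile
#'
#' Full competitive-recruitment accounting for one sample: best hits, species
#' filter, tie discarding, exclusive genomovar assignment, and
#' length-normalised abundances. Per genomovar g with assigned read count
#' `n_g` and representative genome length `L_g`:
#' raw density `d_g = n_g / (L_g * total_reads)`; population fraction
#' `f_g = (n_g / L_g) / sum_h (n_h / L_h)`; species fraction =
#' species reads / total reads.
#'
#' @param hits a `hit_table` with all hits per read.
#' @param representatives genomovar_id -> representative genome_id.
#' @param genome_lengths named vector of representative genome lengths in bp
#'   (names = genome ids or genomovar ids).
#' @param total_reads total number of reads in the metagenome.
#' @param config an [analysis_config()].
#' @param sample_id label carried into the output.
#' @return An object of class `abundance_profile`: list with `sample_id`,
#'   `species_fraction`, per-genomovar table (`genomovar_id`, `reads`,
#'   `genome_length`, `density`, `population_fraction`), and the read
#'   accounting `counts` (species, counted, tie_discarded, sub_threshold,
#'   ambiguous), which partition the species read set.
#' @export
recruit_profile <- function(hits, representatives, genome_lengths,
                            total_reads, config = analysis_config(),
                            sample_id = "sample") {
  config <- .as_config(config)
  best <- best_hits(hits, config$min_alignment_length)
  sp <- species_filter(best, config)
  n_species <- nrow(sp)
  if (n_species == 0L) {
    warning("zero species reads: empty profile")
    return(structure(list(sample_id = sample_id, species_fraction = 0,
                          genomovars = data.frame(), counts = c(
                            species = 0L, counted = 0L, tie_discarded = 0L,
                            sub_threshold = 0L, ambiguous = 0L)),
                     class = "abundance_profile"))
  }
  tied <- sp$read_id[sp$is_tie]
  untied <- sp$read_id[!sp$is_tie]
  asn <- genomovar_assign(hits, representatives, config, reads = untied)
  n_counted <- sum(asn$status == "assigned")
  n_amb <- sum(asn$status == "ambiguous")
  n_sub <- sum(asn$status == "sub_threshold") + (length(untied) - nrow(asn))
  lg <- genome_lengths
  if (!is.null(names(lg)) && all(representatives %in% names(lg)))
    lg <- stats::setNames(lg[representatives], names(representatives))
  reads_g <- table(factor(asn$genomovar_id[asn$status == "assigned"],
                          levels = names(representatives)))
  dens <- as.numeric(reads_g) / (as.numeric(lg[names(representatives)]) *
                                   total_reads)
  rel <- as.numeric(reads_g) / as.numeric(lg[names(representatives)])
  popfrac <- if (sum(rel) > 0) rel / sum(rel) else rel
  gvtab <- data.frame(genomovar_id = names(representatives),
                      reads = as.integer(reads_g),
                      genome_length = as.numeric(lg[names(representatives)]),
                      density = dens, population_fraction = popfrac,
                      stringsAsFactors = FALSE)
  structure(list(
    sample_id = sample_id,
    species_fraction = n_species / total_reads,
    genomovars = gvtab,
    counts = c(species = n_species, counted = n_counted,
               tie_discarded = length(tied), sub_threshold = n_sub,
               ambiguous = n_amb)
  ), class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("Abundance profile '%s': species fraction %.4f\n",
              x$sample_id, x$species_fraction))
  cat(sprintf("  species reads %d = counted %d + ties %d + sub-threshold %d + ambiguous %d\n",
              x$counts["species"], x$counts["counted"],
              x$counts["tie_discarded"], x$counts["sub_threshold"],
              x$counts["ambiguous"]))
  top <- utils::head(x$genomovars[order(-x$genomovars$population_fraction), ],
                     5L)
  for (r in seq_len(nrow(top)))
    cat(sprintf("  %-12s reads %7d  population fraction %.4f\n",
                top$genomovar_id[r], top$reads[r],
                top$population_fraction[r]))
  invisible(x)
}
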