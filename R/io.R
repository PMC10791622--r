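#' Read a genome collection from FASTA files
#'
#' Each file becomes one genome (possibly multi-contig); alternatively a single
#' multi-FASTA can be split so that every header founds its own genome.
#' Sequences are uppercased and any character outside A/C/G/T/N is mapped to N
#' with a warning.
#'
#' @param paths character vector of FASTA file paths. Genome identifiers are
#'   taken from `names(paths)` when present, otherwise from the file base name
#'   without extension.
#' @param split_headers if TRUE, every FASTA record founds its own
#'   single-contig genome named after its header.
#' @return A named list of [Biostrings::DNAStringSet] objects (one per genome,
#'   elements are contigs), of class `genome_set`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "ACGTACGT"), fa)
#' gs <- read_genomes(fa)
#' genome_lengths(gs)
#' @export
read_genomes <- function(paths, split_headers = FALSE) {
  if (length(paths) == 0L) stop("no input files given")
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(paths))
  out <- list()
  for (i in seq_along(paths)) {
    if (!file.exists(paths[[i]])) stop("file not found: ", paths[[i]])
    ss <- Biostrings::readDNAStringSet(paths[[i]])
    if (length(ss) == 0L) stop("format error: empty FASTA file: ", paths[[i]])
    ss <- .sanitize_seqs(ss, paths[[i]])
    if (split_headers) {
      hdr <- sub("\\s.*$", "", names(ss))
      for (j in seq_along(ss)) {
        if (hdr[j] %in% names(out))
          stop("collision error: duplicate genome_id '", hdr[j], "'")
        out[[hdr[j]]] <- ss[j]
      }
    } else {
      if (ids[i] %in% names(out))
        stop("collision error: duplicate genome_id '", ids[i], "'")
      out[[ids[i]]] <- ss
    }
  }
  structure(out, class = "genome_set")
}

.sanitize_seqs <- function(ss, label = "input") {
  chr <- toupper(as.character(ss))
  bad <- gsub("[ACGTN]", "", chr)
  if (any(nchar(bad) > 0L)) {
    warning(sum(nchar(bad)), " non-ACGTN characters in ", label,
            " mapped to N")
    chr <- vapply(chr, function(s) gsub("[^ACGTN]", "N", s), "",
                  USE.NAMES = FALSE)
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(ss)
  if (any(Biostrings::width(out) == 0L)) stop("format error: empty contig")
  out
}

#' Total length of each genome in a collection
#' @param genomes a `genome_set` (see [read_genomes()]).
#' @return Named integer vector of summed contig lengths.
#' @export
genome_lengths <- function(genomes) {
  vapply(genomes, function(g) sum(Biostrings::width(g)), integer(1))
}

#' Write a genome collection to FASTA files
#' @param genomes a `genome_set`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(genomes), ".fasta"))
  for (i in seq_along(genomes)) {
    Biostrings::writeXStringSet(genomes[[i]], paths[i])
  }
  invisible(paths)
}

#' Read a pairwise ANI table
#'
#' Accepts the common tab-separated dialects emitted by fragment-based ANI
#' tools: 5 columns (query, subject, ANI%, fragments matched, fragments total)
#' or 6 columns with an explicit aligned-fraction percent appended. When the
#' aligned fraction is absent it is derived as `100 * matched / total`.
#'
#' @param path file path.
#' @return A data.frame of class `ani_table` with columns `query_id`,
#'   `subject_id`, `ani`, `aligned_fraction`, `n_fragments_matched`,
#'   `n_fragments_total`. Self-pairs are retained but flagged via the
#'   `self_pair` column. Use [ani_matrix()] for the symmetric accessor.
#' @export
read_ani_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) == 5L) {
    names(df) <- c("query_id", "subject_id", "ani", "n_fragments_matched",
                   "n_fragments_total")
    df$aligned_fraction <- 100 * df$n_fragments_matched / df$n_fragments_total
  } else if (ncol(df) == 6L) {
    names(df) <- c("query_id", "subject_id", "ani", "n_fragments_matched",
                   "n_fragments_total", "aligned_fraction")
  } else {
    stop("format error: expected 5 or 6 tab-separated columns, got ", ncol(df))
  }
  ani_table(df)
}

#' Construct an ANI table from a data.frame
#'
#' @param df data.frame with columns `query_id`, `subject_id`, `ani` and
#'   optionally `aligned_fraction`, `n_fragments_matched`, `n_fragments_total`.
#' @return A validated `ani_table`.
#' @export
ani_table <- function(df) {
  need <- c("query_id", "subject_id", "ani")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (!"aligned_fraction" %in% names(df)) df$aligned_fraction <- NA_real_
  if (!"n_fragments_matched" %in% names(df)) df$n_fragments_matched <- NA_integer_
  if (!"n_fragments_total" %in% names(df)) df$n_fragments_total <- NA_integer_
  ok <- is.na(df$ani) | (df$ani >= 0 & df$ani <= 100)
  if (!all(ok)) stop("validation error: ANI outside [0, 100] in row(s) ",
                     paste(utils::head(which(!ok)), collapse = ", "))
  okf <- is.na(df$aligned_fraction) |
    (df$aligned_fraction >= 0 & df$aligned_fraction <= 100)
  if (!all(okf)) stop("validation error: aligned_fraction outside [0, 100]")
  bad <- !is.na(df$n_fragments_matched) & !is.na(df$n_fragments_total) &
    df$n_fragments_matched > df$n_fragments_total
  if (any(bad)) stop("validation error: matched fragments exceed total")
  df$self_pair <- df$query_id == df$subject_id
  df <- df[, c("query_id", "subject_id", "ani", "aligned_fraction",
               "n_fragments_matched", "n_fragments_total", "self_pair")]
  class(df) <- c("ani_table", "data.frame")
  df
}

#' Write an ANI table in the 6-column dialect
#' @param tab an `ani_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ani_table <- function(tab, path) {
  stopifnot(inherits(tab, "ani_table"))
  utils::write.table(tab[, c("query_id", "subject_id", "ani",
                             "n_fragments_matched", "n_fragments_total",
                             "aligned_fraction")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Symmetric ANI (or aligned-fraction) matrix from an ANI table
#'
#' When both directions of a pair are present their mean is used; the diagonal
#' is 100 by definition.
#'
#' @param tab an `ani_table`.
#' @param value column to spread: `"ani"` or `"aligned_fraction"`.
#' @param genomes optional genome id vector fixing row order.
#' @return A symmetric numeric matrix (NA where a pair is missing).
#' @export
ani_matrix <- function(tab, value = c("ani", "aligned_fraction"),
                       genomes = NULL) {
  value <- match.arg(value)
  stopifnot(inherits(tab, "ani_table"))
  if (is.null(genomes))
    genomes <- sort(unique(c(tab$query_id, tab$subject_id)))
  n <- length(genomes)
  m <- matrix(NA_real_, n, n, dimnames = list(genomes, genomes))
  cnt <- matrix(0L, n, n)
  qi <- match(tab$query_id, genomes)
  si <- match(tab$subject_id, genomes)
  for (r in seq_len(nrow(tab))) {
    v <- tab[[value]][r]
    if (is.na(v)) next
    i <- qi[r]; j <- si[r]
    if (is.na(i) || is.na(j) || i == j) next
    if (cnt[i, j] == 0L) m[i, j] <- 0
    m[i, j] <- m[i, j] + v
    cnt[i, j] <- cnt[i, j] + 1L
  }
  has <- cnt > 0L
  m[has] <- m[has] / cnt[has]
  # symmetric mean of the two directions
  out <- matrix(NA_real_, n, n, dimnames = list(genomes, genomes))
  both <- has & t(has)
  one <- has & !t(has)
  out[both] <- (m[both] + t(m)[both]) / 2
  out[one] <- m[one]
  out[t(one)] <- t(m)[t(one)]
  diag(out) <- 100
  out
}

#' Read a 12-column tabular alignment hit table
#'
#' Parses the standard 12-column tabular output of nucleotide search tools
#' (query, subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, bit score), as produced by competitive
#' read-vs-genome searches.
#'
#' @param path file path.
#' @param read_lengths optional named integer vector of read lengths
#'   (names = read ids); when absent, `nominal_read_length` is assumed for
#'   every read.
#' @param nominal_read_length fallback read length in bp (default 150).
#' @return A data.frame of class `hit_table` with the 12 standard columns plus
#'   `read_length`.
#' @export
read_hit_table <- function(path, read_lengths = NULL,
                           nominal_read_length = 150L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("format error: empty hit table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L)) {
    bad <- which(nc != 12L)[1]
    stop(sprintf("format error: line %d has %d columns (expected 12)",
                 bad, nc[bad]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  df <- data.frame(
    read_id = m[, 1], genome_id = m[, 2],
    identity = as.numeric(m[, 3]), alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  hit_table(df, read_lengths = read_lengths,
            nominal_read_length = nominal_read_length)
}

#' Construct a hit table from a data.frame
#' @param df data.frame with the 12 standard columns (`read_id`, `genome_id`,
#'   `identity`, `alignment_length`, `mismatches`, `gap_opens`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`).
#' @inheritParams read_hit_table
#' @return A validated `hit_table`.
#' @export
hit_table <- function(df, read_lengths = NULL, nominal_read_length = 150L) {
  need <- c("read_id", "genome_id", "identity", "alignment_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$identity < 0 | df$identity > 100))
    stop("validation error: identity outside [0, 100]")
  if (is.null(read_lengths)) {
    df$read_length <- as.integer(nominal_read_length)
  } else {
    rl <- read_lengths[df$read_id]
    if (anyNA(rl)) stop("read length missing for some reads and no usable ",
                        "nominal length")
    df$read_length <- as.integer(rl)
  }
  df <- df[, c(need, "read_length")]
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Write a hit table in 12-column tabular format
#' @param hits a `hit_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(inherits(hits, "hit_table"))
  out <- hits[, c("read_id", "genome_id", "identity", "alignment_length",
                  "mismatches", "gap_opens", "qstart", "qend", "sstart",
                  "send", "evalue", "bitscore")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-genome gene sets from nucleotide FASTA files
#'
#' @param paths named character vector of FASTA paths; names are genome ids
#'   (file base names are used when unnamed). Headers are gene ids.
#' @return A data.frame with columns `genome_id`, `gene_id`, `seq`.
#' @export
read_gene_sets <- function(paths) {
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(paths))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    ss <- Biostrings::readDNAStringSet(paths[[i]])
    if (length(ss) == 0L) stop("format error: empty FASTA file: ", paths[[i]])
    ss <- .sanitize_seqs(ss, paths[[i]])
    gid <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(gid)) stop("duplicate gene_id within genome ", ids[i])
    out[[i]] <- data.frame(genome_id = ids[i], gene_id = gid,
                           seq = as.character(ss), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
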