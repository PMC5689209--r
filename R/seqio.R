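# Sequence I/O and strand/rotation canonicalization.
#
# Coordinates are 0-based half-open everywhere internally and in BED output;
# 1-based inclusive coordinates appear only in human-readable messages.

BASE_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a sequence record
#'
#' A lightweight container for a named nucleotide sequence, optionally with
#' per-base quality scores. Bases are uppercased and restricted to
#' `A,C,G,T,N`; any other symbol (IUPAC ambiguity codes included) is
#' collapsed to `N`.
#'
#' @param id Non-empty record identifier.
#' @param bases Nucleotide string.
#' @param qualities Optional integer vector of per-base Phred scores, same
#'   length as `bases`.
#' @param quiet Suppress the message reporting collapsed non-ACGTN symbols.
#' @return An object of class `seq_record` with elements `id`, `bases`,
#'   `qualities`.
#' @export
seq_record <- function(id, bases, qualities = NULL, quiet = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
  norm <- normalize_bases(bases)
  if (norm$n_replaced > 0L && !quiet)
    message(sprintf("record '%s': collapsed %d non-ACGTN base(s) to N",
                    id, norm$n_replaced))
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != nchar(norm$bases))
      stop("qualities length must equal sequence length")
  }
  structure(list(id = id, bases = norm$bases, qualities = qualities),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp%s)\n", x$id, nchar(x$bases),
              if (is.null(x$qualities)) "" else ", with qualities"))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$bases)

# Uppercase and collapse anything outside {A,C,G,T,N} to N; returns the
# cleaned string and the replacement count.
normalize_bases <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  up <- toupper(bases)
  n_bad <- nchar(gsub("[ACGTN]", "", up))
  if (n_bad > 0L) up <- gsub("[^ACGTN]", "N", up)
  list(bases = up, n_replaced = n_bad)
}

record_bases <- function(x) {
  if (inherits(x, "seq_record")) x$bases
  else if (is.character(x) && length(x) == 1L) x
  else stop("expected a seq_record or a single nucleotide string")
}

#' Read sequences from FASTA/FASTQ
#'
#' Reads all records of a (optionally gzipped) FASTA or FASTQ file in file
#' order. Lowercase bases are uppercased and non-ACGTN symbols are collapsed
#' to `N`; a single message reports the total number of collapsed symbols.
#' Record ids are truncated at the first whitespace.
#'
#' @param path Input file path. `.gz` files are read transparently.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (by file extension;
#'   `.fq`/`.fastq` imply FASTQ).
#' @return A list of [seq_record] objects (empty list for an empty file).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (file.info(path)$size == 0L) return(list())
  if (format == "fastq") {
    ss <- Biostrings::readBStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
    quals <- S4Vectors::mcols(ss)$qualities
  } else {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    quals <- NULL
  }
  ids <- sub("\\s.*$", "", names(ss))
  total_bad <- 0L
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    norm <- normalize_bases(as.character(ss[[i]]))
    total_bad <- total_bad + norm$n_replaced
    q <- if (!is.null(quals)) utf8ToInt(as.character(quals[[i]])) - 33L
    out[[i]] <- structure(list(id = ids[i], bases = norm$bases,
                               qualities = q), class = "seq_record")
  }
  if (total_bad > 0L)
    message(sprintf("%s: collapsed %d non-ACGTN base(s) to N",
                    basename(path), total_bad))
  out
}

#' Write sequences to FASTA
#'
#' @param records List of [seq_record] objects (or named character vector).
#' @param path Output path; a `.gz` extension triggers gzip compression.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  if (is.character(records))
    records <- Map(function(id, b) seq_record(id, b, quiet = TRUE),
                   names(records), unname(records))
  seqs <- vapply(records, function(r) r$bases, character(1))
  names(seqs) <- vapply(records, function(r) r$id, character(1))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences to FASTQ
#'
#' Records without qualities are written with a uniform placeholder quality
#' of 30.
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (r in records) {
    q <- r$qualities
    if (is.null(q)) q <- rep.int(30L, nchar(r$bases))
    writeLines(c(paste0("@", r$id), r$bases, "+",
                 intToUtf8(q + 33L, multiple = FALSE)), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick complement of the reversed input; `N` maps to `N`. The empty
#' string maps to itself.
#'
#' @param bases String over `{A,C,G,T,N}`.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement(mm53())  # the Mm53 FISH probe sequence
#' @export
reverse_complement <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  if (!nzchar(bases)) return("")
  if (grepl("[^ACGTN]", bases))
    stop("reverse_complement: sequence contains characters outside ACGTN")
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", bases))))
}

# All cyclic rotations of a string (vectorized via its doubling).
string_rotations <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(character(0))
  dbl <- paste0(s, s)
  substring(dbl, seq_len(n), seq_len(n) + n - 1L)
}

#' Canonical form of a circularly permutable monomer
#'
#' Tandem-repeat detectors report a monomer in an arbitrary rotation and on
#' an arbitrary strand. The canonical form is the lexicographically smallest
#' string among all rotations of the input and all rotations of its reverse
#' complement, giving a rotation- and strand-invariant identity for the
#' repeat unit. Idempotent.
#'
#' @param bases Non-empty string over `{A,C,G,T}` (no `N`).
#' @return The canonical monomer string.
#' @examples
#' canonical_monomer(mm53()) == canonical_monomer(reverse_complement(mm53()))
#' @export
canonical_monomer <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  if (!nzchar(bases)) stop("canonical_monomer: empty input")
  if (grepl("[^ACGT]", bases))
    stop("canonical_monomer: sequence must contain only A,C,G,T")
  min(c(string_rotations(bases), string_rotations(reverse_complement(bases))))
}

#' Write intervals as BED6
#'
#' Writes 0-based half-open BED6 lines sorted by `(seq_id, start)`. Input is
#' a data frame with columns `seq_id`, `start`, `end` and optionally `name`,
#' `score`, `strand` (defaults `"."`, `0`, `"."`).
#'
#' @param intervals Data frame of intervals.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  req <- c("seq_id", "start", "end")
  if (!all(req %in% names(intervals)))
    stop("intervals must have columns seq_id, start, end")
  df <- as.data.frame(intervals)
  if (nrow(df)) {
    if (any(df$start < 0) || any(df$end <= df$start))
      stop("invalid interval coordinates: need 0 <= start < end")
    if (is.null(df$name)) df$name <- "."
    if (is.null(df$score)) df$score <- 0L
    if (is.null(df$strand)) df$strand <- "."
    if (!all(df$strand %in% c("+", "-", ".")))
      stop("strand must be one of +, -, .")
    df <- df[order(df$seq_id, df$start), c(req, "name", "score", "strand")]
  } else {
    df <- data.frame(seq_id = character(), start = integer(),
                     end = integer(), name = character(),
                     score = integer(), strand = character())
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
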