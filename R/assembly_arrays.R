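# Satellite-array annotation across assembly scaffolds, gap/end context
# flags, and assembly statistics under the 25-N contig convention.

as_named_assembly <- function(assembly) {
  if (inherits(assembly, "seq_record")) assembly <- list(assembly)
  ids <- vapply(assembly, function(r) r$id, character(1))
  names(assembly) <- ids
  assembly
}

empty_arrays <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             monomer_id = character(), copies = numeric(),
             percent_identity = numeric(), strand = character(),
             near_gap = logical(), near_end = logical(),
             stringsAsFactors = FALSE)
}

#' Annotate satellite arrays of a monomer across scaffolds
#'
#' Scans each scaffold for tandem repeats, keeps hits whose period is
#' within 10% of an integer multiple of the monomer's base period and
#' whose consensus matches the monomer's canonical form at
#' `>= min_identity` percent under the best rotation/strand, merges kept
#' hits separated by less than one monomer length, and emits arrays of at
#' least `min_array_len` bp. The default length threshold (2000 bp)
#' matches the ">2 kb" array census convention.
#'
#' @param assembly List of [seq_record] scaffolds.
#' @param monomer A `monomer_consensus` (from [build_consensus()]) or a
#'   plain monomer string.
#' @param min_array_len Minimum emitted array length in bp (default 2000).
#' @param min_identity Consensus-to-monomer identity gate in percent
#'   (default 70).
#' @param params [scan_params] used for the underlying scan.
#' @param monomer_id Name recorded for the arrays (default
#'   `"monomer_<period>"`).
#' @return Data frame of `SatelliteArray` rows: `seq_id`, `start`, `end`
#'   (0-based half-open), `monomer_id`, `copies`, `percent_identity`,
#'   `strand`, `near_gap`, `near_end` (the last two `NA` until
#'   [flag_context()] is applied).
#' @export
annotate_arrays <- function(assembly, monomer, min_array_len = 2000L,
                            min_identity = 70, params = scan_params(),
                            monomer_id = NULL) {
  if (inherits(monomer, "monomer_consensus")) {
    mon <- monomer$canonical
    base_p <- monomer$base_period
  } else {
    mon <- canonical_monomer(record_bases(monomer))
    base_p <- nchar(mon)
  }
  if (is.null(monomer_id)) monomer_id <- paste0("monomer_", base_p)
  assembly <- as_named_assembly(assembly)
  params$min_period <- max(2L, as.integer(floor(0.9 * base_p)))
  out <- list()
  for (rec in assembly) {
    hits <- scan_sequence(rec, params)
    if (!nrow(hits)) next
    m <- round(hits$period / base_p)
    harmonic <- m >= 1 & abs(hits$period - m * base_p) <= 0.1 * hits$period
    hits <- hits[harmonic, , drop = FALSE]
    if (!nrow(hits)) next
    ri <- lapply(hits$consensus, rotational_identity, monomer = mon)
    idt <- vapply(ri, `[[`, numeric(1), "identity")
    strand <- vapply(ri, `[[`, character(1), "strand")
    keep <- idt >= min_identity
    hits <- hits[keep, , drop = FALSE]
    strand <- strand[keep]
    if (!nrow(hits)) next
    o <- order(hits$start)
    hits <- hits[o, , drop = FALSE]; strand <- strand[o]
    grp <- cumsum(c(1L, hits$start[-1L] - hits$end[-nrow(hits)] >= base_p))
    for (g in unique(grp)) {
      sub <- hits[grp == g, , drop = FALSE]
      st <- min(sub$start); en <- max(sub$end)
      if (en - st < min_array_len) next
      len <- sub$end - sub$start
      plus_bp <- sum(len[strand[grp == g] == "+"])
      out[[length(out) + 1L]] <- data.frame(
        seq_id = rec$id, start = st, end = en, monomer_id = monomer_id,
        copies = (en - st) / base_p,
        percent_identity = sum(sub$percent_identity * len) / sum(len),
        strand = if (plus_bp * 2 >= sum(len)) "+" else "-",
        near_gap = NA, near_end = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_arrays())
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# 0-based half-open intervals of N-runs of at least `min_n_run` bases.
n_run_intervals <- function(bases, min_n_run = 25L) {
  m <- gregexpr(sprintf("N{%d,}", min_n_run), bases)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Flag gap and scaffold-end context of satellite arrays
#'
#' Satellite arrays of unassembled centromeres tend to sit at scaffold
#' termini or against runs of Ns; these flags capture that geometry.
#' `near_end` is true when the array lies within `end_margin` bp of either
#' scaffold terminus; `near_gap` when it lies within `gap_margin` bp of an
#' N-run of at least `min_gap_run` bases.
#'
#' @param arrays Data frame from [annotate_arrays()].
#' @param assembly List of [seq_record] scaffolds (must contain every
#'   `seq_id` in `arrays`).
#' @param end_margin Distance to a terminus in bp (default 10000).
#' @param gap_margin Distance to an N-run in bp (default 5000).
#' @param min_gap_run Minimum N-run length counted as a gap (default 25).
#' @return `arrays` with `near_gap` and `near_end` filled in.
#' @export
flag_context <- function(arrays, assembly, end_margin = 10000L,
                         gap_margin = 5000L, min_gap_run = 25L) {
  assembly <- as_named_assembly(assembly)
  if (!nrow(arrays)) return(arrays)
  missing_ids <- setdiff(unique(arrays$seq_id), names(assembly))
  if (length(missing_ids))
    stop("scaffold(s) not in assembly: ", paste(missing_ids, collapse = ", "))
  gaps_by <- lapply(assembly, function(r) n_run_intervals(r$bases, min_gap_run))
  lens <- vapply(assembly, function(r) nchar(r$bases), numeric(1))
  for (i in seq_len(nrow(arrays))) {
    id <- arrays$seq_id[i]
    L <- lens[[id]]
    arrays$near_end[i] <- arrays$start[i] <= end_margin ||
      (L - arrays$end[i]) <= end_margin
    g <- gaps_by[[id]]
    if (nrow(g)) {
      dist <- pmax(0, pmax(g$start - arrays$end[i],
                           arrays$start[i] - g$end))
      arrays$near_gap[i] <- any(dist <= gap_margin)
    } else {
      arrays$near_gap[i] <- FALSE
    }
  }
  arrays
}

#' Split a scaffold into contigs on N-runs
#'
#' Contigs are the maximal intervals containing no N-run of `min_n_run` or
#' more bases; shorter N-runs stay inside contigs. The convention (25-N
#' default) matches contig statistics reported for super-scaffolded
#' assemblies.
#'
#' @param scaffold A [seq_record] or nucleotide string.
#' @param min_n_run Minimum N-run length that splits (default 25).
#' @return Data frame of 0-based half-open contig intervals (`start`,
#'   `end`); empty for an empty scaffold.
#' @export
split_contigs <- function(scaffold, min_n_run = 25L) {
  bases <- record_bases(scaffold)
  L <- nchar(bases)
  if (L == 0L) return(data.frame(start = integer(), end = integer()))
  runs <- n_run_intervals(bases, min_n_run)
  bounds <- c(0L, as.vector(rbind(runs$start, runs$end)), L)
  starts <- bounds[seq(1L, length(bounds), by = 2L)]
  ends <- bounds[seq(2L, length(bounds), by = 2L)]
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

# N50: length of the shortest sequence in the minimal set of longest
# sequences covering at least half of the total length.
n50_value <- function(lengths) {
  if (!length(lengths)) return(NA_real_)
  s <- sort(unname(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Assembly summary statistics
#'
#' Scaffold and contig statistics under the N-run contig convention of
#' [split_contigs()]. `percent_in_scaffolded_contigs` is the percentage of
#' contig bases residing in scaffolds of two or more contigs.
#'
#' @param assembly List of [seq_record] scaffolds (at least one).
#' @param min_n_run Contig-splitting N-run threshold (default 25).
#' @return An `assembly_stats` list: `n_scaffolds`, `total_bp`,
#'   `longest_bp`, `scaffold_N50`, `contig_N50`, `percent_N`,
#'   `percent_in_scaffolded_contigs`.
#' @export
assembly_stats <- function(assembly, min_n_run = 25L) {
  assembly <- as_named_assembly(assembly)
  if (!length(assembly)) stop("empty assembly")
  slens <- vapply(assembly, function(r) nchar(r$bases), numeric(1))
  n_count <- sum(vapply(assembly, function(r)
    nchar(gsub("[^N]", "", r$bases)), numeric(1)))
  contigs <- lapply(assembly, split_contigs, min_n_run = min_n_run)
  clens <- unlist(lapply(contigs, function(ct) ct$end - ct$start))
  if (is.null(clens)) clens <- numeric(0)
  multi <- vapply(contigs, nrow, integer(1)) >= 2L
  scaffolded_bp <- sum(unlist(lapply(contigs[multi], function(ct)
    ct$end - ct$start)))
  structure(list(
    n_scaffolds = length(assembly),
    total_bp = sum(slens),
    longest_bp = max(slens),
    scaffold_N50 = n50_value(slens),
    contig_N50 = n50_value(clens),
    percent_N = 100 * n_count / sum(slens),
    percent_in_scaffolded_contigs =
      if (length(clens)) 100 * scaffolded_bp / sum(clens) else 0),
    class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("<assembly_stats> %d scaffold(s), %.0f bp total\n",
                     "  longest %.0f bp | scaffold N50 %.0f | contig N50 %.0f\n",
                     "  %%N %.2f | %%bp in scaffolded contigs %.2f\n"),
              x$n_scaffolds, x$total_bp, x$longest_bp, x$scaffold_N50,
              x$contig_N50, x$percent_N, x$percent_in_scaffolded_contigs))
  invisible(x)
}
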