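# Optical-map analytics: in silico nicking digestion, molecule filtering,
# label-spacing periodicity, higher-order-repeat region calling, enzyme
# selection, and minimal BNX/CMAP dialects.

IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                H = "D", V = "B", N = "N")

#' Nicking-enzyme specification
#'
#' @param name Enzyme name.
#' @param motif IUPAC recognition motif, length >= 4.
#' @param nick_offset Nick position in bp from the motif start on the
#'   recognition strand; may exceed the motif length (downstream nicking,
#'   e.g. Nt.BspQI nicks one base 3' of its 7-bp site, offset 8).
#' @return An `enzyme_spec` list.
#' @export
enzyme_spec <- function(name, motif, nick_offset) {
  motif <- toupper(motif)
  if (!is.character(name) || !nzchar(name)) stop("enzyme name required")
  if (nchar(motif) < 4L) stop("motif must be at least 4 bases")
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_CLASS), collapse = "")),
            motif))
    stop("invalid IUPAC motif: ", motif)
  structure(list(name = name, motif = motif,
                 nick_offset = as.integer(nick_offset)),
            class = "enzyme_spec")
}

#' Built-in nicking enzymes
#'
#' A small catalog of commercially available nicking endonucleases with
#' their recognition motifs and nick offsets (bp from motif start on the
#' recognition strand). Nt.BspQI (GCTCTTC, offset 8) is the enzyme behind
#' Irys-style optical maps whose single fortuitous site per centromeric
#' higher-order-repeat unit makes those arrays visible as a constant label
#' spacing.
#'
#' @return List of [enzyme_spec] objects.
#' @export
nicking_enzymes <- function() {
  list(enzyme_spec("Nt.BspQI", "GCTCTTC", 8L),
       enzyme_spec("Nt.BstNBI", "GAGTC", 9L),
       enzyme_spec("Nb.BbvCI", "CCTCAGC", 2L),
       enzyme_spec("Nt.AlwI", "GGATC", 9L),
       enzyme_spec("Nb.BsmI", "GAATGC", 1L))
}

#' Read an enzyme table
#'
#' Three whitespace/tab-separated columns: name, IUPAC motif, nick offset.
#' Lines starting with `#` are skipped.
#'
#' @param path Table path.
#' @return List of [enzyme_spec] objects.
#' @export
read_enzyme_table <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("enzyme table needs 3 columns: name motif offset")
  Map(enzyme_spec, df[[1L]], df[[2L]], df[[3L]])
}

# Reverse complement of an IUPAC motif.
iupac_revcomp <- function(motif) {
  chars <- rev(strsplit(motif, "")[[1L]])
  paste(IUPAC_COMP[chars], collapse = "")
}

# 0-based start positions of (overlapping) motif matches; IUPAC codes in
# the motif expand to their base classes, but N in the subject never
# matches because subject Ns are not in any class.
motif_positions <- function(bases, motif) {
  chars <- strsplit(motif, "")[[1L]]
  rx <- paste0("(?=", paste(IUPAC_CLASS[chars], collapse = ""), ")")
  m <- gregexpr(rx, bases, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Construct a label molecule
#'
#' Ordered nick-label positions along one molecule or consensus map.
#'
#' @param molecule_id Identifier.
#' @param length Molecule length in bp.
#' @param labels Numeric vector of label positions, `0 <= label < length`;
#'   sorted and deduplicated on construction.
#' @return A `label_molecule` list.
#' @export
label_molecule <- function(molecule_id, length, labels = numeric(0)) {
  labels <- sort(unique(as.numeric(labels)))
  if (length(labels) && (labels[1L] < 0 || labels[length(labels)] >= length))
    stop("labels must lie in [0, length)")
  structure(list(molecule_id = as.character(molecule_id),
                 length = as.numeric(length), labels = labels),
            class = "label_molecule")
}

#' @export
print.label_molecule <- function(x, ...) {
  cat(sprintf("<label_molecule> %s: %.0f bp, %d label(s)\n",
              x$molecule_id, x$length, length(x$labels)))
  invisible(x)
}

#' In silico nicking digestion
#'
#' Places a label at the nick position of every motif match on both
#' strands: `start + nick_offset` for plus-strand matches and the
#' reflected `start + motif_length - nick_offset` for minus-strand
#' matches. Matches are overlapping, IUPAC degeneracy is expanded, `N` in
#' the sequence never matches, labels outside the molecule are discarded
#' and labels within 1 bp of each other are deduplicated.
#'
#' @param record A [seq_record] or nucleotide string.
#' @param enzyme An [enzyme_spec].
#' @return A [label_molecule].
#' @export
digest_in_silico <- function(record, enzyme) {
  bases <- record_bases(record)
  id <- if (inherits(record, "seq_record")) record$id else "seq"
  L <- nchar(bases)
  ml <- nchar(enzyme$motif)
  f <- motif_positions(bases, enzyme$motif)
  r <- motif_positions(bases, iupac_revcomp(enzyme$motif))
  labs <- sort(c(f + enzyme$nick_offset, r + ml - enzyme$nick_offset))
  labs <- labs[labs >= 0 & labs < L]
  if (length(labs) > 1L) labs <- labs[c(TRUE, diff(labs) > 1)]
  label_molecule(id, L, labs)
}

#' Filter raw label molecules
#'
#' Retains molecules at least `min_len` bp long carrying at least
#' `min_labels` labels — the standard raw-molecule filter for physical-map
#' production (150 kb / 8 labels).
#'
#' @param mols List of [label_molecule] objects.
#' @param min_len Minimum molecule length in bp (default 150000).
#' @param min_labels Minimum label count (default 8).
#' @return The retained sublist.
#' @export
filter_molecules <- function(mols, min_len = 150000, min_labels = 8L) {
  keep <- vapply(mols, function(m)
    m$length >= min_len && length(m$labels) >= min_labels, logical(1))
  mols[keep]
}

empty_runs <- function() {
  data.frame(molecule_id = character(), first_label_index = integer(),
             m = integer(), n_intervals = integer(), unit_bp = numeric(),
             cv = numeric(), start_bp = numeric(), end_bp = numeric(),
             stringsAsFactors = FALSE)
}

# Maximal runs of >= min_run consecutive values within +/- rel_tol of the
# running median, greedily extended from each feasible start.
constant_runs <- function(vals, rel_tol, min_run) {
  nc <- length(vals)
  out <- list()
  i <- 1L
  while (i <= nc - min_run + 1L) {
    run <- vals[i]
    j <- i + 1L
    while (j <= nc) {
      med <- median(run)
      if (abs(vals[j] - med) <= rel_tol * med) {
        run <- c(run, vals[j]); j <- j + 1L
      } else break
    }
    len <- j - i
    if (len >= min_run) {
      out[[length(out) + 1L]] <- c(start = i, len = len)
      i <- j
    } else i <- i + 1L
  }
  out
}

#' Detect runs of near-constant label spacing
#'
#' For each composite order `m` in `1..max_composite`, forms the series of
#' sums of `m` consecutive label spacings and finds maximal runs of at
#' least `min_run` values within `rel_tol` of their running median —
#' composite orders catch repeat units carrying more than one label.
#' Overlapping runs of different orders collapse to the smallest `m`, and
#' runs whose unit falls outside `unit_range` are dropped.
#'
#' @param mol A [label_molecule] (needs >= 2 labels to yield anything).
#' @param rel_tol Relative spacing tolerance (default 0.10, Irys-scale
#'   sizing error).
#' @param min_run Minimum run length in composite values (default 4).
#' @param max_composite Largest composite order tried (default 5).
#' @param unit_range Reportable unit size window in bp (default
#'   `c(2000, 35500)`); `NULL` disables the filter.
#' @return Data frame of `LabelRepeatRun` rows: `molecule_id`,
#'   `first_label_index` (1-based), `m`, `n_intervals`, `unit_bp` (median
#'   spacing), `cv`, `start_bp`, `end_bp`.
#' @export
find_label_repeats <- function(mol, rel_tol = 0.10, min_run = 4L,
                               max_composite = 5L,
                               unit_range = c(2000, 35500)) {
  labs <- mol$labels
  if (length(labs) < 2L) return(empty_runs())
  d <- diff(labs)
  rows <- list()
  for (m in seq_len(max_composite)) {
    if (length(d) < m) break
    comp <- if (m == 1L) d else {
      cs <- cumsum(c(0, d))
      cs[(m + 1L):length(cs)] - cs[1L:(length(cs) - m)]
    }
    for (r in constant_runs(comp, rel_tol, min_run)) {
      i <- r[["start"]]; len <- r[["len"]]
      vals <- comp[i:(i + len - 1L)]
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = mol$molecule_id, first_label_index = i, m = m,
        n_intervals = len, unit_bp = median(vals),
        cv = if (len > 1L) sd(vals) / mean(vals) else 0,
        start_bp = labs[i], end_bp = labs[i + len + m - 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_runs())
  runs <- do.call(rbind, rows)
  # harmonic collapse: drop a run when a smaller-m run overlaps it
  keep <- rep(TRUE, nrow(runs))
  ord <- order(runs$m, -runs$n_intervals)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      j <- ord[b]
      if (i == j || !keep[j] || runs$m[j] <= runs$m[i]) next
      if (runs$start_bp[j] < runs$end_bp[i] &&
          runs$start_bp[i] < runs$end_bp[j]) keep[j] <- FALSE
    }
  }
  runs <- runs[keep, , drop = FALSE]
  if (!is.null(unit_range))
    runs <- runs[runs$unit_bp >= unit_range[1L] &
                   runs$unit_bp <= unit_range[2L], , drop = FALSE]
  runs <- runs[order(runs$start_bp, runs$m), , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Histogram of repeat-unit sizes
#'
#' Bins run unit sizes, weighting each run by its number of intervals, and
#' flags bins sitting at twice another occupied bin — the tandem signature
#' by which a doubled unit betrays a harmonic (e.g. 5.2 kb over 2.6 kb).
#'
#' @param runs Data frame from [find_label_repeats()].
#' @param bin_bp Bin width in bp (default 100).
#' @return Data frame `bin_bp` (bin lower edge), `weight` (summed
#'   intervals), `n_runs`, `twox_of` (lower edge of the half-size bin, or
#'   `NA`).
#' @export
unit_spectrum <- function(runs, bin_bp = 100) {
  if (!nrow(runs))
    return(data.frame(bin_bp = numeric(), weight = numeric(),
                      n_runs = integer(), twox_of = numeric()))
  bin <- floor(runs$unit_bp / bin_bp) * bin_bp
  w <- tapply(runs$n_intervals, bin, sum)
  n <- tapply(runs$n_intervals, bin, length)
  out <- data.frame(bin_bp = as.numeric(names(w)), weight = as.numeric(w),
                    n_runs = as.integer(n))
  out <- out[order(out$bin_bp), , drop = FALSE]
  out$twox_of <- NA_real_
  for (i in seq_len(nrow(out))) {
    half <- out$bin_bp[abs(out$bin_bp * 2 - out$bin_bp[i]) <= bin_bp]
    half <- half[half < out$bin_bp[i]]
    if (length(half)) out$twox_of[i] <- half[1L]
  }
  rownames(out) <- NULL
  out
}

#' Call higher-order-repeat regions on a consensus map
#'
#' Stitches label-repeat runs separated by less than two units into
#' regions. A region is `simple` when it consists of one run with one unit
#' mode, `complex` when stitched across interruptions or carrying two or
#' more unit modes. Regions spanning less than `min_span` bp are still
#' reported but flagged `sub_span`.
#'
#' @param map A [label_molecule] holding a consensus map.
#' @param rel_tol Spacing tolerance passed to [find_label_repeats()].
#' @param min_run Minimum run length passed on.
#' @param min_span Span in bp below which a call is flagged (default
#'   400000, the scale of the smallest simple arrays).
#' @param unit_range Unit window passed on.
#' @return Data frame of `HORCall` rows: `map_id`, `start`, `end`,
#'   `unit_bp`, `n_units`, `complexity`, `sub_span`.
#' @export
call_hor_regions <- function(map, rel_tol = 0.10, min_run = 4L,
                             min_span = 400000,
                             unit_range = c(2000, 35500)) {
  empty <- data.frame(map_id = character(), start = numeric(),
                      end = numeric(), unit_bp = numeric(),
                      n_units = integer(), complexity = character(),
                      sub_span = logical(), stringsAsFactors = FALSE)
  runs <- find_label_repeats(map, rel_tol, min_run,
                             unit_range = unit_range)
  if (!nrow(runs)) return(empty)
  runs <- runs[order(runs$start_bp), , drop = FALSE]
  grp <- 1L
  grps <- integer(nrow(runs))
  grps[1L] <- grp
  for (i in seq_len(nrow(runs))[-1L]) {
    gap <- runs$start_bp[i] - runs$end_bp[i - 1L]
    if (gap >= 2 * max(runs$unit_bp[i], runs$unit_bp[i - 1L])) grp <- grp + 1L
    grps[i] <- grp
  }
  out <- list()
  for (g in unique(grps)) {
    sub <- runs[grps == g, , drop = FALSE]
    st <- min(sub$start_bp); en <- max(sub$end_bp)
    # cluster member units within rel_tol to count modes
    us <- sort(sub$unit_bp)
    modes <- 1L
    for (i in seq_along(us)[-1L])
      if (us[i] - us[i - 1L] > rel_tol * us[i - 1L]) modes <- modes + 1L
    unit <- sum(sub$unit_bp * sub$n_intervals) / sum(sub$n_intervals)
    out[[length(out) + 1L]] <- data.frame(
      map_id = map$molecule_id, start = st, end = en, unit_bp = unit,
      n_units = as.integer(round((en - st) / unit)),
      complexity = if (modes >= 2L || nrow(sub) >= 2L) "complex" else "simple",
      sub_span = (en - st) < min_span, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank nicking enzymes for targeted physical mapping of a repeat unit
#'
#' Reverse-engineering step: given one higher-order-repeat unit (treated
#' as circular, since the unit tiles the array), count each enzyme's nick
#' sites on both strands and rank: (1) exactly one site per unit — the
#' geometry that renders an array as a constant label spacing equal to the
#' unit length; (2) `k >= 2` sites, all circular spacings at least
#' `min_spacing` (smaller `k` better); enzymes with no site or any spacing
#' below `min_spacing` are excluded. Ties break on enzyme name.
#'
#' @param unit_seq Nucleotide string of one unit.
#' @param enzymes List of [enzyme_spec] (default [nicking_enzymes()]).
#' @param min_spacing Minimum resolvable label spacing in bp (default
#'   1500, approximating optical label resolution).
#' @return Data frame of ranked enzymes: `enzyme`, `sites_per_unit`,
#'   `spacings` (comma-separated bp), `rank`; excluded enzymes are
#'   returned in the `excluded` attribute.
#' @export
select_enzyme <- function(unit_seq, enzymes = nicking_enzymes(),
                          min_spacing = 1500) {
  unit_seq <- record_bases(unit_seq)
  if (!nzchar(unit_seq)) stop("unit sequence must be non-empty")
  if (!length(enzymes)) stop("enzyme list must be non-empty")
  L <- nchar(unit_seq)
  dbl <- strrep(unit_seq, 2L)
  rows <- list(); excluded <- character(0)
  for (e in enzymes) {
    ml <- nchar(e$motif)
    f <- motif_positions(dbl, e$motif)
    r <- motif_positions(dbl, iupac_revcomp(e$motif))
    sites <- sort(unique(c((f + e$nick_offset) %% L,
                           (r + ml - e$nick_offset) %% L)))
    sites <- sites[sites >= 0 & sites < L]
    if (length(sites) > 1L) {
      sites <- sites[c(TRUE, diff(sites) > 1)]
      if (length(sites) > 1L && (sites[1L] + L - sites[length(sites)]) <= 1)
        sites <- sites[-length(sites)]
    }
    k <- length(sites)
    if (k == 0L) { excluded <- c(excluded, e$name); next }
    spac <- if (k == 1L) L else diff(c(sites, sites[1L] + L))
    if (k >= 2L && any(spac < min_spacing)) {
      excluded <- c(excluded, e$name); next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      enzyme = e$name, sites_per_unit = k,
      spacings = paste(round(spac, 1), collapse = ","),
      category = if (k == 1L) 1L else 2L, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(enzyme = character(), sites_per_unit = integer(),
                      spacings = character(), rank = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$category, out$sites_per_unit, out$enzyme), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$category <- NULL
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Write label molecules in a minimal BNX dialect
#'
#' One `0` line per molecule (`0 <TAB> id <TAB> length`) followed by one
#' `1` line holding channel-1 label positions plus the molecule length as
#' the final value. Extra channels and quality lines are not written.
#'
#' @param mols List of [label_molecule] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bnx <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# BNX File Version\t1.2",
               "# Label Channels\t1",
               "#0h\tLabelChannel\tMoleculeId\tLength",
               "#1h\tLabelChannel\tLabelPositions[N]"), con)
  for (m in mols) {
    writeLines(sprintf("0\t%s\t%.1f", m$molecule_id, m$length), con)
    writeLines(paste(c("1", sprintf("%.1f", c(m$labels, m$length))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal BNX file
#'
#' Parses `0` (molecule header: id, length) and `1` (channel-1 label
#' positions) lines; the trailing position equal to the molecule length is
#' treated as the end marker and dropped, and any other channels or `Q`
#' lines are ignored.
#'
#' @param path BNX path.
#' @return List of [label_molecule] objects.
#' @export
read_bnx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  mols <- list()
  cur_id <- NULL; cur_len <- NULL
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (f[1L] == "0") {
      cur_id <- f[2L]; cur_len <- as.numeric(f[3L])
    } else if (f[1L] == "1" && !is.null(cur_id)) {
      pos <- as.numeric(f[-1L])
      if (length(pos) && abs(pos[length(pos)] - cur_len) < 1e-6)
        pos <- pos[-length(pos)]
      mols[[length(mols) + 1L]] <- label_molecule(cur_id, cur_len, pos)
      cur_id <- NULL
    }
  }
  mols
}

#' Read a CMAP consensus-map file
#'
#' Tab-separated with columns `CMapId`, `ContigLength`, `NumSites`,
#' `SiteID`, `LabelChannel`, `Position` (a `#h` header line is used when
#' present; otherwise the first six columns are assumed in that order).
#' Channel-0 rows (map end markers) are dropped.
#'
#' @param path CMAP path.
#' @return List of [label_molecule] objects, one per `CMapId`.
#' @export
read_cmap <- function(path) {
  lines <- readLines(path)
  hline <- grep("^#h", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(list())
  df <- read.table(text = body, sep = "\t", stringsAsFactors = FALSE)
  if (length(hline)) {
    cols <- strsplit(sub("^#h\\s*", "", hline[1L]), "\t")[[1L]]
    names(df)[seq_along(cols)] <- trimws(cols)
  } else {
    names(df)[1:6] <- c("CMapId", "ContigLength", "NumSites", "SiteID",
                        "LabelChannel", "Position")
  }
  df <- df[df$LabelChannel != 0, , drop = FALSE]
  out <- list()
  for (id in unique(df$CMapId)) {
    sub <- df[df$CMapId == id, , drop = FALSE]
    len <- sub$ContigLength[1L]
    out[[length(out) + 1L]] <-
      label_molecule(id, len, sub$Position[sub$Position < len])
  }
  out
}
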