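# Monomer mining: filter tandem hits, build the period spectrum, rank
# enriched base monomers and assemble a canonical consensus (the discovery
# step that surfaced the 53-bp Mm53 centromeric monomer).

#' Mining filters for tandem-repeat hits
#'
#' Defaults mirror the satellite-mining thresholds: minimum monomer length
#' 10 bp, minimum of 4 tandem copies, minimum 70% array identity.
#'
#' @param min_monomer_len Minimum period in bp (default 10).
#' @param min_copies Minimum copy number (default 4).
#' @param min_identity Minimum percent identity (default 70).
#' @return A `mining_filters` list.
#' @export
mining_filters <- function(min_monomer_len = 10L, min_copies = 4,
                           min_identity = 70) {
  stopifnot(min_monomer_len > 0, min_copies > 0, min_identity > 0)
  structure(list(min_monomer_len = min_monomer_len,
                 min_copies = min_copies, min_identity = min_identity),
            class = "mining_filters")
}

#' Filter tandem-repeat hits for monomer mining
#'
#' Retains exactly the hits whose monomer length is at least
#' `min_monomer_len`, monomer copy number at least `min_copies` and
#' percent identity at least `min_identity`, preserving input order.
#' When the hits carry `base_period`/`base_copies` columns (from
#' [collapse_harmonics()]), the monomer length and copy number are taken
#' on the base-monomer scale, so that a harmonic hit counts its copies of
#' the underlying monomer rather than of the multiple. Idempotent.
#'
#' @param hits Hit data frame from [scan_sequence()].
#' @param filters A [mining_filters] object.
#' @return The retained subset of `hits`.
#' @export
filter_hits <- function(hits, filters = mining_filters()) {
  mono_len <- if (!is.null(hits$base_period)) hits$base_period
              else hits$period
  copies <- if (!is.null(hits$base_copies)) hits$base_copies
            else hits$copy_number
  keep <- mono_len >= filters$min_monomer_len &
    copies >= filters$min_copies &
    hits$percent_identity >= filters$min_identity
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the monomer-length vs array-length spectrum
#'
#' One point per retained hit (detected period, array length, sequence id)
#' and a histogram of base periods weighted by total array bp — the
#' discovery signal is long arrays, so enrichment is measured in array bp.
#'
#' @param retained Hit data frame carrying a `base_period` column (from
#'   [collapse_harmonics()]); if absent, each hit's own period is used.
#' @return A `period_spectrum` list with elements `points` (data frame
#'   `monomer_len`, `array_len`, `seq_id`, `base_period`) and `bins` (data
#'   frame `base_period`, `n_hits`, `total_bp`).
#' @export
build_spectrum <- function(retained) {
  bp <- if (!is.null(retained$base_period)) retained$base_period
        else retained$period
  alen <- retained$end - retained$start
  points <- data.frame(monomer_len = retained$period, array_len = alen,
                       seq_id = retained$seq_id, base_period = bp,
                       stringsAsFactors = FALSE)
  if (nrow(points)) {
    agg_bp <- tapply(alen, bp, sum)
    agg_n <- tapply(alen, bp, length)
    bins <- data.frame(base_period = as.integer(names(agg_bp)),
                       n_hits = as.integer(agg_n),
                       total_bp = as.numeric(agg_bp))
    bins <- bins[order(bins$base_period), , drop = FALSE]
    rownames(bins) <- NULL
  } else {
    bins <- data.frame(base_period = integer(), n_hits = integer(),
                       total_bp = numeric())
  }
  structure(list(points = points, bins = bins), class = "period_spectrum")
}

#' Rank enriched base monomer lengths
#'
#' Base periods ranked by total array bp, ties broken by hit count then by
#' smaller period.
#'
#' @param spectrum A `period_spectrum` from [build_spectrum()].
#' @param n Number of periods to return (default 5).
#' @param by Ranking weight: `"total_bp"` (default, long arrays are the
#'   discovery signal) or `"n_hits"`.
#' @return Integer vector of `min(n, number of bins)` base periods.
#' @export
top_monomers <- function(spectrum, n = 5L, by = c("total_bp", "n_hits")) {
  stopifnot(n >= 1)
  by <- match.arg(by)
  b <- spectrum$bins
  if (!nrow(b)) return(integer(0))
  ord <- if (by == "total_bp")
    order(-b$total_bp, -b$n_hits, b$base_period)
  else
    order(-b$n_hits, -b$total_bp, b$base_period)
  b$base_period[ord][seq_len(min(n, nrow(b)))]
}

# Cut a hit consensus (possibly an m-fold harmonic of the base period)
# into m tiles of approximately base length.
consensus_tiles <- function(consensus, base_period) {
  len <- nchar(consensus)
  m <- max(1L, as.integer(round(len / base_period)))
  cuts <- round(seq(0L, len, length.out = m + 1L))
  tiles <- substring(consensus, cuts[-length(cuts)] + 1L, cuts[-1L])
  tiles[abs(nchar(tiles) - base_period) <= ceiling(0.1 * base_period) &
          nchar(tiles) > 0L]
}

# Rotate/flip `tile` to best match `ref` (Hamming over the shorter length);
# returns the oriented tile and its percent identity.
orient_to <- function(tile, ref) {
  lt <- nchar(tile)
  L <- min(lt, nchar(ref))
  rcodes <- utf8ToInt(substr(ref, 1L, L))
  best <- -1; bests <- tile
  for (sq in c(tile, reverse_complement(tile))) {
    dbl <- utf8ToInt(paste0(sq, sq))
    for (r in 0:(lt - 1L)) {
      idt <- sum(dbl[(r + 1L):(r + L)] == rcodes) / L
      if (idt > best) {
        best <- idt
        bests <- intToUtf8(dbl[(r + 1L):(r + lt)])
      }
    }
  }
  list(tile = bests, identity = 100 * best)
}

# Per-column majority vote over oriented tiles (columns beyond a shorter
# tile's end are simply not voted on by it).
vote_consensus <- function(tiles, width) {
  tab <- matrix(0L, 4L, width)
  for (t in tiles) {
    codes <- encode_bases(substr(t, 1L, width))
    okk <- which(codes < 4L)
    for (b in 0:3) {
      sel <- okk[codes[okk] == b]
      if (length(sel)) tab[b + 1L, sel] <- tab[b + 1L, sel] + 1L
    }
  }
  cons <- max.col(t(tab), ties.method = "first") - 1L
  decode_bases(cons)
}

#' Build the canonical consensus of a base monomer
#'
#' Each contributing hit's consensus is reduced to base-period length
#' (harmonics are cut into their tiled copies), phase-aligned to the first
#' hit's canonical monomer by the rotation/strand minimizing Hamming
#' distance, and combined by per-column majority vote. Hits whose mean
#' tile identity to the provisional consensus falls below `identity_gate`
#' are excluded (and counted) before the final vote.
#'
#' @param retained Hit data frame with `base_period` column.
#' @param base_period The base period to build (must have >= 1 hit).
#' @param identity_gate Exclusion gate in percent (default 70).
#' @return A `monomer_consensus` list: `canonical`, `base_period`,
#'   `n_hits`, `total_array_bp`, `harmonics_observed`, `mean_identity`,
#'   `n_excluded`.
#' @export
build_consensus <- function(retained, base_period, identity_gate = 70) {
  sel <- retained[retained$base_period == base_period, , drop = FALSE]
  if (!nrow(sel)) stop("no retained hits with base period ", base_period)
  tiles_by_hit <- lapply(sel$consensus, consensus_tiles, base_period)
  nonempty <- which(vapply(tiles_by_hit, length, integer(1)) > 0L)
  if (!length(nonempty)) stop("no usable consensus tiles for base period ",
                              base_period)
  sel <- sel[nonempty, , drop = FALSE]
  tiles_by_hit <- tiles_by_hit[nonempty]
  ref <- canonical_monomer(tiles_by_hit[[1L]][1L])
  oriented <- lapply(tiles_by_hit, function(ts)
    lapply(ts, orient_to, ref = ref))
  all_tiles <- unlist(lapply(oriented, function(o)
    vapply(o, `[[`, character(1), "tile")))
  provisional <- vote_consensus(all_tiles, base_period)
  hit_identity <- vapply(oriented, function(o) {
    mean(vapply(o, function(t) orient_to(t$tile, provisional)$identity,
                numeric(1)))
  }, numeric(1))
  inc <- hit_identity >= identity_gate
  n_excluded <- sum(!inc)
  if (!any(inc)) stop("all hits fall below the identity gate")
  final_tiles <- unlist(lapply(oriented[inc], function(o)
    vapply(o, `[[`, character(1), "tile")))
  vote <- vote_consensus(final_tiles, base_period)
  mean_identity <- mean(vapply(final_tiles, function(t)
    orient_to(t, vote)$identity, numeric(1)))
  structure(list(
    canonical = canonical_monomer(vote),
    base_period = as.integer(base_period),
    n_hits = sum(inc),
    total_array_bp = sum(sel$end[inc] - sel$start[inc]),
    harmonics_observed = sort(unique(sel$period[inc])),
    mean_identity = mean_identity,
    n_excluded = n_excluded), class = "monomer_consensus")
}

#' @export
print.monomer_consensus <- function(x, ...) {
  cat(sprintf(paste0("<monomer_consensus> %d bp, %d hit(s), %d array bp, ",
                     "mean identity %.1f%%\n  %s\n"),
              x$base_period, x$n_hits, x$total_array_bp, x$mean_identity,
              x$canonical))
  invisible(x)
}

#' End-to-end monomer mining
#'
#' Convenience wrapper: scan read records, collapse harmonics, filter,
#' build the spectrum and the consensus of the top-ranked base monomer.
#'
#' @param records List of [seq_record] objects (long reads).
#' @param params [scan_params].
#' @param filters [mining_filters].
#' @param read_mode Apply the read-length floor (default `TRUE`).
#' @return List with `hits`, `retained`, `spectrum`, `consensus` (or
#'   `NULL` consensus when nothing survives the filters).
#' @export
mine_monomer <- function(records, params = scan_params(),
                         filters = mining_filters(), read_mode = TRUE) {
  hits <- scan_sequences(records, params, read_mode = read_mode)
  hits <- collapse_harmonics(hits)
  retained <- filter_hits(hits, filters)
  spectrum <- build_spectrum(retained)
  top <- top_monomers(spectrum, 1L)
  cons <- if (length(top)) build_consensus(retained, top[1L],
                                           filters$min_identity) else NULL
  list(hits = hits, retained = retained, spectrum = spectrum,
       consensus = cons)
}

#' Plot the monomer-length vs array-length spectrum
#'
#' Scatter of detected period against array length, one dot per retained
#' hit, the graphical signature in which an enriched satellite monomer and
#' its harmonics stand out as vertical bands.
#'
#' @param spectrum A `period_spectrum`.
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
plot_spectrum <- function(spectrum, path) {
  grDevices::pdf(path, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  pts <- spectrum$points
  if (nrow(pts)) {
    graphics::plot(pts$monomer_len, pts$array_len,
                   xlab = "monomer length (bp)",
                   ylab = "tandem array length (bp)",
                   pch = 16, cex = 0.5, col = "#00000080")
  } else {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no retained hits")
  }
  invisible(path)
}
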