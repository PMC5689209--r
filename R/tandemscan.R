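# Tandem-repeat detection: k-mer seed proposal, wraparound DP refinement,
# and harmonic collapsing of multiple-of-the-monomer periods.

#' Tandem-repeat scan parameters
#'
#' Defaults follow the TRF-style parameterization used for centromere
#' monomer screening of raw PacBio reads: match weight 2, mismatch penalty
#' 6, indel penalty 6, expected match probability 0.80, expected indel
#' probability 0.10, minimum score 50, maximum period 2000 bp, and an
#' 8000 bp read-length floor when scanning in read mode. The match/indel
#' probabilities size the statistical seed-density test of
#' [propose_periods()]; they are not alignment scores.
#'
#' @param match Score added per aligned match (default 2).
#' @param mismatch Penalty per mismatch (default 6).
#' @param indel Penalty per inserted or deleted base (default 6).
#' @param match_prob Expected per-base match rate inside a true array
#'   (default 0.80).
#' @param indel_prob Expected per-base indel rate; also sets the relative
#'   seed-distance tolerance (default 0.10).
#' @param min_score Minimum reportable alignment score (default 50).
#' @param max_period Maximum reportable period in bp (default 2000).
#' @param min_read_length Reads shorter than this are skipped in read mode
#'   (default 8000 bp).
#' @param k Seed word size (default 12).
#' @param min_period Minimum reportable period (default 10 bp, configurable
#'   down to 2; avoids homopolymer/dinucleotide noise).
#' @param max_n_frac Windows with a higher fraction of `N` are skipped
#'   (default 0.20).
#' @return A `scan_params` list.
#' @export
scan_params <- function(match = 2L, mismatch = 6L, indel = 6L,
                        match_prob = 0.80, indel_prob = 0.10,
                        min_score = 50, max_period = 2000L,
                        min_read_length = 8000L, k = 12L,
                        min_period = 10L, max_n_frac = 0.20) {
  stopifnot(match > 0, mismatch > 0, indel > 0,
            match_prob > 0, match_prob <= 1,
            indel_prob > 0, indel_prob < 1,
            min_score > 0, max_period >= 2, min_read_length >= 0,
            k >= 4, min_period >= 2, max_n_frac >= 0, max_n_frac <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 indel = as.integer(indel), match_prob = match_prob,
                 indel_prob = indel_prob, min_score = min_score,
                 max_period = as.integer(max_period),
                 min_read_length = as.integer(min_read_length),
                 k = as.integer(k), min_period = as.integer(min_period),
                 max_n_frac = max_n_frac),
            class = "scan_params")
}

encode_bases <- function(s) {
  code <- chartr("ACGTN", "01234", s)
  as.integer(utf8ToInt(code)) - utf8ToInt("0")
}

decode_bases <- function(codes) {
  chartr("01234", "ACGTN", intToUtf8(codes + utf8ToInt("0")))
}

empty_candidates <- function() {
  data.frame(period = integer(), start = integer(), end = integer(),
             support = integer())
}

#' Propose candidate tandem periods from recurring k-mer distances
#'
#' Records the distance between consecutive occurrences of every exact
#' k-mer. A distance `d` becomes a candidate period when at least
#' `max(3, ceiling(match_prob * w/d))` seed pairs with distance within
#' `ceiling(indel_prob * d)` of `d` fall inside some window
#' `w = min(10*d, sequence length)` — the density expected from the
#' match/indel probabilities for a genuine array. Supporting seed pairs are
#' clustered along the sequence so that separate arrays on one scaffold
#' yield separate anchors. Distances above `max_period` or below
#' `min_period` are dropped.
#'
#' @param record A [seq_record] or nucleotide string.
#' @param params A [scan_params] object.
#' @return Data frame with columns `period`, `start`, `end` (0-based
#'   half-open anchor) and `support`, sorted by decreasing support; empty
#'   when nothing recurs.
#' @export
propose_periods <- function(record, params = scan_params()) {
  s <- record_bases(record)
  n <- nchar(s)
  k <- params$k
  if (n < 2L * k) return(empty_candidates())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  starts <- starts[ok]; kmers <- kmers[ok]
  if (length(starts) < 2L) return(empty_candidates())
  o <- order(kmers, starts)
  km <- kmers[o]; st <- starts[o]
  same <- km[-1L] == km[-length(km)]
  d <- (st[-1L] - st[-length(st)])[same]
  pos <- st[-length(st)][same]
  dmin <- max(2L, params$min_period)
  keep <- d >= dmin & d <= params$max_period
  d <- d[keep]; pos <- pos[keep]
  if (!length(d)) return(empty_candidates())

  cands <- list()
  accepted <- integer()
  tabd <- sort(table(d), decreasing = TRUE)
  for (dv in as.integer(names(tabd))) {
    if (length(accepted) &&
        any(abs(dv - accepted) <= ceiling(0.1 * pmax(dv, accepted)))) next
    tol <- ceiling(params$indel_prob * dv)
    sel <- abs(d - dv) <= tol
    if (sum(sel) < 3L) next
    idx <- order(pos[sel])
    pp <- pos[sel][idx]; dd <- d[sel][idx]
    grp <- cumsum(c(1L, diff(pp) > max(5L * dv, 250L)))
    made <- FALSE
    for (gi in unique(grp)) {
      gsel <- grp == gi
      ppg <- pp[gsel]; ddg <- dd[gsel]
      if (length(ppg) < 3L) next
      w <- min(10L * dv, n)
      thr <- max(3L, ceiling(params$match_prob * (w / dv)))
      # max number of seed pairs inside any window of length w (two-pointer)
      upper <- findInterval(ppg + w, ppg)
      mx <- max(upper - seq_along(ppg) + 1L)
      if (mx < thr) next
      per <- as.integer(round(median(ddg)))
      cands[[length(cands) + 1L]] <- data.frame(
        period = per,
        start = ppg[1L] - 1L,
        end = min(n, max(ppg) + dv + params$k - 1L),
        support = mx)
      made <- TRUE
    }
    if (made) accepted <- c(accepted, dv)
  }
  if (!length(cands)) return(empty_candidates())
  out <- do.call(rbind, cands)
  out <- out[order(-out$support, out$period), , drop = FALSE]
  if (nrow(out) > 30L) out <- out[seq_len(30L), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One re-estimation of the consensus from an alignment: per-column majority
# re-vote, removal of deletion-dominated columns, and insertion of bases
# present in more than half of the copies. The length change is clamped to
# +/-10% of the starting period.
rebuild_consensus <- function(w, cons, dp, period0) {
  p <- length(cons)
  al <- dp$path_col >= 0L
  cols <- dp$path_col[al] + 1L
  bs <- w[al]
  tab <- matrix(0L, 4L, p)
  for (b in 0:3) tab[b + 1L, ] <- tabulate(cols[bs == b], nbins = p)
  occ <- colSums(tab)
  newbase <- max.col(t(tab), ties.method = "first") - 1L
  newbase[occ == 0L] <- cons[occ == 0L]
  drop <- dp$del_count > occ
  copies <- (dp$n_match + dp$n_mismatch + dp$n_del) / p
  ins_at <- integer(0); ins_base <- integer(0)
  insel <- dp$path_col == -1L
  if (any(insel) && copies >= 2) {
    icols <- dp$ins_after[insel] + 1L
    ibs <- w[insel]
    cnt <- tabulate(icols, nbins = p)
    for (j in which(cnt > copies / 2)) {
      bj <- ibs[icols == j & ibs < 4L]
      if (!length(bj)) next
      ins_at <- c(ins_at, j)
      ins_base <- c(ins_base, as.integer(names(which.max(table(bj)))))
    }
  }
  out <- integer(0)
  for (j in seq_len(p)) {
    if (!drop[j]) out <- c(out, newbase[j])
    hit <- match(j, ins_at)
    if (!is.na(hit)) out <- c(out, ins_base[hit])
  }
  if (!length(out)) return(cons)
  if (abs(length(out) - period0) > ceiling(0.1 * period0)) return(cons)
  out
}

#' Wraparound alignment of a window against a cyclic consensus
#'
#' Aligns the window against an infinitely repeated consensus of length
#' close to `period` by wraparound dynamic programming: `+match` per
#' match, `-mismatch` per mismatch (N always mismatches), `-indel` per
#' inserted or deleted base, local within the window with a free start/end
#' phase. Unless `consensus` is supplied, the starting pattern is one
#' observed copy taken from the window center (robust to the phase drift
#' that indels cause), and the consensus is then re-estimated from the
#' alignment by per-column majority vote — deletion-dominated columns
#' dropped, majority insertions added, total length change clamped to 10%
#' of `period` — for up to two rounds, keeping the best-scoring round.
#'
#' @param window Nucleotide string.
#' @param period Starting period, `1 <= period <= nchar(window)`.
#' @param params A [scan_params] object (scoring weights).
#' @param consensus Optional explicit consensus string; when given, phasing
#'   and re-estimation are skipped and the window is aligned against it
#'   as-is.
#' @return List with `score`, `consensus`, `period` (refined consensus
#'   length), `copy_number` (consensus columns consumed / period),
#'   `percent_identity` (matches / aligned columns, 0-100), and `interval`
#'   (0-based half-open aligned span within the window).
#' @export
wraparound_align <- function(window, period, params = scan_params(),
                             consensus = NULL) {
  n <- nchar(window)
  if (is.null(consensus) && (period < 1L || period > n))
    stop("period must be between 1 and the window length")
  w <- encode_bases(window)
  if (is.null(consensus)) {
    period <- as.integer(period)
    start0 <- max(0L, as.integer(floor((n - period) / 2)))
    cons <- w[(start0 + 1L):(start0 + period)]
    r <- wrap_dp(w, cons, params$match, params$mismatch, params$indel)
    for (iter in 1:2) {
      cons2 <- rebuild_consensus(w, cons, r, period)
      if (identical(cons2, cons)) break
      r2 <- wrap_dp(w, cons2, params$match, params$mismatch, params$indel)
      if (r2$score >= r$score) { r <- r2; cons <- cons2 } else break
    }
  } else {
    cons <- encode_bases(consensus)
    r <- wrap_dp(w, cons, params$match, params$mismatch, params$indel)
  }
  p <- length(cons)
  consumed <- r$n_match + r$n_mismatch + r$n_del
  aligned <- r$n_match + r$n_mismatch + r$n_ins + r$n_del
  list(score = r$score,
       consensus = decode_bases(cons),
       period = p,
       copy_number = consumed / p,
       percent_identity = if (aligned > 0L) 100 * r$n_match / aligned else 0,
       interval = c(r$i_start - 1L, r$i_end))
}

empty_hits <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             period = integer(), copy_number = numeric(),
             percent_identity = numeric(), score = numeric(),
             consensus = character(), canonical = character(),
             stringsAsFactors = FALSE)
}

#' Scan one sequence for tandem repeats
#'
#' Runs [propose_periods()], refines each candidate with
#' [wraparound_align()] on the anchor window padded by one period on each
#' side, discards hits below `min_score` or outside the period bounds,
#' merges hits overlapping at least 50% reciprocally (keeping the higher
#' score, ties broken by smaller period), and sorts by `(start, period)`.
#' Windows with more than `max_n_frac` of `N` are skipped. In read mode,
#' records shorter than `min_read_length` are skipped entirely.
#'
#' @param record A [seq_record] or nucleotide string.
#' @param params A [scan_params] object.
#' @param read_mode Apply the read-length floor (default `FALSE`).
#' @return Data frame of hits with columns `seq_id`, `start`, `end`
#'   (0-based half-open), `period`, `copy_number`, `percent_identity`,
#'   `score`, `consensus`, `canonical`.
#' @export
scan_sequence <- function(record, params = scan_params(),
                          read_mode = FALSE) {
  s <- record_bases(record)
  id <- if (inherits(record, "seq_record")) record$id else "seq"
  n <- nchar(s)
  if (read_mode && n < params$min_read_length) return(empty_hits())
  cands <- propose_periods(s, params)
  if (!nrow(cands)) return(empty_hits())
  rows <- list()
  for (ci in seq_len(nrow(cands))) {
    d <- cands$period[ci]
    # a genuine tandem must be seed-supported across at least two copies
    if (cands$end[ci] - cands$start[ci] < 2L * d) next
    # harmonics of an already-accepted hit over the same span would lose
    # the overlap merge anyway; skip their refinement
    harmonic_dup <- FALSE
    for (r in rows) {
      m <- round(d / r$period)
      if (m < 1) next
      if (abs(d - m * r$period) > 0.1 * d) next
      ov <- min(cands$end[ci], r$end) - max(cands$start[ci], r$start)
      if (ov >= 0.5 * (cands$end[ci] - cands$start[ci])) {
        harmonic_dup <- TRUE; break
      }
    }
    if (harmonic_dup) next
    a <- max(0L, cands$start[ci] - d)
    b <- min(n, cands$end[ci] + d)
    win <- substr(s, a + 1L, b)
    if (d > nchar(win)) next
    n_frac <- nchar(gsub("[^N]", "", win)) / nchar(win)
    if (n_frac > params$max_n_frac) next
    al <- wraparound_align(win, d, params)
    if (al$score < params$min_score) next
    if (al$period < params$min_period || al$period > params$max_period) next
    len <- al$interval[2L] - al$interval[1L]
    if (len < al$period || al$copy_number < 1) next
    canon <- if (grepl("N", al$consensus, fixed = TRUE)) NA_character_
             else canonical_monomer(al$consensus)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = id, start = a + al$interval[1L], end = a + al$interval[2L],
      period = al$period, copy_number = al$copy_number,
      percent_identity = al$percent_identity, score = al$score,
      consensus = al$consensus, canonical = canon,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- merge_reciprocal(hits)
  hits <- hits[order(hits$start, hits$period), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Greedy dominance merge: process by decreasing score (ties: smaller
# period), drop any hit overlapping an already-kept hit by >= 50% of both
# lengths.
merge_reciprocal <- function(hits, frac = 0.5) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$score, hits$period)
  keep <- logical(nrow(hits))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (hits$seq_id[j] != hits$seq_id[i]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov <= 0) next
      li <- hits$end[i] - hits$start[i]
      lj <- hits$end[j] - hits$start[j]
      if (ov >= frac * li && ov >= frac * lj) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

#' Scan many sequences for tandem repeats
#'
#' @param records List of [seq_record] objects.
#' @inheritParams scan_sequence
#' @return Row-bound hits from [scan_sequence()] over all records.
#' @export
scan_sequences <- function(records, params = scan_params(),
                           read_mode = FALSE) {
  out <- lapply(records, scan_sequence, params = params,
                read_mode = read_mode)
  res <- do.call(rbind, c(list(empty_hits()), out))
  rownames(res) <- NULL
  res
}

# Best rotation/strand identity of `seq` against `monomer` tiled to the
# length of `seq` (harmonic periods compare against m tiled copies).
rotational_identity <- function(seq, monomer, both_strands = TRUE) {
  la <- nchar(seq); lb <- nchar(monomer)
  if (la == 0L || lb == 0L) return(list(identity = 0, strand = "+"))
  tile <- substr(strrep(monomer, ceiling(la / lb)), 1L, la)
  tcodes <- utf8ToInt(tile)
  best <- -1; strand <- "+"
  for (str in if (both_strands) c("+", "-") else "+") {
    sq <- if (str == "+") seq else reverse_complement(seq)
    dbl <- utf8ToInt(paste0(sq, sq))
    for (r in 0:(la - 1L)) {
      idt <- sum(dbl[(r + 1L):(r + la)] == tcodes) / la
      if (idt > best) { best <- idt; strand <- str }
    }
  }
  list(identity = 100 * best, strand = strand)
}

#' Collapse harmonic periods to their base monomer
#'
#' Two complementary routes assign each hit a base period. (1) Supported
#' periods: a hit whose period is close to an integer multiple `m >= 2` of
#' a smaller period present in the hit set
#' (`|period - m*p| <= rel_tol * period`) is assigned base period `p`,
#' provided the representative consensus of `p` (highest-scoring hit of
#' that period) matches the hit's consensus at `>= min_identity` percent
#' when tiled, under the best rotation and strand. (2) Internal
#' periodicity: when no supported period collapses the hit, the hit's own
#' consensus is scanned for a shorter tandem structure
#' ([propose_periods()] on the consensus, refined by
#' [wraparound_align()]); if a sub-period covers the consensus at
#' `>= min_identity` with at least two copies and divides the period
#' within `rel_tol`, the refined sub-period becomes the base. Route (2)
#' catches the long harmonic consensi that win the overlap merge on
#' diverged arrays by memorizing several copies at once. Other hits keep
#' their own period.
#'
#' Alongside `base_period`, the column `base_copies` records the array
#' length in base-monomer units.
#'
#' @param hits Hit data frame from [scan_sequence()].
#' @param rel_tol Relative tolerance on the multiple (default 0.05).
#' @param min_identity Tiling identity gate in percent (default 70).
#' @param params [scan_params] used for the internal-periodicity scan.
#' @return `hits` with added columns `base_period` and `base_copies`.
#' @export
collapse_harmonics <- function(hits, rel_tol = 0.05, min_identity = 70,
                               params = scan_params()) {
  hits$base_period <- hits$period
  if (!nrow(hits)) { hits$base_copies <- numeric(0); return(hits) }
  periods <- sort(unique(hits$period))
  reps <- vapply(periods, function(p) {
    sub <- hits[hits$period == p, , drop = FALSE]
    sub$consensus[which.max(sub$score)]
  }, character(1))
  names(reps) <- as.character(periods)
  for (i in seq_len(nrow(hits))) {
    P <- hits$period[i]
    for (p in periods[periods < P]) {
      m <- round(P / p)
      if (m < 2) next
      if (abs(P - m * p) > rel_tol * P) next
      idt <- rotational_identity(hits$consensus[i],
                                 reps[[as.character(p)]])$identity
      if (idt >= min_identity) { hits$base_period[i] <- p; break }
    }
    if (hits$base_period[i] < P) next
    # internal periodicity of the hit's own consensus
    cons <- hits$consensus[i]
    if (is.na(cons) || P < 2L * params$min_period ||
        nchar(cons) < 2L * params$k) next
    ip <- params
    ip$max_period <- as.integer(floor(P / 2))
    cands <- propose_periods(cons, ip)
    for (pc in sort(unique(cands$period))) {
      if (pc > P / 1.8) next
      al <- wraparound_align(cons, pc, params)
      cov <- (al$interval[2L] - al$interval[1L]) / nchar(cons)
      m <- round(P / al$period)
      if (al$percent_identity >= min_identity && al$copy_number >= 1.8 &&
          cov >= 0.6 && m >= 2 && abs(P - m * al$period) <= rel_tol * P) {
        hits$base_period[i] <- al$period
        break
      }
    }
  }
  hits$base_copies <- (hits$end - hits$start) / hits$base_period
  hits
}

#' Write tandem-repeat hits as TSV
#'
#' @param hits Hit data frame (optionally with `base_period`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tandem-repeat hit TSV
#'
#' @param path Path to a TSV written by [write_hits_tsv()].
#' @return Hit data frame.
#' @export
read_hits_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = NA)
}
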