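# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (fixpoint relaxation, explicit
# enumeration, set-membership scans) sharing no code with the package.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force local wraparound alignment score: per-row fixpoint relaxation
# of the cyclic recurrence (Bellman-Ford style), no two-pass trick.
oracle_wrap_score <- function(window, consensus, match = 2, mismatch = 6,
                              indel = 6) {
  w <- utf8ToInt(window); cs <- utf8ToInt(consensus)
  n <- length(w); p <- length(cs)
  Ncode <- utf8ToInt("N")
  prev <- rep(0, p)
  best <- 0
  for (i in seq_len(n)) {
    cur <- rep(-Inf, p)
    repeat {
      changed <- FALSE
      for (j in seq_len(p)) {
        jm <- if (j == 1L) p else j - 1L
        sc <- if (w[i] == cs[j] && w[i] != Ncode) match else -mismatch
        v <- max(prev[jm] + sc, prev[j] - indel, cur[jm] - indel, 0)
        if (v > cur[j] + 1e-9) { cur[j] <- v; changed <- TRUE }
      }
      if (!changed) break
    }
    prev <- cur
    best <- max(best, max(cur))
  }
  best
}

# Canonical monomer by explicit enumeration of every rotation of the
# string and of its reverse complement.
oracle_canonical <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(s, "")[[1L]]
  rc <- paste(rev(unname(comp[chars])), collapse = "")
  variants <- character(0)
  for (x in c(s, rc)) {
    cx <- strsplit(x, "")[[1L]]
    for (r in seq_along(cx))
      variants <- c(variants,
                    paste(c(cx[r:length(cx)], cx[seq_len(r - 1L)]),
                          collapse = ""))
  }
  min(variants)
}

# N50 by accumulating the longest sequences until half the total is covered.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= sum(lengths) / 2) return(x)
  }
  NA_real_
}

# Contig intervals by a linear character scan.
oracle_split_contigs <- function(bases, min_n_run = 25L) {
  chars <- strsplit(bases, "")[[1L]]
  out <- data.frame(start = integer(), end = integer())
  i <- 1L; L <- length(chars); cstart <- NA_integer_
  while (i <= L + 1L) {
    if (i <= L && chars[i] != "N") {
      if (is.na(cstart)) cstart <- i
      i <- i + 1L
      next
    }
    # at an N or past the end: measure the N run
    j <- i
    while (j <= L && chars[j] == "N") j <- j + 1L
    run <- j - i
    if (i > L || run >= min_n_run) {
      if (!is.na(cstart))
        out <- rbind(out, data.frame(start = cstart - 1L, end = i - 1L))
      cstart <- NA_integer_
    } else if (is.na(cstart) && run > 0L) {
      cstart <- i  # leading short N run starts a contig
    }
    i <- max(j, i + 1L)
  }
  out
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# 0-based motif match starts by direct set membership at every offset.
oracle_motif_starts <- function(bases, motif) {
  chars <- strsplit(bases, "")[[1L]]
  mot <- strsplit(motif, "")[[1L]]
  L <- length(chars); ml <- length(mot)
  if (L < ml) return(integer(0))
  ok <- rep(TRUE, L - ml + 1L)
  for (i in seq_len(ml))
    ok <- ok & chars[seq_len(L - ml + 1L) + i - 1L] %in% IUPAC_SETS[[mot[i]]]
  which(ok) - 1L
}

oracle_iupac_rc <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(unname(comp[strsplit(motif, "")[[1L]]])), collapse = "")
}

# Circular nick sites of one enzyme on a unit, by scanning the doubled
# sequence and reducing modulo the unit length.
oracle_circular_sites <- function(unit, motif, offset) {
  L <- nchar(unit)
  dbl <- paste0(unit, unit)
  ml <- nchar(motif)
  f <- oracle_motif_starts(dbl, motif)
  r <- oracle_motif_starts(dbl, oracle_iupac_rc(motif))
  sites <- sort(unique(c((f[f < L] + offset) %% L,
                         (r[r < L] + ml - offset) %% L)))
  sites <- sites[sites >= 0 & sites < L]
  if (length(sites) > 1L) {
    sites <- sites[c(TRUE, diff(sites) > 1)]
    if (length(sites) > 1L && sites[1L] + L - sites[length(sites)] <= 1)
      sites <- sites[-length(sites)]
  }
  sites
}

# Enzyme ranking reproduced from the stated rules.
oracle_rank_enzymes <- function(unit, enzymes, min_spacing = 1500) {
  L <- nchar(unit)
  rows <- list()
  for (e in enzymes) {
    sites <- oracle_circular_sites(unit, e$motif, e$nick_offset)
    k <- length(sites)
    if (k == 0L) next
    spac <- if (k == 1L) L else diff(c(sites, sites[1L] + L))
    if (k >= 2L && any(spac < min_spacing)) next
    rows[[length(rows) + 1L]] <-
      data.frame(enzyme = e$name, k = k, cat = if (k == 1L) 1L else 2L)
  }
  if (!length(rows)) return(character(0))
  df <- do.call(rbind, rows)
  df$enzyme[order(df$cat, df$k, df$enzyme)]
}

# Best rotation/strand percent identity of `a` against `b` tiled to the
# length of `a`, by explicit enumeration.
rotational_identity_pct <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  la <- nchar(a)
  tile <- substr(strrep(b, ceiling(la / nchar(b))), 1L, la)
  tchars <- strsplit(tile, "")[[1L]]
  best <- 0
  for (s in 1:2) {
    x <- if (s == 1L) a
         else paste(rev(unname(comp[strsplit(a, "")[[1L]]])), collapse = "")
    xc <- strsplit(x, "")[[1L]]
    for (r in seq_len(la)) {
      rot <- c(xc[r:la], xc[seq_len(r - 1L)])
      best <- max(best, sum(rot == tchars) / la)
    }
  }
  100 * best
}

# Exhaustive k-mer consecutive-occurrence distances (for propose tests).
oracle_kmer_distances <- function(s, k = 12L) {
  n <- nchar(s)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  res <- list()
  for (km in unique(kmers[duplicated(kmers)])) {
    pos <- starts[kmers == km]
    res[[km]] <- diff(pos)
  }
  res
}
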