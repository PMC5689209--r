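# Deterministic seeded simulators: satellite reads, higher-order-repeat
# arrays, noisy label molecules and toy assemblies. Every generator is a
# pure function of its parameters and seed; the caller's RNG state is
# saved and restored.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply i.i.d. substitutions and indels to one monomer copy.
mutate_copy <- function(monomer, substitution_rate, indel_rate) {
  chars <- strsplit(monomer, "")[[1L]]
  out <- character(0)
  n_sub <- 0L; n_ins <- 0L; n_del <- 0L
  for (ch in chars) {
    u <- runif(1)
    if (u < indel_rate / 2) { n_del <- n_del + 1L; next }
    if (u < indel_rate) {
      out <- c(out, sample(c("A", "C", "G", "T"), 1L))
      n_ins <- n_ins + 1L
    }
    if (runif(1) < substitution_rate) {
      out <- c(out, sample(setdiff(c("A", "C", "G", "T"), ch), 1L))
      n_sub <- n_sub + 1L
    } else out <- c(out, ch)
  }
  list(seq = paste(out, collapse = ""), n_sub = n_sub, n_ins = n_ins,
       n_del = n_del)
}

#' Simulate a long read containing a satellite array
#'
#' Emulates a PacBio-style read holding a tandem array of a mutated
#' monomer between random flanks: `flank + copies x monomer (with i.i.d.
#' substitutions and indels) + flank`. Indels shift downstream
#' coordinates; the truth interval is recorded post-edit. Identical
#' parameters and seed give byte-identical output.
#'
#' @param monomer Monomer string.
#' @param copies Number of tandem copies (>= 1).
#' @param substitution_rate Per-base substitution probability in
#'   `[0, 0.5)` (default 0).
#' @param indel_rate Per-base indel probability in `[0, 0.5)`, split
#'   evenly between insertion and deletion (default 0).
#' @param flank_len Random flank length on each side in bp (default 2500).
#' @param seed Integer seed.
#' @param id Read id (default `"simread"`).
#' @return List with `record` ([seq_record]) and `truth` (list:
#'   `interval` 0-based half-open array span, `period`, `copies`,
#'   `n_sub`, `n_ins`, `n_del`).
#' @export
make_satellite_read <- function(monomer, copies, substitution_rate = 0,
                                indel_rate = 0, flank_len = 2500L,
                                seed = 1L, id = "simread") {
  stopifnot(copies >= 1, substitution_rate >= 0, substitution_rate < 0.5,
            indel_rate >= 0, indel_rate < 0.5, flank_len >= 0)
  with_seed(seed, {
    left <- random_dna(flank_len)
    right <- random_dna(flank_len)
    n_sub <- 0L; n_ins <- 0L; n_del <- 0L
    arr <- character(copies)
    for (i in seq_len(copies)) {
      mc <- mutate_copy(monomer, substitution_rate, indel_rate)
      arr[i] <- mc$seq
      n_sub <- n_sub + mc$n_sub; n_ins <- n_ins + mc$n_ins
      n_del <- n_del + mc$n_del
    }
    array_seq <- paste(arr, collapse = "")
    rec <- seq_record(id, paste0(left, array_seq, right), quiet = TRUE)
    truth <- list(interval = c(flank_len, flank_len + nchar(array_seq)),
                  period = nchar(monomer), copies = copies,
                  n_sub = n_sub, n_ins = n_ins, n_del = n_del)
    list(record = rec, truth = truth)
  })
}

#' Simulate a higher-order-repeat array
#'
#' Creates `monomers_per_hor` diverged variants of the monomer
#' (substitutions only), concatenates them into one higher-order unit,
#' optionally overwrites a fixed in-unit position with an enzyme site
#' motif (so each unit carries exactly one site), and tandemly repeats the
#' unit `n_hors` times.
#'
#' @param monomer Monomer string.
#' @param monomers_per_hor Monomer variants per unit (>= 1).
#' @param n_hors Number of unit copies.
#' @param variant_divergence Per-base substitution rate applied once per
#'   variant (default 0).
#' @param site_motif Optional motif overwritten at the start of every unit.
#' @param seed Integer seed.
#' @param id Record id (default `"simhor"`).
#' @return List with `record` ([seq_record]) and `truth` (list:
#'   `unit_len`, `n_hors`, `monomers_per_hor`, `site_offset` or `NA`).
#' @export
make_hor_array <- function(monomer, monomers_per_hor, n_hors,
                           variant_divergence = 0, site_motif = NULL,
                           seed = 1L, id = "simhor") {
  stopifnot(monomers_per_hor >= 1, n_hors >= 1,
            variant_divergence >= 0, variant_divergence < 0.5)
  with_seed(seed, {
    variants <- vapply(seq_len(monomers_per_hor), function(i)
      mutate_copy(monomer, variant_divergence, 0)$seq, character(1))
    unit <- paste(variants, collapse = "")
    site_offset <- NA_integer_
    if (!is.null(site_motif)) {
      if (nchar(site_motif) > nchar(unit))
        stop("site motif is longer than the higher-order unit")
      unit <- paste0(site_motif,
                     substr(unit, nchar(site_motif) + 1L, nchar(unit)))
      site_offset <- 0L
    }
    rec <- seq_record(id, strrep(unit, n_hors), quiet = TRUE)
    list(record = rec,
         truth = list(unit_len = nchar(unit), n_hors = n_hors,
                      monomers_per_hor = monomers_per_hor,
                      site_offset = site_offset))
  })
}

#' Simulate a noisy optical-map molecule
#'
#' Emulates Irys-type molecule noise: each true label is observed with
#' probability `1 - miss_rate`; multiplicative Gaussian sizing error
#' (mean 1, sd `sizing_sd_frac`) is applied to the inter-label spacings of
#' the retained labels (stretch error acts on spacings, not absolute
#' positions); false labels arrive as a Poisson process at
#' `false_per_100kb` per 100 kb. Output positions are sorted and
#' deduplicated.
#'
#' @param true_labels Numeric vector of true label positions in
#'   `[0, molecule_len)`.
#' @param molecule_len Molecule length in bp.
#' @param sizing_sd_frac Spacing sizing-error sd as a fraction
#'   (default 0.02).
#' @param miss_rate Label miss probability (default 0.10).
#' @param false_per_100kb False-label rate per 100 kb (default 0.5).
#' @param seed Integer seed.
#' @param id Molecule id (default `"simmol"`).
#' @return List with `molecule` ([label_molecule]) and `truth` (data frame
#'   mapping each observed label to its true position, `NA` for false
#'   labels).
#' @export
make_molecule <- function(true_labels, molecule_len, sizing_sd_frac = 0.02,
                          miss_rate = 0.10, false_per_100kb = 0.5,
                          seed = 1L, id = "simmol") {
  stopifnot(miss_rate >= 0, miss_rate <= 1, sizing_sd_frac >= 0,
            false_per_100kb >= 0)
  true_labels <- sort(as.numeric(true_labels))
  if (length(true_labels) &&
      (true_labels[1L] < 0 || true_labels[length(true_labels)] >= molecule_len))
    stop("true labels must lie in [0, molecule_len)")
  with_seed(seed, {
    kept_idx <- which(runif(length(true_labels)) >= miss_rate)
    kept <- true_labels[kept_idx]
    if (length(kept)) {
      spac <- diff(c(0, kept))
      spac <- spac * rnorm(length(spac), mean = 1, sd = sizing_sd_frac)
      obs <- cumsum(pmax(spac, 0))
    } else obs <- numeric(0)
    n_false <- rpois(1L, false_per_100kb * molecule_len / 1e5)
    false_pos <- if (n_false > 0L) runif(n_false, 0, molecule_len)
                 else numeric(0)
    all_pos <- c(obs, false_pos)
    src <- c(kept, rep(NA_real_, n_false))
    o <- order(all_pos)
    all_pos <- all_pos[o]; src <- src[o]
    ok <- all_pos >= 0 & all_pos < molecule_len
    all_pos <- all_pos[ok]; src <- src[ok]
    if (length(all_pos) > 1L) {
      dup <- c(FALSE, diff(all_pos) <= 1)
      all_pos <- all_pos[!dup]; src <- src[!dup]
    }
    list(molecule = label_molecule(id, molecule_len, all_pos),
         truth = data.frame(observed = all_pos, true = src))
  })
}

#' Simulate a toy assembly with planted satellite arrays and N gaps
#'
#' Builds one scaffold per requested array: random background, the planted
#' tandem array (exact copies, optionally diverged), an optional N-run gap
#' beside it, and more background — the scaffold-with-gap geometry in
#' which satellite arrays typically surface in draft assemblies. Truth
#' coordinates are returned as a BED-style data frame.
#'
#' @param arrays List of lists with elements `monomer` and `length`
#'   (target array bp; rounded down to whole copies) and optionally
#'   `divergence` (per-base substitution rate, default 0).
#' @param gap_runs Integer vector of N-run lengths, recycled across
#'   scaffolds; 0 plants no gap.
#' @param background_len Background bp on each side of the array
#'   (default 5000).
#' @param seed Integer seed.
#' @return List with `records` (list of [seq_record]) and `truth_bed`
#'   (data frame `seq_id`, `start`, `end`, `name`, `score`, `strand`).
#' @export
make_toy_assembly <- function(arrays, gap_runs = 0L,
                              background_len = 5000L, seed = 1L) {
  with_seed(seed, {
    records <- list()
    bed <- list()
    if (length(arrays)) gap_runs <- rep_len(gap_runs, length(arrays))
    for (i in seq_along(arrays)) {
      a <- arrays[[i]]
      stopifnot(a$length > 0)
      div <- if (is.null(a$divergence)) 0 else a$divergence
      copies <- max(1L, floor(a$length / nchar(a$monomer)))
      arr <- vapply(seq_len(copies), function(j)
        mutate_copy(a$monomer, div, 0)$seq, character(1))
      arr <- paste(arr, collapse = "")
      left <- random_dna(background_len)
      gap <- strrep("N", gap_runs[i])
      right <- random_dna(background_len)
      id <- sprintf("scaffold_%d", i)
      records[[i]] <- seq_record(id, paste0(left, arr, gap, right),
                                 quiet = TRUE)
      bed[[i]] <- data.frame(
        seq_id = id, start = background_len,
        end = background_len + nchar(arr),
        name = sprintf("planted_%dbp", nchar(a$monomer)),
        score = 0L, strand = "+", stringsAsFactors = FALSE)
    }
    truth <- if (length(bed)) do.call(rbind, bed)
             else data.frame(seq_id = character(), start = integer(),
                             end = integer(), name = character(),
                             score = integer(), strand = character(),
                             stringsAsFactors = FALSE)
    list(records = records, truth_bed = truth)
  })
}
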