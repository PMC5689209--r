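# Helper to fabricate hit rows with controlled fields.
fake_hit <- function(period, copies, identity, consensus = NULL,
                     seq_id = "r", start = 0L, base_period = NULL) {
  if (is.null(consensus)) consensus <- random_seq(period)
  data.frame(seq_id = seq_id, start = start,
             end = start + as.integer(round(period * copies)),
             period = as.integer(period), copy_number = copies,
             percent_identity = identity, score = 100,
             consensus = consensus, canonical = NA_character_,
             base_period = if (is.null(base_period)) as.integer(period)
                           else as.integer(base_period),
             base_copies = if (is.null(base_period)) copies
                           else period * copies / base_period,
             stringsAsFactors = FALSE)
}

test_that("filter_hits applies the mining thresholds exactly", {
  # boundary cases around each threshold
  hits <- rbind(fake_hit(53, 80, 92),    # retained (Mm53-class)
                fake_hit(9, 10, 99),     # monomer below 10 bp
                fake_hit(10, 4, 70),     # exactly at every boundary
                fake_hit(30, 3.9, 95),   # too few copies
                fake_hit(30, 4, 69.9))   # identity below gate
  out <- filter_hits(hits)
  expect_equal(out$period, c(53L, 10L))
  # idempotent and a subset of the input
  expect_equal(filter_hits(out), out)
  expect_true(all(out$period %in% hits$period))

  # random tables agree with a direct predicate evaluation
  set.seed(19)
  for (rep in 1:5) {
    tab <- do.call(rbind, lapply(1:30, function(i)
      fake_hit(sample(5:60, 1), runif(1, 1, 8), runif(1, 50, 100))))
    f <- mining_filters()
    expected <- tab[tab$base_period >= f$min_monomer_len &
                      tab$base_copies >= f$min_copies &
                      tab$percent_identity >= f$min_identity, ]
    rownames(expected) <- NULL
    expect_equal(filter_hits(tab, f), expected)
  }
})

test_that("the spectrum bins array bp by base period and conserves weight", {
  hits <- rbind(fake_hit(53, 20, 95),                     # 1060 bp
                fake_hit(106, 20, 95, base_period = 53),  # 2120 bp
                fake_hit(53, 10, 95))                     # 530 bp
  spec <- build_spectrum(hits)
  expect_equal(spec$bins$base_period, 53L)
  expect_equal(spec$bins$total_bp, 3710)
  expect_equal(spec$bins$n_hits, 3L)
  # points keep the detected (harmonic) period
  expect_equal(sort(spec$points$monomer_len), c(53L, 53L, 106L))
  # weight conservation over a random retained set
  set.seed(23)
  tab <- do.call(rbind, lapply(1:40, function(i)
    fake_hit(sample(10:80, 1), runif(1, 4, 10), 90)))
  spec2 <- build_spectrum(tab)
  expect_equal(sum(spec2$bins$total_bp), sum(tab$end - tab$start))
  expect_equal(sum(spec2$bins$n_hits), nrow(tab))
  # empty input -> empty spectrum
  empty <- build_spectrum(tab[0, ])
  expect_equal(nrow(empty$bins), 0L)
  expect_equal(nrow(empty$points), 0L)
})

test_that("top_monomers ranks by array bp with hit-count then period tie-breaks", {
  hits <- rbind(fake_hit(53, 70, 95),   # 3710 bp
                fake_hit(180, 5, 95))   # 900 bp
  expect_equal(top_monomers(build_spectrum(hits)), c(53L, 180L))
  expect_equal(top_monomers(build_spectrum(hits), 1), 53L)
  # single bin
  expect_equal(top_monomers(build_spectrum(fake_hit(37, 5, 95))), 37L)
  # equal weight: 2 hits of 500 bp at period 30 vs 1 hit of 1000 bp at 40
  tie <- rbind(fake_hit(30, 500 / 30, 95), fake_hit(30, 500 / 30, 95),
               fake_hit(40, 25, 95))
  spec <- build_spectrum(tie)
  expect_equal(spec$bins$total_bp, c(1000, 1000))
  expect_equal(top_monomers(spec), c(30L, 40L))
})

test_that("build_consensus recovers the planted monomer by majority vote", {
  # noise-free Mm53 hits across harmonics
  hits <- rbind(fake_hit(53, 20, 100, consensus = mm53()),
                fake_hit(106, 10, 100, consensus = strrep(mm53(), 2),
                         base_period = 53))
  mc <- build_consensus(hits, 53L)
  expect_s3_class(mc, "monomer_consensus")
  expect_equal(mc$canonical, canonical_monomer(mm53()))
  expect_equal(mc$mean_identity, 100)
  expect_equal(mc$n_hits, 2L)
  expect_equal(mc$harmonics_observed, c(53L, 106L))

  # one hit: consensus is that hit's canonical monomer
  one <- build_consensus(fake_hit(53, 10, 100, consensus = mm53()), 53L)
  expect_equal(one$canonical, canonical_monomer(mm53()))

  # 20 noisy hits (5% substitutions) vote back to the planted monomer,
  # regardless of per-hit rotation and strand
  set.seed(31)
  planted <- random_seq(20)
  noisy <- do.call(rbind, lapply(1:20, function(i) {
    chars <- strsplit(planted, "")[[1]]
    nmut <- rbinom(1, 20, 0.05)
    if (nmut > 0) {
      at <- sample(20, nmut)
      chars[at] <- vapply(chars[at], function(ch)
        sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    }
    v <- paste(chars, collapse = "")
    r <- sample(20, 1)
    v <- paste0(substr(v, r, 20), substr(v, 1, r - 1L))
    if (i %% 2 == 0) v <- reverse_complement(v)
    fake_hit(20, 10, 95, consensus = v)
  }))
  voted <- build_consensus(noisy, 20L)
  expect_equal(voted$canonical, canonical_monomer(planted))
  expect_error(build_consensus(noisy, 99L), "no retained hits")
})

test_that("mining is invariant to read strand", {
  reads <- lapply(1:3, function(i)
    make_satellite_read(mm53(), 60L, substitution_rate = 0.02,
                        seed = 40 + i, id = sprintf("r%d", i))$record)
  flipped <- lapply(reads, function(r)
    seq_record(r$id, reverse_complement(r$bases)))
  fwd <- mine_monomer(reads)
  rev <- mine_monomer(flipped)
  expect_equal(fwd$consensus$base_period, 53L)
  expect_equal(rev$consensus$base_period, 53L)
  expect_equal(fwd$consensus$canonical, rev$consensus$canonical)
})

test_that("end-to-end mining recovers a planted monomer from noisy reads", {
  set.seed(55)
  for (rep in 1:5) {
    len <- sample(20:200, 1)
    planted <- random_seq(len)
    reads <- lapply(1:3, function(i)
      make_satellite_read(planted, max(5L, ceiling(2500 / len)),
                          substitution_rate = 0.05, flank_len = 2800,
                          seed = rep * 10 + i,
                          id = sprintf("r%d_%d", rep, i))$record)
    res <- mine_monomer(reads)
    expect_false(is.null(res$consensus))
    expect_lte(abs(res$consensus$base_period - len), 1)
    idt <- rotational_identity_pct(res$consensus$canonical, planted)
    expect_gte(idt, 95)
  }
})
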