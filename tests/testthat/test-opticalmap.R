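BSPQI <- nicking_enzymes()[[1]]

test_that("in silico digestion places nick labels on both strands", {
  # no recognition site anywhere -> no label
  expect_length(digest_in_silico("ATATATATATATATATAT", BSPQI)$labels, 0L)
  # the 53-bp centromeric monomer itself carries no Nt.BspQI site
  expect_length(digest_in_silico(mm53(), BSPQI)$labels, 0L)
  # one site per unit across 50 units -> 50 labels at constant spacing
  hor <- make_hor_array(mm53(), 74L, 50L, site_motif = BSPQI$motif,
                        seed = 4)
  mol <- digest_in_silico(hor$record, BSPQI)
  expect_length(mol$labels, 50L)
  expect_equal(unique(diff(mol$labels)), hor$truth$unit_len)
  # forward match: label at start + offset
  s <- paste0(strrep("A", 20), "GCTCTTC", strrep("A", 20))
  expect_equal(digest_in_silico(s, BSPQI)$labels, 20 + 8)
  # reverse match: label at start + motif length - offset
  s2 <- paste0(strrep("A", 20), "GAAGAGC", strrep("A", 20))
  expect_equal(digest_in_silico(s2, BSPQI)$labels, 20 + 7 - 8)
  # IUPAC degeneracy expands, N never matches
  enzN <- enzyme_spec("degen", "GCWC", 1L)
  expect_equal(digest_in_silico("AAGCACAA", enzN)$labels, 3)
  expect_length(digest_in_silico("AAGCNCAA", enzN)$labels, 0L)
  expect_error(enzyme_spec("bad", "GCXC", 1L), "IUPAC")
})

test_that("digestion of the reverse complement mirrors the label positions", {
  set.seed(91)
  for (i in 1:10) {
    s <- random_seq(4000)
    fwd <- digest_in_silico(s, BSPQI)$labels
    rev <- digest_in_silico(reverse_complement(s), BSPQI)$labels
    expect_equal(sort(4000 - fwd), rev, tolerance = 1e-9,
                 info = paste("case", i))
    expect_true(all(diff(fwd) > 0))
  }
})

test_that("molecule filtering applies the 150 kb / 8 label floor", {
  mk <- function(len, nlab)
    label_molecule(paste0("m", len, "_", nlab), len,
                   seq(0, len - 1, length.out = max(nlab, 1))[seq_len(nlab)])
  mols <- list(mk(160000, 9),    # retained
               mk(149999, 50),   # too short despite many labels
               mk(150000, 8),    # exactly at both boundaries
               mk(300000, 7))    # too few labels
  kept <- filter_molecules(mols)
  expect_equal(vapply(kept, function(m) m$molecule_id, character(1)),
               c("m160000_9", "m150000_8"))
  # predicate oracle on random molecules + monotonicity in both thresholds
  set.seed(93)
  rand <- lapply(1:50, function(i)
    mk(round(runif(1, 1e5, 3e5)), sample(0:20, 1)))
  kept2 <- filter_molecules(rand)
  expected <- Filter(function(m)
    m$length >= 150000 && length(m$labels) >= 8, rand)
  expect_equal(kept2, expected)
  expect_lte(length(filter_molecules(rand, 200000, 8)), length(kept2))
  expect_lte(length(filter_molecules(rand, 150000, 12)), length(kept2))
})

test_that("constant label spacing yields one run with the planted unit", {
  mol <- label_molecule("m", 80000, seq(0, 19 * 3900, by = 3900))
  runs <- find_label_repeats(mol)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$unit_bp, 3900)
  expect_equal(runs$n_intervals, 19L)
  expect_equal(runs$m, 1L)
  expect_equal(runs$cv, 0)
})

test_that("random label positions produce no run", {
  for (s in 1:20) {
    set.seed(800 + s)
    mol <- label_molecule("m", 2e5, sort(runif(8, 0, 2e5 - 1)))
    expect_equal(nrow(find_label_repeats(mol)), 0L,
                 info = sprintf("seed %d", s))
  }
})

test_that("alternating spacings are caught at composite order two", {
  # 1300/2600 alternation: no constant order-1 run, but every sum of two
  # consecutive spacings is 3900
  mol <- label_molecule("m", 60000, cumsum(c(100, rep(c(1300, 2600), 10))))
  runs <- find_label_repeats(mol)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$m, 2L)
  expect_equal(runs$unit_bp, 3900)
  # oracle: composite sums of order 2
  d <- diff(mol$labels)
  expect_true(all(d[-length(d)] + d[-1] == 3900))
})

test_that("order-1 runs absorb their composite harmonics", {
  mol <- label_molecule("m", 80000, seq(0, 19 * 3900, by = 3900))
  runs <- find_label_repeats(mol, unit_range = NULL)
  expect_equal(runs$m, 1L)  # the m=2 run at 7800 was collapsed away
})

test_that("unit spectrum flags doubled-unit bins", {
  runs <- rbind(
    data.frame(molecule_id = "a", first_label_index = 1L, m = 1L,
               n_intervals = 10L, unit_bp = 2600, cv = 0.01,
               start_bp = 0, end_bp = 26000),
    data.frame(molecule_id = "b", first_label_index = 1L, m = 1L,
               n_intervals = 5L, unit_bp = 5200, cv = 0.01,
               start_bp = 0, end_bp = 26000))
  spec <- unit_spectrum(runs)
  expect_equal(spec$bin_bp, c(2600, 5200))
  expect_equal(spec$weight, c(10, 5))
  expect_true(is.na(spec$twox_of[1]))
  expect_equal(spec$twox_of[2], 2600)
  expect_equal(nrow(unit_spectrum(runs[0, ])), 0L)
  # a planted 2.6/3.9 kb mixture shows two modal bins
  set.seed(97)
  mix <- do.call(rbind, lapply(1:40, function(i) {
    u <- sample(c(2600, 3900), 1) * runif(1, 0.99, 1.01)
    data.frame(molecule_id = paste0("m", i), first_label_index = 1L,
               m = 1L, n_intervals = sample(4:20, 1), unit_bp = u,
               cv = 0.02, start_bp = 0, end_bp = u * 10)
  }))
  sp <- unit_spectrum(mix)
  # the two planted units carry essentially all the spectrum weight
  w26 <- sum(sp$weight[abs(sp$bin_bp - 2600) <= 100])
  w39 <- sum(sp$weight[abs(sp$bin_bp - 3900) <= 100])
  expect_gte(w26 / sum(sp$weight), 0.3)
  expect_gte(w39 / sum(sp$weight), 0.3)
  expect_gte((w26 + w39) / sum(sp$weight), 0.99)
})

test_that("HOR regions are called with span, unit and complexity", {
  # 110 consecutive 3.9 kb spacings: a simple ~429 kb array
  mol <- label_molecule("map1", 5e5, seq(1000, 1000 + 110 * 3900, by = 3900))
  calls <- call_hor_regions(mol)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$complexity, "simple")
  expect_equal(calls$unit_bp, 3900)
  expect_equal(calls$n_units, 110L)
  expect_false(calls$sub_span)
  expect_lte(abs((calls$end - calls$start) - calls$unit_bp * calls$n_units),
             0.1 * calls$unit_bp * calls$n_units)

  # two runs separated by ten units of irregular spacing -> two calls
  set.seed(2)
  left <- seq(0, 20 * 3900, by = 3900)
  irregular <- max(left) + cumsum(runif(10, 1000, 7000))
  right <- max(irregular) + seq(3900, 20 * 3900, by = 3900)
  mol2 <- label_molecule("map2", 3e5, c(left, irregular, right))
  calls2 <- call_hor_regions(mol2)
  expect_equal(nrow(calls2), 2L)
  expect_true(all(calls2$sub_span))  # each ~78 kb, below the 400 kb span

  # empty map -> empty calls
  expect_equal(nrow(call_hor_regions(label_molecule("e", 1000))), 0L)
})

test_that("enzyme selection prefers one site per unit and obeys the oracle", {
  hor <- make_hor_array(mm53(), 74L, 3L, site_motif = "GCTCTTC", seed = 6)
  unit <- substr(hor$record$bases, 1, hor$truth$unit_len)
  ranked <- select_enzyme(unit)
  expect_equal(ranked$enzyme[1], "Nt.BspQI")
  expect_equal(ranked$sites_per_unit[1], 1L)
  expect_equal(as.numeric(ranked$spacings[1]), nchar(unit))
  # an absent motif is excluded
  absent <- enzyme_spec("ghost", "TTAATTAACC", 1L)
  r2 <- select_enzyme("ACGTACGTACGT", list(absent))
  expect_equal(nrow(r2), 0L)
  expect_equal(attr(r2, "excluded"), "ghost")
  # random units against the brute-force circular oracle
  set.seed(103)
  for (i in 1:10) {
    u <- random_seq(4000)
    got <- select_enzyme(u)
    expect_equal(got$enzyme, oracle_rank_enzymes(u, nicking_enzymes()),
                 info = paste("unit", i))
  }
})

test_that("BNX round-trips and CMAP parses the minimal dialect", {
  set.seed(107)
  mols <- lapply(1:3, function(i)
    label_molecule(paste0("mol", i), 2e5,
                   sort(sample(0:(2e5 - 1), sample(5:15, 1)))))
  bnx <- tempfile(fileext = ".bnx")
  write_bnx(mols, bnx)
  back <- read_bnx(bnx)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$molecule_id, mols[[i]]$molecule_id)
    expect_equal(back[[i]]$length, mols[[i]]$length)
    expect_equal(back[[i]]$labels, mols[[i]]$labels, tolerance = 1e-6)
  }
  cmap <- tempfile(fileext = ".cmap")
  writeLines(c(
    "# CMAP File Version:\t0.1",
    "#h CMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition",
    "1\t50000.0\t3\t1\t1\t1000.0",
    "1\t50000.0\t3\t2\t1\t4900.0",
    "1\t50000.0\t3\t3\t1\t8800.0",
    "1\t50000.0\t3\t4\t0\t50000.0",
    "2\t20000.0\t1\t1\t1\t700.0",
    "2\t20000.0\t1\t2\t0\t20000.0"), cmap)
  maps <- read_cmap(cmap)
  expect_length(maps, 2L)
  expect_equal(maps[[1]]$labels, c(1000, 4900, 8800))
  expect_equal(maps[[2]]$length, 20000)
})
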