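test_that("pattern strings parse in PROSITE and compact notation", {
  p <- parse_pattern("S-x(3)-H")
  expect_length(p$elements, 3L)
  expect_equal(p$elements[[2]]$min, 3L)
  expect_equal(parse_pattern("SxxxH")$elements[[1]]$residue, "S")
  q <- parse_pattern("S-x(3)-H-x(100,10000)-H-x(3)-H")
  expect_equal(q$elements[[4]]$max, 10000L)
  expect_error(parse_pattern("x(3)"), "literal")
  expect_error(motif_pattern("bad", list(list(type = "wildcard",
                                              min = 5L, max = 2L))))
})

test_that("find_pattern enumerates all matches including overlaps and spacers", {
  p <- crest_patterns()$sxxxh
  expect_equal(find_pattern("SAAAH", p),
               data.frame(start = 1L, end = 5L), ignore_attr = TRUE)
  expect_equal(find_pattern("SAAAHSAAAH", p)$start, c(1L, 6L))
  # overlapping matches
  expect_equal(find_pattern("HAAAHAAAH", crest_patterns()$hxxxh)$start,
               c(1L, 5L))
  comp <- parse_pattern("S-x(3)-H-x(100,10000)-H-x(3)-H")
  m <- find_pattern(paste0("SAAAH", strrep("A", 100), "HAAAH"), comp)
  expect_equal(m, data.frame(start = 1L, end = 110L), ignore_attr = TRUE)
})

test_that("ambiguity letters match wildcards but never literals", {
  p <- crest_patterns()$sxxxh
  expect_equal(nrow(find_pattern("SXXXH", p)), 1L)
  expect_equal(nrow(find_pattern("XAAAH", p)), 0L)
  expect_equal(nrow(find_pattern("SAAAX", p)), 0L)
})

test_that("find_pattern agrees with the brute-force matcher on random strings", {
  set.seed(31)
  pats <- list(crest_patterns()$sxxxh, crest_patterns()$hxxxh,
               parse_pattern("S-x(1,6)-H-x(0,3)-D"))
  for (k in 1:15) {
    s <- random_sequence(sample(20:150, 1))
    for (p in pats) {
      expect_equal(find_pattern(s, p), brute_match(s, p),
                   ignore_attr = TRUE)
    }
  }
})

test_that("half-windows follow the (i+j)/2 floor formulas and clamp to bounds", {
  tm <- list(start = 10L, end = 30L)
  expect_equal(window_for(tm, "c_half", sequence_length = 500), c(20L, 35L))
  expect_equal(window_for(tm, "n_half", sequence_length = 500), c(5L, 20L))
  expect_equal(window_for(list(start = 3L, end = 21L), "n_half",
                          sequence_length = 500), c(1L, 12L))
  expect_equal(window_for(tm, "c_half", sequence_length = 32), c(20L, 32L))
})

test_that("windowed scan keeps only motifs fully inside their half-window", {
  # TM at 31..52; SxxxH occupying the last 5 TM residues is a c_half hit
  s <- paste0(strrep("L", 30), strrep("V", 17), "SAAAH", strrep("G", 30))
  topo <- data.frame(index = 1L, start = 31L, end = 52L)
  hits <- scan_tm_windows(rec1(s), topo)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$window, "c_half")
  expect_equal(hits$start, 48L)
  # the same motif planted in the N-terminal half is not reported
  s2 <- paste0(strrep("L", 30), "SAAAH", strrep("V", 17), strrep("G", 30))
  expect_equal(nrow(scan_tm_windows(rec1(s2), topo)), 0L)
  expect_equal(nrow(scan_tm_windows(rec1(s), crestscan:::empty_topology())),
               0L)
})

test_that("windowed scan equals match-everywhere-then-filter-containment", {
  set.seed(17)
  for (k in 1:40) {
    n <- sample(60:800, 1)
    s <- random_sequence(n)
    topo <- random_topology(n)
    if (nrow(topo) == 0) next
    got <- scan_tm_windows(rec1(s), topo)
    want <- brute_scan(s, topo)
    got <- got[order(got$pattern, got$tm_index, got$start), ]
    want <- want[order(want$pattern, want$tm_index, want$start), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("hits are shift-equivariant under sequence prefixing", {
  set.seed(23)
  s <- random_sequence(300)
  topo <- random_topology(300)
  skip_if(nrow(topo) == 0)
  base <- scan_tm_windows(rec1(s), topo)
  for (k in c(1L, 7L, 40L)) {
    s2 <- paste0(strrep("G", k), s)
    topo2 <- transform(topo, start = start + k, end = end + k)
    shifted <- scan_tm_windows(rec1(s2), topo2)
    expect_equal(shifted$start, base$start + k)
    expect_equal(shifted$end, base$end + k)
    expect_equal(shifted$tm_index, base$tm_index)
  }
})

test_that("naive composite scan enforces exact spacer bounds", {
  mk <- function(spacer) rec1(paste0("SAAAH", strrep("A", spacer), "HAAAH"))
  expect_equal(nrow(naive_scan(mk(99))), 0L)
  expect_equal(nrow(naive_scan(mk(100))), 1L)
  small <- scan_config(naive_spacer_min = 2L, naive_spacer_max = 5L)
  expect_equal(nrow(naive_scan(mk(1), small)), 0L)
  expect_equal(naive_scan(mk(2), small)$end, 12L)
  expect_equal(nrow(naive_scan(mk(5), small)), 1L)
  expect_equal(nrow(naive_scan(mk(6), small)), 0L)
})

test_that("every naive hit has its spacer inside the configured bounds", {
  set.seed(41)
  cfg <- scan_config(naive_spacer_min = 5L, naive_spacer_max = 30L)
  for (k in 1:10) {
    s <- random_sequence(150, s_h_boost = 6)
    hits <- naive_scan(rec1(s), cfg)
    if (nrow(hits) == 0) next
    # recover the HxxxH start: end - 4; SxxxH occupies start..start+4
    spacer <- (hits$end - 4L) - (hits$start + 5L)
    expect_true(all(spacer >= 5L & spacer <= 30L))
  }
})
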