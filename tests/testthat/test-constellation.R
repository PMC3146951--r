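# Seven equal TM segments at regular spacing, for handmade hit tables.
toy_topology <- function(n_tm = 7L) {
  start <- 30L + (seq_len(n_tm) - 1L) * 50L
  data.frame(index = seq_len(n_tm), start = start, end = start + 19L)
}

toy_hit <- function(pattern, tm, topo, window) {
  w <- window_for(topo[tm, ], window, sequence_length = 1000L)
  data.frame(pattern = pattern, start = w[1L], end = w[1L] + 4L,
             tm_index = tm, window = window, stringsAsFactors = FALSE)
}

test_that("ordering and separation constraints decide the call", {
  topo <- toy_topology()
  # SxxxH in TM2, HxxxH in TM7: separation 5, pass
  hits <- rbind(toy_hit("SxxxH", 2L, topo, "c_half"),
                toy_hit("HxxxH", 7L, topo, "n_half"))
  calls <- call_constellations(hits, topo, protein_id = "t")
  expect_equal(calls$tm_separation, 5L)
  expect_true(calls$passed)
  # SxxxH in TM2, HxxxH in TM4: separation 2, fail
  hits2 <- rbind(toy_hit("SxxxH", 2L, topo, "c_half"),
                 toy_hit("HxxxH", 4L, topo, "n_half"))
  calls2 <- call_constellations(hits2, topo, protein_id = "t")
  expect_equal(calls2$tm_separation, 2L)
  expect_false(calls2$passed)
  # reversed order: HxxxH in TM2, SxxxH in TM7: fail
  hits3 <- rbind(toy_hit("SxxxH", 7L, topo, "c_half"),
                 toy_hit("HxxxH", 2L, topo, "n_half"))
  calls3 <- call_constellations(hits3, topo, protein_id = "t")
  expect_false(calls3$passed)
  expect_equal(calls3$tm_separation, -5L)
})

test_that("extended mode additionally requires the TM3 aspartate", {
  topo <- toy_topology()
  cfg <- scan_config(mode = "extended")
  hits <- rbind(toy_hit("SxxxH", 2L, topo, "c_half"),
                toy_hit("HxxxH", 7L, topo, "n_half"))
  expect_false(any(call_constellations(hits, topo, cfg)$passed))
  hits_d <- rbind(hits, toy_hit("D", 3L, topo, "n_half"))
  expect_true(any(call_constellations(hits_d, topo, cfg)$passed))
  # D in the wrong segment does not rescue the call
  hits_wrong <- rbind(hits, toy_hit("D", 5L, topo, "n_half"))
  expect_false(any(call_constellations(hits_wrong, topo, cfg)$passed))
})

test_that("hits referencing unknown TM indices are rejected", {
  topo <- toy_topology(3L)
  bad <- toy_hit("SxxxH", 2L, toy_topology(7L), "c_half")
  bad$tm_index <- 9L
  expect_error(call_constellations(bad, topo), "absent")
})

test_that("classification is positive iff a passing call exists", {
  set.seed(3)
  pos <- generate_positive()
  expect_true(classify_protein(pos$record, pos$truth$topology)$positive)
  nm <- generate_decoy("decoy_no_motif")
  expect_false(classify_protein(nm$record, nm$truth$topology)$positive)
  sol <- generate_decoy("soluble")
  expect_equal(nrow(sol$truth$topology), 0L)
  expect_false(classify_protein(sol$record, sol$truth$topology)$positive)
})

test_that("classification is invariant to hit-list ordering", {
  set.seed(13)
  pos <- generate_positive()
  hits <- scan_tm_windows(pos$record, pos$truth$topology)
  topo <- pos$truth$topology
  base <- call_constellations(hits, topo, protein_id = "p")
  for (k in 1:5) {
    perm <- call_constellations(hits[sample.int(nrow(hits)), ], topo,
                                protein_id = "p")
    expect_equal(perm, base)
  }
})

test_that("passing calls have disjoint, ordered motif spans", {
  set.seed(29)
  gen <- generate_dataset(10, seed = 29, classes = "positive")
  cls <- classify_all(gen$records, gen$topologies)
  passed <- cls$calls[cls$calls$passed, ]
  expect_gt(nrow(passed), 0L)
  expect_true(all(passed$sxxxh_end < passed$hxxxh_start))
})

test_that("relaxing min_tm_separation never shrinks the positive set", {
  set.seed(47)
  gen <- generate_dataset(4, seed = 47)
  for (sep in list(c(5L, 3L), c(3L, 1L), c(4L, 0L))) {
    strict <- classify_all(gen$records, gen$topologies,
                           scan_config(min_tm_separation = sep[1]))
    loose <- classify_all(gen$records, gen$topologies,
                          scan_config(min_tm_separation = sep[2]))
    strict_pos <- strict$predictions$id[strict$predictions$positive]
    loose_pos <- loose$predictions$id[loose$predictions$positive]
    expect_true(all(strict_pos %in% loose_pos))
  }
})

test_that("evaluation reports exact rates and rejects malformed input", {
  truth <- data.frame(id = c("a", "b", "c", "d"),
                      label = c("positive", "positive", "decoy_order",
                                "soluble"))
  pred <- data.frame(id = c("a", "b", "c", "d"),
                     positive = c(TRUE, TRUE, FALSE, FALSE))
  ev <- evaluate(truth, pred)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(unname(ev$specificity[["pooled"]]), 1.0)
  expect_equal(sum(ev$confusion), 4L)

  pred2 <- pred; pred2$positive[2] <- FALSE
  expect_equal(evaluate(truth, pred2)$sensitivity, 0.5)

  expect_error(evaluate(truth[0, ], pred[0, ]), "empty")
  expect_error(evaluate(truth, pred[c(1, 2, 3, 3), ]), "identical")
  expect_output(print(ev), "sensitivity")
})
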