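space <- build_state_space()

tagset <- function(mt, t) sort(space$states$tag[mt[[t]]])

test_that("h-center follows the 7-residue Kyte-Doolittle window, ties leftmost", {
  # window sums from the standard KD table put the max at center 7
  expect_equal(find_h_center("MKKLLLLLLASA"), 7L)
  # all windows tie -> leftmost admissible full-window center
  expect_equal(find_h_center("AAAAAAAAAA"), 4L)
  expect_error(find_h_center("MKLLA"), "too short")
  # length-6 fallback: single most hydrophobic residue within [3, L-3]
  expect_equal(find_h_center("MKLAAA"), 3L)
})

test_that("twin-arginine motif search keeps a 2-residue n-region", {
  expect_equal(find_rr_motif("MNRRDFLK"), 3L)
  expect_equal(find_rr_motif("MAKRRSRR"), 4L)
  expect_error(find_rr_motif("MRRA"), "RR")
  expect_error(find_rr_motif("MAKAAA"), "RR")
})

test_that("SPI labeling reproduces the worked 10-mer layout", {
  # construct an SP whose h-center lands at 4: KD max window centered there
  seq10 <- "MKLLLIKKKD"
  expect_equal(find_h_center(seq10), 4L)
  sp <- annotated_sp(paste0(seq10, "AAAAA"), "SEC_SPI", cs = 10,
                     organism_group = "GRAM_NEG")
  mt <- label_regions(sp, space)
  expect_equal(lapply(1:10, tagset, mt = mt),
               list("N", "N", c("H", "N"), "H", c("C", "H"), c("C", "H"),
                    c("C", "H"), "C", "C", "C"))
  expect_equal(tagset(mt, 11), "O")
  expect_true(all(space$states$class[unlist(mt)] %in% c("SEC_SPI")))
})

test_that("SPIII labeling is a single undifferentiated block", {
  sp <- annotated_sp(paste0(strrep("A", 20), strrep("G", 10)), "SEC_SPIII",
                     cs = 20, organism_group = "GRAM_NEG")
  mt <- label_regions(sp, space)
  expect_true(all(vapply(1:20, function(t) tagset(mt, t) == "P", TRUE)))
  expect_true(all(vapply(21:30, function(t) tagset(mt, t) == "O", TRUE)))
})

test_that("Tat labeling places the motif and post-motif n position", {
  # RR at positions 3-4
  sp <- annotated_sp("MNRRDFLLLLLIAGASTAAAAA", "TAT_SPI", cs = 16,
                     organism_group = "GRAM_NEG")
  mt <- label_regions(sp, space)
  expect_equal(tagset(mt, 1), "N1")
  expect_equal(tagset(mt, 2), "N1")
  expect_equal(tagset(mt, 3), "R1")
  expect_equal(tagset(mt, 4), "R2")
  expect_equal(tagset(mt, 5), "N2")
  expect_equal(tagset(mt, 14), "C")
  expect_error(label_regions(
    annotated_sp("MAAAAALLLLLAAAA", "TAT_SPI", cs = 12,
                 organism_group = "GRAM_NEG"), space), "RR")
})

test_that("SPII labeling ends in the lipobox with h-only before it", {
  sp <- annotated_sp("MKKALLLLLLLAGCAAAAA", "SEC_SPII", cs = 13,
                     organism_group = "GRAM_POS")
  mt <- label_regions(sp, space)
  i <- find_h_center(substr(sp$sequence, 1, 13))
  expect_equal(tagset(mt, 11), "L1")
  expect_equal(tagset(mt, 12), "L2")
  expect_equal(tagset(mt, 13), "L3")
  for (t in i:(13 - 3)) expect_equal(tagset(mt, t), "H")
  expect_equal(tagset(mt, 1), "N")
  expect_equal(tagset(mt, 2), "N")
})

test_that("labeling errors identify the offending record", {
  bad <- annotated_sp("MKLAGAAAA", "SEC_SPI", cs = 5, organism_group = "EUKARYA",
                      id = "too_short")
  expect_error(label_regions(bad, space), "too_short")
})

test_that("labelings are deterministic and structurally sound over many SPs", {
  cfg <- generator_config(counts = c(SEC_SPI = 60, SEC_SPII = 40,
                                     TAT_SPI = 40, TAT_SPII = 30,
                                     SEC_SPIII = 30), seed = 77)
  recs <- generate_dataset(cfg)
  for (r in recs) {
    mt <- label_regions(r, space)
    mt2 <- label_regions(r, space)
    expect_identical(mt, mt2)
    sizes <- lengths(mt)
    expect_true(all(sizes %in% 1:2))
    # two-element sets are only {N,H}-like or {H,C}, one class, no motif states
    for (t in which(sizes == 2)) {
      tg <- tagset(mt, t)
      expect_true(identical(tg, c("H", "N")) || identical(tg, c("H", "N2")) ||
                    identical(tg, c("C", "H")))
      expect_length(unique(space$states$class[mt[[t]]]), 1L)
    }
    # mature tail after the CS
    expect_true(all(vapply((r$cs + 1):nchar(r$sequence),
                           function(t) tagset(mt, t) == "O", TRUE)))
  }
})
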