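# Gap normalization, indel-event extraction, polarization, SIC coding and
# family-specificity tallies.

chars <- function(s) strsplit(s, "")[[1]]

test_that("slideable gaps are left-justified onto common columns", {
  aln <- rbind(r1 = chars("AC--GT"), r2 = chars("A--CGT"))
  norm <- normalize_gaps(aln)
  # both rows occupy identical gap columns after normalization
  expect_identical(norm["r1", ], norm["r2", ])
  # residue content of every row unchanged
  expect_equal(paste(norm["r1", ][norm["r1", ] != "-"], collapse = ""), "ACGT")
  # gapless and non-slideable alignments unchanged
  clean <- rbind(a = chars("ACGTAA"), b = chars("ACGTAA"))
  expect_identical(normalize_gaps(clean), clean)
  fixed <- rbind(a = chars("AG--CT"), b = chars("AGTTCT"))
  expect_identical(normalize_gaps(fixed), fixed)
})

test_that("events carry exact coordinates and union bearer sets", {
  aln <- rbind(t1 = chars("ACGTACGT"),
               t2 = chars("ACG--CGT"),
               t3 = chars("ACG--CGT"))
  ev <- extract_indel_events(aln, "toy")
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end, ev$length_nt), c(3L, 5L, 2L))
  expect_setequal(ev$bearers[[1L]], c("t2", "t3"))
})

test_that("runs sharing a start but not an end are distinct events", {
  aln <- rbind(t1 = chars("ACGTACGTAA"),
               t2 = chars("ACG--CGTAA"),
               t3 = chars("ACG---GTAA"))
  ev <- extract_indel_events(aln, "toy")
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start, c(3L, 3L))
  expect_equal(ev$end, c(5L, 6L))
})

test_that("terminal gap runs are missing data, not events", {
  aln <- rbind(t1 = chars("---ACGT"),
               t2 = chars("CCCACGT"),
               t3 = chars("CCCAC--"))
  expect_equal(nrow(extract_indel_events(aln, "toy")), 0L)
})

test_that("all-gap columns are rejected", {
  aln <- rbind(t1 = chars("AC-GT"), t2 = chars("AC-GT"))
  expect_error(extract_indel_events(aln, "x"), "all-gap")
})

test_that("extraction equals the brute-force oracle on random alignments", {
  set.seed(41)
  for (rep in 1:40) {
    aln <- random_gapped_alignment(sample(3:12, 1), sample(60:200, 1),
                                   sample(0:6, 1))
    ev <- extract_indel_events(aln, "r")
    or <- oracle_indel_events(aln)
    got <- data.frame(start = ev$start, end = ev$end,
                      bearers = vapply(ev$bearers, function(x)
                        paste(sort(x), collapse = ";"), ""))
    rownames(got) <- NULL
    expect_equal(got, or, info = paste("rep", rep))
  }
})

test_that("polarity follows the outgroup and majority references", {
  aln <- rbind(og = chars("AAACGTAA"),
               t2 = chars("AAA--TAA"),
               t3 = chars("AAA--TAA"),
               t4 = chars("AAACGTAA"))
  ev <- extract_indel_events(aln, "x")
  del <- polarize_events(ev, aln, "outgroup", outgroups = "og")
  expect_equal(del$polarity, "deletion")
  expect_setequal(del$carriers[[1L]], c("t2", "t3"))
  # gap in the outgroup: an insertion confined to the residue carriers
  aln2 <- rbind(og = chars("AAA--TAA"),
                t2 = chars("AAACGTAA"),
                t3 = chars("AAACGTAA"),
                t4 = chars("AAA--TAA"))
  ev2 <- extract_indel_events(aln2, "x")
  ins <- polarize_events(ev2, aln2, "outgroup", outgroups = "og")
  expect_equal(ins$polarity, "insertion")
  expect_setequal(ins$carriers[[1L]], c("t2", "t3"))
  # 50/50 split under majority mode is ambiguous
  amb <- polarize_events(ev2, aln2, "majority")
  expect_equal(amb$polarity, "ambiguous")
  expect_error(polarize_events(ev, aln, "outgroup", outgroups = "nope"),
               "absent")
})

test_that("size spectra report counts, shares and the <=10 nt mass", {
  ev <- plastcmp:::empty_indel_events("x", c("a", "b"))
  expect_equal(size_spectrum(ev)$total, 0L)
  aln <- rbind(t1 = chars("AACGTACGTTAAGGAAC"),
               t2 = chars("AA-GTACGTTAA--AAC"),
               t3 = chars("AACGTAC--TAAGGAAC"))
  ev2 <- extract_indel_events(aln, "x")
  sp <- size_spectrum(ev2)
  expect_equal(sp$total, 3L)
  h <- sp$histogram
  expect_equal(h$count[h$length_nt == 2L], 2L)
  expect_equal(h$share_pct[h$length_nt == 2L], 200 / 3)
  expect_equal(sp$share_le10_pct, 100)
})

test_that("family-unique tallies respect strict and relaxed modes", {
  taxonomy <- data.frame(
    taxon = c(paste0("F", 1:4), paste0("G", 1:4)),
    family = rep(c("FamF", "FamG"), each = 4))
  taxa <- c(taxonomy$taxon, "og")
  mk_aln <- function() {
    m <- matrix("A", length(taxa), 40, dimnames = list(taxa, NULL))
    m[, 5] <- "C"; m[, 12] <- "C"; m[, 19] <- "C"; m[, 26] <- "C"
    m
  }
  aln <- mk_aln()
  aln[paste0("F", 1:4), 6:8] <- "-"       # strict family event
  aln[paste0("F", 1:2), 13:15] <- "-"     # partial family event
  aln[c("F1", "G1"), 20:22] <- "-"        # cross-family event
  ev <- polarize_events(extract_indel_events(aln, "locusA"), aln,
                        "outgroup", outgroups = "og")
  strict <- family_unique(ev, taxonomy)
  expect_equal(sum(strict$totals$total), 1L)
  expect_equal(strict$totals$total[strict$totals$family == "FamF"], 1L)
  relaxed <- family_unique(ev, taxonomy, mode = "relaxed")
  expect_equal(relaxed$totals$total[relaxed$totals$family == "FamF"], 2L)
  # the cross-family event is unique nowhere in either mode
  expect_true(all(is.na(
    strict$events$unique_family[vapply(strict$events$carriers, length, 0L) == 2L])))
  # strict counts are invariant to taxon order
  taxonomy2 <- taxonomy[sample(nrow(taxonomy)), ]
  strict2 <- family_unique(ev, taxonomy2)
  expect_equal(strict$totals, strict2$totals)
})

test_that("insertions mark the residue-carrying family", {
  taxonomy <- data.frame(taxon = c(paste0("F", 1:3), paste0("G", 1:3)),
                         family = rep(c("FamF", "FamG"), each = 3))
  taxa <- c(taxonomy$taxon, "og")
  aln <- matrix("A", length(taxa), 30, dimnames = list(taxa, NULL))
  aln[, 4] <- "C"; aln[, 11] <- "C"
  # insertion present only in FamF: everyone else gapped
  aln[setdiff(taxa, paste0("F", 1:3)), 5:7] <- "-"
  ev <- polarize_events(extract_indel_events(aln, "locusB"), aln,
                        "outgroup", outgroups = "og")
  expect_equal(ev$polarity, "insertion")
  fu <- family_unique(ev, taxonomy)
  expect_equal(fu$totals$ins[fu$totals$family == "FamF"], 1L)
  expect_equal(sum(fu$totals$total), 1L)
})

test_that("SIC codes bearers 1, outsiders 0 and nested gaps ?", {
  aln <- rbind(t1 = chars("AAACGTACGTAA"),
               t2 = chars("AAA------TAA"),
               t3 = chars("AAACG--CGTAA"),
               t4 = chars("AAACGTACGTAA"),
               t5 = chars("AAACGTACGTAA"))
  ev <- extract_indel_events(aln, "x")
  m <- encode_sic(ev, aln)
  short <- which(ev$length_nt == 2L)
  long <- which(ev$length_nt == 6L)
  expect_equal(unname(m[, short]),
               c("0", "?", "1", "0", "0"))
  expect_equal(unname(m[, long]),
               c("0", "1", "0", "0", "0"))
  none <- plastcmp:::empty_indel_events("x", rownames(aln))
  expect_equal(ncol(encode_sic(none, aln)), 0L)
})

test_that("normalization preserves every row's ungapped sequence", {
  set.seed(43)
  for (rep in 1:10) {
    aln <- random_gapped_alignment(6, 80, 3)
    norm <- normalize_gaps(aln)
    for (i in seq_len(nrow(aln)))
      expect_equal(paste(norm[i, ][norm[i, ] != "-"], collapse = ""),
                   paste(aln[i, ][aln[i, ] != "-"], collapse = ""))
  }
})
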