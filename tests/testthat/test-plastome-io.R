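# Flat-file parsing, quadripartite region inference and per-region summaries.

toy_record_text <- function() {
  rec <- plastome_record(
    id = "TOY1", taxon = "Toyus example",
    sequence = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                     collapse = ""),
    features = list(
      gene_feature("rps16", "PCG", "+", rbind(c(99L, 199L), c(349L, 499L))),
      gene_feature("trnH-GUG", "tRNA", "-", rbind(c(599L, 670L)))))
  write_plastome_genbank(rec)
}

test_that("parser captures exon structure, strand and qualifiers", {
  set.seed(42)
  rec <- parse_plastome(toy_record_text())
  expect_s3_class(rec, "plastome_record")
  expect_equal(length(rec$features), 2L)
  f <- rec$features[[1L]]
  expect_equal(f$name, "rps16")
  expect_equal(nrow(f$exons), 2L)
  expect_equal(f$exons[, 1L], c(99L, 349L))
  expect_equal(f$exons[, 2L], c(199L, 499L))
  expect_equal(rec$features[[2L]]$strand, "-")
})

test_that("trans-spliced rps12 keeps two same-name features", {
  cfg <- sim_config(seed = 4)
  g <- gen_plastome(cfg, 4, 1)
  rec <- parse_plastome(g$text)
  rps12 <- Filter(function(f) f$name == "rps12", rec$features)
  expect_equal(length(rps12), 2L)
  expect_setequal(vapply(rps12, function(f) nrow(f$exons), 0L), c(1L, 2L))
})

test_that("records without ORIGIN or with malformed coordinates error", {
  expect_error(parse_plastome("LOCUS  X 10 bp\nFEATURES\n//"), "ORIGIN")
  bad <- c("LOCUS       B1 4 bp    DNA     circular PLN",
           "FEATURES             Location/Qualifiers",
           "     CDS             12..x9",
           "                     /gene=\"bad\"",
           "ORIGIN", "        1 acgt", "//")
  expect_error(parse_plastome(paste(bad, collapse = "\n")),
               "malformed coordinates")
})

test_that("write/parse round-trip preserves the feature set", {
  cfg <- sim_config(seed = 9)
  g <- gen_plastome(cfg, 1, 2)
  rec <- parse_plastome(g$text)
  expect_equal(rec$id, g$record$id)
  expect_equal(nchar(rec$sequence), nchar(g$record$sequence))
  expect_equal(rec$sequence, g$record$sequence)
  sig <- function(r) sort(vapply(r$features, function(f)
    paste(f$name, f$strand, f$pseudo, paste(t(f$exons), collapse = ","),
          sep = "|"), ""))
  expect_identical(sig(rec), sig(g$record))
})

test_that("inferred regions recover the planted quadripartite map exactly", {
  cfg <- sim_config(seed = 2)
  for (f in c(1L, 3L)) {
    g <- gen_plastome(cfg, f, 1)
    rec <- parse_plastome(g$text)
    m <- infer_regions(rec)
    tm <- g$truth$regions
    expect_identical(m$lsc, tm$lsc)
    expect_identical(m$irb, tm$irb)
    expect_identical(m$ssc, tm$ssc)
    expect_identical(m$ira, tm$ira)
    # invariants: tiling and byte-exact IR symmetry
    lens <- vapply(m[c("lsc", "irb", "ssc", "ira")],
                   function(iv) iv[2L] - iv[1L], 0L)
    expect_equal(sum(lens), m$genome_length)
    rec$regions <- m
    ira_seq <- substring(rec$sequence, m$ira[1L] + 1L, m$ira[2L])
    irb_seq <- substring(rec$sequence, m$irb[1L] + 1L, m$irb[2L])
    expect_identical(ira_seq, revcomp(irb_seq))
  }
})

test_that("a genome without inverted repeats is reported as IR-lacking", {
  set.seed(5)
  rec <- plastome_record("NOIR", "t", rand_dna_test(5000))
  expect_warning(m <- infer_regions(rec), "no IR detected")
  expect_null(m)
})

test_that("equal-length repeat pairs resolve to the smallest-start pair", {
  # two disjoint reverse-complement repeat pairs of identical length in a toy
  set.seed(8)
  u1 <- rand_dna_test(60); u2 <- rand_dna_test(60)
  filler <- function(n) rand_dna_test(n)
  seqs <- paste0(filler(40), u1, filler(50), revcomp(u1),
                 filler(50), u2, filler(50), revcomp(u2), filler(40))
  rec <- plastome_record("TIE", "t", seqs)
  m <- infer_regions(rec, min_ir = 50L)
  cand <- oracle_ir_pairs(seqs, 50L)
  maxlen <- max(cand$length)
  best <- cand[cand$length == maxlen, ]
  best <- best[order(best$start1, best$start2), ][1L, ]
  expect_equal(m$irb[2L] - m$irb[1L], maxlen)
  starts <- sort(c(m$irb[1L] %% nchar(seqs), m$ira[1L] %% nchar(seqs)))
  expect_equal(starts, c(best$start1, best$start2))
})

test_that("GC percentages match a direct single-pass count, N excluded", {
  expect_equal(gc_of("ATGC"), 50)
  expect_equal(gc_of(strrep("A", 100)), 0)
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 10000,
                    replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
             collapse = "")
  ch <- strsplit(s, "")[[1]]
  direct <- 100 * sum(ch %in% c("G", "C")) / sum(ch != "N")
  expect_equal(gc_of(s), direct)
})

test_that("summaries report per-region lengths and GC", {
  cfg <- sim_config(seed = 6)
  g <- gen_plastome(cfg, 2, 3)
  rec <- parse_plastome(g$text)
  rec$regions <- infer_regions(rec)
  s <- summarize_plastome(rec)
  expect_equal(s$total_bp, cfg$lsc + 2L * cfg$ir + cfg$ssc)
  expect_equal(s$lsc_bp, cfg$lsc)
  expect_equal(s$ir_bp, cfg$ir)
  expect_equal(s$ssc_bp, cfg$ssc)
  expect_true(all(s[, c("gc_total", "gc_lsc", "gc_ir", "gc_ssc")] > 30 &
                    s[, c("gc_total", "gc_lsc", "gc_ir", "gc_ssc")] < 70))
})
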