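# Junction expansion/contraction profiling and family pattern typing.

demo_profiles <- function(seed = 11) {
  cfg <- sim_config(seed = seed, n_families = 4L, taxa_per_family = 3L)
  sim_profiles <- NULL
  recs <- list()
  for (f in seq_len(cfg$n_families)) for (i in seq_len(cfg$taxa_per_family)) {
    g <- gen_plastome(cfg, f, i)
    rec <- g$record
    rec$regions <- g$truth$regions
    recs[[rec$taxon]] <- list(rec = rec, truth = g$truth)
    sim_profiles <- rbind(sim_profiles, junction_profile(rec))
  }
  list(cfg = cfg, profiles = sim_profiles, recs = recs)
}

test_that("published family-signature overlaps are reported exactly", {
  cfg <- sim_config(seed = 21)
  # family 2 carries the 110-bp rps19 signature, family 1 the 1077-bp ycf1
  g2 <- gen_plastome(cfg, 2, 1)
  r2 <- g2$record; r2$regions <- g2$truth$regions
  p2 <- junction_profile(r2)
  jlb <- p2[p2$junction == "JLB" & p2$state != "pseudo-fragment", ]
  expect_equal(jlb$state, "spans")
  expect_equal(jlb$overlap_bp, 110L)
  g1 <- gen_plastome(cfg, 1, 1)
  r1 <- g1$record; r1$regions <- g1$truth$regions
  p1 <- junction_profile(r1)
  jsa <- p1[p1$junction == "JSA" & p1$gene == "ycf1" & p1$state == "spans", ]
  expect_equal(jsa$overlap_bp, 1077L)
})

test_that("overlap arithmetic agrees with per-base membership counting", {
  d <- demo_profiles(31)
  for (tx in names(d$recs)[c(1, 5, 9)]) {
    rec <- d$recs[[tx]]$rec
    m <- rec$regions
    L <- m$genome_length
    in_ir <- rep(FALSE, L)
    for (lab in c("irb", "ira")) {
      p <- plastcmp:::region_pieces(m[[lab]], L)
      for (i in seq_len(nrow(p))) in_ir[(p[i, 1L] + 1L):p[i, 2L]] <- TRUE
    }
    prof <- d$profiles[d$profiles$taxon == rec$taxon &
                         d$profiles$state %in% c("spans", "ir-side"), ]
    for (k in seq_len(nrow(prof))) {
      f <- Filter(function(x) tolower(x$name) == tolower(prof$gene[k]) &&
                    !x$pseudo, rec$features)[[1L]]
      pieces <- plastcmp:::feature_pieces(f, L)
      covered <- rep(FALSE, L)
      for (i in seq_len(nrow(pieces)))
        covered[(pieces[i, 1L] + 1L):pieces[i, 2L]] <- TRUE
      expect_equal(prof$overlap_bp[k], sum(covered & in_ir),
                   info = paste(rec$taxon, prof$gene[k]))
    }
  }
})

test_that("a gene ending exactly at a junction abuts it", {
  l <- 2000L; r <- 1000L; s <- 1200L
  set.seed(12)
  irb <- rand_dna_test(r)
  seqs <- paste0(rand_dna_test(l), irb, rand_dna_test(s), revcomp(irb))
  rec <- plastome_record("AB1", "t", seqs, features = list(
    gene_feature("rps19", "PCG", "+", rbind(c(l - 279L, l)))),
    regions = region_map(c(0L, l), c(l, l + r), c(l + r, l + r + s),
                         c(l + r + s, l + 2L * r + s), l + 2L * r + s))
  p <- junction_profile(rec)
  jlb <- p[p$junction == "JLB", ]
  expect_equal(jlb$state, "abuts")
  expect_equal(jlb$overlap_bp, 0L)
  expect_equal(jlb$distance_bp, 0L)
})

test_that("missing focal genes are recorded, not raised", {
  cfg <- sim_config(seed = 13)
  g <- gen_plastome(cfg, 3, 1)
  rec <- g$record
  rec$features <- Filter(function(f) f$name != "ndhF", rec$features)
  rec$regions <- g$truth$regions
  p <- junction_profile(rec)
  expect_equal(p$state[p$junction == "JSB" & p$gene == "ndhF"],
               "gene-missing")
})

test_that("IR-copy fragments appear as pseudo-fragment rows at the mirrored junction", {
  cfg <- sim_config(seed = 14)
  g <- gen_plastome(cfg, 2, 1)       # pattern 4: ndhF expands into IRb
  rec <- g$record; rec$regions <- g$truth$regions
  p <- junction_profile(rec)
  spans <- p[p$junction == "JSB" & p$gene == "ndhF" & p$state == "spans", ]
  mirror <- p[p$junction == "JSA" & p$gene == "ndhF" &
                p$state == "pseudo-fragment", ]
  expect_equal(nrow(mirror), 1L)
  expect_equal(mirror$overlap_bp, spans$overlap_bp)
  # ycf1's IRb fragment mirrors its JSA overlap
  yc <- p[p$gene == "ycf1", ]
  expect_equal(yc$overlap_bp[yc$state == "pseudo-fragment"],
               yc$overlap_bp[yc$state == "spans"])
})

test_that("families map onto the six-way junction pattern table", {
  d <- demo_profiles(15)   # families get patterns 1, 4, 5, 6
  pat <- classify_junction_patterns(d$profiles,
    data.frame(taxon = vapply(d$recs, function(x) x$rec$taxon, ""),
               family = vapply(d$recs, function(x) x$truth$family, "")))
  got <- setNames(pat$pattern_id, pat$family)
  expect_equal(unname(got[c("Fam01", "Fam02", "Fam03", "Fam04")]),
               c(1L, 4L, 5L, 6L))
  expect_equal(pat$rps19_at_JLB[pat$family == "Fam04"], "mixed")
})

test_that("pattern classification ignores record order within a family", {
  d <- demo_profiles(16)
  tax <- data.frame(taxon = vapply(d$recs, function(x) x$rec$taxon, ""),
                    family = vapply(d$recs, function(x) x$truth$family, ""))
  p1 <- classify_junction_patterns(d$profiles, tax)
  set.seed(1)
  shuffled <- d$profiles[sample(nrow(d$profiles)), ]
  p2 <- classify_junction_patterns(shuffled, tax)
  p2 <- p2[match(p1$family, p2$family), ]
  rownames(p2) <- NULL
  expect_equal(p1, p2)
})

test_that("conserved ycf1/trnH junction features are flagged", {
  d <- demo_profiles(17)
  cf <- check_conserved_features(d$profiles)
  expect_true(all(cf$ycf1_jsa_conserved))
  expect_true(all(cf$trnh_3bp_in_ira))
  # an out-of-range ycf1 overlap clears flag (a)
  p <- d$profiles
  p$overlap_bp[p$junction == "JSA" & p$gene == "ycf1" &
                 p$state == "spans"] <- 0L
  p$state[p$junction == "JSA" & p$gene == "ycf1" &
            p$state == "spans"] <- "single-copy-side"
  cf2 <- check_conserved_features(p)
  expect_false(any(cf2$ycf1_jsa_conserved))
})
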