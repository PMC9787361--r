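# Newick support parsing, monophyly, Fitch counts and node annotation.

test_that("support labels parse as BS/PP pairs or single values", {
  tr <- read_tree_support("((A,B)97/0.99,(C,D));")
  expect_equal(tr$BS[!is.na(tr$BS)], 97)
  expect_equal(tr$PP[!is.na(tr$PP)], 0.99)
  tr2 <- read_tree_support("((A,B),(C,D));")
  expect_true(all(is.na(tr2$BS)) && all(is.na(tr2$PP)))
  tr3 <- read_tree_support("((A,B)100,(C,D)0.87);")
  expect_equal(sort(tr3$BS[!is.na(tr3$BS)]), 100)
  expect_equal(sort(tr3$PP[!is.na(tr3$PP)]), 0.87)
  expect_error(read_tree_support("((A,B,(C;"), regexp = ".")
})

test_that("monophyly is exact MRCA leaf-set equality", {
  tr <- read_tree_support("((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B"))$monophyletic)
  expect_false(is_monophyletic(tr, c("A", "C"))$monophyletic)
  expect_true(is_monophyletic(tr, "A")$monophyletic)
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
})

test_that("Fitch counts match hand-worked binary cases", {
  tr <- read_tree_support("((A,B),(C,D));")
  f1 <- fitch_steps(tr, c(A = "1", B = "1", C = "0", D = "0"))
  expect_equal(c(f1$steps, f1$origins), c(1L, 1L))
  f2 <- fitch_steps(tr, c(A = "1", B = "0", C = "1", D = "0"))
  expect_equal(c(f2$steps, f2$origins), c(2L, 2L))
  # wildcards resolve parsimoniously
  f3 <- fitch_steps(tr, c(A = "1", B = "?", C = "0", D = "0"))
  expect_equal(f3$steps, 1L)
  expect_error(fitch_steps(tr, c(A = "?", B = "?", C = "?", D = "?")),
               "all states")
})

test_that("Fitch equals exhaustive enumeration on random small trees", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = TRUE, br = NULL)
    states <- setNames(sample(c("0", "1", "?"), n, replace = TRUE,
                              prob = c(.4, .4, .2)), tr$tip.label)
    if (all(states == "?")) states[1] <- "1"
    expect_equal(fitch_steps(tr, states)$steps,
                 oracle_fitch_steps(tr, states),
                 info = paste("rep", rep))
  }
})

test_that("Fitch agrees with phangorn on binary characters", {
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, rooted = TRUE, br = NULL)
    states <- setNames(sample(c("0", "1"), n, replace = TRUE), tr$tip.label)
    if (length(unique(states)) == 1L) states[1] <- setdiff(c("0", "1"),
                                                           states[1])
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(names(states), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(fitch_steps(tr, states)$steps,
                 phangorn::fitch(tr, dat, site = "pscore"),
                 info = paste("rep", rep))
  }
})

test_that("steps are invariant under leaf rotation and re-rooting", {
  set.seed(63)
  tr <- ape::rtree(7, rooted = TRUE, br = NULL)
  states <- setNames(c("1", "1", "0", "1", "0", "0", "0"), tr$tip.label)
  s0 <- fitch_steps(tr, states)$steps
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(fitch_steps(rot, states)$steps, s0)
  for (tip in tr$tip.label) {
    rr <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_steps(rr, states)$steps, s0, info = tip)
  }
})

test_that("characters classify as family-specific, clade-specific or homoplastic", {
  cfg <- sim_config(seed = 64, n_families = 4L, taxa_per_family = 3L)
  tt <- gen_taxonomy_and_tree(cfg)
  taxonomy <- tt$taxonomy
  leaves <- tt$tree$tip.label
  mk <- function(on) setNames(ifelse(leaves %in% on, "1", "0"), leaves)
  famB <- taxonomy$taxon[taxonomy$family == "Fam02"]
  c1 <- classify_character(tt$tree, mk(famB), taxonomy)
  expect_equal(c1$category, "family-specific")
  expect_equal(c1$family, "Fam02")
  # two distant leaves: homoplastic with two origins
  far <- c(taxonomy$taxon[taxonomy$family == "Fam01"][1],
           taxonomy$taxon[taxonomy$family == "Fam03"][1])
  c2 <- classify_character(tt$tree, mk(far), taxonomy)
  expect_equal(c2$category, "homoplastic")
  expect_equal(c2$origins, 2L)
  # a sub-family clade marker is clade-specific but not family-specific
  sub <- clade_tips_test(tt$tree, famB[1:2])
  if (length(sub) < length(famB)) {
    c3 <- classify_character(tt$tree, mk(sub), taxonomy)
    expect_equal(c3$category, "clade-specific")
    expect_true(is.na(c3$family))
  }
  # single bearer: autapomorphy
  c4 <- classify_character(tt$tree, mk(famB[1]), taxonomy)
  expect_equal(c4$category, "autapomorphy")
})

test_that("node annotation gathers clade-specific characters and homoplasies", {
  cfg <- sim_config(seed = 65, n_families = 3L, taxa_per_family = 3L)
  tt <- gen_taxonomy_and_tree(cfg)
  leaves <- tt$tree$tip.label
  mk <- function(on) setNames(ifelse(leaves %in% on, "1", "0"), leaves)
  famA <- tt$taxonomy$taxon[tt$taxonomy$family == "Fam01"]
  chars <- list(i1 = mk(famA), i2 = mk(famA),
                i3 = mk(c(famA[1], leaves[length(leaves)])))
  ann <- annotate_nodes(tt$tree, chars, tt$taxonomy)
  famA_node <- is_monophyletic(tt$tree, famA)$mrca
  expect_setequal(
    ann$node_annotations$character[ann$node_annotations$node == famA_node],
    c("i1", "i2"))
  expect_equal(ann$homoplastic$character, "i3")
  empty <- annotate_nodes(tt$tree, list(z = mk(character(0))), tt$taxonomy)
  expect_equal(nrow(empty$node_annotations), 0L)
})

test_that("strict family-unique indels map as family-specific on the tree", {
  # cross-module consistency: generator -> indel pipeline -> SIC -> mapping
  cfg <- sim_config(seed = 66, n_families = 3L, taxa_per_family = 4L)
  tt <- gen_taxonomy_and_tree(cfg)
  taxa <- c(tt$taxonomy$taxon, "og")
  fam2 <- tt$taxonomy$taxon[tt$taxonomy$family == "Fam02"]
  plan <- data.frame(start = 100L, length = 6L,
                     carriers = paste(fam2, collapse = ";"),
                     polarity = "deletion", stringsAsFactors = FALSE)
  g <- gen_intron_alignment(cfg, "petB", taxa, plan, outgroups = "og")
  ev <- polarize_events(extract_indel_events(normalize_gaps(g$aln), "petB"),
                        g$aln, "outgroup", outgroups = "og")
  fu <- family_unique(ev, tt$taxonomy)
  expect_equal(fu$events$unique_family, "Fam02")
  sic <- encode_sic(ev, g$aln)
  states <- setNames(sic[tt$taxonomy$taxon, 1L], tt$taxonomy$taxon)
  cls <- classify_character(tt$tree, states, tt$taxonomy)
  expect_equal(cls$category, "family-specific")
  expect_equal(cls$family, "Fam02")
})
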