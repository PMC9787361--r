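# Cloverleaf decomposition, structural typing and the constrained folder.

test_that("a canonical cloverleaf decomposes into four arms without anomalies", {
  set.seed(51)
  t0 <- make_cloverleaf_test("GAA")
  d <- parse_cloverleaf(t0)
  expect_equal(d$acceptor$n_pairs, 7L)
  expect_equal(d$d_arm$n_pairs, 4L)
  expect_equal(d$ac_arm$n_pairs, 5L)
  expect_equal(d$t_arm$n_pairs, 5L)
  expect_equal(d$v_region$length, 4L)
  expect_length(d$anomalies, 0L)
  # arms ordered 5'->3': D before AC before T
  expect_lt(d$d_arm$outer[2L], d$ac_arm$outer[1L])
  expect_lt(d$ac_arm$outer[2L], d$t_arm$outer[1L])
})

test_that("long paired V-arms, bulge loops and expanded AC loops are flagged", {
  set.seed(52)
  tv <- make_cloverleaf_test("GCU", v_mode = "paired", v_seq = "GUUAU")
  dv <- parse_cloverleaf(tv)
  expect_true("long-V-arm" %in% dv$anomalies)
  expect_gte(dv$v_region$length, 10L)
  expect_false(is.null(dv$v_region$stem))
  tb <- make_cloverleaf_test("UGU", ac_bulge = "UU")
  db <- parse_cloverleaf(tb)
  expect_true("extra-loop-at-AC-arm" %in% db$anomalies)
  tp <- make_cloverleaf_test("UGU", t_bulge = "GG")
  dp <- parse_cloverleaf(tp)
  expect_true("extra-loop-at-psi-arm" %in% dp$anomalies)
  te <- make_cloverleaf_test("UAC", anc_loop_len = 9L)
  de <- parse_cloverleaf(te)
  expect_true("expanded-ANC-loop" %in% de$anomalies)
})

test_that("malformed structures raise parse errors", {
  expect_error(parse_cloverleaf(trna_structure("ACGU", "((..")), "unbalanced")
  expect_error(parse_cloverleaf(trna_structure("ACGUACGUAC", "((......))")),
               "hairpins")
})

test_that("V-arm typing follows the 4-5 / >=10 nt rule exhaustively", {
  set.seed(53)
  for (v in 0:12) {
    t1 <- if (v > 0) make_cloverleaf_test("GAA", v_seq = paste(rep("A", v),
                                                               collapse = ""))
          else make_cloverleaf_test("GAA", v_seq = "")
    cls <- classify_structure(parse_cloverleaf(t1))
    want <- if (v >= 4 && v <= 5) "I" else if (v >= 10) "II" else "intermediate"
    expect_equal(cls$v_arm_type, want, info = paste("v =", v))
  }
})

test_that("catalog motifs map to their type codes", {
  set.seed(54)
  catalog <- read_trna_catalog()
  cases <- list(
    list("tRNA-Tyr-GUA", list(anticodon = "GUA", v_mode = "paired",
                              v_seq = "AUA"), "C1"),
    list("tRNA-Val-UAC", list(anticodon = "UAC", anc_loop_len = 9L), "E1"),
    list("tRNA-Val-UAC", list(anticodon = "UAC"), "E2"),
    list("tRNA-Ser-GCU", list(anticodon = "GCU", v_mode = "paired",
                              v_seq = "UUA"), "B7"),
    list("tRNA-Thr-UGU", list(anticodon = "UGU", ac_bulge = "CU"), "D1"),
    list("tRNA-Thr-UGU", list(anticodon = "UGU", t_bulge = "GG"), "D4"),
    list("tRNA-Thr-UGU", list(anticodon = "UGU"), "D3"))
  for (cs in cases) {
    t1 <- do.call(make_cloverleaf_test, cs[[2L]])
    t1$label <- cs[[1L]]
    cls <- classify_structure(parse_cloverleaf(t1), catalog)
    expect_equal(cls$type_code, cs[[3L]], info = cs[[3L]])
  }
})

test_that("an anticodon/label mismatch warns but does not fail", {
  set.seed(55)
  t1 <- make_cloverleaf_test("GAA")
  t1$label <- "tRNA-Phe-AAA"
  expect_warning(parse_cloverleaf(t1), "anticodon")
})

test_that("family patterns flag intrafamilial variation and uniqueness", {
  taxonomy <- data.frame(taxon = sprintf("t%d", 1:6),
                         family = rep(c("A", "B", "C"), each = 2))
  set.seed(56)
  structs <- list()
  add <- function(taxon, label, ...) {
    t1 <- make_cloverleaf_test(...)
    t1$label <- label; t1$taxon <- taxon
    structs[[length(structs) + 1L]] <<- t1
  }
  # family A unique paired-V class for Ser-GCU; B and C share the typical one
  for (tx in c("t1", "t2")) add(tx, "tRNA-Ser-GCU", anticodon = "GCU",
                                v_mode = "paired", v_seq = "UUA")
  for (tx in c("t3", "t4", "t5", "t6")) add(tx, "tRNA-Ser-GCU",
                                            anticodon = "GCU", v_seq = "AGCA")
  # family B intrafamilially variable Val loop
  add("t3", "tRNA-Val-UAC", anticodon = "UAC", anc_loop_len = 9L)
  add("t4", "tRNA-Val-UAC", anticodon = "UAC")
  for (tx in c("t1", "t2", "t5", "t6")) add(tx, "tRNA-Val-UAC",
                                            anticodon = "UAC")
  cls <- classify_trna_set(structs, read_trna_catalog())
  cv <- catalog_variants(cls, taxonomy)
  ser_a <- cv[cv$isotype == "tRNA-Ser-GCU" & cv$family == "A", ]
  expect_true(ser_a$interfam_unique)
  expect_false(ser_a$intrafam_variable)
  val_b <- cv[cv$isotype == "tRNA-Val-UAC" & cv$family == "B", ]
  expect_true(val_b$intrafam_variable)
  expect_equal(val_b$n_types, 2L)
  ser_b <- cv[cv$isotype == "tRNA-Ser-GCU" & cv$family == "B", ]
  expect_false(ser_b$interfam_unique)
  # all-identical datasets carry no flags
  cls2 <- cls[cls$isotype == "tRNA-Ser-GCU" & cls$taxon %in%
                c("t3", "t4", "t5", "t6"), ]
  cv2 <- catalog_variants(cls2, taxonomy[3:6, ])
  expect_false(any(cv2$intrafam_variable))
})

test_that("unique flags equal a brute-force family set-difference", {
  cfg <- sim_config(seed = 57, n_families = 4L, taxa_per_family = 3L)
  tt <- gen_taxonomy_and_tree(cfg)
  gset <- gen_trna_set(cfg, tt$taxonomy)
  cls <- classify_trna_set(gset$structs, read_trna_catalog())
  cv <- catalog_variants(cls, tt$taxonomy)
  for (k in seq_len(nrow(cv))) {
    fam <- cv$family[k]; iso <- cv$isotype[k]
    sub <- cls[cls$isotype == iso, ]
    sub$family <- tt$taxonomy$family[match(sub$taxon, tt$taxonomy$taxon)]
    here <- unique(sub$signature[sub$family == fam])
    elsewhere <- unique(sub$signature[sub$family != fam])
    expect_equal(cv$interfam_unique[k],
                 length(setdiff(here, elsewhere)) > 0L,
                 info = paste(fam, iso))
  }
})

test_that("the folder reproduces planted structures and rejects unfoldables", {
  set.seed(58)
  for (rep in 1:3) {
    t0 <- make_cloverleaf_test(c("GAA", "CAU", "GUC")[rep])
    f <- fold_trna(t0$sequence)
    expect_identical(f$structure, t0$structure)
  }
  expect_error(fold_trna(strrep("A", 76)), "no feasible cloverleaf")
})

test_that("decomposition round-trips the folder's own output", {
  set.seed(59)
  t0 <- make_cloverleaf_test("UGG")
  f <- fold_trna(t0$sequence)
  d <- parse_cloverleaf(f)
  expect_equal(d$acceptor$n_pairs, 7L)
  expect_length(d$anomalies, 0L)
})
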