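test_that("direct occurrence scan agrees with the worked example and edge cases", {
  ins <- example1_instance()
  sc <- occurrence_scan(example1_dataset(), c("AAA", "TTT"), ins)
  expect_identical(sc$support, 2L)
  expect_gte(sc$weighted_support, sc$support)
  # motif longer than every sequence
  long_ins <- motif_instance(k = c(6, 6), e = c(0, 0), dmin = 0, dmax = 0,
                             quorum = 1, quorum_kind = "absolute")
  sc2 <- occurrence_scan(tibble::tibble(id = "s", seq = "ACGTACG"),
                         c("ACGTAC", "ACGTAC"), long_ins)
  expect_identical(sc2$support, 0L)
  expect_identical(sc2$weighted_support, 0)
})

test_that("scan support matches extraction support on random datasets", {
  set.seed(113)
  for (rep in 1:5) {
    ds <- rand_dataset(4, 45)
    ins <- motif_instance(k = c(3, 3), e = c(1, 0), dmin = 0, dmax = 2,
                          quorum = 2, quorum_kind = "absolute")
    res <- extract_structured(ds, ins)
    for (r in seq_len(nrow(res))) {
      sc <- occurrence_scan(ds, res$boxes[[r]], ins)
      expect_identical(as.integer(sc$support), res$support[r])
      expect_identical(as.integer(sc$weighted_support),
                       res$weighted_support[r])
    }
  }
})

test_that("z-scores are finite under degenerate variance and rank deterministically", {
  ds <- example1_dataset()
  ins <- example1_instance()
  res <- extract_structured(ds, ins)
  z <- motif_zscores(res, ds, replicates = 5, seed = 5)
  expect_true(all(is.finite(z$z_support)))
  expect_setequal(z$rank_support, seq_len(nrow(z)))
  expect_setequal(z$rank_weighted, seq_len(nrow(z)))
  # identical z-scores break ties lexicographically by motif string
  tie <- tibble::tibble(
    motif = c("CCC[1,1]AAA", "AAA[1,1]CCC"),
    boxes = list(c("CCC", "AAA"), c("AAA", "CCC")),
    support = c(1L, 1L), weighted_support = c(1L, 1L))
  ins2 <- motif_instance(k = c(3, 3), e = c(0, 0), dmin = 1, dmax = 1,
                         quorum = 1, quorum_kind = "absolute")
  zt <- motif_zscores(tie, tibble::tibble(id = "s", seq = "GGGGGGGGGG"),
                      instance = ins2, replicates = 3, seed = 9)
  expect_identical(zt$rank_support[zt$motif == "AAA[1,1]CCC"], 1L)
  expect_identical(zt$rank_support[zt$motif == "CCC[1,1]AAA"], 2L)
})

test_that("z-scores are invariant under report input order", {
  set.seed(127)
  ds <- rand_dataset(6, 50)
  ins <- motif_instance(k = c(3, 3), e = c(1, 1), dmin = 0, dmax = 2,
                        quorum = 2, quorum_kind = "absolute")
  res <- extract_structured(ds, ins)
  expect_gt(nrow(res), 1)
  z1 <- motif_zscores(res, ds, replicates = 8, seed = 44)
  rev_rows <- res[rev(seq_len(nrow(res))), ]
  z2 <- motif_zscores(rev_rows, ds, replicates = 8, seed = 44)
  m <- match(z1$motif, z2$motif)
  expect_equal(z1$z_support, z2$z_support[m])
  expect_identical(z1$rank_support, z2$rank_support[m])
})

test_that("an implanted motif outranks chance motifs and z grows with implant count", {
  ins <- parse_instance("(3,0)[2,2](5,0),7")
  res <- run_implant_benchmark(ins, n_motifs = 1, n_seq = 80, seq_len = 150,
                               seed = 77, zscore = TRUE, replicates = 15)
  expect_identical(res$summary$identified, 1L)
  expect_identical(res$summary$rank_support, 1L)
  # monotone: more implanted copies -> larger z for the same motif
  z_at <- function(targets) {
    set.seed(88)
    bg <- generate_background(60, 120)
    imp <- implant_motifs(bg, ins, n_motifs = 1, targets = targets)
    sc <- occurrence_scan(imp$dataset, imp$consensus$boxes[[1]], ins)
    rep_tbl <- tibble::tibble(motif = imp$consensus$motif,
                              boxes = imp$consensus$boxes,
                              support = as.integer(sc$support),
                              weighted_support = as.integer(sc$weighted_support))
    motif_zscores(rep_tbl, imp$dataset, instance = ins,
                  replicates = 12, seed = 89)$z_support
  }
  expect_gt(z_at(30), z_at(6))
})

test_that("subsampling randomization works and exclusion filtering drops motifs", {
  ds <- example1_dataset()
  res <- extract_structured(ds, example1_instance())
  z <- motif_zscores(res, ds, replicates = 6, randomization = "subsample",
                     subsample_fraction = 0.5, seed = 13)
  expect_true(all(is.finite(z$z_support)))
  # both motifs occur in the very sequences they came from -> excluded
  dropped <- filter_excluded(res, ds, quorum_ratio = 100)
  expect_identical(nrow(dropped), 0L)
  kept <- filter_excluded(res, tibble::tibble(id = "z", seq = "GGGGGGGGG"),
                          quorum_ratio = 50)
  expect_identical(kept$motif, res$motif)
})
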