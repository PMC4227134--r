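test_that("the worked two-string example merges to its two motifs, support 2", {
  res <- extract_structured(example1_dataset(), example1_instance())
  expect_identical(res$motif, c("AAA[1,2]TAT", "AAA[1,2]TTT"))
  expect_identical(res$support, c(2L, 2L))
  expect_true(all(res$weighted_support >= res$support))
  # trivial merge agrees
  res_t <- extract_structured(example1_dataset(), example1_instance(),
                              mode = "trivial")
  expect_identical(res$motif, res_t$motif)
  expect_identical(res$support, res_t$support)
  expect_identical(res$weighted_support, res_t$weighted_support)
})

test_that("merge_pair finds each direction's motif through cell (9,9)", {
  ins <- example1_instance()
  fwd <- merge_pair("CAAACCTTT", "CGAAAGTAT", ins)
  expect_identical(fwd$motif, "AAA[1,2]TTT")
  expect_identical(fwd$source_gaps[[1]], 2L)
  expect_identical(fwd$target_ends[[1]], c(5L, 9L))
  expect_identical(fwd$target_gaps[[1]], 1L)
  rev <- merge_pair("CGAAAGTAT", "CAAACCTTT", ins)
  expect_identical(rev$motif, "AAA[1,2]TAT")
  expect_identical(rev$target_ends[[1]], c(4L, 9L))
  expect_identical(rev$target_gaps[[1]], 2L)
})

test_that("pruned merging never inspects more than sum(|p_t|^2) cells per anchor", {
  set.seed(41)
  for (rep in 1:8) {
    ins <- rand_instance(beta = sample(2:3, 1), quorum = 1)
    pr <- build_progressions(ins)
    x <- rand_seq(40); y <- rand_seq(40)
    pruned <- merge_pair(x, y, ins, mode = "pruned")
    trivial <- merge_pair(x, y, ins, mode = "trivial")
    keyed <- function(d) {
      key <- paste(d$motif, purrr::map_chr(d$target_ends, paste,
                                           collapse = ","))
      as.data.frame(d[order(key), ], stringsAsFactors = FALSE)
    }
    expect_equal(keyed(pruned), keyed(trivial), ignore_attr = TRUE)
    expect_lte(attr(pruned, "n_cell_checks"),
               attr(pruned, "n_anchors") * pr$n_cells)
    expect_lte(attr(trivial, "n_cell_checks"),
               attr(trivial, "n_anchors") * pr$n_cell_refs_trivial)
  }
})

test_that("extraction equals the brute-force enumeration oracle", {
  set.seed(53)
  for (rep in 1:12) {
    n_seq <- sample(2:4, 1)
    ins <- rand_instance(beta = sample(2:3, 1), kmax = 4, emax = 1,
                         dmax_width = 2,
                         quorum = sample(seq_len(n_seq), 1))
    ds <- rand_dataset(n_seq, sample(25:40, 1))
    got <- extract_structured(ds, ins)
    want <- oracle_extract(ds, ins)
    expect_identical(got$motif, want$motif,
                     info = paste(render_instance(ins),
                                  paste(ds$seq, collapse = "/")))
    expect_identical(got$support, as.integer(want$support))
    expect_identical(got$weighted_support, as.integer(want$weighted_support))
  }
})

test_that("reported motifs are strictly valid and independently confirmed", {
  set.seed(67)
  ds <- rand_dataset(4, 60)
  ins <- motif_instance(k = c(3, 4), e = c(1, 1), dmin = 0, dmax = 2,
                        quorum = 2, quorum_kind = "absolute")
  res <- extract_structured(ds, ins)
  expect_gt(nrow(res), 0)
  for (r in seq_len(nrow(res))) {
    boxes <- res$boxes[[r]]
    gaps <- res$source_gaps[[r]]
    src <- ds$seq[ds$id == res$source_id[r]]
    # reconstruct box1.spacer.box2 from source coordinates
    pos <- res$source_start[r]
    rebuilt <- character(0)
    for (t in seq_along(boxes)) {
      rebuilt <- c(rebuilt, substr(src, pos, pos + nchar(boxes[t]) - 1L))
      if (t < length(boxes)) pos <- pos + nchar(boxes[t]) + gaps[t]
    }
    expect_identical(rebuilt, boxes)
    # soundness: direct sliding-window scan reaches the quorum
    counts <- vapply(ds$seq, oracle_count_occurrences, 0,
                     boxes = boxes, instance = ins)
    expect_gte(sum(counts > 0), 2)
    expect_identical(res$support[r], sum(counts > 0))
  }
})

test_that("with e = 0 and quorum 1 the reports are exactly the literal arrangements", {
  set.seed(71)
  ds <- rand_dataset(3, 30)
  ins <- motif_instance(k = c(3, 3), e = c(0, 0), dmin = 1, dmax = 2,
                        quorum = 1, quorum_kind = "absolute")
  res <- extract_structured(ds, ins)
  lit <- sort(unique(unlist(lapply(ds$seq, oracle_enumerate, instance = ins))))
  expect_identical(res$motif, lit)
})

test_that("raising the quorum or tightening e never adds motifs", {
  set.seed(83)
  ds <- rand_dataset(4, 40)
  loose <- motif_instance(k = c(3, 3), e = c(1, 1), dmin = 1, dmax = 2,
                          quorum = 2, quorum_kind = "absolute")
  tight_e <- motif_instance(k = c(3, 3), e = c(0, 0), dmin = 1, dmax = 2,
                            quorum = 2, quorum_kind = "absolute")
  high_q <- motif_instance(k = c(3, 3), e = c(1, 1), dmin = 1, dmax = 2,
                           quorum = 4, quorum_kind = "absolute")
  base <- extract_structured(ds, loose)
  expect_true(all(extract_structured(ds, tight_e)$motif %in% base$motif))
  expect_true(all(extract_structured(ds, high_q)$motif %in% base$motif))
})

test_that("identical sequence copies report every arrangement at full support", {
  s <- "ACGTTACG"
  ds <- tibble::tibble(id = paste0("c", 1:3), seq = rep(s, 3))
  ins <- motif_instance(k = c(2, 2), e = c(0, 0), dmin = 1, dmax = 1,
                        quorum = 3, quorum_kind = "absolute")
  res <- extract_structured(ds, ins)
  expect_identical(res$motif, sort(oracle_enumerate(s, ins)))
  expect_true(all(res$support == 3L))
})

test_that("edit-model extraction matches Hamming when e = 0", {
  set.seed(97)
  ds <- rand_dataset(3, 35)
  mk <- function(model) {
    ins <- motif_instance(k = c(3, 3), e = c(0, 0), dmin = 1, dmax = 2,
                          quorum = 2, quorum_kind = "absolute", model = model)
    extract_structured(ds, ins)
  }
  h <- mk("hamming"); d <- mk("edit")
  expect_identical(h$motif, d$motif)
  expect_identical(h$support, d$support)
})

test_that("single-motif extraction equals an exhaustive k-mer oracle", {
  set.seed(103)
  ds <- rand_dataset(5, 50)
  got <- extract_single(ds, k = 6, e = 1, quorum = 2)
  # oracle: enumerate all 6-mers present, count sequences within distance 1
  kmers <- sort(unique(unlist(lapply(ds$seq, function(s)
    vapply(1:(nchar(s) - 5L), function(p) substr(s, p, p + 5L), "")))))
  ins1 <- motif_instance(k = 6, e = 1, quorum = 2, quorum_kind = "absolute")
  sup <- vapply(kmers, function(km)
    sum(vapply(ds$seq, function(s)
      any(oracle_box_ends(s, km) <= 1L), TRUE)), 0L)
  expect_identical(got$motif, kmers[sup >= 2L])
  expect_identical(got$support, unname(sup[sup >= 2L]))
  # quorum 1 reports every k-mer present
  all1 <- extract_single(ds, k = 6, e = 0, quorum = 1)
  expect_identical(all1$motif, kmers)
})

test_that("the two-string example reports AAA for exact single extraction", {
  res <- extract_single(example1_dataset(), k = 3, e = 0, quorum = 2)
  expect_identical(res$motif, "AAA")
  expect_identical(res$support, 2L)
})

test_that("motif_set accessors summarise and plot", {
  res <- extract_structured(example1_dataset(), example1_instance())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "motif_set"))
  gl <- glance(res)
  expect_identical(gl$n_motifs, 2L)
  expect_identical(gl$quorum, 2L)
  expect_s3_class(autoplot(res), "ggplot")
  M <- flasm_matrix("CAAACCTTT", "CGAAAGTAT", 3)
  expect_s3_class(autoplot(M), "ggplot")
})
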