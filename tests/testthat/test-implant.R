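test_that("background generation is alphabet-true, sized, and seed-reproducible", {
  bg <- generate_background(5, 40, seed = 11)
  expect_equal(nrow(bg), 5L)
  expect_true(all(nchar(bg$seq) == 40L))
  expect_true(all(strsplit(paste(bg$seq, collapse = ""), "")[[1]] %in% DNA))
  bg2 <- generate_background(5, 40, seed = 11)
  expect_identical(bg, bg2)
  # letter frequencies close to uniform over many letters (binomial 3 sigma)
  big <- generate_background(1, 2e5, seed = 12)
  freq <- table(strsplit(big$seq, "")[[1]]) / 2e5
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 2e5)))
})

test_that("error-free implantation writes the consensus verbatim at recorded spots", {
  ins <- parse_instance("(3,0)[2,2](5,0),7")
  bg <- generate_background(30, 80, seed = 21)
  imp <- implant_motifs(bg, ins, n_motifs = 3, targets = 5, seed = 22)
  expect_equal(nrow(imp$truth), 15L)
  expect_true(all(vapply(imp$truth$gaps, identical, TRUE, 2L)))  # fixed gap
  for (r in seq_len(nrow(imp$truth))) {
    row <- imp$truth[r, ]
    written <- substring(imp$dataset$seq[imp$dataset$id == row$seq_id],
                         row$start, row$start + nchar(row$instance) - 1L)
    expect_identical(written, row$instance)
    # e = 0: instance boxes equal consensus boxes exactly
    cons <- imp$consensus[imp$consensus$motif_id == row$motif_id, ]
    expect_identical(substr(row$instance, 1, 3), cons$boxes[[1]][1])
    expect_identical(substr(row$instance, 6, 10), cons$boxes[[1]][2])
  }
})

test_that("implanted instances respect per-box error budgets and intervals", {
  ins <- parse_instance("(6,2)[1,3](5,1),7")
  bg <- generate_background(25, 100, seed = 31)
  imp <- implant_motifs(bg, ins, n_motifs = 4, targets = 6, seed = 32)
  for (r in seq_len(nrow(imp$truth))) {
    row <- imp$truth[r, ]
    cons <- imp$consensus$boxes[[row$motif_id]]
    g <- row$gaps[[1]]
    expect_true(g >= 1L && g <= 3L)
    b1 <- substr(row$instance, 1, 6)
    b2 <- substr(row$instance, 6 + g + 1, 6 + g + 5)
    ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_lte(ham(b1, cons[1]), 2L)
    expect_lte(ham(b2, cons[2]), 1L)
  }
  # strict mutation always realises the full budget
  imp2 <- implant_motifs(bg, ins, n_motifs = 4, targets = 6, seed = 33,
                         mutation = "strict")
  for (r in seq_len(nrow(imp2$truth))) {
    row <- imp2$truth[r, ]
    cons <- imp2$consensus$boxes[[row$motif_id]]
    g <- row$gaps[[1]]
    ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_identical(ham(substr(row$instance, 1, 6), cons[1]), 2L)
    expect_identical(ham(substr(row$instance, 6 + g + 1, 6 + g + 5),
                         cons[2]), 1L)
  }
})

test_that("collision-free implants never overlap in a sequence", {
  ins <- parse_instance("(4,0)[1,2](4,0),7")
  bg <- generate_background(6, 60, seed = 41)
  imp <- implant_motifs(bg, ins, n_motifs = 6, targets = 4, seed = 42)
  spans <- imp$truth |>
    dplyr::mutate(end = start + nchar(instance) - 1L) |>
    dplyr::group_by(seq_id) |>
    dplyr::arrange(start, .by_group = TRUE)
  by_seq <- split(spans, spans$seq_id)
  for (sp in by_seq) {
    if (nrow(sp) < 2L) next
    expect_true(all(sp$start[-1] > sp$end[-nrow(sp)]))
  }
})

test_that("implantation is deterministic under a fixed seed", {
  ins <- parse_instance("(5,1)[0,2](4,1),7")
  bg <- generate_background(15, 70, seed = 51)
  a <- implant_motifs(bg, ins, n_motifs = 2, targets = 4, seed = 52)
  b <- implant_motifs(bg, ins, n_motifs = 2, targets = 4, seed = 52)
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth, b$truth)
})

test_that("error-free implanted motifs are always re-extracted (completeness)", {
  ins <- parse_instance("(4,0)[1,3](4,0),10")
  res <- run_implant_benchmark(ins, n_motifs = 5, n_seq = 40, seq_len = 120,
                               seed = 61)
  expect_identical(res$summary$identified, 5L)
  expect_gte(res$summary$extracted, 5L)
})

test_that("identification counts verbatim consensus reports only", {
  reports <- tibble::tibble(motif = c("AAA[1,2]TTT", "CCC[1,2]GGG"))
  cons <- tibble::tibble(motif_id = 1:2,
                         motif = c("AAA[1,2]TTT", "TTT[1,2]AAA"))
  res <- evaluate_identification(reports, cons)
  expect_identical(res$implanted, 2L)
  expect_identical(res$identified, 1L)
  expect_identical(res$extracted, 2L)
  empty <- evaluate_identification(tibble::tibble(motif = character()), cons)
  expect_identical(empty$identified, 0L)
  expect_identical(empty$extracted, 0L)
})
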