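#' Extract strictly valid structured motifs
#'
#' Runs the pairwise reduction over all ordered sequence pairs (self-pairs
#' included, so a motif's own source counts toward its quorum): for each
#' pair, one fixed-length matching matrix per distinct box length is
#' computed, anchor cells holding e1-occurrences of the first box are
#' enumerated, and per-box occurrences are merged under the gap-interval
#' constraints. Every reported motif is *strictly valid*: its boxes are
#' literal windows of some input sequence with spacer lengths inside the
#' intervals, so reconstructing `box1 . spacer . box2 ...` from the source
#' coordinates reproduces a substring of that sequence.
#'
#' `mode = "pruned"` walks only the distinct prefix-sum progression cells
#' per anchor and discards whole candidate sets through the precomputed
#' cell-to-candidate association; `mode = "trivial"` enumerates every
#' candidate's cells directly. Both modes return identical reports.
#'
#' Under the edit model the matrix cells fix only end positions in the
#' target sequence, so gap lengths there are certified only up to a slack
#' of `e` per box; the merge widens the checked rows accordingly. Hamming
#' is the reference model for structured extraction.
#'
#' @param dataset Dataset tibble (columns `id`, `seq`) or named character
#'   vector; at least two sequences.
#' @param instance A [motif_instance()] (or instance string accepted by
#'   [parse_instance()]).
#' @param mode `"pruned"` (default) or `"trivial"` candidate merging.
#' @param engine Matrix engine: `"sliding"` (default) or `"bitparallel"`.
#' @param rounding Quorum ratio rounding, see [quorum_size()].
#' @return A `motif_set` tibble: one row per reported motif, columns
#'   `motif` (rendered string, boxes joined by `[dmin,dmax]`), `boxes`
#'   (list of box strings), `support` (distinct sequences with at least one
#'   occurrence), `weighted_support` (total distinct occurrences over all
#'   sequences), and the coordinates of one exact occurrence (`source_id`,
#'   `source_start`, `source_gaps`). Rows are ordered lexicographically by
#'   motif string.
#' @examples
#' ds <- tibble::tibble(id = c("s1", "s2"),
#'                      seq = c("CAAACCTTT", "CGAAAGTAT"))
#' ins <- parse_instance("(3,0)[1,2](3,1),2", quorum_kind = "absolute")
#' extract_structured(ds, ins)
#' @export
extract_structured <- function(dataset, instance,
                               mode = c("pruned", "trivial"),
                               engine = c("sliding", "bitparallel"),
                               rounding = c("ceiling", "floor")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (is.character(instance)) instance <- parse_instance(instance)
  stopifnot(inherits(instance, "motif_instance"))
  dataset <- as_dataset(dataset, min_n = 2L)
  min_len <- min(nchar(dataset$seq))
  if (max(instance$k) > min_len)
    stop(sprintf("box length %d exceeds the shortest sequence (%d letters)",
                 max(instance$k), min_len), call. = FALSE)
  q <- resolve_quorum(instance, nrow(dataset), match.arg(rounding))
  geom <- merge_geometry(instance)
  raw <- cpp_extract(dataset$seq, instance$k, instance$e, geom$K,
                     geom$Vx, geom$Vy, geom$pmin, geom$pmax,
                     pruned = (mode == "pruned"),
                     edit = (instance$model == "edit"),
                     bitparallel = (engine == "bitparallel"))
  occ <- records_to_occurrences(
    tibble::tibble(xid = raw$xid, yid = raw$yid, i = raw$i, j = raw$j,
                   cand = raw$cand),
    dataset, instance, geom)
  reports <- aggregate_reports(occ, quorum = q)
  new_motif_set(reports, dataset = dataset, instance = instance,
                quorum = q, mode = mode, engine = engine)
}

#' Merge per-box occurrences for one ordered sequence pair
#'
#' The per-pair step of [extract_structured()], exposed for inspection:
#' given source `x` and target `y`, finds every pair of a strictly valid
#' structured motif (boxes = windows of `x`, spacers inside the intervals)
#' and an approximate occurrence of it in `y`. Matrix computation is reused
#' across boxes sharing a window length.
#'
#' @param x,y Source and target strings.
#' @inheritParams extract_structured
#' @param matrices Optional named list of precomputed [flasm_matrix()]
#'   objects keyed by window length (as character); computed when missing.
#' @return A tibble with one row per (motif, occurrence) pair: `motif`,
#'   `boxes`, `source_start`, `source_gaps`, `target_ends`, `target_gaps`.
#'   Attributes `n_anchors` and `n_cell_checks` report merge effort (the
#'   pruned mode inspects at most `sum(|p_t|^2)` distinct cells per
#'   anchor).
#' @export
merge_pair <- function(x, y, instance, mode = c("pruned", "trivial"),
                       engine = c("sliding", "naive", "bitparallel"),
                       matrices = NULL) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (is.character(instance)) instance <- parse_instance(instance)
  stopifnot(inherits(instance, "motif_instance"))
  geom <- merge_geometry(instance)
  kd <- unique(instance$k)
  if (is.null(matrices)) {
    matrices <- lapply(kd, function(kk)
      flasm_matrix(x, y, kk, model = instance$model, engine = engine))
    names(matrices) <- as.character(kd)
  }
  mats <- lapply(instance$k, function(kk) {
    M <- matrices[[as.character(kk)]]
    if (is.null(M)) stop("no matrix supplied for k = ", kk, call. = FALSE)
    unclass(M)
  })
  res <- cpp_merge_pair(mats, instance$k, instance$e, geom$K,
                        geom$Vx, geom$Vy, geom$pmin, geom$pmax,
                        pruned = (mode == "pruned"),
                        edit = (instance$model == "edit"))
  ds <- tibble::tibble(id = c("x", "y"), seq = c(toupper(x), toupper(y)))
  occ <- records_to_occurrences(
    tibble::tibble(xid = 1L, yid = 2L, i = res$i, j = res$j,
                   cand = res$cand),
    ds, instance, geom)
  out <- tibble::tibble(
    motif = occ$motif,
    boxes = strsplit(occ$box_key, "\t", fixed = TRUE),
    source_start = occ$j - instance$k[1] + 1L,
    source_gaps = lapply(occ$cand, function(cd)
      unname(geom$gaps[, geom$gap_x[cd]])),
    target_ends = strsplit(occ$occ_key, ":", fixed = TRUE) |>
      lapply(as.integer),
    target_gaps = lapply(occ$cand, function(cd)
      unname(geom$gaps[, geom$gap_y[cd]]))
  )
  attr(out, "n_anchors") <- res$n_anchors
  attr(out, "n_cell_checks") <- res$n_cell_checks
  out
}

#' Extract strictly valid single motifs
#'
#' The degenerate one-box case: every length-`k` factor of any input
#' sequence that e-occurs in at least `quorum` input sequences is reported.
#' Occurrence endpoints are deduplicated per motif string, so
#' `weighted_support` counts distinct (sequence, end position) pairs.
#'
#' @inheritParams extract_structured
#' @param k Window length.
#' @param e Error threshold, `e < k`.
#' @param quorum Quorum value; by default an absolute sequence count
#'   (matching the single-motif problem statement), or a percent ratio with
#'   `quorum_kind = "ratio"`.
#' @param quorum_kind `"absolute"` (default) or `"ratio"`.
#' @param model `"hamming"` or `"edit"`.
#' @return A `motif_set` tibble as in [extract_structured()]; `motif` is
#'   the bare k-mer.
#' @examples
#' ds <- tibble::tibble(id = c("s1", "s2"),
#'                      seq = c("CAAACCTTT", "CGAAAGTAT"))
#' extract_single(ds, k = 3, e = 0, quorum = 2)
#' @export
extract_single <- function(dataset, k, e, quorum,
                           quorum_kind = c("absolute", "ratio"),
                           model = c("hamming", "edit"),
                           engine = c("sliding", "bitparallel"),
                           rounding = c("ceiling", "floor")) {
  quorum_kind <- match.arg(quorum_kind)
  instance <- motif_instance(k = k, e = e, quorum = quorum,
                             quorum_kind = quorum_kind,
                             model = match.arg(model))
  extract_structured(dataset, instance, mode = "trivial",
                     engine = match.arg(engine),
                     rounding = match.arg(rounding))
}

# ------------------------------------------------------------------ internal

# Turn raw merge records into occurrence rows with rendered motif strings.
records_to_occurrences <- function(rec, dataset, instance, geom) {
  empty <- tibble::tibble(motif = character(), box_key = character(),
                          xid = integer(), yid = integer(),
                          i = integer(), j = integer(), cand = integer(),
                          occ_key = character())
  if (nrow(rec) == 0L) return(empty)
  beta <- instance$beta
  k <- instance$k
  xseq <- dataset$seq[rec$xid]
  boxes <- vector("list", beta)
  ends_y <- vector("list", beta)
  for (t in seq_len(beta)) {
    off <- if (t == 1L) 0L else geom$K[t - 1L] + geom$Vx[t - 1L, rec$cand]
    end_x <- rec$j + off
    boxes[[t]] <- substring(xseq, end_x - k[t] + 1L, end_x)
    ends_y[[t]] <- if (t == 1L) rec$i
                   else rec$i + geom$K[t - 1L] + geom$Vy[t - 1L, rec$cand]
  }
  ivs <- interval_strings(instance)
  pieces <- character(0)
  for (t in seq_len(beta)) {
    pieces <- if (t == 1L) boxes[[1L]]
              else paste0(pieces, ivs[t - 1L], boxes[[t]])
  }
  tibble::tibble(
    motif = pieces,
    box_key = do.call(paste, c(boxes, sep = "\t")),
    xid = rec$xid, yid = rec$yid, i = rec$i, j = rec$j, cand = rec$cand,
    occ_key = do.call(paste, c(ends_y, sep = ":"))
  )
}

# Deduplicate occurrences, count support, apply the quorum.
aggregate_reports <- function(occ, quorum) {
  empty <- tibble::tibble(motif = character(), boxes = list(),
                          support = integer(), weighted_support = integer(),
                          source_id = integer(), source_start = integer(),
                          source_cand = integer())
  if (nrow(occ) == 0L) return(empty)
  # one row per distinct (motif, sequence, endpoint tuple)
  occ <- occ[!duplicated(paste(occ$motif, occ$yid, occ$occ_key,
                               sep = "\r")), , drop = FALSE]
  u <- unique(occ$motif)
  gi <- match(occ$motif, u)
  weighted <- tabulate(gi, length(u))
  seq_hit <- !duplicated(paste(gi, occ$yid, sep = "\r"))
  support <- tabulate(gi[seq_hit], length(u))
  keep <- which(support >= quorum)
  keep <- keep[order(u[keep])]
  first_idx <- match(u[keep], occ$motif)
  tibble::tibble(
    motif = u[keep],
    boxes = strsplit(occ$box_key[first_idx], "\t", fixed = TRUE),
    support = support[keep],
    weighted_support = weighted[keep],
    source_id = occ$xid[first_idx],
    source_start = occ$j[first_idx],
    source_cand = occ$cand[first_idx]
  )
}

new_motif_set <- function(reports, dataset, instance, quorum, mode, engine) {
  k1 <- instance$k[1]
  geom <- merge_geometry(instance)
  out <- tibble::tibble(
    motif = reports$motif,
    boxes = reports$boxes,
    support = as.integer(reports$support),
    weighted_support = as.integer(reports$weighted_support),
    source_id = dataset$id[reports$source_id],
    source_start = as.integer(reports$source_start - k1 + 1L),
    source_gaps = lapply(reports$source_cand, function(cd)
      if (instance$gamma == 0L) integer(0)
      else unname(geom$gaps[, geom$gap_x[cd]]))
  )
  structure(out,
            instance = instance, n_seq = nrow(dataset), quorum = quorum,
            mode = mode, engine = engine,
            class = c("motif_set", class(tibble::tibble())))
}
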