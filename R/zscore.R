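#' Directly scan a dataset for occurrences of one motif
#'
#' Sliding-window test of an (e_i)-occurrence with in-interval gaps,
#' independent of the matrix machinery (it doubles as a soundness oracle
#' for the extraction path). Occurrences are counted as distinct per-box
#' end-position tuples. Under the edit model each box is matched as the
#' best factor ending at a position, and gaps are measured between nominal
#' window starts, so gap lengths carry up to `e` slack per box.
#'
#' @param dataset Dataset tibble (`id`, `seq`) or named character vector.
#' @param boxes Character vector of box strings (a single motif).
#' @param instance A [motif_instance()] supplying `e`, the intervals and
#'   the model; its `k` must match `nchar(boxes)`.
#' @return A list with `support` (sequences containing at least one
#'   occurrence) and `weighted_support` (total occurrences), plus
#'   `per_sequence` counts.
#' @examples
#' ds <- tibble::tibble(id = c("s1", "s2"),
#'                      seq = c("CAAACCTTT", "CGAAAGTAT"))
#' ins <- parse_instance("(3,0)[1,2](3,1),2", quorum_kind = "absolute")
#' occurrence_scan(ds, c("AAA", "TTT"), ins)$support  # 2
#' @export
occurrence_scan <- function(dataset, boxes, instance) {
  if (is.character(instance)) instance <- parse_instance(instance)
  stopifnot(inherits(instance, "motif_instance"),
            length(boxes) == instance$beta,
            all(nchar(boxes) == instance$k))
  dataset <- as_dataset(dataset, min_n = 1L)
  counts <- cpp_occurrence_scan(dataset$seq, toupper(boxes), instance$e,
                                instance$dmin, instance$dmax,
                                instance$model == "edit")
  list(support = sum(counts > 0),
       weighted_support = sum(counts),
       per_sequence = setNames(counts, dataset$id))
}

#' z-score significance ranking of reported motifs
#'
#' Post-analysis in the style of classic motif-significance tools: each
#' motif's support and weighted support are recomputed (by direct
#' occurrence scan, not re-extraction) in `replicates` randomized versions
#' of the input dataset, and the observed counts are standardized against
#' the randomized mean and standard deviation,
#' `z = (observed - mean) / max(sd, sd_floor)`. Motifs are ranked by
#' descending z-score (ties broken lexicographically by motif string),
#' once for support and once for weighted support.
#'
#' Randomization is a per-sequence letter shuffle by default
#' (composition-preserving); `randomization = "subsample"` instead scores
#' each motif against random subsets of the sequences.
#'
#' @param reports A `motif_set` from [extract_structured()] /
#'   [extract_single()].
#' @param dataset The dataset the reports were extracted from.
#' @param instance The [motif_instance()] used; defaults to the one stored
#'   on `reports`.
#' @param replicates Number of randomized datasets (default 50).
#' @param randomization `"shuffle"` (default) or `"subsample"`.
#' @param subsample_fraction Fraction of sequences kept per subsample.
#' @param sd_floor Lower bound on the randomized standard deviation (in
#'   count units) so that motifs never seen in the randomized data still
#'   get a finite z-score; default 1.
#' @param seed Optional integer seed.
#' @return `reports` with columns `z_support`, `z_weighted`,
#'   `rank_support`, `rank_weighted` appended (ranks are a permutation of
#'   `1..nrow(reports)`).
#' @export
motif_zscores <- function(reports, dataset,
                          instance = attr(reports, "instance"),
                          replicates = 50,
                          randomization = c("shuffle", "subsample"),
                          subsample_fraction = 0.5,
                          sd_floor = 1, seed = NULL) {
  randomization <- match.arg(randomization)
  if (is.character(instance)) instance <- parse_instance(instance)
  stopifnot(inherits(instance, "motif_instance"),
            replicates >= 1, sd_floor > 0)
  dataset <- as_dataset(dataset, min_n = 1L)
  if (!is.null(seed)) set.seed(seed)
  n_mot <- nrow(reports)
  if (n_mot == 0L) {
    out <- dplyr::mutate(reports, z_support = numeric(0),
                         z_weighted = numeric(0),
                         rank_support = integer(0),
                         rank_weighted = integer(0))
    return(preserve_motif_set(out, reports))
  }
  sup <- matrix(0, nrow = n_mot, ncol = replicates)
  wsup <- matrix(0, nrow = n_mot, ncol = replicates)
  for (r in seq_len(replicates)) {
    rnd <- randomize_dataset(dataset, randomization, subsample_fraction)
    for (mi in seq_len(n_mot)) {
      counts <- cpp_occurrence_scan(rnd$seq, reports$boxes[[mi]],
                                    instance$e, instance$dmin,
                                    instance$dmax,
                                    instance$model == "edit")
      sup[mi, r] <- sum(counts > 0)
      wsup[mi, r] <- sum(counts)
    }
  }
  zs <- function(obs, mat) {
    mu <- rowMeans(mat)
    sdev <- apply(mat, 1, sd)
    if (replicates == 1L) sdev[] <- 0
    (obs - mu) / pmax(sdev, sd_floor)
  }
  z_support <- zs(reports$support, sup)
  z_weighted <- zs(reports$weighted_support, wsup)
  rank_of <- function(z) {
    ord <- order(-z, reports$motif)
    rk <- integer(n_mot)
    rk[ord] <- seq_len(n_mot)
    rk
  }
  out <- dplyr::mutate(tibble::as_tibble(reports),
                       z_support = z_support, z_weighted = z_weighted,
                       rank_support = rank_of(z_support),
                       rank_weighted = rank_of(z_weighted))
  preserve_motif_set(out, reports)
}

randomize_dataset <- function(dataset, randomization, fraction) {
  if (randomization == "shuffle") {
    dataset$seq <- vapply(strsplit(dataset$seq, ""), function(ch)
      paste(sample(ch), collapse = ""), "")
    dataset
  } else {
    keep <- sample.int(nrow(dataset),
                       max(1L, round(fraction * nrow(dataset))))
    dataset[sort(keep), ]
  }
}

preserve_motif_set <- function(out, template) {
  for (a in c("instance", "n_seq", "quorum", "mode", "engine"))
    attr(out, a) <- attr(template, a)
  class(out) <- class(template)
  out
}

#' Drop motifs that are also supported in an exclusion dataset
#'
#' Generic exclusion-region filtering: motifs whose support in a second
#' sequence set (e.g. coding regions) meets the given quorum ratio are
#' removed from the reports.
#'
#' @param reports A `motif_set`.
#' @param exclude_dataset Dataset tibble of exclusion sequences.
#' @param quorum_ratio Percent of exclusion sequences (in `(0, 100]`) at or
#'   above which a motif is dropped.
#' @param instance Instance used for scanning; defaults to the reports'.
#' @return The filtered `motif_set`.
#' @export
filter_excluded <- function(reports, exclude_dataset, quorum_ratio,
                            instance = attr(reports, "instance")) {
  if (is.character(instance)) instance <- parse_instance(instance)
  stopifnot(inherits(instance, "motif_instance"))
  exclude_dataset <- as_dataset(exclude_dataset, min_n = 1L)
  if (nrow(reports) == 0L) return(reports)
  qx <- quorum_size(quorum_ratio, nrow(exclude_dataset))
  drop <- vapply(reports$boxes, function(bx)
    occurrence_scan(exclude_dataset, bx, instance)$support >= qx, TRUE)
  preserve_motif_set(tibble::as_tibble(reports)[!drop, ], reports)
}
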