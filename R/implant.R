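#' Generate a uniform random background dataset
#'
#' I.i.d. uniform letters over the alphabet; a stand-in for a downloaded
#' background sequence set so benchmarks need no external data.
#'
#' @param n_seq Number of sequences.
#' @param length Letters per sequence (recycled to `n_seq`).
#' @param alphabet Alphabet (default DNA).
#' @param seed Optional integer seed for reproducibility; `NULL` uses the
#'   current RNG state.
#' @return A dataset tibble (`id`, `seq`).
#' @export
generate_background <- function(n_seq, length, alphabet = dna_alphabet(),
                                seed = NULL) {
  stopifnot(n_seq >= 1, all(length >= 1))
  if (!is.null(seed)) set.seed(seed)
  len <- rep_len(as.integer(length), n_seq)
  tibble::tibble(
    id = sprintf("bg%04d", seq_len(n_seq)),
    seq = vapply(len, function(L)
      paste(sample(alphabet, L, replace = TRUE), collapse = ""), "")
  )
}

#' Implant structured motifs into a background dataset
#'
#' Implements the planted-motif benchmark protocol. For each of `n_motifs`
#' motifs: (1) consensus boxes are drawn uniformly from the alphabet;
#' (2)–(3) `q` target sequences are selected uniformly without replacement;
#' (4) in each target, an instance of the motif is built by choosing
#' exactly `e_i` positions per box and replacing each with a uniformly
#' drawn alphabet letter (so the realized error count may be smaller —
#' `mutation = "strict"` forces a different letter), generating spacers of
#' uniform length within each interval with uniform letters, and replacing
#' a uniformly chosen factor of the instance's length with it.
#'
#' With `collisions = "reject"` (default) the replacement window may not
#' overlap a previously implanted window, keeping the ground truth intact;
#' if a selected sequence has no free window, another sequence with space
#' is drawn in its place. `collisions = "overwrite"` places windows
#' anywhere, which can destroy earlier implants.
#'
#' @param dataset Background dataset tibble (`id`, `seq`).
#' @param instance A [motif_instance()]; its error thresholds, intervals
#'   and quorum drive the implantation.
#' @param n_motifs Number of motifs to implant.
#' @param targets Number of target sequences per motif; default is the
#'   instance quorum resolved against the dataset size.
#' @param seed Optional integer seed.
#' @param mutation `"redraw"` (default; protocol-faithful) or `"strict"`.
#' @param collisions `"reject"` (default) or `"overwrite"`.
#' @param alphabet Alphabet (default DNA).
#' @return An object of class `implant_result`: list with `dataset` (the
#'   mutated tibble), `consensus` (tibble: `motif_id`, `motif` rendered
#'   string, `boxes`), and `truth` (tibble: `motif_id`, `seq_id`, `start`,
#'   `gaps` list-column, `instance` string actually written).
#' @export
implant_motifs <- function(dataset, instance, n_motifs = 1, targets = NULL,
                           seed = NULL, mutation = c("redraw", "strict"),
                           collisions = c("reject", "overwrite"),
                           alphabet = dna_alphabet()) {
  mutation <- match.arg(mutation)
  collisions <- match.arg(collisions)
  if (is.character(instance)) instance <- parse_instance(instance)
  stopifnot(inherits(instance, "motif_instance"))
  dataset <- as_dataset(dataset, min_n = 1L)
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(dataset)
  q <- if (is.null(targets)) resolve_quorum(instance, N) else as.integer(targets)
  stopifnot(q >= 1, q <= N)
  max_span <- instance_max_span(instance)
  if (min(nchar(dataset$seq)) < max_span)
    stop(sprintf(
      "every sequence must be able to host the longest instance (%d letters)",
      max_span), call. = FALSE)
  seqs <- dataset$seq
  lens <- nchar(seqs)
  occupied <- lapply(lens, function(L) logical(L))
  ivs <- interval_strings(instance)

  consensus <- vector("list", n_motifs)
  truth <- vector("list", n_motifs)
  for (m in seq_len(n_motifs)) {
    boxes <- vapply(instance$k, function(kk)
      paste(sample(alphabet, kk, replace = TRUE), collapse = ""), "")
    chosen <- sample.int(N, q)
    rows <- vector("list", q)
    for (ti in seq_len(q)) {
      s <- chosen[ti]
      inst <- build_instance_string(boxes, instance, mutation, alphabet)
      pos <- place_window(occupied[[s]], nchar(inst$string), collisions)
      if (is.na(pos)) {
        # crowded sequence: draw a replacement target with space
        others <- setdiff(sample.int(N), chosen)
        for (alt in others) {
          pos <- place_window(occupied[[alt]], nchar(inst$string), collisions)
          if (!is.na(pos)) { s <- alt; chosen[ti] <- alt; break }
        }
        if (is.na(pos))
          stop("no sequence can host another implant; dataset too crowded",
               call. = FALSE)
      }
      substr(seqs[s], pos, pos + nchar(inst$string) - 1L) <- inst$string
      if (collisions == "reject")
        occupied[[s]][pos:(pos + nchar(inst$string) - 1L)] <- TRUE
      rows[[ti]] <- tibble::tibble(
        motif_id = m, seq_id = dataset$id[s], start = pos,
        gaps = list(inst$gaps), instance = inst$string)
    }
    consensus[[m]] <- tibble::tibble(
      motif_id = m,
      motif = paste0(boxes[1], if (instance$beta > 1L)
        paste0(ivs, boxes[-1], collapse = "") else ""),
      boxes = list(boxes))
    truth[[m]] <- dplyr::bind_rows(rows)
  }
  out <- dataset
  out$seq <- seqs
  structure(list(dataset = out,
                 consensus = dplyr::bind_rows(consensus),
                 truth = dplyr::bind_rows(truth),
                 instance = instance),
            class = "implant_result")
}

#' @export
print.implant_result <- function(x, ...) {
  cat(sprintf(
    "implant_result: %d motif(s) x %d target(s) in %d sequences [%s]\n",
    nrow(x$consensus), nrow(x$truth) / max(1L, nrow(x$consensus)),
    nrow(x$dataset), render_instance(x$instance)))
  invisible(x)
}

# mutate boxes, draw spacers, assemble one instance string
build_instance_string <- function(boxes, instance, mutation, alphabet) {
  mut <- character(length(boxes))
  for (b in seq_along(boxes)) {
    letters_b <- strsplit(boxes[b], "")[[1]]
    eb <- instance$e[b]
    if (eb > 0L) {
      pos <- sample.int(instance$k[b], eb)
      for (p in pos) {
        pool <- if (mutation == "strict") setdiff(alphabet, letters_b[p])
                else alphabet
        letters_b[p] <- sample(pool, 1L)
      }
    }
    mut[b] <- paste(letters_b, collapse = "")
  }
  gaps <- integer(instance$gamma)
  spacers <- character(instance$gamma)
  for (t in seq_len(instance$gamma)) {
    gaps[t] <- if (instance$dmax[t] > instance$dmin[t])
      sample(instance$dmin[t]:instance$dmax[t], 1L) else instance$dmin[t]
    spacers[t] <- if (gaps[t] > 0L)
      paste(sample(alphabet, gaps[t], replace = TRUE), collapse = "") else ""
  }
  string <- mut[1]
  for (t in seq_len(instance$gamma))
    string <- paste0(string, spacers[t], mut[t + 1L])
  list(string = string, gaps = gaps, boxes = mut)
}

# uniform free start position, or NA if none
place_window <- function(occ, len, collisions) {
  L <- length(occ)
  if (L < len) return(NA_integer_)
  if (collisions == "overwrite") return(sample.int(L - len + 1L, 1L))
  blocked <- c(0L, cumsum(occ))
  starts <- seq_len(L - len + 1L)
  free <- (blocked[starts + len] - blocked[starts]) == 0L
  ok <- starts[free]
  if (length(ok) == 0L) return(NA_integer_)
  ok[sample.int(length(ok), 1L)]
}

#' Compare extraction reports with implantation ground truth
#'
#' @param reports A `motif_set` (or tibble with a `motif` column).
#' @param implants An `implant_result` (or its `consensus` tibble).
#' @return A one-row tibble: `implanted`, `identified` (consensus motifs
#'   whose rendered string appears verbatim in the reports), `extracted`
#'   (total motifs reported).
#' @export
evaluate_identification <- function(reports, implants) {
  consensus <- if (inherits(implants, "implant_result")) implants$consensus
               else implants
  tibble::tibble(
    implanted = nrow(consensus),
    identified = sum(consensus$motif %in% reports$motif),
    extracted = nrow(tibble::as_tibble(reports))
  )
}
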