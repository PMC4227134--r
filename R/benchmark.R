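#' Run the planted-motif accuracy benchmark end to end
#'
#' Generates a uniform random background, implants `n_motifs` structured
#' motifs per the implantation protocol (the instance quorum decides how
#' many target sequences each motif receives), re-extracts with the same
#' instance, and counts how many implanted consensus motifs appear
#' verbatim in the reports. Optionally computes z-score ranks for the
#' reported motifs and records the rank of the implanted motif.
#'
#' @param instance A [motif_instance()] (or instance string).
#' @param n_motifs Motifs to implant.
#' @param n_seq,seq_len Background size: number of sequences and letters
#'   per sequence.
#' @param seed Optional integer seed covering background, implantation and
#'   z-score randomization.
#' @param zscore Compute z-score ranks for the reports (default FALSE).
#' @param replicates Randomized replicates for the z-scores.
#' @param mode,engine Passed to [extract_structured()].
#' @param collisions Passed to [implant_motifs()].
#' @return A list with `summary` (one-row tibble: `implanted`,
#'   `identified`, `extracted`, and when `zscore = TRUE` the implanted
#'   motif's `rank_support` / `rank_weighted`), `reports`, and `implants`.
#' @examples
#' \donttest{
#' res <- run_implant_benchmark("(3,0)[2,2](5,0),7", n_motifs = 1,
#'                              n_seq = 60, seq_len = 120, seed = 7,
#'                              zscore = TRUE, replicates = 10)
#' res$summary
#' }
#' @export
run_implant_benchmark <- function(instance, n_motifs, n_seq, seq_len,
                                  seed = NULL, zscore = FALSE,
                                  replicates = 50,
                                  mode = c("pruned", "trivial"),
                                  engine = c("sliding", "bitparallel"),
                                  collisions = c("reject", "overwrite")) {
  if (is.character(instance)) instance <- parse_instance(instance)
  if (!is.null(seed)) set.seed(seed)
  background <- generate_background(n_seq, seq_len)
  implants <- implant_motifs(background, instance, n_motifs = n_motifs,
                             collisions = match.arg(collisions))
  reports <- extract_structured(implants$dataset, instance,
                                mode = match.arg(mode),
                                engine = match.arg(engine))
  summary <- evaluate_identification(reports, implants)
  if (zscore) {
    reports <- motif_zscores(reports, implants$dataset, instance,
                             replicates = replicates)
    hit <- match(implants$consensus$motif, reports$motif)
    summary$rank_support <- if (all(is.na(hit))) NA_integer_
      else min(reports$rank_support[hit], na.rm = TRUE)
    summary$rank_weighted <- if (all(is.na(hit))) NA_integer_
      else min(reports$rank_weighted[hit], na.rm = TRUE)
  }
  list(summary = summary, reports = reports, implants = implants)
}
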