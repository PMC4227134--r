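#' @export
print.motif_set <- function(x, ...) {
  ins <- attr(x, "instance")
  cat(sprintf("# motif_set: %d motif(s) | instance %s | N=%d, quorum=%d, %s/%s\n",
              nrow(x), render_instance(ins), attr(x, "n_seq"),
              attr(x, "quorum"), ins$model, attr(x, "mode")))
  NextMethod()
}

#' Tidy a motif set
#'
#' Returns the reports as a plain tibble (one row per motif), ordered by
#' descending support then motif string.
#'
#' @param x A `motif_set` from [extract_structured()] or
#'   [extract_single()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy motif_set
#' @export
tidy.motif_set <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$motif)
}

#' One-row summary of a motif set
#'
#' @param x A `motif_set`.
#' @param ... Unused.
#' @return A one-row tibble: instance string, distance model, merge mode,
#'   dataset size, resolved quorum, number of motifs, and the maximum
#'   support observed.
#' @method glance motif_set
#' @export
glance.motif_set <- function(x, ...) {
  ins <- attr(x, "instance")
  tibble::tibble(
    instance = render_instance(ins),
    model = ins$model,
    mode = attr(x, "mode"),
    n_seq = attr(x, "n_seq"),
    quorum = attr(x, "quorum"),
    n_motifs = nrow(x),
    max_support = if (nrow(x)) max(x$support) else NA_integer_
  )
}

#' Bar chart of motif support
#'
#' Shows support and weighted support for the top motifs (by support).
#'
#' @param object A `motif_set`.
#' @param top Number of motifs to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motif_set
#' @export
autoplot.motif_set <- function(object, top = 20, ...) {
  df <- tidy.motif_set(object) |>
    head(top) |>
    dplyr::select("motif", "support", "weighted_support") |>
    tidyr::pivot_longer(c("support", "weighted_support"),
                        names_to = "measure", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$motif, .data$count),
    y = .data$count, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sequences / occurrences",
                  title = "Motif support") +
    ggplot2::theme_minimal()
}

#' Write a motif report file
#'
#' Writes one line per motif with tab-separated fields `motif`, `support`,
#' `weighted_support` (plus z-scores and ranks when present), preceded by
#' `#`-prefixed metadata lines (instance, dataset size, quorum, distance
#' model). `dialect = "smile"` emits the same columns in the order used by
#' z-score post-analysis tools (a documented TSV dialect; positions are
#' 1-based, intervals inclusive).
#'
#' @param reports A `motif_set` (or compatible tibble with at least
#'   `motif`, `support`, `weighted_support`).
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"smile"`.
#' @param extra_header Additional `#`-prefixed metadata lines (e.g. run
#'   configuration, seed).
#' @return The path, invisibly.
#' @export
write_motif_report <- function(reports, path, dialect = c("tsv", "smile"),
                               extra_header = character()) {
  dialect <- match.arg(dialect)
  cols <- intersect(c("motif", "support", "weighted_support",
                      "z_support", "z_weighted",
                      "rank_support", "rank_weighted"),
                    names(reports))
  df <- tibble::as_tibble(reports)[, cols, drop = FALSE]
  ins <- attr(reports, "instance")
  hdr <- c(
    sprintf("# motifbox %s report", dialect),
    if (!is.null(ins)) sprintf("# instance: %s", render_instance(ins)),
    if (!is.null(attr(reports, "n_seq")))
      sprintf("# sequences: %d  quorum: %d", attr(reports, "n_seq"),
              attr(reports, "quorum")),
    "# coordinates: 1-based, intervals inclusive",
    extra_header
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(df) > 0L) {
    lines <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a motif report file written by [write_motif_report()]
#'
#' @param path Report path.
#' @return A tibble.
#' @export
read_motif_report <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
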