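#' Describe a motif extraction problem instance
#'
#' A problem instance bundles the box specifications (window lengths `k` and
#' error thresholds `e`), the spacer length intervals between consecutive
#' boxes, the quorum, and the distance model. With `beta = length(k)` boxes
#' there must be `beta - 1` gap intervals; `beta = 1` describes single-motif
#' extraction.
#'
#' Derived quantities: `gamma = beta - 1` (number of intervals) and
#' `delta = max(dmax - dmin + 1)` (widest interval; `delta = 1` when all
#' gaps are fixed). Per anchor occurrence of the first box there are
#' `delta^gamma` possible spacer-length sequences in each of the two
#' sequences of a pair, hence up to `delta^(2*gamma)` candidate gap-vector
#' pairs to merge.
#'
#' @param k Integer vector of box window lengths (letters), one per box.
#' @param e Integer vector of per-box error thresholds, `0 <= e < k`.
#' @param dmin,dmax Integer vectors of length `length(k) - 1`: inclusive
#'   bounds on the number of letters strictly between consecutive boxes.
#' @param quorum Quorum value: a percentage of sequences when
#'   `quorum_kind = "ratio"` (in `(0, 100]`), or an absolute sequence count
#'   when `quorum_kind = "absolute"`.
#' @param quorum_kind Either `"ratio"` (default) or `"absolute"`.
#' @param model Distance model, `"hamming"` (default) or `"edit"`.
#' @return An object of class `motif_instance`.
#' @examples
#' motif_instance(k = c(3, 3), e = c(0, 1), dmin = 1, dmax = 2,
#'                quorum = 2, quorum_kind = "absolute")
#' parse_instance("(8,1)[3,3](8,1),7")
#' @export
motif_instance <- function(k, e, dmin = integer(), dmax = integer(),
                           quorum = 100, quorum_kind = c("ratio", "absolute"),
                           model = c("hamming", "edit")) {
  quorum_kind <- match.arg(quorum_kind)
  model <- match.arg(model)
  k <- as.integer(k); e <- as.integer(e)
  dmin <- as.integer(dmin); dmax <- as.integer(dmax)
  if (length(k) < 1L) stop("at least one box is required", call. = FALSE)
  if (length(e) != length(k)) stop("`e` must have one entry per box", call. = FALSE)
  if (any(k < 1L)) stop("box lengths `k` must be >= 1", call. = FALSE)
  if (any(e < 0L) || any(e >= k))
    stop("error thresholds must satisfy 0 <= e < k for every box", call. = FALSE)
  beta <- length(k)
  if (length(dmin) != beta - 1L || length(dmax) != beta - 1L)
    stop(sprintf("%d boxes require %d gap interval(s), got %d",
                 beta, beta - 1L, length(dmin)), call. = FALSE)
  if (any(dmin < 0L)) stop("`dmin` must be >= 0", call. = FALSE)
  if (any(dmin > dmax)) stop("`dmin` must not exceed `dmax`", call. = FALSE)
  if (length(quorum) != 1L || !is.finite(quorum))
    stop("`quorum` must be a single finite number", call. = FALSE)
  if (quorum_kind == "ratio" && (quorum <= 0 || quorum > 100))
    stop("quorum ratio must lie in (0, 100]", call. = FALSE)
  if (quorum_kind == "absolute" && (quorum < 1 || quorum != floor(quorum)))
    stop("absolute quorum must be a positive integer", call. = FALSE)
  structure(
    list(k = k, e = e, dmin = dmin, dmax = dmax,
         beta = beta, gamma = beta - 1L,
         delta = if (beta > 1L) max(dmax - dmin + 1L) else 1L,
         quorum = as.numeric(quorum), quorum_kind = quorum_kind,
         model = model),
    class = "motif_instance"
  )
}

#' Parse a problem-instance string
#'
#' Parses the compact notation `"(k1,e1)[dmin1,dmax1](k2,e2)...,q"` — boxes
#' as `(k,e)` pairs alternating with gap intervals `[dmin,dmax]`, followed
#' by a trailing comma and the quorum. By default the quorum is a ratio
#' (percent of sequences); pass `quorum_kind = "absolute"` for an absolute
#' count.
#'
#' @param text Instance string, e.g. `"(8,1)[3,3](8,1),7"`.
#' @inheritParams motif_instance
#' @return A [motif_instance()].
#' @export
parse_instance <- function(text, quorum_kind = c("ratio", "absolute"),
                           model = c("hamming", "edit")) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]<>]", "", text)
  body_re <- "^(\\((\\d+),(\\d+)\\)(\\[(\\d+),(\\d+)\\])?)+,([0-9.]+)$"
  if (!grepl(body_re, s))
    stop("cannot parse instance string: ", text, call. = FALSE)
  quorum <- as.numeric(sub(".*,([0-9.]+)$", "\\1", s))
  body <- sub(",[0-9.]+$", "", s)
  boxes <- stringr::str_match_all(body, "\\((\\d+),(\\d+)\\)")[[1]]
  gaps <- stringr::str_match_all(body, "\\[(\\d+),(\\d+)\\]")[[1]]
  # boxes and intervals must strictly alternate: (k,e)[a,b](k,e)...
  tokens <- stringr::str_extract_all(body, "\\([^)]*\\)|\\[[^]]*\\]")[[1]]
  expected <- rep(c("(", "["), length.out = length(tokens))
  if (!all(substr(tokens, 1, 1) == expected) ||
      nrow(gaps) != nrow(boxes) - 1L)
    stop("boxes and gap intervals must alternate: (k,e)[a,b](k,e)...,q",
         call. = FALSE)
  motif_instance(
    k = as.integer(boxes[, 2]), e = as.integer(boxes[, 3]),
    dmin = as.integer(gaps[, 2]), dmax = as.integer(gaps[, 3]),
    quorum = quorum, quorum_kind = quorum_kind, model = model
  )
}

#' Render an instance back to its compact string form
#'
#' Inverse of [parse_instance()] on canonical strings (the quorum is printed
#' without trailing zeros).
#'
#' @param instance A [motif_instance()].
#' @return A single string.
#' @export
render_instance <- function(instance) {
  stopifnot(inherits(instance, "motif_instance"))
  boxes <- sprintf("(%d,%d)", instance$k, instance$e)
  gaps <- sprintf("[%d,%d]", instance$dmin, instance$dmax)
  body <- paste0(boxes, c(gaps, ""), collapse = "")
  paste0(body, ",", format(instance$quorum, trim = TRUE, scientific = FALSE))
}

#' @export
format.motif_instance <- function(x, ...) {
  sprintf("<motif_instance %s | %s quorum, %s model, beta=%d gamma=%d delta=%d>",
          render_instance(x), x$quorum_kind, x$model, x$beta, x$gamma, x$delta)
}

#' @export
print.motif_instance <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Absolute quorum from a quorum ratio
#'
#' Converts a quorum ratio `q'` (percent) into an absolute sequence count
#' `q` for a dataset of `N` sequences. The quorum is a lower bound ("at
#' least q sequences"), so the default rounds up — rounding down could admit
#' under-supported motifs; `rounding = "floor"` is available for
#' compatibility experiments. The result is clamped to `[1, N]`.
#'
#' @param q_prime Quorum ratio in percent, in `(0, 100]`.
#' @param n_seq Number of sequences `N`.
#' @param rounding `"ceiling"` (default) or `"floor"`.
#' @return Integer quorum in `[1, N]`.
#' @examples
#' quorum_size(7, 1062)   # 75
#' quorum_size(15, 1062)  # 160
#' @export
quorum_size <- function(q_prime, n_seq, rounding = c("ceiling", "floor")) {
  rounding <- match.arg(rounding)
  stopifnot(length(q_prime) == 1L, q_prime > 0, q_prime <= 100,
            length(n_seq) == 1L, n_seq >= 1)
  raw <- q_prime * n_seq / 100
  # guard against floating-point drift on exact integer ratios
  q <- if (rounding == "ceiling") ceiling(raw - 1e-9) else floor(raw + 1e-9)
  as.integer(min(max(q, 1), n_seq))
}

#' Resolve an instance's quorum against a dataset size
#'
#' @param instance A [motif_instance()].
#' @param n_seq Number of sequences in the dataset.
#' @inheritParams quorum_size
#' @return Integer absolute quorum.
#' @export
resolve_quorum <- function(instance, n_seq, rounding = c("ceiling", "floor")) {
  stopifnot(inherits(instance, "motif_instance"))
  if (instance$quorum_kind == "absolute") {
    q <- as.integer(instance$quorum)
    if (q > n_seq)
      stop(sprintf("absolute quorum %d exceeds dataset size %d", q, n_seq),
           call. = FALSE)
    q
  } else {
    quorum_size(instance$quorum, n_seq, rounding)
  }
}

# total span in letters of the longest possible exact occurrence
instance_max_span <- function(instance) {
  sum(instance$k) + if (instance$gamma > 0L) sum(instance$dmax) else 0L
}

instance_min_span <- function(instance) {
  sum(instance$k) + if (instance$gamma > 0L) sum(instance$dmin) else 0L
}

# interval strings used when rendering motifs, e.g. "[1,2]"
interval_strings <- function(instance) {
  if (instance$gamma == 0L) character(0)
  else sprintf("[%d,%d]", instance$dmin, instance$dmax)
}
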