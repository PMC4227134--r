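#' Arithmetic progressions of cumulative gap offsets
#'
#' For a structured instance, the cumulative spacer length after interval
#' `t` ranges over the inclusive prefix-sum progression
#' `p_t = [dmin_1 + ... + dmin_t, dmax_1 + ... + dmax_t]`. Two gap vectors
#' whose prefix sums agree at interval `t` address the same DP-matrix cell
#' there, so per anchor only `sum(|p_t|^2)` distinct cells ever need
#' inspection instead of the `gamma * delta^(2*gamma)` cell references of
#' trivial enumeration — and one failing cell invalidates every candidate
#' gap-vector pair routed through it. The progressions and the
#' cell-to-candidate association depend only on the instance, so they are
#' precomputed once and reused for every sequence pair.
#'
#' @param instance A [motif_instance()] with at least two boxes.
#' @return An object of class `gap_progressions`: a list with elements
#'   `p` (list of the `gamma` progressions), `n_cells`
#'   (`sum(lengths(p)^2)`), `n_distance_seqs` (`delta^gamma`-style count of
#'   spacer-length sequences in one string), `n_candidates` (gap-vector
#'   pairs per anchor), `n_cell_refs_trivial`
#'   (`gamma * n_candidates` cell references touched by trivial
#'   enumeration), `gaps` (matrix of gap vectors, one column per
#'   spacer-length sequence), `Vx`/`Vy` (`gamma x n_candidates` prefix-sum
#'   offsets of each candidate in the source/occurrence string), and
#'   `cell_candidates` (tibble mapping each interval cell `(v_y, v_x)` to
#'   the candidate ids routed through it).
#' @examples
#' ins <- motif_instance(k = c(3, 3, 3), e = c(0, 0, 0),
#'                       dmin = c(1, 4), dmax = c(2, 5))
#' pr <- build_progressions(ins)
#' pr$p          # offsets 1:2 and 5:7
#' pr$n_cells    # 13
#' @export
build_progressions <- function(instance) {
  stopifnot(inherits(instance, "motif_instance"))
  if (instance$beta < 2L)
    stop("progressions require a structured instance (beta >= 2)",
         call. = FALSE)
  g <- instance$gamma
  pmin <- cumsum(instance$dmin)
  pmax <- cumsum(instance$dmax)
  p <- purrr::map2(pmin, pmax, seq.int)

  # spacer-length sequences for one string: all gap vectors, one per column
  grids <- purrr::map2(instance$dmin, instance$dmax, seq.int)
  gaps <- t(as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE)))
  dimnames(gaps) <- NULL
  n_seq <- ncol(gaps)
  V <- apply(gaps, 2, cumsum)
  if (g == 1L) V <- matrix(V, nrow = 1L)

  # candidates = ordered pairs (source gap vector, occurrence gap vector);
  # source index varies fastest
  ix <- rep(seq_len(n_seq), times = n_seq)
  iy <- rep(seq_len(n_seq), each = n_seq)
  Vx <- V[, ix, drop = FALSE]
  Vy <- V[, iy, drop = FALSE]
  n_cand <- n_seq * n_seq

  cell_candidates <- purrr::map_dfr(seq_len(g), function(t) {
    tidyr::expand_grid(interval = t, v_y = p[[t]], v_x = p[[t]])
  }) |>
    dplyr::mutate(candidates = purrr::pmap(
      list(.data$interval, .data$v_y, .data$v_x),
      function(t, vy, vx) which(Vy[t, ] == vy & Vx[t, ] == vx)
    ))

  structure(
    list(p = p, pmin = pmin, pmax = pmax,
         n_cells = as.integer(sum(lengths(p)^2)),
         n_distance_seqs = n_seq,
         n_candidates = n_cand,
         n_cell_refs_trivial = g * n_cand,
         gaps = gaps, gap_x = ix, gap_y = iy,
         Vx = Vx, Vy = Vy,
         cell_candidates = cell_candidates),
    class = "gap_progressions"
  )
}

#' Candidates invalidated by one failing cell
#'
#' Given the precomputed cell-to-candidate association, returns the ids of
#' the candidate gap-vector pairs that a failing DP cell at interval
#' `interval` with prefix-sum offsets `(v_y, v_x)` rules out.
#'
#' @param progressions A [build_progressions()] result.
#' @param interval Interval index (1-based).
#' @param v_y,v_x Prefix-sum offsets of the cell in the occurrence / source
#'   string.
#' @return Integer vector of candidate ids.
#' @export
cell_candidates <- function(progressions, interval, v_y, v_x) {
  stopifnot(inherits(progressions, "gap_progressions"))
  cc <- progressions$cell_candidates
  row <- cc[cc$interval == interval & cc$v_y == v_y & cc$v_x == v_x, ]
  if (nrow(row) == 0L) return(integer(0))
  row$candidates[[1]]
}

#' @export
print.gap_progressions <- function(x, ...) {
  cat(sprintf(
    "gap_progressions: %d interval(s), %d distinct cells, %d candidates (%d trivial cell refs)\n",
    length(x$p), x$n_cells, x$n_candidates, x$n_cell_refs_trivial))
  for (t in seq_along(x$p))
    cat(sprintf("  p_%d = {%s}\n", t, paste(x$p[[t]], collapse = ",")))
  invisible(x)
}

# Internal: merge-ready pieces for an instance (handles beta == 1 too).
merge_geometry <- function(instance) {
  if (instance$beta == 1L) {
    list(K = integer(0),
         Vx = matrix(integer(0), 0, 1), Vy = matrix(integer(0), 0, 1),
         pmin = integer(0), pmax = integer(0),
         gaps = matrix(integer(0), 0, 1),
         gap_x = 1L, gap_y = 1L, n_candidates = 1L)
  } else {
    pr <- build_progressions(instance)
    list(K = cumsum(instance$k[-1]),
         Vx = pr$Vx, Vy = pr$Vy, pmin = pr$pmin, pmax = pr$pmax,
         gaps = pr$gaps, gap_x = pr$gap_x, gap_y = pr$gap_y,
         n_candidates = pr$n_candidates)
  }
}
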