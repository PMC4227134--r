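#' Fixed-length approximate string matching matrix
#'
#' Computes the `(n+1) x (m+1)` distance matrix for an ordered pair of
#' strings and a window length `k`. Under the Hamming model, cell `[i, j]`
#' (1-based end positions, row `i` in `y`, column `j` in `x`) holds the
#' Hamming distance between the window of `y` ending at `i` and the window
#' of `x` ending at `j`; cells whose two windows have unequal lengths hold
#' the sentinel `k + 1` (an "infinity" strictly greater than any attainable
#' window distance — never written to reports). Under the edit model, cell
#' `[i, j]` holds the minimum edit distance between any factor of `y`
#' ending at `i` (the empty factor included) and the window of `x` ending
#' at `j` (the length-`min(j, k)` window).
#'
#' Three engines share this semantics: `"naive"` evaluates the per-cell
#' definition directly in R (the reference), `"sliding"` uses the O(1)
#' per-cell diagonal update (Hamming) or per-window dynamic programming
#' with column collation (edit), and `"bitparallel"` packs windows into
#' machine words (mismatch masks for Hamming, Myers-style bit vectors for
#' edit; requires `k <= 64`).
#'
#' @param x Source string (windows are drawn from `x`; columns).
#' @param y Target string (occurrences end in `y`; rows).
#' @param k Window length, `1 <= k <= min(nchar(x), nchar(y))`.
#' @param model `"hamming"` (default) or `"edit"`.
#' @param engine `"sliding"` (default), `"naive"`, or `"bitparallel"`.
#' @return An integer matrix of class `flasm_matrix` with attributes `k`,
#'   `model` and `sentinel`; `dimnames` give the 0-based end positions.
#' @examples
#' M <- flasm_matrix("CAAACCTTT", "CGAAAGTAT", k = 3)
#' matrix_cell(M, 5, 4)  # 0: AAA aligns exactly
#' matrix_cell(M, 9, 9)  # 1: TTT vs TAT
#' @export
flasm_matrix <- function(x, y, k, model = c("hamming", "edit"),
                         engine = c("sliding", "naive", "bitparallel")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  stopifnot(is.character(x), length(x) == 1L, is.character(y), length(y) == 1L)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  lim <- if (model == "hamming") min(nchar(x), nchar(y)) else nchar(x)
  if (k > lim)
    stop(sprintf("window length k=%d exceeds the admissible maximum %d",
                 k, lim), call. = FALSE)
  M <- switch(engine,
    naive = flasm_matrix_naive(x, y, k, model),
    sliding = cpp_flasm_matrix(x, y, k, model == "edit", FALSE),
    bitparallel = cpp_flasm_matrix(x, y, k, model == "edit", TRUE)
  )
  dimnames(M) <- list(0:nchar(y), 0:nchar(x))
  structure(M, k = k, model = model,
            sentinel = if (model == "hamming") k + 1L else NA_integer_,
            class = c("flasm_matrix", "matrix", "array"))
}

# Direct per-cell evaluation of the matrix definition (reference engine).
flasm_matrix_naive <- function(x, y, k, model) {
  n <- nchar(y); m <- nchar(x)
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  M <- matrix(0L, n + 1L, m + 1L)
  if (model == "hamming") {
    sent <- k + 1L
    for (i in 0:n) {
      for (j in 0:m) {
        leny <- min(i, k); lenx <- min(j, k)
        M[i + 1L, j + 1L] <- if (leny != lenx) sent
        else if (leny == 0L) 0L
        else sum(ys[(i - leny + 1L):i] != xs[(j - lenx + 1L):j])
      }
    }
  } else {
    for (j in 0:m) {
      L <- min(j, k)
      pat <- if (L > 0L) xs[(j - L + 1L):j] else character(0)
      # Sellers DP: free start in y (first column zero), pattern across
      prev <- 0:L
      M[1L, j + 1L] <- L
      for (i in seq_len(n)) {
        cur <- integer(L + 1L)
        if (L > 0L) {
          for (l in seq_len(L)) {
            cur[l + 1L] <- min(prev[l] + (ys[i] != pat[l]),
                               prev[l + 1L] + 1L, cur[l] + 1L)
          }
        }
        M[i + 1L, j + 1L] <- cur[L + 1L]
        prev <- cur
      }
    }
  }
  M
}

#' Read a matrix cell by 1-based end positions
#'
#' @param M A [flasm_matrix()].
#' @param i End position in `y` (row), `0 <= i <= nchar(y)`.
#' @param j End position in `x` (column), `0 <= j <= nchar(x)`.
#' @return The integer cell value.
#' @export
matrix_cell <- function(M, i, j) {
  stopifnot(inherits(M, "flasm_matrix"))
  unname(M[i + 1L, j + 1L])
}

#' Cells holding e-occurrences
#'
#' Returns the matrix cells `[i, j]` with value at most `e` and
#' `i, j >= k` — i.e. window `j` of `x` e-occurs in `y` ending at `i` — in
#' deterministic row-major order.
#'
#' @param M A [flasm_matrix()].
#' @param e Error threshold, `e < k`.
#' @return A tibble with columns `i`, `j`, `dist`.
#' @export
e_occurrences <- function(M, e) {
  stopifnot(inherits(M, "flasm_matrix"))
  k <- attr(M, "k")
  if (e >= k) stop("`e` must be smaller than the window length k", call. = FALSE)
  n <- nrow(M) - 1L; m <- ncol(M) - 1L
  sub <- unclass(M)[(k + 1L):(n + 1L), (k + 1L):(m + 1L), drop = FALSE]
  hit <- which(t(sub) <= e)  # transpose => row-major enumeration
  jj <- (hit - 1L) %% (m - k + 1L) + k
  ii <- (hit - 1L) %/% (m - k + 1L) + k
  tibble::tibble(i = ii, j = jj, dist = as.integer(t(sub)[hit]))
}

#' @export
print.flasm_matrix <- function(x, ...) {
  cat(sprintf("flasm_matrix: %s model, k=%d, %d x %d end positions\n",
              attr(x, "model"), attr(x, "k"), nrow(x) - 1L, ncol(x) - 1L))
  print(unclass(x), ...)
  invisible(x)
}

#' Heatmap of a fixed-length matching matrix
#'
#' Tiles the matrix with fill proportional to window distance; sentinel
#' (infinite) cells are blanked. Useful to eyeball where e-occurrences
#' cluster.
#'
#' @param object A [flasm_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flasm_matrix
#' @export
autoplot.flasm_matrix <- function(object, ...) {
  k <- attr(object, "k")
  sent <- attr(object, "sentinel")
  df <- tidyr::expand_grid(i = 0:(nrow(object) - 1L),
                           j = 0:(ncol(object) - 1L))
  df$dist <- as.vector(unclass(object))[df$i + 1L +
                                          df$j * nrow(object)]
  if (!is.na(sent)) df$dist[df$dist >= sent] <- NA_integer_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$dist)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey92") +
    ggplot2::labs(x = "end position in x", y = "end position in y",
                  fill = "distance",
                  title = sprintf("%s window distances, k = %d",
                                  attr(object, "model"), k)) +
    ggplot2::theme_minimal()
}
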