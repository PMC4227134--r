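# Brute-force oracles, fully independent of the package's matrix/merge code
# paths: plain substring loops and utils::adist only.

DNA <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = DNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_dataset <- function(n_seq, len, alphabet = DNA) {
  tibble::tibble(id = paste0("s", seq_len(n_seq)),
                 seq = vapply(rep_len(len, n_seq), rand_seq, "",
                              alphabet = alphabet))
}

# Hamming distance of `box` against every window of `seq`, named by end pos
oracle_box_ends <- local({
  cache <- new.env(parent = emptyenv())
  function(seq, box) {
    key <- paste(seq, box, sep = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    k <- nchar(box); n <- nchar(seq)
    if (k > n) return(setNames(integer(0), character(0)))
    ch <- strsplit(seq, "")[[1]]
    bv <- strsplit(box, "")[[1]]
    ends <- k:n
    d <- vapply(ends, function(e) sum(ch[(e - k + 1):e] != bv), 0L)
    res <- setNames(d, ends)
    cache[[key]] <- res
    res
  }
})

oracle_gap_vectors <- function(instance) {
  if (instance$gamma == 0L) return(matrix(integer(0), 0, 1))
  grids <- Map(seq.int, instance$dmin, instance$dmax)
  gv <- t(as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE)))
  dimnames(gv) <- NULL
  gv
}

oracle_render <- function(boxes, instance) {
  if (instance$gamma == 0L) return(boxes[1])
  ivs <- sprintf("[%d,%d]", instance$dmin, instance$dmax)
  paste0(boxes[1], paste0(ivs, boxes[-1], collapse = ""))
}

# every strictly valid arrangement present literally in one sequence
oracle_enumerate <- function(seq, instance) {
  k <- instance$k
  gv <- oracle_gap_vectors(instance)
  n <- nchar(seq)
  out <- character(0)
  for (g in seq_len(ncol(gv))) {
    gvec <- gv[, g]
    span <- sum(k) + sum(gvec)
    if (span > n) next
    for (st in seq_len(n - span + 1L)) {
      pos <- st
      boxes <- character(length(k))
      for (t in seq_along(k)) {
        boxes[t] <- substr(seq, pos, pos + k[t] - 1L)
        pos <- pos + k[t] + if (t < length(k)) gvec[t] else 0L
      }
      out <- c(out, oracle_render(boxes, instance))
    }
  }
  unique(out)
}

# number of distinct endpoint tuples realising an occurrence in one sequence
oracle_count_occurrences <- function(seq, boxes, instance) {
  occ <- lapply(seq_along(boxes), function(t) {
    d <- oracle_box_ends(seq, boxes[t])
    as.integer(names(d)[d <= instance$e[t]])
  })
  if (length(occ[[1]]) == 0L) return(0)
  count_from <- function(t, i) {
    if (t == length(boxes)) return(1)
    nxt <- i + nchar(boxes[t + 1L]) + instance$dmin[t]:instance$dmax[t]
    hits <- intersect(nxt, occ[[t + 1L]])
    if (length(hits) == 0L) return(0)
    sum(vapply(hits, function(i2) count_from(t + 1L, i2), 0))
  }
  sum(vapply(occ[[1]], function(i) count_from(1L, i), 0))
}

# full brute-force extraction: tibble(motif, support, weighted_support)
oracle_extract <- function(dataset, instance) {
  q <- if (instance$quorum_kind == "absolute") instance$quorum
       else min(max(ceiling(instance$quorum * nrow(dataset) / 100 - 1e-9), 1),
                nrow(dataset))
  motifs <- sort(unique(unlist(lapply(dataset$seq, oracle_enumerate,
                                      instance = instance))))
  if (length(motifs) == 0L) {
    return(tibble::tibble(motif = character(), support = integer(),
                          weighted_support = integer()))
  }
  box_lists <- strsplit(motifs, "\\[\\d+,\\d+\\]")
  rows <- lapply(seq_along(motifs), function(mi) {
    counts <- vapply(dataset$seq, oracle_count_occurrences, 0,
                     boxes = box_lists[[mi]], instance = instance)
    tibble::tibble(motif = motifs[mi], support = sum(counts > 0),
                   weighted_support = sum(counts))
  })
  out <- dplyr::bind_rows(rows)
  out[out$support >= q, ]
}

# exhaustive min-over-factors Levenshtein for one edit-matrix cell
oracle_edit_cell <- function(x, y, k, i, j) {
  L <- min(j, k)
  win <- substr(x, j - L + 1L, j)
  if (L == 0L) return(0L)
  facs <- c("", vapply(seq_len(max(i, 1L))[seq_len(i)],
                       function(s) substr(y, s, i), ""))
  min(utils::adist(facs, win))
}

example1_dataset <- function() {
  tibble::tibble(id = c("s1", "s2"), seq = c("CAAACCTTT", "CGAAAGTAT"))
}

example1_instance <- function() {
  parse_instance("(3,0)[1,2](3,1),2", quorum_kind = "absolute")
}

# a random structured instance within given complexity bounds
rand_instance <- function(beta = sample(2:3, 1), kmax = 5, emax = 1,
                          dmax_width = 2, quorum = 1) {
  k <- sample(2:kmax, beta, replace = TRUE)
  e <- vapply(k, function(kk) sample(0:min(emax, kk - 1L), 1L), 0L)
  dmin <- sample(0:3, beta - 1L, replace = TRUE)
  dmax <- dmin + sample(0:dmax_width, beta - 1L, replace = TRUE)
  motif_instance(k = k, e = e, dmin = dmin, dmax = dmax,
                 quorum = quorum, quorum_kind = "absolute")
}
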