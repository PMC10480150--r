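#' Dinucleotide-preserving sequence shuffle
#'
#' Random permutation of a sequence that preserves the exact multiset of
#' overlapping dinucleotides (hence also length, mononucleotide composition,
#' GC content, and the first and last nucleotide). Implemented by the
#' Altschul-Erikson Eulerian-path construction: the sequence is viewed as an
#' Eulerian walk over the 4-vertex dinucleotide multigraph and a random
#' Eulerian walk with the same edge multiset is drawn. This is the null
#' model used for secondary-structure distance significance, where "same
#' dinucleotide frequency" must mean the same *number* of each dinucleotide.
#'
#' @param t A single transcript; must have length >= 3 and contain no `N`.
#' @param seed Integer seed; the same seed always yields the same output.
#' @return The shuffled sequence as a character string (named like the
#'   input id with a `_shuf` suffix).
#' @examples
#' dinucleotide_shuffle("ACACGTGTAC", seed = 1)
#' @export
dinucleotide_shuffle <- function(t, seed) {
  s <- as_seq_char(t)
  n <- nchar(s)
  if (n < 3L) stop("sequence too short to shuffle (length < 3)")
  if (grepl("N", s, fixed = TRUE))
    stop("dinucleotide_shuffle requires a sequence without N")
  check_alphabet(s, seq_id(t))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  set.seed(as.integer(seed))

  first <- chars[1L]
  last <- chars[n]
  # outgoing edge target lists per vertex, in order of appearance
  edges <- split(chars[-1L], factor(chars[-n], levels = unique(chars[-n])))
  verts <- names(edges)

  # pick a designated last outgoing edge for every vertex except `last`
  # such that following last edges from any vertex reaches `last`
  # (i.e. the last edges form an arborescence into the end vertex)
  pick_last <- function() {
    cand <- lapply(edges, function(e) e[sample.int(length(e), 1L)])
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v
      seen <- character(0)
      repeat {
        if (cur == last) break
        if (cur %in% seen || !(cur %in% verts)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- cand[[cur]]
      }
      if (!ok) break
    }
    if (ok) cand else NULL
  }

  if (length(verts) == 1L && verts == last) {
    last_edge <- list()
  } else {
    repeat {
      last_edge <- pick_last()
      if (!is.null(last_edge)) break
    }
  }

  # shuffle the remaining edges per vertex; designated last edge goes last
  ordered <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v != last && v %in% names(last_edge)) {
      # remove one instance of the designated edge
      drop <- match(last_edge[[v]], e)
      rest <- e[-drop]
      c(rest[sample.int(length(rest))], last_edge[[v]])
    } else {
      e[sample.int(length(e))]
    }
  })
  names(ordered) <- verts

  # Eulerian walk from the first character, consuming edges in list order
  out <- character(n)
  out[1L] <- first
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- first
  for (i in 2L:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  res <- paste(out, collapse = "")
  names(res) <- paste0(seq_id(t), "_shuf")
  res
}

# overlapping dinucleotide counts, used by tests and generators
dinucleotide_counts <- function(t) {
  s <- as_seq_char(t)
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), width = 2L)
}
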