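#' Find tandem-repeat and homopolymer runs in a sequence
#'
#' Single definition of "tandem-repeat context", shared by the read
#' simulator (where indel errors are inflated inside context) and the
#' variant filters (where indels inside context are excluded). A
#' homopolymer is a unit-length-1 run of at least `min_hp` bases; a
#' multi-base tandem repeat has unit length 2..`max_unit`, at least
#' `min_copies` copies and a total span of at least `min_span` nt. Units
#' that are themselves periodic (e.g. `"AA"`, `"ATAT"`) are reported at
#' their minimal period only.
#'
#' @param seq Character scalar (nucleotide sequence).
#' @param max_unit Maximum repeat unit length (nt).
#' @param min_hp Minimum homopolymer run length.
#' @param min_copies Minimum copies for multi-base units.
#' @param min_span Minimum total span (nt) for multi-base units.
#' @return data.frame with columns `unit`, `unit_length`, `copies`,
#'   `start`, `end` (1-based inclusive spans).
#' @export
tandem_runs <- function(seq, max_unit = 4L, min_hp = 3L, min_copies = 2L,
                        min_span = 6L) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- list()

  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_hp
  if (any(keep))
    out[[1L]] <- data.frame(unit = r$values[keep], unit_length = 1L,
                            copies = r$lengths[keep],
                            start = starts[keep], end = ends[keep])

  for (u in 2:max_unit) {
    if (n < 2L * u) next
    eq <- chars[seq_len(n - u)] == chars[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span_len <- r$lengths[j] + u
      copies <- span_len %/% u
      if (copies < min_copies || span_len < min_span) next
      s <- starts[j]
      unit <- substr(seq, s, s + u - 1L)
      if (.min_period(unit) < u) next
      out[[length(out) + 1L]] <-
        data.frame(unit = unit, unit_length = u, copies = copies,
                   start = s, end = s + span_len - 1L)
    }
  }
  if (length(out) == 0L)
    return(data.frame(unit = character(0), unit_length = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.min_period <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (identical(strrep(substr(unit, 1L, d), u %/% d), unit)) return(d)
  }
  u
}

#' Per-base tandem-repeat context mask
#'
#' @inheritParams tandem_runs
#' @return Logical vector of length `nchar(seq)`, `TRUE` where the base
#'   lies inside a tandem-repeat or homopolymer run.
#' @export
tandem_mask <- function(seq, max_unit = 4L, min_hp = 3L, min_copies = 2L,
                        min_span = 6L) {
  runs <- tandem_runs(seq, max_unit, min_hp, min_copies, min_span)
  mask <- rep(FALSE, nchar(seq))
  for (i in seq_len(nrow(runs))) mask[runs$start[i]:runs$end[i]] <- TRUE
  mask
}

#' Tandem-repeat context at one reference position
#'
#' Scans repeat units of length 1..`max_unit` and reports the context
#' covering `pos` with the longest total span (ties broken toward the
#' shortest unit). Used to decide whether an indel call sits in the
#' error-prone repeat context that nanopore sequencing resolves poorly.
#'
#' @param reference Character scalar reference sequence.
#' @param pos 1-based position.
#' @inheritParams tandem_runs
#' @return Object of class `repeat_context`: `is_tandem`, `unit`,
#'   `unit_length`, `copies`, `span` (`c(start, end)`), `pos`.
#' @export
detect_repeat_context <- function(reference, pos, max_unit = 4L,
                                  min_hp = 3L, min_copies = 2L,
                                  min_span = 6L) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L || pos > nchar(reference))
    stop("position out of reference bounds")
  runs <- tandem_runs(reference, max_unit, min_hp, min_copies, min_span)
  hit <- runs[runs$start <= pos & runs$end >= pos, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(structure(list(is_tandem = FALSE, unit = NA_character_,
                          unit_length = NA_integer_, copies = NA_integer_,
                          span = c(NA_integer_, NA_integer_), pos = pos),
                     class = "repeat_context"))
  hit$span_len <- hit$end - hit$start + 1L
  hit <- hit[order(-hit$span_len, hit$unit_length), , drop = FALSE]
  structure(list(is_tandem = TRUE, unit = hit$unit[1L],
                 unit_length = hit$unit_length[1L],
                 copies = hit$copies[1L],
                 span = c(hit$start[1L], hit$end[1L]), pos = pos),
            class = "repeat_context")
}

#' @export
print.repeat_context <- function(x, ...) {
  if (x$is_tandem)
    cat(sprintf("<repeat_context> pos %d: unit '%s' x %d (span %d-%d)\n",
                x$pos, x$unit, x$copies, x$span[1L], x$span[2L]))
  else cat(sprintf("<repeat_context> pos %d: no tandem context\n", x$pos))
  invisible(x)
}
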