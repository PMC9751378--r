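# Sliding-window read-count and depth profiles, transcribed intergenic
# region calls (the proxy for NUMT expression), and six-frame ORF scanning.

#' Sliding-window read counts or depth means
#'
#' Windows of width `bin` slide by `step` (the last windows may be short).
#' In count mode a read is counted in every window its alignment overlaps
#' by at least one base; in depth mode the per-window value is the mean
#' per-base depth.  The transcription profile convention is bin = 100,
#' step = 50; the sequencing-depth convention is bin = 500, step = 200.
#'
#' @param x data.frame of read alignments (`start`/`end`, 0-based
#'   half-open) for count mode, or a numeric per-base depth vector for
#'   depth mode.
#' @param genome_length genome size in bp (defaults to `length(x)` in depth
#'   mode).
#' @param bin window width in bp (`bin >= step`).
#' @param step slide in bp.
#' @param mode `"count"` or `"depth"` (chosen from the input type by
#'   default).
#' @return A `window_profile` data.frame (`start`, `end`, `value`) with
#'   attributes `window_size` and `step`.
#' @export
window_counts <- function(x, genome_length = NULL, bin = 100L, step = 50L,
                          mode = c("auto", "count", "depth")) {
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (is.data.frame(x)) "count" else "depth"
  stopifnot(step > 0, bin >= step)
  if (mode == "depth" && is.null(genome_length)) genome_length <- length(x)
  stopifnot(genome_length > 0)
  starts <- seq(0L, genome_length - 1L, by = step)
  ends <- pmin(starts + bin, genome_length)
  if (mode == "count") {
    rs <- sort(x$start); re <- sort(x$end)
    n <- length(rs)
    # reads overlapping [ws, we): all minus (end <= ws) minus (start >= we)
    val <- n - findInterval(starts, re) -
      (n - findInterval(ends - 1L, rs))
  } else {
    stopifnot(length(x) == genome_length)
    cs <- c(0, cumsum(x))
    val <- (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts)
  }
  prof <- data.frame(start = starts, end = ends, value = val)
  attr(prof, "window_size") <- bin
  attr(prof, "step") <- step
  class(prof) <- c("window_profile", "data.frame")
  prof
}

#' Call highly transcribed intergenic regions
#'
#' Considers only windows that are wholly intergenic (no overlap with any
#' annotated feature); among those, windows whose value strictly exceeds
#' the intergenic mean + 2 standard deviations are flagged, and adjacent
#' or overlapping flagged windows are merged into regions.
#'
#' @param profile a `window_profile` from [window_counts()].
#' @param features a feature table (see [organelle_genome()]).
#' @return data.frame of regions (`start`, `end`, `max_value`,
#'   `n_windows`); attribute `"threshold"` holds the cutoff used.
#' @export
call_high_expression_igs <- function(profile, features) {
  gene_iv <- merge_intervals(data.frame(start = features$start,
                                        end = features$end))
  intergenic <- vapply(seq_len(nrow(profile)), function(i) {
    ov <- pmin(gene_iv$end, profile$end[i]) - pmax(gene_iv$start, profile$start[i])
    !any(ov > 0)
  }, TRUE)
  ig <- profile[intergenic, , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0),
                      max_value = numeric(0), n_windows = integer(0))
  if (!nrow(ig)) return(empty)
  thr <- mean(ig$value) + 2 * sd(ig$value)
  if (is.na(thr)) thr <- Inf
  hot <- ig[ig$value > thr, , drop = FALSE]
  attr(empty, "threshold") <- thr
  if (!nrow(hot)) return(empty)
  hot <- hot[order(hot$start), , drop = FALSE]
  grp <- cumsum(c(TRUE, hot$start[-1] > hot$end[-nrow(hot)]))
  out <- do.call(rbind, lapply(split(hot, grp), function(d) data.frame(
    start = min(d$start), end = max(d$end), max_value = max(d$value),
    n_windows = nrow(d))))
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Find open reading frames
#'
#' All ATG-to-stop ORFs of at least `min_len` bp on both strands and all
#' three frames; nested ORFs sharing a stop are reported once (the
#' longest, i.e. the first ATG).  An ORF running into the sequence end
#' without a stop is reported with `has_stop = FALSE`.
#'
#' @param seq DNA string (a region sequence or whole genome).
#' @param min_len minimum ORF length in bp, start through stop inclusive
#'   (default 150).
#' @return data.frame: `start`, `end` (0-based half-open on the forward
#'   strand), `strand`, `frame` (0-2 on its own strand), `length`,
#'   `aa_len` (protein length, stop excluded), `has_stop`.
#' @export
find_orfs <- function(seq, min_len = 150L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  scan1 <- function(s, strand) {
    out <- list()
    for (fr in 0:2) {
      starts3 <- seq(fr + 1L, n - 2L, by = 3L)
      if (!length(starts3)) next
      cods <- substring(s, starts3, starts3 + 2L)
      is_stop <- cods %in% stop_codons
      is_atg <- cods == "ATG"
      seg <- cumsum(c(FALSE, is_stop[-length(is_stop)]))  # segment index per codon
      for (g in unique(seg)) {
        idx <- which(seg == g)
        a <- idx[which(is_atg[idx])[1]]
        if (is.na(a)) next
        stop_i <- idx[length(idx)]
        has_stop <- is_stop[stop_i]
        s0 <- starts3[a] - 1L                  # 0-based
        e0 <- starts3[stop_i] + 2L
        if (e0 - s0 < min_len) next
        out[[length(out) + 1L]] <- data.frame(
          start = s0, end = e0, strand = strand, frame = fr,
          length = e0 - s0, aa_len = (e0 - s0) %/% 3L - as.integer(has_stop),
          has_stop = has_stop, stringsAsFactors = FALSE)
      }
    }
    out
  }
  fwd <- scan1(seq, "+")
  rc <- revcomp(seq)
  rev <- scan1(rc, "-")
  rev <- lapply(rev, function(d) {
    s <- d$start; e <- d$end
    d$start <- n - e; d$end <- n - s
    d
  })
  out <- do.call(rbind, c(fwd, rev))
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length = integer(0), aa_len = integer(0),
                      has_stop = logical(0)))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
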