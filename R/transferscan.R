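# Homology search between organelle genomes and everything built on it:
# inverted-repeat collapsing, transferred-fragment (MTPT) detection with
# side-wise interval merging, windowed transfer profiles and hotspot calls,
# and synteny block extraction.
#
# The search is seed-and-extend: exact k-mer seeds (k = 15 by default) on
# both strands, clustered per diagonal, extended with X-drop termination
# under match +1 / mismatch -2 scoring; collinear fragments separated by a
# small indel-sized diagonal shift are chained with affine penalties.
# Significance follows the ungapped Karlin-Altschul statistic for the
# chosen scores over the m x n search space.  Circular molecules are
# scanned with an origin-spanning pad and the coordinates folded back, so
# fragments crossing the origin (up to the pad length) are not missed.

# Karlin-Altschul lambda for a match/mismatch scoring scheme over uniform
# base composition: solves sum_ij p_i p_j exp(lambda * s_ij) = 1.
karlin_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-10)$root
}

# K is taken as 0.62, the standard value tabulated for +1/-2 ungapped
# nucleotide scoring.
KARLIN_K <- 0.62

fragment_evalue <- function(score, m, n, match, mismatch) {
  lambda <- karlin_lambda(match, mismatch)
  KARLIN_K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

empty_fragments <- function() {
  data.frame(q_start = integer(0), q_end = integer(0), s_start = integer(0),
             s_end = integer(0), strand = character(0), length = integer(0),
             identity = numeric(0), score = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Search for homologous fragments between two genomes
#'
#' Seed-and-extend local search on both strands.  Fragments shorter than
#' `fragment_min_len`, below `homology_min_identity`, or with e-value above
#' `homology_evalue` are dropped; overlapping fragments on the same
#' diagonal are deduplicated to the highest-scoring one.
#'
#' @param query,subject [organelle_genome()] objects (circular topology is
#'   honoured by scanning across the origin with a pad of
#'   `config$circular_pad` bases).
#' @param config an [orgdyn_config()].
#' @param self treat this as a self-comparison and skip the trivial main
#'   diagonal; defaults to `TRUE` when query and subject share both id and
#'   sequence.
#' @return data.frame of fragments: `q_start`, `q_end`, `s_start`, `s_end`
#'   (0-based half-open on the forward strand of each genome; `*_end` may
#'   exceed the genome length for an origin-spanning fragment of a circular
#'   molecule), `strand` (`same`/`opposite`), `length` (aligned bp),
#'   `identity`, `score`, `evalue`.
#' @export
homology_search <- function(query, subject, config = orgdyn_config(),
                            self = identical(query$id, subject$id) &&
                              identical(query$sequence, subject$sequence)) {
  Lq <- genome_length(query); Ls <- genome_length(subject)
  qpad <- if (query$topology == "circular") min(config$circular_pad, Lq - 1L) else 0L
  spad <- if (subject$topology == "circular") min(config$circular_pad, Ls - 1L) else 0L
  qs <- paste0(query$sequence, substr(query$sequence, 1L, qpad))
  ss <- paste0(subject$sequence, substr(subject$sequence, 1L, spad))
  same <- search_strand(qs, ss, config, self_skip_diag0 = self)
  if (nrow(same)) same$strand <- "same"
  opp <- search_strand(qs, revcomp(ss), config, self_skip_diag0 = FALSE)
  if (nrow(opp)) {
    Lt <- nchar(ss)
    t0 <- opp$s_start; t1 <- opp$s_end
    opp$s_start <- Lt - t1; opp$s_end <- Lt - t0
    opp$strand <- "opposite"
  }
  fr <- rbind(same, opp)
  if (!nrow(fr)) return(empty_fragments())
  # fold padded coordinates back onto the original molecules
  fold <- function(st, en, L) {
    shift <- ifelse(st >= L, L, 0L)
    cbind(st - shift, en - shift)
  }
  qf <- fold(fr$q_start, fr$q_end, Lq)
  sf <- fold(fr$s_start, fr$s_end, Ls)
  fr$q_start <- qf[, 1]; fr$q_end <- qf[, 2]
  fr$s_start <- sf[, 1]; fr$s_end <- sf[, 2]
  fr <- fr[!duplicated(fr[, c("strand", "q_start", "s_start", "length")]), ,
           drop = FALSE]
  # filters
  fr$evalue <- fragment_evalue(fr$score, Lq, Ls, config$match, config$mismatch)
  fr <- fr[fr$length >= config$fragment_min_len &
             fr$identity >= config$homology_min_identity &
             fr$evalue <= config$homology_evalue, , drop = FALSE]
  fr <- fr[order(fr$q_start, fr$s_start), , drop = FALSE]
  rownames(fr) <- NULL
  fr[, c("q_start", "q_end", "s_start", "s_end", "strand", "length",
         "identity", "score", "evalue")]
}

# k-mer start positions encoded as exact base-4 numerics (k <= 15 keeps the
# code below 2^30, exactly representable); windows containing N give NA.
kmer_codes <- function(chint, k) {
  n <- length(chint)
  if (n < k) return(numeric(0))
  idx <- 1:(n - k + 1L)
  code <- numeric(n - k + 1L)
  for (j in 0:(k - 1L)) code <- code * 4 + chint[idx + j]
  code
}

# One-strand search between plain sequences; coordinates 0-based half-open
# in q and in t as given.
search_strand <- function(q, t, config, self_skip_diag0 = FALSE) {
  nq <- nchar(q); nt <- nchar(t)
  k <- config$seed_kmer
  if (nq < k || nt < k) return(empty_fragments())
  qch <- strsplit(q, "")[[1]]
  tch <- strsplit(t, "")[[1]]
  qint <- match(qch, c("A", "C", "G", "T")) - 1L
  tint <- match(tch, c("A", "C", "G", "T")) - 1L
  qcode <- kmer_codes(qint, k)
  tcode <- kmer_codes(tint, k)
  common <- intersect(qcode[!is.na(qcode)], tcode[!is.na(tcode)])
  if (!length(common)) return(empty_fragments())
  fq <- match(qcode, common)
  ft <- match(tcode, common)
  qp_by <- split(which(!is.na(fq)), fq[!is.na(fq)])
  tp_by <- split(which(!is.na(ft)), ft[!is.na(ft)])
  pairs <- lapply(seq_along(common), function(i) {
    a <- qp_by[[i]]; b <- tp_by[[i]]
    if (length(a) * length(b) > 4096L) return(NULL)  # low-complexity guard
    list(rep(a, times = length(b)), rep(b, each = length(a)))
  })
  qpos <- unlist(lapply(pairs, `[[`, 1L))
  tpos <- unlist(lapply(pairs, `[[`, 2L))
  if (is.null(qpos)) qpos <- integer(0)
  if (is.null(tpos)) tpos <- integer(0)
  d <- tpos - qpos
  if (self_skip_diag0) {
    keep <- d != 0L
    qpos <- qpos[keep]; d <- d[keep]
  }
  if (!length(qpos)) return(empty_fragments())
  ord <- order(d, qpos)
  d <- d[ord]; qpos <- qpos[ord]
  frs <- list()
  i <- 1L
  n_seed <- length(qpos)
  while (i <= n_seed) {
    j <- i
    while (j < n_seed && d[j + 1L] == d[i] && qpos[j + 1L] - qpos[j] <= 400L)
      j <- j + 1L
    dg <- d[i]
    qlim <- c(max(1L, 1L - dg), min(nq, nt - dg))
    anchor <- qpos[i]
    core_end <- qpos[j] + k - 1L
    core <- score_range(qch, tch, dg, anchor, core_end, config)
    left <- xdrop_extend(qch, tch, dg, anchor - 1L, -1L, qlim, config)
    right <- xdrop_extend(qch, tch, dg, core_end + 1L, +1L, qlim, config)
    a0 <- left$end; a1 <- right$end
    score <- core + left$gain + right$gain
    len <- a1 - a0 + 1L
    nmatch <- round((score - len * config$mismatch) /
                      (config$match - config$mismatch))
    frs[[length(frs) + 1L]] <- data.frame(
      q_start = a0 - 1L, q_end = a1, s_start = a0 - 1L + dg, s_end = a1 + dg,
      diag = dg, length = len, identity = nmatch / len, score = score,
      strand = NA_character_, stringsAsFactors = FALSE)
    i <- j + 1L
  }
  fr <- do.call(rbind, frs)
  fr <- dedupe_same_diagonal(fr)
  fr <- chain_fragments(fr, config)
  fr$diag <- NULL
  fr$evalue <- NA_real_
  fr
}

score_range <- function(qch, tch, dg, from, to, config) {
  if (to < from) return(0)
  mv <- qch[from:to] == tch[(from:to) + dg] & qch[from:to] != "N"
  sum(ifelse(mv, config$match, config$mismatch))
}

# X-drop extension along a diagonal.  Starts at q position `from`
# (1-based), walks in direction `dir`, and returns the furthest position
# attaining the maximum cumulative score before the score falls more than
# xdrop below the running best.  `end` is the last included position (or
# from - dir for a zero-length extension); `gain` the score added.
xdrop_extend <- function(qch, tch, dg, from, dir, qlim, config) {
  best <- 0; cur <- 0; end_at <- from - dir
  p <- from
  chunk_size <- 512L
  repeat {
    if (dir > 0L) {
      if (p > qlim[2]) break
      idx <- p:min(qlim[2], p + chunk_size - 1L)
    } else {
      if (p < qlim[1]) break
      idx <- p:max(qlim[1], p - chunk_size + 1L)
    }
    mv <- qch[idx] == tch[idx + dg] & qch[idx] != "N"
    cum <- cur + cumsum(ifelse(mv, config$match, config$mismatch))
    run_best <- cummax(pmax(cum, best))
    dropped <- which(cum < run_best - config$xdrop)
    upto <- if (length(dropped)) dropped[1] - 1L else length(idx)
    if (upto > 0L) {
      seg_max <- max(cum[1:upto])
      if (seg_max > best) {
        best <- seg_max
        end_at <- idx[which.max(cum[1:upto])]
      }
    }
    if (length(dropped)) break
    cur <- cum[length(cum)]
    p <- idx[length(idx)] + dir
  }
  list(end = end_at, gain = best)
}

# Overlapping fragments on one diagonal collapse to the highest-scoring.
dedupe_same_diagonal <- function(fr) {
  if (nrow(fr) < 2L) return(fr)
  fr <- fr[order(fr$diag, fr$q_start, -fr$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(fr))
  last_end <- -1L; last_diag <- NA_integer_; last_keep <- 1L
  for (i in seq_len(nrow(fr))) {
    if (!is.na(last_diag) && fr$diag[i] == last_diag &&
        fr$q_start[i] < last_end) {
      if (fr$score[i] > fr$score[last_keep]) {
        keep[last_keep] <- FALSE
        last_keep <- i
        last_end <- max(last_end, fr$q_end[i])
      } else keep[i] <- FALSE
    } else {
      last_keep <- i
      last_diag <- fr$diag[i]
      last_end <- fr$q_end[i]
    }
  }
  fr[keep, , drop = FALSE]
}

# Join collinear fragments separated by a small gap and diagonal shift
# (an indel), applying affine penalties at the join.
chain_fragments <- function(fr, config, max_gap = 50L, max_shift = 10L) {
  if (nrow(fr) < 2L) return(fr)
  fr <- fr[order(fr$q_start), , drop = FALSE]
  rownames(fr) <- NULL
  i <- 1L
  while (i < nrow(fr)) {
    j <- i + 1L
    gq <- fr$q_start[j] - fr$q_end[i]
    shift <- abs(fr$diag[j] - fr$diag[i])
    gs <- fr$s_start[j] - fr$s_end[i]
    if (gq >= 0L && gq <= max_gap && gs >= 0L && gs <= max_gap &&
        shift > 0L && shift <= max_shift) {
      nmatch_i <- round((fr$score[i] - fr$length[i] * config$mismatch) /
                          (config$match - config$mismatch))
      nmatch_j <- round((fr$score[j] - fr$length[j] * config$mismatch) /
                          (config$match - config$mismatch))
      new_len <- fr$length[i] + fr$length[j] + max(gq, gs)
      new_score <- fr$score[i] + fr$score[j] +
        config$gap_open + config$gap_extend * shift
      fr$q_end[i] <- fr$q_end[j]; fr$s_end[i] <- fr$s_end[j]
      fr$length[i] <- new_len
      fr$identity[i] <- (nmatch_i + nmatch_j) / new_len
      fr$score[i] <- new_score
      fr$diag[i] <- fr$diag[j]
      fr <- fr[-j, , drop = FALSE]
    } else i <- i + 1L
  }
  fr
}

## ---- inverted repeat ------------------------------------------------------

#' Collapse the large inverted repeat of a plastome
#'
#' Locates the longest self-palindromic pair of at least
#' `config$ir_min_len` bp (tolerating internal substitutions) and excises
#' the second copy, so downstream transfer counts are not doubled by the
#' IR.  Features inside the removed copy are dropped; later features are
#' shifted.
#'
#' @param plastome an [organelle_genome()] of kind `"plastome"`.
#' @param config an [orgdyn_config()].
#' @return list with `genome` (the reduced genome, unchanged if no IR was
#'   found), `ir_kept` and `ir_removed` (0-based half-open intervals or
#'   `NULL`), and `removed_bp`.
#' @export
collapse_inverted_repeat <- function(plastome, config = orgdyn_config()) {
  if (plastome$kind != "plastome") stop("collapse_inverted_repeat expects a plastome")
  s <- plastome$sequence
  fr <- search_strand(s, revcomp(s), config, self_skip_diag0 = FALSE)
  none <- list(genome = plastome, ir_kept = NULL, ir_removed = NULL, removed_bp = 0L)
  if (!nrow(fr)) return(none)
  n <- nchar(s)
  b_start <- n - fr$s_end; b_end <- n - fr$s_start
  ok <- fr$length >= config$ir_min_len &
    fr$identity >= config$homology_min_identity &
    !(fr$q_start == b_start & fr$q_end == b_end) &
    pmin(fr$q_end, b_end) - pmax(fr$q_start, b_start) <= 0L   # disjoint copies
  if (!any(ok)) return(none)
  best <- which(ok)[which.max(fr$length[ok])]
  a <- c(fr$q_start[best], fr$q_end[best])
  b <- c(b_start[best], b_end[best])
  if (b[1] < a[1]) { tmp <- a; a <- b; b <- tmp }
  cut_len <- b[2] - b[1]
  reduced <- paste0(substr(s, 1L, b[1]), substr(s, b[2] + 1L, n))
  ft <- plastome$features
  if (nrow(ft)) {
    inside <- ft$start < b[2] & ft$end > b[1]
    drop_ids <- unique(ft$feature_id[inside])
    ft <- ft[!ft$feature_id %in% drop_ids, , drop = FALSE]
    after <- ft$start >= b[2]
    ft$start[after] <- ft$start[after] - cut_len
    ft$end[after] <- ft$end[after] - cut_len
    rownames(ft) <- NULL
  }
  g <- organelle_genome(plastome$id, reduced, topology = plastome$topology,
                        kind = "plastome", features = ft)
  list(genome = g, ir_kept = a, ir_removed = b, removed_bp = cut_len)
}

## ---- merging, transfers, windows ------------------------------------------

# split origin-wrapping intervals (end > L) into two pieces
fold_intervals <- function(iv, L) {
  if (!nrow(iv)) return(iv)
  wrap <- iv$end > L
  if (!any(wrap)) return(iv)
  extra <- data.frame(start = 0L, end = iv$end[wrap] - L)
  iv$end[wrap] <- L
  rbind(iv, extra)
}

#' Merge homologous-fragment intervals on one side
#'
#' Overlapping or bookended intervals are coalesced into the disjoint,
#' sorted union, mirroring the rule that fragments with overlapping
#' positions in either genome are merged to be unique.
#'
#' @param fragments a fragment data.frame from [homology_search()], or any
#'   data.frame with `start`/`end` columns.
#' @param side `"query"` or `"subject"` (ignored for plain interval input).
#' @param genome_length when given, origin-wrapping intervals are folded
#'   into the `[0, genome_length)` range before merging.
#' @return data.frame of disjoint sorted intervals (`start`, `end`,
#'   0-based half-open).
#' @export
merge_intervals <- function(fragments, side = c("query", "subject"),
                            genome_length = NULL) {
  side <- match.arg(side)
  if (all(c("start", "end") %in% names(fragments))) {
    iv <- fragments[, c("start", "end"), drop = FALSE]
  } else {
    cols <- if (side == "query") c("q_start", "q_end") else c("s_start", "s_end")
    iv <- setNames(fragments[, cols, drop = FALSE], c("start", "end"))
  }
  if (!is.null(genome_length)) iv <- fold_intervals(iv, genome_length)
  if (!nrow(iv)) return(data.frame(start = integer(0), end = integer(0)))
  r <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

#' Detect plastome-to-mitogenome transferred fragments (MTPTs)
#'
#' Runs the homology search once and merges the fragment intervals on each
#' side: the plastome union describes where fragments were transferred
#' from, the mitogenome union where they integrated; the two counts can
#' differ because of recombination and rearrangement on either side.
#'
#' @param plastome an IR-collapsed plastome ([collapse_inverted_repeat()]).
#' @param mitogenome the mitogenome to scan.
#' @param config an [orgdyn_config()].
#' @return An object of class `transfer_set`: list with `fragments`,
#'   `plastome_intervals`, `mitogenome_intervals` (disjoint sorted
#'   data.frames), `plastome_total_bp`, `mitogenome_total_bp`,
#'   `plastome_count`, `mitogenome_count`.
#' @export
detect_transfers <- function(plastome, mitogenome, config = orgdyn_config()) {
  fr <- homology_search(plastome, mitogenome, config)
  pl <- merge_intervals(fr, "query", genome_length = genome_length(plastome))
  mt <- merge_intervals(fr, "subject", genome_length = genome_length(mitogenome))
  structure(list(
    fragments = fr,
    plastome_intervals = pl, mitogenome_intervals = mt,
    plastome_total_bp = sum(pl$end - pl$start),
    mitogenome_total_bp = sum(mt$end - mt$start),
    plastome_count = nrow(pl), mitogenome_count = nrow(mt)
  ), class = "transfer_set")
}

#' @export
print.transfer_set <- function(x, ...) {
  cat(sprintf("transfer_set: %d plastome fragment(s) (%d bp) -> %d mitogenome fragment(s) (%d bp)\n",
              x$plastome_count, x$plastome_total_bp,
              x$mitogenome_count, x$mitogenome_total_bp))
  invisible(x)
}

#' Histogram of transferred-fragment lengths
#'
#' @param intervals data.frame with `start`/`end` (0-based half-open), e.g.
#'   one side of a `transfer_set`.
#' @return named integer vector over the bins `100-200`, `201-300`,
#'   `301-500`, `501-1000`, `>1000` (bp, inclusive bounds).
#' @export
bin_fragment_lengths <- function(intervals) {
  len <- intervals$end - intervals$start
  if (any(len < 100L)) stop("fragment shorter than 100 bp in length binning")
  c(`100-200` = sum(len >= 100 & len <= 200),
    `201-300` = sum(len >= 201 & len <= 300),
    `301-500` = sum(len >= 301 & len <= 500),
    `501-1000` = sum(len >= 501 & len <= 1000),
    `>1000` = sum(len > 1000))
}

# union of exonic bases for the given feature types, as disjoint intervals
coding_union <- function(features, ftypes = c("CDS", "tRNA", "rRNA")) {
  ft <- features[features$ftype %in% ftypes, , drop = FALSE]
  merge_intervals(data.frame(start = ft$start, end = ft$end))
}

#' Classify transferred intervals as coding or non-coding
#'
#' An interval is labelled `cds` when at least half of its bases overlap
#' exonic bases of CDS, tRNA or rRNA features.
#'
#' @param intervals data.frame with `start`/`end`.
#' @param features a feature table (see [organelle_genome()]).
#' @return `intervals` with added `coding_fraction` and `label`
#'   (`cds`/`non-cds`) columns.
#' @export
classify_fragment_content <- function(intervals, features) {
  cu <- coding_union(features)
  frac <- vapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e <= s) return(0)
    ov <- pmin(cu$end, e) - pmax(cu$start, s)
    sum(ov[ov > 0]) / (e - s)
  }, 0)
  intervals$coding_fraction <- frac
  intervals$label <- ifelse(frac >= 0.5, "cds", "non-cds")
  intervals
}

#' Windowed transfer profile
#'
#' Tiles the genome with non-overlapping windows (the last may be short)
#' and totals, per window, the transferred bases whose positions fall in
#' it; a fragment spanning a window boundary contributes per base, so the
#' window sums conserve the merged total.
#'
#' @param intervals merged transfer intervals (`start`/`end`, disjoint).
#' @param genome_length genome size in bp.
#' @param window_size window width in bp (5000 for mitogenomes, 3000 for
#'   plastomes by convention).
#' @return A `window_profile` data.frame (`start`, `end`, `value`) with
#'   attributes `window_size` and `step`.
#' @export
window_transfer_profile <- function(intervals, genome_length, window_size) {
  stopifnot(window_size > 0)
  iv <- fold_intervals(intervals, genome_length)
  cov <- integer(genome_length)
  for (i in seq_len(nrow(iv)))
    if (iv$end[i] > iv$start[i])
      cov[(iv$start[i] + 1L):iv$end[i]] <- 1L
  starts <- seq(0L, genome_length - 1L, by = window_size)
  ends <- pmin(starts + window_size, genome_length)
  cs <- c(0L, cumsum(cov))
  prof <- data.frame(start = starts, end = ends,
                     value = cs[ends + 1L] - cs[starts + 1L])
  attr(prof, "window_size") <- window_size
  attr(prof, "step") <- window_size
  class(prof) <- c("window_profile", "data.frame")
  prof
}

#' Call transfer hotspots
#'
#' Windows whose transferred-bp total strictly exceeds `hotspot_min_bp`
#' (2000 bp by default).
#'
#' @param profile a `window_profile` from [window_transfer_profile()].
#' @param hotspot_min_bp strict lower bound in bp.
#' @return the hotspot rows of `profile`.
#' @export
call_hotspots <- function(profile, hotspot_min_bp = 2000) {
  out <- profile[profile$value > hotspot_min_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag hotspots containing a tRNA
#'
#' A hotspot window "contains" a tRNA when at least one base of any tRNA
#' feature (complete or partial) overlaps the window.
#'
#' @param hotspots hotspot windows ([call_hotspots()]).
#' @param features a feature table.
#' @return `hotspots` with `trna` (logical) and `n_trna` columns; attribute
#'   `"fraction"` holds flagged/total.
#' @export
annotate_hotspot_trnas <- function(hotspots, features) {
  tr <- features[features$ftype == "tRNA", , drop = FALSE]
  n <- vapply(seq_len(nrow(hotspots)), function(i) {
    ov <- pmin(tr$end, hotspots$end[i]) - pmax(tr$start, hotspots$start[i])
    length(unique(tr$feature_id[ov > 0]))
  }, 0L)
  hotspots$n_trna <- n
  hotspots$trna <- n > 0L
  attr(hotspots, "fraction") <- if (nrow(hotspots)) mean(hotspots$trna) else NA_real_
  hotspots
}

#' Extract synteny blocks between (or within) genomes
#'
#' Homologous fragments reported as blocks; in self mode the trivial
#' full-length self-match is removed and each pair is reported once.  A
#' display subset keeps blocks of at least `config$synteny_display_min` bp
#' (5000 by default), the scale at which interspecific synteny is drawn.
#'
#' @param genome_a,genome_b [organelle_genome()] objects (pass the same
#'   genome twice with `self_mode = TRUE` for internal synteny).
#' @param config an [orgdyn_config()].
#' @param self_mode drop the self-diagonal and mirrored duplicates.
#' @return list with `blocks` and `display` data.frames (`genome_a`,
#'   `genome_b`, `a_start`, `a_end`, `b_start`, `b_end`, `orientation`,
#'   `length`, `identity`).
#' @export
synteny_blocks <- function(genome_a, genome_b, config = orgdyn_config(),
                           self_mode = FALSE) {
  fr <- homology_search(genome_a, genome_b, config)
  if (self_mode && nrow(fr)) {
    fr <- fr[!(fr$strand == "same" & fr$q_start == fr$s_start &
                 fr$q_end == fr$s_end), , drop = FALSE]
    # report each pair once (canonical order)
    key_fwd <- paste(fr$strand, fr$q_start, fr$q_end, fr$s_start, fr$s_end)
    key_rev <- paste(fr$strand, fr$s_start, fr$s_end, fr$q_start, fr$q_end)
    fr <- fr[!(fr$s_start < fr$q_start & key_rev %in% key_fwd), , drop = FALSE]
  }
  blocks <- data.frame(
    genome_a = rep(genome_a$id, nrow(fr)),
    genome_b = rep(genome_b$id, nrow(fr)),
    a_start = fr$q_start, a_end = fr$q_end,
    b_start = fr$s_start, b_end = fr$s_end,
    orientation = ifelse(fr$strand == "same", "+", "-"),
    length = fr$length, identity = fr$identity,
    stringsAsFactors = FALSE
  )
  list(blocks = blocks,
       display = blocks[blocks$length >= config$synteny_display_min, ,
                        drop = FALSE])
}

#' Write synteny blocks as a Circos-style link file
#'
#' One line per block: `genome_a start end genome_b start end`, 1-based
#' inclusive.
#'
#' @param blocks a block data.frame from [synteny_blocks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_circos_links <- function(blocks, path) {
  lines <- sprintf("%s %d %d %s %d %d",
                   blocks$genome_a, blocks$a_start + 1L, blocks$a_end,
                   blocks$genome_b, blocks$b_start + 1L, blocks$b_end)
  writeLines(lines, path)
  invisible(path)
}
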