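# Microsatellite (SSR) and dispersed-repeat scanning.
#
# SSRs follow MISA semantics: motif sizes 1-6 with minimum repeat numbers
# from the configuration, maximal runs only, a run reported under its
# first-occurring phase, and motifs that are powers of a shorter motif
# rejected (so an (AT)n run is never also reported as (ATAT)m).
#
# Dispersed repeats are maximal forward/palindromic pairs of length >=
# repeat_min_len with at most repeat_max_mismatch substitutions (Hamming,
# no gaps), screened by a REPuter-style e-value.

# motif is primitive iff it is not a whole-number repetition of a shorter motif
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && motif == strrep(substr(motif, 1L, d), k %/% d))
      return(FALSE)
  }
  TRUE
}

#' Find simple sequence repeats (microsatellites)
#'
#' Scans for maximal tandem runs of 1-6 bp motifs passing the per-unit
#' minimum repeat numbers (defaults 8, 5, 4, 3, 3, 3).  Runs are reported
#' once, under the first-occurring phase; N truncates runs.  On a circular
#' genome a run spanning the origin is reported exactly once with wrapped
#' coordinates (`end` may exceed the genome length; `wrapped = TRUE`).
#'
#' @param genome an [organelle_genome()].
#' @param config an [orgdyn_config()].
#' @return data.frame with columns `motif`, `unit_len`, `n_repeats`,
#'   `start`, `end` (0-based half-open), `wrapped`, sorted by `start`.
#' @export
find_ssrs <- function(genome, config = orgdyn_config()) {
  L <- genome_length(genome)
  circular <- genome$topology == "circular" && L > 12L
  seq_use <- if (circular) paste0(genome$sequence, genome$sequence) else genome$sequence
  recs <- ssr_scan_linear(seq_use, config$ssr_min_repeats)
  if (circular && nrow(recs)) {
    recs <- recs[recs$start < L, , drop = FALSE]
    # cap runs at one full turn and drop calls that are still extendable
    # leftwards around the origin (their wrapped image is the maximal one)
    keep <- logical(nrow(recs))
    for (i in seq_len(nrow(recs))) {
      k <- recs$unit_len[i]
      span <- recs$end[i] - recs$start[i]
      if (span > L) {
        n <- L %/% k
        recs$n_repeats[i] <- n
        recs$end[i] <- recs$start[i] + n * k
      }
      prev_start <- ((recs$start[i] - k) %% L)
      prev <- genome_slice(genome, prev_start, prev_start + k)
      keep[i] <- prev != recs$motif[i] || recs$end[i] - recs$start[i] >= L
    }
    recs <- recs[keep, , drop = FALSE]
  }
  recs$wrapped <- recs$end > L
  recs <- recs[order(recs$start, recs$unit_len), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

# Linear-sequence scan: shift-compare per unit length, run-length encode.
ssr_scan_linear <- function(seq, min_repeats) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  out <- list()
  for (k in 1:6) {
    if (n < k * min_repeats[k]) next
    ok <- ch[seq_len(n - k)] == ch[(k + 1L):n] &
      ch[seq_len(n - k)] != "N" & ch[(k + 1L):n] != "N"
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + k) >= k * min_repeats[k])
    for (j in hit) {
      s <- starts[j]                       # 1-based position of first match
      span <- r$lengths[j] + k             # total repeat-tract length
      units <- span %/% k
      if (units < min_repeats[k]) next
      motif <- substr(seq, s, s + k - 1L)
      if (!is_primitive_motif(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_len = k, n_repeats = units,
        start = s - 1L, end = s - 1L + units * k, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), unit_len = integer(0),
                      n_repeats = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## ---- dispersed repeats ----------------------------------------------------

# Expected number of repeated pairs of length len with exactly mm mismatches
# in a random sequence of length n (REPuter-style significance for the
# match-mismatch model): E = n^2 * C(len, mm) * 3^mm / 4^len.
repeat_evalue <- function(len, mm, n) {
  exp(2 * log(n) + lchoose(len, mm) + mm * log(3) - len * log(4))
}

#' Find dispersed forward and palindromic repeats
#'
#' Reports maximal repeated pairs: equal-length segment pairs with at most
#' `repeat_max_mismatch` substitutions that cannot be extended on either
#' side without exceeding the mismatch budget.  Palindromic pairs compare a
#' segment with the reverse complement of its partner.  Pairs failing the
#' e-value cutoff are dropped, each pair is reported once (canonical order
#' `a_start <= b_start`), and the list is truncated to
#' `repeat_max_reports` by descending length (ties by `a_start`).
#'
#' @param genome an [organelle_genome()].
#' @param config an [orgdyn_config()].
#' @return data.frame with `rtype` (`forward`/`palindromic`), `a_start`,
#'   `a_end`, `b_start`, `b_end` (0-based half-open), `length`,
#'   `mismatches`, `evalue`.
#' @export
find_dispersed_repeats <- function(genome, config = orgdyn_config()) {
  s <- genome$sequence
  n <- nchar(s)
  min_len <- config$repeat_min_len
  mm_max <- config$repeat_max_mismatch
  if (n < min_len) return(empty_repeats())
  fwd <- dispersed_pairs(s, s, min_len, mm_max, self_forward = TRUE)
  pal <- dispersed_pairs(s, revcomp(s), min_len, mm_max, self_forward = FALSE)
  res <- list()
  if (nrow(fwd)) {
    fwd$rtype <- "forward"
    fwd$b_start <- fwd$t_start; fwd$b_end <- fwd$t_end
    res[[length(res) + 1L]] <- fwd
  }
  if (nrow(pal)) {
    pal$rtype <- "palindromic"
    # map the partner interval from reverse-complement coordinates back
    pal$b_start <- n - pal$t_end; pal$b_end <- n - pal$t_start
    res[[length(res) + 1L]] <- pal
  }
  if (!length(res)) return(empty_repeats())
  df <- do.call(rbind, lapply(res, function(d)
    d[, c("rtype", "a_start", "a_end", "b_start", "b_end", "length", "mismatches")]))
  # canonical order within each pair; drop coincident intervals
  swap <- df$b_start < df$a_start
  tmp <- df[swap, c("a_start", "a_end")]
  df[swap, c("a_start", "a_end")] <- df[swap, c("b_start", "b_end")]
  df[swap, c("b_start", "b_end")] <- tmp
  df <- df[!(df$a_start == df$b_start & df$a_end == df$b_end), , drop = FALSE]
  df <- unique(df)
  # mirror twins of a palindromic locus share a_start + b_end; forward
  # windows of one locus share b_start - a_start
  df$diag <- paste(df$rtype, ifelse(df$rtype == "forward",
                                    df$b_start - df$a_start,
                                    df$a_start + df$b_end))
  df <- reduce_diagonal_windows(df)
  df$evalue <- repeat_evalue(df$length, df$mismatches, n)
  df <- df[df$evalue <= config$homology_evalue, , drop = FALSE]
  df <- df[order(-df$length, df$a_start, df$b_start), , drop = FALSE]
  df <- head(df, config$repeat_max_reports)
  rownames(df) <- NULL
  df
}

empty_repeats <- function() {
  data.frame(rtype = character(0), a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0), length = integer(0),
             mismatches = integer(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

# Seed-based enumeration of maximal <=mm-mismatch pairs between s and t.
# Seeds: exact w-mers with w = floor(min_len / (mm + 1)), so every
# qualifying pair contains a seed (pigeonhole).  Around each seed group the
# local mismatch positions on the diagonal bound all maximal windows.
# Returns intervals in s ("a_*") and in t ("t_*").
dispersed_pairs <- function(s, t, min_len, mm_max, self_forward) {
  n <- nchar(s); m <- nchar(t)
  w <- max(7L, min_len %/% (mm_max + 1L))
  sch <- strsplit(s, "")[[1]]
  tch <- strsplit(t, "")[[1]]
  skm <- substring(s, 1:(n - w + 1L), w:n)
  tkm <- substring(t, 1:(m - w + 1L), w:m)
  valid_s <- !grepl("N", skm, fixed = TRUE)
  valid_t <- !grepl("N", tkm, fixed = TRUE)
  common <- intersect(skm[valid_s], tkm[valid_t])
  if (!length(common)) return(data.frame())
  ssel <- valid_s & skm %in% common
  tsel <- valid_t & tkm %in% common
  sp <- split(which(ssel), factor(skm[ssel], levels = common))
  tp <- split(which(tsel), factor(tkm[tsel], levels = common))
  pairs <- lapply(seq_along(common), function(i) {
    a <- sp[[i]]; b <- tp[[i]]
    if (length(a) * length(b) > 4096L) return(NULL)  # low-complexity guard
    list(rep(a, times = length(b)), rep(b, each = length(a)))
  })
  qpos <- unlist(lapply(pairs, `[[`, 1L))
  spos <- unlist(lapply(pairs, `[[`, 2L))
  if (is.null(qpos)) qpos <- integer(0)
  if (is.null(spos)) spos <- integer(0)
  if (self_forward) {
    keep <- spos > qpos                        # one orientation, no self-diagonal
    qpos <- qpos[keep]; spos <- spos[keep]
  }
  if (!length(qpos)) return(data.frame())
  d <- spos - qpos
  out <- list()
  seen <- new.env(hash = TRUE)
  for (dg in unique(d)) {
    pos <- sort(qpos[d == dg])                 # 1-based seed starts in s
    # group seeds whose windows could coalesce
    grp <- cumsum(c(TRUE, diff(pos) > (min_len + 8L * (mm_max + 1L))))
    for (g in unique(grp)) {
      p <- pos[grp == g]
      lo <- min(p); hi <- max(p) + w - 1L      # 1-based span covered by seeds
      # diagonal limits in s coordinates
      dmin <- max(1L, 1L - dg); dmax <- min(n, m - dg)
      mis <- local_mismatches(sch, tch, dg, lo, hi, dmin, dmax, mm_max + 1L)
      wins <- maximal_windows(mis$mm, mis$lo_bound, mis$hi_bound, mm_max)
      for (wdw in wins) {
        a0 <- wdw[1]; a1 <- wdw[2]             # 1-based inclusive in s
        len <- a1 - a0 + 1L
        if (len < min_len) next
        if (a1 < lo || a0 > hi) next           # must touch the seed group
        key <- paste(dg, a0, a1, sep = ":")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        nmm <- wdw[3]
        out[[length(out) + 1L]] <- data.frame(
          a_start = a0 - 1L, a_end = a1, t_start = a0 - 1L + dg,
          t_end = a1 + dg, diag = dg, length = len, mismatches = nmm)
      }
    }
  }
  if (!length(out)) return(data.frame())
  df <- unique(do.call(rbind, out))
  reduce_diagonal_windows(df)
}

# Overlapping maximal windows on one diagonal describe the same repeated
# locus with the mismatch budget spent on different flanks; keep the
# best-scoring one (matches - 2*mismatches = length - 3*mismatches,
# ties to the longest, then leftmost), so a planted exact copy is
# reported once with its exact extent.
reduce_diagonal_windows <- function(df) {
  df <- df[order(df$diag, df$a_start), , drop = FALSE]
  grp <- integer(nrow(df))
  g <- 0L; last_end <- -1L; last_diag <- NA
  for (i in seq_len(nrow(df))) {
    if (is.na(last_diag) || df$diag[i] != last_diag || df$a_start[i] >= last_end) {
      g <- g + 1L
      last_end <- df$a_end[i]
    } else last_end <- max(last_end, df$a_end[i])
    last_diag <- df$diag[i]
    grp[i] <- g
  }
  df$score <- df$length - 3L * df$mismatches
  picked <- do.call(rbind, lapply(split(df, grp), function(d) {
    d <- d[order(-d$score, -d$length, d$a_start), , drop = FALSE]
    d[1L, , drop = FALSE]
  }))
  picked$score <- NULL
  picked$diag <- NULL
  rownames(picked) <- NULL
  picked
}

# Walk outwards from [lo, hi] on diagonal dg collecting up to `budget`
# mismatch positions on each side (plus any inside), stopping at the
# diagonal limits.  Positions are 1-based in s.
local_mismatches <- function(sch, tch, dg, lo, hi, dmin, dmax, budget) {
  differs <- function(p) sch[p] != tch[p + dg] || sch[p] == "N" ||
    tch[p + dg] == "N"
  inside <- integer(0)
  for (p in lo:hi) if (differs(p)) inside <- c(inside, p)
  left <- integer(0); p <- lo - 1L
  while (p >= dmin && length(left) < budget) {
    if (differs(p)) left <- c(left, p)
    p <- p - 1L
  }
  lo_bound <- if (length(left) >= budget) NULL else dmin - 1L  # sequence edge sentinel
  right <- integer(0); p <- hi + 1L
  while (p <= dmax && length(right) < budget) {
    if (differs(p)) right <- c(right, p)
    p <- p + 1L
  }
  hi_bound <- if (length(right) >= budget) NULL else dmax + 1L
  list(mm = sort(c(rev(left), inside, right)), lo_bound = lo_bound,
       hi_bound = hi_bound)
}

# Enumerate maximal windows with <= mm_max mismatches from a sorted local
# mismatch list.  A window is maximal when each side either abuts a
# sequence edge or is flanked by a mismatch whose inclusion would exceed
# the budget; those are exactly the stretches between list entries q and
# q + mm_max + 1 once edge sentinels are appended.  lo_bound/hi_bound are
# sentinel positions just outside the diagonal (NULL when the outward walk
# stopped on its mismatch budget instead of the edge; windows reaching
# beyond a budget-stopped side would exceed mm_max and need not be
# represented).  Returns list of c(start, end, n_mismatch), 1-based
# inclusive.
maximal_windows <- function(mm, lo_bound, hi_bound, mm_max) {
  M <- mm
  both_edges <- !is.null(lo_bound) && !is.null(hi_bound)
  if (!is.null(lo_bound)) M <- c(lo_bound, M)
  if (!is.null(hi_bound)) M <- c(M, hi_bound)
  K <- length(M)
  span <- mm_max + 1L
  res <- list()
  if (K < span + 1L) {
    # fewer interior mismatches than the budget: the whole stretch is one
    # maximal window, valid only when bounded by sequence edges on both sides
    if (both_edges && M[K] - 1L >= M[1] + 1L)
      res[[1L]] <- c(M[1] + 1L, M[K] - 1L, K - 2L)
    return(res)
  }
  for (q in 1:(K - span)) {
    a <- M[q] + 1L; b <- M[q + span] - 1L
    if (b < a) next
    res[[length(res) + 1L]] <- c(a, b, mm_max)
  }
  res
}

#' Summarise repeat content of a genome
#'
#' @param ssrs output of [find_ssrs()].
#' @param repeats output of [find_dispersed_repeats()].
#' @param genome_length genome size in bp (> 0).
#' @return list with `ssr_count`, `ssr_by_unit` (named counts, mono..hexa),
#'   `dispersed_count`, `dispersed_bp` (per-base union over both intervals
#'   of every pair), `dispersed_fraction`, and `ssr_bp`.
#' @export
summarize_repeats <- function(ssrs, repeats, genome_length) {
  if (genome_length <= 0) stop("genome_length must be > 0")
  units <- factor(ssrs$unit_len, levels = 1:6)
  by_unit <- as.integer(table(units))
  names(by_unit) <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  rep_iv <- if (nrow(repeats))
    rbind(data.frame(start = repeats$a_start, end = repeats$a_end),
          data.frame(start = repeats$b_start, end = repeats$b_end))
  else data.frame(start = integer(0), end = integer(0))
  rep_bp <- sum_interval_union(rep_iv)
  ssr_iv <- data.frame(start = pmin(ssrs$start, genome_length),
                       end = pmin(ssrs$end, genome_length))
  list(
    ssr_count = nrow(ssrs),
    ssr_by_unit = by_unit,
    dispersed_count = nrow(repeats),
    dispersed_bp = rep_bp,
    dispersed_fraction = rep_bp / genome_length,
    ssr_bp = sum_interval_union(ssr_iv)
  )
}

# total bp covered by the union of 0-based half-open intervals
sum_interval_union <- function(iv) {
  if (!nrow(iv)) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  sum(IRanges::width(r))
}
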