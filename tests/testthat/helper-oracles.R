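# Independent brute-force oracles used to check the scanning operations,
# plus small fixture builders.  The oracles deliberately take different
# algorithmic routes from the package implementations (regular
# expressions, exhaustive all-diagonal scans, per-base boolean masks).

random_seq <- function(n, gc = 0.45) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

rc_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

motif_is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L))
    if (k %% d == 0L && motif == strrep(substr(motif, 1L, d), k %/% d))
      return(FALSE)
  TRUE
}

# Regular-expression SSR oracle: for each unit size, a backreference
# pattern finds leftmost maximal runs of complete units; motifs that are
# repetitions of a shorter motif are discarded.
ssr_oracle <- function(seq, min_repeats = c(8, 5, 4, 3, 3, 3)) {
  out <- list()
  for (k in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, min_repeats[k] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      motif <- substr(seq, m[i], m[i] + k - 1L)
      if (!motif_is_primitive(motif)) next
      n_rep <- len[i] %/% k
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_len = k, n_repeats = n_rep,
        start = m[i] - 1L, end = m[i] - 1L + n_rep * k,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), unit_len = integer(0),
                      n_repeats = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$start, df$unit_len), , drop = FALSE]
}

ssr_cols <- c("motif", "unit_len", "n_repeats", "start", "end")

# Exhaustive all-diagonal dispersed-repeat oracle: for every diagonal the
# full mismatch vector is computed by direct comparison and every maximal
# <=mm window is enumerated, then the same locus reduction and e-value
# screen as the operation's contract are applied.
dispersed_oracle <- function(seq, min_len = 30L, mm_max = 3L,
                             evalue_max = 1e-5) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  collect <- function(tch, forward) {
    rows <- list()
    dr <- if (forward) 1:(n - 1L) else (-(n - 1L)):(n - 1L)
    for (d in dr) {
      lo <- max(1L, 1L - d); hi <- min(n, n - d)
      if (hi - lo + 1L < min_len) next
      idx <- lo:hi
      mism <- idx[ch[idx] != tch[idx + d] | ch[idx] == "N" | tch[idx + d] == "N"]
      M <- c(lo - 1L, mism, hi + 1L)
      K <- length(M); span <- mm_max + 1L
      wins <- list()
      if (K < span + 1L) {
        if (M[K] - 1L >= M[1] + 1L) wins[[1L]] <- c(M[1] + 1L, M[K] - 1L)
      } else {
        for (q in 1:(K - span)) {
          a <- M[q] + 1L; b <- M[q + span] - 1L
          if (b >= a) wins[[length(wins) + 1L]] <- c(a, b)
        }
      }
      for (w in wins) {
        if (w[2] - w[1] + 1L < min_len) next
        nmm <- sum(mism >= w[1] & mism <= w[2])
        rows[[length(rows) + 1L]] <- data.frame(
          a_start = w[1] - 1L, a_end = w[2],
          t_start = w[1] - 1L + d, t_end = w[2] + d,
          length = w[2] - w[1] + 1L, mismatches = nmm)
      }
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  fwd <- collect(ch, forward = TRUE)
  pal <- collect(strsplit(rc_str(seq), "")[[1]], forward = FALSE)
  res <- list()
  if (!is.null(fwd)) {
    fwd$rtype <- "forward"
    fwd$b_start <- fwd$t_start; fwd$b_end <- fwd$t_end
    res[[length(res) + 1L]] <- fwd
  }
  if (!is.null(pal)) {
    pal$rtype <- "palindromic"
    pal$b_start <- n - pal$t_end; pal$b_end <- n - pal$t_start
    res[[length(res) + 1L]] <- pal
  }
  if (!length(res))
    return(find_dispersed_repeats(organelle_genome("x", strrep("A", 40),
                                                   "linear", "mitogenome"))[0, ])
  df <- do.call(rbind, res)[, c("rtype", "a_start", "a_end", "b_start",
                                "b_end", "length", "mismatches")]
  swap <- df$b_start < df$a_start
  tmp <- df[swap, c("a_start", "a_end")]
  df[swap, c("a_start", "a_end")] <- df[swap, c("b_start", "b_end")]
  df[swap, c("b_start", "b_end")] <- tmp
  df <- df[!(df$a_start == df$b_start & df$a_end == df$b_end), , drop = FALSE]
  df <- unique(df)
  # locus reduction: same contract as the caller
  df$key <- paste(df$rtype, ifelse(df$rtype == "forward",
                                   df$b_start - df$a_start,
                                   df$a_start + df$b_end))
  df <- df[order(df$key, df$a_start), , drop = FALSE]
  grp <- integer(nrow(df)); g <- 0L; le <- -1L; lk <- ""
  for (i in seq_len(nrow(df))) {
    if (df$key[i] != lk || df$a_start[i] >= le) { g <- g + 1L; le <- df$a_end[i] }
    else le <- max(le, df$a_end[i])
    lk <- df$key[i]; grp[i] <- g
  }
  df$score <- df$length - 3L * df$mismatches
  df <- do.call(rbind, lapply(split(df, grp), function(d) {
    d[order(-d$score, -d$length, d$a_start), ][1L, ]
  }))
  df$key <- NULL; df$score <- NULL
  ev <- exp(2 * log(n) + lchoose(df$length, df$mismatches) +
              df$mismatches * log(3) - df$length * log(4))
  df <- df[ev <= evalue_max, , drop = FALSE]
  df <- df[order(-df$length, df$a_start, df$b_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

rep_cols <- c("rtype", "a_start", "a_end", "b_start", "b_end", "length",
              "mismatches")

# per-base boolean-mask oracle for interval unions and window tallies
mask_union_bp <- function(iv, L) {
  m <- logical(L)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) m[(iv$start[i] + 1L):iv$end[i]] <- TRUE
  }
  sum(m)
}

mask_window_sums <- function(iv, L, win) {
  m <- logical(L)
  for (i in seq_len(nrow(iv)))
    if (iv$end[i] > iv$start[i]) m[(iv$start[i] + 1L):iv$end[i]] <- TRUE
  starts <- seq(0L, L - 1L, by = win)
  vapply(starts, function(s) sum(m[(s + 1L):min(s + win, L)]), 0L)
}

# per-column brute-force site classifier
site_class_oracle <- function(aln) {
  m <- do.call(rbind, strsplit(aln, ""))
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(!col %in% c("A", "C", "G", "T"))) return("gap")
    tb <- table(col)
    if (length(tb) == 1L) return("invariant")
    if (sum(tb >= 2L) >= 2L) paste0("informative", length(tb))
    else paste0("singleton", length(tb))
  }, "")
}

# small genome fixture with explicit features
toy_genome <- function(seq, features = NULL, kind = "mitogenome",
                       topology = "linear", id = "toy") {
  if (is.null(features)) {
    organelle_genome(id, seq, topology, kind)
  } else organelle_genome(id, seq, topology, kind, features = features)
}

feat_row <- function(id, ftype, strand, start, end, rank = 1L, name = id) {
  data.frame(feature_id = id, name = name, ftype = ftype, strand = strand,
             start = start, end = end, exon_rank = rank, partial = FALSE,
             wrapped = FALSE, stringsAsFactors = FALSE)
}
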