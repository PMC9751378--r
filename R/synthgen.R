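# Synthetic organelle genomes, pileups and alignments with exhaustive
# planted truth, so every pipeline stage can be tested against known
# ground truth without external data.
#
# Defaults mirror the study regime the pipeline targets: a ~60-kb
# plastome carrying one large (15-kb) inverted repeat, a ~120-kb
# mitogenome, ten plastid-derived transfers of 150-3000 bp at 85-100%
# identity (substitution-only mutation, so planted identity is exact),
# tRNA annotations enriched near insertion sites, and editing pileups at
# depth ~30.  Randomness is R's default Mersenne-Twister generator under
# the caller's seed; all draws are made through it, so outputs are fully
# reproducible from (seed, parameters).

random_dna <- function(n, gc = 0.45) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

substr_set <- function(s, start, replacement) {
  # 0-based start
  paste0(substr(s, 1L, start), replacement,
         substr(s, start + nchar(replacement) + 1L, nchar(s)))
}

# mutate a sequence to an exact target identity with substitutions only
mutate_to_identity <- function(s, identity) {
  n <- nchar(s)
  n_sub <- round((1 - identity) * n)
  if (n_sub == 0L) return(s)
  pos <- sample.int(n, n_sub)
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste0(ch, collapse = "")
}

# sample `n` non-overlapping 0-based intervals of the given widths inside
# [lo, hi), also avoiding `avoid` (data.frame start/end), with a margin
# between picks; rejection sampling with a retry cap.
place_intervals <- function(n, widths, lo, hi, avoid = NULL, margin = 100L,
                            retries = 2000L) {
  placed <- if (is.null(avoid)) data.frame(start = integer(0), end = integer(0))
            else avoid
  out <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(n)) {
    w <- widths[i]
    ok <- FALSE
    for (r in seq_len(retries)) {
      st <- sample(lo:(hi - w), 1L)
      clash <- any(pmin(placed$end + margin, st + w) -
                     pmax(placed$start - margin, st) > 0)
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop("infeasible packing: could not place interval of ", w,
           " bp; reduce the feature budget or lengths")
    placed <- rbind(placed, data.frame(start = st, end = st + w))
    out <- rbind(out, data.frame(start = st, end = st + w))
  }
  out
}

random_primitive_motif <- function(unit_len) {
  repeat {
    m <- paste0(sample(c("A", "C", "G", "T"), unit_len, replace = TRUE),
                collapse = "")
    if (is_primitive_motif(m)) return(m)
  }
}

# random coding sequence: ATG + non-stop codons + one stop
random_cds_seq <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), stop_codons)
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste0(c("ATG", body, sample(stop_codons, 1L)), collapse = "")
}

#' Simulate a plastome/mitogenome pair with planted truth
#'
#' Generates i.i.d. background sequence at the requested GC, plants a
#' large exact inverted repeat in the plastome, copies `n_transfers`
#' plastome segments into the mitogenome mutated (substitutions only) to
#' identities drawn from `identity_range`, and plants SSRs, dispersed
#' repeats, tRNA annotations (enriched next to transfer insertions) and
#' CDS features with known coding sequences.  Every planted feature is
#' recorded in the returned truth table.
#'
#' @param seed integer RNG seed; the pair is reproducible from it.
#' @param plastome_len,mito_len genome sizes in bp.
#' @param gc background GC content.
#' @param n_transfers number of transferred fragments.
#' @param transfer_len_range,identity_range transfer length (bp) and
#'   identity ranges, drawn uniformly.
#' @param n_ssrs,n_repeats,n_trnas,n_cds planted feature budgets for the
#'   mitogenome.
#' @param ir_len inverted-repeat length in bp (0 disables).
#' @param repeat_len_range dispersed-repeat unit length range (bp).
#' @param trna_near_transfer_frac fraction of tRNAs placed within 500 bp
#'   of a transfer insertion.
#' @return list with `plastome`, `mitogenome` ([organelle_genome()]s,
#'   circular) and `truth`, a `truth_table` list recording every planted
#'   feature (transfer coordinates are given both on the full plastome and
#'   on the IR-collapsed plastome as `p_start_reduced`/`p_end_reduced`).
#' @export
simulate_organelle_pair <- function(seed,
                                    plastome_len = 60000L, mito_len = 120000L,
                                    gc = 0.45,
                                    n_transfers = 10L,
                                    transfer_len_range = c(150L, 3000L),
                                    identity_range = c(0.85, 1.0),
                                    n_ssrs = 6L, n_repeats = 4L,
                                    ir_len = 15000L, n_trnas = 12L,
                                    n_cds = 8L,
                                    repeat_len_range = c(50L, 80L),
                                    trna_near_transfer_frac = 0.6) {
  if (plastome_len < 10000L || mito_len < 10000L)
    stop("genome lengths must be at least 10 kb")
  set.seed(seed)
  pl <- random_dna(plastome_len, gc)

  ## inverted repeat: overwrite a second segment with the reverse
  ## complement of the first
  ir_a <- ir_b <- NULL
  if (ir_len > 0L) {
    a0 <- 1000L
    b0 <- plastome_len - ir_len - 1000L
    if (b0 - (a0 + ir_len) < 2000L) stop("infeasible packing: IR too large")
    ira_seq <- substr(pl, a0 + 1L, a0 + ir_len)
    pl <- substr_set(pl, b0, revcomp(ira_seq))
    ir_a <- c(a0, a0 + ir_len); ir_b <- c(b0, b0 + ir_len)
  }

  ## transfer sources on the plastome, outside both IR copies
  tlen <- round(runif(n_transfers, transfer_len_range[1], transfer_len_range[2]))
  tid <- runif(n_transfers, identity_range[1], identity_range[2])
  free_lo <- if (!is.null(ir_a)) ir_a[2] + 200L else 0L
  free_hi <- if (!is.null(ir_b)) ir_b[1] - 200L else plastome_len
  src <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(n_transfers)) {
    st <- sample(free_lo:(free_hi - tlen[i]), 1L)
    src <- rbind(src, data.frame(start = st, end = st + tlen[i]))
  }

  ## mitogenome background and transfer insertions (disjoint)
  mt <- random_dna(mito_len, gc)
  ins <- place_intervals(n_transfers, tlen, 500L, mito_len - 500L,
                         margin = 200L)
  for (i in seq_len(n_transfers)) {
    seg <- substr(pl, src$start[i] + 1L, src$end[i])
    seg <- mutate_to_identity(seg, tid[i])
    mt <- substr_set(mt, ins$start[i], seg)
  }
  occupied <- data.frame(start = ins$start, end = ins$end)

  ## SSRs
  thr <- c(8L, 5L, 4L, 3L, 3L, 3L)
  ssr_truth <- NULL
  if (n_ssrs > 0L) {
    units <- sample(1:6, n_ssrs, replace = TRUE)
    reps <- thr[units] + sample(0:3, n_ssrs, replace = TRUE)
    widths <- units * reps + 2L                       # room for broken flanks
    pos <- place_intervals(n_ssrs, widths, 500L, mito_len - 500L,
                           avoid = occupied, margin = 150L)
    occupied <- rbind(occupied, pos)
    ssr_truth <- data.frame(motif = character(0), unit_len = integer(0),
                            n_repeats = integer(0), start = integer(0),
                            end = integer(0))
    for (i in seq_len(n_ssrs)) {
      motif <- random_primitive_motif(units[i])
      run <- strrep(motif, reps[i])
      mch <- strsplit(motif, "")[[1]]
      left <- sample(setdiff(c("A", "C", "G", "T"), mch[units[i]]), 1L)
      right <- sample(setdiff(c("A", "C", "G", "T"), mch[1]), 1L)
      mt <- substr_set(mt, pos$start[i], paste0(left, run, right))
      ssr_truth <- rbind(ssr_truth, data.frame(
        motif = motif, unit_len = units[i], n_repeats = reps[i],
        start = pos$start[i] + 1L, end = pos$start[i] + 1L + units[i] * reps[i]))
    }
  }

  ## dispersed repeats: a fresh random block copied to two loci
  rep_truth <- NULL
  if (n_repeats > 0L) {
    rl <- round(runif(n_repeats, repeat_len_range[1], repeat_len_range[2]))
    rtype <- sample(c("forward", "palindromic"), n_repeats, replace = TRUE)
    loci <- place_intervals(2L * n_repeats, rep(rl, each = 2L), 500L,
                            mito_len - 500L, avoid = occupied, margin = 150L)
    occupied <- rbind(occupied, loci)
    rep_truth <- data.frame(rtype = character(0), a_start = integer(0),
                            a_end = integer(0), b_start = integer(0),
                            b_end = integer(0), length = integer(0))
    for (i in seq_len(n_repeats)) {
      block <- random_dna(rl[i], gc)
      a <- loci[2L * i - 1L, ]; b <- loci[2L * i, ]
      if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
      mt <- substr_set(mt, a$start, block)
      mt <- substr_set(mt, b$start,
                       if (rtype[i] == "forward") block else revcomp(block))
      rep_truth <- rbind(rep_truth, data.frame(
        rtype = rtype[i], a_start = a$start, a_end = a$start + rl[i],
        b_start = b$start, b_end = b$start + rl[i], length = rl[i]))
    }
  }

  ## tRNA annotations, enriched next to transfer insertions
  mito_feats <- empty_features()
  trna_truth <- NULL
  if (n_trnas > 0L) {
    n_near <- round(trna_near_transfer_frac * n_trnas)
    starts <- integer(0)
    w <- 75L
    for (i in seq_len(n_trnas)) {
      if (i <= n_near) {
        anchor <- ins[((i - 1L) %% nrow(ins)) + 1L, ]
        side <- sample(c(-1L, 1L), 1L)
        st <- if (side < 0L) anchor$start - w - sample(5:120, 1L)
              else anchor$end + sample(5:120, 1L)
        st <- max(0L, min(st, mito_len - w))
      } else {
        st <- place_intervals(1L, w, 500L, mito_len - 500L,
                              avoid = occupied, margin = 50L)$start
      }
      starts <- c(starts, st)
    }
    trna_truth <- data.frame(
      feature_id = paste0("trn", seq_len(n_trnas)),
      name = paste0("trn", seq_len(n_trnas)),
      ftype = "tRNA", strand = sample(c("+", "-"), n_trnas, replace = TRUE),
      start = starts, end = starts + w, exon_rank = 1L,
      partial = FALSE, wrapped = FALSE, stringsAsFactors = FALSE)
    mito_feats <- rbind(mito_feats, trna_truth)
  }

  ## CDS features with known coding sequences; the last one is a
  ## two-exon minus-strand case
  cds_truth <- list()
  if (n_cds > 0L) {
    for (i in seq_len(n_cds)) {
      n_codons <- sample(60:160, 1L)
      cds <- random_cds_seq(n_codons)
      two_exon <- (i == n_cds)
      strand <- if (two_exon) "-" else sample(c("+", "-"), 1L)
      if (!two_exon) {
        pos <- place_intervals(1L, nchar(cds), 500L, mito_len - 500L,
                               avoid = occupied, margin = 50L)
        occupied <- rbind(occupied, pos)
        content <- if (strand == "+") cds else revcomp(cds)
        mt <- substr_set(mt, pos$start, content)
        rows <- data.frame(feature_id = paste0("cds", i),
                           name = paste0("cds", i), ftype = "CDS",
                           strand = strand, start = pos$start,
                           end = pos$start + nchar(cds), exon_rank = 1L,
                           partial = FALSE, wrapped = FALSE)
      } else {
        # intervals concatenated in feature order, then reverse-complemented
        genomic <- revcomp(cds)
        cut <- sample(50:(nchar(genomic) - 50L), 1L)
        pos <- place_intervals(2L, c(cut, nchar(genomic) - cut), 500L,
                               mito_len - 500L, avoid = occupied, margin = 200L)
        if (pos$start[1] > pos$start[2]) {      # keep genome order = exon order
          pos <- pos[2:1, ]
          cut <- pos$end[1] - pos$start[1]
        }
        p1 <- substr(genomic, 1L, cut)
        p2 <- substr(genomic, cut + 1L, nchar(genomic))
        occupied <- rbind(occupied, pos)
        mt <- substr_set(mt, pos$start[1], p1)
        mt <- substr_set(mt, pos$start[2], p2)
        rows <- data.frame(feature_id = paste0("cds", i),
                           name = paste0("cds", i), ftype = "CDS",
                           strand = "-", start = pos$start,
                           end = pos$end, exon_rank = 1:2,
                           partial = FALSE, wrapped = FALSE)
      }
      cds_truth[[paste0("cds", i)]] <- cds
      mito_feats <- rbind(mito_feats, rows)
    }
  }

  ## plastome features: CDS over some transfer sources plus random tRNAs
  pl_feats <- empty_features()
  n_src_cds <- min(4L, n_transfers)
  if (n_src_cds > 0L) {
    idx <- head(order(-tlen), n_src_cds)
    rows <- data.frame(
      feature_id = paste0("pcds", seq_len(n_src_cds)),
      name = paste0("pcds", seq_len(n_src_cds)), ftype = "CDS",
      strand = "+",
      start = src$start[idx],
      end = src$start[idx] + pmax(30L, round(0.7 * tlen[idx])),
      exon_rank = 1L, partial = FALSE, wrapped = FALSE)
    pl_feats <- rbind(pl_feats, rows)
  }

  plastome <- organelle_genome("plastome_sim", pl, topology = "circular",
                               kind = "plastome", features = pl_feats)
  mitogenome <- organelle_genome("mito_sim", mt, topology = "circular",
                                 kind = "mitogenome", features = mito_feats)

  ## transfer coordinates on the IR-collapsed plastome (second copy removed)
  shift <- function(p) {
    if (is.null(ir_b)) return(as.integer(p))
    as.integer(ifelse(p >= ir_b[2], p - ir_len, p))
  }
  transfers <- data.frame(
    p_start = src$start, p_end = src$end,
    m_start = ins$start, m_end = ins$end,
    length = tlen, identity = tid,
    p_start_reduced = shift(src$start),
    p_end_reduced = shift(src$end)
  )

  truth <- structure(list(
    seed = seed,
    plastome_id = "plastome_sim", mitogenome_id = "mito_sim",
    plastome_len = plastome_len, mito_len = mito_len,
    planted_ir = if (is.null(ir_a)) NULL else list(a = ir_a, b = ir_b),
    planted_transfers = transfers,
    planted_ssrs = ssr_truth,
    planted_repeats = rep_truth,
    planted_trnas = trna_truth,
    planted_cds = cds_truth
  ), class = "truth_table")
  list(plastome = plastome, mitogenome = mitogenome, truth = truth)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table (seed ", x$seed, "):\n", sep = "")
  for (nm in setdiff(names(x), "seed")) {
    v <- x[[nm]]
    n <- if (is.data.frame(v)) nrow(v) else length(v)
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "none" else paste0(n, " record(s)")))
  }
  invisible(x)
}

#' Serialize / reload a truth table
#'
#' JSON round trip is byte-identical: writing, reading and writing again
#' produces the same file.
#'
#' @param truth a `truth_table`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "truth_table")
}

#' Simulate an RNA-editing pileup with planted sites
#'
#' Plants C>T / T>C editing sites at reference C/T positions with binomial
#' edited-read counts, plus (optionally) deliberately sub-threshold sites:
#' depth one read below the caller's minimum, base quality 9, or placed
#' within 5 bp of an indel.  The truth table records, per site, the drawn
#' depth and edited-read count and whether the documented filters should
#' pass it.
#'
#' @param genome an [organelle_genome()].
#' @param n_sites number of well-formed planted sites.
#' @param efficiency true editing efficiency, scalar or length `n_sites`.
#' @param depth read depth at planted sites (drawn as given, not Poisson).
#' @param quality phred base quality written at well-formed sites.
#' @param error_rate per-read probability of a random non-edited error
#'   base at planted and background sites.
#' @param n_low_depth,n_low_quality,n_near_indel numbers of deliberately
#'   sub-threshold planted sites (depth threshold - 1; quality 9; 0-5 bp
#'   from an indel).
#' @param n_background background reference-only sites.
#' @param tissue tissue label recorded in the truth.
#' @param seed RNG seed.
#' @param path optional output file for the mpileup text.
#' @return list with `lines` (mpileup text), `truth` (data.frame of
#'   planted sites with `pos`, `ref_base`, `edit_type`, `true_efficiency`,
#'   `depth`, `alt_count`, `quality`, `indel_distance`, `category`,
#'   `expected_pass`) and `path` (or `NULL`).
#' @export
simulate_pileup <- function(genome, n_sites = 50L, efficiency = 0.5,
                            depth = 30L, quality = 40L, error_rate = 0,
                            n_low_depth = 0L, n_low_quality = 0L,
                            n_near_indel = 0L, n_background = 10L,
                            tissue = "tissue1", seed = 1L, path = NULL) {
  set.seed(seed)
  min_depth <- if (genome$kind == "mitogenome") 10L else 20L
  ch <- strsplit(genome$sequence, "")[[1]]
  ct_pos <- which(ch %in% c("C", "T"))
  n_total <- n_sites + n_low_depth + n_low_quality + n_near_indel
  if (length(ct_pos) < n_total + n_background)
    stop("genome too small for the requested site budget")
  # planted sites are kept > 12 bp apart so an indel attached to one site
  # can never fall within the 5-bp exclusion zone of another
  pool <- sample(ct_pos)
  pick <- integer(0)
  for (p in pool) {
    if (!length(pick) || min(abs(pick - p)) > 12L) {
      pick <- c(pick, p)
      if (length(pick) == n_total + n_background) break
    }
  }
  if (length(pick) < n_total + n_background)
    stop("genome too small for the requested site budget at 12-bp spacing")
  site_pos <- pick[seq_len(n_total)]
  bg_pos <- pick[n_total + seq_len(n_background)]
  category <- c(rep("ok", n_sites), rep("low_depth", n_low_depth),
                rep("low_quality", n_low_quality), rep("near_indel", n_near_indel))
  eff <- rep(efficiency, length.out = n_sites)
  eff <- c(eff, rep(0.6, n_total - n_sites))   # sub-threshold sites edit at 0.6
  dpt <- ifelse(category == "low_depth", min_depth - 1L, depth)
  qual <- ifelse(category == "low_quality", 9L, quality)
  alt <- rbinom(n_total, dpt, eff)
  ref <- ch[site_pos]
  alt_base <- ifelse(ref == "C", "T", "C")
  indel_dist <- rep(Inf, n_total)
  indel_dist[category == "near_indel"] <-
    sample(0:5, sum(category == "near_indel"), replace = TRUE)

  truth <- data.frame(
    genome_id = genome$id, pos = site_pos - 1L, ref_base = ref,
    alt_base = alt_base,
    edit_type = ifelse(ref == "C", "C>T", "T>C"),
    true_efficiency = eff, depth = dpt, alt_count = alt, quality = qual,
    indel_distance = indel_dist, category = category, tissue = tissue,
    stringsAsFactors = FALSE
  )
  truth$expected_pass <- truth$depth >= min_depth & truth$quality >= 10 &
    truth$indel_distance > 5 & truth$alt_count >= 2 &
    truth$alt_count / truth$depth >= 0.05

  ## assemble mpileup lines (sorted by position)
  mk_bases <- function(ref_n, alt_n, alt_b, err_n = 0L) {
    refs <- sample(c(".", ","), ref_n, replace = TRUE)
    alts <- sample(c(alt_b, tolower(alt_b)), alt_n, replace = TRUE)
    errs <- if (err_n > 0L) sample(c("G", "g", "A", "a"), err_n, replace = TRUE)
            else character(0)
    paste0(sample(c(refs, alts, errs)), collapse = "")
  }
  rows <- list()
  for (i in seq_len(n_total)) {
    err_n <- rbinom(1L, truth$depth[i] - truth$alt_count[i], error_rate)
    bases <- mk_bases(truth$depth[i] - truth$alt_count[i] - err_n,
                      truth$alt_count[i], truth$alt_base[i], err_n)
    if (truth$category[i] == "near_indel" && truth$indel_distance[i] == 0)
      bases <- paste0(bases, "+2AT")
    rows[[length(rows) + 1L]] <- list(
      pos = truth$pos[i],
      line = paste(genome$id, truth$pos[i] + 1L, truth$ref_base[i],
                   truth$depth[i], bases,
                   strrep(intToUtf8(truth$quality[i] + 33L), truth$depth[i]),
                   sep = "\t"))
    if (truth$category[i] == "near_indel" && truth$indel_distance[i] > 0) {
      ip <- truth$pos[i] + truth$indel_distance[i]
      ipref <- if (ip < length(ch)) ch[ip + 1L] else "A"
      rows[[length(rows) + 1L]] <- list(
        pos = ip,
        line = paste(genome$id, ip + 1L, ipref, 10L,
                     paste0(mk_bases(10L, 0L, "T"), "+2AT"),
                     strrep(intToUtf8(quality + 33L), 10L), sep = "\t"))
    }
  }
  for (p in bg_pos) {
    d <- max(1L, rpois(1L, depth))
    rows[[length(rows) + 1L]] <- list(
      pos = p - 1L,
      line = paste(genome$id, p, ch[p], d, mk_bases(d, 0L, "T"),
                   strrep(intToUtf8(quality + 33L), d), sep = "\t"))
  }
  ord <- order(vapply(rows, `[[`, 0, "pos"))
  lines <- vapply(rows[ord], `[[`, "", "line")
  if (!is.null(path)) writeLines(lines, path)
  list(lines = lines, truth = truth, path = path)
}

#' Simulate an alignment with known site-class counts
#'
#' Builds each column to an assigned class: invariant; singleton with 2-4
#' distinct bases (one base in all but the variant rows, the others once
#' each); parsimony-informative with 2-4 distinct bases (at least two
#' bases in at least two sequences); remaining columns carry one gap and
#' count as gap/missing.
#'
#' @param n_taxa number of sequences (>= 4 for informative columns; >= 6
#'   for the four-variant classes).
#' @param length alignment width in columns.
#' @param class_mix named fractions over `invariant`, `singleton2`,
#'   `singleton3`, `singleton4`, `informative2`, `informative3`,
#'   `informative4`; must sum to at most 1 (remainder becomes gap
#'   columns).
#' @param seed RNG seed.
#' @param path optional aligned-FASTA output.
#' @return list with `alignment` (named character vector), `truth` (list
#'   with realized per-class column counts and per-column labels) and
#'   `path`.
#' @export
simulate_alignment <- function(n_taxa = 6L, length = 1000L,
                               class_mix = c(invariant = 0.80,
                                             singleton2 = 0.08,
                                             singleton3 = 0.01,
                                             singleton4 = 0.002,
                                             informative2 = 0.06,
                                             informative3 = 0.01,
                                             informative4 = 0.002),
                               seed = 1L, path = NULL) {
  set.seed(seed)
  classes <- c("invariant", "singleton2", "singleton3", "singleton4",
               "informative2", "informative3", "informative4")
  mix <- setNames(rep(0, length(classes)), classes)
  mix[names(class_mix)] <- class_mix
  if (sum(mix) > 1 + 1e-9) stop("class_mix fractions must sum to at most 1")
  counts <- setNames(as.integer(round(mix * length)), classes)
  if (sum(counts) > length) stop("class_mix fractions must sum to at most 1")
  n_gap <- length - sum(counts)
  min_taxa <- c(invariant = 1L, singleton2 = 3L, singleton3 = 4L,
                singleton4 = 5L, informative2 = 4L, informative3 = 5L,
                informative4 = 6L)
  short <- names(counts)[counts > 0 & n_taxa < min_taxa[classes]]
  if (length(short))
    stop("class '", short[1], "' requires at least ",
         min_taxa[[short[1]]], " taxa")
  bases <- c("A", "C", "G", "T")
  make_col <- function(cl) {
    b <- sample(bases)
    col <- rep(b[1], n_taxa)
    extra <- switch(cl,
      invariant = integer(0),
      singleton2 = { col[1] <- b[2]; integer(0) },
      singleton3 = { col[1:2] <- b[2:3]; integer(0) },
      singleton4 = { col[1:3] <- b[2:4]; integer(0) },
      informative2 = { col[1:2] <- b[2]; integer(0) },
      informative3 = { col[1:3] <- c(b[2], b[2], b[3]); integer(0) },
      informative4 = { col[1:4] <- c(b[2], b[2], b[3], b[4]); integer(0) },
      gap = { col[1] <- "-"; integer(0) }
    )
    sample(col)                               # shuffle rows
  }
  labels <- sample(c(rep(classes, times = counts), rep("gap", n_gap)))
  mat <- vapply(labels, make_col, character(n_taxa))
  aln <- setNames(apply(mat, 1L, paste0, collapse = ""),
                  paste0("taxon", seq_len(n_taxa)))
  if (!is.null(path)) {
    ss <- Biostrings::BStringSet(aln)
    Biostrings::writeXStringSet(ss, path, width = 80L)
  }
  list(alignment = aln,
       truth = list(counts = c(counts, gap = n_gap), labels = unname(labels)),
       path = path)
}
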