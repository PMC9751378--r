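# Readers and writers for the external formats the pipeline consumes:
# FASTA (via Biostrings), GFF3 (via rtracklayer), GenBank-style five-column
# feature tables, samtools-mpileup text, BED and 1-based TSV interval tables.

#' Read an organelle genome from FASTA
#'
#' @param path FASTA file (single- or multi-record).
#' @param annotations optional GFF3 (`.gff`/`.gff3`) or GenBank-style
#'   feature-table (`.tbl`) file; 1-based inclusive coordinates are converted
#'   to the internal 0-based half-open convention.
#' @param kind `"mitogenome"` or `"plastome"`.
#' @param topology `"circular"` or `"linear"`.
#' @param id for multi-record FASTA, the record to return; by default a
#'   single record is required and returned.
#'
#' @return An [organelle_genome()] object; for a multi-record file with
#'   `id = NULL`, a named list of them (annotations are split by seqid).
#' @export
read_genome <- function(path, annotations = NULL,
                        kind = c("mitogenome", "plastome"),
                        topology = c("circular", "linear"), id = NULL) {
  kind <- match.arg(kind)
  topology <- match.arg(topology)
  check_fasta_lines(path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no sequence records in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  feats <- if (is.null(annotations)) NULL else read_features(annotations)
  build <- function(i) {
    ft <- empty_features()
    if (!is.null(feats)) {
      ft <- feats[feats$seqid == names(seqs)[i] | feats$seqid == ".", ,
                  drop = FALSE]
      ft$seqid <- NULL
      rownames(ft) <- NULL
    }
    organelle_genome(names(seqs)[i], as.character(seqs[[i]]),
                     topology = topology, kind = kind, features = ft)
  }
  if (!is.null(id)) {
    i <- match(id, names(seqs))
    if (is.na(i)) stop("record '", id, "' not found in ", path)
    return(build(i))
  }
  if (length(seqs) == 1L) return(build(1L))
  setNames(lapply(seq_along(seqs), build), names(seqs))
}

# Cheap structural validation so malformed FASTA errors name the line.
check_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) stop("malformed FASTA ", path, ": file is empty")
  if (!startsWith(lines[nonempty[1]], ">"))
    stop("malformed FASTA ", path, ": line ", nonempty[1],
         " should be a '>' header")
  for (i in nonempty) {
    ln <- lines[i]
    if (startsWith(ln, ">")) next
    if (grepl("[^ACGTNacgtn]", ln))
      stop("malformed FASTA ", path, ": line ", i,
           " contains a non-ACGTN character")
  }
  invisible(TRUE)
}

#' Read feature annotations
#'
#' Accepts GFF3 or a GenBank-style five-column feature table (tab-separated
#' `start  end  type` rows followed by indented qualifier rows; a start
#' greater than its end denotes the minus strand).  Coordinates are returned
#' 0-based half-open with one row per interval.
#'
#' @param path annotation file; format chosen by extension (`.tbl` means
#'   feature table, everything else GFF3).
#' @return A feature data.frame with a `seqid` column plus the columns of
#'   [organelle_genome()] feature tables.
#' @export
read_features <- function(path) {
  if (grepl("\\.tbl$", path, ignore.case = TRUE)) read_feature_table(path)
  else read_gff3(path)
}

normalize_ftype <- function(x) {
  ifelse(x %in% c("CDS", "tRNA", "rRNA", "ORF"), x, "other")
}

read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- if (!is.null(md$ID)) as.character(md$ID) else rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0("feat", seq_len(sum(is.na(ids))))
  nm <- if (!is.null(md$Name)) as.character(md$Name) else ids
  nm[is.na(nm)] <- ids[is.na(nm)]
  out <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    feature_id = ids,
    name = nm,
    ftype = normalize_ftype(as.character(md$type)),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    start = GenomicRanges::start(gr) - 1L,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    partial = FALSE, wrapped = FALSE,
    stringsAsFactors = FALSE
  )
  out <- out[out$ftype != "other" | !(as.character(md$type) %in% c("region", "gene")), ,
             drop = FALSE]
  out <- out[order(out$feature_id, out$start), , drop = FALSE]
  out$exon_rank <- stats::ave(out$start, out$feature_id, FUN = seq_along)
  rownames(out) <- NULL
  out[, c("seqid", "feature_id", "name", "ftype", "strand", "start", "end",
          "exon_rank", "partial", "wrapped")]
}

read_feature_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqid <- "."
  rows <- list(); cur <- NULL
  flush <- function(cur, rows) { if (!is.null(cur)) rows[[length(rows) + 1L]] <- cur; rows }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">Feature")) {
      seqid <- trimws(sub("^>Feature", "", ln))
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (nzchar(f[1])) {                    # interval line: start end [type]
      s <- suppressWarnings(as.integer(f[1])); e <- suppressWarnings(as.integer(f[2]))
      if (is.na(s) || is.na(e)) stop("cannot parse feature-table line: ", ln)
      partial <- grepl("[<>]", paste(f[1], f[2]))
      if (length(f) >= 3L && nzchar(f[3])) {      # new feature
        rows <- flush(cur, rows)
        cur <- list(seqid = seqid, type = f[3], ints = list(c(s, e)), partial = partial,
                    quals = character(0))
      } else {
        cur$ints[[length(cur$ints) + 1L]] <- c(s, e)
        cur$partial <- cur$partial || partial
      }
    } else if (length(f) >= 5L && !is.null(cur)) { # qualifier line
      cur$quals[f[4]] <- f[5]
    }
  }
  rows <- flush(cur, rows)
  if (!length(rows)) return(cbind(seqid = character(0), empty_features()))
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    ints <- do.call(rbind, r$ints)
    minus <- ints[1, 1] > ints[1, 2]
    if (minus) ints <- ints[, 2:1, drop = FALSE]
    nm <- if (!is.null(r$quals[["gene"]])) r$quals[["gene"]]
          else if (!is.null(r$quals[["product"]])) r$quals[["product"]]
          else paste0("feat", i)
    data.frame(seqid = r$seqid, feature_id = paste0("ft", i, "_", nm), name = nm,
               ftype = normalize_ftype(r$type),
               strand = if (minus) "-" else "+",
               start = ints[, 1] - 1L, end = ints[, 2],
               exon_rank = seq_len(nrow(ints)),
               partial = r$partial, wrapped = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write features as GFF3
#'
#' 1-based inclusive coordinates on output, one line per interval;
#' multi-interval features share an `ID` attribute.
#'
#' @param genome an [organelle_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  ft <- genome$features
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ft)) {
    lines <- sprintf("%s\torgdyn\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     genome$id, ft$ftype, ft$start + 1L, ft$end, ft$strand,
                     ft$feature_id, ft$name)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome an [organelle_genome()] (or list of them).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  gs <- if (inherits(genome, "organelle_genome")) list(genome) else genome
  seqs <- Biostrings::DNAStringSet(vapply(gs, `[[`, "", "sequence"))
  names(seqs) <- vapply(gs, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

## ---- pileup ---------------------------------------------------------------

#' Read samtools-mpileup text
#'
#' Decodes the base column on the reference strand (`.`/`,` count as the
#' reference base; letters as the alternative base, case-folded), registers
#' insertion/deletion markers so the distance from every site to its nearest
#' indel is available, and converts positions to 0-based.  Where the depth
#' column disagrees with the decoded base count by more than the deletions
#' and reference skips present, a warning is raised and the decoded counts
#' win.
#'
#' @param path mpileup-dialect text file (chrom, 1-based pos, ref, depth,
#'   bases, qualities).
#' @return A `pileup_sites` data.frame: `genome_id`, `pos` (0-based),
#'   `ref_base`, per-base counts `nA`..`nN`, `depth` (decoded), per-base mean
#'   qualities `qA`..`qT`, `mean_quality`, `n_del`, `has_indel`,
#'   `distance_to_nearest_indel` (Inf when the stream has no indel).
#' @export
read_pileup <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) stop("malformed pileup line ", i, ": fewer than 6 columns")
    dec <- decode_pileup_bases(f[5], toupper(f[3]), f[6])
    depth_col <- as.integer(f[4])
    if (abs(depth_col - dec$n_bases) > dec$n_del + dec$n_skip)
      warning("pileup line ", i, ": depth column (", depth_col,
              ") disagrees with decoded base count (", dec$n_bases,
              "); using decoded counts")
    out[[i]] <- data.frame(
      genome_id = f[1], pos = as.integer(f[2]) - 1L, ref_base = toupper(f[3]),
      nA = dec$counts[["A"]], nC = dec$counts[["C"]], nG = dec$counts[["G"]],
      nT = dec$counts[["T"]], nN = dec$counts[["N"]],
      depth = dec$n_bases,
      qA = dec$qmean[["A"]], qC = dec$qmean[["C"]], qG = dec$qmean[["G"]],
      qT = dec$qmean[["T"]],
      mean_quality = dec$mean_quality, n_del = dec$n_del,
      has_indel = dec$has_indel, stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame()
  df$distance_to_nearest_indel <- Inf
  for (g in unique(df$genome_id)) {
    sel <- df$genome_id == g
    ip <- df$pos[sel & df$has_indel]
    if (length(ip))
      df$distance_to_nearest_indel[sel] <-
        vapply(df$pos[sel], function(p) min(abs(p - ip)), 0)
  }
  class(df) <- c("pileup_sites", "data.frame")
  df
}

# Decode one mpileup base string together with its quality string.
decode_pileup_bases <- function(bases, ref, quals) {
  ch <- strsplit(bases, "")[[1]]
  qch <- strsplit(quals, "")[[1]]
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  qsum <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  i <- 1L; qi <- 1L; n_del <- 0L; n_skip <- 0L; has_indel <- FALSE
  take_qual <- function() {
    q <- if (qi <= length(qch)) utf8ToInt(qch[qi]) - 33L else NA_integer_
    qi <<- qi + 1L
    q
  }
  while (i <= length(ch)) {
    c0 <- ch[i]
    if (c0 == "^") { i <- i + 2L; next }              # read start + mapq char
    if (c0 == "$") { i <- i + 1L; next }
    if (c0 == "+" || c0 == "-") {                      # indel attached to previous base
      rest <- substr(bases, i + 1L, nchar(bases))
      m <- regmatches(rest, regexpr("^[0-9]+", rest))
      len <- as.integer(m)
      i <- i + 1L + nchar(m) + len
      has_indel <- TRUE
      next
    }
    if (c0 == "*") { n_del <- n_del + 1L; has_indel <- TRUE; take_qual(); i <- i + 1L; next }
    if (c0 == ">" || c0 == "<") { n_skip <- n_skip + 1L; take_qual(); i <- i + 1L; next }
    base <- if (c0 == "." || c0 == ",") ref else toupper(c0)
    if (!base %in% names(counts)) base <- "N"
    q <- take_qual()
    counts[base] <- counts[base] + 1L
    if (!is.na(q)) qsum[base] <- qsum[base] + q
    i <- i + 1L
  }
  n_bases <- sum(counts)
  qmean <- ifelse(counts > 0, qsum / counts, NA_real_)
  list(counts = counts, n_bases = n_bases,
       qmean = qmean,
       mean_quality = if (n_bases > 0) sum(qsum) / n_bases else NA_real_,
       n_del = n_del, n_skip = n_skip, has_indel = has_indel)
}

## ---- intervals ------------------------------------------------------------

#' Write an interval table
#'
#' BED is written 0-based half-open; TSV is written 1-based inclusive with a
#' header line naming the convention.
#'
#' @param records data.frame carrying `genome_id`, `start`, `end`
#'   (0-based half-open internal coordinates); extra columns are preserved
#'   in TSV output.
#' @param path output file.
#' @param format `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(records, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  stopifnot(all(c("genome_id", "start", "end") %in% names(records)))
  if (format == "bed") {
    df <- records[, c("genome_id", "start", "end")]
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    df <- records
    df$start <- df$start + 1L                      # 1-based inclusive
    con <- file(path, "w"); on.exit(close(con))
    writeLines("# coordinates: 1-based inclusive", con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = TRUE))
  }
  invisible(path)
}

#' Read an interval table written by [write_intervals()]
#'
#' @param path input file.
#' @param format `"bed"` or `"tsv"`.
#' @return data.frame with internal 0-based half-open `start`/`end`.
#' @export
read_intervals <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    names(df)[1:3] <- c("genome_id", "start", "end")
  } else {
    df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     stringsAsFactors = FALSE)
    df$start <- df$start - 1L
  }
  df
}
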