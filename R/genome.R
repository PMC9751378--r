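# Organelle genome container and feature bookkeeping.
#
# Features are stored as a data.frame with one row per interval
# (0-based half-open); multi-interval features share a feature_id and are
# ordered by exon_rank.  A feature wrapping the origin of a circular
# molecule is represented as two rows flagged wrapped = TRUE.

empty_features <- function() {
  data.frame(
    feature_id = character(0), name = character(0), ftype = character(0),
    strand = character(0), start = integer(0), end = integer(0),
    exon_rank = integer(0), partial = logical(0), wrapped = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Construct an organelle genome object
#'
#' @param id sequence identifier, unique within a dataset.
#' @param sequence DNA string over A, C, G, T, N (lowercase is folded up).
#' @param topology `"circular"` or `"linear"`.
#' @param kind `"mitogenome"` or `"plastome"`.
#' @param features feature table as produced by [read_features()]; one row
#'   per interval with 0-based half-open `start`/`end`.
#'
#' @return An object of class `organelle_genome`.
#' @export
organelle_genome <- function(id, sequence,
                             topology = c("circular", "linear"),
                             kind = c("mitogenome", "plastome"),
                             features = empty_features()) {
  topology <- match.arg(topology)
  kind <- match.arg(kind)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("genome '", id, "': sequence length must be > 0")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad))
    stop("genome '", id, "': sequence contains non-ACGTN character '",
         substr(bad, 1, 1), "'")
  g <- structure(
    list(id = as.character(id), sequence = sequence, topology = topology,
         kind = kind, features = features),
    class = "organelle_genome"
  )
  validate_features(g)
  g
}

#' Genome length in base pairs
#'
#' @param genome an [organelle_genome()].
#' @return integer sequence length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

validate_features <- function(genome) {
  ft <- genome$features
  if (!nrow(ft)) return(invisible(genome))
  L <- genome_length(genome)
  if (any(ft$start >= ft$end))
    stop("feature '", ft$feature_id[which(ft$start >= ft$end)[1]],
         "': empty or reversed interval")
  oob <- ft$start < 0 | ft$end > L
  if (any(oob))
    stop("feature '", ft$feature_id[which(oob)[1]],
         "' lies outside the ", L, "-bp sequence of genome '", genome$id, "'")
  if (any(ft$wrapped) && genome$topology != "circular")
    stop("wrapped features are only valid on circular genomes (genome '",
         genome$id, "')")
  invisible(genome)
}

#' @export
print.organelle_genome <- function(x, ...) {
  cat(sprintf("organelle_genome '%s': %s %s, %d bp, %d feature interval(s)\n",
              x$id, x$topology, x$kind, genome_length(x), nrow(x$features)))
  invisible(x)
}

# Extract a (possibly wrapped) subsequence, 0-based half-open.
genome_slice <- function(genome, start, end) {
  L <- genome_length(genome)
  if (end <= L) return(substr(genome$sequence, start + 1L, end))
  if (genome$topology != "circular") stop("slice beyond the end of a linear genome")
  paste0(substr(genome$sequence, start + 1L, L),
         substr(genome$sequence, 1L, end - L))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Per-feature interval list (rows of the feature table grouped by feature_id,
# in exon_rank order).
feature_intervals <- function(features, ftypes = NULL) {
  ft <- features
  if (!is.null(ftypes)) ft <- ft[ft$ftype %in% ftypes, , drop = FALSE]
  if (!nrow(ft)) return(list())
  ft <- ft[order(ft$feature_id, ft$exon_rank), , drop = FALSE]
  split(ft, ft$feature_id)
}
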