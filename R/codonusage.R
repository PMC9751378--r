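# Coding-sequence extraction and relative synonymous codon usage (RSCU).

#' Extract coding sequences from an annotated genome
#'
#' Exon intervals of each CDS feature are concatenated in feature order and
#' the concatenation is reverse-complemented for minus-strand features.
#' Sequences whose length is not divisible by 3 or that contain an internal
#' stop codon are flagged and, by default, excluded.
#'
#' @param genome an [organelle_genome()] with CDS features.
#' @param drop_invalid drop flagged sequences (default `TRUE`).
#' @param genetic_code NCBI translation table id; only table 1 (the
#'   standard code, used by plant mitochondria) is provided.
#' @return named character vector of CDS sequences (names are feature ids);
#'   attribute `"flagged"` lists excluded/flagged feature ids with reasons.
#' @export
extract_cds <- function(genome, drop_invalid = TRUE, genetic_code = "1") {
  feats <- feature_intervals(genome$features, "CDS")
  L <- genome_length(genome)
  out <- character(0); flagged <- character(0)
  for (fid in names(feats)) {
    ft <- feats[[fid]]
    if (any(ft$start < 0 | ft$end > L))
      stop("CDS '", fid, "' interval out of bounds")
    s <- paste0(vapply(seq_len(nrow(ft)), function(i)
      genome_slice(genome, ft$start[i], ft$end[i]), ""), collapse = "")
    if (ft$strand[1] == "-") s <- revcomp(s)
    reason <- NULL
    if (nchar(s) %% 3L != 0L) reason <- "length not divisible by 3"
    else if (has_internal_stop(s, genetic_code)) reason <- "internal stop codon"
    if (!is.null(reason)) {
      flagged[fid] <- reason
      if (drop_invalid) next
    }
    out[fid] <- s
  }
  attr(out, "flagged") <- flagged
  out
}

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

stop_codons <- c("TAA", "TAG", "TGA")

has_internal_stop <- function(s, genetic_code = "1") {
  cods <- codon_split(s)
  if (length(cods) <= 1L) return(FALSE)
  any(cods[-length(cods)] %in% stop_codons)
}

# codon -> amino acid map for the standard code, with the three stop codons
# treated as one synonymous family ("*")
codon_families <- function(genetic_code = "1") {
  gc <- Biostrings::GENETIC_CODE
  aa <- setNames(as.character(gc), names(gc))
  aa[names(aa) %in% stop_codons] <- "*"
  aa
}

#' Compute relative synonymous codon usage
#'
#' RSCU of a codon is its observed count multiplied by the size of its
#' synonymous family and divided by the family's total count; codons of an
#' observed family that were never used get RSCU 0.  The three stop codons
#' form one family, so a stop codon can be reported as preferred (RSCU > 1)
#' like any sense codon.  Codons are written with U for T in the output
#' table.
#'
#' @param cds_list character vector of coding sequences (each length
#'   divisible by 3), e.g. from [extract_cds()].
#' @param genetic_code NCBI translation table id (table 1 supported).
#' @return An object of class `codon_usage_table`: list with `counts` and
#'   `rscu` (named over the 64 codons, DNA alphabet) and `table`, a
#'   data.frame with columns `codon` (RNA alphabet), `amino_acid`, `count`,
#'   `rscu`.
#' @export
compute_rscu <- function(cds_list, genetic_code = "1") {
  fam <- codon_families(genetic_code)
  codons <- names(fam)
  counts <- setNames(integer(64), codons)
  if (length(cds_list)) {
    bad <- which(nchar(cds_list) %% 3L != 0L)
    if (length(bad))
      stop("sequence ", bad[1], " has length not divisible by 3")
    tab <- table(unlist(lapply(cds_list, codon_split)))
    counts[names(tab)] <- as.integer(tab)
  }
  rscu <- setNames(numeric(64), codons)
  for (a in unique(fam)) {
    members <- codons[fam == a]
    tot <- sum(counts[members])
    rscu[members] <- if (tot > 0) counts[members] * length(members) / tot else 0
  }
  tbl <- data.frame(
    codon = chartr("T", "U", codons),
    amino_acid = unname(fam),
    count = unname(counts),
    rscu = unname(rscu),
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, rscu = rscu, table = tbl),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("codon_usage_table:", sum(x$counts), "codons,",
      sum(x$rscu > 1), "codon(s) with RSCU > 1\n")
  invisible(x)
}

#' Codons preferred in every species
#'
#' @param tables list of `codon_usage_table` objects (>= 2), one per species.
#' @return character vector of codons (RNA alphabet) with RSCU > 1 in every
#'   table.
#' @export
shared_preferred_codons <- function(tables) {
  if (length(tables) < 2L) stop("need at least two codon usage tables")
  sets <- lapply(tables, function(t) names(t$rscu)[t$rscu > 1])
  chartr("T", "U", sort(Reduce(intersect, sets)))
}
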