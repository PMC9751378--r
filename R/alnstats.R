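# Concatenation of per-gene alignments and matrix site classification:
# columns containing any gap or ambiguity are counted as gap/missing and
# excluded from the variability classes; among clean columns, variable
# sites split into singleton (at most one base seen twice or more) and
# parsimony-informative (at least two bases each in at least two
# sequences), each sub-counted by the number of distinct bases.

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA.
#' @return named character vector, one aligned sequence per taxon.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Concatenate per-gene alignment blocks
#'
#' @param blocks list of alignment blocks (each a named character vector of
#'   equal-length aligned sequences); every block must contain every taxon
#'   exactly once.
#' @param taxa taxon set (default: the taxa of the first block).
#' @return list of class `concat_alignment` with `matrix` (named character
#'   vector of concatenated sequences) and `partitions` (data.frame
#'   `block`, `start`, `end`, 1-based inclusive).
#' @export
concat_alignments <- function(blocks, taxa = NULL) {
  if (!length(blocks)) stop("no alignment blocks given")
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  if (is.null(taxa)) taxa <- names(blocks[[1]])
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    missing <- setdiff(taxa, names(b))
    if (length(missing))
      stop("block '", bn, "' is missing taxon '", missing[1], "'")
    if (anyDuplicated(names(b)))
      stop("block '", bn, "' contains a duplicated taxon")
    if (length(unique(nchar(b))) != 1L)
      stop("block '", bn, "' has unequal sequence lengths")
  }
  widths <- vapply(blocks, function(b) nchar(b[[1]]), 0L)
  ends <- cumsum(widths)
  mat <- vapply(taxa, function(tx)
    paste0(vapply(blocks, function(b) unname(b[[tx]]), ""), collapse = ""), "")
  structure(list(
    matrix = mat,
    partitions = data.frame(block = names(blocks),
                            start = ends - widths + 1L, end = ends)
  ), class = "concat_alignment")
}

#' Write a 1-based partition table
#'
#' @param concat a `concat_alignment`.
#' @param path output TSV (gene, start, end; 1-based inclusive).
#' @return `path`, invisibly.
#' @export
write_partitions <- function(concat, path) {
  write.table(concat$partitions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Classify alignment sites
#'
#' @param aln a named character vector of aligned sequences, a
#'   `concat_alignment`, or a character matrix (rows = taxa).
#' @return An object of class `site_class_summary`: `total_sites`,
#'   `gap_or_missing_sites`, `invariant_sites`, `variable_sites`,
#'   `singleton_sites` and `informative_sites` with sub-counts by variant
#'   number (`two`, `three`, `four`), and `pct_variable` over the total
#'   alignment length.
#' @export
classify_sites <- function(aln) {
  if (inherits(aln, "concat_alignment")) aln <- aln$matrix
  if (is.character(aln) && !is.matrix(aln)) {
    if (length(unique(nchar(aln))) != 1L) stop("unequal row lengths")
    m <- do.call(rbind, strsplit(toupper(aln), ""))
  } else m <- toupper(aln)
  ncol_m <- ncol(m)
  cls <- apply(m, 2L, classify_column)
  tab <- function(x) sum(cls == x)
  summary <- list(
    total_sites = ncol_m,
    gap_or_missing_sites = tab("gap"),
    invariant_sites = tab("invariant"),
    variable_sites = sum(startsWith(cls, "singleton") | startsWith(cls, "informative")),
    singleton_sites = c(total = sum(startsWith(cls, "singleton")),
                        two = tab("singleton2"), three = tab("singleton3"),
                        four = tab("singleton4")),
    informative_sites = c(total = sum(startsWith(cls, "informative")),
                          two = tab("informative2"), three = tab("informative3"),
                          four = tab("informative4"))
  )
  summary$pct_variable <- 100 * summary$variable_sites / summary$total_sites
  structure(summary, class = "site_class_summary")
}

# one alignment column -> class label
classify_column <- function(col) {
  if (any(!col %in% c("A", "C", "G", "T"))) return("gap")
  counts <- table(col)
  k <- length(counts)
  if (k == 1L) return("invariant")
  informative <- sum(counts >= 2L) >= 2L
  paste0(if (informative) "informative" else "singleton", k)
}

#' @export
print.site_class_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "site_class_summary: %d sites; %d gap/missing; %d variable (%.2f%%):\n",
    "  singleton %d (two %d, three %d, four %d)\n",
    "  parsimony-informative %d (two %d, three %d, four %d)\n"),
    x$total_sites, x$gap_or_missing_sites, x$variable_sites, x$pct_variable,
    x$singleton_sites[["total"]], x$singleton_sites[["two"]],
    x$singleton_sites[["three"]], x$singleton_sites[["four"]],
    x$informative_sites[["total"]], x$informative_sites[["two"]],
    x$informative_sites[["three"]], x$informative_sites[["four"]]))
  invisible(x)
}
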