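#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline in one place.
#' Defaults follow the analysis protocol the package implements: MISA-style
#' SSR minimum repeat numbers of 8, 5, 4, 3, 3 and 3 units for mono- through
#' hexanucleotide motifs; dispersed repeats of at least 30 bp with at most 3
#' mismatches and at most 5000 reported pairs at an e-value cutoff of 1e-5;
#' homologous-fragment cutoffs of e-value 1e-5, 80% identity and 100 bp
#' minimum length; 5000-bp mitogenome and 3000-bp plastome transfer windows
#' with a strict >2000-bp hotspot rule; RNA-editing depth minima of 10
#' (mitogenome) and 20 (plastome) reads with base quality >= 10 and exclusion
#' within 5 bp of an indel; transcription windows of 100/50 bp and
#' sequencing-depth windows of 500/200 bp.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return An object of class `orgdyn_config`: a named list with elements
#'   `ssr_min_repeats` (integer six-vector, mono..hexa), `repeat_min_len`,
#'   `repeat_max_mismatch`, `repeat_max_reports`, `homology_evalue`,
#'   `homology_min_identity`, `fragment_min_len`, `mito_window`,
#'   `plastid_window`, `hotspot_min_bp`, `edit_min_depth_mito`,
#'   `edit_min_depth_plastid`, `edit_min_quality`, `edit_indel_exclusion`,
#'   `edit_min_alt_count`, `edit_min_alt_fraction`, `rna_window_bin`,
#'   `rna_window_step`, `depth_window_bin`, `depth_window_step`,
#'   `synteny_display_min`, `orf_min_len`, `ir_min_len`, `seed_kmer`,
#'   `xdrop`, `match`, `mismatch`, `gap_open`, `gap_extend`,
#'   `circular_pad`, `rng_seed`.
#'
#' @examples
#' cfg <- orgdyn_config(hotspot_min_bp = 1500)
#' cfg$hotspot_min_bp
#' @export
orgdyn_config <- function(...) {
  cfg <- list(
    ssr_min_repeats = c(8L, 5L, 4L, 3L, 3L, 3L),
    repeat_min_len = 30L,
    repeat_max_mismatch = 3L,
    repeat_max_reports = 5000L,
    homology_evalue = 1e-5,
    homology_min_identity = 0.80,
    fragment_min_len = 100L,
    mito_window = 5000L,
    plastid_window = 3000L,
    hotspot_min_bp = 2000L,
    edit_min_depth_mito = 10L,
    edit_min_depth_plastid = 20L,
    edit_min_quality = 10,
    edit_indel_exclusion = 5L,
    edit_min_alt_count = 2L,
    edit_min_alt_fraction = 0.05,
    rna_window_bin = 100L,
    rna_window_step = 50L,
    depth_window_bin = 500L,
    depth_window_step = 200L,
    synteny_display_min = 5000L,
    orf_min_len = 150L,
    ir_min_len = 1000L,
    seed_kmer = 15L,
    xdrop = 20,
    match = 1,
    mismatch = -2,
    gap_open = -5,
    gap_extend = -2,
    circular_pad = 10000L,
    rng_seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "orgdyn_config")
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$ssr_min_repeats) == 6L, all(cfg$ssr_min_repeats > 0))
  pos <- c("repeat_min_len", "repeat_max_reports", "homology_evalue",
           "fragment_min_len", "mito_window", "plastid_window", "hotspot_min_bp",
           "edit_min_depth_mito", "edit_min_depth_plastid", "edit_min_quality",
           "rna_window_bin", "rna_window_step", "depth_window_bin",
           "depth_window_step", "synteny_display_min", "orf_min_len",
           "ir_min_len", "seed_kmer", "xdrop")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("configuration field '", f, "' must be a single positive number")
  }
  if (cfg$homology_min_identity <= 0 || cfg$homology_min_identity > 1)
    stop("homology_min_identity must lie in (0, 1]")
  if (cfg$repeat_max_mismatch < 0) stop("repeat_max_mismatch must be >= 0")
  invisible(cfg)
}

#' Read a configuration file
#'
#' Plain `key = value` (or `key: value`) text; vector values comma-separated.
#' Unknown keys are rejected.
#'
#' @param path path to the configuration file.
#' @return An [orgdyn_config()] object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse configuration line: ", ln)
    vals <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    kv[[m[2]]] <- if (anyNA(num)) vals else num
  }
  do.call(orgdyn_config, kv)
}

#' @export
print.orgdyn_config <- function(x, ...) {
  cat("orgdyn pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}
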