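# RNA-editing site calling from pileups: C>T and T>C sites on the
# reference plus strand, filtered on depth (10 reads for mitogenomes, 20
# for plastomes), base quality (>= 10 on the variant-supporting reads),
# distance to the nearest indel (> 5 bp), and minimum variant evidence
# (>= 2 supporting reads at >= 5% of the depth, to suppress singleton
# sequencing errors).  Efficiency is the edited-read fraction.

empty_editing_sites <- function() {
  structure(data.frame(
    genome_id = character(0), pos = integer(0), ref_base = character(0),
    alt_base = character(0), edit_type = character(0), depth = integer(0),
    alt_count = integer(0), efficiency = numeric(0), location = character(0),
    tissue = character(0), stringsAsFactors = FALSE
  ), class = c("editing_sites", "data.frame"))
}

#' Call RNA-editing sites from a pileup
#'
#' @param pileup a `pileup_sites` data.frame from [read_pileup()] (or
#'   [simulate_pileup()]).
#' @param genome the [organelle_genome()] the reads were aligned to; its
#'   `kind` selects the depth threshold (mitogenome 10, plastome 20).
#' @param tissue tissue label attached to every site.
#' @param config an [orgdyn_config()].
#' @param strand_aware also accept G>A / A>G evidence remapped through the
#'   coding strand of an overlapping gene (off by default: edit types are
#'   evaluated on the reference plus strand exactly as stated).
#' @return An `editing_sites` data.frame: `genome_id`, `pos` (0-based),
#'   `ref_base`, `alt_base`, `edit_type` (`C>T`/`T>C`), `depth`,
#'   `alt_count`, `efficiency`, `location` (`NA` until
#'   [classify_site_location()]), `tissue`.
#' @export
call_editing_sites <- function(pileup, genome, tissue = "unknown",
                               config = orgdyn_config(), strand_aware = FALSE) {
  min_depth <- switch(genome$kind,
                      mitogenome = config$edit_min_depth_mito,
                      plastome = config$edit_min_depth_plastid,
                      stop("unknown genome kind: ", genome$kind))
  p <- pileup[pileup$genome_id == genome$id, , drop = FALSE]
  if (!nrow(p)) return(empty_editing_sites())
  cand <- rbind(
    make_candidates(p, ref = "C", alt = "T", type = "C>T"),
    make_candidates(p, ref = "T", alt = "C", type = "T>C"),
    if (strand_aware) rbind(
      make_candidates(p, ref = "G", alt = "A", type = "C>T"),
      make_candidates(p, ref = "A", alt = "G", type = "T>C"))
  )
  if (is.null(cand) || !nrow(cand)) return(empty_editing_sites())
  if (strand_aware) {
    minus <- strand_at(genome$features, cand$pos) == "-"
    keep_sa <- cand$ref_base %in% c("C", "T") |
      (cand$ref_base %in% c("G", "A") & minus)
    cand <- cand[keep_sa, , drop = FALSE]
  }
  pass <- cand$depth >= min_depth &
    cand$alt_quality >= config$edit_min_quality &
    cand$indel_distance > config$edit_indel_exclusion &
    cand$alt_count >= config$edit_min_alt_count &
    cand$alt_count / cand$depth >= config$edit_min_alt_fraction
  cand <- cand[pass, , drop = FALSE]
  if (!nrow(cand)) return(empty_editing_sites())
  out <- data.frame(
    genome_id = cand$genome_id, pos = cand$pos, ref_base = cand$ref_base,
    alt_base = cand$alt_base, edit_type = cand$edit_type, depth = cand$depth,
    alt_count = cand$alt_count, efficiency = cand$alt_count / cand$depth,
    location = NA_character_, tissue = tissue, stringsAsFactors = FALSE
  )
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("editing_sites", "data.frame")
  out
}

make_candidates <- function(p, ref, alt, type) {
  sel <- p$ref_base == ref & p[[paste0("n", alt)]] >= 1L
  if (!any(sel)) return(NULL)
  q <- p[sel, , drop = FALSE]
  data.frame(
    genome_id = q$genome_id, pos = q$pos, ref_base = ref, alt_base = alt,
    edit_type = type, depth = q$depth, alt_count = q[[paste0("n", alt)]],
    alt_quality = q[[paste0("q", alt)]],
    indel_distance = q$distance_to_nearest_indel, stringsAsFactors = FALSE
  )
}

strand_at <- function(features, pos) {
  out <- rep("+", length(pos))
  for (i in seq_len(nrow(features))) {
    hit <- pos >= features$start[i] & pos < features$end[i]
    out[hit] <- features$strand[i]
  }
  out
}

#' Classify editing sites as CDS or non-CDS
#'
#' A site is `cds` when its position lies inside an exonic interval of a
#' CDS feature; introns and intergenic positions are `non-cds`.
#'
#' @param sites an `editing_sites` data.frame.
#' @param features a feature table.
#' @return `sites` with the `location` column filled.
#' @export
classify_site_location <- function(sites, features) {
  cds <- features[features$ftype == "CDS", , drop = FALSE]
  inside <- vapply(sites$pos, function(p)
    any(p >= cds$start & p < cds$end), TRUE)
  sites$location <- ifelse(inside, "cds", "non-cds")
  sites
}

#' Bin editing efficiencies
#'
#' Five bins `[0,0.2) [0.2,0.4) [0.4,0.6) [0.6,0.8) [0.8,1]`; the top bin
#' is closed so an efficiency of exactly 0.8 falls in `0.8-1`.
#'
#' @param sites an `editing_sites` data.frame (or numeric efficiencies).
#' @return list with `counts` and `fractions`, named by bin.
#' @export
bin_efficiency <- function(sites) {
  eff <- if (is.numeric(sites)) sites else sites$efficiency
  labs <- c("0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", "0.8-1")
  b <- cut(eff, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1), right = FALSE,
           include.lowest = TRUE, labels = labs)
  counts <- as.integer(table(b))
  names(counts) <- labs
  list(counts = counts,
       fractions = if (length(eff)) counts / length(eff) else setNames(rep(NA_real_, 5), labs))
}

#' Summarise editing sites across tissues
#'
#' @param site_lists list of `editing_sites` data.frames (one per tissue,
#'   possibly covering several genomes), or a single combined data.frame.
#' @return list with `per_tissue` (one row per tissue x genome: site count,
#'   counts by edit type, percentage in CDS, percentage per efficiency
#'   bin) and `contributions` (per genome, each tissue's percentage of all
#'   its sites).
#' @export
tissue_summary <- function(site_lists) {
  df <- if (is.data.frame(site_lists)) site_lists else do.call(rbind, site_lists)
  if (is.null(df) || !nrow(df))
    return(list(per_tissue = data.frame(), contributions = data.frame()))
  key <- interaction(df$tissue, df$genome_id, drop = TRUE)
  rows <- lapply(split(df, key), function(d) {
    eb <- bin_efficiency(d)
    data.frame(
      tissue = d$tissue[1], genome_id = d$genome_id[1], n_sites = nrow(d),
      n_ct = sum(d$edit_type == "C>T"), n_tc = sum(d$edit_type == "T>C"),
      pct_ct = 100 * mean(d$edit_type == "C>T"),
      pct_cds = 100 * mean(d$location == "cds"),
      pct_eff_0.8_1 = 100 * eb$fractions[["0.8-1"]],
      pct_eff_0.6_0.8 = 100 * eb$fractions[["0.6-0.8"]],
      pct_eff_0.4_0.6 = 100 * eb$fractions[["0.4-0.6"]],
      pct_eff_0.2_0.4 = 100 * eb$fractions[["0.2-0.4"]],
      pct_eff_0_0.2 = 100 * eb$fractions[["0-0.2"]],
      stringsAsFactors = FALSE
    )
  })
  per_tissue <- do.call(rbind, rows)
  rownames(per_tissue) <- NULL
  contrib <- do.call(rbind, lapply(split(per_tissue, per_tissue$genome_id),
                                   function(d) {
    d$pct_of_genome <- 100 * d$n_sites / sum(d$n_sites)
    d[, c("genome_id", "tissue", "n_sites", "pct_of_genome")]
  }))
  rownames(contrib) <- NULL
  list(per_tissue = per_tissue, contributions = contrib)
}
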