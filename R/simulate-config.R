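#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the simulators into one validated object. The
#' defaults describe a small but realistic stem-cell-like experiment: a few
#' hundred coding sequences spanning a broad GC3 gradient, four biological
#' replicates per cell state, footprints concentrated at read lengths
#' 27-29 nt with 5' ends in frame 0, elevated ribosome dwell on stop codons,
#' and heavily inosine-modified hetADAT tRNAs.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_genes Number of coding sequences to simulate.
#' @param length_range_codons Inclusive range of CDS lengths, in codons
#'   (including the start and stop codon). The default brackets the human
#'   mean protein length (~460 aa); much shorter genes inflate
#'   initiation/termination boundary effects on the flank positions.
#' @param gc3_range Range from which each gene's target third-position GC is
#'   drawn uniformly; synonymous codons are then sampled with weights
#'   favouring G/C-ending codons accordingly.
#' @param utr_length_range Range of simulated 5' and 3' UTR lengths (nt).
#'   The minimum must be at least 20 so that any footprint whose A-site lies
#'   on the first or last codon still fits inside the transcript.
#' @param n_replicates Biological replicates per condition.
#' @param de_fraction Fraction of genes differentially expressed between
#'   conditions.
#' @param de_log2fc_range Magnitude range of planted expression log2
#'   fold-changes (sign random).
#' @param dwell_weights Named numeric vector of per-codon ribosome dwell
#'   multipliers; codons not named default to 1. The default gives the three
#'   stop codons weight 4, emulating slow termination.
#' @param dwell_site Ribosome-protected codon position (-5..+3) at which the
#'   dwell weights act; 0 (the A-site) by default, -1 plants a P-site signal.
#' @param read_length_table Tibble with columns `length`, `fraction`,
#'   `frame`: the footprint length mixture and the reading frame of the
#'   5' ends for each (length, frame) stratum. Fractions must sum to 1, and
#'   each length must satisfy `length - (3 - frame) %% 3 >= 27` so nine
#'   codons remain after frame trimming.
#' @param n_footprints Number of ribosome footprints per sample.
#' @param trna_set Tibble describing the tRNA pool: `trna_id`, `isotype`,
#'   `anticodon`, and optional intron placement flag `has_intron`. The
#'   default holds the eight hetADAT-substrate tRNAs (wobble A34) plus two
#'   unmodified controls, with introns planted in two tRNAs.
#' @param inosine_rates Named vector of per-tRNA wobble inosine levels
#'   (fraction of transcripts edited). Defaults to 0.85 for every
#'   hetADAT-substrate tRNA, the level typical of self-renewing cells.
#' @param reads_per_trna tRNA-seq reads simulated per tRNA.
#' @param seq_error_rate Per-base sequencing error probability (uniform
#'   substitution to one of the three other bases).
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- simulation_config(seed = 1, n_genes = 50)
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 300L,
                              length_range_codons = c(150L, 750L),
                              gc3_range = c(0.2, 0.8),
                              utr_length_range = c(25L, 60L),
                              n_replicates = 4L,
                              de_fraction = 0.2,
                              de_log2fc_range = c(0.5, 3),
                              dwell_weights = c(TAA = 4, TAG = 4, TGA = 4),
                              dwell_site = 0L,
                              read_length_table = default_read_lengths(),
                              n_footprints = 100000L,
                              trna_set = default_trna_set(),
                              inosine_rates = NULL,
                              reads_per_trna = 500L,
                              seq_error_rate = 0.001) {
  if (is.null(inosine_rates)) {
    het <- trna_set$trna_id[trna_set$isotype %in% names(HETADAT_ISOTYPES)]
    inosine_rates <- stats::setNames(rep(0.85, length(het)), het)
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    length_range_codons = as.integer(length_range_codons),
    gc3_range = gc3_range, utr_length_range = as.integer(utr_length_range),
    n_replicates = as.integer(n_replicates), de_fraction = de_fraction,
    de_log2fc_range = de_log2fc_range, dwell_weights = dwell_weights,
    dwell_site = as.integer(dwell_site),
    read_length_table = read_length_table,
    n_footprints = as.integer(n_footprints), trna_set = trna_set,
    inosine_rates = inosine_rates,
    reads_per_trna = as.integer(reads_per_trna),
    seq_error_rate = seq_error_rate
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, cfg$n_genes >= 1L,
    length(cfg$length_range_codons) == 2L,
    cfg$length_range_codons[1] >= 2L,
    diff(cfg$length_range_codons) >= 0L,
    all(cfg$gc3_range >= 0), all(cfg$gc3_range <= 1),
    cfg$utr_length_range[1] >= 20L,
    cfg$n_replicates >= 1L,
    cfg$de_fraction >= 0, cfg$de_fraction <= 1,
    cfg$seq_error_rate >= 0, cfg$seq_error_rate <= 1,
    cfg$dwell_site >= -5L, cfg$dwell_site <= 3L
  )
  if (cfg$length_range_codons[1] == cfg$length_range_codons[2] &&
    cfg$length_range_codons[1] < 2L) {
    stop("degenerate length range")
  }
  if (any(cfg$dwell_weights <= 0)) stop("dwell weights must be positive")
  rl <- cfg$read_length_table
  stopifnot(all(c("length", "fraction", "frame") %in% names(rl)))
  if (abs(sum(rl$fraction) - 1) > 1e-9) {
    stop("read length fractions must sum to 1")
  }
  if (!all(rl$frame %in% 0:2)) stop("frames must be 0, 1 or 2")
  trim <- (3L - rl$frame) %% 3L
  if (any(rl$length - trim < 27L)) {
    stop("read length too short to hold nine codons after frame trimming")
  }
  if (any(cfg$inosine_rates < 0 | cfg$inosine_rates > 1)) {
    stop("inosine rates must lie in [0, 1]")
  }
  unknown <- setdiff(names(cfg$inosine_rates), cfg$trna_set$trna_id)
  if (length(unknown)) {
    stop("inosine rate given for unknown tRNA: ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' @rdname simulation_config
#' @export
default_read_lengths <- function() {
  tibble::tibble(
    length = c(27L, 28L, 29L),
    fraction = c(0.25, 0.5, 0.25),
    frame = c(0L, 0L, 0L)
  )
}

#' @rdname simulation_config
#' @export
default_trna_set <- function() {
  iso <- names(HETADAT_ISOTYPES)
  # Anticodons of the eight hetADAT substrates all carry wobble A34.
  anticodon <- c(
    Ala = "AGC", Arg = "ACG", Ile = "AAT", Leu = "AAG",
    Pro = "AGG", Ser = "AGA", Thr = "AGT", Val = "AAC"
  )
  het <- tibble::tibble(
    trna_id = paste0("tRNA-", iso, "-", anticodon[iso]),
    isotype = iso,
    anticodon = unname(anticodon[iso]),
    has_intron = iso %in% c("Ile", "Leu")
  )
  ctrl <- tibble::tibble(
    trna_id = c("tRNA-Gly-GCC", "tRNA-Phe-GAA"),
    isotype = c("Gly", "Phe"),
    anticodon = c("GCC", "GAA"),
    has_intron = FALSE
  )
  dplyr::bind_rows(het, ctrl)
}
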