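# In-silico model of the glycosylase-coupled deamination assays: a
# 5'-radiolabeled ssDNA oligo with one target base at the central
# position is deaminated with a per-molecule Bernoulli probability, the
# deaminated base is excised by a glycosylase, and alkali cleaves the
# strand at the abasic site. Only 5'-labeled fragments are visible on the
# gel, so complete deamination of an 80-mer with the target at position
# 41 yields a 40-nt product band. Band quantification, relative activity
# (percent of wild type) and the C-vs-5mC Pearson correlation follow.

DEAMINATION_PRODUCT <- c("C" = "U", "5mC" = "T", "5hmC" = "5hmU")
CONTROL_BASES <- c("U", "T", "5hmU")

#' Substrate oligonucleotide
#'
#' A 5'->3' ssDNA sequence with exactly one annotated special position
#' carrying the assay-relevant base. The standard assay substrate is 80
#' nt with the special base at the central position, defined as position
#' 41 (1-based) so that cleavage 5' of it leaves a 40-nt labeled
#' fragment.
#'
#' @param sequence character string over A/C/G/T (the special position's
#'   letter is a placeholder and is interpreted via `base_kind`).
#' @param special_pos 1-based index of the special base.
#' @param base_kind one of C, 5mC, 5hmC, U, T, 5hmU.
#' @param labeled logical, 5'-radiolabel flag (default TRUE).
#' @return object of class `SubstrateOligo`.
#' @export
substrate_oligo <- function(sequence, special_pos = nchar(sequence) %/% 2 + 1,
                            base_kind = c("C", "5mC", "5hmC", "U", "T", "5hmU"),
                            labeled = TRUE) {
  base_kind <- match.arg(base_kind)
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("substrate sequence must be over A/C/G/T")
  }
  n <- nchar(sequence)
  if (special_pos < 1L || special_pos > n) stop("special position out of range")
  structure(list(sequence = sequence, special_pos = as.integer(special_pos),
                 base_kind = base_kind, length = n, labeled = labeled),
            class = "SubstrateOligo")
}

#' Standard 80-nt assay substrate
#'
#' Builds the canonical assay oligo: 80 nt with a single special base at
#' the central position (41) inside an AGXT motif, all other positions
#' free of the special base. The flanking sequence is a fixed
#' deterministic C-free filler so that the target position is the only
#' deamination-eligible site.
#'
#' @param base_kind the central base kind (default `"C"`).
#' @return a `SubstrateOligo` of length 80.
#' @export
standard_assay_oligo <- function(base_kind = "C") {
  filler <- paste(rep(c("A", "G", "T", "G"), 30L), collapse = "")
  left <- substr(filler, 1L, 38L)
  right <- substr(filler, 1L, 38L)
  seqn <- paste0(left, "AGCT", right)  # special base is position 41 ("C")
  substrate_oligo(seqn, special_pos = 41L, base_kind = base_kind)
}

#' Enzyme deamination profile
#'
#' Per-reaction Bernoulli deamination probabilities of an AID variant on
#' each substrate base kind. The shipped presets scale the wild-type
#' probabilities to configurable baselines and set the variant ratios to
#' the published relative activities (percent of wild type on C:
#' R190X 140, R50A 20, N51A 0; on 5mC: R190X 55, R50A 60, N51A 78); all
#' presets have zero efficiency on 5hmC, on which no variant showed
#' detectable activity. These are fixture values for simulation, not
#' measurements.
#'
#' @param variant one of `"wt"`, `"R50A"`, `"N51A"`, `"R190X"`, or
#'   `"custom"` with explicit `efficiency`.
#' @param efficiency named numeric vector base_kind -> probability in
#'   [0,1]; required for `"custom"`, otherwise derived from the preset
#'   ratios.
#' @param wt_c_baseline,wt_5mc_baseline wild-type per-reaction
#'   deamination probabilities on C and 5mC used to anchor the presets.
#' @return object of class `EnzymeProfile`.
#' @export
enzyme_profile <- function(variant = c("wt", "R50A", "N51A", "R190X", "custom"),
                           efficiency = NULL, wt_c_baseline = 0.5,
                           wt_5mc_baseline = 0.4) {
  variant <- match.arg(variant)
  if (variant == "custom") {
    if (is.null(efficiency)) stop("custom profile requires an efficiency map")
  } else {
    ratios_c <- c(wt = 1.0, R50A = 0.20, N51A = 0.0, R190X = 1.40)
    ratios_5mc <- c(wt = 1.0, R50A = 0.60, N51A = 0.78, R190X = 0.55)
    efficiency <- c("C" = unname(wt_c_baseline * ratios_c[variant]),
                    "5mC" = unname(wt_5mc_baseline * ratios_5mc[variant]),
                    "5hmC" = 0)
  }
  if (any(efficiency < 0 | efficiency > 1)) {
    stop("deamination probabilities must lie in [0, 1]")
  }
  if (!is.null(efficiency["5hmC"]) && !is.na(efficiency["5hmC"]) &&
      variant != "custom" && efficiency["5hmC"] != 0) {
    stop("preset profiles must have zero 5hmC efficiency")
  }
  structure(list(variant = variant, efficiency = efficiency),
            class = "EnzymeProfile")
}

#' Glycosylase specification
#'
#' The excision step of the coupled assay: UDG excises U from ssDNA,
#' hSMUG1 excises U and 5hmU, and TDG excises T opposite G after the
#' product strand is annealed to a fully complementary oligo (creating a
#' central G:T mismatch) — so TDG requires the duplex.
#'
#' @param name `"UDG"`, `"hSMUG1"` or `"TDG"`.
#' @return object of class `GlycosylaseSpec` with fields `name`,
#'   `excises`, `requires_duplex`.
#' @export
glycosylase_spec <- function(name = c("UDG", "hSMUG1", "TDG")) {
  name <- match.arg(name)
  excises <- switch(name, UDG = "U", hSMUG1 = c("U", "5hmU"), TDG = "T")
  structure(list(name = name, excises = excises,
                 requires_duplex = name == "TDG"),
            class = "GlycosylaseSpec")
}

#' Gel lane
#'
#' @param bands data.frame with columns `length` (nt, >= 1) and
#'   `intensity` (arbitrary units, >= 0).
#' @param label lane label.
#' @return object of class `GelLane`.
#' @export
gel_lane <- function(bands, label = "") {
  bands <- as.data.frame(bands)
  stopifnot(all(c("length", "intensity") %in% names(bands)))
  if (any(bands$intensity < 0)) stop("band intensities must be >= 0")
  if (any(bands$length < 1)) stop("band lengths must be >= 1 nt")
  structure(list(bands = bands, label = label), class = "GelLane")
}

#' Simulate a glycosylase-coupled deamination assay
#'
#' Per molecule: the special base deaminates with probability
#' `enzyme$efficiency[base_kind]` (C -> U, 5mC -> T, 5hmC -> 5hmU);
#' control bases (U, T, 5hmU) bypass deamination and enter the excision
#' step directly. The glycosylase excises its eligible base, creating an
#' abasic site, and alkaline cleavage splits the strand there; both
#' steps are treated as complete, saturating control steps. Only the
#' 5'-labeled fragment is visible, with length `special_pos - 1`.
#' Calling the duplex-dependent TDG branch without annealing yields zero
#' product.
#'
#' @param oligo a `SubstrateOligo`.
#' @param enzyme an `EnzymeProfile`.
#' @param glyco a `GlycosylaseSpec`.
#' @param n_molecules number of molecules simulated (>= 1).
#' @param seed RNG seed for the Bernoulli deamination draws.
#' @param annealed logical; whether the post-deamination annealing step
#'   was performed (defaults to the glycosylase's requirement, i.e. the
#'   standard protocol).
#' @param detection_limit product fraction below which the result is
#'   labeled as no detectable activity (default 0.01; labeling only).
#' @return list with `product_fraction`, `fragments` (labeled fragment
#'   length histogram as a data.frame), `detectable`, and the echoed
#'   settings.
#' @export
simulate_assay <- function(oligo, enzyme, glyco, n_molecules = 1e5, seed = 1,
                           annealed = glyco$requires_duplex,
                           detection_limit = 0.01) {
  stopifnot(inherits(oligo, "SubstrateOligo"), inherits(enzyme, "EnzymeProfile"),
            inherits(glyco, "GlycosylaseSpec"))
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  kind <- oligo$base_kind
  if (kind %in% CONTROL_BASES) {
    converted <- kind
    n_conv <- n_molecules  # control oligos carry the product base already
  } else {
    converted <- DEAMINATION_PRODUCT[[kind]]
    p <- enzyme$efficiency[[kind]]
    if (is.null(p) || is.na(p)) stop("no efficiency for base kind ", kind)
    n_conv <- with_seed(seed, stats::rbinom(1L, n_molecules, p))
  }
  excisable <- converted %in% glyco$excises &&
    (!glyco$requires_duplex || annealed)
  n_cleaved <- if (excisable) n_conv else 0L
  frag_len <- oligo$special_pos - 1L
  fragments <- data.frame(
    length = c(frag_len, oligo$length),
    count = c(n_cleaved, n_molecules - n_cleaved))
  fragments <- fragments[fragments$count > 0L, , drop = FALSE]
  rownames(fragments) <- NULL
  pf <- n_cleaved / n_molecules
  list(product_fraction = pf, fragments = fragments,
       product_length = frag_len, substrate_length = oligo$length,
       detectable = pf >= detection_limit,
       base_kind = kind, glycosylase = glyco$name, n_molecules = n_molecules,
       seed = seed)
}

#' Quantify a gel lane into a product fraction
#'
#' `I_product / (I_product + I_substrate)` over the named product and
#' substrate bands; an absent band counts as zero intensity.
#'
#' @param lane a `GelLane`.
#' @param product_length product band length in nt.
#' @param substrate_length substrate band length in nt.
#' @return product fraction in [0, 1].
#' @export
quantify_lane <- function(lane, product_length, substrate_length) {
  stopifnot(inherits(lane, "GelLane"))
  ip <- sum(lane$bands$intensity[lane$bands$length == product_length])
  is <- sum(lane$bands$intensity[lane$bands$length == substrate_length])
  if (ip + is == 0) {
    stop("undefined lane: no intensity in either the product or the ",
         "substrate band")
  }
  ip / (ip + is)
}

#' Relative activity as percent of wild type
#'
#' `100 * mean(variant) / mean(wt)` over replicate product fractions,
#' with the standard deviation propagated from the replicate spread:
#' sd(percent) = 100 * sqrt(var(v)/n_v / m_w^2 + m_v^2 var(w)/n_w / m_w^4)
#' (delta method on the ratio of replicate means).
#'
#' @param variant_fractions replicate product fractions of the variant.
#' @param wt_fractions replicate product fractions of wild type.
#' @return list with `percent_of_wt` and `sd`.
#' @export
relative_activity <- function(variant_fractions, wt_fractions) {
  mw <- mean(wt_fractions)
  if (mw <= 0) stop("wild-type mean activity is zero; percent undefined")
  mv <- mean(variant_fractions)
  vv <- if (length(variant_fractions) > 1L) {
    stats::var(variant_fractions) / length(variant_fractions)
  } else 0
  vw <- if (length(wt_fractions) > 1L) {
    stats::var(wt_fractions) / length(wt_fractions)
  } else 0
  sd <- 100 * sqrt(vv / mw^2 + mv^2 * vw / mw^4)
  list(percent_of_wt = 100 * mv / mw, sd = sd)
}

#' Pearson correlation between activity profiles
#'
#' The product-moment correlation between per-variant activity percents
#' on two substrates (e.g. C vs 5mC).
#'
#' @param values_c,values_5mc equal-length numeric vectors (>= 3), each
#'   with nonzero variance.
#' @return Pearson r in [-1, 1].
#' @export
activity_correlation <- function(values_c, values_5mc) {
  if (length(values_c) != length(values_5mc) || length(values_c) < 3L) {
    stop("activity vectors must have equal length >= 3")
  }
  if (stats::var(values_c) == 0 || stats::var(values_5mc) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(values_c, values_5mc)
}

#' Read and write gel lanes as TSV
#'
#' The TSV has columns `length` and `intensity`, one band per row.
#'
#' @param path TSV path.
#' @param label lane label for [read_gel_lane()].
#' @return a `GelLane` / `path` invisibly.
#' @export
read_gel_lane <- function(path, label = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  gel_lane(df, label = label)
}

#' @rdname read_gel_lane
#' @param lane a `GelLane` for [write_gel_lane()].
#' @export
write_gel_lane <- function(lane, path) {
  utils::write.table(lane$bands, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
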