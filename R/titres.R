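#' A titration observation from a transduction assay
#'
#' One supernatant dilution scored by flow cytometry: the percentage of
#' transgene-positive cells, the number of cells seeded per well, the
#' inoculum volume, and the dilution factor.
#'
#' @param percent_positive Percent transgene-positive cells, in `[0, 100]`.
#' @param cells_seeded Cells seeded per well (`C`).
#' @param volume_ml Inoculum volume in mL (`V`); 0.1 mL in a standard
#'   24-well titration.
#' @param dilution Dilution factor (`D`), > 0.
#' @return A `titre_observation` data.frame (one row per observation; the
#'   arguments recycle), with `F = percent_positive / 100`.
#' @export
titre_observation <- function(percent_positive, cells_seeded,
                              volume_ml = 0.1, dilution) {
  obs <- data.frame(
    percent_positive = as.numeric(percent_positive),
    F = as.numeric(percent_positive) / 100,
    cells_seeded = cells_seeded,
    volume_ml = volume_ml,
    dilution = dilution
  )
  if (any(obs$percent_positive < 0 | obs$percent_positive > 100)) {
    stop("percent_positive must be in [0, 100]", call. = FALSE)
  }
  if (any(obs$cells_seeded <= 0)) stop("cells_seeded must be > 0", call. = FALSE)
  class(obs) <- c("titre_observation", "data.frame")
  obs
}

#' Infectious titre in transducing units per mL
#'
#' `TU/mL = (F * C / V) * D` with `F` the frequency of transgene-positive
#' cells (percent positive / 100), `C` cells seeded per well, `V` the
#' inoculum volume in mL and `D` the dilution factor.
#'
#' @param obs A `titre_observation` (any number of rows).
#' @return Numeric vector of TU/mL, one per observation.
#' @export
infectious_titre <- function(obs) {
  if (any(obs$volume_ml <= 0)) stop("volume_ml must be > 0", call. = FALSE)
  if (any(obs$dilution <= 0)) stop("dilution must be > 0", call. = FALSE)
  (obs$F * obs$cells_seeded / obs$volume_ml) * obs$dilution
}

#' Keep the dilutions inside the linear gating window
#'
#' Only dilutions giving 5-25% positive cells (bounds inclusive) are in the
#' assay's linear range and usable for titre calculation.
#'
#' @param series A `titre_observation` with one row per dilution.
#' @param lower,upper Gating bounds in percent (default 5 and 25).
#' @return The retained rows, in input order.
#' @export
select_valid_dilutions <- function(series, lower = 5, upper = 25) {
  series[series$percent_positive >= lower &
           series$percent_positive <= upper, , drop = FALSE]
}

#' Reported titre for a dilution series
#'
#' Applies the 5-25% gate and averages the infectious titre over the
#' retained dilutions. When no dilution falls in the window the result is an
#' explicit no-valid-dilution outcome (`NA` with a reason), never 0.
#'
#' @inheritParams select_valid_dilutions
#' @return List: `tu_per_ml` (mean over valid dilutions, or `NA`),
#'   `n_valid`, `note`.
#' @export
titre_from_series <- function(series, lower = 5, upper = 25) {
  valid <- select_valid_dilutions(series, lower, upper)
  if (nrow(valid) == 0L) {
    return(list(tu_per_ml = NA_real_, n_valid = 0L,
                note = sprintf("no dilution in the %g-%g%% window",
                               lower, upper)))
  }
  list(tu_per_ml = mean(infectious_titre(valid)), n_valid = nrow(valid),
       note = "")
}

#' Vector DNA copies delivered per cell from qPCR
#'
#' Cell number is inferred from a reference gene assayed in the same
#' material (RNase P by default, 2 copies per diploid genome):
#' `cells = reference_copies / reference_copies_per_cell`, and
#' `copies/cell = target_copies / cells`.
#'
#' @param target_copies Vector copies in the reaction (standard curve).
#' @param reference_copies Reference-gene copies in the reaction; must be
#'   > 0.
#' @param reference_copies_per_cell Reference copies per cell; default 2
#'   (diploid host).
#' @return Copies per cell.
#' @export
copies_per_cell <- function(target_copies, reference_copies,
                            reference_copies_per_cell = 2L) {
  if (reference_copies_per_cell < 1) {
    stop("reference_copies_per_cell must be >= 1", call. = FALSE)
  }
  if (any(reference_copies <= 0)) {
    stop("reference_copies must be > 0", call. = FALSE)
  }
  target_copies / (reference_copies / reference_copies_per_cell)
}

#' Genome-containing particle titre
#'
#' Converts a vector-genome copy concentration (RT-qPCR) into genome
#' particles per mL. Lentiviral particles package two genome copies, so the
#' default divisor is 2; the conversion a given titration kit applies is not
#' always disclosed, so the divisor is explicit and reported with results.
#'
#' @param genome_copies_per_ml Vector genome copies per mL.
#' @param genomes_per_particle Genome copies per particle; default 2.
#' @return GP/mL.
#' @export
genome_particle_titre <- function(genome_copies_per_ml,
                                  genomes_per_particle = 2L) {
  if (genomes_per_particle <= 0) {
    stop("genomes_per_particle must be > 0", call. = FALSE)
  }
  genome_copies_per_ml / genomes_per_particle
}

#' A set of co-transfected constructs with their ratio
#'
#' @param id Construct names (e.g. transfer vector, GagPol, Rev, VSVg).
#' @param length_bp Construct lengths in bp, > 0.
#' @param ratio Positive ratio values, interpreted per `ratio_kind`.
#' @param ratio_kind `"mass"` or `"molar"` — molar ratios express relative
#'   copy number (mass scaled by inverse length), mass ratios relative mass.
#' @param total_mass_conc Total DNA concentration of the mix in ug/mL.
#' @return A `construct_set` data.frame with attributes `ratio_kind` and
#'   `total_mass_conc`.
#' @export
construct_set <- function(id, length_bp, ratio,
                          ratio_kind = c("mass", "molar"),
                          total_mass_conc = 1) {
  ratio_kind <- match.arg(ratio_kind)
  if (any(length_bp <= 0)) stop("construct lengths must be > 0", call. = FALSE)
  if (any(ratio <= 0)) stop("ratio values must be > 0", call. = FALSE)
  if (total_mass_conc <= 0) stop("total_mass_conc must be > 0", call. = FALSE)
  cs <- data.frame(id = as.character(id), length_bp = as.numeric(length_bp),
                   ratio = as.numeric(ratio), stringsAsFactors = FALSE)
  attr(cs, "ratio_kind") <- ratio_kind
  attr(cs, "total_mass_conc") <- total_mass_conc
  class(cs) <- c("construct_set", "data.frame")
  cs
}

#' Convert a construct ratio between mass and molar
#'
#' Molar values are proportional to mass over length (copy number); mass
#' values to molar times length. The converted ratio is rescaled so its
#' smallest element is 1 (the conventional `0.5:3:3:1`-style notation, up to
#' that global rescale). Per-construct mass concentrations are always
#' computed from the mass-ratio view so they sum to the configured total.
#'
#' @param set A [construct_set()].
#' @param to Target kind, `"mass"` or `"molar"`.
#' @return A `construct_set` of kind `to`, with an added `mass_conc` column
#'   (ug/mL) summing to `total_mass_conc`.
#' @export
convert_ratio <- function(set, to = c("mass", "molar")) {
  to <- match.arg(to)
  from <- attr(set, "ratio_kind")
  mass_ratio <- if (from == "mass") set$ratio else set$ratio * set$length_bp
  new_ratio <- switch(to,
    mass = mass_ratio,
    molar = mass_ratio / set$length_bp
  )
  out <- construct_set(
    set$id, set$length_bp, new_ratio / min(new_ratio),
    ratio_kind = to, total_mass_conc = attr(set, "total_mass_conc")
  )
  out$mass_conc <- attr(set, "total_mass_conc") * mass_ratio / sum(mass_ratio)
  out
}
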